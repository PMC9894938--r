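flat_bins <- function(n = 200, coverage = 100, gc = NULL, chrom = "sim1") {
  starts <- seq(0, by = 10000, length.out = n)
  if (is.null(gc)) gc <- rep(0.5, n)
  coverage_bins(data.frame(chrom = chrom, start = starts,
                           end = starts + 10000, gc = gc,
                           coverage = coverage, stringsAsFactors = FALSE))
}

test_that("bin validation rejects malformed grids", {
  expect_error(coverage_bins(data.frame(chrom = 1, start = 0, end = 5000,
                                        gc = 0.5, coverage = 1)), "width")
  b <- flat_bins(5)
  b2 <- rbind(b, b[1, ])
  expect_error(coverage_bins(as.data.frame(b2)), "overlapping")
})

test_that("GC model is flat for unbiased coverage and tracks a known bias", {
  set.seed(1)
  gc <- runif(300, 0.3, 0.7)
  # no GC dependence
  b <- flat_bins(300, coverage = 100, gc = gc)
  m <- fit_gc_model(b)
  expect_true(all(abs(m(seq(0.35, 0.65, 0.05)) - 100) < 1e-6))
  # coverage = 100 * (1 + gc): recovered within 1% over the interior
  b2 <- flat_bins(300, coverage = 100 * (1 + gc), gc = gc)
  m2 <- fit_gc_model(b2)
  g <- seq(0.35, 0.65, by = 0.02)
  expect_true(all(abs(m2(g) / (100 * (1 + g)) - 1) < 0.01))
  # robustness: 5% of bins with 10x coverage barely move the curve
  cov3 <- 100 * (1 + gc)
  out <- sample(300, 15)
  cov3[out] <- cov3[out] * 10
  m3 <- fit_gc_model(flat_bins(300, coverage = cov3, gc = gc))
  expect_true(all(abs(m3(g) / m2(g) - 1) < 0.03))
  expect_warning(fit_gc_model(flat_bins(60, coverage = 50, gc = 0.5)),
                 "degenerate")
  expect_error(fit_gc_model(flat_bins(10)), "at least 50")
})

test_that("GC adjustment flattens a pure-GC trend and keeps the median", {
  set.seed(2)
  gc <- runif(300, 0.3, 0.7)
  cov <- 80 * (1 + gc)
  b <- flat_bins(300, coverage = cov, gc = gc)
  m <- fit_gc_model(b)
  adj <- adjust_coverage(b, m)
  expect_lt(stats::sd(adj) / mean(adj), 0.02)   # GC-only variation removed
  expect_equal(stats::median(adj), stats::median(cov), tolerance = 0.02)
  # flat model: adjusted = raw
  bf <- flat_bins(300, coverage = 100, gc = gc)
  expect_equal(adjust_coverage(bf, fit_gc_model(bf)), rep(100, 300),
               tolerance = 1e-9)
})

test_that("log2 ratios are centered and reference-mode aware", {
  tum <- rep(100, 100)
  lr <- compute_log2_ratios(tum, tum)
  expect_identical(lr$reference_mode, "matched_normal")
  expect_true(all(lr$log2_ratio == 0))
  # no normal: half the genome at 2x self-median gives two levels 1 apart
  tum2 <- c(rep(100, 60), rep(200, 40))
  lr2 <- compute_log2_ratios(tum2)
  expect_identical(lr2$reference_mode, "self_median")
  lev <- sort(unique(round(lr2$log2_ratio, 9)))
  expect_length(lev, 2)
  expect_equal(diff(lev), 1)
  expect_equal(stats::median(lr2$log2_ratio), 0)
  expect_error(compute_log2_ratios(tum, tum[1:10]), "grid")
})

test_that("segmentation finds a single step within 2 bins across seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    y <- c(rnorm(150, 0, 0.1), rnorm(150, 1, 0.1))
    b <- flat_bins(300)
    segs <- segment_track(b, y, n_perm = 300, seed = s)
    if (nrow(segs) == 2 && abs(segs$end[1] / 10000 - 150) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("segmentation handles constant tracks, focal events and NA bins", {
  b <- flat_bins(100)
  segs <- segment_track(b, rep(0.3, 100), n_perm = 100, seed = 1)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$mean_log2, 0.3)
  # focal event of min_bins width and amplitude 2 becomes its own segment
  set.seed(9)
  y <- rnorm(100, 0, 0.05)
  y[48:52] <- y[48:52] + 2
  segs2 <- segment_track(b, y, n_perm = 300, min_bins = 5, seed = 9)
  expect_identical(nrow(segs2), 3L)
  expect_gt(segs2$mean_log2[2], 1.5)
  # masked bins excluded, not imputed
  y3 <- rep(0.2, 100); y3[10:20] <- NA
  segs3 <- segment_track(b, y3, n_perm = 100, seed = 2)
  expect_identical(sum(segs3$n_bins), 89L)
  # conservation: weighted mean of segment means equals the track mean
  w <- segs2$n_bins
  expect_equal(sum(segs2$mean_log2 * w) / sum(w), mean(y), tolerance = 1e-9)
})

test_that("first change-points agree with brute-force arc enumeration", {
  # oracle: double loop over every arc (i, i+m], standardised mean
  # difference against the complement with the global sd
  brute_arc <- function(y, min_bins) {
    n <- length(y); s <- sd(y)
    best <- c(i = NA, m = NA); zbest <- -Inf
    for (m in min_bins:(n - min_bins)) for (i in 0:(n - m)) {
      inside <- mean(y[(i + 1):(i + m)])
      z <- abs(inside - mean(y)) * m / (s * sqrt(m * (1 - m / n)))
      if (z > zbest) { zbest <- z; best <- c(i = i, m = m) }
    }
    best
  }
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(16:30, 1)
    k_true <- sample(6:(n - 6), 1)
    y <- c(rnorm(k_true, 0, 0.15), rnorm(n - k_true, 1.5, 0.15))
    best <- brute_arc(y, 3)
    want <- sort(setdiff(unique(c(best["i"], best["i"] + best["m"])), c(0, n)))
    segs <- segment_track(flat_bins(n), y, n_perm = 200, min_bins = 3,
                          seed = rep)
    got <- segs$end / 10000
    expect_true(all(want %in% got))
  }
})

test_that("gene mapping averages overlapping segments on the chosen scale", {
  segs <- data.frame(chrom = "sim1", start = c(0, 100000),
                     end = c(100000, 200000), mean_log2 = c(0.5, 1.5),
                     n_bins = c(10L, 10L))
  exons <- data.frame(gene = c("inA", "spans", "off"),
                      chrom = c("sim1", "sim1", "sim9"),
                      start = c(10000, 90000, 0),
                      end = c(20000, 110000, 10000))
  cn <- gene_copy_number(segs, exons, scale = "log2")
  expect_equal(cn$cn[cn$gene == "inA"], 0.5)
  expect_equal(cn$cn[cn$gene == "spans"], 1.0)   # unweighted average
  expect_true(is.na(cn$cn[cn$gene == "off"]))
  cnr <- gene_copy_number(segs, exons)           # ratio scale
  expect_equal(cnr$cn[cnr$gene == "spans"], mean(2^c(0.5, 1.5)))
})

test_that("paired delta calls follow the thresholds and evaluability rule", {
  pt <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   cn = c(0.6, 1.5, 0.6, 1.0))
  ib <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   cn = c(1.5, 0.6, -0.4, 1.0))
  calls <- delta_cn_calls(pt, ib)
  get <- function(g) calls$call[calls$gene == g]
  expect_identical(get("g1"), "gain")            # delta +0.9
  expect_identical(get("g2"), "loss")            # delta -0.9
  expect_identical(get("g3"), "not_evaluable")   # ibtr below min CN
  expect_identical(get("g4"), "none")
  # antisymmetry of the delta
  rev <- delta_cn_calls(ib, pt)
  expect_equal(rev$delta, -calls$delta)
  # identical profiles: no gains or losses
  same <- delta_cn_calls(pt, pt)
  expect_identical(unname(count_cn_calls(same)[c("gain", "loss")]), c(0L, 0L))
})

test_that("an injected recurrence-only amplification is recovered end to end", {
  run_cn <- function(bins, seed) {
    lr <- compute_log2_ratios(adjust_coverage(bins, fit_gc_model(bins)))
    segment_track(bins, lr$log2_ratio, n_perm = 200, seed = seed)
  }
  ok <- 0
  for (s in 1:10) {
    cfg <- cohort_config(
      n_patients = 1, coverage_noise_sd = 0.1, seed = 100 + s,
      cn_events = list(list(chrom = "sim1", start = 5e6, end = 6e6,
                            log2 = 1, sample = "IBTR", patient = 1)))
    sim <- simulate_cohort(cfg)
    b <- sim$bundle
    cn_pt <- gene_copy_number(run_cn(b$bins$P01_PT, s), b$exons)
    cn_ib <- gene_copy_number(run_cn(b$bins$P01_IBTR, s), b$exons)
    calls <- delta_cn_calls(cn_pt, cn_ib)
    truth <- sim$truth$cn_events[[1]]$genes
    if (setequal(calls$gene[calls$call == "gain"], truth) &&
        sum(calls$call == "loss") == 0) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
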