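test_that("panel of normals keeps keys seen in at least two normals", {
  sets <- list(c("X", "Y"), c("X"), c("Z"))
  pon <- build_panel_of_normals(sets)
  expect_true("X" %in% pon)
  expect_false("Y" %in% pon)
  expect_false("Z" %in% pon)
  # set semantics: a key repeated within one sample counts once
  expect_identical(build_panel_of_normals(list(c("Z", "Z"), "W")), character(0))
  # a key in all 5 normals appears once
  expect_identical(build_panel_of_normals(rep(list("K"), 5)), "K")
  expect_identical(build_panel_of_normals(list(character(0), character(0))),
                   character(0))
  expect_error(build_panel_of_normals(list()), "at least one")
  # enumeration oracle: membership counted per-sample on random sets
  set.seed(42)
  keys <- paste0("k", 1:30)
  sets <- replicate(6, sample(keys, sample(5:15, 1)), simplify = FALSE)
  counts <- table(unlist(lapply(sets, unique)))
  expect_setequal(build_panel_of_normals(sets), names(counts)[counts >= 2])
})

test_that("population AF filter passes only 0-or-missing frequencies", {
  v <- make_variants(4,
    pop_af_gnomad = c(0, 0.0001, NA, NA),
    pop_af_swefreq = c(NA, 0, NA, 0.2))
  expect_identical(population_af_pass(v), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(population_af_pass(make_variants(1, pop_af_gnomad = -0.1)))
})

test_that("allelic depth and coverage filters respect their boundaries", {
  v <- make_variants(3, alt_support_tumor = c(2L, 1L, 10L),
                     depth_tumor = c(20L, 20L, 20L),
                     alt_support_normal = c(NA, NA, 2L),
                     depth_normal = c(NA, NA, 30L))
  expect_identical(allelic_depth_pass(v), c(TRUE, FALSE, FALSE))
  v2 <- make_variants(3, depth_tumor = c(10L, 9L, 30L),
                      alt_support_normal = c(NA, NA, 1L),
                      depth_normal = c(NA, NA, 8L))
  expect_identical(coverage_pass(v2), c(TRUE, FALSE, FALSE))
})

test_that("PoN filter keys on the full (chrom,pos,ref,alt) tuple", {
  v <- make_variants(1, chrom = "sim1", pos = 500L, ref = "C", alt = "T")
  expect_false(pon_pass(v, "sim1:500:C:T"))
  expect_true(pon_pass(v, "sim1:500:C:G"))  # other alt allele at same site
  expect_true(pon_pass(v, character(0)))
})

test_that("purity likelihood log2 ratio matches direct pmf computation", {
  # frozen examples, verified against the binomial pmf directly
  expect_equal(tpes_log2_ratio(5, 20, 0.25, 0.5),
               log2(2 * dbinom(5, 20, 0.25) / dbinom(5, 20, 0.5)))
  expect_equal(tpes_log2_ratio(5, 20, 0.25, 0.5), 4.7744, tolerance = 1e-4)
  expect_equal(tpes_log2_ratio(10, 20, 0.05, 0.5), -22.9593, tolerance = 1e-4)
  # purity 1 het model: identical distributions, the factor 2 survives
  for (sc in list(c(0, 7), c(3, 9), c(25, 25)))
    expect_equal(tpes_log2_ratio(sc[1], sc[2], 0.5, 0.5), 1)
  # oracle equivalence grid: all s <= c <= 25, purity 0.1..1.0
  for (t in seq(0.1, 1, by = 0.1)) {
    for (c in 1:25) {
      s <- 0:c
      got <- tpes_log2_ratio(s, c, 0.5 * t, 0.5)
      want <- log2(2 * dbinom(s, c, 0.5 * t) / dbinom(s, c, 0.5))
      fin <- is.finite(got) & is.finite(want)
      expect_equal(got[fin], want[fin], tolerance = 1e-9)
    }
  }
  # edge semantics
  expect_identical(tpes_log2_ratio(5, 10, 0, 0.5), -Inf)   # numerator 0
  expect_true(is.nan(tpes_log2_ratio(5, 10, 0.5, 0)))      # denominator 0
  expect_error(tpes_log2_ratio(11, 10, 0.2, 0.5), "exceed")
})

test_that("het log2 ratio is non-increasing in support when purity < 1", {
  set.seed(7)
  for (i in 1:20) {
    c <- sample(5:60, 1)
    t <- runif(1, 0.05, 0.95)
    r <- tpes_log2_ratio(0:c, c, 0.5 * t, 0.5)
    expect_true(all(diff(r[is.finite(r)]) <= 1e-12))
  }
})

test_that("purity filter keeps/drops per the disjunction with the hom guard", {
  v <- make_variants(2, alt_support_tumor = c(5L, 10L),
                     depth_tumor = c(20L, 20L))
  # no purity estimate: filter skipped
  expect_identical(tpes_pass(v, NA), c(TRUE, TRUE))
  # s=5,c=20,t=0.5: het log2 ~ 4.77 > -1, keep
  expect_true(tpes_pass(v, 0.5)[1])
  # s=10,c=20,t=0.1: het ~ -22.96; hom background P(10;20,1)=0 is
  # non-informative, so the variant is dropped
  expect_false(tpes_pass(v, 0.1)[2])
  # literal reading keeps it through the vacuous hom branch
  expect_true(tpes_pass(v, 0.1, literal_hom = TRUE)[2])
  # s=c: hom background defined (P=1), hom ratio decides;
  # s=c=4, t=0.9: hom log2 = 1 + 4*log2(0.9) ~ 0.39 > -1 keeps
  v2 <- make_variants(1, alt_support_tumor = 4L, depth_tumor = 4L)
  expect_true(tpes_pass(v2, 0.9))
  # deeper s=c at the same purity is background-favoured and dropped:
  # het 1 + 20*log2(0.9) ~ -2.04 and hom identical
  v3 <- make_variants(1, alt_support_tumor = 20L, depth_tumor = 20L)
  expect_false(tpes_pass(v3, 0.9))
})

test_that("cascade attributes removals to the first failing filter", {
  v <- make_variants(4,
    pop_af_gnomad = c(0.5, 0, 0, 0),        # 1 fails AF (and coverage)
    depth_tumor = c(5L, 8L, 20L, 20L),      # 2 fails coverage
    alt_support_tumor = c(2L, 2L, 5L, 5L),
    pos = c(100L, 200L, 300L, 400L))
  pon <- "sim1:300:C:T"                     # 3 fails PoN
  res <- apply_cascade(v, purity = 0.5, pon = pon)
  rm <- setNames(res$report$removed, res$report$filter)
  expect_identical(rm[["population_af"]], 1L)  # double failure counted once
  expect_identical(rm[["coverage"]], 1L)
  expect_identical(rm[["pon"]], 1L)
  expect_identical(nrow(res$kept), 1L)
  expect_identical(res$kept$pos, 400L)
  expect_identical(attr(res$report, "input") - sum(res$report$removed),
                   attr(res$report, "surviving"))
})

test_that("cascade keep-set equals the filter conjunction and is idempotent", {
  set.seed(11)
  n <- 60
  v <- variant_table(data.frame(
    chrom = "sim1", pos = seq_len(n),
    ref = "C", alt = "T",
    depth_tumor = sample(5:40, n, replace = TRUE),
    pop_af_gnomad = sample(c(0, NA, 0.01), n, replace = TRUE),
    stringsAsFactors = FALSE) |>
    transform(alt_support_tumor = pmin(sample(0:15, n, replace = TRUE),
                                       depth_tumor)))
  pon <- variant_keys(v)[sample(n, 10)]
  res <- apply_cascade(v, purity = 0.4, pon = pon)
  conj <- population_af_pass(v) & allelic_depth_pass(v) & coverage_pass(v) &
    pon_pass(v, pon) & tpes_pass(v, 0.4)
  expect_setequal(variant_keys(res$kept), variant_keys(v)[conj])
  again <- apply_cascade(res$kept, purity = 0.4, pon = pon)
  expect_identical(nrow(again$kept), nrow(res$kept))
  expect_true(all(again$report$removed == 0L))
  # empty input
  empty <- apply_cascade(v[0, ], purity = 0.4, pon = pon)
  expect_identical(nrow(empty$kept), 0L)
  expect_true(all(empty$report$removed == 0L))
})

test_that("impact/consequence filter includes moderate+high, drops UTR-like", {
  v <- make_variants(6,
    impact = c("MODERATE", "HIGH", "LOW", "HIGH", "MODERATE", "MODIFIER"),
    consequence = c("missense_variant", "synonymous_variant", "missense_variant",
                    "stop_gained", "3' UTR variant", "upstream_gene_variant"))
  expect_identical(consequence_pass(v),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(consequence_pass(make_variants(1, impact = "BOGUS")),
               "unknown impact")
})

test_that("paired SNV gain/loss is plain set algebra", {
  gl <- snv_gain_loss(c("a", "b"), c("b", "c", "d"))
  expect_setequal(gl$gains, c("c", "d"))
  expect_identical(gl$losses, "a")
  expect_identical(gl$shared, "b")
  same <- snv_gain_loss(c("a", "b"), c("a", "b"))
  expect_length(same$gains, 0)
  expect_length(same$losses, 0)
  disj <- snv_gain_loss(c("a"), c("b"))
  expect_identical(disj$gains, "b")
  expect_identical(disj$losses, "a")
  # |gains| + |shared| = |ibtr|
  expect_identical(length(gl$gains) + length(gl$shared), 3L)
})

test_that("variant TSV round-trips and VCF import maps AD/DP and INFO keys", {
  v <- make_variants(3, pop_af_gnomad = c(0, NA, 0.1), gene = "TP53",
                     impact = "MODERATE", consequence = "missense_variant")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(v, path)
  back <- read_variants_tsv(path)
  expect_equal(back$pos, v$pos)
  expect_equal(back$pop_af_gnomad, v$pop_af_gnomad)
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"gnomAD AF\">",
    "##INFO=<ID=SWEFREQ_AF,Number=1,Type=Float,Description=\"SweFreq AF\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"impact\">",
    "##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description=\"csq\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"allele depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUM",
    paste0("sim1\t1234\t.\tC\tT\t.\tPASS\t",
           "GNOMAD_AF=0;GENE=TP53;IMPACT=MODERATE;CONSEQUENCE=missense_variant",
           "\tAD:DP\t15,6:21")), vcf)
  vv <- read_variants_vcf(vcf)
  expect_identical(vv$pos, 1234L)
  expect_identical(vv$alt_support_tumor, 6L)
  expect_identical(vv$depth_tumor, 21L)
  expect_equal(vv$pop_af_gnomad, 0)
  expect_identical(vv$gene, "TP53")
})
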