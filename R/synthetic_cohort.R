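# Synthetic genome: a few short chromosomes at desk scale. Coordinates are
# deliberately not GRCh38-like.
.synthetic_genome <- c(sim1 = 20e6, sim2 = 10e6)

.default_gc_curve <- function(g) exp(-8 * (g - 0.5)^2)

# decode "A[C>T]G" into its parts
.decode_context <- function(label) {
  ref <- substr(label, 3, 3); alt <- substr(label, 5, 5)
  f5 <- substr(label, 1, 1); f3 <- substr(label, 7, 7)
  data.frame(ref = ref, alt = alt, context5 = f5, context3 = f3,
             stringsAsFactors = FALSE)
}

.check_simplex <- function(x, what) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9)
    stop(what, " must be a nonnegative vector summing to 1")
}

#' Configuration for the synthetic paired cohort
#'
#' Defaults emulate the statistical structure of a paired primary /
#' in-breast recurrence breast-cancer cohort: 27 patients, whole-genome
#' depth around 45x, a clonal trunk of shared variants with private
#' variants accruing preferentially in the recurrence, purity varying
#' across specimens, germline-polymorphism contaminants, recurrent
#' sequencing artifacts shared across normals, and a tunable expression
#' drift between pair members.
#'
#' @param n_patients number of PT-IBTR pairs.
#' @param purity_range interval in (0,1] from which per-sample tumor
#'   purities are drawn.
#' @param depth_mean mean sequencing depth (reads) at variant positions
#'   and per 10-kb coverage bin.
#' @param n_shared_variants,n_private_pt,n_private_ibtr somatic variant
#'   counts per patient: clonal trunk shared by both members, and variants
#'   private to each member.
#' @param signature_mix_pt,signature_mix_ibtr simplex vectors over the K
#'   signatures of the supplied signature matrix; NULL for the built-in
#'   defaults (trunk/PT mixture shifted toward a second process in the
#'   recurrence).
#' @param cn_events list of copy-number events, each
#'   \code{list(chrom, start, end, log2 = shift, sample = "PT"|"IBTR"|"both",
#'   patient = index or NULL for all)}.
#' @param drift_sigma nonnegative standard deviation of the per-feature
#'   expression perturbation separating IBTR from PT columns; scalar or
#'   one value per patient.
#' @param germline_af_fraction fraction (of the somatic variant count) of
#'   injected population-polymorphic germline contaminants.
#' @param pon_artifact_fraction fraction of injected recurrent artifacts
#'   that also occur in at least two simulated normals.
#' @param n_normals simulated normal samples used to build the panel of
#'   normals.
#' @param n_rna,n_protein feature counts of the expression and protein
#'   matrices.
#' @param coverage_noise_sd coverage noise standard deviation as a
#'   fraction of the expected bin coverage.
#' @param seed integer RNG seed.
#' @return validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 27,
                          purity_range = c(0.3, 0.9),
                          depth_mean = 45,
                          n_shared_variants = 100,
                          n_private_pt = 30,
                          n_private_ibtr = 60,
                          signature_mix_pt = NULL,
                          signature_mix_ibtr = NULL,
                          cn_events = list(),
                          drift_sigma = 0.5,
                          germline_af_fraction = 0.1,
                          pon_artifact_fraction = 0.05,
                          n_normals = 5,
                          n_rna = 500,
                          n_protein = 300,
                          coverage_noise_sd = 0.05,
                          seed = 1) {
  if (n_patients < 1) stop("empty cohort")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (any(purity_range <= 0) || any(purity_range > 1) ||
      purity_range[1] > purity_range[2])
    stop("purity_range must be an interval in (0,1]")
  if (any(c(n_shared_variants, n_private_pt, n_private_ibtr) < 0))
    stop("variant counts must be nonnegative")
  if (any(drift_sigma < 0)) stop("drift_sigma must be nonnegative")
  if (!(length(drift_sigma) %in% c(1, n_patients)))
    stop("drift_sigma must be scalar or one value per patient")
  frac_ok <- function(x) x >= 0 && x <= 1
  if (!frac_ok(germline_af_fraction) || !frac_ok(pon_artifact_fraction))
    stop("fractions must lie in [0,1]")
  if (!is.null(signature_mix_pt)) .check_simplex(signature_mix_pt, "signature_mix_pt")
  if (!is.null(signature_mix_ibtr)) .check_simplex(signature_mix_ibtr, "signature_mix_ibtr")
  structure(list(
    n_patients = n_patients, purity_range = purity_range,
    depth_mean = depth_mean, n_shared_variants = n_shared_variants,
    n_private_pt = n_private_pt, n_private_ibtr = n_private_ibtr,
    signature_mix_pt = signature_mix_pt,
    signature_mix_ibtr = signature_mix_ibtr,
    cn_events = cn_events, drift_sigma = drift_sigma,
    germline_af_fraction = germline_af_fraction,
    pon_artifact_fraction = pon_artifact_fraction,
    n_normals = n_normals, n_rna = n_rna, n_protein = n_protein,
    coverage_noise_sd = coverage_noise_sd, seed = seed),
    class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' The YAML keys mirror the arguments of \code{\link{cohort_config}}; an
#' example schema ships in \code{inst/extdata/cohort_config_example.yaml}.
#'
#' @param path YAML path.
#' @return \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_cohort_config requires the yaml package")
  args <- yaml::yaml.load_file(path)
  for (f in c("purity_range", "signature_mix_pt", "signature_mix_ibtr",
              "drift_sigma"))
    if (!is.null(args[[f]])) args[[f]] <- as.numeric(unlist(args[[f]]))
  do.call(cohort_config, args)
}

#' A small synthetic signature matrix
#'
#' K well-separated 96-context profiles for testing and simulation: each
#' signature concentrates most of its mass on a distinct block of
#' contexts. Columns sum to 1. This is a synthetic stand-in for a
#' reference signature catalogue, not a reconstruction of one.
#'
#' @param k number of signatures (2-8).
#' @return \code{signature_matrix} with columns SigA, SigB, ...
#' @export
synthetic_signature_matrix <- function(k = 3) {
  stopifnot(k >= 2, k <= 8)
  labs <- context_labels()
  m <- matrix(0.1 / 96, nrow = 96, ncol = k,
              dimnames = list(labs, paste0("Sig", LETTERS[seq_len(k)])))
  block <- split(seq_len(96), cut(seq_len(96), k, labels = FALSE))
  for (j in seq_len(k)) {
    w <- seq_along(block[[j]])
    m[block[[j]], j] <- m[block[[j]], j] + 0.9 * w / sum(w)
  }
  signature_matrix(sweep(m, 2, colSums(m), "/"))
}

#' Simulate per-sample coverage bins
#'
#' Tiles each chromosome of the synthetic genome in fixed-width bins and
#' draws a coverage per bin with expectation
#' \code{depth_mean * gc_bias_curve(gc) * 2^(true log2 CN)} and Gaussian
#' noise of standard deviation \code{noise_sd} times the expectation.
#'
#' @param cn_profile data.frame (chrom, start, end, log2) of copy-number
#'   shifts; regions not covered have log2 = 0. Overlapping entries are an
#'   error. NULL for a flat profile.
#' @param gc_bias_curve function gc -> positive multiplier; NULL for the
#'   built-in unimodal curve.
#' @param depth_mean expected coverage at neutral copy number and curve
#'   value 1.
#' @param seed RNG seed.
#' @param genome named vector of chromosome lengths.
#' @param bin_width bin width, default 10000.
#' @param noise_sd fractional noise standard deviation (0 = deterministic).
#' @param gc optional per-bin GC vector (recycled grid across samples);
#'   drawn uniform in [0.3, 0.7] when NULL.
#' @return \code{coverage_bins} data.frame.
#' @export
simulate_coverage_bins <- function(cn_profile = NULL, gc_bias_curve = NULL,
                                   depth_mean = 45, seed = 1,
                                   genome = .synthetic_genome,
                                   bin_width = 10000, noise_sd = 0.05,
                                   gc = NULL) {
  set.seed(seed)
  if (is.null(gc_bias_curve)) gc_bias_curve <- .default_gc_curve
  grid <- do.call(rbind, lapply(names(genome), function(chr) {
    starts <- seq(0, genome[[chr]] - bin_width, by = bin_width)
    data.frame(chrom = chr, start = starts, end = starts + bin_width,
               stringsAsFactors = FALSE)
  }))
  if (is.null(gc)) gc <- stats::runif(nrow(grid), 0.3, 0.7)
  log2cn <- numeric(nrow(grid))
  if (!is.null(cn_profile) && nrow(cn_profile)) {
    for (i in seq_len(nrow(cn_profile))) {
      hit <- grid$chrom == cn_profile$chrom[i] &
        grid$start >= cn_profile$start[i] & grid$end <= cn_profile$end[i]
      if (any(log2cn[hit] != 0)) stop("overlapping copy-number events")
      log2cn[hit] <- cn_profile$log2[i]
    }
  }
  expected <- depth_mean * gc_bias_curve(gc) * 2^log2cn
  coverage <- expected +
    if (noise_sd > 0) stats::rnorm(length(expected), 0, noise_sd * expected)
    else 0
  coverage <- pmax(coverage, 0)
  coverage_bins(data.frame(grid, gc = gc, coverage = coverage,
                           stringsAsFactors = FALSE), bin_width = bin_width)
}

# synthetic gene model: one gene per 100 kb, single central 20-kb exon
.synthetic_exons <- function(genome = .synthetic_genome) {
  do.call(rbind, lapply(names(genome), function(chr) {
    starts <- seq(0, genome[[chr]] - 1e5, by = 1e5)
    data.frame(gene = sprintf("%s_g%04d", chr, seq_along(starts)),
               chrom = chr, start = starts + 4e4, end = starts + 6e4,
               stringsAsFactors = FALSE)
  }))
}

# draw one sample's variant rows at given keys/contexts with binomial support
.draw_support <- function(n, depth_mean, p) {
  depth <- pmax(stats::rpois(n, depth_mean), 1L)
  alt <- stats::rbinom(n, depth, p)
  list(depth = depth, alt = alt)
}

#' Simulate a paired PT-IBTR cohort with known ground truth
#'
#' Generates, per patient, a clonal trunk of shared somatic variants
#' (present in both pair members with support Binomial(depth, purity/2)),
#' private variants in exactly one member, germline contaminants carrying
#' a nonzero population allele frequency, and recurrent artifacts that
#' also occur in at least two simulated normals; trinucleotide contexts
#' are drawn from each sample's signature mixture applied to \code{sigs}.
#' Also emits per-sample GC-biased coverage bins with the configured
#' copy-number events, paired expression and protein matrices whose
#' within-pair divergence is controlled by \code{drift_sigma}, a clinical
#' table, and a gene-exon model.
#'
#' Draws are threaded through per-patient sub-streams derived from the
#' seed by fixed offsets, so enlarging the cohort does not perturb
#' earlier patients. Identical config (and signature matrix) always
#' yields an identical bundle.
#'
#' @param config \code{\link{cohort_config}}.
#' @param sigs \code{signature_matrix}; default
#'   \code{synthetic_signature_matrix(3)}.
#' @return list with \code{bundle} (variants: named list of
#'   \code{variant_table}; purity, pairs, clinical data.frames; bins:
#'   named list of \code{coverage_bins}; expression, protein matrices;
#'   exons; normals: list of key sets; pon) and \code{truth} (true
#'   signature mixtures, shared/private/germline/artifact keys per
#'   patient, cn event gene lists, drift order).
#' @export
simulate_cohort <- function(config, sigs = synthetic_signature_matrix(3)) {
  stopifnot(inherits(config, "cohort_config"))
  K <- ncol(sigs)
  mix_pt <- config$signature_mix_pt
  mix_ib <- config$signature_mix_ibtr
  if (is.null(mix_pt)) mix_pt <- c(0.7, 0.3, numeric(K - 2))
  if (is.null(mix_ib)) mix_ib <- c(0.4, 0.6, numeric(K - 2))
  if (length(mix_pt) != K || length(mix_ib) != K)
    stop("signature mixtures must have one entry per signature column")
  .check_simplex(mix_pt, "signature_mix_pt")
  .check_simplex(mix_ib, "signature_mix_ibtr")
  labs <- context_labels()
  p_ctx_pt <- as.numeric(unclass(sigs) %*% mix_pt)
  p_ctx_ib <- as.numeric(unclass(sigs) %*% mix_ib)
  genome <- .synthetic_genome
  chr_prob <- genome / sum(genome)
  sigma <- rep(config$drift_sigma, length.out = config$n_patients)

  draw_positions <- function(n) {
    chrom <- sample(names(genome), n, replace = TRUE, prob = chr_prob)
    pos <- floor(stats::runif(n) * genome[chrom]) + 1
    list(chrom = chrom, pos = as.integer(pos))
  }
  exons <- .synthetic_exons(genome)
  gene_at <- function(chrom, pos) {
    sprintf("%s_g%04d", chrom, pmin(floor((pos - 1) / 1e5) + 1,
                                    floor(genome[chrom] / 1e5)))
  }

  # cohort-level stream: artifacts, normals, bin GC grid, clinical
  set.seed(config$seed)
  n_som <- config$n_shared_variants + config$n_private_pt +
    config$n_private_ibtr
  n_art <- round(config$pon_artifact_fraction * max(n_som, 1))
  art_pos <- draw_positions(n_art)
  art_ctx <- if (n_art) sample(labs, n_art, replace = TRUE, prob = p_ctx_pt) else character(0)
  art_dec <- if (n_art) .decode_context(art_ctx) else NULL
  art_keys <- if (n_art) paste(art_pos$chrom, art_pos$pos, art_dec$ref,
                               art_dec$alt, sep = ":") else character(0)
  # each artifact is observed in >=2 of the simulated normals
  normals <- replicate(config$n_normals, character(0), simplify = FALSE)
  if (n_art) for (i in seq_len(n_art)) {
    in_n <- sample(config$n_normals, sample(2:config$n_normals, 1))
    for (j in in_n) normals[[j]] <- c(normals[[j]], art_keys[i])
  }
  # plus singleton noise keys never promoted to the panel
  for (j in seq_along(normals)) {
    np <- draw_positions(3)
    nd <- .decode_context(sample(labs, 3, replace = TRUE))
    normals[[j]] <- c(normals[[j]],
                      paste(np$chrom, np$pos, nd$ref, nd$alt, sep = ":"))
  }
  gc_grid <- stats::runif(sum(floor(genome / 1e4)), 0.3, 0.7)

  clinical <- NULL
  samples <- character(0)
  purity_tab <- NULL
  variants <- list()
  bins <- list()
  expr_cols <- list(); prot_cols <- list()
  truth_shared <- list(); truth_priv_pt <- list(); truth_priv_ib <- list()
  truth_germ <- list()
  base_rna <- NULL; base_prot <- NULL

  make_rows <- function(chrom, pos, dec, depth, alt, pop_af, gene, impact,
                        consequence) {
    data.frame(chrom = chrom, pos = pos, ref = dec$ref, alt = dec$alt,
               alt_support_tumor = alt, depth_tumor = depth,
               alt_support_normal = NA, depth_normal = NA,
               pop_af_gnomad = pop_af, pop_af_swefreq = 0,
               context5 = dec$context5, context3 = dec$context3,
               gene = gene, impact = impact, consequence = consequence,
               stringsAsFactors = FALSE)
  }
  draw_annot <- function(n) {
    impact <- sample(c("MODERATE", "HIGH", "LOW", "MODIFIER"), n,
                     replace = TRUE, prob = c(0.45, 0.15, 0.2, 0.2))
    consequence <- c(MODERATE = "missense_variant", HIGH = "stop_gained",
                     LOW = "synonymous_variant",
                     MODIFIER = "upstream_gene_variant")[impact]
    list(impact = impact, consequence = unname(consequence))
  }

  for (i in seq_len(config$n_patients)) {
    set.seed(config$seed + 7919L * i)  # fixed per-patient offset
    pid <- sprintf("P%02d", i)
    sid_pt <- paste0(pid, "_PT"); sid_ib <- paste0(pid, "_IBTR")
    pur_pt <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    pur_ib <- stats::runif(1, config$purity_range[1], config$purity_range[2])

    n_sh <- config$n_shared_variants
    n_pp <- config$n_private_pt
    n_pi <- config$n_private_ibtr
    n_ge <- round(config$germline_af_fraction * max(n_sh + n_pp + n_pi, 1))
    n_all <- n_sh + n_pp + n_pi + n_ge
    loc <- draw_positions(n_all)
    grp <- rep(c("shared", "priv_pt", "priv_ib", "germ"),
               c(n_sh, n_pp, n_pi, n_ge))
    ctx <- character(n_all)
    ctx[grp %in% c("shared", "priv_pt")] <-
      sample(labs, sum(grp %in% c("shared", "priv_pt")), replace = TRUE,
             prob = p_ctx_pt)
    ctx[grp == "priv_ib"] <- sample(labs, n_pi, replace = TRUE, prob = p_ctx_ib)
    if (n_ge) ctx[grp == "germ"] <- sample(labs, n_ge, replace = TRUE)
    dec <- .decode_context(ctx)
    keys <- paste(loc$chrom, loc$pos, dec$ref, dec$alt, sep = ":")
    ann <- draw_annot(n_all)
    gene <- gene_at(loc$chrom, loc$pos)
    pop_af <- ifelse(grp == "germ", stats::runif(n_all, 0.01, 0.5), 0)

    build_sample <- function(member, purity) {
      take <- grp %in% c("shared", "germ") |
        (grp == "priv_pt" & member == "PT") |
        (grp == "priv_ib" & member == "IBTR")
      n_t <- sum(take)
      p_vaf <- ifelse(grp[take] == "germ", 0.5, purity / 2)
      sup <- .draw_support(n_t, config$depth_mean, p_vaf)
      rows <- make_rows(loc$chrom[take], loc$pos[take],
                        dec[take, , drop = FALSE], sup$depth, sup$alt,
                        pop_af[take], gene[take], ann$impact[take],
                        ann$consequence[take])
      if (n_art) {
        asup <- .draw_support(n_art, config$depth_mean, 0.15)
        rows <- rbind(rows, make_rows(
          art_pos$chrom, art_pos$pos, art_dec, asup$depth,
          pmin(pmax(asup$alt, 2L), asup$depth), rep(0, n_art),
          gene_at(art_pos$chrom, art_pos$pos),
          rep("MODERATE", n_art), rep("missense_variant", n_art)))
      }
      variant_table(rows)
    }
    variants[[sid_pt]] <- build_sample("PT", pur_pt)
    variants[[sid_ib]] <- build_sample("IBTR", pur_ib)
    truth_shared[[pid]] <- keys[grp == "shared"]
    truth_priv_pt[[pid]] <- keys[grp == "priv_pt"]
    truth_priv_ib[[pid]] <- keys[grp == "priv_ib"]
    truth_germ[[pid]] <- keys[grp == "germ"]

    # coverage bins: cohort-wide GC grid, patient-specific events
    ev_for <- function(member) {
      ev <- Filter(function(e)
        (is.null(e$patient) || e$patient == i) &&
          (e$sample == "both" || e$sample == member), config$cn_events)
      if (!length(ev)) return(NULL)
      do.call(rbind, lapply(ev, function(e)
        data.frame(chrom = e$chrom, start = e$start, end = e$end,
                   log2 = e$log2, stringsAsFactors = FALSE)))
    }
    bins[[sid_pt]] <- simulate_coverage_bins(
      ev_for("PT"), NULL, config$depth_mean,
      seed = config$seed + 7919L * i + 1L, genome = genome,
      noise_sd = config$coverage_noise_sd, gc = gc_grid)
    bins[[sid_ib]] <- simulate_coverage_bins(
      ev_for("IBTR"), NULL, config$depth_mean,
      seed = config$seed + 7919L * i + 2L, genome = genome,
      noise_sd = config$coverage_noise_sd, gc = gc_grid)

    # expression / protein drift: IBTR = PT + N(0, sigma) per feature
    set.seed(config$seed + 7919L * i + 3L)
    rna_pt <- stats::rnorm(config$n_rna, mean = 8, sd = 2)
    rna_ib <- rna_pt + if (sigma[i] > 0)
      stats::rnorm(config$n_rna, 0, sigma[i]) else 0
    prot_pt <- stats::rnorm(config$n_protein, mean = 20, sd = 3)
    prot_ib <- prot_pt + if (sigma[i] > 0)
      stats::rnorm(config$n_protein, 0, sigma[i]) else 0
    expr_cols[[sid_pt]] <- rna_pt; expr_cols[[sid_ib]] <- rna_ib
    prot_cols[[sid_pt]] <- prot_pt; prot_cols[[sid_ib]] <- prot_ib

    purity_tab <- rbind(purity_tab, data.frame(
      sample_id = c(sid_pt, sid_ib), purity = c(pur_pt, pur_ib),
      stringsAsFactors = FALSE))
    samples <- c(samples, sid_pt, sid_ib)

    # clinical: patient-level categories with occasional PT/IBTR switches
    set.seed(config$seed + 7919L * i + 4L)
    cat2 <- function(p) sample(c("positive", "negative"), 1,
                               prob = c(p, 1 - p))
    er <- cat2(0.65); pgr <- cat2(0.5)
    ki <- sample(c("low", "high"), 1, prob = c(0.4, 0.6))
    her <- sample(c("normal", "amplified"), 1, prob = c(0.8, 0.2))
    grd <- sample(c("low", "intermediate", "high"), 1,
                  prob = c(0.05, 0.55, 0.4))
    age <- sample(c(">55", "<=55"), 1)
    flip <- function(x, lv) if (stats::runif(1) < 0.1)
      sample(setdiff(lv, x), 1) else x
    clinical <- rbind(clinical, data.frame(
      patient_id = pid, role = c("PT", "IBTR"),
      ER = c(er, flip(er, c("positive", "negative"))),
      PgR = c(pgr, flip(pgr, c("positive", "negative"))),
      Ki67 = c(ki, flip(ki, c("low", "high"))),
      ERBB2 = c(her, flip(her, c("normal", "amplified"))),
      grade = c(grd, flip(grd, c("low", "intermediate", "high"))),
      age_group = age,
      ibtrfs_time = round(stats::rexp(1, 1 / 36), 1),
      event = stats::runif(1) < 0.6,
      stringsAsFactors = FALSE))
  }

  pairs <- data.frame(patient = sprintf("P%02d", seq_len(config$n_patients)),
                      pt = paste0(sprintf("P%02d", seq_len(config$n_patients)), "_PT"),
                      ibtr = paste0(sprintf("P%02d", seq_len(config$n_patients)), "_IBTR"),
                      stringsAsFactors = FALSE)
  expression <- do.call(cbind, expr_cols)
  rownames(expression) <- sprintf("rna_%04d", seq_len(config$n_rna))
  protein <- do.call(cbind, prot_cols)
  rownames(protein) <- sprintf("prot_%04d", seq_len(config$n_protein))

  # truth: genes affected by each configured CN event
  ev_truth <- lapply(config$cn_events, function(e) {
    hit <- exons$chrom == e$chrom & exons$start < e$end & exons$end > e$start
    list(chrom = e$chrom, start = e$start, end = e$end, log2 = e$log2,
         sample = e$sample, patient = e$patient, genes = exons$gene[hit])
  })

  sig_truth <- rbind(
    matrix(rep(mix_pt, config$n_patients), ncol = K, byrow = TRUE,
           dimnames = list(pairs$pt, colnames(sigs))),
    matrix(rep(mix_ib, config$n_patients), ncol = K, byrow = TRUE,
           dimnames = list(pairs$ibtr, colnames(sigs))))
  # the trunk is drawn from the PT mixture, so the recurrence sample's
  # realised context distribution is the shared/private-weighted blend
  n_sh <- config$n_shared_variants; n_pi <- config$n_private_ibtr
  mix_ib_eff <- if (n_sh + n_pi > 0)
    (n_sh * mix_pt + n_pi * mix_ib) / (n_sh + n_pi) else mix_ib
  sig_truth_eff <- rbind(
    matrix(rep(mix_pt, config$n_patients), ncol = K, byrow = TRUE,
           dimnames = list(pairs$pt, colnames(sigs))),
    matrix(rep(mix_ib_eff, config$n_patients), ncol = K, byrow = TRUE,
           dimnames = list(pairs$ibtr, colnames(sigs))))

  list(bundle = list(variants = variants, purity = purity_tab,
                     pairs = pairs, clinical = clinical, bins = bins,
                     expression = expression, protein = protein,
                     exons = exons, normals = normals,
                     pon = build_panel_of_normals(normals)),
       truth = list(signature_mixtures = sig_truth,
                    signature_mixtures_effective = sig_truth_eff,
                    shared = truth_shared, private_pt = truth_priv_pt,
                    private_ibtr = truth_priv_ib, germline = truth_germ,
                    artifacts = art_keys, cn_events = ev_truth,
                    drift_sigma = stats::setNames(sigma, pairs$patient),
                    drift_order = pairs$patient[order(sigma)]))
}

#' Write a simulated cohort bundle to disk
#'
#' Emits the same plain-text formats the pipeline reads: one variant TSV
#' per sample, a purity TSV, per-sample bins TSV, expression and protein
#' matrices as TSV with feature rows, the pair map and clinical table as
#' CSV, and the exon model as TSV.
#'
#' @param bundle the \code{bundle} element of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(bundle$variants))
    write_variants_tsv(bundle$variants[[s]],
                       file.path(dir, paste0(s, ".variants.tsv")))
  for (s in names(bundle$bins))
    utils::write.table(bundle$bins[[s]],
                       file.path(dir, paste0(s, ".bins.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$purity, file.path(dir, "purity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wm <- function(m, f) utils::write.table(
    data.frame(feature = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm(bundle$expression, "expression.tsv")
  wm(bundle$protein, "protein.tsv")
  utils::write.csv(bundle$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.table(bundle$exons, file.path(dir, "exons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
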