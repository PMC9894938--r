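#' Construct a table of somatic variant records
#'
#' Validates and normalises a per-sample somatic SNV table. Columns beyond
#' the required set are preserved. Missing optional columns are added as NA.
#'
#' @param df data.frame with at least \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{alt_support_tumor}, \code{depth_tumor}.
#'   Optional: \code{alt_support_normal}, \code{depth_normal},
#'   \code{pop_af_gnomad}, \code{pop_af_swefreq}, \code{context5},
#'   \code{context3}, \code{gene}, \code{impact}, \code{consequence}.
#' @return data.frame of class \code{variant_table}.
#' @export
variant_table <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "alt_support_tumor", "depth_tumor")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  opt <- c("alt_support_normal", "depth_normal", "pop_af_gnomad",
           "pop_af_swefreq", "context5", "context3", "gene", "impact",
           "consequence")
  for (col in setdiff(opt, names(df))) df[[col]] <- rep(NA, nrow(df))
  bases <- c("A", "C", "G", "T")
  if (nrow(df)) {
    if (!all(df$ref %in% bases) || !all(df$alt %in% bases))
      stop("ref/alt must be single bases in {A,C,G,T}")
    if (any(df$ref == df$alt)) stop("ref must differ from alt")
    if (any(df$alt_support_tumor < 0 | df$alt_support_tumor > df$depth_tumor))
      stop("require 0 <= alt_support_tumor <= depth_tumor")
    has_n <- !is.na(df$alt_support_normal) & !is.na(df$depth_normal)
    if (any(has_n & (df$alt_support_normal < 0 |
                     df$alt_support_normal > df$depth_normal)))
      stop("require 0 <= alt_support_normal <= depth_normal")
    af <- c(df$pop_af_gnomad, df$pop_af_swefreq)
    if (any(!is.na(af) & (af < 0 | af > 1)))
      stop("population allele frequencies must lie in [0,1]")
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Variant identity keys
#'
#' The identity of a variant is the tuple (chrom, pos, ref, alt) throughout
#' the pipeline (panel of normals, gain/loss comparison). Multi-allelic
#' records must be decomposed upstream.
#'
#' @param v variant table or data.frame with chrom/pos/ref/alt columns.
#' @return character vector of keys.
#' @export
variant_keys <- function(v) {
  if (!nrow(v)) return(character(0))
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Build a panel of normals (PoN)
#'
#' A blacklist of variant keys observed in at least two distinct normal
#' samples, used to remove recurrent artifacts and residual germline calls.
#'
#' @param normal_variant_sets list of character vectors of variant keys,
#'   one per normal sample.
#' @return character vector of unique blacklisted keys.
#' @export
build_panel_of_normals <- function(normal_variant_sets) {
  if (!is.list(normal_variant_sets) || length(normal_variant_sets) == 0)
    stop("need at least one normal sample variant set")
  per_sample <- lapply(normal_variant_sets, unique)
  tab <- table(unlist(per_sample, use.names = FALSE))
  as.character(sort(names(tab)[tab >= 2]))
}

#' Population allele-frequency filter
#'
#' A variant passes iff its gnomAD and SweFreq population frequencies are
#' each missing or exactly 0 (never observed in those population datasets).
#'
#' @param v variant table.
#' @return logical vector, one per record.
#' @export
population_af_pass <- function(v) {
  if (!nrow(v)) return(logical(0))
  g <- v$pop_af_gnomad
  s <- v$pop_af_swefreq
  if (any(!is.na(g) & g < 0) || any(!is.na(s) & s < 0))
    stop("negative population allele frequency")
  (is.na(g) | g == 0) & (is.na(s) | s == 0)
}

#' Allelic depth (support) filter
#'
#' Requires >= 2 reads supporting the variant in the tumor and, when a
#' matched normal is present, <= 1 supporting read in the normal.
#'
#' @param v variant table.
#' @return logical vector.
#' @export
allelic_depth_pass <- function(v) {
  if (!nrow(v)) return(logical(0))
  ok <- v$alt_support_tumor >= 2
  has_n <- !is.na(v$alt_support_normal)
  ok[has_n] <- ok[has_n] & v$alt_support_normal[has_n] <= 1
  ok
}

#' Coverage filter
#'
#' Requires >= 10 reads total depth at the position in the tumor and, when
#' a matched normal is present, >= 10 in the normal.
#'
#' @param v variant table.
#' @param min_depth minimum depth, default 10.
#' @return logical vector.
#' @export
coverage_pass <- function(v, min_depth = 10) {
  if (!nrow(v)) return(logical(0))
  ok <- v$depth_tumor >= min_depth
  has_n <- !is.na(v$depth_normal)
  ok[has_n] <- ok[has_n] & v$depth_normal[has_n] >= min_depth
  ok
}

#' Panel-of-normals filter
#'
#' A variant passes iff its (chrom, pos, ref, alt) key is absent from the
#' panel of normals.
#'
#' @param v variant table.
#' @param pon character vector of blacklisted keys
#'   (\code{\link{build_panel_of_normals}}).
#' @return logical vector.
#' @export
pon_pass <- function(v, pon) {
  if (!nrow(v)) return(logical(0))
  !(variant_keys(v) %in% pon)
}

#' Purity-scaled binomial log2 likelihood ratio
#'
#' For a variant with \code{s} supporting reads out of \code{c}, computes
#' \deqn{\log_2\!\left( 2\, P(s; c, p_{cancer}) / P(s; c, p_{background}) \right)}
#' where \eqn{P(k; n, p)} is the binomial pmf. Evaluated in log space
#' (via \code{dbinom(log = TRUE)}, i.e. log-gamma) so high depths do not
#' underflow. Returns \code{-Inf} when the numerator is 0 and the
#' denominator positive, and \code{NaN} (the UNDEFINED flag) when the
#' denominator is 0.
#'
#' @param s supporting read count(s).
#' @param c total depth(s), \code{s <= c}.
#' @param p_cancer binomial success probability under the cancer model.
#' @param p_background probability under the background model.
#' @return numeric vector of extended-real log2 ratios.
#' @export
tpes_log2_ratio <- function(s, c, p_cancer, p_background) {
  if (any(s > c)) stop("support cannot exceed coverage")
  if (any(s < 0) || any(c < 0)) stop("counts must be nonnegative")
  if (any(p_cancer < 0 | p_cancer > 1 | p_background < 0 | p_background > 1))
    stop("probabilities must lie in [0,1]")
  ln <- dbinom(s, c, p_cancer, log = TRUE)
  ld <- dbinom(s, c, p_background, log = TRUE)
  out <- 1 + (ln - ld) / log(2)
  # denominator exactly 0 -> undefined (NaN); numerator 0, denominator >0 -> -Inf
  out[is.infinite(ld) & ld < 0] <- NaN
  num0 <- is.infinite(ln) & ln < 0 & is.finite(ld)
  out[num0] <- -Inf
  out
}

#' Purity (TPES-style) likelihood-ratio filter
#'
#' Evaluates the heterozygous model (cancer p = 0.5 * purity vs background
#' 0.5) and the homozygous model (purity vs 1.0) for each variant and keeps
#' it when any defined model's log2 ratio exceeds \code{threshold}. If the
#' sample has no purity estimate the filter is skipped (all pass).
#'
#' A model whose background probability is exactly 0 (e.g. the homozygous
#' background \eqn{P(s; c, 1) = 0} whenever \eqn{s < c}) would make its
#' branch keep every variant; such models are flagged non-informative and
#' excluded from the disjunction unless \code{literal_hom = TRUE}, which
#' restores the as-printed behaviour. If every model is non-informative the
#' variant is kept.
#'
#' @param v variant table.
#' @param purity tumor purity in (0,1], or NA to skip the filter.
#' @param threshold keep when log2 ratio > threshold; default -1.
#' @param literal_hom if TRUE, treat an infinite ratio from a
#'   zero-probability background as a pass (the literal reading).
#' @return logical vector.
#' @export
tpes_pass <- function(v, purity, threshold = -1, literal_hom = FALSE) {
  if (!nrow(v)) return(logical(0))
  if (is.na(purity)) return(rep(TRUE, nrow(v)))
  if (purity <= 0 || purity > 1) stop("purity must lie in (0,1]")
  s <- v$alt_support_tumor
  c <- v$depth_tumor
  het <- tpes_log2_ratio(s, c, 0.5 * purity, 0.5)
  hom <- tpes_log2_ratio(s, c, purity, 1.0)
  if (literal_hom) {
    # as printed: a zero-probability background makes the ratio infinite,
    # so that branch keeps the variant
    return((is.nan(het) | het > threshold) | (is.nan(hom) | hom > threshold))
  }
  informative <- is.finite(het) | is.finite(hom)
  keep <- (is.finite(het) & het > threshold) |
    (is.finite(hom) & hom > threshold)
  keep | !informative
}

#' Apply the ordered somatic-variant filter cascade
#'
#' Filters are applied in order: population allele frequency, allelic
#' depth, coverage, panel of normals, purity likelihood ratio. Each removed
#' record is attributed to the first filter it fails; the kept set equals
#' the conjunction of all filters regardless of order.
#'
#' @param v variant table for one sample.
#' @param purity tumor purity for that sample (NA skips the purity filter).
#' @param pon panel-of-normals key vector (possibly empty).
#' @param threshold purity-filter log2-ratio threshold, default -1.
#' @return list with \code{kept} (variant table) and \code{report}
#'   (data.frame of per-filter removal counts plus input/surviving counts).
#' @export
apply_cascade <- function(v, purity = NA, pon = character(0), threshold = -1) {
  filters <- list(
    population_af = function(x) population_af_pass(x),
    allelic_depth = function(x) allelic_depth_pass(x),
    coverage      = function(x) coverage_pass(x),
    pon           = function(x) pon_pass(x, pon),
    tpes          = function(x) tpes_pass(x, purity, threshold)
  )
  alive <- rep(TRUE, nrow(v))
  removed <- integer(length(filters))
  names(removed) <- names(filters)
  for (i in seq_along(filters)) {
    p <- filters[[i]](v)
    if (!length(p)) p <- logical(0)
    fail <- alive & !p
    removed[i] <- sum(fail)
    alive <- alive & p
  }
  kept <- v[alive, , drop = FALSE]
  rownames(kept) <- NULL
  report <- data.frame(
    filter = names(removed), removed = as.integer(removed),
    stringsAsFactors = FALSE)
  attr(report, "input") <- nrow(v)
  attr(report, "surviving") <- nrow(kept)
  stopifnot(nrow(v) - sum(removed) == nrow(kept))
  list(kept = kept, report = report)
}

.excluded_consequences <- c(
  "downstream_gene_variant", "upstream_gene_variant",
  "3_prime_utr_variant", "5_prime_utr_variant", "synonymous_variant")

# normalise a consequence label: lower case, primes/apostrophes/spaces to
# underscores, "3_utr" -> "3_prime_utr" so both spellings match
.normalise_consequence <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[ '′]+", "_", x)
  x <- gsub("_+", "_", x)
  x <- sub("^3_utr", "3_prime_utr", x)
  x <- sub("^5_utr", "5_prime_utr", x)
  x
}

#' Impact / consequence filter for the cancer-gene SNV list
#'
#' Keeps variants of MODERATE or HIGH predicted impact whose consequence is
#' not one of: downstream gene variant, upstream gene variant, 3' UTR
#' variant, 5' UTR variant, synonymous variant.
#'
#' @param v variant table with \code{impact} and \code{consequence}.
#' @return logical vector.
#' @export
consequence_pass <- function(v) {
  if (!nrow(v)) return(logical(0))
  known <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  imp <- toupper(as.character(v$impact))
  if (any(!is.na(imp) & !(imp %in% known)))
    stop("unknown impact label: ",
         paste(unique(imp[!is.na(imp) & !(imp %in% known)]), collapse = ", "))
  cons <- .normalise_consequence(v$consequence)
  !is.na(imp) & imp %in% c("MODERATE", "HIGH") &
    !(cons %in% .excluded_consequences)
}

#' Paired SNV gain/loss comparison
#'
#' Compares the filtered variant-key sets of a matched PT-IBTR pair:
#' gains are keys private to the recurrence, losses private to the primary.
#'
#' @param pt_kept,ibtr_kept character vectors of variant keys.
#' @return list with \code{gains}, \code{losses}, \code{shared}.
#' @export
snv_gain_loss <- function(pt_kept, ibtr_kept) {
  pt <- unique(pt_kept); ib <- unique(ibtr_kept)
  list(gains = setdiff(ib, pt),
       losses = setdiff(pt, ib),
       shared = intersect(pt, ib))
}

#' Read a variant TSV (the dialect written by the synthetic cohort module)
#'
#' @param path TSV with a header row; empty fields are NA.
#' @return \code{variant_table}.
#' @export
read_variants_tsv <- function(path) {
  # read everything as character first: bare base columns like "T" would
  # otherwise be parsed as logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = c("NA", ""))
  int_cols <- c("pos", "alt_support_tumor", "depth_tumor",
                "alt_support_normal", "depth_normal")
  num_cols <- c("pop_af_gnomad", "pop_af_swefreq")
  for (col in intersect(int_cols, names(df))) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(num_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  variant_table(df)
}

#' Write a variant table as TSV
#'
#' @param v variant table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_variants_tsv <- function(v, path) {
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF 4.2 file
#'
#' Maps the first sample's AD/DP FORMAT fields to tumor support and depth
#' (second sample, if present, to the matched normal) and configurable INFO
#' keys to population frequencies, gene, impact and consequence. Requires
#' the vcfR package.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param info_keys named character vector mapping variant-table columns to
#'   INFO keys; defaults cover \code{pop_af_gnomad}, \code{pop_af_swefreq},
#'   \code{gene}, \code{impact}, \code{consequence}.
#' @return \code{variant_table}.
#' @export
read_variants_vcf <- function(path,
                              info_keys = c(pop_af_gnomad = "GNOMAD_AF",
                                            pop_af_swefreq = "SWEFREQ_AF",
                                            gene = "GENE", impact = "IMPACT",
                                            consequence = "CONSEQUENCE")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants_vcf requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs come back as a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  df <- data.frame(chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = fix[, "ALT"],
                   stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, "AD")
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  alt_from_ad <- function(x) as.integer(vapply(strsplit(x, ","), function(p)
    if (length(p) >= 2) p[2] else NA_character_, character(1)))
  df$alt_support_tumor <- alt_from_ad(ad[, 1])
  df$depth_tumor <- as.integer(dp[, 1])
  if (ncol(ad) >= 2) {
    df$alt_support_normal <- alt_from_ad(ad[, 2])
    df$depth_normal <- as.integer(dp[, 2])
  }
  for (col in names(info_keys)) {
    val <- vcfR::extract.info(vcf, info_keys[[col]])
    if (col %in% c("pop_af_gnomad", "pop_af_swefreq")) val <- as.numeric(val)
    df[[col]] <- val
  }
  variant_table(df)
}
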