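#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value under the "probability at most that of the observed
#' table" convention: the sum of hypergeometric probabilities of all
#' tables with the observed margins that are no more likely than the
#' observed one. A table with a zero margin is flagged degenerate and
#' returns p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list with \code{p} and \code{degenerate}.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = stats::fisher.test(table)$p.value, degenerate = FALSE)
}

#' Pearson chi-square test on an RxC table
#'
#' No continuity correction; df = (R-1)(C-1).
#'
#' @param table RxC matrix of counts, R,C >= 2.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (sum(table) == 0) stop("zero-sum table")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact null distribution for combined n <= 20 without ties; normal
#' approximation with tie correction otherwise. Fully tied data are
#' flagged and return p = 1.
#'
#' @param values_a,values_b numeric vectors, each nonempty.
#' @return list with \code{p}, \code{tied} flag.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("each group needs at least one value")
  all_vals <- c(values_a, values_b)
  if (length(unique(all_vals)) == 1) return(list(p = 1, tied = TRUE))
  has_ties <- any(duplicated(all_vals))
  exact <- !has_ties && length(all_vals) <= 20
  res <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, exact = exact, correct = !exact))
  list(p = res$p.value, tied = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to input order.
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value from the t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho} and \code{p}.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths of at least 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman undefined for a constant vector")
  res <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  list(rho = unname(res$estimate), p = res$p.value)
}

#' Ki-67 / leukocyte histo-score
#'
#' The sum of cohort z-scores of the Ki-67-positive cell percentage and
#' the infiltrating-leukocyte percentage:
#' \deqn{(Ki67 - mean(Ki67))/sd(Ki67) + (Leu - mean(Leu))/sd(Leu)}
#'
#' @param ki67_pct Ki-67 percentage(s) to score, in [0,100].
#' @param leukocyte_pct leukocyte percentage(s) to score.
#' @param cohort data.frame with \code{ki67_pct} and \code{leukocyte_pct}
#'   columns defining the standardisation cohort (>= 2 records).
#' @return numeric histo-score(s).
#' @export
histoscore <- function(ki67_pct, leukocyte_pct, cohort) {
  if (nrow(cohort) < 2) stop("cohort needs at least 2 records")
  rng_ok <- function(x) all(x >= 0 & x <= 100)
  if (!rng_ok(ki67_pct) || !rng_ok(leukocyte_pct) ||
      !rng_ok(cohort$ki67_pct) || !rng_ok(cohort$leukocyte_pct))
    stop("percentages must lie in [0,100]")
  sk <- stats::sd(cohort$ki67_pct)
  sl <- stats::sd(cohort$leukocyte_pct)
  if (sk == 0) stop("zero cohort standard deviation for ki67_pct")
  if (sl == 0) stop("zero cohort standard deviation for leukocyte_pct")
  (ki67_pct - mean(cohort$ki67_pct)) / sk +
    (leukocyte_pct - mean(cohort$leukocyte_pct)) / sl
}

#' Median split of patient scores
#'
#' Scores at or below the median go to the low group, above to the high
#' group (ties low). With all scores equal the split is degenerate and
#' flagged.
#'
#' @param scores named numeric vector, names are patient identifiers.
#' @return list with \code{low}, \code{high} (names) and
#'   \code{degenerate}.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 patients")
  med <- stats::median(scores)
  low <- names(scores)[scores <= med]
  high <- names(scores)[scores > med]
  list(low = low, high = high, degenerate = length(high) == 0)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 df, two-sided. With no events at all
#' the test is flagged and returns p = 1.
#'
#' @param groups factor-like group labels (two nonempty groups).
#' @param times follow-up times.
#' @param events event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @return list with \code{statistic}, \code{p}, \code{no_events}.
#' @export
logrank <- function(groups, times, events) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("need exactly two nonempty groups")
  events <- as.integer(events)
  if (sum(events) == 0) return(list(statistic = 0, p = 1, no_events = TRUE))
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(statistic = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
       no_events = FALSE)
}

#' Associate per-pair deltas with a clinical grouping
#'
#' For each column of \code{deltas} (one family, e.g. signature
#' contribution deltas), runs a two-sided Wilcoxon rank-sum test between
#' the two clinical groups and adjusts the family's p-values by
#' Benjamini-Hochberg. Records with missing group labels are dropped
#' pairwise and the n used is reported.
#'
#' @param deltas numeric matrix or data.frame, patients x variables.
#' @param group vector of two-level group labels aligned to rows of
#'   \code{deltas}; NAs dropped.
#' @return data.frame variable, n, p, p_adjusted.
#' @export
associate_deltas <- function(deltas, group) {
  deltas <- as.matrix(deltas)
  group <- as.factor(group)
  res <- lapply(colnames(deltas), function(v) {
    x <- deltas[, v]
    keep <- !is.na(x) & !is.na(group)
    g <- droplevels(group[keep])
    if (nlevels(g) != 2)
      return(data.frame(variable = v, n = sum(keep), p = NA_real_))
    p <- wilcoxon_rank_sum(x[keep][g == levels(g)[1]],
                           x[keep][g == levels(g)[2]])$p
    data.frame(variable = v, n = sum(keep), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
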