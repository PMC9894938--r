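#' Validate a coverage-bin table
#'
#' Bins are fixed-width (default 10 kb), 0-based half-open, non-overlapping
#' within each chromosome, with a GC fraction and a nonnegative coverage.
#'
#' @param df data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{gc}, \code{coverage}.
#' @param bin_width expected bin width in bp, default 10000.
#' @return the validated data.frame (class \code{coverage_bins}).
#' @export
coverage_bins <- function(df, bin_width = 10000) {
  req <- c("chrom", "start", "end", "gc", "coverage")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("bins missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$end - df$start != bin_width))
      stop("all bins must have width ", bin_width)
    if (any(df$gc < 0 | df$gc > 1)) stop("gc must lie in [0,1]")
    if (any(!is.na(df$coverage) & df$coverage < 0))
      stop("coverage must be nonnegative")
    for (chr in unique(df$chrom)) {
      s <- sort(df$start[df$chrom == chr])
      if (any(diff(s) < bin_width)) stop("overlapping bins on ", chr)
    }
  }
  class(df) <- c("coverage_bins", "data.frame")
  df
}

#' Read coverage bins from a BED-like TSV
#'
#' @param path TSV with header columns chrom, start, end, gc, coverage.
#' @param bin_width expected bin width, default 10000.
#' @return \code{coverage_bins}.
#' @export
read_bins_tsv <- function(path, bin_width = 10000) {
  coverage_bins(utils::read.delim(path, stringsAsFactors = FALSE),
                bin_width = bin_width)
}

#' Fit the GC-content vs coverage relationship
#'
#' Robust locally weighted regression of bin coverage on GC fraction
#' (\code{stats::lowess}, which iteratively downweights outliers by
#' bisquare weights), evaluable over the observed GC range by linear
#' interpolation. A degenerate GC range yields a flat model with a warning.
#'
#' @param bins \code{coverage_bins} for one sample.
#' @param bandwidth lowess smoother span, default 0.3.
#' @param iterations robustness iterations, default 3.
#' @return object of class \code{gc_model}: a function \code{gc ->
#'   expected coverage} with fitting metadata attached.
#' @export
fit_gc_model <- function(bins, bandwidth = 0.3, iterations = 3) {
  ok <- !is.na(bins$coverage) & bins$coverage > 0
  if (sum(ok) < 50) stop("need at least 50 bins with positive coverage")
  gc <- bins$gc[ok]; cov <- bins$coverage[ok]
  if (diff(range(gc)) < 1e-12) {
    warning("degenerate GC range; using flat model")
    level <- stats::median(cov)
    fun <- function(g) rep(level, length(g))
  } else {
    lw <- stats::lowess(gc, cov, f = bandwidth, iter = iterations)
    fun <- function(g) stats::approx(lw$x, lw$y, xout = g, rule = 2)$y
  }
  structure(fun, class = "gc_model", bandwidth = bandwidth,
            iterations = iterations, gc_range = range(gc))
}

#' GC-correct bin coverages
#'
#' Rescales each bin by the ratio of the sample's median fitted coverage to
#' the fitted coverage at that bin's GC, removing the GC trend while
#' preserving the sample's overall median coverage. Bins whose fitted value
#' is not positive are masked (NA).
#'
#' @param bins \code{coverage_bins}.
#' @param model \code{gc_model} fitted on the same sample.
#' @return numeric vector of adjusted coverages (NA where masked).
#' @export
adjust_coverage <- function(bins, model) {
  fitted <- model(bins$gc)
  med <- stats::median(fitted[fitted > 0], na.rm = TRUE)
  adj <- bins$coverage * med / fitted
  adj[!is.na(fitted) & fitted <= 0] <- NA
  adj
}

#' Compute centered log2 coverage ratios
#'
#' log2(tumor / reference) per bin, where the reference is the matched
#' normal's adjusted coverage when available and otherwise the median
#' adjusted coverage of the tumor sample itself; the track is then
#' median-centered. Bins with zero or missing denominator are masked.
#'
#' @param tumor_adjusted adjusted tumor coverages
#'   (\code{\link{adjust_coverage}}).
#' @param reference_adjusted matched-normal adjusted coverages on the same
#'   bin grid, or NULL for self-median mode.
#' @return list with \code{log2_ratio} (median-centered, NA where masked)
#'   and \code{reference_mode}.
#' @export
compute_log2_ratios <- function(tumor_adjusted, reference_adjusted = NULL) {
  if (is.null(reference_adjusted)) {
    denom <- rep(stats::median(tumor_adjusted, na.rm = TRUE),
                 length(tumor_adjusted))
    mode <- "self_median"
  } else {
    if (length(reference_adjusted) != length(tumor_adjusted))
      stop("tumor and reference must share the bin grid")
    denom <- reference_adjusted
    mode <- "matched_normal"
  }
  lr <- log2(tumor_adjusted / denom)
  lr[!is.finite(lr)] <- NA
  lr <- lr - stats::median(lr, na.rm = TRUE)
  list(log2_ratio = lr, reference_mode = mode)
}

# Maximal circular-arc statistic: over all arcs (i, i+m] with
# min_bins <= m <= n - min_bins, the standardised mean difference between
# the arc and its complement,
#   Z(i,m) = |D[i+m] - D[i]| / (sigma * sqrt(m (1 - m/n)))
# with D the cumulative sum of centered values and sigma the global sd.
# Prefix arcs (i = 0) are ordinary single splits, so the search subsumes
# plain binary splitting while still catching focal interior events.
# Returns list(i, m, z) or NULL.
.best_arc <- function(y, min_bins) {
  n <- length(y)
  if (n < 2 * min_bins) return(NULL)
  sigma <- stats::sd(y)
  if (!is.finite(sigma) || sigma == 0) return(NULL)
  D <- c(0, cumsum(y - mean(y)))
  best <- list(i = 0L, m = 0L, z = 0)
  for (m in min_bins:(n - min_bins)) {
    d <- abs(D[(m + 1):(n + 1)] - D[1:(n + 1 - m)])
    j <- which.max(d)
    z <- d[j] / (sigma * sqrt(m * (1 - m / n)))
    if (z > best$z) best <- list(i = j - 1L, m = m, z = z)
  }
  if (best$m == 0L) NULL else best
}

# permutation test of the observed max arc statistic; stops early once
# enough exceedances guarantee p >= alpha
.arc_perm_keep <- function(y, z_obs, alpha, n_perm, min_bins) {
  need <- ceiling(alpha * (1 + n_perm))
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    s <- .best_arc(y[sample.int(length(y))], min_bins)
    if (!is.null(s) && s$z >= z_obs) {
      cnt <- cnt + 1L
      if (cnt >= need) return(FALSE)
    }
  }
  (1 + cnt) / (1 + n_perm) < alpha
}

# recursive segmentation of one chromosome's values; returns segment end
# indices in order
.segment_values <- function(y, alpha, n_perm, min_bins) {
  n <- length(y)
  arc <- .best_arc(y, min_bins)
  if (is.null(arc) || arc$z <= 0) return(n)
  if (!.arc_perm_keep(y, arc$z, alpha, n_perm, min_bins)) return(n)
  bounds <- setdiff(unique(c(arc$i, arc$i + arc$m)), c(0L, n))
  ends <- integer(0)
  lo <- 0L
  for (b in c(bounds, n)) {
    ends <- c(ends, lo + .segment_values(y[(lo + 1):b], alpha, n_perm,
                                         min_bins))
    lo <- b
  }
  ends
}

#' Segment a log2-ratio track
#'
#' Recursive circular binary segmentation per chromosome: the arc whose
#' mean differs most (in standardised units) from its complement is
#' accepted as a change-point pair when its permutation p-value falls
#' below \code{alpha}, and the resulting pieces are segmented
#' recursively; prefix arcs make plain terminal splits a special case. Adjacent segments whose means differ by less than
#' \code{merge_epsilon} are merged. Masked (NA) bins are excluded.
#' Deterministic for a fixed \code{seed}.
#'
#' @param bins \code{coverage_bins} providing coordinates.
#' @param log2_ratio per-bin centered log2 ratios
#'   (\code{\link{compute_log2_ratios}}).
#' @param alpha split acceptance level, default 0.01.
#' @param n_perm permutations per split test, default 1000.
#' @param min_bins minimum bins per segment arm, default 5.
#' @param merge_epsilon merge adjacent segments closer than this in mean,
#'   default 0 (no merging).
#' @param seed RNG seed for the permutation test.
#' @return data.frame of segments: chrom, start, end, mean_log2, n_bins.
#' @export
segment_track <- function(bins, log2_ratio, alpha = 0.01, n_perm = 1000,
                          min_bins = 5, merge_epsilon = 0, seed = 1) {
  stopifnot(length(log2_ratio) == nrow(bins))
  set.seed(seed)
  segs <- list()
  for (chr in unique(bins$chrom)) {
    idx <- which(bins$chrom == chr & !is.na(log2_ratio))
    idx <- idx[order(bins$start[idx])]
    if (!length(idx)) next
    y <- log2_ratio[idx]
    ends <- .segment_values(y, alpha, n_perm, min_bins)
    starts <- c(1, utils::head(ends, -1) + 1)
    means <- mapply(function(a, b) mean(y[a:b]), starts, ends)
    # merge adjacent segments with nearly equal means
    if (merge_epsilon > 0 && length(means) > 1) {
      i <- 1
      while (i < length(means)) {
        if (abs(means[i + 1] - means[i]) < merge_epsilon) {
          ends[i] <- ends[i + 1]
          means[i] <- mean(y[starts[i]:ends[i]])
          starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
          means <- means[-(i + 1)]
        } else i <- i + 1
      }
    }
    segs[[chr]] <- data.frame(
      chrom = chr,
      start = bins$start[idx[starts]],
      end = bins$end[idx[ends]],
      mean_log2 = means,
      n_bins = as.integer(ends - starts + 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Map segments onto genes through exon overlap
#'
#' A gene's copy number is the unweighted mean over every segment
#' overlapping at least one of its exons; genes with no overlapping
#' segment are NA. On the default \code{"ratio"} scale each segment mean
#' log2 ratio is converted to a coverage ratio \code{2^mean_log2}
#' (copy-neutral = 1) before averaging, which is the scale the paired
#' delta thresholds operate on: a minimum CN of 0.5 then excludes genes in
#' near-homozygous-deletion territory rather than (as a centered-log2
#' reading would) almost every copy-neutral gene. \code{scale = "log2"}
#' averages the segment means directly.
#'
#' @param segments segment data.frame (\code{\link{segment_track}}).
#' @param gene_exons data.frame with \code{gene}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open exon intervals).
#' @param scale \code{"ratio"} (default) or \code{"log2"}.
#' @return data.frame gene, cn.
#' @export
gene_copy_number <- function(segments, gene_exons,
                             scale = c("ratio", "log2")) {
  scale <- match.arg(scale)
  seg_cn <- if (scale == "ratio") 2^segments$mean_log2 else segments$mean_log2
  genes <- unique(gene_exons$gene)
  cn <- vapply(genes, function(g) {
    ex <- gene_exons[gene_exons$gene == g, , drop = FALSE]
    hit <- logical(nrow(segments))
    for (i in seq_len(nrow(ex))) {
      hit <- hit | (segments$chrom == ex$chrom[i] &
                    segments$start < ex$end[i] &
                    segments$end > ex$start[i])
    }
    if (any(hit)) mean(seg_cn[hit]) else NA_real_
  }, numeric(1))
  data.frame(gene = genes, cn = unname(cn), stringsAsFactors = FALSE)
}

#' Paired per-gene copy-number delta calls
#'
#' DeltaCN = CN(IBTR) - CN(PT) on the centered log2-ratio scale. A gene is
#' evaluable only when both samples show CN of at least \code{min_cn};
#' evaluable genes are called gain when the delta exceeds \code{gain} and
#' loss when below \code{loss}.
#'
#' @param pt,ibtr data.frames gene, cn (\code{\link{gene_copy_number}});
#'   gene universes are intersected.
#' @param gain gain threshold, default +0.75.
#' @param loss loss threshold, default -0.75.
#' @param min_cn minimum CN in both samples for evaluability, default 0.5.
#' @return data.frame gene, cn_pt, cn_ibtr, delta, call in
#'   \{gain, loss, none, not_evaluable\}.
#' @export
delta_cn_calls <- function(pt, ibtr, gain = 0.75, loss = -0.75,
                           min_cn = 0.5) {
  m <- merge(pt, ibtr, by = "gene", suffixes = c("_pt", "_ibtr"))
  delta <- m$cn_ibtr - m$cn_pt
  evaluable <- !is.na(m$cn_pt) & !is.na(m$cn_ibtr) &
    m$cn_pt >= min_cn & m$cn_ibtr >= min_cn
  call <- rep("not_evaluable", nrow(m))
  call[evaluable] <- "none"
  call[evaluable & delta > gain] <- "gain"
  call[evaluable & delta < loss] <- "loss"
  data.frame(gene = m$gene, cn_pt = m$cn_pt, cn_ibtr = m$cn_ibtr,
             delta = delta, call = call, stringsAsFactors = FALSE)
}

#' Count gains and losses per pair
#'
#' @param calls output of \code{\link{delta_cn_calls}}.
#' @return named integer vector: gains, losses, none, not_evaluable.
#' @export
count_cn_calls <- function(calls) {
  tab <- table(factor(calls$call,
                      levels = c("gain", "loss", "none", "not_evaluable")))
  stats::setNames(as.integer(tab), names(tab))
}
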