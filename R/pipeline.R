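#' Run the paired variant / signature / drift analysis on a cohort bundle
#'
#' Convenience composition of the module functions over a cohort bundle
#' (as produced by \code{\link{simulate_cohort}} or assembled from files):
#' builds the panel of normals, applies the five-filter cascade per
#' sample, computes per-pair SNV gains/losses, refits 96-context spectra
#' against \code{sigs} with per-pair contribution deltas, and computes
#' per-pair expression and protein cosine-dissimilarity drift.
#'
#' @param bundle list with \code{variants}, \code{purity}, \code{pairs},
#'   \code{normals} (or \code{pon}), \code{expression}, \code{protein}.
#' @param sigs \code{signature_matrix} for the refit.
#' @param threshold purity-filter log2-ratio threshold, default -1.
#' @return list with \code{kept} (filtered variant tables),
#'   \code{reports}, \code{gain_loss} (per-patient key sets),
#'   \code{contributions} (samples x signatures fractions),
#'   \code{deltas} (patients x signatures), \code{selected} signatures,
#'   \code{drift} (per-pair dissimilarities per layer).
#' @export
analyze_pairs <- function(bundle, sigs = synthetic_signature_matrix(3),
                          threshold = -1) {
  pon <- if (!is.null(bundle$pon)) bundle$pon
         else build_panel_of_normals(bundle$normals)
  purity_of <- function(s) {
    p <- bundle$purity$purity[bundle$purity$sample_id == s]
    if (length(p)) p[1] else NA
  }
  kept <- list(); reports <- list()
  for (s in names(bundle$variants)) {
    res <- apply_cascade(bundle$variants[[s]], purity_of(s), pon,
                         threshold = threshold)
    kept[[s]] <- res$kept
    reports[[s]] <- res$report
  }
  contributions <- do.call(rbind, lapply(names(kept), function(s)
    coef(fit_contributions(build_spectrum(kept[[s]]), sigs))))
  rownames(contributions) <- names(kept)
  pairs <- bundle$pairs
  gain_loss <- lapply(seq_len(nrow(pairs)), function(i)
    snv_gain_loss(variant_keys(kept[[pairs$pt[i]]]),
                  variant_keys(kept[[pairs$ibtr[i]]])))
  names(gain_loss) <- pairs$patient
  deltas <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    contribution_delta(contributions[pairs$pt[i], ],
                       contributions[pairs$ibtr[i], ])))
  rownames(deltas) <- pairs$patient
  drift <- list(RNA = pair_dissimilarities(bundle$expression, pairs),
                protein = pair_dissimilarities(bundle$protein, pairs))
  list(kept = kept, reports = reports, gain_loss = gain_loss,
       contributions = contributions, deltas = deltas,
       selected = select_signatures(contributions), drift = drift)
}
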