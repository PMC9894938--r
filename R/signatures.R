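.base_complement <- c(A = "T", C = "G", G = "C", T = "A")
.substitution_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context labels
#'
#' Pyrimidine-centered contexts in COSMIC v2 order: substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G, each with 16 flank combinations in
#' lexicographic A,C,G,T order, labelled like \code{"A[C>A]A"}.
#'
#' @return character vector of length 96.
#' @export
context_labels <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (sub in .substitution_classes)
    for (f5 in bases)
      for (f3 in bases)
        out <- c(out, paste0(f5, "[", sub, "]", f3))
  out
}

#' Classify a substitution into its pyrimidine-centered context
#'
#' When the reference base is a purine, the substitution and both flanks
#' are reverse-complemented (flanks swap and complement) so the reference
#' is always C or T; the 192 raw strand representations collapse onto 96
#' classes.
#'
#' @param ref,alt single bases, \code{ref != alt}.
#' @param flank5,flank3 bases immediately 5' and 3' of the variant.
#' @return context label such as \code{"A[C>T]A"}; vectorised.
#' @export
classify_context <- function(ref, alt, flank5, flank3) {
  bases <- c("A", "C", "G", "T")
  if (any(!(c(ref, alt, flank5, flank3) %in% bases)))
    stop("ambiguous base; only A/C/G/T supported")
  if (any(ref == alt)) stop("ref must differ from alt")
  n <- length(ref)
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, .base_complement[ref], ref)
  a <- ifelse(flip, .base_complement[alt], alt)
  f5 <- ifelse(flip, .base_complement[flank3], flank5)
  f3 <- ifelse(flip, .base_complement[flank5], flank3)
  paste0(f5, "[", r, ">", a, "]", f3)
}

#' Build a 96-context mutation spectrum
#'
#' Counts each variant's trinucleotide context. Records with missing
#' flanking bases are not silently dropped: their row indices are returned
#' in the \code{unclassified} attribute.
#'
#' @param v variant table with \code{ref}, \code{alt}, \code{context5},
#'   \code{context3}.
#' @return named integer vector of length 96 (class \code{spectrum96})
#'   with attribute \code{unclassified}.
#' @export
build_spectrum <- function(v) {
  labs <- context_labels()
  counts <- stats::setNames(integer(96), labs)
  bad <- integer(0)
  if (nrow(v)) {
    ok <- !is.na(v$context5) & !is.na(v$context3) &
      !is.na(v$ref) & !is.na(v$alt)
    bad <- which(!ok)
    if (any(ok)) {
      ctx <- classify_context(v$ref[ok], v$alt[ok],
                              v$context5[ok], v$context3[ok])
      tab <- table(factor(ctx, levels = labs))
      counts <- stats::setNames(as.integer(tab), labs)
    }
  }
  structure(counts, unclassified = bad, class = "spectrum96")
}

#' Validate / construct a signature matrix
#'
#' @param profiles 96 x K nonnegative matrix; rows named by the 96 context
#'   labels (any order), columns by signature names. Columns must each sum
#'   to 1 within 1e-6.
#' @return matrix with rows in canonical context order, class
#'   \code{signature_matrix}.
#' @export
signature_matrix <- function(profiles) {
  labs <- context_labels()
  if (is.null(rownames(profiles)) || !setequal(rownames(profiles), labs))
    stop("signature matrix rows must be the 96 context labels")
  profiles <- profiles[labs, , drop = FALSE]
  if (any(profiles < 0)) stop("signature profiles must be nonnegative")
  cs <- colSums(profiles)
  if (any(abs(cs - 1) > 1e-6))
    stop("each signature column must sum to 1")
  class(profiles) <- c("signature_matrix", class(profiles))
  profiles
}

#' Read a signature matrix in COSMIC v2 tab-delimited layout
#'
#' Expects a TSV whose first column holds the 96 context labels
#' (\code{"A[C>A]A"} ... \code{"T[T>G]T"}) and remaining columns one
#' signature each; extra annotation columns without numeric content are
#' dropped.
#'
#' @param path TSV path.
#' @return \code{signature_matrix}.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lab_col <- which(vapply(df, function(x)
    any(grepl("\\[[CT]>[ACGT]\\]", x)), logical(1)))[1]
  if (is.na(lab_col)) stop("no context-label column found")
  labs <- df[[lab_col]]
  num <- df[vapply(df, is.numeric, logical(1))]
  m <- as.matrix(num)
  rownames(m) <- labs
  signature_matrix(m)
}

# Lawson-Hanson active-set non-negative least squares:
# minimise ||A x - b||_2 subject to x >= 0.
.nnls_activeset <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      denom <- x[neg] - z[neg]
      ratio <- ifelse(denom > 0, x[neg] / denom, Inf)
      alpha <- min(ratio)
      if (!is.finite(alpha)) { x[neg] <- 0; passive[neg] <- FALSE; break }
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Refit a spectrum against reference signatures
#'
#' Solves \eqn{\min_w \|counts - profiles \cdot w\|_2, w \ge 0} by the
#' Lawson-Hanson active-set method, then normalises the weights to
#' fractional contributions. An all-zero spectrum yields all-zero
#' fractions with \code{empty = TRUE}.
#'
#' @param spectrum 96-vector of context counts (\code{\link{build_spectrum}}
#'   output or any named numeric over the 96 labels).
#' @param sigs \code{signature_matrix}.
#' @param tol active-set tolerance, default 1e-10.
#' @return object of class \code{signature_fit}: list with
#'   \code{fractions} (named, sums to 1 for nonzero spectra),
#'   \code{weights} (raw nonnegative scale), \code{residual_norm},
#'   \code{fitted}, \code{spectrum}, \code{empty}.
#' @export
fit_contributions <- function(spectrum, sigs, tol = 1e-10) {
  labs <- context_labels()
  if (is.null(names(spectrum)) || !setequal(names(spectrum), labs))
    stop("spectrum must be named by the 96 context labels")
  b <- as.numeric(spectrum[labs])
  A <- unclass(sigs)[labs, , drop = FALSE]
  if (sum(b) == 0) {
    w <- stats::setNames(numeric(ncol(A)), colnames(A))
    fit <- structure(list(fractions = w, weights = w, residual_norm = 0,
                          fitted = stats::setNames(numeric(96), labs),
                          spectrum = stats::setNames(b, labs), empty = TRUE),
                     class = "signature_fit")
    return(fit)
  }
  w <- .nnls_activeset(A, b, tol = tol)
  names(w) <- colnames(A)
  fitted <- as.numeric(A %*% w)
  fractions <- if (sum(w) > 0) w / sum(w) else w
  structure(list(fractions = fractions, weights = w,
                 residual_norm = sqrt(sum((b - fitted)^2)),
                 fitted = stats::setNames(fitted, labs),
                 spectrum = stats::setNames(b, labs), empty = FALSE),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature refit (non-negative least squares)\n")
  cat("  mutations:", sum(x$spectrum), "  residual norm:",
      format(x$residual_norm, digits = 4), "\n")
  nz <- x$fractions[x$fractions > 0]
  if (length(nz)) {
    cat("  contributions:\n")
    print(round(sort(nz, decreasing = TRUE), 4))
  } else cat("  empty spectrum: all contributions zero\n")
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$fractions

#' @export
fitted.signature_fit <- function(object, ...) object$fitted

#' @export
residuals.signature_fit <- function(object, ...) object$spectrum - object$fitted

#' Select signatures by mean contribution across samples
#'
#' Retains the upper half (top two quartiles) of signatures ranked by mean
#' fractional contribution across samples; ties at the median are kept.
#'
#' @param contributions matrix samples x signatures of fractions, or a list
#'   of \code{signature_fit} objects.
#' @return character vector of retained signature names.
#' @export
select_signatures <- function(contributions) {
  if (is.list(contributions) && !is.data.frame(contributions) &&
      !is.matrix(contributions))
    contributions <- do.call(rbind, lapply(contributions, coef))
  contributions <- as.matrix(contributions)
  if (!nrow(contributions)) stop("need at least one sample")
  means <- colMeans(contributions)
  keep <- means >= stats::median(means)
  names(means)[keep]
}

#' Per-pair signature contribution delta
#'
#' The change in fractional signature contribution from primary to
#' recurrence: \code{delta = fraction(IBTR) - fraction(PT)}. Since both
#' inputs sum to 1 the deltas sum to 0.
#'
#' @param pt,ibtr \code{signature_fit} objects or named fraction vectors
#'   over the same signatures.
#' @return named numeric vector of deltas.
#' @export
contribution_delta <- function(pt, ibtr) {
  fp <- if (inherits(pt, "signature_fit")) coef(pt) else pt
  fi <- if (inherits(ibtr, "signature_fit")) coef(ibtr) else ibtr
  if (is.null(names(fp)) || !setequal(names(fp), names(fi)))
    stop("contribution vectors must share the same signature labels")
  fi[names(fp)] - fp
}

#' Base-change (substitution class) frequencies
#'
#' Per-sample fractions over the six pyrimidine-centered substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G after strand normalisation.
#'
#' @param v variant table with \code{ref} and \code{alt}.
#' @return named numeric vector of 6 fractions (sums to 1 for nonempty
#'   input; all zero for empty input).
#' @export
base_change_frequencies <- function(v) {
  out <- stats::setNames(numeric(6), .substitution_classes)
  if (!nrow(v)) return(out)
  flip <- v$ref %in% c("A", "G")
  r <- ifelse(flip, .base_complement[v$ref], v$ref)
  a <- ifelse(flip, .base_complement[v$alt], v$alt)
  tab <- table(factor(paste0(r, ">", a), levels = .substitution_classes))
  out[] <- as.numeric(tab) / sum(tab)
  out
}
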