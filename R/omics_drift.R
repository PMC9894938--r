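#' Cosine dissimilarity between two profiles
#'
#' \code{1 - (x . y) / (||x|| ||y||)}; 0 for positively proportional
#' profiles, 1 for orthogonal, 2 for opposite. Errors on zero-norm input.
#'
#' @param x,y numeric vectors of equal length.
#' @return dissimilarity in [0, 2].
#' @export
cosine_dissimilarity <- function(x, y) {
  if (length(x) != length(y) || !length(x))
    stop("x and y must have equal, positive length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine dissimilarity undefined for zero-norm vector")
  1 - sum(x * y) / (nx * ny)
}

# complete-case filter: drop feature rows carrying any missing value
.complete_features <- function(m) {
  m[stats::complete.cases(m), , drop = FALSE]
}

# full sample x sample cosine-dissimilarity matrix
.dissimilarity_matrix <- function(m) {
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) stop("zero-norm sample column")
  d <- 1 - crossprod(m) / tcrossprod(norms)
  diag(d) <- 0
  d
}

#' Per-pair cosine dissimilarities on one omics layer
#'
#' Computes, per patient, the cosine dissimilarity between the matched
#' primary and recurrence columns of a feature-by-sample matrix. Feature
#' rows containing any missing value are excluded first (complete-case per
#' layer), so dissimilarities are comparable across layers of different
#' feature counts. Pairs with a missing member are skipped with a warning.
#'
#' @param matrix numeric features x samples matrix with column names.
#' @param pairs data.frame with \code{patient}, \code{pt}, \code{ibtr}
#'   sample-column names.
#' @return data.frame patient, dissimilarity.
#' @export
pair_dissimilarities <- function(matrix, pairs) {
  m <- .complete_features(as.matrix(matrix))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$pt[i]; b <- pairs$ibtr[i]
    if (!(a %in% colnames(m)) || !(b %in% colnames(m))) {
      warning("pair ", pairs$patient[i], " missing a member; skipped")
      return(NULL)
    }
    data.frame(patient = pairs$patient[i],
               dissimilarity = cosine_dissimilarity(m[, a], m[, b]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(patient = character(0),
                                      dissimilarity = numeric(0))
  rownames(out) <- NULL
  out
}

#' Pair co-clustering by mutual nearest neighbors
#'
#' Builds the full sample-by-sample cosine-dissimilarity matrix
#' (complete-case features), runs average-linkage agglomerative clustering
#' for the dendrogram, and flags a pair as co-clustering when each member
#' is the other's nearest neighbor under the dissimilarity.
#'
#' @param matrix numeric features x samples matrix with column names.
#' @param pairs data.frame with \code{patient}, \code{pt}, \code{ibtr}.
#' @param linkage hclust agglomeration method, default "average".
#' @return list with \code{cocluster} (data.frame patient, cocluster),
#'   \code{dissimilarity} (sample matrix) and \code{hclust}.
#' @export
pair_cocluster <- function(matrix, pairs, linkage = "average") {
  m <- .complete_features(as.matrix(matrix))
  if (ncol(m) < 4) stop("need at least 4 samples")
  d <- .dissimilarity_matrix(m)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  nn <- apply(d + diag(Inf, ncol(d)), 1, which.min)
  names(nn) <- colnames(d)
  flag <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$pt[i]; b <- pairs$ibtr[i]
    if (!(a %in% colnames(d)) || !(b %in% colnames(d))) return(NA)
    colnames(d)[nn[a]] == b && colnames(d)[nn[b]] == a
  }, logical(1))
  list(cocluster = data.frame(patient = pairs$patient, cocluster = flag,
                              stringsAsFactors = FALSE),
       dissimilarity = d, hclust = hc)
}

#' Read a feature-by-sample matrix from TSV
#'
#' Feature identifiers in the first column, one sample per remaining
#' column.
#'
#' @param path TSV path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_omics_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
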