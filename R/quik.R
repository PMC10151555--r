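# Todeschini's K multivariate correlation index and the QUIK rule.
#
# For a column-standardized block Z with correlation-matrix eigenvalues
# lambda_j (p columns):
#   K = sum_j | lambda_j / sum(lambda) - 1/p |  /  (2 (p - 1) / p)
# K is 0 for mutually orthogonal columns and 1 for perfectly collinear ones.
# The QUIK rule accepts a model only when the descriptor-plus-response block
# is more correlated than the descriptor block alone:
#   Kxy - Kxx >= delta.

#' Todeschini K multivariate correlation index
#'
#' @param x numeric matrix/data.frame (>= 2 columns, no zero-variance
#'   columns).
#' @return K in [0, 1].
#' @export
k_correlation <- function(x) {
  X <- as.matrix(x)
  if (ncol(X) < 2L) stop("K needs at least two columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  lambda <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  p <- ncol(X)
  sum(abs(lambda / sum(lambda) - 1 / p)) / (2 * (p - 1) / p)
}

#' QUIK collinearity filter
#'
#' Computes Kxx (descriptor block) and Kxy (descriptor block augmented with
#' the response) and accepts the subset when Kxy - Kxx >= `delta`.
#'
#' @param x descriptor matrix/data.frame.
#' @param y numeric response.
#' @param delta acceptance threshold (default 0.05).
#' @return list with `kxx`, `kxy`, `delta_k` and logical `pass`.
#' @export
quik_filter <- function(x, y, delta = 0.05) {
  X <- as.matrix(x)
  kxx <- k_correlation(X)
  kxy <- k_correlation(cbind(X, y = as.numeric(y)))
  list(kxx = kxx, kxy = kxy, delta_k = kxy - kxx,
       pass = (kxy - kxx) >= delta)
}
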