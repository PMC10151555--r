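# Cross-validated statistics. Q2-LOO uses the hat-matrix shortcut
# (LOO residual = e_i / (1 - h_ii)), which agrees with n explicit refits for
# least squares; the brute-force route lives in the test suite as oracle.

# PRESS residuals for an OLS fit of y on X (with intercept)
.loo_residuals <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) return(NULL)  # singular subset
  res <- stats::lm.fit(Xi, y)$residuals
  h <- .hat_values(Xi)
  if (any(h > 1 - 1e-10)) return(NULL)   # a point determines its own fit
  res / (1 - h)
}

#' Leave-one-out cross-validated Q2
#'
#' Q2_LOO = 1 - PRESS / TSS, with PRESS the sum of squared leave-one-out
#' prediction errors of the OLS model of `y` on `x` (intercept included),
#' and TSS about the mean of `y`. A singular descriptor subset returns
#' `-Inf` so subset searches reject it.
#'
#' @param x descriptor matrix/data.frame.
#' @param y numeric response.
#' @return Q2_LOO (scalar; `-Inf` for singular subsets).
#' @export
q2_loo <- function(x, y) {
  y <- as.numeric(y)
  e <- .loo_residuals(x, y)
  if (is.null(e)) return(-Inf)
  1 - sum(e^2) / sum((y - mean(y))^2)
}

#' Leave-many-out cross-validated Q2
#'
#' Repeatedly leaves out a random `leave_fraction` of the compounds, refits
#' on the rest and predicts the left-out block. Per repeat,
#' Q2 = 1 - PRESS_out / TSS_out with TSS_out about the training mean; the
#' mean over repeats is returned.
#'
#' @param x descriptor matrix/data.frame.
#' @param y numeric response.
#' @param leave_fraction fraction left out each repeat, in (0, 0.5].
#' @param repeats number of random groups (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return mean Q2_LMO; per-repeat values in attribute `"per_repeat"`.
#' @export
lmo_cv <- function(x, y, leave_fraction = 0.3, repeats = 1000, seed = NULL) {
  if (leave_fraction <= 0 || leave_fraction > 0.5)
    stop("leave_fraction must be in (0, 0.5]")
  X <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(X)
  m <- max(1L, round(n * leave_fraction))
  if (n - m <= ncol(X) + 1L)
    stop("left-in group too small to fit the model")
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  q2 <- vapply(seq_len(repeats), function(r) {
    out <- sample.int(n, m)
    Xi <- cbind(1, X[-out, , drop = FALSE])
    fit <- stats::lm.fit(Xi, y[-out])
    pred <- drop(cbind(1, X[out, , drop = FALSE]) %*% fit$coefficients)
    press <- sum((y[out] - pred)^2)
    tss <- sum((y[out] - mean(y[-out]))^2)
    1 - press / tss
  }, numeric(1))
  structure(mean(q2), per_repeat = q2)
}

#' Y-scrambling (response randomization) check
#'
#' Permutes the response, refits the model on the untouched descriptors and
#' records R2, Q2_LOO and RMSE per iteration. Means near zero (R2) and below
#' zero (Q2) indicate the original model is not a chance correlation.
#'
#' @param x descriptor matrix/data.frame.
#' @param y numeric response.
#' @param iterations number of scrambles (the conventional battery uses
#'   2000).
#' @param seed optional RNG seed.
#' @param permutations optional list of index vectors overriding the random
#'   permutations (for reproducibility studies).
#' @return list of class `"y_scramble"` with `r2_mean`, `q2_mean`,
#'   `rmse_mean` and the per-iteration vectors.
#' @export
y_scramble <- function(x, y, iterations = 2000, seed = NULL,
                       permutations = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  X <- as.matrix(x); y <- as.numeric(y)
  n <- length(y)
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  if (!is.null(permutations)) iterations <- length(permutations)
  Xi <- cbind(1, X)
  tssf <- function(v) sum((v - mean(v))^2)
  r2 <- q2 <- rmse <- numeric(iterations)
  for (i in seq_len(iterations)) {
    perm <- if (is.null(permutations)) sample.int(n) else permutations[[i]]
    ys <- y[perm]
    res <- stats::lm.fit(Xi, ys)$residuals
    r2[i] <- 1 - sum(res^2) / tssf(ys)
    q2[i] <- q2_loo(X, ys)
    rmse[i] <- sqrt(mean(res^2))
  }
  structure(list(iterations = iterations, r2_mean = mean(r2),
                 q2_mean = mean(q2), rmse_mean = mean(rmse),
                 r2 = r2, q2 = q2, rmse = rmse, seed = seed),
            class = "y_scramble")
}

#' @export
print.y_scramble <- function(x, ...) {
  cat(sprintf("Y-scrambling (%d iterations): mean R2 = %.4f, mean Q2 = %.4f, mean RMSE = %.4f\n",
              x$iterations, x$r2_mean, x$q2_mean, x$rmse_mean))
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
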