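# The multi-linear QSAR model: one fitting function returning a classed
# object, with the usual complement of methods. Internals are plain QR least
# squares through lm.fit; everything else in the package (cross-validation,
# external statistics, applicability domain, screening) consumes this object.

#' Convert IC50 (nM) to pIC50 and back
#'
#' pIC50 = -log10(IC50 in molar) = 9 - log10(IC50 in nM).
#'
#' @param ic50_nM IC50 in nanomolar (positive).
#' @param pic50 pIC50 value.
#' @return the converted value(s).
#' @examples
#' pic50_from_ic50(0.095)  # 10.022
#' pic50_from_ic50(1)      # 9
#' @export
pic50_from_ic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM) | ic50_nM <= 0))
    stop("ic50_nM must be positive and finite")
  -log10(ic50_nM * 1e-9)
}

#' @rdname pic50_from_ic50
#' @export
ic50_from_pic50 <- function(pic50) 10^(9 - pic50)

#' Fit a multi-linear QSAR model
#'
#' Ordinary least squares of an activity (pIC50) on a set of molecular
#' descriptors. `qsar_mlr()` is generic: give it a formula plus data, or a
#' descriptor matrix/data.frame plus a response vector. The returned object
#' supports `print`, `summary` (the full internal validation battery),
#' `coef`, `predict`, `residuals`, `fitted`, `plot` (Williams plot) and
#' `simulate`.
#'
#' @param x a formula or a descriptor matrix/data.frame (compounds x
#'   descriptors, no missing values).
#' @param ... further arguments passed to methods.
#' @return an object of class `"qsar_mlr"` with components
#'   `coefficients` (intercept first), `descriptor_names`, `fitted.values`,
#'   `residuals`, `hat` (leverages), `sigma`, `n`, `p`, `r.squared`, and the
#'   training data (`X`, `y`).
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
#' d$y <- 1 + 2 * d$x1 - 3 * d$x2 + rnorm(30, sd = 0.1)
#' fit <- qsar_mlr(y ~ x1 + x2, data = d)
#' coef(fit)
#' @export
qsar_mlr <- function(x, ...) UseMethod("qsar_mlr")

#' @rdname qsar_mlr
#' @param data data.frame holding the formula's variables.
#' @export
qsar_mlr.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  qsar_mlr.default(X, y, ...)
}

#' @rdname qsar_mlr
#' @param y numeric response (pIC50), same length as `nrow(x)`.
#' @export
qsar_mlr.default <- function(x, y, ...) {
  X <- as.matrix(x)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (anyNA(X) || anyNA(y)) stop("missing values in descriptors or response")
  if (n <= p + 1L) stop("need more compounds (", n, ") than descriptors + 1 (",
                        p + 1L, ")")
  Xi <- cbind("(Intercept)" = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_$pivot[(qr_$rank + 1L):ncol(Xi)]]
    stop("rank-deficient descriptor matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(Xi, y)
  beta <- fit$coefficients
  res <- unname(fit$residuals)
  fitted <- unname(fit$fitted.values)
  h <- .hat_values(Xi)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = beta,
    descriptor_names = colnames(X),
    fitted.values = fitted,
    residuals = res,
    hat = h,
    sigma = sqrt(rss / (n - p - 1)),
    n = n, p = p,
    r.squared = if (tss > 0) 1 - rss / tss else 1,
    X = X, y = y,
    coef_uncertainties = NULL,
    provenance = "fitted"),
    class = "qsar_mlr")
}

.hat_values <- function(Xi) {
  q <- qr.Q(qr(Xi))
  unname(rowSums(q^2))
}

#' The published arginase-I pIC50 equation
#'
#' The frozen six-descriptor multi-linear equation relating arginase-I
#' inhibitory potency (pIC50, IC50 in molar) to the descriptors
#' rsa, com_lipohyd_3A, fringNdon3B, fsp2OC9B, fHringC2B and fringCC3B,
#' with the reported coefficient uncertainties attached. The model was
#' trained on 119 compounds; no training data ship with it, so methods
#' needing residuals or leverages are unavailable for this object.
#'
#' @return a `"qsar_mlr"` object holding the published coefficients.
#' @examples
#' m <- published_arginase_model()
#' predict(m, data.frame(rsa = 0, com_lipohyd_3A = 0, fringNdon3B = 0,
#'                       fsp2OC9B = 0, fHringC2B = 0, fringCC3B = 0))
#' @export
published_arginase_model <- function() {
  cf <- c("(Intercept)" = -7.008, rsa = 19.791, com_lipohyd_3A = 0.344,
          fringNdon3B = 0.905, fsp2OC9B = 0.402, fHringC2B = -0.375,
          fringCC3B = -0.567)
  un <- c("(Intercept)" = 2.115, rsa = 3.496, com_lipohyd_3A = 0.067,
          fringNdon3B = 0.125, fsp2OC9B = 0.16, fHringC2B = 0.069,
          fringCC3B = 0.205)
  structure(list(
    coefficients = cf,
    descriptor_names = names(cf)[-1],
    fitted.values = NULL, residuals = NULL, hat = NULL,
    sigma = NA_real_, n = 119L, p = 6L, r.squared = NA_real_,
    X = NULL, y = NULL,
    coef_uncertainties = un,
    provenance = "published arginase-I equation"),
    class = "qsar_mlr")
}

#' @export
print.qsar_mlr <- function(x, digits = 4, ...) {
  cat("Multi-linear QSAR model (", x$provenance, ")\n", sep = "")
  cat("  n =", x$n, " descriptors =", x$p, "\n")
  cf <- format(round(x$coefficients, digits))
  if (!is.null(x$coef_uncertainties))
    cf <- paste0(cf, " (+/-", format(round(x$coef_uncertainties, digits)), ")")
  cat(paste0("  ", format(names(x$coefficients)), "  ", cf), sep = "\n")
  if (is.finite(x$r.squared)) cat(sprintf("  R2 = %.4f\n", x$r.squared))
  invisible(x)
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
residuals.qsar_mlr <- function(object, ...) {
  if (is.null(object$residuals))
    stop("no residuals: model carries no training data")
  object$residuals
}

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted.values

#' Predict pIC50 for new descriptor vectors
#'
#' @param object a `"qsar_mlr"` model.
#' @param newdata data.frame/matrix with (at least) the model's descriptor
#'   columns, or a named numeric vector; omitted to return fitted values.
#' @param ... unused.
#' @return numeric vector of predicted pIC50.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted.values))
      stop("no training data; supply newdata")
    return(object$fitted.values)
  }
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  X <- as.data.frame(newdata)
  missing <- setdiff(object$descriptor_names, colnames(X))
  if (length(missing))
    stop("newdata lacks descriptor(s): ", paste(missing, collapse = ", "))
  M <- as.matrix(X[, object$descriptor_names, drop = FALSE])
  storage.mode(M) <- "double"
  drop(cbind(1, M) %*% object$coefficients)
}

#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted.values) || !is.finite(object$sigma))
    stop("simulate needs a model fitted to training data")
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim,
    object$fitted.values + stats::rnorm(object$n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Williams plot of a fitted QSAR model
#'
#' Standardized residuals against leverage for the training compounds, with
#' the warning leverage h* = 3(p+1)/n and the +/-3 standardized-residual
#' applicability-domain boundaries. External compounds can be overlaid via
#' `newdata` (their residuals need `newy`).
#'
#' @param x a fitted `"qsar_mlr"`.
#' @param newdata optional external descriptor data.frame to overlay.
#' @param newy optional observed activities for `newdata`.
#' @param ... passed to [plot()].
#' @return invisibly, the data.frame of (h, std_residual, set) that was
#'   plotted.
#' @export
plot.qsar_mlr <- function(x, newdata = NULL, newy = NULL, ...) {
  lev <- leverage_analysis(x)
  df <- data.frame(h = lev$h, std_residual = lev$std_residuals,
                   set = "train", stringsAsFactors = FALSE)
  if (!is.null(newdata)) {
    le <- leverage_analysis(x, newdata)
    stde <- if (!is.null(newy))
      (newy - predict(x, newdata)) / x$sigma else rep(NA_real_, nrow(newdata))
    df <- rbind(df, data.frame(h = le$h, std_residual = stde, set = "external"))
  }
  plot(df$h, df$std_residual,
       pch = ifelse(df$set == "train", 19, 17),
       col = ifelse(df$set == "train", "grey30", "steelblue"),
       xlab = "leverage h", ylab = "standardized residual",
       main = "Williams plot", ...)
  graphics::abline(v = lev$h_star, lty = 2)
  graphics::abline(h = c(-3, 3), lty = 3)
  invisible(df)
}
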