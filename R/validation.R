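# The validation battery: internal (training) statistics, cross-validated
# statistics, external predictivity, and leverage-based applicability domain.

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2), with population
#' (1/n) moments. Symmetric in its arguments; 1 only for perfect agreement.
#'
#' @param x,y numeric vectors of equal length.
#' @return CCC in [-1, 1].
#' @export
ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Random training/prediction split
#'
#' Reproducible random split of compound ids: `round(n * fraction)` ids go
#' to training, the remainder to the prediction (external) set.
#'
#' @param ids vector of compound identifiers (>= 5).
#' @param fraction training fraction (default 0.8, the conventional 80/20).
#' @param seed optional RNG seed.
#' @return list with `train`, `prediction` and the echoed `seed`.
#' @export
random_split <- function(ids, fraction = 0.8, seed = NULL) {
  if (length(ids) < 5L) stop("need at least 5 compounds")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  n <- length(ids)
  ntr <- round(n * fraction)
  tr <- sort(sample.int(n, ntr))
  if (ntr == n) warning("fraction leaves an empty prediction set")
  list(train = ids[tr], prediction = ids[setdiff(seq_len(n), tr)],
       seed = seed)
}

#' Adjusted coefficient of determination
#'
#' R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1).
#'
#' @param r2 coefficient of determination.
#' @param n number of training compounds.
#' @param p number of descriptors.
#' @return adjusted R2.
#' @examples
#' adjusted_r2(0.8926, 119, 6)
#' @export
adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Internal (training-set) validation statistics
#'
#' The fit and leave-one-out statistic family of a fitted model:
#' R2, adjusted R2, Friedman's lack-of-fit (smoothing parameter `lof_d`),
#' RMSE/MAE/RSS over training, Lin's CCC, the residual standard error s,
#' the overall F statistic, and the LOO block (Q2_LOO, RMSE_cv, MAE_cv,
#' PRESS, CCC_cv) computed from hat-shortcut LOO predictions, plus the QUIK
#' quantities Kxx and delta-K.
#'
#' @param model a fitted [qsar_mlr()] (with training data).
#' @param lof_d Friedman LOF smoothing parameter (default 0.5).
#' @return list of class `"qsar_internal_stats"`.
#' @export
internal_stats <- function(model, lof_d = 0.5) {
  if (is.null(model$X)) stop("model carries no training data")
  y <- model$y; n <- model$n; p <- model$p
  res <- model$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  loo_res <- res / (1 - model$hat)
  press <- sum(loo_res^2)
  loo_pred <- y - loo_res
  qk <- quik_filter(model$X, y)
  out <- list(
    n = n, p = p,
    r2 = r2,
    r2_adj = adjusted_r2(r2, n, p),
    lof = (rss / n) / (1 - (p + 1 + lof_d * p) / n)^2,
    rmse_tr = sqrt(rss / n),
    mae_tr = mean(abs(res)),
    rss_tr = rss,
    ccc_tr = ccc(y, model$fitted.values),
    s = sqrt(rss / (n - p - 1)),
    f_stat = (r2 / p) / ((1 - r2) / (n - p - 1)),
    q2_loo = 1 - press / tss,
    rmse_cv = sqrt(press / n),
    mae_cv = mean(abs(loo_res)),
    press_cv = press,
    ccc_cv = ccc(y, loo_pred),
    kxx = qk$kxx,
    delta_k = qk$delta_k)
  class(out) <- "qsar_internal_stats"
  out
}

#' @export
print.qsar_internal_stats <- function(x, ...) {
  cat(sprintf(
    "Internal validation (n = %d, p = %d)\n  R2 = %.4f  R2adj = %.4f  LOF = %.4f\n  RMSEtr = %.4f  MAEtr = %.4f  RSStr = %.4f  CCCtr = %.4f\n  s = %.4f  F = %.4f\n  Q2loo = %.4f  RMSEcv = %.4f  MAEcv = %.4f  PRESS = %.4f  CCCcv = %.4f\n  Kxx = %.4f  deltaK = %.4f\n",
    x$n, x$p, x$r2, x$r2_adj, x$lof, x$rmse_tr, x$mae_tr, x$rss_tr, x$ccc_tr,
    x$s, x$f_stat, x$q2_loo, x$rmse_cv, x$mae_cv, x$press_cv, x$ccc_cv,
    x$kxx, x$delta_k))
  invisible(x)
}

# through-origin regression pieces for one orientation (x -> y):
# slope k = sum(xy)/sum(x^2); r2o = 1 - sum((y - k x)^2) / sum((y - mean y)^2)
.origin_fit <- function(x, y) {
  k <- sum(x * y) / sum(x^2)
  r2o <- 1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
  list(k = k, r2o = r2o)
}

.rm2 <- function(r2, r2o) r2 * (1 - sqrt(pmax(r2 - r2o, 0)))

#' External validation statistics
#'
#' The external predictivity battery for a model applied to a held-out set:
#' RMSE/MAE/PRESS, R2_ext (squared Pearson correlation of observed and
#' predicted), Q2_F1 (training-mean reference), Q2_F2 (external-mean
#' reference), Q2_F3 (variance-scaled), Lin's CCC, the Golbraikh-Tropsha
#' through-origin diagnostics in both orientations (k, k', R2o, R'2o), the
#' r2m metrics (average and delta over orientations) and the angle of the
#' predicted-vs-observed regression from the diagonal.
#'
#' @param model a `"qsar_mlr"` (fitted or published).
#' @param x_ext external descriptor data.frame (>= 3 rows).
#' @param y_ext observed activities for the external set.
#' @param y_train training response used for the Q2_F1/Q2_F3 references;
#'   defaults to the model's own training response.
#' @return list of class `"qsar_external_stats"`.
#' @export
external_stats <- function(model, x_ext, y_ext, y_train = model$y) {
  y <- as.numeric(y_ext)
  if (length(y) < 3L) stop("external set needs >= 3 compounds")
  if (is.null(y_train)) stop("y_train required for a model without training data")
  pred <- predict(model, x_ext)
  nex <- length(y)
  press <- sum((y - pred)^2)
  r2 <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(y, pred)^2
  # orientation 1: observed on x-axis, predicted on y-axis
  o1 <- .origin_fit(y, pred)
  # orientation 2: predicted on x-axis, observed on y-axis
  o2 <- .origin_fit(pred, y)
  rm2_1 <- .rm2(r2, o1$r2o)
  rm2_2 <- .rm2(r2, o2$r2o)
  slope <- stats::cov(y, pred) / stats::var(y)
  out <- list(
    n_ext = nex,
    rmse_ext = sqrt(press / nex),
    mae_ext = mean(abs(y - pred)),
    press_ext = press,
    r2_ext = r2,
    q2_f1 = 1 - press / sum((y - mean(y_train))^2),
    q2_f2 = 1 - press / sum((y - mean(y))^2),
    q2_f3 = 1 - (press / nex) /
      (sum((y_train - mean(y_train))^2) / length(y_train)),
    ccc_ext = ccc(y, pred),
    k = o2$k, k_prime = o1$k,
    r2o = o2$r2o, r2o_prime = o1$r2o,
    rm2_average = (rm2_1 + rm2_2) / 2,
    rm2_delta = abs(rm2_1 - rm2_2),
    regression_angle_deg = atan(slope) * 180 / pi - 45)
  class(out) <- "qsar_external_stats"
  out
}

#' @export
print.qsar_external_stats <- function(x, ...) {
  cat(sprintf(
    "External validation (n = %d)\n  RMSE = %.4f  MAE = %.4f  PRESS = %.4f  R2ext = %.4f\n  Q2F1 = %.4f  Q2F2 = %.4f  Q2F3 = %.4f  CCC = %.4f\n  k = %.4f  k' = %.4f  R2o = %.4f  R'2o = %.4f\n  r2m avg = %.4f  r2m delta = %.4f  angle = %.4f deg\n",
    x$n_ext, x$rmse_ext, x$mae_ext, x$press_ext, x$r2_ext, x$q2_f1, x$q2_f2,
    x$q2_f3, x$ccc_ext, x$k, x$k_prime, x$r2o, x$r2o_prime,
    x$rm2_average, x$rm2_delta, x$regression_angle_deg))
  invisible(x)
}

#' Leverage-based applicability domain analysis
#'
#' Hat values h = x (X'X)^-1 x' (intercept included) for the training
#' compounds and, optionally, query compounds; the warning leverage
#' h* = 3 (p + 1) / n_train; standardized training residuals (residual / s);
#' and in-domain flags: h <= h* and, where residuals exist,
#' |standardized residual| <= `resid_cutoff`.
#'
#' @param model a fitted [qsar_mlr()].
#' @param x_query optional descriptor data.frame of query compounds; omitted
#'   to analyse the training set itself.
#' @param resid_cutoff standardized-residual boundary (default 3).
#' @return list of class `"qsar_leverage"` with `h`, `h_star`,
#'   `std_residuals` (training only, else NA), `in_domain`.
#' @export
leverage_analysis <- function(model, x_query = NULL, resid_cutoff = 3) {
  if (is.null(model$X)) stop("model carries no training descriptor matrix")
  Xi <- cbind(1, model$X)
  XtXinv <- tryCatch(solve(crossprod(Xi)), error = function(e)
    stop("singular X'X for the training block"))
  if (is.null(x_query)) {
    h <- model$hat
    stdres <- model$residuals / model$sigma
  } else {
    if (is.numeric(x_query) && is.null(dim(x_query)))
      x_query <- as.data.frame(as.list(x_query))
    Xq <- as.data.frame(x_query)
    missing <- setdiff(model$descriptor_names, colnames(Xq))
    if (length(missing))
      stop("query lacks descriptor(s): ", paste(missing, collapse = ", "))
    M <- cbind(1, as.matrix(Xq[, model$descriptor_names, drop = FALSE]))
    storage.mode(M) <- "double"
    h <- unname(rowSums((M %*% XtXinv) * M))
    stdres <- rep(NA_real_, length(h))
  }
  h_star <- 3 * (model$p + 1) / model$n
  in_dom <- h <= h_star & (is.na(stdres) | abs(stdres) <= resid_cutoff)
  structure(list(h = h, h_star = h_star, std_residuals = stdres,
                 in_domain = in_dom, resid_cutoff = resid_cutoff),
            class = "qsar_leverage")
}

#' @export
print.qsar_leverage <- function(x, ...) {
  cat(sprintf("Applicability domain: h* = %.4f; %d/%d in domain\n",
              x$h_star, sum(x$in_domain), length(x$in_domain)))
  invisible(x)
}

#' Full validation summary of a fitted QSAR model
#'
#' Bundles [internal_stats()] with, when an external set is supplied,
#' [external_stats()], and optionally [lmo_cv()] and [y_scramble()].
#'
#' @param object a fitted [qsar_mlr()].
#' @param x_ext,y_ext optional external descriptor data and response.
#' @param lmo repeats for leave-many-out (0 to skip; default 0).
#' @param yscramble iterations of Y-scrambling (0 to skip; default 0).
#' @param seed RNG seed for the stochastic blocks.
#' @param ... unused.
#' @return list of class `"summary.qsar_mlr"`.
#' @export
summary.qsar_mlr <- function(object, x_ext = NULL, y_ext = NULL,
                             lmo = 0, yscramble = 0, seed = NULL, ...) {
  out <- list(model = object, internal = internal_stats(object))
  if (!is.null(x_ext))
    out$external <- external_stats(object, x_ext, y_ext)
  if (lmo > 0)
    out$q2_lmo <- as.numeric(lmo_cv(object$X, object$y, repeats = lmo,
                                    seed = seed))
  if (yscramble > 0)
    out$yscramble <- y_scramble(object$X, object$y, iterations = yscramble,
                                seed = seed)
  out$leverage <- leverage_analysis(object)
  class(out) <- "summary.qsar_mlr"
  out
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  print(x$model)
  print(x$internal)
  if (!is.null(x$q2_lmo)) cat(sprintf("  Q2lmo = %.4f\n", x$q2_lmo))
  if (!is.null(x$yscramble)) print(x$yscramble)
  if (!is.null(x$external)) print(x$external)
  print(x$leverage)
  invisible(x)
}
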