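test_that("random split reproduces the 80/20 convention", {
  sp <- random_split(paste0("c", 1:149), 0.8, seed = 1)
  expect_length(sp$train, 119)
  expect_length(sp$prediction, 30)
  expect_length(intersect(sp$train, sp$prediction), 0)
  sp2 <- random_split(paste0("c", 1:149), 0.8, seed = 1)
  expect_identical(sp, sp2)
  expect_warning(full <- random_split(letters[1:10], 1.0), "empty")
  expect_length(full$prediction, 0)
})

test_that("internal statistics match direct formulas on a random instance", {
  set.seed(50)
  n <- 25; p <- 3
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- 1 + drop(X %*% c(1, -2, 0.5)) + rnorm(n, sd = 0.5)
  fit <- qsar_mlr(X, y)
  st <- internal_stats(fit)
  lmfit <- lm(y ~ X)
  res <- unname(residuals(lmfit))
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  expect_equal(st$r2, r2, tolerance = 1e-10)
  expect_equal(st$r2_adj, 1 - (1 - r2) * (n - 1) / (n - p - 1), tolerance = 1e-10)
  expect_equal(st$rmse_tr, sqrt(rss / n), tolerance = 1e-10)
  expect_equal(st$mae_tr, mean(abs(res)), tolerance = 1e-10)
  expect_equal(st$rss_tr, rss, tolerance = 1e-10)
  expect_equal(st$s, sqrt(rss / (n - p - 1)), tolerance = 1e-10)
  expect_equal(st$f_stat, (r2 / p) / ((1 - r2) / (n - p - 1)), tolerance = 1e-10)
  expect_equal(st$lof, (rss / n) / (1 - (p + 1 + 0.5 * p) / n)^2, tolerance = 1e-10)
  h <- unname(hatvalues(lmfit))
  press <- sum((res / (1 - h))^2)
  expect_equal(st$press_cv, press, tolerance = 1e-8)
  expect_equal(st$q2_loo, 1 - press / tss, tolerance = 1e-10)
  expect_equal(st$rmse_cv, sqrt(press / n), tolerance = 1e-10)
  # CCC against the covariance-form definition
  fitv <- unname(fitted(lmfit))
  ccc_oracle <- function(a, b) {
    n <- length(a)
    2 * cov(a, b) * (n - 1) / n /
      (var(a) * (n - 1) / n + var(b) * (n - 1) / n + (mean(a) - mean(b))^2)
  }
  expect_equal(st$ccc_tr, ccc_oracle(y, fitv), tolerance = 1e-10)
  expect_lte(st$q2_loo, st$r2)
})

test_that("a perfect fit yields the boundary statistics", {
  set.seed(51)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- 2 + drop(X %*% c(1, 1, 1))
  st <- internal_stats(qsar_mlr(X, y))
  expect_equal(st$r2, 1, tolerance = 1e-12)
  expect_equal(st$r2_adj, 1, tolerance = 1e-12)
  expect_equal(st$ccc_tr, 1, tolerance = 1e-10)
  expect_equal(st$rmse_tr, 0, tolerance = 1e-8)
})

test_that("external statistics equal 1 under perfect prediction", {
  set.seed(52)
  Xtr <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("d", 1:3)))
  ytr <- 1 + drop(Xtr %*% c(2, -1, 1))
  fit <- qsar_mlr(Xtr, ytr)
  Xe <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("d", 1:3)))
  ye <- drop(predict(fit, Xe))      # exactly the model's predictions
  ex <- external_stats(fit, Xe, ye)
  for (f in c("r2_ext", "q2_f1", "q2_f2", "q2_f3", "ccc_ext", "k", "k_prime"))
    expect_equal(ex[[f]], 1, tolerance = 1e-10)
  expect_equal(ex$rm2_delta, 0, tolerance = 1e-10)
  expect_equal(ex$rmse_ext, 0, tolerance = 1e-8)
})

test_that("constant predictions floor Q2F2 at or below zero", {
  set.seed(53)
  Xtr <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, paste0("d", 1:3)))
  ytr <- rnorm(30)
  fit <- qsar_mlr(Xtr, ytr)
  # external compounds identical in descriptors -> identical predictions
  Xe <- Xtr[rep(1, 5), ]
  ye <- rnorm(5)
  ex <- external_stats(fit, Xe, ye)
  expect_lte(ex$q2_f2, 0 + 1e-12)
})

test_that("external statistics match a direct-formula oracle field by field", {
  set.seed(54)
  Xtr <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(NULL, c("a", "b")))
  ytr <- 1 + drop(Xtr %*% c(1, -1)) + rnorm(25, sd = 0.4)
  fit <- qsar_mlr(Xtr, ytr)
  Xe <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  ye <- 1 + drop(Xe %*% c(1, -1)) + rnorm(10, sd = 0.4)
  ex <- external_stats(fit, Xe, ye)
  pred <- predict(fit, Xe)
  press <- sum((ye - pred)^2)
  expect_equal(ex$press_ext, press, tolerance = 1e-10)
  expect_equal(ex$rmse_ext, sqrt(press / 10), tolerance = 1e-10)
  expect_equal(ex$mae_ext, mean(abs(ye - pred)), tolerance = 1e-10)
  expect_equal(ex$r2_ext, cor(ye, pred)^2, tolerance = 1e-10)
  expect_equal(ex$q2_f1, 1 - press / sum((ye - mean(ytr))^2), tolerance = 1e-10)
  expect_equal(ex$q2_f2, 1 - press / sum((ye - mean(ye))^2), tolerance = 1e-10)
  expect_equal(ex$q2_f3,
               1 - (press / 10) / (sum((ytr - mean(ytr))^2) / 25),
               tolerance = 1e-10)
  expect_lte(ex$q2_f2, ex$q2_f1 + 1e-12)
  k <- sum(ye * pred) / sum(pred^2)
  kp <- sum(ye * pred) / sum(ye^2)
  expect_equal(ex$k, k, tolerance = 1e-10)
  expect_equal(ex$k_prime, kp, tolerance = 1e-10)
  r2o <- 1 - sum((ye - k * pred)^2) / sum((ye - mean(ye))^2)
  r2op <- 1 - sum((pred - kp * ye)^2) / sum((pred - mean(pred))^2)
  expect_equal(ex$r2o, r2o, tolerance = 1e-10)
  expect_equal(ex$r2o_prime, r2op, tolerance = 1e-10)
  r2 <- cor(ye, pred)^2
  rm2a <- r2 * (1 - sqrt(max(r2 - r2op, 0)))
  rm2b <- r2 * (1 - sqrt(max(r2 - r2o, 0)))
  expect_equal(ex$rm2_average, (rm2a + rm2b) / 2, tolerance = 1e-10)
  expect_equal(ex$rm2_delta, abs(rm2a - rm2b), tolerance = 1e-10)
  slope <- cov(ye, pred) / var(ye)
  expect_equal(ex$regression_angle_deg, atan(slope) * 180 / pi - 45,
               tolerance = 1e-10)
})

test_that("leverage analysis reproduces hat-matrix identities", {
  set.seed(55)
  n <- 40; p <- 4
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- rnorm(n)
  fit <- qsar_mlr(X, y)
  lev <- leverage_analysis(fit)
  expect_equal(sum(lev$h), p + 1, tolerance = 1e-8)
  expect_true(all(lev$h >= 1 / n - 1e-12 & lev$h <= 1 + 1e-12))
  expect_equal(lev$h_star, 3 * (p + 1) / n)
  expect_equal(lev$std_residuals, residuals(fit) / fit$sigma, tolerance = 1e-12)
  # a query at the training mean has the minimal leverage 1/n
  xbar <- colMeans(X)
  lq <- leverage_analysis(fit, rbind(xbar))
  expect_equal(lq$h, 1 / n, tolerance = 1e-10)
  expect_true(lq$in_domain)
  # far outside the training cloud -> out of domain
  lfar <- leverage_analysis(fit, rbind(10 * apply(X, 2, max)))
  expect_false(lfar$in_domain)
})

test_that("pipeline recovers the planted population R2 across seeds", {
  stats <- t(vapply(1:8, function(s) {
    d <- make_regression_dataset(seed = 100 + s)
    sp <- random_split(seq_along(d$y), 0.8, seed = s)
    Xs <- as.matrix(d$X[, d$truth$informative])
    fit <- qsar_mlr(Xs[sp$train, ], d$y[sp$train])
    st <- internal_stats(fit)
    ex <- external_stats(fit, Xs[sp$prediction, ], d$y[sp$prediction])
    c(r2 = st$r2, q2 = st$q2_loo, r2ext = ex$q2_f2)
  }, numeric(3)))
  expect_lt(abs(mean(stats[, "r2"]) - 0.9), 0.05)
  expect_lt(abs(mean(stats[, "q2"]) - 0.9), 0.05)
  expect_lt(abs(mean(stats[, "r2ext"]) - 0.9), 0.05)
})

test_that("summary bundles the battery and prints", {
  set.seed(56)
  d <- make_regression_dataset(n_compounds = 60, n_pool = 5, seed = 9)
  fit <- qsar_mlr(as.matrix(d$X[, 1:3]), d$y)
  sm <- summary(fit, lmo = 20, yscramble = 20, seed = 3)
  expect_s3_class(sm, "summary.qsar_mlr")
  expect_true(is.numeric(sm$q2_lmo))
  expect_output(print(sm), "Internal validation")
})
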