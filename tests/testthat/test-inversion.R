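test_that("linear-Gaussian free energy matches the closed form", {
  # with a linear forward model and pinned noise precision, the converged
  # free energy must equal the analytic log marginal likelihood
  set.seed(41)
  for (rep in 1:3) {
    n <- 40L; p <- 3L
    X <- matrix(rnorm(n * p), n, p)
    v0 <- c(0.5, 0.25, 1)
    s2 <- 0.7
    theta_true <- rnorm(p, 0, sqrt(v0))
    y <- as.numeric(X %*% theta_true) + rnorm(n, sd = sqrt(s2))
    fit <- vl_fit(y, function(th) as.numeric(X %*% th),
                  mu0 = rep(0, p), var0 = v0,
                  lambda0 = log(1 / s2), lambda_var = 0,
                  tol = 1e-8, max_iter = 50)
    expect_lt(abs(fit$F - gaussian_log_evidence(y, X, v0, s2)), 0.1)
    # accepted-step trace is monotone non-decreasing
    expect_true(all(diff(fit$trace) > -1e-3))
    expect_true(fit$converged)
  }
})

test_that("linear posteriors shrink and scale as Bayes prescribes", {
  set.seed(42)
  n <- 60L; p <- 4L
  X <- matrix(rnorm(n * p), n, p)
  v0 <- rep(0.5, p)
  y <- as.numeric(X %*% rnorm(p, 0, 0.5)) + rnorm(n, sd = 0.6)
  fit <- vl_fit(y, function(th) as.numeric(X %*% th), rep(0, p), v0,
                lambda0 = log(1 / 0.36), lambda_var = 0, tol = 1e-8)
  # posterior variance never exceeds prior variance
  expect_true(all(diag(fit$cov) <= v0 + 1e-10))
  # posterior mean equals the ridge solution
  ridge <- solve(crossprod(X) / 0.36 + diag(1 / v0, p),
                 crossprod(X, y) / 0.36)
  expect_equal(fit$mean, as.numeric(ridge), tolerance = 1e-6)
  # scaling data and noise SD jointly leaves the parameter posterior alone
  k <- 3
  fit_k <- vl_fit(k * y, function(th) as.numeric((k * X) %*% th),
                  rep(0, p), v0, lambda0 = log(1 / (k^2 * 0.36)),
                  lambda_var = 0, tol = 1e-8)
  expect_equal(fit_k$mean, fit$mean, tolerance = 1e-6)
  expect_equal(fit_k$cov, fit$cov, tolerance = 1e-6)
})

test_that("a redundant duplicated regressor costs only complexity", {
  # adding an exact copy of an existing column cannot improve fit; the
  # evidence penalty for the extra parameter is bounded by the occam term
  set.seed(43)
  n <- 50L
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = 0.5)
  F1 <- vl_fit(y, function(th) th[1] * x, 0, 0.25,
               lambda0 = log(4), lambda_var = 0, tol = 1e-8)$F
  X2 <- cbind(x, x)
  F2 <- vl_fit(y, function(th) as.numeric(X2 %*% th), c(0, 0),
               c(0.25, 0.25), lambda0 = log(4), lambda_var = 0,
               tol = 1e-8)$F
  o1 <- gaussian_log_evidence(y, matrix(x), 0.25, 0.25)
  o2 <- gaussian_log_evidence(y, X2, c(0.25, 0.25), 0.25)
  expect_lt(abs(F1 - o1), 0.1)
  expect_lt(abs(F2 - o2), 0.1)
  # duplicating a column is equivalent to doubling its prior variance:
  # the evidence may move either way, but only by a modest occam factor
  o_eq <- gaussian_log_evidence(y, matrix(x), 0.5, 0.25)
  expect_lt(abs(F2 - o_eq), 0.1)
  expect_lt(abs(F1 - F2), 1.5)
})

test_that("free noise precision recovers the generating noise level", {
  set.seed(44)
  n <- 400L
  X <- matrix(rnorm(n * 2), n, 2)
  s2 <- 0.49
  y <- as.numeric(X %*% c(0.5, -0.3)) + rnorm(n, sd = sqrt(s2))
  fit <- vl_fit(y, function(th) as.numeric(X %*% th), c(0, 0),
                c(0.25, 0.25), lambda0 = 0, lambda_var = 16,
                tol = 1e-6, max_iter = 100)
  # lambda is the log precision; compare sd estimates at 15% relative
  expect_lt(abs(exp(-fit$lambda / 2) - sqrt(s2)) / sqrt(s2), 0.15)
})

test_that("noiseless DCM data at the prior mean invert to the prior mean", {
  d <- short_design()
  models <- build_modulatory_space()
  spec <- to_dcm_spec(winning_structural_model(), models[[2]], "sad")
  # prior-mean parameters: all coupling zero, self -1; the output is flat
  Y <- matrix(0, d$n_volumes, 4, dimnames = list(NULL, spec$regions))
  set.seed(9); Y <- Y + rnorm(length(Y), sd = 0.01)
  flat <- structure(list(data = Y, time_s = (seq_len(d$n_volumes) - 1) *
                           d$tr_s, tr_s = d$tr_s, regions = spec$regions),
                    class = "bold_ts")
  fit <- invert_dcm(spec, flat, d, confounds = "none",
                    priors = prior_spec(lambda0 = log(1 / 1e-4),
                                        lambda_var = 0), tol = 1e-4)
  # drift stays small relative to the prior scale (sd 0.25-0.5)
  expect_lt(max(abs(fit$mean)), 0.1)
  expect_true(is.finite(fit$F))
  expect_equal(nrow(fit$posterior), length(fit$mean))
  expect_setequal(unique(fit$posterior$class), c("a", "self", "c", "b"))
})

test_that("the true modulated model beats the null by clear evidence", {
  d <- full_design()
  models <- build_modulatory_space()
  truth <- simulate_truth(2, "sad", design = d)
  noisy <- add_noise(truth$bold, sd = 0.5 * sd(truth$bold$data), seed = 3)
  spec_true <- truth$spec
  spec_null <- to_dcm_spec(winning_structural_model(), models[[3]], "sad")
  f_true <- invert_dcm(spec_true, noisy, d, tol = 0.05)
  f_null <- invert_dcm(spec_null, noisy, d, tol = 0.05)
  expect_gt(f_true$F - f_null$F, 3)
  # the planted B(FG->OFC) is recovered with the right sign
  b_row <- grepl("^B\\.", f_true$posterior$label)
  expect_gt(f_true$posterior$mean[b_row], 0)
})

test_that("invert_dcm validates its inputs", {
  d <- short_design()
  models <- build_modulatory_space()
  spec <- to_dcm_spec(winning_structural_model(), models[[1]], "sad")
  sim <- simulate_truth(1, "sad", design = d)
  bad <- sim$bold
  colnames(bad$data) <- c("V1", "FG", "AMY", "XX")
  bad$regions <- colnames(bad$data)
  expect_error(invert_dcm(spec, bad, d), "regions")
  short <- sim$bold
  short$data <- short$data[1:10, ]
  expect_error(invert_dcm(spec, short, d), "volume count")
  nf <- sim$bold; nf$data[3, 2] <- NaN
  expect_error(invert_dcm(spec, nf, d), "non-finite")
})
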