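test_that("neural derivative implements the bilinear form exactly", {
  spec <- dcm_spec(regions = c("A", "B"),
                   intrinsic_edges = list(c("A", "B")),
                   modulated_edges = list(mod = list(c("A", "B"))),
                   driving = list(inp = "A"))
  A <- matrix(c(-0.5, 0.3, 0, -0.5), 2, 2)
  Bm <- matrix(c(0, 0.2, 0, 0), 2, 2)
  p <- dcm_parameters(spec, A, B = list(mod = Bm),
                      C = list(inp = c(1, 0)))
  expect_equal(neural_derivative(c(0, 0), c(inp = 0, mod = 0), p), c(0, 0))
  # direct matrix-product oracle with the modulator on
  x <- c(0.4, -0.2); u <- c(inp = 1, mod = 1)
  expect_equal(neural_derivative(x, u, p),
               as.numeric((A + Bm) %*% x + c(1, 0)))
  expect_error(neural_derivative(c(1, 2, 3), u, p), "dimension")
})

test_that("a driven scalar node settles at its analytic steady state", {
  spec <- dcm_spec(regions = "A", intrinsic_edges = list(),
                   driving = list(inp = "A"))
  A <- matrix(-0.5, 1, 1)
  p <- dcm_parameters(spec, A, C = list(inp = 1))
  expect_equal(neural_derivative(0, c(inp = 1), p), 1)  # dx/dt = c u
  expect_equal(neural_derivative(2, c(inp = 1), p), 0)  # x* = c/|a| = 2
})

test_that("balloon dynamics have the resting fixed point and limits", {
  h <- list(s = 0, f = 1, v = 1, q = 1)
  d0 <- hemodynamic_derivative(h, x = 0)
  expect_equal(unlist(d0), c(s = 0, f = 0, v = 0, q = 0))
  # overdamped limit: enormous signal decay collapses s
  hemo <- default_hemo(); hemo["kappa"] <- 1e6
  d1 <- hemodynamic_derivative(list(s = 1, f = 1, v = 1, q = 1), 0, hemo)
  expect_lt(d1$s, -1e5)
  expect_error(hemodynamic_derivative(list(s = 0, f = -1, v = 1, q = 1), 0),
               "strictly positive")
})

test_that("sustained neural drive raises flow toward a plateau above 1", {
  hemo <- default_hemo()
  rhs <- function(t, y, parms) {
    d <- hemodynamic_derivative(list(s = y[1], f = y[2], v = y[3],
                                     q = y[4]), x = 0.3, hemo)
    list(c(d$s, d$f, d$v, d$q))
  }
  out <- deSolve::ode(c(0, 1, 1, 1), seq(0, 60, by = 0.5), rhs, NULL)
  f <- out[, 3]
  expect_gt(max(f), 1.05)              # rises
  expect_gt(f[length(f)], 1)           # settles above baseline
  expect_lt(abs(f[length(f)] - f[length(f) - 4]), 1e-3)  # plateau
})

test_that("the observation equation matches hand arithmetic", {
  expect_equal(bold_observation(1, 1), 0)
  expect_gt(bold_observation(1, 0.9), 0)  # less deoxyhemoglobin, more BOLD
  hemo <- default_hemo()
  v <- 1.1; q <- 0.85
  k1 <- 7 * 0.4; k2 <- 2; k3 <- 2 * 0.4 - 0.2
  expect_equal(bold_observation(v, q, hemo),
               100 * 0.02 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v)))
  expect_error(bold_observation(-1, 1), "strictly positive")
})

test_that("simulation is flat with no drive and bitwise deterministic", {
  sim <- simulate_truth(21, design = short_design())
  p0 <- sim$params
  p0$C$faces[] <- 0
  inp <- build_inputs(sim$design)
  y0 <- integrate_and_sample(p0, inp, sim$design)
  expect_true(all(y0$data == 0))
  y1 <- integrate_and_sample(sim$params, inp, sim$design)
  y2 <- integrate_and_sample(sim$params, inp, sim$design)
  expect_identical(y1$data, y2$data)
  # noisy runs reproduce under the same seed
  p <- sim$params; p$noise_sd <- 0.5
  n1 <- integrate_and_sample(p, inp, sim$design, noise = TRUE, seed = 7)
  n2 <- integrate_and_sample(p, inp, sim$design, noise = TRUE, seed = 7)
  expect_identical(n1$data, n2$data)
})

test_that("instability is rejected with the offending eigenvalue named", {
  spec <- dcm_spec(regions = c("A", "B"),
                   intrinsic_edges = list(c("A", "B"), c("B", "A")),
                   driving = list(faces = "A"))
  A <- matrix(c(-0.1, 0.5, 0.5, -0.1), 2, 2)  # eigen max = 0.4 > 0
  p <- dcm_parameters(spec, A, C = list(faces = c(1, 0)))
  d <- short_design()
  expect_error(integrate_and_sample(p, build_inputs(d), d),
               "eigenvalue 0.4000")
})

test_that("integration matches a fine-grid adaptive reference", {
  # single driven region: neural + balloon integrated by deSolve at high
  # accuracy, observed at the volume times
  d <- parse_block_order("NRN", n_volumes = 30, microtime_bins_per_tr = 16)
  spec <- dcm_spec(regions = "A", intrinsic_edges = list(),
                   driving = list(faces = "A"))
  p <- dcm_parameters(spec, matrix(-0.5, 1, 1), C = list(faces = 0.8))
  inp <- build_inputs(d)
  y <- integrate_and_sample(p, inp, d)
  hemo <- default_hemo()
  u_of <- function(t) as.numeric(t %% 63 < 21 | t >= 42)  # N blocks
  rhs <- function(t, s, parms) {
    x <- s[1]
    dh <- hemodynamic_derivative(list(s = s[2], f = s[3], v = s[4],
                                      q = s[5]), x, hemo)
    list(c(-0.5 * x + 0.8 * u_of(t), dh$s, dh$f, dh$v, dh$q))
  }
  tv <- (seq_len(30) - 1) * d$tr_s
  ref <- deSolve::ode(c(0, 0, 1, 1, 1), c(tv, 63), rhs, NULL,
                      rtol = 1e-9, atol = 1e-10)
  y_ref <- bold_observation(ref[seq_len(30), 5], ref[seq_len(30), 6], hemo)
  expect_lt(max(abs(y$data[, 1] - y_ref)) / max(abs(y_ref)), 1e-4)
})

test_that("the weak-drive response is first-order in the driving gain", {
  # the balloon observation is nonlinear, but for small inputs the whole
  # cascade linearises: halving the gain should halve the output
  d <- short_design()
  sim <- simulate_truth(21, design = d, cin = 0.01)
  half <- simulate_truth(21, design = d, cin = 0.005)
  ratio <- max(abs(half$bold$data * 2 - sim$bold$data)) /
    max(abs(sim$bold$data))
  expect_lt(ratio, 0.03)
  # and at full strength the response is visibly sublinear, not scaled
  full <- simulate_truth(21, design = d, cin = 0.8)
  pred <- sim$bold$data * (0.8 / 0.01)
  expect_gt(max(abs(full$bold$data - pred)) / max(abs(full$bold$data)),
            0.05)
})

test_that("doubling microtime resolution barely changes the output", {
  d16 <- parse_block_order(n_volumes = 60, microtime_bins_per_tr = 16)
  d32 <- parse_block_order(n_volumes = 60, microtime_bins_per_tr = 32)
  y16 <- simulate_truth(21, design = d16)$bold$data
  y32 <- simulate_truth(21, design = d32)$bold$data
  expect_lt(max(abs(y16 - y32)) / max(abs(y32)), 1e-3)
})

test_that("region relabeling permutes the simulated output consistently", {
  d <- short_design()
  edges <- list(c("V1", "FG"), c("FG", "AMY"), c("AMY", "OFC"))
  vals <- c(0.35, 0.2, 0.15)
  build <- function(regions) {
    spec <- dcm_spec(regions = regions, intrinsic_edges = edges,
                     driving = list(faces = "V1"))
    A <- matrix(0, 4, 4, dimnames = list(regions, regions))
    for (i in seq_along(edges)) A[edges[[i]][2], edges[[i]][1]] <- vals[i]
    diag(A) <- c(-1, -0.8, -0.9, -1.1)[match(regions,
                                             c("V1", "FG", "AMY", "OFC"))]
    cv <- as.numeric(regions == "V1") * 0.8
    dcm_parameters(spec, A, C = list(faces = cv))
  }
  inp <- build_inputs(d)
  y <- integrate_and_sample(build(c("V1", "FG", "AMY", "OFC")), inp, d)
  y2 <- integrate_and_sample(build(c("OFC", "V1", "AMY", "FG")), inp, d)
  expect_equal(y2$data[, c("V1", "FG", "AMY", "OFC")],
               y$data[, c("V1", "FG", "AMY", "OFC")], tolerance = 1e-12)
})

test_that("time-series tables round-trip through TSV", {
  sim <- simulate_truth(5, design = short_design())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bold_ts(sim$bold, path)
  back <- read_bold_ts(path)
  expect_equal(back$data, sim$bold$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$regions, sim$bold$regions)
})
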