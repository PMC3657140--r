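# Shared fixtures, built in code.

full_design <- function(...) parse_block_order(...)

# A small design (fewer volumes) for tests that only need the machinery,
# not the full scan length.
short_design <- function(n_volumes = 60L, bins = 8L)
  parse_block_order("NHNSNR", n_volumes = n_volumes,
                    microtime_bins_per_tr = bins)

# Noiseless BOLD simulated from the fully connected winner with a given
# modulatory truth (model id) and emotion.
simulate_truth <- function(model_id, emotion = "sad",
                           design = full_design(), b = 0.4, ...) {
  models <- build_modulatory_space()
  spec <- to_dcm_spec(winning_structural_model(), models[[model_id]],
                      emotion)
  params <- default_parameters(spec, b = b, ...)
  inputs <- build_inputs(design)
  list(spec = spec, params = params, design = design,
       bold = integrate_and_sample(params, inputs, design))
}

add_noise <- function(bold, sd, seed) {
  out <- bold
  set.seed(seed)
  out$data <- bold$data + matrix(stats::rnorm(length(bold$data), sd = sd),
                                 nrow(bold$data))
  out
}

# Closed-form Gaussian log marginal likelihood of y under
# y = X theta + e, theta ~ N(0, diag(v0)), e ~ N(0, s2 I): the
# independent oracle for the linear-Gaussian evidence checks.
gaussian_log_evidence <- function(y, X, v0, s2) {
  S <- X %*% diag(v0, ncol(X)) %*% t(X) + diag(s2, length(y))
  ch <- chol(S)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
}
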