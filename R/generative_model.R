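#' Network architecture of a dynamic causal model
#'
#' A `dcm_spec` fixes which couplings exist: intrinsic (always-on) directed
#' edges, modulated edges per modulatory input, and the region(s) receiving
#' each driving input. Edges are directed `c(src, dst)` pairs over the
#' region labels; self-connections are implicit (every region has one) and
#' are not listed as edges.
#'
#' @param regions ordered character vector of region labels.
#' @param intrinsic_edges list of `c(src, dst)` pairs.
#' @param modulated_edges named list (one element per modulatory input) of
#'   lists of `c(src, dst)` pairs; each must be a subset of
#'   `intrinsic_edges`.
#' @param driving named list mapping driving-input name to the region
#'   label(s) it enters.
#' @return object of class `dcm_spec`.
#' @export
dcm_spec <- function(regions = c("V1", "FG", "AMY", "OFC"),
                     intrinsic_edges,
                     modulated_edges = list(),
                     driving = list(faces = "V1")) {
  stopifnot(is.character(regions), !anyDuplicated(regions))
  check_edges <- function(edges, what) {
    for (e in edges) {
      if (length(e) != 2L || !all(e %in% regions))
        stop(sprintf("%s edge must be a pair of region labels: %s",
                     what, paste(e, collapse = "->")))
      if (e[1] == e[2])
        stop("self-connections are implicit and must not be listed as edges")
    }
  }
  check_edges(intrinsic_edges, "intrinsic")
  ikeys <- vapply(intrinsic_edges, paste, "", collapse = "->")
  for (m in names(modulated_edges)) {
    check_edges(modulated_edges[[m]], m)
    mkeys <- vapply(modulated_edges[[m]], paste, "", collapse = "->")
    if (!all(mkeys %in% ikeys))
      stop(sprintf("modulated edges of '%s' are not a subset of intrinsic edges", m))
  }
  for (d in names(driving)) {
    if (!all(driving[[d]] %in% regions))
      stop(sprintf("driving input '%s' targets an unknown region", d))
  }
  inputs <- c(names(driving), names(modulated_edges))
  if (anyDuplicated(inputs)) stop("input names must be distinct")
  structure(list(regions = regions,
                 intrinsic_edges = intrinsic_edges,
                 modulated_edges = modulated_edges,
                 driving = driving,
                 inputs = inputs), class = "dcm_spec")
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat(sprintf("dcm_spec: %d regions (%s); %d intrinsic edges; modulators: %s\n",
              length(x$regions), paste(x$regions, collapse = ", "),
              length(x$intrinsic_edges),
              if (length(x$modulated_edges))
                paste(names(x$modulated_edges), collapse = ", ") else "none"))
  invisible(x)
}

# R x R logical mask with [dst, src] = TRUE for each (src, dst) edge;
# convention throughout: A[i, j] is the influence of region j on region i.
edge_mask <- function(edges, regions) {
  R <- length(regions)
  m <- matrix(FALSE, R, R, dimnames = list(regions, regions))
  for (e in edges) m[e[2], e[1]] <- TRUE
  m
}

#' Default hemodynamic parameters
#'
#' Balloon-windkessel constants per region: signal decay `kappa` (1/s),
#' autoregulation `gamma` (1/s), mean transit time `tau` (s), vessel
#' stiffness `alpha`, resting oxygen extraction `e0`, and resting venous
#' volume fraction `v0` used by the observation equation.
#'
#' @return named numeric vector.
#' @export
default_hemo <- function() {
  c(kappa = 0.64, gamma = 0.32, tau = 2.0, alpha = 0.32, e0 = 0.4, v0 = 0.02)
}

#' Numeric parameterisation of a DCM
#'
#' @param spec a [dcm_spec()].
#' @param A `R x R` intrinsic coupling matrix (Hz); entries must be zero
#'   off the spec's edges and strictly negative on the diagonal.
#' @param B named list of `R x R` modulation matrices (Hz), one per
#'   modulatory input in `spec`; zero off the modulated edges.
#' @param C named list mapping driving-input name to a length-`R` gain
#'   vector (Hz); nonzero only on the input's target regions.
#' @param hemo per-region hemodynamics: either a single vector from
#'   [default_hemo()] (recycled) or an `R x 6` matrix.
#' @param noise_sd observation noise standard deviation (percent signal).
#' @param drift_coeffs coefficients of 1st- and 2nd-order Legendre drift
#'   terms added to the sampled signal (percent signal).
#' @return object of class `dcm_parameters`.
#' @export
dcm_parameters <- function(spec, A, B = list(), C = list(),
                           hemo = default_hemo(),
                           noise_sd = 0, drift_coeffs = c(0, 0)) {
  stopifnot(inherits(spec, "dcm_spec"))
  R <- length(spec$regions)
  A <- as.matrix(A)
  if (!all(dim(A) == R)) stop("A has wrong dimensions")
  amask <- edge_mask(spec$intrinsic_edges, spec$regions)
  if (any(A[!amask & !diag(R)] != 0))
    stop("A has nonzero entries on absent edges")
  if (any(diag(A) >= 0)) stop("diagonal of A must be strictly negative")
  for (m in names(spec$modulated_edges)) {
    Bm <- B[[m]]
    if (is.null(Bm)) stop(sprintf("missing B matrix for modulator '%s'", m))
    if (!all(dim(as.matrix(Bm)) == R)) stop("B has wrong dimensions")
    bmask <- edge_mask(spec$modulated_edges[[m]], spec$regions)
    if (any(as.matrix(Bm)[!bmask] != 0))
      stop(sprintf("B[['%s']] has nonzero entries off its modulated edges", m))
  }
  for (d in names(spec$driving)) {
    cv <- C[[d]]
    if (is.null(cv)) stop(sprintf("missing C vector for driving input '%s'", d))
    if (length(cv) != R) stop("C vector has wrong length")
    off <- !(spec$regions %in% spec$driving[[d]])
    if (any(cv[off] != 0))
      stop(sprintf("C[['%s']] is nonzero outside its target regions", d))
  }
  if (is.null(dim(hemo))) hemo <- matrix(hemo, R, length(hemo), byrow = TRUE,
                                         dimnames = list(spec$regions,
                                                         names(hemo)))
  if (any(hemo[, c("kappa", "gamma", "tau", "alpha", "e0", "v0")] <= 0))
    stop("hemodynamic parameters must be strictly positive")
  if (any(hemo[, "e0"] >= 1) || any(hemo[, "alpha"] >= 1))
    stop("e0 and alpha must lie in (0, 1)")
  structure(list(spec = spec, A = A, B = B, C = C, hemo = hemo,
                 noise_sd = noise_sd, drift_coeffs = drift_coeffs),
            class = "dcm_parameters")
}

#' Build default parameters for a spec
#'
#' Population-typical values: off-diagonal intrinsic coupling `a` on every
#' intrinsic edge, self-connections `self`, modulation `b` on every
#' modulated edge, driving gain `cin` on each driving target.
#'
#' @inheritParams dcm_parameters
#' @param a,self,b,cin coupling values in Hz.
#' @param ... passed to [dcm_parameters()].
#' @export
default_parameters <- function(spec, a = 0.2, self = -1.0, b = 0.4,
                               cin = 0.8, ...) {
  R <- length(spec$regions)
  A <- matrix(0, R, R, dimnames = list(spec$regions, spec$regions))
  A[edge_mask(spec$intrinsic_edges, spec$regions)] <- a
  diag(A) <- self
  B <- lapply(spec$modulated_edges, function(edges) {
    Bm <- matrix(0, R, R, dimnames = dimnames(A))
    Bm[edge_mask(edges, spec$regions)] <- b
    Bm
  })
  C <- lapply(spec$driving, function(targets) {
    cv <- numeric(R)
    cv[spec$regions %in% targets] <- cin
    cv
  })
  dcm_parameters(spec, A, B, C, ...)
}

#' Bilinear neural state derivative
#'
#' `dx/dt = (A + sum_j u_j B_j) x + C u` for the current inputs `u`.
#'
#' @param x length-`R` neural state vector.
#' @param u named numeric vector of input values (names matching the
#'   spec's inputs; absent inputs are treated as 0).
#' @param params a [dcm_parameters()].
#' @return length-`R` derivative.
#' @export
neural_derivative <- function(x, u, params) {
  stopifnot(inherits(params, "dcm_parameters"))
  R <- nrow(params$A)
  if (length(x) != R) stop("state dimension mismatch")
  M <- params$A
  drive <- numeric(R)
  for (m in names(params$B)) {
    um <- if (m %in% names(u)) u[[m]] else 0
    M <- M + um * params$B[[m]]
  }
  for (d in names(params$C)) {
    ud <- if (d %in% names(u)) u[[d]] else 0
    drive <- drive + params$C[[d]] * ud
  }
  as.numeric(M %*% x + drive)
}

#' Balloon-windkessel hemodynamic derivative
#'
#' States per region: vasodilatory signal `s`, normalised blood flow `f`,
#' venous volume `v`, deoxyhemoglobin content `q`. With oxygen extraction
#' `E(f) = 1 - (1 - e0)^(1/f)`:
#' `ds/dt = x - kappa s - gamma (f - 1)`; `df/dt = s`;
#' `dv/dt = (f - v^(1/alpha)) / tau`;
#' `dq/dt = (f E(f)/e0 - v^(1/alpha) q / v) / tau`.
#'
#' @param h named list or vector with elements `s`, `f`, `v`, `q`
#'   (scalars or per-region vectors).
#' @param x neural state (same length).
#' @param hemo named vector as from [default_hemo()].
#' @return list with derivatives `s`, `f`, `v`, `q`.
#' @export
hemodynamic_derivative <- function(h, x, hemo = default_hemo()) {
  if (any(h$f <= 0) || any(h$v <= 0) || any(h$q <= 0))
    stop("f, v and q must be strictly positive")
  fv <- h$v^(1 / hemo[["alpha"]])
  ef <- 1 - (1 - hemo[["e0"]])^(1 / h$f)
  list(s = x - hemo[["kappa"]] * h$s - hemo[["gamma"]] * (h$f - 1),
       f = h$s,
       v = (h$f - fv) / hemo[["tau"]],
       q = (h$f * ef / hemo[["e0"]] - fv * h$q / h$v) / hemo[["tau"]])
}

#' BOLD observation equation
#'
#' `y = 100 v0 [k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)]` in percent signal
#' change, with the 1.5 T coefficients `k1 = 7 e0`, `k2 = 2`,
#' `k3 = 2 e0 - 0.2`.
#'
#' @param v,q venous volume and deoxyhemoglobin state (positive).
#' @param hemo named vector as from [default_hemo()].
#' @return BOLD value(s), percent signal change.
#' @export
bold_observation <- function(v, q, hemo = default_hemo()) {
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be strictly positive")
  e0 <- hemo[["e0"]]
  k1 <- 7 * e0; k2 <- 2; k3 <- 2 * e0 - 0.2
  100 * hemo[["v0"]] * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

# Assemble the microtime input matrix (bins x inputs) for a spec.
input_matrix <- function(spec, inputs) {
  stopifnot(inherits(inputs, "input_functions"))
  lookup <- list(faces = inputs$u_faces, neutral = inputs$u_neutral,
                 happy = inputs$u_happy, sad = inputs$u_sad,
                 fear = inputs$u_fear)
  U <- vapply(spec$inputs, function(nm) {
    if (is.null(lookup[[nm]])) stop(sprintf("no input function named '%s'", nm))
    lookup[[nm]]
  }, numeric(length(inputs$time)))
  matrix(U, ncol = length(spec$inputs),
         dimnames = list(NULL, spec$inputs))
}

# Collapse params into the (A, B-cube, C-matrix) arrays the integrator uses.
param_arrays <- function(params) {
  spec <- params$spec
  R <- nrow(params$A)
  nu <- length(spec$inputs)
  Bcube <- array(0, c(R, R, nu))
  Cmat <- matrix(0, R, nu)
  for (j in seq_along(spec$inputs)) {
    nm <- spec$inputs[j]
    if (nm %in% names(params$B)) Bcube[, , j] <- params$B[[nm]]
    if (nm %in% names(params$C)) Cmat[, j] <- params$C[[nm]]
  }
  list(A = params$A, B = Bcube, C = Cmat)
}

#' Check bilinear stability for all attained input combinations
#'
#' @param params a [dcm_parameters()].
#' @param U microtime input matrix (bins x inputs).
#' @param margin required stability margin on the largest real part (Hz).
#' @return invisibly `TRUE`; errors naming the offending eigenvalue
#'   otherwise.
#' @export
check_stability <- function(params, U, margin = 0) {
  arr <- param_arrays(params)
  combos <- unique(as.data.frame(U))
  for (i in seq_len(nrow(combos))) {
    u <- as.numeric(combos[i, ])
    M <- arr$A
    for (j in seq_along(u)) M <- M + u[j] * arr$B[, , j]
    lam <- eigen(M, only.values = TRUE)$values
    worst <- lam[which.max(Re(lam))]
    if (Re(worst) >= -margin)
      stop(sprintf(
        "unstable bilinear system: eigenvalue %.4f%+.4fi at input (%s)",
        Re(worst), Im(worst), paste(format(u), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Simulate a BOLD time series from a DCM
#'
#' Integrates the neural states exactly per microtime bin (matrix
#' exponential of the bilinear matrix, which is piecewise constant for
#' boxcar inputs) and the balloon states by 4th-order Runge-Kutta on the
#' same grid, then samples the BOLD observation at volume acquisition
#' times. Optionally adds low-order Legendre drift and i.i.d. Gaussian
#' noise.
#'
#' @param params a [dcm_parameters()].
#' @param inputs an `input_functions` object from [build_inputs()].
#' @param design the `task_design` the inputs were built from.
#' @param noise add observation noise of sd `params$noise_sd` and the
#'   drift in `params$drift_coeffs`?
#' @param seed integer seed used (locally) for the noise draw.
#' @return object of class `bold_ts`: list with `data` (volumes x regions
#'   matrix, percent signal change), `time_s`, `tr_s`, `regions`.
#' @export
integrate_and_sample <- function(params, inputs, design,
                                 noise = FALSE, seed = NULL) {
  stopifnot(inherits(params, "dcm_parameters"),
            inherits(design, "task_design"))
  spec <- params$spec
  U <- input_matrix(spec, inputs)
  check_stability(params, U)
  arr <- param_arrays(params)
  g <- microtime_grid(design)
  hemo <- params$hemo[, c("kappa", "gamma", "tau", "alpha", "e0"),
                      drop = FALSE]
  v0 <- params$hemo[1, "v0"]
  Y <- dcm_integrate_cpp(arr$A, arr$B, arr$C, U, hemo, v0, g$dt,
                         g$sample_bins)
  colnames(Y) <- spec$regions
  tvec <- g$sample_bins * g$dt
  if (noise) {
    tt <- 2 * (tvec - min(tvec)) / (max(tvec) - min(tvec)) - 1
    drift <- params$drift_coeffs[1] * tt +
      params$drift_coeffs[2] * (3 * tt^2 - 1) / 2
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                         .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    Y <- Y + drift +
      matrix(stats::rnorm(length(Y), sd = params$noise_sd), nrow(Y))
  }
  structure(list(data = Y, time_s = tvec, tr_s = design$tr_s,
                 regions = spec$regions), class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("bold_ts: %d volumes x %d regions (%s), TR %gs\n",
              nrow(x$data), ncol(x$data),
              paste(x$regions, collapse = ", "), x$tr_s))
  invisible(x)
}

#' Read and write region time-series tables
#'
#' Tab-separated with a `time_s` column followed by one column per region.
#'
#' @param x a `bold_ts`.
#' @param path file path.
#' @export
write_bold_ts <- function(x, path) {
  stopifnot(inherits(x, "bold_ts"))
  df <- data.frame(time_s = x$time_s, x$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bold_ts
#' @export
read_bold_ts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot("time_s" %in% names(df))
  regions <- setdiff(names(df), "time_s")
  tr <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else NA_real_
  structure(list(data = as.matrix(df[regions]), time_s = df$time_s,
                 tr_s = tr, regions = regions), class = "bold_ts")
}
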