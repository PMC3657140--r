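#' High-pass filter cutoff implied by a task design
#'
#' The cutoff is twice the maximum stimulus repetition time: for a block
#' design, twice the longest interval between consecutive onsets of the
#' same stimulus condition (rest blocks are not stimuli).
#'
#' @param design a `task_design`.
#' @return cutoff period in seconds.
#' @export
design_hp_cutoff <- function(design) {
  stopifnot(inherits(design, "task_design"))
  conds <- setdiff(unique(design$blocks$condition), "R")
  gaps <- unlist(lapply(conds, function(k) {
    on <- design$blocks$onset[design$blocks$condition == k]
    if (length(on) > 1) diff(sort(on)) else numeric(0)
  }))
  if (!length(gaps)) stop("no repeated stimulus condition in design")
  2 * max(gaps)
}

# Discrete-cosine low-frequency basis: columns k = 1..K with period
# 2*N*dt/k, keeping those with period longer than `cutoff_s`.
dct_basis <- function(n, dt, cutoff_s) {
  K <- floor(2 * n * dt / cutoff_s)
  if (K < 1) return(matrix(numeric(0), n, 0))
  t <- seq_len(n) - 0.5
  sapply(seq_len(K), function(k) cos(pi * k * t / n))
}

#' High-pass filter a time series by discrete-cosine regression
#'
#' Removes the mean and all discrete-cosine components with period longer
#' than the cutoff; output is zero-mean.
#'
#' @param series numeric vector or volumes-x-regions matrix.
#' @param design a `task_design` (used for TR and, when `cutoff_s` is
#'   missing, the cutoff via [design_hp_cutoff()]).
#' @param cutoff_s cutoff period in seconds.
#' @return filtered series, same shape as the input.
#' @export
highpass_filter <- function(series, design, cutoff_s = design_hp_cutoff(design)) {
  y <- as.matrix(series)
  if (cutoff_s < 2 * design$tr_s)
    stop("cutoff must be at least twice the TR")
  X <- cbind(1, dct_basis(nrow(y), design$tr_s, cutoff_s))
  out <- stats::lm.fit(X, y)$residuals
  if (is.vector(series)) as.numeric(out) else out
}

#' GLM activation statistic
#'
#' Ordinary least squares of a region time series on a design matrix,
#' returning the t statistic of a contrast (default: the faces-vs-rest
#' column) with its residual degrees of freedom and one-sided p value.
#'
#' @param series numeric vector (one region's time series).
#' @param X design matrix including nuisance columns; an intercept is
#'   appended automatically if absent.
#' @param contrast numeric contrast vector over the columns of `X` (after
#'   the intercept append), or the name of a single column.
#' @param t_cap magnitude at which a numerically infinite t (zero residual
#'   variance) is reported.
#' @return list with `t`, `df`, `p` (one-sided, positive direction) and
#'   `beta` (the contrast estimate).
#' @export
glm_activation <- function(series, X, contrast = "faces", t_cap = 1e6) {
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- cbind(X, `(intercept)` = 1)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.character(contrast)) {
    hit <- colnames(X) == contrast
    if (!any(hit)) stop(sprintf("no column named '%s'", contrast))
    cvec <- as.numeric(hit)
  } else cvec <- c(contrast, rep(0, ncol(X) - length(contrast)))
  fit <- stats::lm.fit(X, series)
  df <- length(series) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  se2 <- sigma2 * drop(t(cvec) %*% chol2inv(qr.R(qr(X))) %*% cvec)
  est <- drop(cvec %*% fit$coefficients)
  t <- if (se2 <= 0 || !is.finite(est / sqrt(se2)))
    sign(est) * t_cap else est / sqrt(se2)
  t <- max(min(t, t_cap), -t_cap)
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE), beta = est)
}

#' A region focus: group maximum vs subject local maximum
#'
#' @param region region label.
#' @param group_mm,subject_mm length-3 mm coordinates of the group maximum
#'   and the subject's local maximum.
#' @return list with the coordinates and their Euclidean `distance` (mm).
#' @export
region_focus <- function(region, group_mm, subject_mm) {
  stopifnot(length(group_mm) == 3, length(subject_mm) == 3)
  list(region = region, group_mm = group_mm, subject_mm = subject_mm,
       distance = sqrt(sum((group_mm - subject_mm)^2)))
}

#' Subject inclusion rule
#'
#' A subject enters the DCM analysis only if every region shows
#' significant activation (one-sided p below `alpha`) at a local maximum
#' within `max_dist` mm of the group maximum.
#'
#' @param foci data frame with one row per region and columns `region`,
#'   `distance`, `t`, `df` (as from [glm_activation()] plus
#'   [region_focus()]).
#' @param alpha significance level (uncorrected).
#' @param max_dist locality threshold in mm.
#' @param required regions that must all be assessed.
#' @return list with `included` (logical) and `reasons`, a per-region data
#'   frame flagging which rule failed.
#' @export
subject_included <- function(foci, alpha = 0.05, max_dist = 14,
                             required = c("V1", "FG", "AMY", "OFC")) {
  missing <- setdiff(required, foci$region)
  if (length(missing))
    stop("missing region assessment: ", paste(missing, collapse = ", "))
  p <- stats::pt(foci$t, foci$df, lower.tail = FALSE)
  pass_act <- p < alpha
  pass_loc <- foci$distance <= max_dist
  reasons <- data.frame(region = foci$region,
                        activation = pass_act, locality = pass_loc,
                        p = p, distance = foci$distance,
                        stringsAsFactors = FALSE)
  list(included = all(pass_act & pass_loc), reasons = reasons)
}

# Voxel-center coordinates (mm) of a patch, as an n_voxels x 3 matrix in
# the same linear order as the flattened spatial dimensions.
patch_coords <- function(patch) {
  d <- dim(patch$data)[1:3]
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  sweep(sweep(idx - 1, 2, patch$voxel_mm, `*`), 2, patch$origin_mm, `+`)
}

#' First eigenvariate of a sphere within a voxel patch
#'
#' All voxels whose centers lie within `radius_mm` of `center` (a closed
#' ball) are collected into a volumes-x-voxels matrix, column-centered,
#' and summarised by the first singular-vector time course, scaled by the
#' first singular value over the square root of the voxel count (so its
#' amplitude is comparable to an average voxel) and signed so that it
#' correlates positively with the sphere-mean series.
#'
#' @param patch an `roi_patch` (see [render_patch()]).
#' @param center length-3 mm coordinate of the sphere center.
#' @param radius_mm sphere radius in mm.
#' @return object of class `eigenvariate_series`: list with `values`,
#'   `explained_variance`, `n_voxels`.
#' @export
extract_eigenvariate <- function(patch, center, radius_mm) {
  stopifnot(inherits(patch, "roi_patch"))
  co <- patch_coords(patch)
  d2 <- rowSums(sweep(co, 2, center, `-`)^2)
  keep <- which(d2 <= radius_mm^2 + 1e-9)
  if (!length(keep)) stop("no voxels within the sphere")
  d <- dim(patch$data)
  Y <- matrix(aperm(patch$data, c(4, 1, 2, 3)), d[4], prod(d[1:3]))[, keep,
                                                                    drop = FALSE]
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc)
  ev <- sv$u[, 1] * sv$d[1] / sqrt(length(keep))
  m <- rowMeans(Yc)
  if (sum(ev * m) < 0) ev <- -ev
  structure(list(values = ev,
                 explained_variance = sv$d[1]^2 / sum(sv$d^2),
                 n_voxels = length(keep)),
            class = "eigenvariate_series")
}
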