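#' Cohort specification for the synthetic-data generator
#'
#' Each cohort is defined by its group label, size, and the ground-truth
#' modulatory pattern (a model id from the 21-model space) per emotion.
#' The defaults encode the group-by-valence reversal: healthy controls
#' (HC) have happy modulating the single OFC-to-FG backward connection
#' (Model 5) and sad modulating OFC-amygdala and OFC-FG bidirectionally
#' (Model 21); remitted-depression (rMDD) subjects show the opposite
#' pattern (happy Model 21, sad Model 2, the single forward FG-to-OFC
#' connection).
#'
#' @param group `"HC"` or `"rMDD"`.
#' @param n_subjects cohort size (defaults: 21 HC, 22 rMDD).
#' @param truth_by_emotion named list mapping `happy` and `sad` to model
#'   ids in the modulatory space.
#' @param a_mean,self_mean,b_mean,c_mean population means of the
#'   intrinsic, self, modulatory and driving couplings (Hz).
#' @param dispersion between-subject SD of every coupling (Hz).
#' @param snr signal-to-noise ratio, sd(noiseless signal)/noise sd.
#' @param drift_sd SD of the random Legendre drift coefficients (percent
#'   signal).
#' @param madrs_sigma scale of the half-normal symptom-score distribution.
#' @param weak_ofc_fraction fraction of subjects whose couplings into OFC
#'   are attenuated, giving the inclusion rule real work.
#' @param seed cohort-level RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("HC", "rMDD"),
                        n_subjects = if (group == "HC") 21L else 22L,
                        truth_by_emotion = if (group == "HC")
                          list(happy = 5L, sad = 21L) else
                            list(happy = 21L, sad = 2L),
                        a_mean = 0.2, self_mean = -1.0,
                        b_mean = 0.4, c_mean = 0.8,
                        dispersion = 0.08,
                        snr = 1,
                        drift_sd = 0.15,
                        madrs_sigma = if (group == "HC") 1.5 else 3.5,
                        weak_ofc_fraction = 0.25,
                        seed = 1L) {
  group <- match.arg(group)
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (snr <= 0) stop("snr must be positive")
  stopifnot(all(c("happy", "sad") %in% names(truth_by_emotion)))
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 truth_by_emotion = truth_by_emotion,
                 a_mean = a_mean, self_mean = self_mean, b_mean = b_mean,
                 c_mean = c_mean, dispersion = dispersion, snr = snr,
                 drift_sd = drift_sd, madrs_sigma = madrs_sigma,
                 weak_ofc_fraction = weak_ofc_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# The generating spec of one cohort subject: fully interconnected
# intrinsic winner with both emotions' true patterns as modulators.
cohort_dcm_spec <- function(cohort, models = build_modulatory_space()) {
  ids <- vapply(models, `[[`, 1L, "id")
  winner <- winning_structural_model()
  mod <- lapply(cohort$truth_by_emotion, function(id) {
    if (!id %in% ids) stop(sprintf("truth model %d not in the model space", id))
    models[[which(ids == id)]]$edges
  })
  dcm_spec(intrinsic_edges = winner$edges, modulated_edges = mod,
           driving = winner$driving)
}

# Draw one stable parameter set around the population means. Errors after
# `max_draws` stability rejections.
draw_subject_parameters <- function(cohort, spec, U, weak_ofc,
                                    max_draws = 100L) {
  R <- length(spec$regions)
  regs <- spec$regions
  for (try in seq_len(max_draws)) {
    A <- matrix(0, R, R, dimnames = list(regs, regs))
    am <- edge_mask(spec$intrinsic_edges, regs)
    A[am] <- stats::rnorm(sum(am), cohort$a_mean, cohort$dispersion)
    diag(A) <- pmin(stats::rnorm(R, cohort$self_mean, cohort$dispersion),
                    -0.1)
    B <- lapply(spec$modulated_edges, function(edges) {
      Bm <- matrix(0, R, R, dimnames = dimnames(A))
      bm <- edge_mask(edges, regs)
      Bm[bm] <- stats::rnorm(sum(bm), cohort$b_mean, cohort$dispersion)
      Bm
    })
    C <- lapply(spec$driving, function(targets) {
      cv <- numeric(R)
      cv[regs %in% targets] <- stats::rnorm(sum(regs %in% targets),
                                            cohort$c_mean,
                                            cohort$dispersion)
      cv
    })
    if (weak_ofc) {
      A["OFC", -which(regs == "OFC")] <-
        0.1 * A["OFC", -which(regs == "OFC")]
      B <- lapply(B, function(Bm) { Bm["OFC", ] <- 0.1 * Bm["OFC", ]; Bm })
    }
    drift <- stats::rnorm(2, 0, cohort$drift_sd)
    params <- try(dcm_parameters(spec, A, B, C, drift_coeffs = drift),
                  silent = TRUE)
    if (inherits(params, "try-error")) next
    ok <- try(check_stability(params, U, margin = 0.01), silent = TRUE)
    if (!inherits(ok, "try-error")) return(params)
  }
  stop(sprintf(
    "no stable coupling draw for the A/B matrices after %d attempts",
    max_draws))
}

#' Simulate one subject
#'
#' Draws subject-level couplings from the cohort's population
#' distributions (truncated to bilinear stability), simulates noiseless
#' BOLD through the forward model, sets the noise SD from the requested
#' SNR, and adds drift and observation noise. Deterministic given the
#' cohort seed and subject index.
#'
#' @param cohort a [cohort_spec()].
#' @param design a `task_design`.
#' @param subject_index 1-based index within the cohort.
#' @param models the modulatory model space.
#' @return object of class `subject_record`: `id`, `group`, `bold` (a
#'   `bold_ts`), `design`, `madrs`, `true_params`, `weak_ofc`,
#'   `focus_distances` (simulated subject-to-group maxima distances, mm).
#' @export
sample_subject <- function(cohort, design, subject_index,
                           models = build_modulatory_space()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  spec <- cohort_dcm_spec(cohort, models)
  inputs <- build_inputs(design)
  U <- input_matrix(spec, inputs)
  with_local_seed(cohort$seed * 1000L + subject_index, {
    weak_ofc <- stats::runif(1) < cohort$weak_ofc_fraction
    params <- draw_subject_parameters(cohort, spec, U, weak_ofc)
    noiseless <- integrate_and_sample(params, inputs, design, noise = FALSE)
    sig_sd <- stats::sd(as.numeric(scale(noiseless$data, scale = FALSE)))
    params$noise_sd <- sig_sd / cohort$snr
    noisy <- noiseless
    dims <- dim(noisy$data)
    tt <- 2 * (noisy$time_s - min(noisy$time_s)) /
      diff(range(noisy$time_s)) - 1
    drift <- params$drift_coeffs[1] * tt +
      params$drift_coeffs[2] * (3 * tt^2 - 1) / 2
    noisy$data <- noisy$data + drift +
      matrix(stats::rnorm(prod(dims), sd = params$noise_sd), dims[1])
    madrs <- abs(stats::rnorm(1, 0, cohort$madrs_sigma))
    dists <- stats::runif(4, 0, 10)
    names(dists) <- spec$regions
    structure(list(
      id = sprintf("%s%02d", cohort$group, subject_index),
      group = cohort$group, bold = noisy, noiseless = noiseless,
      design = design, madrs = madrs, true_params = params,
      weak_ofc = weak_ofc, focus_distances = dists,
      seed = cohort$seed * 1000L + subject_index
    ), class = "subject_record")
  })
}

#' Generate the two-cohort dataset
#'
#' @param hc,rmdd [cohort_spec()]s with distinct seeds.
#' @param design a `task_design`.
#' @param out_dir optional directory; when given, per-subject time-series
#'   TSVs and a `manifest.csv` (subject_id, group, seed, madrs_like) are
#'   written there.
#' @param models the modulatory model space.
#' @return list with `subjects` (list of `subject_record`) and `manifest`
#'   (data frame).
#' @export
make_cohorts <- function(hc, rmdd, design, out_dir = NULL,
                         models = build_modulatory_space()) {
  if (hc$seed == rmdd$seed) stop("cohorts must use distinct seeds")
  subjects <- c(
    lapply(seq_len(hc$n_subjects), function(i)
      sample_subject(hc, design, i, models)),
    lapply(seq_len(rmdd$n_subjects), function(i)
      sample_subject(rmdd, design, i, models))
  )
  ids <- vapply(subjects, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  manifest <- data.frame(
    subject_id = ids,
    group = vapply(subjects, `[[`, "", "group"),
    seed = vapply(subjects, `[[`, 1L, "seed"),
    madrs_like = vapply(subjects, `[[`, 1.0, "madrs"),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects)
      write_bold_ts(s$bold, file.path(out_dir, paste0(s$id, ".tsv")))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(subjects = subjects, manifest = manifest)
}

#' Render a voxel patch around one region's focus
#'
#' Builds a small 4-D (x, y, z, t) neighborhood in which every voxel
#' carries the region's time series weighted by a spatial Gaussian kernel
#' centered on the focus voxel (which therefore has maximal loading),
#' plus i.i.d. voxel noise.
#'
#' @param subject a `subject_record`.
#' @param region region label.
#' @param shape patch dimensions in voxels (odd, so a center voxel
#'   exists).
#' @param voxel_mm voxel size in mm (default matches a 3.5 x 3.5 mm
#'   in-plane, 5 mm slice acquisition).
#' @param kernel_fwhm_mm FWHM of the spatial loading kernel; 0 puts all
#'   signal in the focus voxel.
#' @param voxel_noise_sd SD of the added voxel noise.
#' @param focus_mm mm coordinate assigned to the focus (center) voxel.
#' @param seed RNG seed for the voxel noise.
#' @return object of class `roi_patch`: `data` (4-D array), `voxel_mm`,
#'   `origin_mm`, `focus_mm`, `region`.
#' @export
render_patch <- function(subject, region, shape = c(7, 7, 7),
                         voxel_mm = c(3.5, 3.5, 5.0),
                         kernel_fwhm_mm = 8, voxel_noise_sd = 0.1,
                         focus_mm = c(0, 0, 0), seed = subject$seed + 1L) {
  stopifnot(inherits(subject, "subject_record"), all(shape %% 2 == 1))
  series <- subject$bold$data[, region]
  center_idx <- (shape + 1) / 2
  origin <- focus_mm - (center_idx - 1) * voxel_mm
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
  mm <- sweep(sweep(idx - 1, 2, voxel_mm, `*`), 2, origin, `+`)
  d2 <- rowSums(sweep(mm, 2, focus_mm, `-`)^2)
  if (kernel_fwhm_mm > 0) {
    sig <- kernel_fwhm_mm / (2 * sqrt(2 * log(2)))
    w <- exp(-d2 / (2 * sig^2))
  } else w <- as.numeric(d2 < 1e-9)
  T <- length(series)
  with_local_seed(seed, {
    flat <- outer(series, w) +
      matrix(stats::rnorm(T * nrow(idx), sd = voxel_noise_sd), T)
  })
  arr <- aperm(array(flat, c(T, shape)), c(2, 3, 4, 1))
  structure(list(data = arr, voxel_mm = voxel_mm, origin_mm = origin,
                 focus_mm = focus_mm, region = region),
            class = "roi_patch")
}

#' Write a patch as a NIfTI-1 image
#'
#' @param patch an `roi_patch`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param tr_s repetition time stored in the header.
#' @export
write_patch_nifti <- function(patch, path, tr_s = 2.1) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to write NIfTI files")
  img <- RNifti::asNifti(patch$data,
                         reference = list(pixdim = c(patch$voxel_mm, tr_s)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
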