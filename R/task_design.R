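#' Parse a block-order string into a timed task design
#'
#' The emotional face task is a block design described by a string over the
#' alphabet N (neutral faces), H (happy), S (sad), F (fear), R (rest
#' fixation). Each block lasts `block_s` seconds and face blocks contain
#' `faces_per_block` faces of `stim_s` seconds each followed by a `gap_s`
#' gap, so `faces_per_block * (stim_s + gap_s)` must equal `block_s`.
#'
#' @param order character string of block codes, e.g.
#'   `"NHNSNFNRSNHNFNRFNSNHNR"`.
#' @param block_s block duration in seconds.
#' @param stim_s,gap_s face presentation and inter-stimulus gap in seconds.
#' @param faces_per_block number of faces per block.
#' @param tr_s repetition time of the scanner in seconds.
#' @param n_volumes number of volumes acquired. The default 218 samples
#'   457.8 s of the 462-s task, truncating the final (rest) block at
#'   sampling; use `full_coverage = TRUE` for 220 volumes covering the task.
#' @param microtime_bins_per_tr temporal up-sampling factor used when
#'   building input functions and convolving regressors.
#' @param full_coverage if `TRUE`, override `n_volumes` with the smallest
#'   count whose scan duration covers the whole task.
#' @return an object of class `task_design` with the parsed block table,
#'   per-condition block lists and counts, and total duration.
#' @examples
#' d <- parse_block_order("NHNSNFNRSNHNFNRFNSNHNR")
#' d$n_blocks          # 22
#' d$total_duration_s  # 462
#' @export
parse_block_order <- function(order = "NHNSNFNRSNHNFNRFNSNHNR",
                              block_s = 21,
                              stim_s = 3.0, gap_s = 0.5,
                              faces_per_block = 6,
                              tr_s = 2.1,
                              n_volumes = 218L,
                              microtime_bins_per_tr = 16L,
                              full_coverage = FALSE) {
  if (!is.character(order) || length(order) != 1L || nchar(order) == 0L)
    stop("'order' must be a non-empty character string")
  codes <- strsplit(order, "")[[1]]
  bad <- which(!codes %in% c("N", "H", "S", "F", "R"))
  if (length(bad))
    stop(sprintf("invalid block code '%s' at position %d", codes[bad[1]], bad[1]))
  if (abs(faces_per_block * (stim_s + gap_s) - block_s) > 1e-9)
    stop("faces_per_block * (stim_s + gap_s) must equal block_s")
  if (microtime_bins_per_tr < 1L)
    stop("microtime_bins_per_tr must be a positive integer")
  n_blocks <- length(codes)
  total <- n_blocks * block_s
  if (full_coverage) n_volumes <- as.integer(ceiling(total / tr_s))
  blocks <- data.frame(
    index = seq_len(n_blocks),
    condition = codes,
    onset = (seq_len(n_blocks) - 1) * block_s,
    duration = block_s,
    stringsAsFactors = FALSE
  )
  counts <- vapply(c("N", "H", "S", "F", "R"),
                   function(k) sum(codes == k), integer(1))
  structure(list(
    block_order = order,
    blocks = blocks,
    counts = counts,
    n_blocks = n_blocks,
    total_duration_s = total,
    block_s = block_s, stim_s = stim_s, gap_s = gap_s,
    faces_per_block = faces_per_block,
    tr_s = tr_s, n_volumes = as.integer(n_volumes),
    microtime_bins_per_tr = as.integer(microtime_bins_per_tr)
  ), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("task_design: %d blocks of %gs (%gs total), TR %gs, %d volumes\n",
              x$n_blocks, x$block_s, x$total_duration_s, x$tr_s, x$n_volumes))
  cat("block counts:", paste(names(x$counts), x$counts, sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Events table for a task design
#'
#' Three-column BIDS-style representation (onset, duration, trial_type) in
#' seconds with 0-based onsets. `design_from_events` inverts it, so
#' design -> events -> design round-trips exactly.
#'
#' @param design a `task_design`.
#' @return data frame with columns onset, duration, trial_type.
#' @export
events_table <- function(design) {
  stopifnot(inherits(design, "task_design"))
  data.frame(onset = design$blocks$onset,
             duration = design$blocks$duration,
             trial_type = design$blocks$condition,
             stringsAsFactors = FALSE)
}

#' @rdname events_table
#' @param events data frame as produced by [events_table()].
#' @param ... further arguments passed to [parse_block_order()].
#' @export
design_from_events <- function(events, ...) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  events <- events[order(events$onset), , drop = FALSE]
  block_s <- unique(as.numeric(events$duration))
  if (length(block_s) != 1L)
    stop("events do not form a uniform block design")
  parse_block_order(paste(events$trial_type, collapse = ""),
                    block_s = block_s, ...)
}

#' @rdname events_table
#' @param path file path for the tab-separated events file.
#' @export
write_events <- function(design, path) {
  utils::write.table(events_table(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname events_table
#' @export
read_events <- function(path, ...) {
  design_from_events(utils::read.delim(path, stringsAsFactors = FALSE), ...)
}

#' Microtime grid of a design
#'
#' @param design a `task_design`.
#' @return list with `dt` (bin width, s), `time` (bin start times, s) and
#'   `sample_bins` (0-based bin index of each volume acquisition).
#' @keywords internal
microtime_grid <- function(design) {
  bins <- design$microtime_bins_per_tr
  dt <- design$tr_s / bins
  nbin <- design$n_volumes * bins
  list(dt = dt,
       time = (seq_len(nbin) - 1) * dt,
       n_bins = nbin,
       sample_bins = (seq_len(design$n_volumes) - 1L) * bins)
}

#' Build stimulus input functions
#'
#' Unit-height boxcars on the microtime grid: one per emotion condition, one
#' for neutral blocks, and `u_faces`, the union of all face blocks (the
#' driving input to V1). Rest blocks carry no input.
#'
#' @param design a `task_design`.
#' @return object of class `input_functions`: list with `time`, `dt`, and
#'   the vectors `u_faces`, `u_neutral`, `u_happy`, `u_sad`, `u_fear`.
#' @export
build_inputs <- function(design) {
  stopifnot(inherits(design, "task_design"))
  if (design$microtime_bins_per_tr <= 0L)
    stop("microtime_bins_per_tr must be positive")
  g <- microtime_grid(design)
  cond_at <- function(t) {
    i <- floor(t / design$block_s) + 1
    out <- rep("R", length(t))
    ok <- i >= 1 & i <= design$n_blocks
    out[ok] <- design$blocks$condition[i[ok]]
    out
  }
  cond <- cond_at(g$time)
  u <- function(k) as.numeric(cond == k)
  u_n <- u("N"); u_h <- u("H"); u_s <- u("S"); u_f <- u("F")
  structure(list(
    time = g$time, dt = g$dt,
    u_faces = pmax(u_n, u_h, u_s, u_f),
    u_neutral = u_n, u_happy = u_h, u_sad = u_s, u_fear = u_f
  ), class = "input_functions")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Standard parameterisation: response peak 6 s, undershoot peak 16 s, both
#' with dispersion 1, undershoot ratio 1/6, 32-s support. Sampled on a grid
#' of width `dt` and scaled to unit peak.
#'
#' @param dt grid spacing in seconds.
#' @param length_s support of the kernel in seconds.
#' @return numeric vector of kernel values.
#' @export
canonical_hrf <- function(dt, length_s = 32) {
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolved GLM regressors for a design
#'
#' One regressor per stimulus condition (N, H, S, F), built by convolving
#' the microtime boxcar with `hrf` and sampling at volume acquisition
#' times. A `faces` column (all face conditions) is appended for the
#' faces-vs-rest contrast.
#'
#' @param design a `task_design`.
#' @param hrf impulse response sampled on the design's microtime grid
#'   (default [canonical_hrf()]).
#' @return numeric matrix `n_volumes x 5` with columns N, H, S, F, faces.
#' @export
build_glm_regressors <- function(design,
                                 hrf = canonical_hrf(design$tr_s /
                                                       design$microtime_bins_per_tr)) {
  stopifnot(inherits(design, "task_design"))
  if (length(hrf) < 1L) stop("hrf must have at least one sample")
  inp <- build_inputs(design)
  g <- microtime_grid(design)
  conv_ds <- function(u) {
    full <- stats::convolve(u, rev(hrf), type = "open")[seq_along(u)]
    full[g$sample_bins + 1L]
  }
  X <- cbind(N = conv_ds(inp$u_neutral),
             H = conv_ds(inp$u_happy),
             S = conv_ds(inp$u_sad),
             F = conv_ds(inp$u_fear))
  cbind(X, faces = conv_ds(inp$u_faces))
}
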