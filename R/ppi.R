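#' Psychological contrast vector at volume resolution
#'
#' +1 on volumes acquired during the contrast's emotion blocks, -1 on
#' neutral blocks, 0 elsewhere (rest and fear).
#'
#' @param design a `task_design`.
#' @param contrast `"happy-neutral"` or `"sad-neutral"`.
#' @return length-`n_volumes` vector in \{-1, 0, +1\}.
#' @export
psychological_vector <- function(design,
                                 contrast = c("happy-neutral",
                                              "sad-neutral")) {
  contrast <- match.arg(contrast)
  emo <- if (contrast == "happy-neutral") "H" else "S"
  t <- (seq_len(design$n_volumes) - 1) * design$tr_s
  blk <- floor(t / design$block_s) + 1
  cond <- rep("R", length(t))
  ok <- blk <= design$n_blocks
  cond[ok] <- design$blocks$condition[blk[ok]]
  out <- numeric(length(t))
  out[cond == emo] <- 1
  out[cond == "N"] <- -1
  out
}

#' Build a psychophysiological-interaction design
#'
#' The interaction regressor is the elementwise product of the seed
#' (physiological) time series and the psychological contrast vector.
#' Nuisance columns are an intercept and a linear drift.
#'
#' @param seed an `eigenvariate_series` or numeric vector (the seed
#'   region's time series, length `n_volumes`).
#' @param design a `task_design`.
#' @param contrast `"happy-neutral"` or `"sad-neutral"`.
#' @return object of class `ppi_design`: list with `interaction`,
#'   `physio`, `psych`, `nuisance`, `contrast`.
#' @export
build_ppi_design <- function(seed, design,
                             contrast = c("happy-neutral", "sad-neutral")) {
  contrast <- match.arg(contrast)
  phys <- if (inherits(seed, "eigenvariate_series")) seed$values else
    as.numeric(seed)
  if (length(phys) != design$n_volumes)
    stop("seed length does not match the design's volume count")
  psych <- psychological_vector(design, contrast)
  t <- seq_along(phys)
  nuis <- cbind(intercept = 1, drift = scale(t)[, 1])
  structure(list(interaction = phys * psych, physio = phys, psych = psych,
                 nuisance = nuis, contrast = contrast),
            class = "ppi_design")
}

#' Fit the PPI regression for one target region
#'
#' OLS of the target series on the interaction regressor, partialling the
#' physiological and psychological main effects and nuisance columns.
#'
#' @param target numeric target time series.
#' @param ppi a [build_ppi_design()].
#' @return list with `beta` (interaction coefficient), `t`, `df`, `p`
#'   (two-sided).
#' @export
fit_ppi <- function(target, ppi) {
  stopifnot(inherits(ppi, "ppi_design"))
  X <- cbind(interaction = ppi$interaction, physio = ppi$physio,
             psych = ppi$psych, ppi$nuisance)
  if (qr(X)$rank < ncol(X)) stop("PPI design matrix is rank deficient")
  fit <- stats::lm(target ~ X - 1)
  sm <- summary(fit)$coefficients
  beta <- sm["Xinteraction", "Estimate"]
  t <- sm["Xinteraction", "t value"]
  df <- fit$df.residual
  list(beta = beta, t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Group comparison of PPI interaction betas
#'
#' Two-sample comparison per target with Bonferroni family-wise
#' correction over the composite target set (FG + OFC).
#'
#' @param betas_a,betas_b matrices (subjects x targets) of interaction
#'   betas for the two groups; column names label the targets.
#' @param labels group labels, in the order (a, b).
#' @param alpha family-wise significance level.
#' @return object of class `ppi_group_result`: per-target data frame with
#'   group means, difference (a - b), t, raw and corrected p, decision
#'   and direction; plus `alpha` and `correction`.
#' @export
group_compare <- function(betas_a, betas_b, labels = c("HC", "rMDD"),
                          alpha = 0.05) {
  betas_a <- as.matrix(betas_a); betas_b <- as.matrix(betas_b)
  if (nrow(betas_a) < 2 || nrow(betas_b) < 2)
    stop("each group needs at least 2 subjects")
  targets <- colnames(betas_a)
  if (is.null(targets)) targets <- sprintf("T%d", seq_len(ncol(betas_a)))
  res <- lapply(seq_along(targets), function(j) {
    tt <- stats::t.test(betas_a[, j], betas_b[, j])
    data.frame(target = targets[j],
               mean_a = mean(betas_a[, j]), mean_b = mean(betas_b[, j]),
               diff = mean(betas_a[, j]) - mean(betas_b[, j]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_fwe <- stats::p.adjust(res$p, method = "bonferroni")
  res$significant <- res$p_fwe < alpha
  res$direction <- ifelse(res$diff > 0,
                          sprintf("%s > %s", labels[1], labels[2]),
                          sprintf("%s > %s", labels[2], labels[1]))
  structure(list(table = res, alpha = alpha, correction = "bonferroni",
                 labels = labels), class = "ppi_group_result")
}

#' Correlation of PPI betas with symptom scores
#'
#' Product-moment correlation per target with the exact t-based p value.
#'
#' @param betas subjects x targets matrix of interaction betas.
#' @param scores symptom scores (one per subject).
#' @return data frame with target, r, p, n.
#' @export
symptom_correlation <- function(betas, scores) {
  betas <- as.matrix(betas)
  if (length(scores) != nrow(betas)) stop("scores length mismatch")
  if (nrow(betas) < 3) stop("need at least 3 subjects")
  if (stats::sd(scores) == 0) stop("symptom scores have zero variance")
  targets <- colnames(betas)
  if (is.null(targets)) targets <- sprintf("T%d", seq_len(ncol(betas)))
  out <- lapply(seq_along(targets), function(j) {
    ct <- stats::cor.test(betas[, j], scores)
    data.frame(target = targets[j], r = unname(ct$estimate),
               p = ct$p.value, n = nrow(betas), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
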