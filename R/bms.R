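#' Evidence table: subjects x models free energies
#'
#' @param F matrix of free energies (nats), rows = subjects, columns =
#'   models; must be complete.
#' @param model_ids integer ids of the columns.
#' @param families named list mapping family id to member model ids (as
#'   from [family_map()]); must partition `model_ids`.
#' @return object of class `evidence_table`.
#' @export
evidence_table <- function(F, model_ids = seq_len(ncol(F)),
                           families = NULL) {
  F <- as.matrix(F)
  if (any(is.na(F))) {
    idx <- which(is.na(F), arr.ind = TRUE)[1, ]
    stop(sprintf("missing free energy for subject %d, model %s",
                 idx[1], model_ids[idx[2]]))
  }
  if (length(model_ids) != ncol(F)) stop("model_ids length mismatch")
  if (!is.null(families)) {
    mem <- sort(unlist(families, use.names = FALSE))
    if (!identical(as.integer(mem), as.integer(sort(model_ids))))
      stop("families do not partition the model ids")
  }
  structure(list(F = F, model_ids = as.integer(model_ids),
                 families = families), class = "evidence_table")
}

#' Fixed-effects group log evidence
#'
#' Under fixed effects the group log evidence of a model is the sum of
#' the subject free energies.
#'
#' @param table an [evidence_table()].
#' @return named numeric vector of group log evidences per model.
#' @export
group_log_evidence <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  le <- colSums(table$F)
  names(le) <- table$model_ids
  le
}

#' Posterior model probabilities from group log evidences
#'
#' Softmax of log prior plus group log evidence, computed stably via
#' log-sum-exp.
#'
#' @param group_le named vector of group log evidences.
#' @param prior prior model probabilities (summing to 1; uniform by
#'   default).
#' @return named probability vector summing to 1.
#' @export
model_posteriors <- function(group_le,
                             prior = rep(1 / length(group_le),
                                         length(group_le))) {
  if (length(prior) != length(group_le)) stop("prior length mismatch")
  if (all(prior == 0)) stop("degenerate prior: all probabilities zero")
  if (abs(sum(prior) - 1) > 1e-8) stop("prior must sum to 1")
  lp <- log(prior) + group_le
  out <- exp(lp - logsumexp(lp))
  names(out) <- names(group_le)
  out / sum(out)
}

#' Family-level Bayesian model selection
#'
#' Each family receives an equal prior, split equally among its member
#' models so that family size does not bias the selection. Family
#' posteriors are sums of member model posteriors; within the winning
#' family, model posteriors are renormalised to pick the winning model.
#'
#' @param table an [evidence_table()] with a family map.
#' @param family_prior prior over families (uniform by default).
#' @param method `"ffx"` (summed log evidence, default) or `"rfx"`
#'   (hierarchical Dirichlet over model frequencies, variational update);
#'   under `"rfx"` the reported model "posteriors" are expected model
#'   frequencies.
#' @return object of class `bms_result`: `model_posterior`,
#'   `family_posterior`, `winning_family`, `winning_model`,
#'   `within_family_posterior`, `group_log_evidence`, `method`.
#' @export
family_inference <- function(table, family_prior = NULL,
                             method = c("ffx", "rfx")) {
  stopifnot(inherits(table, "evidence_table"))
  method <- match.arg(method)
  fams <- table$families
  if (is.null(fams)) stop("evidence table has no family map")
  nf <- length(fams)
  if (is.null(family_prior)) family_prior <- rep(1 / nf, nf)
  if (abs(sum(family_prior) - 1) > 1e-8)
    stop("family prior must sum to 1")
  # model prior: family prior split equally within the family
  prior <- numeric(length(table$model_ids))
  names(prior) <- table$model_ids
  for (i in seq_along(fams))
    prior[as.character(fams[[i]])] <- family_prior[i] / length(fams[[i]])

  if (method == "ffx") {
    gle <- group_log_evidence(table)
    mp <- model_posteriors(gle, prior[as.character(names(gle))])
  } else {
    mp <- rfx_frequencies(table$F, prior)
    names(mp) <- table$model_ids
    gle <- group_log_evidence(table)
  }
  fp <- vapply(fams, function(m) sum(mp[as.character(m)]), 1.0)
  wf <- names(fams)[which.max(fp)]
  within <- mp[as.character(fams[[wf]])]
  within <- within / sum(within)
  wm <- as.integer(names(within)[which.max(within)])
  structure(list(model_posterior = mp, family_posterior = fp,
                 winning_family = as.integer(wf), winning_model = wm,
                 within_family_posterior = within,
                 group_log_evidence = gle, method = method),
            class = "bms_result")
}

# Variational random-effects scheme: Dirichlet over model frequencies
# with concentration prior alpha0 proportional to the model prior.
rfx_frequencies <- function(F, prior, max_iter = 64, tol = 1e-6) {
  K <- ncol(F)
  alpha0 <- prior * K  # total concentration K, apportioned by the prior
  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    lg <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- t(apply(lg, 1, function(r) exp(r - logsumexp(r))))
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  alpha / sum(alpha)
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("bms_result (%s): winning family %d (p = %.3f), model %d (within-family p = %.3f)\n",
              x$method, x$winning_family,
              x$family_posterior[as.character(x$winning_family)],
              x$winning_model,
              x$within_family_posterior[as.character(x$winning_model)]))
  invisible(x)
}

#' Interpret a log evidence difference
#'
#' Standard Bayesian evidence categories on the log Bayes factor:
#' below 1.1 "weak", from 1.1 "positive", from 3 "strong", from 5
#' "very strong" (closed lower bounds).
#'
#' @param delta_logE log evidence difference in nats.
#' @return character category.
#' @export
bayes_factor_interpretation <- function(delta_logE) {
  vapply(delta_logE, function(d) {
    if (d >= 5) "very strong" else if (d >= 3) "strong"
    else if (d >= 1.1) "positive" else "weak"
  }, "")
}

#' Read and write evidence tables
#'
#' Long CSV with columns subject_id, model_id, free_energy.
#'
#' @param table an [evidence_table()].
#' @param path file path.
#' @param subject_ids optional row labels.
#' @export
write_evidence_csv <- function(table, path, subject_ids = NULL) {
  stopifnot(inherits(table, "evidence_table"))
  n <- nrow(table$F)
  if (is.null(subject_ids)) subject_ids <- rownames(table$F)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  long <- data.frame(
    subject_id = rep(subject_ids, times = ncol(table$F)),
    model_id = rep(table$model_ids, each = n),
    free_energy = as.numeric(table$F))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_csv
#' @param families family map to attach on read.
#' @export
read_evidence_csv <- function(path, families = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- sort(unique(long$model_id))
  subs <- unique(long$subject_id)
  F <- matrix(NA_real_, length(subs), length(ids),
              dimnames = list(subs, ids))
  F[cbind(match(long$subject_id, subs), match(long$model_id, ids))] <-
    long$free_energy
  evidence_table(F, ids, families)
}
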