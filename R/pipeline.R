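#' Configuration of an end-to-end run
#'
#' Collects every knob of the pipeline: task design, cohort sizes and
#' noise level, model space, inversion settings, BMS method, PPI
#' contrasts and the master seed (which fixes every downstream RNG).
#' Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param order,block_s,tr_s,n_volumes,microtime_bins_per_tr task design
#'   (see [parse_block_order()]).
#' @param n_hc,n_rmdd cohort sizes.
#' @param snr,dispersion,weak_ofc_fraction generator settings (see
#'   [cohort_spec()]).
#' @param model_space_path YAML model space (`NULL` = shipped default).
#' @param inversion_tol,inversion_max_iter variational-Laplace settings.
#' @param bms_method `"ffx"` or `"rfx"`.
#' @param fit_mode `"separate"` fits each emotion's model space with that
#'   emotion as the sole modulator (the reported analysis structure);
#'   `"joint"` additionally includes the other emotion as a saturated
#'   nuisance modulator in every candidate (see [to_dcm_spec()]), which
#'   removes the misspecification bias that the other emotion's
#'   unmodelled modulation otherwise induces.
#' @param emotions emotions analysed (each gets its own model space fit).
#' @param alpha significance level for inclusion and PPI.
#' @param master_seed integer master seed.
#' @param out_dir output directory (`NULL` = no artifacts written).
#' @return object of class `run_config`.
#' @export
run_config <- function(order = "NHNSNFNRSNHNFNRFNSNHNR", block_s = 21,
                       tr_s = 2.1, n_volumes = 218L,
                       microtime_bins_per_tr = 16L,
                       n_hc = 21L, n_rmdd = 22L,
                       snr = 1, dispersion = 0.08,
                       weak_ofc_fraction = 0.25,
                       model_space_path = NULL,
                       inversion_tol = 0.05, inversion_max_iter = 32L,
                       bms_method = "ffx", fit_mode = "separate",
                       emotions = c("happy", "sad"),
                       alpha = 0.05,
                       master_seed = 1L, out_dir = NULL) {
  structure(list(order = order, block_s = block_s, tr_s = tr_s,
                 n_volumes = as.integer(n_volumes),
                 microtime_bins_per_tr = as.integer(microtime_bins_per_tr),
                 n_hc = as.integer(n_hc), n_rmdd = as.integer(n_rmdd),
                 snr = snr, dispersion = dispersion,
                 weak_ofc_fraction = weak_ofc_fraction,
                 model_space_path = model_space_path,
                 inversion_tol = inversion_tol,
                 inversion_max_iter = as.integer(inversion_max_iter),
                 bms_method = bms_method,
                 fit_mode = match.arg(fit_mode, c("separate", "joint")),
                 emotions = emotions,
                 alpha = alpha, master_seed = as.integer(master_seed),
                 out_dir = out_dir), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# Fit all modulatory models for one group x emotion and return the
# evidence table. Uses (and writes) a cached CSV when out_dir is set.
fit_group_evidence <- function(subjects, emotion, design, models,
                               config, fams, out_dir = NULL,
                               label = "") {
  cache <- if (!is.null(out_dir))
    file.path(out_dir, "evidences", paste0(label, ".csv")) else NULL
  if (!is.null(cache) && file.exists(cache))
    return(read_evidence_csv(cache, fams))
  winner <- winning_structural_model()
  ids <- vapply(models, `[[`, 1L, "id")
  F <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(vapply(subjects, `[[`, "", "id"), ids))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    filt <- s$bold
    filt$data <- highpass_filter(filt$data, design)
    nuis <- if (identical(config$fit_mode, "joint"))
      setdiff(c("happy", "sad"), emotion)[1] else NULL
    for (j in seq_along(models)) {
      spec <- to_dcm_spec(winner, models[[j]], emotion,
                          nuisance_emotion = nuis)
      res <- invert_dcm(spec, filt, design,
                        tol = config$inversion_tol,
                        max_iter = config$inversion_max_iter)
      F[i, j] <- res$F
    }
  }
  tab <- evidence_table(F, ids, fams)
  if (!is.null(cache)) {
    dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
    write_evidence_csv(tab, cache)
  }
  tab
}

#' Run the full analysis pipeline
#'
#' Stages: simulate the two cohorts; apply the inclusion rule
#' (activation at p < alpha in all four regions within 14 mm); high-pass
#' filter; fit all 21 modulatory models per included subject and
#' emotion; family-level BMS per group x emotion; PPI with the amygdala
#' seed against FG and OFC targets per contrast, with group comparison
#' and (rMDD) symptom correlation; assemble the report. Deterministic
#' given the config (identical config + seed gives an identical report).
#'
#' @param config a [run_config()].
#' @return a `run_report` (see [make_report()]).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- parse_block_order(config$order, config$block_s,
                              tr_s = config$tr_s,
                              n_volumes = config$n_volumes,
                              microtime_bins_per_tr =
                                config$microtime_bins_per_tr)
  msp <- if (is.null(config$model_space_path)) build_modulatory_space()
  else build_modulatory_space(config$model_space_path)
  fams <- family_map(msp)

  hc <- cohort_spec("HC", n_subjects = config$n_hc, snr = config$snr,
                    dispersion = config$dispersion,
                    weak_ofc_fraction = config$weak_ofc_fraction,
                    seed = config$master_seed * 10L + 1L)
  rmdd <- cohort_spec("rMDD", n_subjects = config$n_rmdd, snr = config$snr,
                      dispersion = config$dispersion,
                      weak_ofc_fraction = config$weak_ofc_fraction,
                      seed = config$master_seed * 10L + 2L)
  cohorts <- make_cohorts(hc, rmdd, design, out_dir = config$out_dir,
                          models = msp)

  # Inclusion: GLM activation in every region within the locality rule.
  regs <- build_glm_regressors(design)
  Xact <- cbind(faces = regs[, "faces"],
                dct_basis(design$n_volumes, design$tr_s,
                          design_hp_cutoff(design)))
  included <- vapply(cohorts$subjects, function(s) {
    foci <- do.call(rbind, lapply(s$bold$regions, function(r) {
      act <- glm_activation(s$bold$data[, r], Xact, "faces")
      data.frame(region = r, distance = s$focus_distances[[r]],
                 t = act$t, df = act$df, stringsAsFactors = FALSE)
    }))
    subject_included(foci, alpha = config$alpha)$included
  }, TRUE)
  retention <- data.frame(
    group = c("HC", "rMDD"),
    n_recruited = c(config$n_hc, config$n_rmdd),
    n_included = c(sum(included[seq_len(config$n_hc)]),
                   sum(included[-seq_len(config$n_hc)])))
  subjects <- cohorts$subjects[included]
  groups <- vapply(subjects, `[[`, "", "group")
  if (any(retention$n_included < 2))
    stop("fewer than 2 included subjects in a group; raise snr or n")

  # Stage: model fitting and BMS per group x emotion.
  bms <- list()
  evid <- list()
  for (g in c("HC", "rMDD")) for (emo in config$emotions) {
    lab <- paste(g, emo, sep = ".")
    tab <- fit_group_evidence(subjects[groups == g], emo, design, msp,
                              config, fams, config$out_dir, lab)
    evid[[lab]] <- tab
    bms[[lab]] <- family_inference(tab, method = config$bms_method)
  }

  # Stage: PPI with the amygdala seed against FG and OFC.
  ppi <- list()
  contrast_of <- c(happy = "happy-neutral", sad = "sad-neutral")
  betas_all <- list()
  for (emo in config$emotions) {
    betas <- t(vapply(subjects, function(s) {
      filt <- highpass_filter(s$bold$data, design)
      pd <- build_ppi_design(filt[, "AMY"], design, contrast_of[[emo]])
      c(FG = fit_ppi(filt[, "FG"], pd)$beta,
        OFC = fit_ppi(filt[, "OFC"], pd)$beta)
    }, c(FG = 0, OFC = 0)))
    betas_all[[emo]] <- betas
    cmp <- group_compare(betas[groups == "HC", , drop = FALSE],
                         betas[groups == "rMDD", , drop = FALSE],
                         alpha = config$alpha)
    scores <- vapply(subjects[groups == "rMDD"], `[[`, 1.0, "madrs")
    cor <- symptom_correlation(betas[groups == "rMDD", , drop = FALSE],
                               scores)
    ppi[[emo]] <- list(group = cmp, symptom = cor)
  }

  make_report(list(config = config, design = design, bms = bms,
                   evidence = evid, retention = retention, ppi = ppi,
                   manifest = cohorts$manifest))
}

#' Assemble the run report
#'
#' Collects the per-group, per-emotion winning family/model with their
#' posteriors into a group-by-emotion summary table, together with retention
#' counts and PPI decisions; writes `report.md`, `report.json` and a
#' provenance record (config hash, evidence-file hashes) when the config
#' names an output directory, and verifies any cached evidence files
#' against their recorded hashes.
#'
#' @param artifacts list with `config`, `bms`, `evidence`, `retention`,
#'   `ppi`, `manifest` (as built by [run_all()]).
#' @return object of class `run_report`.
#' @export
make_report <- function(artifacts) {
  need <- c("config", "bms", "evidence", "retention", "ppi")
  miss <- setdiff(need, names(artifacts))
  if (length(miss)) stop("missing artifact: ", paste(miss, collapse = ", "))
  config <- artifacts$config
  rows <- do.call(rbind, lapply(names(artifacts$bms), function(lab) {
    b <- artifacts$bms[[lab]]
    parts <- strsplit(lab, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1], emotion = parts[2],
               family = b$winning_family,
               family_posterior =
                 unname(b$family_posterior[as.character(b$winning_family)]),
               model = b$winning_model,
               model_posterior =
                 unname(b$within_family_posterior[as.character(b$winning_model)]),
               stringsAsFactors = FALSE)
  }))
  ppi_rows <- do.call(rbind, lapply(names(artifacts$ppi), function(emo) {
    tb <- artifacts$ppi[[emo]]$group$table
    data.frame(emotion = emo, target = tb$target, diff = tb$diff,
               p_fwe = tb$p_fwe, significant = tb$significant,
               direction = tb$direction, stringsAsFactors = FALSE)
  }))
  caveat <- if (any(artifacts$retention$n_included < 8))
    "low-n: fewer than 8 included subjects in a group; selection outcomes are unstable" else NULL

  provenance <- list(package_version =
                       as.character(utils::packageVersion("emoconn")),
                     master_seed = config$master_seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(config$out_dir, "run_config.yaml")
    write_run_config(config, cfg_path)
    provenance$config_md5 <- unname(tools::md5sum(cfg_path))
    ev_files <- list.files(file.path(config$out_dir, "evidences"),
                           full.names = TRUE)
    provenance$evidence_md5 <- tools::md5sum(ev_files)
    hash_path <- file.path(config$out_dir, "evidence_hashes.txt")
    if (file.exists(hash_path)) {
      old <- utils::read.table(hash_path, stringsAsFactors = FALSE)
      cur <- provenance$evidence_md5[old$V1]
      if (any(cur != old$V2, na.rm = TRUE))
        stop("provenance error: evidence file hash mismatch for ",
             paste(old$V1[which(cur != old$V2)], collapse = ", "))
    } else if (length(ev_files)) {
      utils::write.table(data.frame(names(provenance$evidence_md5),
                                    unname(provenance$evidence_md5)),
                         hash_path, row.names = FALSE, col.names = FALSE)
    }
  }
  report <- structure(list(selection = rows, retention = artifacts$retention,
                           ppi = ppi_rows,
                           symptom = lapply(artifacts$ppi, `[[`, "symptom"),
                           caveat = caveat, provenance = provenance),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(format_report_md(report),
               file.path(config$out_dir, "report.md"))
  }
  report
}

format_report_md <- function(report) {
  md <- c("# Effective connectivity run report", "",
          "## Bayesian model selection (winning family / model)", "",
          "| Group | Emotion | Family | Family posterior | Model | Within-family posterior |",
          "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report$selection))) {
    r <- report$selection[i, ]
    md <- c(md, sprintf("| %s | %s | F%d | %.3f | %d | %.3f |",
                        r$group, r$emotion, r$family, r$family_posterior,
                        r$model, r$model_posterior))
  }
  md <- c(md, "", "## Retention", "",
          sprintf("- %s: %d of %d included", report$retention$group,
                  report$retention$n_included, report$retention$n_recruited),
          "", "## PPI group comparisons (amygdala seed)", "")
  for (i in seq_len(nrow(report$ppi))) {
    r <- report$ppi[i, ]
    md <- c(md, sprintf("- %s / %s: diff %.3f (%s), p_fwe = %.4f%s",
                        r$emotion, r$target, r$diff, r$direction, r$p_fwe,
                        if (r$significant) " *" else ""))
  }
  if (!is.null(report$caveat)) md <- c(md, "", paste("Caveat:", report$caveat))
  md
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
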