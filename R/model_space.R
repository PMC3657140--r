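#' Structural candidate models
#'
#' The first model-selection stage compares seven structurally distinct
#' intrinsic architectures over V1, FG, amygdala and OFC, all driven by the
#' all-faces input into V1: serial and parallel feedforward chains, their
#' feedback-augmented variants, hub-centred bidirectional networks, and the
#' fully interconnected model (both directions for every FG/AMY/OFC pair
#' plus V1-FG in both directions), which is the designated winner used to
#' host the modulatory model space.
#'
#' @return list of 7 `structural_model` objects, each with `id`, `edges`
#'   (list of `c(src, dst)`), and `driving` (always faces into V1).
#' @export
build_structural_space <- function() {
  amy_ofc <- list(c("AMY", "OFC"), c("OFC", "AMY"))
  fg_amy <- list(c("FG", "AMY"), c("AMY", "FG"))
  fg_ofc <- list(c("FG", "OFC"), c("OFC", "FG"))
  defs <- list(
    list(c("V1", "FG"), c("FG", "AMY"), c("AMY", "OFC")),
    list(c("V1", "FG"), c("FG", "AMY"), c("FG", "OFC")),
    list(c("V1", "FG"), c("FG", "V1"), c("FG", "AMY"), c("AMY", "FG"),
         c("AMY", "OFC"), c("OFC", "AMY")),
    list(c("V1", "FG"), c("FG", "V1"), c("FG", "AMY"), c("AMY", "FG"),
         c("FG", "OFC"), c("OFC", "FG")),
    c(list(c("V1", "FG")), fg_amy, fg_ofc),
    c(list(c("V1", "FG")), fg_amy, fg_ofc, amy_ofc),
    c(list(c("V1", "FG"), c("FG", "V1")), fg_amy, fg_ofc, amy_ofc)
  )
  lapply(seq_along(defs), function(i) {
    structure(list(id = i, edges = defs[[i]],
                   driving = list(faces = "V1")),
              class = "structural_model")
  })
}

#' The fully interconnected structural winner
#'
#' @return the `structural_model` hosting the modulatory space (id 7).
#' @export
winning_structural_model <- function() {
  build_structural_space()[[7]]
}

edge_key <- function(edges) {
  paste(sort(vapply(edges, paste, "", collapse = "->")), collapse = ";")
}

allowed_modulated_edges <- function() {
  regs <- c("FG", "AMY", "OFC")
  out <- list()
  for (s in regs) for (d in regs) if (s != d) out <- c(out, list(c(s, d)))
  out
}

#' Build (or load) the 21-model modulatory space
#'
#' The space is table-driven: a YAML file lists, for each model, its id,
#' family and modulated directed edges among FG, AMY and OFC. The shipped
#' default satisfies every structural constraint of the published space
#' (21 models; 7 families partitioning them; Family 1 = the six single-edge
#' models with Model 2 = FG to OFC and Model 5 = OFC to FG; Family 7 = the
#' three two-pair bidirectional models with Model 21 = OFC-AMY plus OFC-FG,
#' both directions). The loader validates these invariants and rejects
#' files that break them.
#'
#' @param path YAML file; defaults to the table shipped with the package.
#' @return list of 21 `modulatory_model` objects (`id`, `family`, `edges`).
#' @export
build_modulatory_space <- function(path = system.file("extdata",
                                                      "model_space.yaml",
                                                      package = "emoconn")) {
  raw <- yaml::read_yaml(path)$models
  models <- lapply(raw, function(m) {
    structure(list(id = as.integer(m$id), family = as.integer(m$family),
                   edges = lapply(m$edges, unlist)),
              class = "modulatory_model")
  })
  validate_model_space(models)
  models
}

#' Validate a modulatory model space
#'
#' @param models list of `modulatory_model` objects.
#' @return invisibly `TRUE`; errors on any violated invariant.
#' @export
validate_model_space <- function(models) {
  ids <- vapply(models, `[[`, 1L, "id")
  fams <- vapply(models, `[[`, 1L, "family")
  if (length(models) != 21L || !identical(sort(ids), 1:21))
    stop("model space must contain models 1..21 exactly")
  if (!identical(sort(unique(fams)), 1:7))
    stop("families must be numbered 1..7 and each non-empty")
  keys <- vapply(models, function(m) edge_key(m$edges), "")
  if (anyDuplicated(keys)) stop("modulated edge-sets must be pairwise distinct")
  allowed <- vapply(allowed_modulated_edges(), paste, "", collapse = "->")
  for (m in models) {
    if (length(m$edges) == 0L)
      stop(sprintf("model %d has an empty modulated set", m$id))
    ek <- vapply(m$edges, paste, "", collapse = "->")
    if (!all(ek %in% allowed))
      stop(sprintf("model %d modulates a non-candidate edge", m$id))
  }
  by_id <- function(i) models[[which(ids == i)]]
  f1 <- which(fams == by_id(2)$family)
  if (length(f1) != 6L || any(vapply(models[f1], function(m)
    length(m$edges), 1L) != 1L))
    stop("the family containing Model 2 must be the six single-edge models")
  if (edge_key(by_id(2)$edges) != "FG->OFC")
    stop("Model 2 must modulate the single FG to OFC connection")
  if (edge_key(by_id(5)$edges) != "OFC->FG")
    stop("Model 5 must modulate the single OFC to FG connection")
  if (by_id(2)$family != by_id(5)$family)
    stop("Models 2 and 5 must share a family")
  f7 <- which(fams == by_id(21)$family)
  if (length(f7) != 3L)
    stop("the family containing Model 21 must have exactly 3 members")
  if (edge_key(by_id(21)$edges) !=
      edge_key(list(c("OFC", "AMY"), c("AMY", "OFC"),
                    c("OFC", "FG"), c("FG", "OFC"))))
    stop("Model 21 must modulate OFC-AMY and OFC-FG bidirectionally")
  invisible(TRUE)
}

#' Family partition of a model space
#'
#' @param models list from [build_modulatory_space()].
#' @return named list mapping family id (as character) to member model ids.
#' @export
family_map <- function(models) {
  fams <- vapply(models, `[[`, 1L, "family")
  ids <- vapply(models, `[[`, 1L, "id")
  split(ids, fams)
}

#' Combine structural and modulatory models into a DCM specification
#'
#' @param structural a `structural_model` (typically the fully connected
#'   winner).
#' @param modulatory a `modulatory_model`.
#' @param emotion name of the emotion whose input modulates the edges
#'   (`"happy"`, `"sad"` or `"fear"`).
#' @param nuisance_emotion optional second emotion added as a nuisance
#'   modulator acting on every edge among the non-input regions. When
#'   the data contain modulations by more than one emotion, fitting one
#'   emotion alone is misspecified: the unmodelled modulation leaks into
#'   the intrinsic coupling estimates and biases model comparison. The
#'   nuisance modulator is deliberately saturated (all interconnections
#'   free) so it carries no information about the candidate under test.
#' @return a [dcm_spec()] with the emotion as modulator of the
#'   candidate's edges (plus the optional nuisance modulator) and faces
#'   driving V1.
#' @export
to_dcm_spec <- function(structural, modulatory, emotion,
                        nuisance_emotion = NULL) {
  stopifnot(inherits(structural, "structural_model"),
            inherits(modulatory, "modulatory_model"))
  if (length(structural$edges) == 0L) stop("structural model has no edges")
  emotion <- match.arg(emotion, c("happy", "sad", "fear"))
  skeys <- vapply(structural$edges, paste, "", collapse = "->")
  mkeys <- vapply(modulatory$edges, paste, "", collapse = "->")
  if (!all(mkeys %in% skeys))
    stop(sprintf("model %d modulates edges absent from structural model %d",
                 modulatory$id, structural$id))
  mod <- list(modulatory$edges)
  names(mod) <- emotion
  if (!is.null(nuisance_emotion)) {
    nuisance_emotion <- match.arg(nuisance_emotion,
                                  c("happy", "sad", "fear"))
    if (nuisance_emotion == emotion)
      stop("nuisance emotion must differ from the tested emotion")
    driven <- unique(unlist(structural$driving))
    inter <- Filter(function(e) !any(e %in% driven), structural$edges)
    if (!length(inter))
      stop("structural model has no edges between non-input regions")
    mod[[nuisance_emotion]] <- inter
  }
  dcm_spec(intrinsic_edges = structural$edges,
           modulated_edges = mod,
           driving = structural$driving)
}
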