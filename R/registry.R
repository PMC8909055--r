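# NTCP model registry: config-driven set of published dose-response models,
# their CTS weights and model-based selection (MBS) thresholds.

#' One NTCP registry entry
#'
#' @param model_id unique identifier, e.g. `"xerostomia_loizeau"`.
#' @param organ structure_id the model reads its dose from.
#' @param endpoint free-text endpoint with grade and time horizon.
#' @param form one of `"lkb_probit"`, `"logistic_linear"`,
#'   `"loglogistic_d50_gamma"`.
#' @param dose_summary list: `type` in mean/geud/dx plus `a` or `x`.
#' @param parameters named list of model parameters (see [evaluate_model()]).
#' @param weight non-negative CTS weight.
#' @param mbs logical; member of the 7-model MBS set?
#' @param threshold_standard,threshold_young MBS thresholds in percentage
#'   points (required when `mbs` is TRUE).
#' @param evidence_level 3 or 4 (published level-of-evidence class).
#' @param reference citation key of the source publication.
#' @return an `ntcp_model_spec`.
#' @export
ntcp_model_spec <- function(model_id, organ, endpoint, form, dose_summary,
                            parameters, weight, mbs = FALSE,
                            threshold_standard = NULL, threshold_young = NULL,
                            evidence_level = NA_integer_, reference = NA_character_) {
  if (!form %in% c("lkb_probit", "logistic_linear", "loglogistic_d50_gamma"))
    abort("model '%s': unknown form '%s'", model_id, form)
  if (!is_scalar_number(weight) || weight < 0)
    abort("model '%s': weight must be a non-negative number", model_id)
  if (isTRUE(mbs) && (is.null(threshold_standard) || is.null(threshold_young)))
    abort("MBS model '%s' must carry both standard and young thresholds", model_id)
  if (form == "lkb_probit") {
    for (nm in c("td50", "m"))
      if (!is_scalar_number(parameters[[nm]] %||% NA))
        abort("model '%s': lkb_probit needs numeric parameter '%s'", model_id, nm)
  }
  if (form == "loglogistic_d50_gamma") {
    for (nm in c("d50", "gamma50"))
      if (!is_scalar_number(parameters[[nm]] %||% NA))
        abort("model '%s': loglogistic needs numeric parameter '%s'", model_id, nm)
  }
  if (form == "logistic_linear" && !is_scalar_number(parameters$intercept %||% NA))
    abort("model '%s': logistic_linear needs numeric 'intercept'", model_id)
  structure(
    list(model_id = model_id, organ = organ, endpoint = endpoint, form = form,
         dose_summary = dose_summary, parameters = parameters,
         weight = weight, mbs = isTRUE(mbs),
         threshold_standard = threshold_standard,
         threshold_young = threshold_young,
         evidence_level = evidence_level, reference = reference),
    class = "ntcp_model_spec")
}

#' Assemble and validate an NTCP registry
#'
#' Enforces the structural invariants at load time: CTS weights sum to unity
#' (within 1e-9) and every MBS member carries both threshold sets. Violations
#' are configuration errors raised immediately, not at scoring time.
#'
#' @param models list of `ntcp_model_spec` entries.
#' @param composite_threshold composite MBS threshold in percentage points
#'   (default 35, i.e. an ideal concomitant 5-point gain on each of 7 models).
#' @return an `ntcp_registry`.
#' @export
ntcp_registry <- function(models, composite_threshold = 35) {
  ok <- vapply(models, inherits, logical(1), "ntcp_model_spec")
  if (!all(ok)) abort("registry entries must be ntcp_model_spec objects")
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) abort("duplicate model_id in registry: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  w <- vapply(models, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    abort("CTS weights must sum to unity; got %.12f", sum(w))
  names(models) <- ids
  structure(list(models = models, composite_threshold = composite_threshold),
            class = "ntcp_registry")
}

#' @export
print.ntcp_registry <- function(x, ...) {
  n_mbs <- sum(vapply(x$models, `[[`, logical(1), "mbs"))
  cat(sprintf("<ntcp_registry> %d models (%d in the MBS set), composite threshold %.0f points\n",
              length(x$models), n_mbs, x$composite_threshold))
  for (m in x$models)
    cat(sprintf("  %-28s %-14s w=%.3f%s\n", m$model_id, m$organ, m$weight,
                if (m$mbs) sprintf("  MBS thr %.1f/%.1f", m$threshold_standard,
                                   m$threshold_young) else ""))
  invisible(x)
}

registry_model_ids <- function(registry) names(registry$models)

mbs_model_ids <- function(registry) {
  names(registry$models)[vapply(registry$models, `[[`, logical(1), "mbs")]
}

#' CTS weight set of a registry
#'
#' @param registry an `ntcp_registry`.
#' @return named numeric vector of weights summing to 1.
#' @export
weight_set <- function(registry) {
  stopifnot(inherits(registry, "ntcp_registry"))
  vapply(registry$models, `[[`, numeric(1), "weight")
}

#' MBS threshold set of a registry
#'
#' @param registry an `ntcp_registry`.
#' @param mode `"standard"` or `"young"` (relaxed thresholds for patients
#'   with long life expectancy).
#' @return a `threshold_set`: list with `mode`, named `thresholds`
#'   (percentage points, one per MBS model) and `composite` threshold.
#' @export
threshold_set <- function(registry, mode = c("standard", "young")) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "ntcp_registry"))
  ids <- mbs_model_ids(registry)
  field <- if (mode == "standard") "threshold_standard" else "threshold_young"
  thr <- vapply(registry$models[ids], function(m) as.numeric(m[[field]]), numeric(1))
  structure(list(mode = mode, thresholds = thr,
                 composite = registry$composite_threshold),
            class = "threshold_set")
}

#' Read an NTCP registry from a YAML or JSON config file
#'
#' The config carries one block per model (`id`, `organ`, `endpoint`, `form`,
#' `dose_summary`, `parameters`, `weight`, `mbs`, `threshold_standard`,
#' `threshold_young`, `evidence_level`, `reference`) plus a top-level
#' `composite_threshold`. See the file returned by
#' `system.file("extdata", "ntcp_registry_synthetic.yaml", package =
#' "protonMBS")` for the documented schema.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return an `ntcp_registry`.
#' @export
read_ntcp_registry <- function(path) {
  if (!file.exists(path)) abort("registry file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$models)) abort("%s: registry config needs a 'models' list", path)
  models <- lapply(cfg$models, function(m) {
    ntcp_model_spec(
      model_id = m$id %||% abort("%s: model block without id", path),
      organ = m$organ, endpoint = m$endpoint %||% "",
      form = m$form, dose_summary = m$dose_summary %||% list(type = "mean"),
      parameters = m$parameters,
      weight = m$weight,
      mbs = isTRUE(m$mbs),
      threshold_standard = m$threshold_standard,
      threshold_young = m$threshold_young,
      evidence_level = m$evidence_level %||% NA_integer_,
      reference = m$reference %||% NA_character_)
  })
  ntcp_registry(models, composite_threshold = cfg$composite_threshold %||% 35)
}

#' The default 16-model registry
#'
#' Loads the registry shipped with the package: 16 head-and-neck NTCP models
#' spanning xerostomia, dysphagia, trismus, brain necrosis, temporal-lobe
#' infarction, optic toxicity, mucositis, laryngeal edema, aspiration,
#' swallowing dysfunction, parotid flow loss, tinnitus and hypothyroidism.
#' CTS weights, MBS membership and threshold sets are the published ones; the
#' dose-response parameters in the shipped file are synthetic representative
#' values (see the file header) to be replaced with transcriptions from the
#' cited source publications for clinical use.
#'
#' @return an `ntcp_registry` with 16 entries, 7 of them MBS members.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "ntcp_registry_synthetic.yaml",
                      package = "protonMBS", mustWork = TRUE)
  read_ntcp_registry(path)
}
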