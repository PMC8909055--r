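# Command-line orchestration: simulate / evaluate / select / report
# subcommands over the package's functions, with a provenance manifest in
# every output directory. A thin Rscript wrapper lives in
# inst/scripts/mbs_pipeline.R.

log_event <- function(level, fmt, ...) {
  message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, sprintf(fmt, ...)))
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]; i <- i + 2L
    } else {
      flags[[key]] <- TRUE; i <- i + 1L
    }
  }
  flags
}

file_digest <- function(path) unname(tools::md5sum(path))

write_manifest <- function(out_dir, seed = NULL, mode = NULL, registry_path = NULL,
                           inputs = character()) {
  # keyed by basename so identical content hashes identically regardless of
  # where the inputs live
  digests <- lapply(inputs[file.exists(inputs)], file_digest)
  names(digests) <- basename(inputs[file.exists(inputs)])
  manifest <- list(
    tool = "protonMBS", version = as.character(utils::packageVersion("protonMBS")),
    seed = seed, threshold_mode = mode,
    registry = if (!is.null(registry_path))
      list(path = registry_path, md5 = file_digest(registry_path)) else NULL,
    input_digests = digests)
  # hash over the deterministic fields only, so reruns with identical inputs
  # produce identical hashes (and byte-identical downstream reports)
  manifest$manifest_hash <- substr(digest_of(manifest), 1, 12)
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  manifest
}

digest_of <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null"), tmp)
  file_digest(tmp)
}

#' Run the analysis pipeline from command-line style arguments
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--n <int> --seed <int> --out <dir> [--bin-width <gy>]` —
#'     generate a paired synthetic cohort and write `dvh.csv`,
#'     `covariates.csv`, `prescriptions.csv`.}
#'   \item{evaluate}{`--dvh <csv> --covariates <csv> [--registry <yaml>]
#'     --out <dir>` — per-patient, per-model NTCP for both plans
#'     (`ntcp.csv`).}
#'   \item{select}{`--dvh <csv> --covariates <csv> [--registry <yaml>]
#'     [--mode standard|young] [--clamp-negative] --out <dir>` — full
#'     selection: cohort CSV, per-patient JSON verdicts under `verdicts/`, a
#'     registry echo and a plain-text passing-rate report.}
#'   \item{report}{`--in <select-output-dir>` — print the report of a
#'     previous `select` run.}
#' }
#' Every output directory receives exactly one `manifest.json` recording
#' seed, threshold mode, registry digest and input file digests; reports
#' embed the manifest hash. Validation failures (e.g. a registry whose
#' weights do not sum to unity, a malformed DVH file) abort with a nonzero
#' status before any output is written.
#'
#' @param args character vector of CLI arguments (subcommand first).
#' @return invisibly, 0 on success (errors propagate as conditions; the
#'   script wrapper maps them to exit status 1).
#' @export
run_pipeline <- function(args) {
  if (length(args) == 0L)
    abort("usage: mbs_pipeline <simulate|evaluate|select|report> [--flags]")
  cmd <- args[1]
  flags <- parse_flags(args[-1])
  switch(cmd,
    simulate = pipeline_simulate(flags),
    evaluate = pipeline_evaluate(flags),
    select = pipeline_select(flags),
    report = pipeline_report(flags),
    abort("unknown subcommand '%s' (expected simulate/evaluate/select/report)", cmd))
  invisible(0L)
}

pipeline_simulate <- function(flags) {
  out <- flags$out %||% abort("simulate: --out is required")
  n <- as.integer(flags$n %||% 50)
  seed <- as.integer(flags$seed %||% 1)
  bw <- as.numeric(flags[["bin-width"]] %||% 0.1)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_event("INFO", "simulating cohort: n=%d seed=%d bin_width=%.2f", n, seed, bw)
  coh <- generate_cohort(generator_config(n_patients = n, seed = seed,
                                          bin_width = bw))
  write_dvh_csv(coh$plans, file.path(out, "dvh.csv"))
  write_covariates_csv(coh$covariates, file.path(out, "covariates.csv"))
  write_prescriptions_csv(coh, file.path(out, "prescriptions.csv"))
  write_manifest(out, seed = seed)
  log_event("INFO", "wrote %s", file.path(out, "dvh.csv"))
}

pipeline_registry <- function(flags) {
  if (!is.null(flags$registry)) read_ntcp_registry(flags$registry)
  else default_registry()
}

pipeline_cohort <- function(flags) {
  dvh <- flags$dvh %||% abort("--dvh is required")
  cov <- flags$covariates %||% abort("--covariates is required")
  read_cohort(dvh, cov, flags$prescriptions)
}

pipeline_evaluate <- function(flags) {
  out <- flags$out %||% abort("evaluate: --out is required")
  registry <- pipeline_registry(flags)
  coh <- pipeline_cohort(flags)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pid in names(coh$plans)) {
    pcov <- coh$covariates[coh$covariates$patient_id == pid, , drop = FALSE]
    for (mod in names(coh$plans[[pid]])) {
      v <- withCallingHandlers(
        evaluate_plan_ntcp(registry, coh$plans[[pid]][[mod]], pcov),
        warning = function(w) {
          log_event("WARNING", "%s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, plan = mod, model_id = names(v),
        ntcp = as.numeric(v), stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(out, "ntcp.csv"),
                   row.names = FALSE)
  write_manifest(out, registry_path = flags$registry,
                 inputs = c(flags$dvh, flags$covariates))
  log_event("INFO", "wrote %s", file.path(out, "ntcp.csv"))
}

pipeline_select <- function(flags) {
  out <- flags$out %||% abort("select: --out is required")
  mode <- flags$mode %||% "standard"
  if (!mode %in% c("standard", "young"))
    abort("--mode must be standard or young")
  registry <- pipeline_registry(flags)
  coh <- pipeline_cohort(flags)
  clamp <- isTRUE(flags[["clamp-negative"]])
  fit <- withCallingHandlers(
    mbs(coh, registry, mode = mode, clamp_negative = clamp),
    warning = function(w) {
      log_event("WARNING", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  dir.create(file.path(out, "verdicts"), recursive = TRUE, showWarnings = FALSE)
  manifest <- write_manifest(out, mode = mode, registry_path = flags$registry,
                             inputs = c(flags$dvh, flags$covariates))
  # cohort CSV: covariates + scores + verdicts
  cohort_tab <- merge(fit$covariates, fit$eligibility, by = "patient_id")
  utils::write.csv(cohort_tab, file.path(out, "cohort.csv"), row.names = FALSE)
  # per-patient JSON verdicts
  for (i in seq_len(nrow(fit$eligibility))) {
    row <- fit$eligibility[i, ]
    jsonlite::write_json(
      list(patient_id = row$patient_id, mode = row$mode,
           clamp_negative = clamp,
           delta_ntcp = as.list(fit$delta[row$patient_id, ]),
           single_pass = as.list(fit$single_pass[row$patient_id, ]),
           composite_sum = row$composite_sum, cts = row$cts,
           eligible = row$eligible, reason = row$reason,
           manifest_hash = manifest$manifest_hash),
      file.path(out, "verdicts", paste0(row$patient_id, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  # registry echo (model table) + plain-text report
  reg_tab <- do.call(rbind, lapply(registry$models, function(m)
    data.frame(model_id = m$model_id, organ = m$organ, endpoint = m$endpoint,
               form = m$form, weight = m$weight, mbs = m$mbs,
               threshold_standard = m$threshold_standard %||% NA,
               threshold_young = m$threshold_young %||% NA,
               stringsAsFactors = FALSE)))
  utils::write.csv(reg_tab, file.path(out, "registry_echo.csv"), row.names = FALSE)
  writeLines(render_report(fit, manifest), file.path(out, "report.txt"))
  log_event("INFO", "selection complete: %d/%d eligible (%s mode)",
            eligibility_summary(fit)$n_eligible, nrow(fit$eligibility), mode)
}

render_report <- function(fit, manifest) {
  s <- summary(fit)
  txt <- utils::capture.output(print(s))
  c(sprintf("protonMBS selection report  [manifest %s]", manifest$manifest_hash),
    sprintf("negative-delta handling: %s",
            if (fit$clamp_negative) "clamped at zero in composite sum"
            else "included as-is in composite sum"),
    "", txt,
    "", "Note: per-endpoint p-values carry no multiple-testing correction.")
}

pipeline_report <- function(flags) {
  dir <- flags[["in"]] %||% abort("report: --in <select output dir> is required")
  path <- file.path(dir, "report.txt")
  if (!file.exists(path)) abort("no report.txt under %s (run select first)", dir)
  cat(readLines(path), sep = "\n")
}
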