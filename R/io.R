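# Plain-text I/O: the DVH CSV dialect, covariate and prescription tables.
#
# DVH CSV dialect (one row per structure dose point, dose ascending within
# structure, cumulative volume fractions):
#   patient_id, plan, structure, total_volume_cc, dose_gy, cum_volume_fraction

DVH_CSV_COLUMNS <- c("patient_id", "plan", "structure", "total_volume_cc",
                     "dose_gy", "cum_volume_fraction")

#' Write paired-plan DVHs to CSV
#'
#' Emits the package's DVH dialect: UTF-8 CSV with header
#' `patient_id, plan, structure, total_volume_cc, dose_gy,
#' cum_volume_fraction`, cumulative fractions, dose ascending within each
#' structure. Reading the file back reproduces the DVHs within 1e-9.
#'
#' @param plans either a single `plan_record`, a list of `plan_record`s, or a
#'   cohort-style named list of `list(photon = , proton = )` pairs.
#' @param path output file path.
#' @return invisibly, the number of rows written.
#' @export
write_dvh_csv <- function(plans, path) {
  recs <- flatten_plans(plans)
  rows <- lapply(recs, function(p) {
    do.call(rbind, lapply(p$structures, function(s) {
      cc <- cum_dvh(s)
      data.frame(patient_id = p$patient_id, plan = p$modality,
                 structure = cc$structure_id,
                 total_volume_cc = cc$total_volume_cc,
                 dose_gy = cc$dose, cum_volume_fraction = cc$frac,
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(nrow(tab))
}

flatten_plans <- function(plans) {
  if (inherits(plans, "plan_record")) return(list(plans))
  recs <- list()
  for (el in plans) {
    if (inherits(el, "plan_record")) recs[[length(recs) + 1L]] <- el
    else if (is.list(el)) for (p in el) {
      if (!inherits(p, "plan_record")) abort("write_dvh_csv: unrecognised plans input")
      recs[[length(recs) + 1L]] <- p
    } else abort("write_dvh_csv: unrecognised plans input")
  }
  recs
}

#' Read paired-plan DVHs from CSV
#'
#' Parses the DVH dialect written by [write_dvh_csv()]. Malformed files fail
#' with a line-numbered parse error; dose grids must be ascending within each
#' (patient, plan, structure) block.
#'
#' @param path CSV file path.
#' @return a named list (by patient) of `list(photon = plan_record,
#'   proton = plan_record)`; a missing modality is absent rather than NULL.
#' @export
read_dvh_csv <- function(path) {
  if (!file.exists(path)) abort("DVH file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(DVH_CSV_COLUMNS, names(tab))
  if (length(missing_cols))
    abort("%s: missing columns: %s", path, paste(missing_cols, collapse = ", "))
  for (col in c("total_volume_cc", "dose_gy", "cum_volume_fraction")) {
    bad <- which(!is.finite(tab[[col]]))
    if (length(bad))
      abort("%s: non-numeric %s at data line %d", path, col, bad[1] + 1L)
  }
  bad_plan <- which(!tab$plan %in% c("photon", "proton"))
  if (length(bad_plan))
    abort("%s: plan must be photon/proton at data line %d", path, bad_plan[1] + 1L)
  out <- list()
  for (pid in unique(tab$patient_id)) {
    ptab <- tab[tab$patient_id == pid, , drop = FALSE]
    pair <- list()
    for (mod in unique(ptab$plan)) {
      mtab <- ptab[ptab$plan == mod, , drop = FALSE]
      structs <- list()
      for (sid in unique(mtab$structure)) {
        stab <- mtab[mtab$structure == sid, , drop = FALSE]
        if (is.unsorted(stab$dose_gy, strictly = TRUE)) {
          ln <- as.integer(rownames(stab)[which(diff(stab$dose_gy) <= 0)[1] + 1L]) + 1L
          abort("%s: dose not strictly ascending for %s/%s/%s at data line %d",
                path, pid, mod, sid, ln)
        }
        structs[[sid]] <- structure_dvh(sid, stab$total_volume_cc[1],
                                        stab$dose_gy, stab$cum_volume_fraction,
                                        "cumulative")
      }
      pair[[mod]] <- plan_record(as.character(pid), mod, structs)
    }
    out[[as.character(pid)]] <- pair
  }
  out
}

#' Write a patient covariate table to CSV
#'
#' @param covariates `data.frame` with at least `patient_id`, `age`,
#'   `t_stage`, `n_stage`, `overall_stage`, `treatment`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_covariates_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a patient covariate table from CSV
#'
#' Validates the categorical levels: T stage 1-4, N stage 0-3, treatment one
#' of "RT alone", "RT-CHT", "iCHT+RT-CHT".
#'
#' @param path CSV file path.
#' @return a `data.frame` of covariates.
#' @export
read_covariates_csv <- function(path) {
  if (!file.exists(path)) abort("covariate file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("patient_id", "age", "t_stage", "n_stage", "treatment")
  miss <- setdiff(req, names(tab))
  if (length(miss)) abort("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  tab$patient_id <- as.character(tab$patient_id)
  validate_covariates(tab)
  tab
}

validate_covariates <- function(tab) {
  if (!all(tab$t_stage %in% 1:4))
    abort("t_stage outside 1-4 for patient(s) %s",
          paste(tab$patient_id[!tab$t_stage %in% 1:4], collapse = ", "))
  if (!all(tab$n_stage %in% 0:3))
    abort("n_stage outside 0-3 for patient(s) %s",
          paste(tab$patient_id[!tab$n_stage %in% 0:3], collapse = ", "))
  ok_trt <- c("RT alone", "RT-CHT", "iCHT+RT-CHT")
  if (!all(tab$treatment %in% ok_trt))
    abort("treatment must be one of %s", paste(ok_trt, collapse = " / "))
  if (anyDuplicated(tab$patient_id))
    abort("duplicate patient_id in covariate table")
  invisible(TRUE)
}

#' Write prescription levels to CSV
#'
#' One row per (patient, target dose level): `patient_id, target, dose_gy,
#' fractions`.
#'
#' @param cohort a cohort list as returned by [generate_cohort()], or a list
#'   of plan pairs whose photon plans carry prescriptions.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_prescriptions_csv <- function(cohort, path) {
  plans <- if (!is.null(cohort$plans)) cohort$plans else cohort
  rows <- lapply(plans, function(pair) {
    p <- pair$photon %||% pair[[1]]
    if (is.null(p$prescriptions)) return(NULL)
    cbind(patient_id = p$patient_id, p$prescriptions)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble a cohort from plain-text inputs
#'
#' @param dvh_path DVH CSV (see [read_dvh_csv()]).
#' @param covariates_path covariate CSV (see [read_covariates_csv()]).
#' @param prescriptions_path optional prescriptions CSV.
#' @return a cohort list with elements `covariates` (data.frame) and `plans`
#'   (named list of photon/proton `plan_record` pairs), the input shape of
#'   [mbs()].
#' @export
read_cohort <- function(dvh_path, covariates_path, prescriptions_path = NULL) {
  plans <- read_dvh_csv(dvh_path)
  cov <- read_covariates_csv(covariates_path)
  if (!setequal(names(plans), cov$patient_id))
    abort("patients differ between DVH file and covariate table")
  plans <- plans[cov$patient_id]
  if (!is.null(prescriptions_path)) {
    rx <- utils::read.csv(prescriptions_path, stringsAsFactors = FALSE)
    rx$patient_id <- as.character(rx$patient_id)
    for (pid in names(plans)) {
      sub <- rx[rx$patient_id == pid, c("target", "dose_gy", "fractions"), drop = FALSE]
      if (nrow(sub)) {
        for (mod in names(plans[[pid]]))
          plans[[pid]][[mod]]$prescriptions <- sub
      }
    }
  }
  for (pid in names(plans)) {
    pair <- plans[[pid]]
    if (!is.null(pair$photon) && !is.null(pair$proton))
      validate_plan_pair(pair$photon, pair$proton)
  }
  list(covariates = cov, plans = plans)
}
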