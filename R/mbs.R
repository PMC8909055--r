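# Central entry point: evaluate the NTCP registry on a paired cohort and
# derive per-patient scores and eligibility verdicts, returned as a classed
# object in the style of a fitted-model result.

#' Model-based selection analysis of a paired photon/proton cohort
#'
#' Evaluates every registry NTCP model on both plans of each patient,
#' computes the photon-minus-proton differences \eqn{\Delta NTCP_{x-p}} in
#' percentage points, the comprehensive toxicity score
#' \eqn{CTS = \sum_i w_i \Delta NTCP_i}, and the MBS eligibility verdict
#' (single-endpoint strict threshold or composite sum \eqn{\ge} 35 points
#' over the 7 MBS models).
#'
#' Threshold mode is selected per run and applied to the whole cohort by
#' default (an in-silico design choice: age is assumed not to change plan
#' optimization). With `age_switch = TRUE` the young threshold set is instead
#' applied per patient below `age_cutoff` years.
#'
#' @param cohort a cohort list with elements `covariates` (data.frame with at
#'   least `patient_id`; `age`, `t_stage`, `n_stage` enable age switching and
#'   stratified tables) and `plans` (named list of
#'   `list(photon = plan_record, proton = plan_record)`), as produced by
#'   [generate_cohort()] or [read_cohort()].
#' @param registry an `ntcp_registry` (default: the shipped 16-model set).
#' @param mode `"standard"` or `"young"` MBS thresholds.
#' @param clamp_negative floor negative MBS differences at zero in the
#'   composite sum? Off by default; the choice is recorded in the object and
#'   every report.
#' @param age_switch apply young thresholds to patients younger than
#'   `age_cutoff` instead of one cohort-wide mode?
#' @param age_cutoff age in years below which `age_switch` selects the young
#'   set (default 40).
#' @return an object of class `mbs_selection` with components
#'   `ntcp_photon`/`ntcp_proton` (patients x models probability matrices),
#'   `delta` (percentage points), `cts`, `eligibility` (data.frame),
#'   `single_pass` (patients x MBS-models logical matrix), per-structure
#'   `davg_*`/`d1_*` matrices, `integral_dose_photon/proton`, `covariates`,
#'   `registry`, `mode`. Methods: [print.mbs_selection()],
#'   [summary.mbs_selection()], [plot.mbs_selection()],
#'   [predict.mbs_selection()].
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_config(n_patients = 6, seed = 42))
#' fit <- mbs(coh)
#' fit
#' summary(fit)
#' }
#' @export
mbs <- function(cohort, registry = default_registry(),
                mode = c("standard", "young"), clamp_negative = FALSE,
                age_switch = FALSE, age_cutoff = 40) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "ntcp_registry"))
  if (is.null(cohort$plans) || is.null(cohort$covariates))
    abort("cohort must carry 'covariates' and 'plans' (see generate_cohort / read_cohort)")
  cov <- cohort$covariates
  plans <- cohort$plans
  ids <- cov$patient_id
  if (!setequal(names(plans), ids))
    abort("covariate table and plan list cover different patients")
  model_ids <- registry_model_ids(registry)
  mids <- mbs_model_ids(registry)
  weights <- weight_set(registry)
  thr_std <- threshold_set(registry, "standard")
  thr_yng <- threshold_set(registry, "young")
  structs <- sort(unique(unlist(lapply(plans, function(p) names(p$photon$structures)))))

  n <- length(ids)
  m <- length(model_ids)
  ntcp_x <- ntcp_p <- matrix(NA_real_, n, m, dimnames = list(ids, model_ids))
  delta <- matrix(NA_real_, n, m, dimnames = list(ids, model_ids))
  davg_x <- davg_p <- d1_x <- d1_p <-
    matrix(NA_real_, n, length(structs), dimnames = list(ids, structs))
  idose_x <- idose_p <- rep(NA_real_, n)
  cts <- rep(NA_real_, n)
  single_pass <- matrix(NA, n, length(mids), dimnames = list(ids, mids))
  elig_rows <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- ids[i]
    pair <- plans[[pid]]
    if (is.null(pair$photon) || is.null(pair$proton))
      abort("patient %s lacks a %s plan", pid,
            if (is.null(pair$photon)) "photon" else "proton")
    validate_plan_pair(pair$photon, pair$proton)
    pcov <- cov[cov$patient_id == pid, , drop = FALSE]
    nx <- evaluate_plan_ntcp(registry, pair$photon, pcov)
    np <- evaluate_plan_ntcp(registry, pair$proton, pcov)
    ntcp_x[i, ] <- as.numeric(nx); ntcp_p[i, ] <- as.numeric(np)
    dlt <- delta_ntcp(nx, np)
    delta[i, ] <- as.numeric(dlt)
    cts[i] <- cts_score(dlt, weights)
    thr_i <- if (age_switch && !is.null(pcov$age) && pcov$age < age_cutoff)
      thr_yng else if (age_switch) thr_std else switch(mode, standard = thr_std,
                                                       young = thr_yng)
    er <- mbs_eligibility(dlt, thr_i, clamp_negative = clamp_negative,
                          patient_id = pid)
    single_pass[i, ] <- er$single_pass[mids]
    elig_rows[[i]] <- data.frame(patient_id = pid, mode = er$mode,
                                 composite_sum = er$composite_sum,
                                 cts = cts[i], eligible = er$eligible,
                                 reason = er$reason, stringsAsFactors = FALSE)
    for (s in names(pair$photon$structures)) {
      davg_x[i, s] <- mean_dose(pair$photon$structures[[s]])
      davg_p[i, s] <- mean_dose(pair$proton$structures[[s]])
      d1_x[i, s] <- dose_at_volume(pair$photon$structures[[s]], 0.01)
      d1_p[i, s] <- dose_at_volume(pair$proton$structures[[s]], 0.01)
    }
    bx <- pair$photon$structures[[pair$photon$body_structure]]
    bp <- pair$proton$structures[[pair$proton$body_structure]]
    if (!is.null(bx)) idose_x[i] <- integral_dose(bx)
    if (!is.null(bp)) idose_p[i] <- integral_dose(bp)
  }

  structure(
    list(ntcp_photon = ntcp_x, ntcp_proton = ntcp_p, delta = delta,
         cts = stats::setNames(cts, ids),
         eligibility = do.call(rbind, elig_rows),
         single_pass = single_pass,
         davg_photon = davg_x, davg_proton = davg_p,
         d1_photon = d1_x, d1_proton = d1_p,
         integral_dose_photon = stats::setNames(idose_x, ids),
         integral_dose_proton = stats::setNames(idose_p, ids),
         covariates = cov, registry = registry, mode = mode,
         clamp_negative = clamp_negative, age_switch = age_switch,
         call = match.call()),
    class = "mbs_selection")
}

#' Build a selection object from precomputed NTCP differences
#'
#' Constructs an `mbs_selection` directly from a patients x models matrix of
#' \eqn{\Delta NTCP_{x-p}} values (percentage points), scoring and
#' classifying each patient with the same CTS and eligibility machinery as
#' [mbs()]. Useful when NTCP values were computed by an external engine, and
#' for auditing the selection arithmetic in isolation. Dosimetric components
#' (`davg_*`, `d1_*`, integral dose) are empty.
#'
#' @param delta numeric matrix, rows = patients (rownames used as ids),
#'   columns named by registry model ids, values in percentage points.
#' @param covariates optional covariate `data.frame`; defaults to bare ids.
#' @param registry an `ntcp_registry`.
#' @param mode,clamp_negative as in [mbs()].
#' @return an `mbs_selection`.
#' @export
mbs_from_deltas <- function(delta, covariates = NULL,
                            registry = default_registry(),
                            mode = c("standard", "young"),
                            clamp_negative = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(delta))
  ids <- rownames(delta) %||% sprintf("P%03d", seq_len(nrow(delta)))
  rownames(delta) <- ids
  miss <- setdiff(registry_model_ids(registry), colnames(delta))
  if (length(miss))
    abort("delta matrix lacks registry model(s): %s", paste(miss, collapse = ", "))
  delta <- delta[, registry_model_ids(registry), drop = FALSE]
  if (is.null(covariates))
    covariates <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  weights <- weight_set(registry)
  thr <- threshold_set(registry, mode)
  mids <- mbs_model_ids(registry)
  cts <- rep(NA_real_, nrow(delta))
  single_pass <- matrix(NA, nrow(delta), length(mids), dimnames = list(ids, mids))
  rows <- vector("list", nrow(delta))
  for (i in seq_len(nrow(delta))) {
    cts[i] <- cts_score(delta[i, ], weights)
    er <- mbs_eligibility(delta[i, ], thr, clamp_negative = clamp_negative,
                          patient_id = ids[i])
    single_pass[i, ] <- er$single_pass[mids]
    rows[[i]] <- data.frame(patient_id = ids[i], mode = mode,
                            composite_sum = er$composite_sum, cts = cts[i],
                            eligible = er$eligible, reason = er$reason,
                            stringsAsFactors = FALSE)
  }
  empty <- matrix(NA_real_, nrow(delta), 0, dimnames = list(ids, NULL))
  structure(
    list(ntcp_photon = NULL, ntcp_proton = NULL, delta = delta,
         cts = stats::setNames(cts, ids),
         eligibility = do.call(rbind, rows), single_pass = single_pass,
         davg_photon = empty, davg_proton = empty,
         d1_photon = empty, d1_proton = empty,
         integral_dose_photon = stats::setNames(rep(NA_real_, length(ids)), ids),
         integral_dose_proton = stats::setNames(rep(NA_real_, length(ids)), ids),
         covariates = covariates, registry = registry, mode = mode,
         clamp_negative = clamp_negative, age_switch = FALSE,
         call = match.call()),
    class = "mbs_selection")
}

#' @export
print.mbs_selection <- function(x, ...) {
  ef <- eligibility_summary(x)
  cat(sprintf("Model-based selection: %d patients, %d NTCP models (%s thresholds%s)\n",
              nrow(x$delta), ncol(x$delta), x$mode,
              if (x$clamp_negative) ", negatives clamped" else ""))
  cat(sprintf("Eligible for proton therapy: %d/%d (%.1f%%) — %d single-only, %d composite-only, %d both\n",
              ef$n_eligible, ef$n, 100 * ef$fraction,
              ef$n_single_only, ef$n_composite_only, ef$n_both))
  cat(sprintf("Mean CTS %.2f (range %.2f to %.2f)\n",
              mean(x$cts, na.rm = TRUE), min(x$cts, na.rm = TRUE),
              max(x$cts, na.rm = TRUE)))
  invisible(x)
}

# eligible_fraction() on the stored verdict table
eligibility_summary <- function(fit) {
  reasons <- fit$eligibility$reason
  union_counts(sum(reasons %in% c("single", "both")),
               sum(reasons %in% c("composite", "both")),
               sum(reasons == "both"), length(reasons),
               n_not_evaluable = sum(reasons == "not_evaluable"))
}

#' Summarize a model-based selection analysis
#'
#' Compiles the cohort-level analysis: per-endpoint paired Wilcoxon
#' signed-rank tests on the NTCP differences, the CTS comparison between
#' eligible and non-eligible patients (rank-sum by default), the stratified
#' passing-rate table and the per-structure dosimetric gain summary.
#'
#' @param object an `mbs_selection`.
#' @param ... unused.
#' @return a `summary.mbs_selection` list with components `eligibility`,
#'   `endpoint_tests`, `cts_comparison`, `passing_rates`, `dose_deltas`,
#'   `integral_dose_reduction_pct`.
#' @export
summary.mbs_selection <- function(object, ...) {
  ef <- eligibility_summary(object)
  idx <- object$integral_dose_photon; idp <- object$integral_dose_proton
  ok <- !is.na(idx) & !is.na(idp) & idx > 0
  out <- list(
    mode = object$mode, n = ef$n, eligibility = ef,
    endpoint_tests = endpoint_tests(object),
    cts_comparison = compare_groups_cts(object$cts,
                                        object$eligibility$eligible %in% TRUE),
    passing_rates = passing_rate_table(object),
    dose_deltas = dose_delta_summary(object),
    integral_dose_reduction_pct = if (any(ok))
      mean(100 * (idx[ok] - idp[ok]) / idx[ok]) else NA_real_)
  class(out) <- "summary.mbs_selection"
  out
}

#' @export
print.summary.mbs_selection <- function(x, ...) {
  ef <- x$eligibility
  cat(sprintf("=== Model-based selection summary (%s thresholds, n = %d) ===\n",
              x$mode, x$n))
  cat(sprintf("Eligible: %d (%.1f%%); single %d, composite %d, both %d\n",
              ef$n_eligible, 100 * ef$fraction, ef$n_single,
              ef$n_composite, ef$n_both))
  cat("\nPer-endpoint paired Wilcoxon signed-rank tests (photon - proton, percentage points):\n")
  et <- x$endpoint_tests
  et$mean_delta <- sprintf("%+.2f", et$mean_delta)
  et$p_value <- signif(et$p_value, 3)
  print(et[, c("model_id", "n", "mean_delta", "method", "p_value", "significant")],
        row.names = FALSE)
  cat("(no multiple-testing correction across endpoints; each at nominal 0.05)\n")
  g <- x$cts_comparison
  cat(sprintf("\nCTS: eligible %.2f +/- %.2f (n=%d) vs non-eligible %.2f +/- %.2f (n=%d)",
              g$mean_eligible, g$sd_eligible, g$n_eligible,
              g$mean_other, g$sd_other, g$n_other))
  if (g$testable) cat(sprintf("; %s p = %.4g\n", g$method, g$p_value))
  else cat(sprintf(" [%s]\n", g$note))
  if (!is.na(x$integral_dose_reduction_pct))
    cat(sprintf("Integral dose reduction with protons: %.1f%%\n",
                x$integral_dose_reduction_pct))
  cat("\n")
  print(x$passing_rates)
  invisible(x)
}

#' Re-apply eligibility thresholds to a fitted selection object
#'
#' Recomputes eligibility verdicts from the stored \eqn{\Delta NTCP} matrix
#' under a different threshold mode or negative-clamping choice, without
#' re-evaluating any NTCP model.
#'
#' @param object an `mbs_selection`.
#' @param mode `"standard"` or `"young"`.
#' @param clamp_negative floor negative MBS differences at zero?
#' @param ... unused.
#' @return a new `mbs_selection` with updated `eligibility`, `single_pass`
#'   and `mode`.
#' @export
predict.mbs_selection <- function(object, mode = c("standard", "young"),
                                  clamp_negative = object$clamp_negative, ...) {
  mode <- match.arg(mode)
  thr <- threshold_set(object$registry, mode)
  ids <- rownames(object$delta)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    er <- mbs_eligibility(object$delta[i, ], thr, clamp_negative = clamp_negative,
                          patient_id = ids[i])
    object$single_pass[i, ] <- er$single_pass[colnames(object$single_pass)]
    rows[[i]] <- data.frame(patient_id = ids[i], mode = mode,
                            composite_sum = er$composite_sum,
                            cts = object$cts[i], eligible = er$eligible,
                            reason = er$reason, stringsAsFactors = FALSE)
  }
  object$eligibility <- do.call(rbind, rows)
  object$mode <- mode
  object$clamp_negative <- clamp_negative
  object
}

#' Plot cohort-mean NTCP differences per model
#'
#' Horizontal bar chart of the cohort mean \eqn{\Delta NTCP_{x-p}} per
#' registry model (percentage points; positive favours protons), MBS members
#' highlighted.
#'
#' @param x an `mbs_selection`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the vector of cohort means.
#' @export
plot.mbs_selection <- function(x, ...) {
  means <- colMeans(x$delta, na.rm = TRUE)
  ord <- order(means)
  is_mbs <- colnames(x$delta)[ord] %in% mbs_model_ids(x$registry)
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(means[ord], horiz = TRUE, las = 1,
                    col = ifelse(is_mbs, "steelblue", "grey70"),
                    xlab = expression(Delta * "NTCP (photon - proton), percentage points"),
                    main = "Cohort mean NTCP gain per model", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(means)
}
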