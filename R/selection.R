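# Patient selection: comprehensive toxicity score and MBS eligibility rule.

#' Comprehensive toxicity score (CTS)
#'
#' Weighted sum \eqn{\sum_i w_i \Delta NTCP_i} over all registry models, with
#' \eqn{\Delta NTCP} in percentage points (photon minus proton). Because the
#' weights sum to unity the CTS is itself on the percentage-point scale: a
#' uniform 10-point gain on every endpoint scores exactly 10. Negative
#' differences (proton worse) reduce the score sign-preservingly.
#'
#' Not-evaluable entries (NA) are excluded from the sum with a warning;
#' nothing is imputed and weights are not renormalized.
#'
#' @param delta_map named numeric vector of per-model \eqn{\Delta NTCP} in
#'   percentage points (as from [delta_ntcp()]).
#' @param weights named weight vector from [weight_set()], summing to 1.
#' @return the CTS in weighted percentage points.
#' @export
cts_score <- function(delta_map, weights) {
  if (abs(sum(weights) - 1) > 1e-9)
    abort("weights must sum to unity (registry config error); got %.12f", sum(weights))
  miss <- setdiff(names(weights), names(delta_map))
  if (length(miss))
    abort("delta_map does not cover the registry: missing %s", paste(miss, collapse = ", "))
  d <- delta_map[names(weights)]
  na <- is.na(d)
  if (any(na)) {
    warning(sprintf("CTS computed without not-evaluable models: %s",
                    paste(names(weights)[na], collapse = ", ")))
  }
  sum(weights[!na] * d[!na])
}

#' MBS eligibility verdict for one patient
#'
#' A patient qualifies for proton therapy if the NTCP gain for any single MBS
#' endpoint is strictly larger than that endpoint's threshold, or if the
#' summed gain over the 7 MBS models reaches the composite threshold
#' (\eqn{\ge} 35 points by default). Note the asymmetry, which matters on
#' boundary cases: the single-endpoint rule is a strict ">", the composite
#' rule is ">=".
#'
#' Negative differences enter the composite sum as-is by default; setting
#' `clamp_negative = TRUE` floors each MBS difference at zero before summing
#' (the choice is recorded in the result).
#'
#' @param delta_map named \eqn{\Delta NTCP} vector in percentage points
#'   covering at least the MBS models.
#' @param thresholds a `threshold_set` from [threshold_set()].
#' @param clamp_negative floor negative MBS differences at zero in the
#'   composite sum?
#' @param patient_id optional label carried into the result.
#' @return an `eligibility_result`: list with `delta` (MBS subset),
#'   `single_pass` (named logical), `composite_sum`, `eligible`, `reason`
#'   (`"single"`, `"composite"`, `"both"`, `"none"` or `"not_evaluable"`).
#' @export
mbs_eligibility <- function(delta_map, thresholds, clamp_negative = FALSE,
                            patient_id = NA_character_) {
  stopifnot(inherits(thresholds, "threshold_set"))
  thr <- thresholds$thresholds
  miss <- setdiff(names(thr), names(delta_map))
  if (length(miss))
    abort("MBS deltas missing for model(s): %s", paste(miss, collapse = ", "))
  d <- delta_map[names(thr)]
  if (anyNA(d)) {
    warning(sprintf("patient %s: MBS verdict not evaluable (missing %s)",
                    patient_id, paste(names(d)[is.na(d)], collapse = ", ")))
    return(structure(list(patient_id = patient_id, mode = thresholds$mode,
                          delta = d, single_pass = is.finite(d) & NA,
                          composite_sum = NA_real_, cts = NA_real_,
                          eligible = NA, reason = "not_evaluable",
                          clamp_negative = clamp_negative),
                     class = "eligibility_result"))
  }
  single_pass <- d > thr
  dc <- if (clamp_negative) pmax(d, 0) else d
  composite_sum <- sum(dc)
  composite_pass <- composite_sum >= thresholds$composite
  eligible <- any(single_pass) || composite_pass
  reason <- if (any(single_pass) && composite_pass) "both"
    else if (any(single_pass)) "single"
    else if (composite_pass) "composite"
    else "none"
  structure(list(patient_id = patient_id, mode = thresholds$mode,
                 delta = d, single_pass = single_pass,
                 composite_sum = composite_sum,
                 eligible = eligible, reason = reason,
                 clamp_negative = clamp_negative),
            class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("<eligibility_result> patient %s (%s thresholds%s): %s (reason: %s)\n",
              x$patient_id, x$mode,
              if (x$clamp_negative) ", negatives clamped" else "",
              if (isTRUE(x$eligible)) "ELIGIBLE" else if (isFALSE(x$eligible))
                "not eligible" else "not evaluable",
              x$reason))
  cat(sprintf("  composite sum %.2f points; single passes: %s\n",
              x$composite_sum,
              if (any(x$single_pass %in% TRUE))
                paste(names(x$single_pass)[x$single_pass %in% TRUE], collapse = ", ")
              else "none"))
  invisible(x)
}

#' Cohort eligibility fraction with inclusion-exclusion counts
#'
#' Tallies how many patients pass the single-endpoint rule, the composite
#' rule, or both, and derives the eligible union by inclusion-exclusion.
#'
#' @param results list of `eligibility_result` objects (non-empty).
#' @return list with `n`, `n_single`, `n_composite`, `n_both`,
#'   `n_single_only`, `n_composite_only`, `n_eligible`, `fraction`,
#'   `n_not_evaluable`.
#' @export
eligible_fraction <- function(results) {
  if (length(results) == 0L) abort("empty cohort")
  ok <- vapply(results, inherits, logical(1), "eligibility_result")
  if (!all(ok)) abort("results must be eligibility_result objects")
  reasons <- vapply(results, `[[`, character(1), "reason")
  n <- length(results)
  n_single <- sum(reasons %in% c("single", "both"))
  n_composite <- sum(reasons %in% c("composite", "both"))
  n_both <- sum(reasons == "both")
  union_counts(n_single, n_composite, n_both, n,
               n_not_evaluable = sum(reasons == "not_evaluable"))
}

#' Eligible-union arithmetic from rule counts
#'
#' Inclusion-exclusion on the two qualification routes: patients passing a
#' single-endpoint threshold, passing the composite threshold, or both.
#' With 18 single, 10 composite and 8 both in a 50-patient cohort the union
#' is 20 patients (40%), 10 by single criterion only and 2 by composite only.
#'
#' @param n_single patients passing any single-endpoint threshold.
#' @param n_composite patients passing the composite threshold.
#' @param n_both patients passing both routes.
#' @param n cohort size.
#' @param n_not_evaluable optional count of non-evaluable patients.
#' @return list of counts plus the eligible `fraction` of the cohort.
#' @export
union_counts <- function(n_single, n_composite, n_both, n, n_not_evaluable = 0L) {
  if (n <= 0) abort("cohort size must be positive")
  if (n_both > min(n_single, n_composite))
    abort("n_both cannot exceed either route count")
  n_eligible <- n_single + n_composite - n_both
  list(n = n, n_single = n_single, n_composite = n_composite, n_both = n_both,
       n_single_only = n_single - n_both,
       n_composite_only = n_composite - n_both,
       n_eligible = n_eligible, fraction = n_eligible / n,
       n_not_evaluable = n_not_evaluable)
}
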