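#' Dose-volume histogram for a single structure
#'
#' Constructs a `structure_dvh`, the basic container for the dose distribution
#' over one delineated structure (a target volume or an organ at risk). Doses
#' are RBE-weighted physical doses in Gy(RBE); volumes are fractions of the
#' structure's total volume.
#'
#' Two representations are supported on a common dose grid:
#' \describe{
#'   \item{differential}{`frac[k]` is the volume fraction receiving a dose of
#'     `dose[k]` (bin mass placed at the bin's representative dose). Fractions
#'     sum to at most 1; a sum below 1 means the structure is only partially
#'     covered by the dose grid.}
#'   \item{cumulative}{`frac[k]` is the volume fraction receiving at least
#'     `dose[k]`; the curve is non-increasing and, for a fully covered
#'     structure whose grid starts at 0 Gy, starts at 1.}
#' }
#' The cumulative form is the canonical internal representation; metric
#' functions convert on the fly as needed. Conversion between the two forms on
#' the same grid is exact.
#'
#' @param structure_id character label for the structure.
#' @param total_volume_cc absolute structure volume in cm^3 (positive).
#' @param dose strictly increasing, non-negative dose grid in Gy(RBE).
#' @param frac volume fractions, same length as `dose` (see Details).
#' @param representation `"cumulative"` or `"differential"`.
#' @return an object of class `structure_dvh`.
#' @examples
#' # half the volume at 40 Gy, half at 60 Gy
#' dvh <- structure_dvh("parotid", 25, c(40, 60), c(0.5, 0.5), "differential")
#' mean_dose(dvh)
#' dose_at_volume(dvh, 0.5)
#' @export
structure_dvh <- function(structure_id, total_volume_cc, dose, frac,
                          representation = c("cumulative", "differential")) {
  representation <- match.arg(representation)
  if (!is.character(structure_id) || length(structure_id) != 1L || !nzchar(structure_id))
    abort("structure_id must be a non-empty string")
  if (!is_scalar_number(total_volume_cc) || total_volume_cc <= 0)
    abort("total_volume_cc must be a positive number (structure '%s')", structure_id)
  dose <- as.numeric(dose)
  frac <- as.numeric(frac)
  if (length(dose) == 0L) abort("empty DVH for structure '%s'", structure_id)
  if (length(dose) != length(frac))
    abort("dose and frac lengths differ for structure '%s'", structure_id)
  if (anyNA(dose) || anyNA(frac))
    abort("NA values in DVH for structure '%s'", structure_id)
  if (any(dose < 0)) abort("negative doses in DVH for structure '%s'", structure_id)
  if (is.unsorted(dose, strictly = TRUE))
    abort("dose grid must be strictly increasing for structure '%s'", structure_id)
  if (any(frac < -1e-12))
    abort("negative volume fractions for structure '%s'", structure_id)
  frac[frac < 0] <- 0
  if (representation == "differential") {
    if (sum(frac) > 1 + 1e-9)
      abort("differential fractions sum to %.6f > 1 for structure '%s'",
            sum(frac), structure_id)
  } else {
    if (any(frac > 1 + 1e-9))
      abort("cumulative fractions exceed 1 for structure '%s'", structure_id)
    if (any(diff(frac) > 1e-9))
      abort("cumulative curve must be non-increasing for structure '%s'", structure_id)
  }
  structure(
    list(structure_id = structure_id,
         total_volume_cc = total_volume_cc,
         dose = dose, frac = frac,
         representation = representation),
    class = "structure_dvh")
}

#' @export
print.structure_dvh <- function(x, ...) {
  cat(sprintf("<structure_dvh> %s: %.2f cc, %d dose points (%.2f-%.2f Gy), %s\n",
              x$structure_id, x$total_volume_cc, length(x$dose),
              min(x$dose), max(x$dose), x$representation))
  cat(sprintf("  covered fraction %.4f, mean dose %.2f Gy(RBE)\n",
              dvh_coverage(x), mean_dose(x)))
  invisible(x)
}

is_structure_dvh <- function(x) inherits(x, "structure_dvh")

#' Convert a DVH to cumulative representation
#'
#' The cumulative value at each grid dose is the total fraction at that dose
#' or above (reverse cumulative sum of the differential fractions). Applying
#' it to an already-cumulative DVH is a no-op with a notice.
#'
#' @param dvh a `structure_dvh`.
#' @return the DVH in cumulative representation, same grid.
#' @export
as_cumulative <- function(dvh) {
  stopifnot(is_structure_dvh(dvh))
  if (dvh$representation == "cumulative") {
    message("as_cumulative: input already cumulative; returning unchanged")
    return(dvh)
  }
  cum <- rev(cumsum(rev(dvh$frac)))
  structure_dvh(dvh$structure_id, dvh$total_volume_cc, dvh$dose, cum, "cumulative")
}

#' Convert a DVH to differential representation
#'
#' Inverse of [as_cumulative()] on the same dose grid: the mass at grid point
#' k is the drop of the cumulative curve between k and k+1 (the final point
#' keeps its full remaining mass).
#'
#' @param dvh a `structure_dvh`.
#' @return the DVH in differential representation, same grid.
#' @export
as_differential <- function(dvh) {
  stopifnot(is_structure_dvh(dvh))
  if (dvh$representation == "differential") {
    message("as_differential: input already differential; returning unchanged")
    return(dvh)
  }
  f <- -diff(c(dvh$frac, 0))
  f[f < 0] <- 0 # numerical dust from non-increasing validation tolerance
  structure_dvh(dvh$structure_id, dvh$total_volume_cc, dvh$dose, f, "differential")
}

# silent internal coercions (no notice when already in the requested form)
cum_dvh <- function(dvh) {
  if (dvh$representation == "cumulative") dvh else suppressMessages(as_cumulative(dvh))
}
diff_dvh <- function(dvh) {
  if (dvh$representation == "differential") dvh else suppressMessages(as_differential(dvh))
}

# fraction of the structure covered by the dose grid (1 when fully covered)
dvh_coverage <- function(dvh) {
  if (dvh$representation == "cumulative") max(dvh$frac) else sum(dvh$frac)
}

#' Dose received by the hottest fraction of a structure (Dx%)
#'
#' Returns the dose D such that the fraction of the structure receiving at
#' least D equals `volume_fraction` — the "minimum dose to the hottest x% of
#' the volume" convention, with linear interpolation between cumulative grid
#' points. On flat segments of the cumulative curve the highest qualifying
#' dose is returned, so for a step DVH with half the volume at 40 Gy and half
#' at 60 Gy, D50% is 60 Gy. If the requested fraction lies within the top
#' point mass the maximum grid dose is returned.
#'
#' @param dvh a `structure_dvh` (converted to cumulative as needed).
#' @param volume_fraction fraction in (0, 1]; e.g. 0.02 gives D2%.
#' @return dose in Gy(RBE).
#' @export
dose_at_volume <- function(dvh, volume_fraction) {
  stopifnot(is_structure_dvh(dvh))
  if (!is_scalar_number(volume_fraction) || volume_fraction <= 0 || volume_fraction > 1)
    abort("volume_fraction must lie in (0, 1], got %s", format(volume_fraction))
  d <- cum_dvh(dvh)
  v <- volume_fraction
  cum <- d$frac
  dose <- d$dose
  cov <- cum[1]
  if (v >= cov) {
    if (v > cov + 1e-9)
      warning(sprintf("structure '%s' covers only %.4f of its volume; D%.0f%% capped at the lowest grid dose",
                      d$structure_id, cov, 100 * v))
    return(dose[1])
  }
  # last grid point where at least v of the volume still qualifies
  k <- max(which(cum >= v))
  if (k == length(cum)) return(dose[k])
  if (cum[k] <= cum[k + 1]) return(dose[k + 1]) # flat to tolerance
  dose[k] + (cum[k] - v) / (cum[k] - cum[k + 1]) * (dose[k + 1] - dose[k])
}

#' Volume fraction receiving at least a given dose (Vd)
#'
#' Counts the volume whose dose is greater than or equal to `dose_gy`,
#' honouring the "equal or higher" convention exactly: mass sitting exactly
#' at `dose_gy` is included. Used for V95%, V100% and the conformity index.
#'
#' @param dvh a `structure_dvh`.
#' @param dose_gy dose threshold in Gy(RBE), non-negative.
#' @return fraction of the structure volume in [0, 1].
#' @export
volume_at_dose <- function(dvh, dose_gy) {
  stopifnot(is_structure_dvh(dvh))
  if (!is_scalar_number(dose_gy) || dose_gy < 0)
    abort("dose_gy must be a non-negative number")
  d <- diff_dvh(dvh)
  tol <- 1e-9 * max(1, dose_gy)
  sum(d$frac[d$dose >= dose_gy - tol])
}

#' Mean (average) dose of a structure
#'
#' Volume-weighted mean of the differential DVH, \eqn{\sum_i v_i d_i}. When a
#' structure is only partially covered by the dose grid the mean is computed
#' over the covered fraction with a warning.
#'
#' @param dvh a `structure_dvh`.
#' @return mean dose in Gy(RBE).
#' @export
mean_dose <- function(dvh) {
  stopifnot(is_structure_dvh(dvh))
  d <- diff_dvh(dvh)
  s <- sum(d$frac)
  if (s <= 0) abort("structure '%s' has zero covered volume", d$structure_id)
  if (s < 1 - 1e-6)
    warning(sprintf("structure '%s' covers only %.4f of its volume; mean over covered fraction",
                    d$structure_id, s))
  sum(d$frac * d$dose) / s
}

#' Conformity index of a target
#'
#' CI = fraction of the PTV receiving at least 95% of its prescription dose
#' (V95% divided by the PTV volume); lies in [0, 1] by construction.
#'
#' @param ptv_dvh `structure_dvh` of the planning target volume.
#' @param prescription prescription dose in Gy(RBE), positive.
#' @return dimensionless CI in [0, 1].
#' @export
conformity_index <- function(ptv_dvh, prescription) {
  stopifnot(is_structure_dvh(ptv_dvh))
  if (!is_scalar_number(prescription) || prescription <= 0)
    abort("prescription must be a positive dose")
  if (ptv_dvh$total_volume_cc <= 0) abort("zero-volume PTV")
  volume_at_dose(ptv_dvh, 0.95 * prescription)
}

#' Homogeneity index of a target
#'
#' HI = (D2% - D98%) / D50%; zero for a perfectly uniform dose and invariant
#' under rescaling of all doses.
#'
#' @param dvh `structure_dvh` of the target.
#' @return dimensionless HI, >= 0 up to interpolation tolerance.
#' @export
homogeneity_index <- function(dvh) {
  d50 <- dose_at_volume(dvh, 0.50)
  if (d50 <= 0) abort("homogeneity index undefined: D50%% is zero for structure '%s'",
                      dvh$structure_id)
  (dose_at_volume(dvh, 0.02) - dose_at_volume(dvh, 0.98)) / d50
}

#' Integral dose over the scanned body
#'
#' Mean dose to the CT-scanned body volume times that volume, in
#' Gy(RBE) x cm^3, assuming no exposure outside the scanned volume.
#'
#' @param body_dvh `structure_dvh` of the external/body contour.
#' @return integral dose in Gy(RBE) cm^3.
#' @export
integral_dose <- function(body_dvh) {
  stopifnot(is_structure_dvh(body_dvh))
  mean_dose(body_dvh) * body_dvh$total_volume_cc
}

#' Standard dosimetric quantifier set for one structure
#'
#' Computes the Dx% family (D99, D98, D95, D50, D2, D1), the mean dose, and —
#' when a prescription is supplied — V95%/V100% fractions, conformity and
#' homogeneity indices. V100% is taken against the structure's own
#' prescription level, so multi-level prescriptions are handled per target.
#'
#' @param dvh a `structure_dvh`.
#' @param prescription optional prescription dose in Gy(RBE) for target metrics.
#' @return a one-row `data.frame` of metrics (NA for target metrics when no
#'   prescription is given) with columns `D99`,`D98`,`D95`,`D50`,`D2`,`D1`,
#'   `Davg`,`V95_fraction`,`V100_fraction`,`CI`,`HI`,`integral_dose`.
#' @export
dose_metrics <- function(dvh, prescription = NULL) {
  stopifnot(is_structure_dvh(dvh))
  dx <- function(x) dose_at_volume(dvh, x)
  out <- data.frame(
    structure = dvh$structure_id,
    D99 = dx(0.99), D98 = dx(0.98), D95 = dx(0.95),
    D50 = dx(0.50), D2 = dx(0.02), D1 = dx(0.01),
    Davg = mean_dose(dvh),
    V95_fraction = NA_real_, V100_fraction = NA_real_,
    CI = NA_real_, HI = NA_real_,
    integral_dose = mean_dose(dvh) * dvh$total_volume_cc,
    stringsAsFactors = FALSE)
  if (!is.null(prescription)) {
    out$V95_fraction <- volume_at_dose(dvh, 0.95 * prescription)
    out$V100_fraction <- volume_at_dose(dvh, prescription)
    out$CI <- conformity_index(dvh, prescription)
    out$HI <- homogeneity_index(dvh)
  }
  out
}

#' A patient's treatment plan
#'
#' Bundles one modality's structure DVHs with the prescription levels. The
#' standard fractionation is 33 fractions with a high-dose level of 69.96
#' Gy(RBE) and lower levels of 59.4 / 56.1 Gy(RBE).
#'
#' @param patient_id character patient label.
#' @param modality `"photon"` (VMAT) or `"proton"` (IMPT).
#' @param structures named list of `structure_dvh` objects.
#' @param prescriptions `data.frame` with columns `target`, `dose_gy`,
#'   `fractions` (one row per dose level), or NULL.
#' @param body_structure name of the body/external structure within
#'   `structures`, used for the integral dose.
#' @return an object of class `plan_record`.
#' @export
plan_record <- function(patient_id, modality = c("photon", "proton"),
                        structures, prescriptions = NULL,
                        body_structure = "body") {
  modality <- match.arg(modality)
  if (!is.character(patient_id) || length(patient_id) != 1L)
    abort("patient_id must be a string")
  if (!is.list(structures) || length(structures) == 0L)
    abort("structures must be a non-empty named list of structure_dvh")
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    abort("structures must be named by structure_id")
  ok <- vapply(structures, is_structure_dvh, logical(1))
  if (!all(ok)) abort("structures[%s] is not a structure_dvh",
                      paste(which(!ok), collapse = ","))
  if (!is.null(prescriptions)) {
    req <- c("target", "dose_gy")
    if (!all(req %in% names(prescriptions)))
      abort("prescriptions needs columns target, dose_gy")
    if (is.null(prescriptions$fractions)) prescriptions$fractions <- 33L
  }
  structure(
    list(patient_id = patient_id, modality = modality,
         structures = structures, prescriptions = prescriptions,
         body_structure = body_structure),
    class = "plan_record")
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> patient %s, %s plan, %d structures\n",
              x$patient_id, x$modality, length(x$structures)))
  if (!is.null(x$prescriptions))
    cat("  prescriptions:",
        paste(sprintf("%s=%.2f Gy", x$prescriptions$target, x$prescriptions$dose_gy),
              collapse = ", "), "\n")
  invisible(x)
}

# body volume of a plan, cm^3 (NA when no body structure present)
plan_body_volume <- function(plan) {
  b <- plan$structures[[plan$body_structure]]
  if (is.null(b)) NA_real_ else b$total_volume_cc
}

#' Check that two rival plans are comparable
#'
#' Both plans of a photon/proton pair must belong to the same patient,
#' reference the same structure set, and agree on structure volumes within 1%.
#'
#' @param photon,proton `plan_record` objects.
#' @return invisibly TRUE; errors describe the first violated condition.
#' @export
validate_plan_pair <- function(photon, proton) {
  stopifnot(inherits(photon, "plan_record"), inherits(proton, "plan_record"))
  if (photon$patient_id != proton$patient_id)
    abort("plan pair mixes patients '%s' and '%s'", photon$patient_id, proton$patient_id)
  sx <- sort(names(photon$structures)); sp <- sort(names(proton$structures))
  if (!identical(sx, sp))
    abort("plan pair for patient '%s' references different structure sets", photon$patient_id)
  for (s in sx) {
    vx <- photon$structures[[s]]$total_volume_cc
    vp <- proton$structures[[s]]$total_volume_cc
    if (abs(vx - vp) > 0.01 * max(vx, vp))
      abort("structure '%s' volumes differ by >1%% between plans of patient '%s'",
            s, photon$patient_id)
  }
  invisible(TRUE)
}
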