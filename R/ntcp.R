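# NTCP computation layer: gEUD dose summaries and the three dose-response
# functional forms (LKB probit, multivariable logistic, log-logistic).

#' Generalized equivalent uniform dose
#'
#' Power-mean dose summary \eqn{(\sum_i v_i d_i^a)^{1/a}} over the
#' differential DVH with volume-effect parameter `a`: a = 1 gives the mean
#' dose, large positive `a` approaches the maximum dose (serial organs),
#' negative `a` approaches the minimum dose (target cold spots). Fractions
#' are normalized to the covered volume so the summary is a proper power
#' mean.
#'
#' For `a < 0`, zero-dose bins would make the power mean collapse to zero;
#' such bins are excluded (with a warning) and the summary is taken over the
#' irradiated fraction. An all-zero dose distribution with `a < 0` is
#' undefined and returns NaN with a warning.
#'
#' @param dvh a `structure_dvh`.
#' @param a volume-effect parameter, nonzero.
#' @return gEUD in Gy(RBE), bounded by the minimum and maximum structure dose.
#' @examples
#' dvh <- structure_dvh("x", 10, c(0, 10), c(0.5, 0.5), "differential")
#' geud(dvh, 2)   # sqrt(50)
#' geud(dvh, 1)   # mean dose 5
#' @export
geud <- function(dvh, a) {
  stopifnot(is_structure_dvh(dvh))
  if (!is_scalar_number(a) || a == 0)
    abort("gEUD volume-effect parameter a must be a nonzero number (the log form is not used)")
  d <- diff_dvh(dvh)
  keep <- d$frac > 0
  dose <- d$dose[keep]; v <- d$frac[keep]
  if (length(dose) == 0L) abort("structure '%s' has zero covered volume", d$structure_id)
  v <- v / sum(v)
  if (a < 0 && any(dose <= 0)) {
    if (all(dose <= 0)) {
      warning(sprintf("gEUD undefined: all-zero dose with a = %g for structure '%s'",
                      a, d$structure_id))
      return(NaN)
    }
    warning(sprintf("gEUD(a=%g): excluding zero-dose bins of structure '%s' (%.3f of volume)",
                    a, d$structure_id, sum(v[dose <= 0])))
    v <- v[dose > 0]; dose <- dose[dose > 0]
    v <- v / sum(v)
  }
  if (all(dose == 0)) return(0)
  # scale by the extreme dose for numerical stability at large |a|
  ref <- if (a > 0) max(dose) else min(dose[dose > 0])
  ref * sum(v * (dose / ref)^a)^(1 / a)
}

# Resolve a model's dose summary on a plan structure.
# spec: list(type = "mean" | "geud" | "dx", a = ..., x = ...)
dose_summary_value <- function(summary_spec, dvh) {
  type <- summary_spec$type %||% "mean"
  switch(type,
    mean = mean_dose(dvh),
    geud = geud(dvh, summary_spec$a %||% abort("gEUD dose summary needs parameter a")),
    dx   = dose_at_volume(dvh, (summary_spec$x %||% 1) / 100),
    dmax = dose_at_volume(dvh, 0.01), # near-maximum dose, D1% convention
    abort("unknown dose summary type '%s'", type))
}

#' Evaluate one NTCP model on a plan
#'
#' Applies the model's dose summary to its organ structure and maps it
#' through the model's dose-response form:
#' \describe{
#'   \item{lkb_probit}{\eqn{\Phi((S - TD50)/(m \cdot TD50))} — the
#'     Lyman-Kutcher-Burman probit with tolerance dose `td50` and slope `m`.}
#'   \item{logistic_linear}{\eqn{1/(1+e^{-(\beta_0 + \sum_i \beta_i x_i)})}
#'     with `intercept` \eqn{\beta_0} and named `coefficients`; the
#'     coefficient named `dose` multiplies the dose summary, any other name
#'     is looked up among the patient covariates.}
#'   \item{loglogistic_d50_gamma}{\eqn{1/(1+(D50/S)^{4\gamma_{50}})} with
#'     parameters `d50` and `gamma50`.}
#' }
#' A missing organ structure or covariate yields NA with a warning (the
#' model is "not evaluable" — never silently zero).
#'
#' @param model an `ntcp_model_spec` (one registry entry).
#' @param plan a `plan_record`.
#' @param covariates optional one-row `data.frame` / named list of patient
#'   covariates for covariate-bearing logistic models.
#' @return complication probability in [0, 1], or NA if not evaluable.
#' @export
evaluate_model <- function(model, plan, covariates = NULL) {
  stopifnot(inherits(model, "ntcp_model_spec"), inherits(plan, "plan_record"))
  dvh <- plan$structures[[model$organ]]
  if (is.null(dvh)) {
    warning(sprintf("model '%s' not evaluable: structure '%s' missing from %s plan of patient %s",
                    model$model_id, model$organ, plan$modality, plan$patient_id))
    return(NA_real_)
  }
  S <- dose_summary_value(model$dose_summary, dvh)
  p <- model$parameters
  switch(model$form,
    lkb_probit = stats::pnorm((S - p$td50) / (p$m * p$td50)),
    loglogistic_d50_gamma = {
      if (S <= 0) 0 else 1 / (1 + (p$d50 / S)^(4 * p$gamma50))
    },
    logistic_linear = {
      lp <- p$intercept
      for (nm in names(p$coefficients)) {
        xi <- if (identical(nm, "dose")) S else {
          val <- if (!is.null(covariates)) covariates[[nm]] else NULL
          if (is.null(val) || length(val) == 0L || is.na(val[1])) {
            warning(sprintf("model '%s' not evaluable: covariate '%s' missing for patient %s",
                            model$model_id, nm, plan$patient_id))
            return(NA_real_)
          }
          as.numeric(val[1])
        }
        lp <- lp + p$coefficients[[nm]] * xi
      }
      stats::plogis(lp)
    },
    abort("unknown NTCP form '%s' in model '%s'", model$form, model$model_id))
}

#' Evaluate the full registry on a plan
#'
#' @param registry an `ntcp_registry`.
#' @param plan a `plan_record`.
#' @param covariates optional named covariates for this patient.
#' @return a `plan_ntcp`: named numeric vector of probabilities (NA for
#'   not-evaluable models) with attributes `patient_id` and `modality`.
#' @export
evaluate_plan_ntcp <- function(registry, plan, covariates = NULL) {
  stopifnot(inherits(registry, "ntcp_registry"))
  vals <- vapply(registry$models, function(m) evaluate_model(m, plan, covariates),
                 numeric(1))
  names(vals) <- vapply(registry$models, `[[`, character(1), "model_id")
  fin <- vals[!is.na(vals)]
  if (any(fin < 0 | fin > 1))
    abort("NTCP outside [0,1] — invalid model parameterisation")
  structure(vals, patient_id = plan$patient_id, modality = plan$modality,
            class = "plan_ntcp")
}

#' Photon-minus-proton NTCP differences in percentage points
#'
#' \eqn{\Delta NTCP_{x-p} = 100\,(NTCP_{photon} - NTCP_{proton})} per model;
#' positive values favour protons. A model evaluable in only one plan is
#' marked NA (not evaluable) with a warning.
#'
#' @param photon,proton `plan_ntcp` vectors of the same patient over the same
#'   registry.
#' @return named numeric vector of differences in percentage points.
#' @export
delta_ntcp <- function(photon, proton) {
  stopifnot(inherits(photon, "plan_ntcp"), inherits(proton, "plan_ntcp"))
  if (!identical(attr(photon, "patient_id"), attr(proton, "patient_id")))
    abort("delta_ntcp: plans belong to different patients ('%s' vs '%s')",
          attr(photon, "patient_id"), attr(proton, "patient_id"))
  if (!identical(names(photon), names(proton)))
    abort("delta_ntcp: NTCP vectors cover different model registries")
  d <- 100 * (as.numeric(photon) - as.numeric(proton))
  names(d) <- names(photon)
  half <- xor(is.na(photon), is.na(proton))
  if (any(half)) {
    warning(sprintf("models evaluable in only one plan marked not evaluable: %s",
                    paste(names(photon)[half], collapse = ", ")))
    d[half] <- NA_real_
  }
  structure(d, patient_id = attr(photon, "patient_id"))
}
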