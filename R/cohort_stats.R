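# Cohort-level statistics: paired endpoint tests, CTS group comparison,
# stratified passing-rate tables and dosimetric delta summaries.

# deterministic stratum labels
t_stratum <- function(t_stage) ifelse(t_stage <= 2, "T1T2", "T3T4")
n_stratum <- function(n_stage) c("N0", "N1", "N2N3", "N2N3")[n_stage + 1L]

#' Paired NTCP tests per endpoint
#'
#' Runs the two-sided Wilcoxon signed-rank test on the paired
#' photon-minus-proton NTCP differences of every registry model, at
#' significance level 0.05. No multiple-testing correction is applied across
#' endpoints (each endpoint is reported at its nominal level; see the
#' report footnote).
#'
#' @param fit an `mbs_selection` object from [mbs()].
#' @return a `data.frame` with one row per model: mean difference
#'   (percentage points), W+ statistic, method, two-sided p, significance.
#' @export
endpoint_tests <- function(fit) {
  stopifnot(inherits(fit, "mbs_selection"))
  out <- lapply(colnames(fit$delta), function(id) {
    d <- fit$delta[, id]
    d <- d[!is.na(d)]
    res <- suppressMessages(wilcoxon_signed_rank(d, label = id))
    data.frame(model_id = id, n = res$n,
               mean_delta = mean(d), statistic = res$statistic,
               method = res$method, p_value = res$p_value,
               significant = res$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare CTS between eligible and non-eligible patients
#'
#' Reports group means and standard deviations of the comprehensive toxicity
#' score, and a two-sided rank-based p-value. The two groups are independent
#' samples, so the default test is the Wilcoxon rank-sum; a signed-rank
#' variant is also exposed but requires equal group sizes (it pairs the
#' sorted values) and is provided only for auditability of the published
#' analysis choice. The method used is always recorded in the result.
#'
#' @param cts numeric CTS vector over the cohort.
#' @param eligible logical eligibility vector (same length; NA allowed).
#' @param method `"rank_sum"` (default) or `"signed_rank"`.
#' @param alpha significance level (default 0.05).
#' @return list with group sizes, means, SDs, `p_value`, `method`,
#'   `significant` and a `testable` flag (FALSE with an explanatory `note`
#'   when a group is empty; p is NA then).
#' @export
compare_groups_cts <- function(cts, eligible, method = c("rank_sum", "signed_rank"),
                               alpha = 0.05) {
  method <- match.arg(method)
  keep <- !is.na(cts) & !is.na(eligible)
  x <- cts[keep & eligible]   # eligible group
  y <- cts[keep & !eligible]  # non-eligible group
  out <- list(n_eligible = length(x), n_other = length(y),
              mean_eligible = if (length(x)) mean(x) else NA_real_,
              sd_eligible = if (length(x) > 1) stats::sd(x) else NA_real_,
              mean_other = if (length(y)) mean(y) else NA_real_,
              sd_other = if (length(y) > 1) stats::sd(y) else NA_real_,
              method = method, p_value = NA_real_, significant = NA,
              testable = TRUE, note = NULL)
  if (length(x) == 0L || length(y) == 0L) {
    out$testable <- FALSE
    out$note <- "not testable: one eligibility group is empty"
    return(out)
  }
  if (length(x) == 1L && length(y) == 1L) {
    out$testable <- FALSE
    out$note <- "underpowered: single-patient groups; means reported, no test"
    return(out)
  }
  if (method == "rank_sum") {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    out$p_value <- wt$p.value
  } else {
    if (length(x) != length(y))
      abort("signed_rank group comparison needs equal group sizes (%d vs %d); use method = 'rank_sum' for independent groups",
            length(x), length(y))
    res <- suppressMessages(wilcoxon_signed_rank(sort(x) - sort(y)))
    out$p_value <- res$p_value
  }
  out$significant <- out$p_value < alpha
  out
}

#' Stratified passing-rate table
#'
#' Percentage of patients, per stratum, that (i) are eligible overall, (ii)
#' pass the single-endpoint rule, (iii) pass the composite rule, and (iv)
#' pass each individual MBS model's threshold. Strata are the whole cohort,
#' primary tumor stage (T1-T2 vs T3-T4) and nodal stage (N0, N1, N2-N3).
#' Percentages come from integer counts and are rounded half away from zero
#' to one decimal. Empty strata are marked NA (rendered "n=0" in the printed
#' report).
#'
#' @param fit an `mbs_selection` object from [mbs()].
#' @param strata which stratifications to include (subset of
#'   `c("all", "T", "N")`).
#' @return a numeric matrix (rows: eligibility/single/composite/models;
#'   columns: strata) with attribute `n` giving each stratum size.
#' @export
passing_rate_table <- function(fit, strata = c("all", "T", "N")) {
  stopifnot(inherits(fit, "mbs_selection"))
  strata <- match.arg(strata, several.ok = TRUE)
  cov <- fit$covariates
  groups <- list()
  if ("all" %in% strata) groups[["All"]] <- rep(TRUE, nrow(cov))
  if ("T" %in% strata) {
    ts <- t_stratum(cov$t_stage)
    for (g in c("T1T2", "T3T4")) groups[[g]] <- ts == g
  }
  if ("N" %in% strata) {
    ns <- n_stratum(cov$n_stage)
    for (g in c("N0", "N1", "N2N3")) groups[[g]] <- ns == g
  }
  reasons <- fit$eligibility$reason
  rows <- list(
    eligibility = fit$eligibility$eligible %in% TRUE,
    single = reasons %in% c("single", "both"),
    composite = reasons %in% c("composite", "both"))
  for (id in colnames(fit$single_pass))
    rows[[id]] <- fit$single_pass[, id] %in% TRUE
  tab <- matrix(NA_real_, nrow = length(rows), ncol = length(groups),
                dimnames = list(names(rows), names(groups)))
  ns <- integer(length(groups)); names(ns) <- names(groups)
  for (g in names(groups)) {
    idx <- groups[[g]]
    ns[g] <- sum(idx)
    if (ns[g] == 0L) next
    for (r in names(rows))
      tab[r, g] <- round_half_away(100 * sum(rows[[r]][idx]) / ns[g], 1)
  }
  attr(tab, "n") <- ns
  attr(tab, "mode") <- fit$mode
  class(tab) <- c("passing_rate_table", class(tab))
  tab
}

#' @export
print.passing_rate_table <- function(x, ...) {
  ns <- attr(x, "n")
  cat(sprintf("Passing rates (%% of stratum), %s thresholds\n", attr(x, "mode")))
  m <- unclass(x)
  attr(m, "n") <- NULL; attr(m, "mode") <- NULL
  disp <- format(m, nsmall = 1)
  disp[is.na(m)] <- "n=0"
  hdr <- sprintf("%s (n=%d)", colnames(m), ns)
  colnames(disp) <- hdr
  print(disp, quote = FALSE)
  invisible(x)
}

#' Cohort summary of dosimetric gains per structure
#'
#' Per-structure cohort means of the photon-minus-proton differences in mean
#' dose and near-maximum dose (D1%), both absolute (Gy(RBE)) and as percent
#' of the photon value (per-patient percentages averaged; patients with zero
#' photon dose are excluded from the percentage mean). Structures missing in
#' some patients are averaged over the available pairs, with n reported.
#'
#' @param fit an `mbs_selection` object from [mbs()].
#' @return `data.frame` with columns `structure`, `n`, `delta_davg_gy`,
#'   `delta_davg_pct`, `delta_d1_gy`, `delta_d1_pct`.
#' @export
dose_delta_summary <- function(fit) {
  stopifnot(inherits(fit, "mbs_selection"))
  structs <- colnames(fit$davg_photon)
  out <- lapply(structs, function(s) {
    dx <- fit$davg_photon[, s]; dp <- fit$davg_proton[, s]
    ok <- !is.na(dx) & !is.na(dp)
    d1x <- fit$d1_photon[, s]; d1p <- fit$d1_proton[, s]
    pct <- function(a, b) { # mean per-patient percent of photon value
      sel <- ok & a > 0
      if (!any(sel)) NA_real_ else mean(100 * (a[sel] - b[sel]) / a[sel])
    }
    data.frame(structure = s, n = sum(ok),
               delta_davg_gy = mean(dx[ok] - dp[ok]),
               delta_davg_pct = pct(dx, dp),
               delta_d1_gy = mean(d1x[ok] - d1p[ok]),
               delta_d1_pct = pct(d1x, d1p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
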