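# Synthetic paired-cohort generator: reproducibility, construction
# guarantees, cohort composition, effect planting.

test_that("identical seeds reproduce identical cohorts", {
  c1 <- generate_cohort(small_config(n = 4, seed = 77))
  c2 <- generate_cohort(small_config(n = 4, seed = 77))
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$plans, c2$plans)
  c3 <- generate_cohort(small_config(n = 4, seed = 78))
  expect_false(identical(c1$plans, c3$plans))
})

test_that("cohorts extend without reshuffling earlier patients", {
  c4 <- generate_cohort(small_config(n = 4, seed = 19))
  c6 <- generate_cohort(small_config(n = 6, seed = 19))
  expect_identical(c4$plans, c6$plans[1:4])
  expect_identical(c4$covariates, c6$covariates[1:4, ])
})

test_that("generated DVHs satisfy the container invariants", {
  coh <- generate_cohort(small_config(n = 3, seed = 31))
  for (pair in coh$plans) for (plan in pair) for (s in plan$structures) {
    expect_s3_class(s, "structure_dvh")
    expect_equal(s$representation, "cumulative")
    expect_equal(s$dose[1], 0)
    expect_equal(s$frac[1], 1)                      # fully covered at 0 Gy
    expect_true(all(diff(s$frac) <= 1e-9))          # non-increasing
    expect_equal(s$frac[length(s$frac)], 0)         # ends at zero
  }
})

test_that("proton OAR doses are never above photon doses by construction", {
  coh <- generate_cohort(small_config(n = 5, seed = 37))
  oars <- setdiff(names(coh$plans[[1]]$photon$structures),
                  c("ptv_hd", "ptv_id", "ptv_ld"))
  for (pair in coh$plans) for (s in oars) {
    expect_lte(mean_dose(pair$proton$structures[[s]]),
               mean_dose(pair$photon$structures[[s]]) + 1e-9)
    # pointwise cumulative dominance
    expect_true(all(pair$proton$structures[[s]]$frac <=
                      pair$photon$structures[[s]]$frac + 1e-9))
  }
})

test_that("both plans meet the target coverage goal with equivalent metrics", {
  coh <- generate_cohort(small_config(n = 5, seed = 41))
  for (pair in coh$plans) for (mod in c("photon", "proton")) {
    plan <- pair[[mod]]
    for (lev in seq_len(nrow(plan$prescriptions))) {
      tgt <- plan$prescriptions$target[lev]
      rx <- plan$prescriptions$dose_gy[lev]
      expect_gte(volume_at_dose(plan$structures[[tgt]], 0.95 * rx), 0.95)
    }
  }
  # paired PTV D99% agree closely (sub-Gy), emulating equivalent coverage
  d99 <- vapply(coh$plans, function(pair) {
    dose_at_volume(pair$photon$structures$ptv_hd, 0.99) -
      dose_at_volume(pair$proton$structures$ptv_hd, 0.99)
  }, numeric(1))
  expect_lt(max(abs(d99)), 1.0)
})

test_that("covariate composition matches the configured mix at large n", {
  # covariate sampling only needs one cheap structure
  cfg <- generator_config(n_patients = 10000, seed = 101,
                          structures = "cochlea", bin_width = 2)
  coh <- generate_cohort(cfg)
  tt <- table(factor(coh$covariates$t_stage, levels = 1:4)) / 10000
  expect_true(all(abs(tt - c(0.40, 0.14, 0.30, 0.16)) < 0.015))
  nn <- table(factor(coh$covariates$n_stage, levels = 0:3)) / 10000
  expect_true(all(abs(nn - c(0.16, 0.28, 0.30, 0.26)) < 0.015))
  tr <- table(factor(coh$covariates$treatment,
                     levels = c("RT alone", "RT-CHT", "iCHT+RT-CHT"))) / 10000
  expect_true(all(abs(tr - c(0.08, 0.54, 0.38)) < 0.015))
  sc <- table(factor(coh$covariates$scheme,
                     levels = c("two_level_56", "two_level_59", "three_level"))) / 10000
  expect_true(all(abs(sc - c(0.24, 0.20, 0.56)) < 0.015))
  expect_true(all(coh$covariates$age >= 24 & coh$covariates$age <= 72))
})

test_that("unit sparing factors yield identical plans and zero deltas downstream", {
  st <- protonMBS:::default_structure_table()
  st$sparing <- 1; st$sparing_sd <- 0
  coh <- generate_cohort(generator_config(n_patients = 2, seed = 5,
                                          structure_table = st,
                                          bin_width = 0.5))
  fit <- suppressWarnings(mbs(coh))
  oars <- grep("^ptv", colnames(fit$davg_photon), invert = TRUE, value = TRUE)
  expect_equal(fit$davg_photon[, oars], fit$davg_proton[, oars],
               tolerance = 1e-12)
  expect_true(all(abs(fit$delta[, ]) < 1e-9 |
                    is.na(fit$delta[, ])))
  expect_true(all(abs(fit$cts) < 1e-9))
  expect_true(all(!fit$eligibility$eligible))
})

test_that("plant_effect returns unit sparing for a zero target", {
  cfg <- small_config(n = 10, seed = 3)
  out <- plant_effect(cfg, c(xerostomia_loizeau = 0), n_ref = 20)
  row <- out$structure_table$structure == "parotid"
  expect_equal(out$structure_table$sparing[row], 1)
  expect_equal(out$structure_table$sparing_sd[row], 0)
})

test_that("plant_effect calibrates a pass fraction and validates input", {
  cfg <- generator_config(n_patients = 50, seed = 7, structures = "parotid",
                          bin_width = 0.5)
  out <- plant_effect(cfg, c(xerostomia_loizeau = 0.24), n_ref = 300)
  s_cal <- out$structure_table$sparing[out$structure_table$structure == "parotid"]
  expect_true(s_cal > 0.05 && s_cal < 1)
  # observed pass fractions over fresh seeds center near the target
  reg <- default_registry()
  model <- reg$models$xerostomia_loizeau
  thr <- threshold_set(reg, "standard")$thresholds[["xerostomia_loizeau"]]
  fracs <- vapply(1:30, function(k) {
    cfg_k <- out; cfg_k$seed <- 5000L + k
    coh <- generate_cohort(cfg_k)
    mean(vapply(coh$plans, function(pair) {
      100 * (evaluate_model(model, pair$photon) -
               evaluate_model(model, pair$proton)) > thr
    }, logical(1)))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.24), 0.06)
  # invalid targets and unknown models are rejected
  expect_error(plant_effect(cfg, c(xerostomia_loizeau = 1.4)), "\\[0, 1\\]")
  expect_error(plant_effect(cfg, c(nonexistent_model = 0.2)), "not in registry")
  expect_error(plant_effect(cfg, c(tinnitus_lee = 0.2)), "threshold")
})
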