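# gEUD, NTCP functional forms, registry validation, delta computation.

test_that("gEUD reduces to the mean at a = 1 and to D for uniform dose", {
  set.seed(21)
  for (i in 1:10) {
    dvh <- random_dvh(n_bins = sample(5:25, 1))
    expect_equal(geud(dvh, 1), mean_dose(dvh), tolerance = 1e-12)
  }
  u <- uniform_dvh(54.3)
  for (a in c(-5, -1, 0.5, 1, 2, 8)) expect_equal(geud(u, a), 54.3)
})

test_that("gEUD matches the closed form and its structural properties", {
  dvh <- structure_dvh("s", 10, c(0, 10), c(0.5, 0.5), "differential")
  expect_equal(geud(dvh, 2), sqrt(50), tolerance = 1e-12)
  expect_error(geud(dvh, 0), "nonzero")
  # non-decreasing in a, bounded by min/max dose (power-mean inequality)
  set.seed(8)
  for (i in 1:10) {
    dvh <- random_dvh(n_bins = 12)
    as <- c(0.5, 1, 2, 4, 8, 16)
    gs <- vapply(as, function(a) geud(dvh, a), numeric(1))
    expect_true(all(diff(gs) >= -1e-9))
    expect_gte(min(gs), min(dvh$dose) - 1e-9)
    expect_lte(max(gs), max(dvh$dose) + 1e-9)
  }
  # zero-dose handling for negative a
  z <- structure_dvh("s", 10, c(0, 20), c(0.3, 0.7), "differential")
  expect_warning(g <- geud(z, -2), "zero-dose")
  expect_equal(g, 20) # remaining mass is uniform at 20
  allz <- structure_dvh("s", 10, 0, 1, "differential")
  expect_warning(g0 <- geud(allz, -1), "undefined")
  expect_true(is.nan(g0))
})

test_that("NTCP forms hit their anchor points", {
  u50 <- uniform_dvh(50, structure_id = "organ")
  plan <- plan_of(u50)
  # LKB probit at S = TD50 gives 0.5; TD50=50, m=0.2, S=60 gives pnorm(1)
  lkb <- ntcp_model_spec("lkb", "organ", "", "lkb_probit",
                         list(type = "mean"), list(td50 = 50, m = 0.2),
                         weight = 1)
  expect_equal(evaluate_model(lkb, plan), 0.5)
  expect_equal(evaluate_model(lkb, plan_of(uniform_dvh(60, structure_id = "organ"))),
               stats::pnorm(1), tolerance = 1e-12)
  expect_equal(round(stats::pnorm(1), 4), 0.8413)
  # logistic with zero linear predictor gives 0.5
  lgt <- ntcp_model_spec("lgt", "organ", "", "logistic_linear",
                         list(type = "mean"),
                         list(intercept = -2.5, coefficients = list(dose = 0.05)),
                         weight = 1)
  expect_equal(evaluate_model(lgt, plan), 0.5)
  # log-logistic at S = D50 gives 0.5; S = 0 gives 0
  llg <- ntcp_model_spec("llg", "organ", "", "loglogistic_d50_gamma",
                         list(type = "mean"), list(d50 = 50, gamma50 = 1.5),
                         weight = 1)
  expect_equal(evaluate_model(llg, plan), 0.5)
  expect_equal(evaluate_model(llg, plan_of(uniform_dvh(0, structure_id = "organ"))), 0)
})

test_that("missing structures and covariates mark models not evaluable", {
  lkb <- ntcp_model_spec("lkb", "absent_organ", "", "lkb_probit",
                         list(type = "mean"), list(td50 = 50, m = 0.2),
                         weight = 1)
  plan <- plan_of(uniform_dvh(50, structure_id = "organ"))
  expect_warning(v <- evaluate_model(lkb, plan), "not evaluable")
  expect_true(is.na(v))
  lgt <- ntcp_model_spec("lgt", "organ", "", "logistic_linear",
                         list(type = "mean"),
                         list(intercept = -2, coefficients = list(dose = 0.03,
                                                                  age = 0.01)),
                         weight = 1)
  expect_warning(v2 <- evaluate_model(lgt, plan), "covariate 'age' missing")
  expect_true(is.na(v2))
  expect_equal(evaluate_model(lgt, plan, covariates = list(age = 50)),
               stats::plogis(-2 + 0.03 * 50 + 0.01 * 50))
})

test_that("NTCP is monotone in dose scaling for every form", {
  set.seed(31)
  base <- random_dvh(n_bins = 15, structure_id = "organ")
  forms <- list(
    ntcp_model_spec("a", "organ", "", "lkb_probit", list(type = "geud", a = 2),
                    list(td50 = 45, m = 0.3), weight = 1),
    ntcp_model_spec("b", "organ", "", "logistic_linear", list(type = "mean"),
                    list(intercept = -4, coefficients = list(dose = 0.08)),
                    weight = 1),
    ntcp_model_spec("c", "organ", "", "loglogistic_d50_gamma",
                    list(type = "dx", x = 1), list(d50 = 55, gamma50 = 1.2),
                    weight = 1))
  for (m in forms) {
    prev <- -Inf
    for (scale in c(0.5, 0.8, 1, 1.3, 1.8)) {
      scaled <- structure_dvh("organ", 10, scale * base$dose, base$frac,
                              "differential")
      v <- evaluate_model(m, plan_of(scaled))
      expect_gte(v, prev - 1e-12)
      prev <- v
    }
  }
})

test_that("NTCP forms stay in [0,1] for arbitrary finite parameters", {
  set.seed(13)
  dvh <- random_dvh(n_bins = 8, structure_id = "organ")
  plan <- plan_of(dvh)
  for (i in 1:50) {
    lkb <- ntcp_model_spec("x", "organ", "", "lkb_probit", list(type = "mean"),
                           list(td50 = stats::runif(1, 1, 200),
                                m = stats::runif(1, 0.01, 2)), weight = 1)
    lgt <- ntcp_model_spec("y", "organ", "", "logistic_linear", list(type = "mean"),
                           list(intercept = stats::rnorm(1, 0, 10),
                                coefficients = list(dose = stats::rnorm(1, 0, 1))),
                           weight = 1)
    llg <- ntcp_model_spec("z", "organ", "", "loglogistic_d50_gamma",
                           list(type = "mean"),
                           list(d50 = stats::runif(1, 1, 150),
                                gamma50 = stats::runif(1, 0.1, 5)), weight = 1)
    for (m in list(lkb, lgt, llg)) {
      v <- evaluate_model(m, plan)
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("default registry reproduces the published structure", {
  reg <- default_registry()
  expect_length(reg$models, 16)
  expect_length(protonMBS:::mbs_model_ids(reg), 7)
  w <- weight_set(reg)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  # the 11 lowest-weight models (weight <= 0.07) carry exactly 1/4 of the total
  expect_equal(sum(w <= 0.07), 11)
  expect_equal(sum(w[w <= 0.07]), 0.25, tolerance = 1e-12)
  thr <- threshold_set(reg, "standard")
  expect_equal(sort(unname(thr$thresholds)), c(5, 5, 5, 10, 10, 10, 15))
  thr_y <- threshold_set(reg, "young")
  expect_true(all(thr_y$thresholds <= thr$thresholds))
  expect_equal(thr$composite, 35)
  expect_equal(thr_y$composite, 35)
})

test_that("registry load rejects weight-sum violations and bad forms", {
  reg <- default_registry()
  path <- tempfile(fileext = ".yaml")
  cfg <- yaml::read_yaml(system.file("extdata", "ntcp_registry_synthetic.yaml",
                                     package = "protonMBS"))
  cfg$models[[1]]$weight <- cfg$models[[1]]$weight + 0.1
  yaml::write_yaml(cfg, path)
  expect_error(read_ntcp_registry(path), "sum to unity")
  cfg$models[[1]]$weight <- cfg$models[[1]]$weight - 0.1
  cfg$models[[2]]$form <- "weibull"
  yaml::write_yaml(cfg, path)
  expect_error(read_ntcp_registry(path), "unknown form")
  unlink(path)
})

test_that("delta_ntcp subtracts per model in percentage points, sign preserved", {
  reg <- default_registry()
  coh <- generate_cohort(small_config(n = 1, seed = 2))
  pair <- coh$plans[[1]]
  cov <- coh$covariates[1, ]
  nx <- evaluate_plan_ntcp(reg, pair$photon, cov)
  # identical plans give all-zero deltas
  expect_equal(unname(as.numeric(delta_ntcp(nx, nx))),
               rep(0, length(nx)))
  # hand-built vectors: 0.30 vs 0.175 -> +12.5 points; 0.10 vs 0.12 -> -2.0
  mk <- function(p, mod) structure(stats::setNames(p, c("m1", "m2")),
                                   patient_id = "P001", modality = mod,
                                   class = "plan_ntcp")
  d <- delta_ntcp(mk(c(0.30, 0.10), "photon"), mk(c(0.175, 0.12), "proton"))
  expect_equal(unname(d["m1"]), 12.5)
  expect_equal(unname(d["m2"]), -2.0)
  # mismatched patients rejected
  good <- structure(stats::setNames(0.2, "m1"), patient_id = "P001",
                    modality = "photon", class = "plan_ntcp")
  bad <- structure(stats::setNames(0.2, "m1"), patient_id = "P999",
                   modality = "proton", class = "plan_ntcp")
  expect_error(delta_ntcp(good, bad), "different patients")
})
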