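# DVH container, conversions and dosimetric quantifiers.

test_that("differential/cumulative conversion matches reverse partial sums and is lossless", {
  # single point mass: all volume at 60 Gy
  d1 <- uniform_dvh(60)
  c1 <- suppressMessages(as_cumulative(d1))
  expect_equal(c1$frac, 1)
  # two point masses
  d2 <- structure_dvh("s", 10, c(40, 60), c(0.5, 0.5), "differential")
  c2 <- suppressMessages(as_cumulative(d2))
  expect_equal(c2$frac, c(1.0, 0.5))
  # random DVHs against the direct reverse-summation oracle; round trip
  set.seed(42)
  for (i in 1:20) {
    dv <- random_dvh(n_bins = sample(3:30, 1))
    cu <- suppressMessages(as_cumulative(dv))
    oracle <- vapply(seq_along(dv$dose),
                     function(k) sum(dv$frac[k:length(dv$frac)]), numeric(1))
    expect_equal(cu$frac, oracle, tolerance = 1e-12)
    back <- suppressMessages(as_differential(cu))
    expect_equal(back$frac, dv$frac, tolerance = 1e-12)
    expect_identical(back$dose, dv$dose)
  }
  # no-op on already-cumulative input, with a notice
  expect_message(as_cumulative(cu), "already cumulative")
})

test_that("DVH validation rejects malformed input", {
  expect_error(structure_dvh("s", 10, c(1, 2), c(-0.2, 0.5), "differential"),
               "negative")
  expect_error(structure_dvh("s", 10, c(2, 1), c(0.5, 0.5), "differential"),
               "strictly increasing")
  expect_error(structure_dvh("s", 10, numeric(0), numeric(0), "differential"),
               "empty")
  expect_error(structure_dvh("s", -5, 10, 1, "differential"), "positive")
  expect_error(structure_dvh("s", 10, c(1, 2), c(0.5, 1.0), "cumulative"),
               "non-increasing")
})

test_that("dose_at_volume follows the hottest-x% convention with interpolation", {
  # uniform structure: any fraction returns the uniform dose
  u <- uniform_dvh(60)
  for (v in c(0.01, 0.5, 0.99, 1)) expect_equal(dose_at_volume(u, v), 60)
  # step DVH: flat segments resolve to the highest qualifying dose
  d2 <- structure_dvh("s", 10, c(40, 60), c(0.5, 0.5), "differential")
  expect_equal(dose_at_volume(d2, 0.5), 60)
  expect_equal(dose_at_volume(d2, 1.0), 40)
  expect_equal(dose_at_volume(d2, 0.25), 60)
  expect_error(dose_at_volume(d2, 0), "\\(0, 1\\]")
  expect_error(dose_at_volume(d2, 1.2), "\\(0, 1\\]")
})

test_that("Dx% matches the voxel-sorting oracle within one bin width", {
  set.seed(7)
  bw <- 0.1
  voxels <- stats::runif(200, 10, 70)
  dvh <- voxel_dvh(voxels, bin_width = bw)
  # D5% oracle: the 10th-largest of 200 voxel doses
  oracle_d5 <- sort(voxels, decreasing = TRUE)[10]
  expect_lt(abs(dose_at_volume(dvh, 0.05) - oracle_d5), bw)
  # full oracle-equivalence sweep on <=1000 voxels
  voxels <- stats::rnorm(1000, 45, 12)
  voxels <- pmax(voxels, 0)
  dvh <- voxel_dvh(voxels, bin_width = bw)
  for (x in c(0.01, 0.02, 0.05, 0.5, 0.95, 0.98, 0.99)) {
    oracle <- sort(voxels, decreasing = TRUE)[ceiling(x * length(voxels))]
    expect_lt(abs(dose_at_volume(dvh, x) - oracle), bw)
  }
  expect_lt(abs(mean_dose(dvh) - mean(voxels)), bw / 2)
  # V-metric against direct counting
  for (thr in c(30, 45, 60))
    expect_lt(abs(volume_at_dose(dvh, thr) - mean(voxels >= thr)), 0.01)
})

test_that("Dx% is non-increasing in x and metrics survive re-binning", {
  set.seed(11)
  voxels <- stats::rgamma(500, shape = 8, scale = 5)
  dvh <- voxel_dvh(voxels, bin_width = 0.1)
  xs <- seq(0.01, 1, by = 0.01)
  ds <- vapply(xs, function(x) dose_at_volume(dvh, x), numeric(1))
  expect_true(all(diff(ds) <= 1e-9))
  # same voxels at two grid resolutions: metrics agree within the coarse bin
  coarse <- voxel_dvh(voxels, bin_width = 0.5)
  for (x in c(0.01, 0.05, 0.5, 0.95))
    expect_lt(abs(dose_at_volume(dvh, x) - dose_at_volume(coarse, x)), 0.5)
  expect_lt(abs(mean_dose(dvh) - mean_dose(coarse)), 0.5)
})

test_that("mean dose is the fraction-weighted bin average", {
  expect_equal(mean_dose(uniform_dvh(60)), 60)
  d2 <- structure_dvh("s", 10, c(40, 60), c(0.5, 0.5), "differential")
  expect_equal(mean_dose(d2), 50)
  set.seed(3)
  voxels <- stats::runif(300, 0, 50)
  expect_lt(abs(mean_dose(voxel_dvh(voxels, 0.1)) - mean(voxels)), 0.05)
})

test_that("conformity index counts the volume at or above 95% of prescription", {
  rx <- 60
  expect_equal(conformity_index(uniform_dvh(rx), rx), 1.0)
  cold <- uniform_dvh(0.9 * rx)
  expect_equal(conformity_index(cold, rx), 0.0)
  half <- structure_dvh("ptv", 100, c(0.90 * rx, 0.96 * rx), c(0.5, 0.5),
                        "differential")
  expect_equal(conformity_index(half, rx), 0.5)
  expect_error(conformity_index(half, 0), "positive")
})

test_that("homogeneity index matches the linear-DVH closed form and is scale invariant", {
  expect_equal(homogeneity_index(uniform_dvh(60)), 0)
  # cumulative falling linearly from 1 at 60 Gy to 0 at 70 Gy:
  # Dx% = 70 - 10 x/100, so HI = (69.8 - 60.2)/65
  lin <- structure_dvh("ptv", 100, c(60, 70), c(1, 0), "cumulative")
  expect_equal(homogeneity_index(lin), (69.8 - 60.2) / 65, tolerance = 1e-12)
  for (c_scale in c(0.5, 2, 3.7)) {
    scaled <- structure_dvh("ptv", 100, c_scale * c(60, 70), c(1, 0), "cumulative")
    expect_equal(homogeneity_index(scaled), homogeneity_index(lin),
                 tolerance = 1e-12)
  }
})

test_that("integral dose is mean body dose times body volume", {
  body <- structure_dvh("body", 10000, 1, 1, "differential")
  expect_equal(integral_dose(body), 10000)
  zero <- structure_dvh("body", 10000, 0, 1, "differential")
  expect_equal(integral_dose(zero), 0)
  set.seed(5)
  voxels <- stats::rexp(400, rate = 0.2)
  dvh <- voxel_dvh(voxels, bin_width = 0.1, volume_cc = 8000,
                   structure_id = "body")
  expect_equal(integral_dose(dvh), mean_dose(dvh) * 8000)
  expect_lt(abs(integral_dose(dvh) - sum(voxels) / length(voxels) * 8000),
            0.05 * 8000)
})

test_that("partially covered structures warn and compute on the covered fraction", {
  part <- structure_dvh("s", 10, c(10, 20), c(0.4, 0.4), "differential")
  expect_warning(m <- mean_dose(part), "covered")
  expect_equal(m, 15)
})

test_that("DVH CSV round trip is lossless within 1e-9", {
  coh <- generate_cohort(small_config(n = 2, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_dvh_csv(coh$plans, path)
  back <- read_dvh_csv(path)
  expect_setequal(names(back), names(coh$plans))
  for (pid in names(coh$plans)) {
    for (mod in c("photon", "proton")) {
      orig <- coh$plans[[pid]][[mod]]$structures
      got <- back[[pid]][[mod]]$structures
      expect_setequal(names(got), names(orig))
      for (s in names(orig)) {
        oc <- protonMBS:::cum_dvh(orig[[s]])
        gc <- protonMBS:::cum_dvh(got[[s]])
        expect_equal(gc$dose, oc$dose, tolerance = 1e-9)
        expect_equal(gc$frac, oc$frac, tolerance = 1e-9)
        expect_equal(gc$total_volume_cc, oc$total_volume_cc, tolerance = 1e-9)
      }
    }
  }
  unlink(path)
})

test_that("malformed DVH files raise line-numbered parse errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,plan,structure,total_volume_cc,dose_gy,cum_volume_fraction",
               "P1,photon,parotid,25,0,1.0",
               "P1,photon,parotid,25,2,0.8",
               "P1,photon,parotid,25,1,0.5"), path)
  expect_error(read_dvh_csv(path), "line 4")
  writeLines(c("patient_id,plan,structure,total_volume_cc,dose_gy,cum_volume_fraction",
               "P1,carbon,parotid,25,0,1.0"), path)
  expect_error(read_dvh_csv(path), "photon/proton")
  unlink(path)
})
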