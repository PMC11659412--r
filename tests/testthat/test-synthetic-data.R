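test_that("noiseless traces invert exactly through the NPQ equations", {
  p <- protocol_preset("cf_imager")
  tr <- simulate_trace(sustained_quenching = 0, amplitude = 2, half_time = 1,
                       noise_cv = 0, seed = 1, protocol = p)
  npq <- compute_npq(tr, p)
  light <- npq[npq$phase == "light", ]
  expect_equal(light$npq, 2 * light$time_min / (light$time_min + 1),
               tolerance = 1e-12)
})

test_that("a q_s twin pair yields the injected sustained quenching exactly", {
  cold <- simulate_trace(sustained_quenching = 0.3, noise_cv = 0, seed = 1)
  warm <- simulate_trace(sustained_quenching = 0, noise_cv = 0, seed = 2)
  warm_fvfm <- compute_fvfm(warm$f_o[1], warm$f_m[1])
  out <- compute_npq_a(cold, warm_ref = warm_fvfm)
  expect_equal(unique(out$npq_a_dark), 0.3, tolerance = 1e-12)
})

test_that("generators are pure functions of parameters and seed", {
  a <- simulate_trace(sustained_quenching = 0.2, noise_cv = 0.05, seed = 9)
  b <- simulate_trace(sustained_quenching = 0.2, noise_cv = 0.05, seed = 9)
  expect_identical(a, b)
  c <- simulate_trace(sustained_quenching = 0.2, noise_cv = 0.05, seed = 10)
  expect_false(identical(a$f_m_prime, c$f_m_prime))

  s1 <- simulate_spectrum(0.5, seed = 4)
  s2 <- simulate_spectrum(0.5, seed = 4)
  expect_identical(s1, s2)

  e1 <- simulate_plate_experiment(seed = 3, n_reps = 2)
  e2 <- simulate_plate_experiment(seed = 3, n_reps = 2)
  expect_identical(e1$traces, e2$traces)

  t1 <- simulate_assay_tables(n_reps = 2, seed = 5)
  t2 <- simulate_assay_tables(n_reps = 2, seed = 5)
  expect_identical(t1, t2)
})

test_that("dark-phase flashes decay toward the sustained level", {
  tr <- simulate_trace(sustained_quenching = 0.25, amplitude = 2,
                       half_time = 1, relaxation_fraction = 0.4,
                       noise_cv = 0, seed = 1)
  npq <- compute_npq(tr)
  dark <- npq[npq$phase == "dark", ]
  expect_true(all(diff(dark$npq) < 0))
  # measured NPQ relaxes toward 0 (the sustained part is invisible to the
  # unadjusted curve because it also quenches the dark f_m)
  expect_gt(min(dark$npq), 0)
})

test_that("the plate experiment covers the design and records ground truth", {
  exp <- simulate_plate_experiment(seed = 8, n_reps = 3)
  counts <- dplyr::count(exp$ground_truth, accession, treatment)
  expect_equal(nrow(counts), 6)
  expect_true(all(counts$n == 3))
  expect_equal(nrow(exp$traces),
               6 * 3 * length(protocol_preset("cf_imager")$flash_times_min))
  expect_true(all(c("q_s", "amplitude", "half_time", "initial_slope") %in%
                    names(exp$ground_truth)))
  # designed effect structure of the default experiment
  gt <- dplyr::distinct(exp$ground_truth, accession, treatment, q_s,
                        initial_slope)
  warm <- gt[gt$treatment == "warm", ]
  expect_true(all(warm$q_s == 0))
  expect_true(all(warm$initial_slope == 2))
  chill <- gt[gt$treatment == "chilling", ]
  expect_gt(chill$q_s[chill$accession == "MsaRB"],
            chill$q_s[chill$accession == "MsiCR"])
})

test_that("the infiltration design retains the designed rate fractions", {
  des <- default_infiltration_design()
  cells <- des$cells
  for (acc in c("MsaRB", "MxgI", "MsiCR")) {
    w <- cells[cells$accession == acc & cells$treatment == "chilling" &
                 cells$infiltration == "water", ]
    d <- cells[cells$accession == acc & cells$treatment == "chilling" &
                 cells$infiltration == "dtt", ]
    frac <- (d$amplitude / d$half_time) / (w$amplitude / w$half_time)
    expect_equal(frac, c(MsaRB = 0.76, MxgI = 0.48, MsiCR = 0.23)[[acc]],
                 tolerance = 1e-12)
  }
})

test_that("simulated spectra encode the de-epoxidation dip", {
  s0 <- simulate_spectrum(0, noise_sd = 0, seed = 1)
  s1 <- simulate_spectrum(1, noise_sd = 0, seed = 1)
  expect_lt(pri(bin_spectrum(s1)), pri(bin_spectrum(s0)))
  expect_true(all(s0$reflectance > 0))
  expect_true(all(abs(diff(s0$wavelength_nm) - 0.3) < 1e-9))
})

test_that("assay tables invert to their designed effects at zero noise", {
  tabs <- simulate_assay_tables(n_reps = 2, conc_cv = 0, ct_sd = 0, seed = 1)
  # ZEP fold change 4 (chilling vs warm night) in MsiCR, 1 in MsaRB
  zep <- tabs$cts[tabs$cts$target == "ZEP", ]
  rel <- relative_expression(zep, calibrator = "MsiCR_warm_night_1")
  by_cell <- dplyr::distinct(rel, accession, treatment, rel_expr)
  expect_equal(
    by_cell$rel_expr[by_cell$accession == "MsiCR" &
                       by_cell$treatment == "chilling_night"], 4)
  expect_equal(
    by_cell$rel_expr[by_cell$accession == "MsaRB" &
                       by_cell$treatment == "chilling_night"],
    by_cell$rel_expr[by_cell$accession == "MsaRB" &
                       by_cell$treatment == "warm_night"])
  # designed zeaxanthin ratio 3 between high- and low-tolerance accessions
  pig <- tabs$pigments
  z_hi <- mean(pig$zeaxanthin[pig$accession == "MsaRB" &
                                pig$treatment == "chilling_night"])
  z_lo <- mean(pig$zeaxanthin[pig$accession == "MsiCR" &
                                pig$treatment == "chilling_night"])
  expect_equal(z_hi / z_lo, 3)
  # calibration points are exact lines with the designed slopes
  zcal <- tabs$calibration_points[
    tabs$calibration_points$analyte == "zeaxanthin", ]
  cal <- fit_calibration(zcal, analyte = "zeaxanthin")
  expect_equal(cal$slope, 12)
  expect_equal(cal$r_squared, 1)
})

test_that("designed group ratios survive noise at realistic replication", {
  tabs <- simulate_assay_tables(n_reps = 8, seed = 42)
  pig <- tabs$pigments
  z_hi <- mean(pig$zeaxanthin[pig$accession == "MsaRB" &
                                pig$treatment == "chilling_night"])
  z_lo <- mean(pig$zeaxanthin[pig$accession == "MsiCR" &
                                pig$treatment == "chilling_night"])
  expect_equal(z_hi / z_lo, 3, tolerance = 0.25)
})
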