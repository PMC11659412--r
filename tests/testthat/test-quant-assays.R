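exact_curve <- function(analyte = "zeaxanthin", slope = 10) {
  fit_calibration(
    data.frame(concentration = c(0, 10, 20), response = slope * c(0, 10, 20)),
    analyte = analyte
  )
}

test_that("calibration fits the exact line and stores printed limits", {
  cal <- exact_curve()
  expect_equal(cal$slope, 10)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$loq, 21)

  expect_equal(pigment_limits("lutein")[["loq"]], 21)
  expect_equal(pigment_limits("antheraxanthin")[["loq"]], 21)
  expect_equal(pigment_limits("zeaxanthin")[["loq"]], 21)
  expect_equal(pigment_limits("violaxanthin")[["loq"]], 20)
  expect_equal(pigment_limits("chlorophyll_a")[["loq"]], 35)
  expect_equal(pigment_limits("chlorophyll_b")[["loq"]], 25)
  expect_error(pigment_limits("caffeine"), class = "npqkit_unknown_analyte")
})

test_that("degenerate calibrations are rejected", {
  expect_error(
    fit_calibration(data.frame(concentration = c(5, 5), response = c(1, 2))),
    class = "npqkit_singular_fit"
  )
  expect_error(
    fit_calibration(data.frame(concentration = c(0, 10),
                               response = c(10, 0))),
    class = "npqkit_singular_fit"
  )
})

test_that("quantify inverts the calibration exactly on its own points", {
  set.seed(5)
  pts <- data.frame(concentration = c(0, 5, 10, 25, 50),
                    response = 7.3 * c(0, 5, 10, 25, 50) + 2.1)
  cal <- fit_calibration(pts, analyte = "violaxanthin")
  q <- quantify(cal, pts$response)
  expect_equal(q$concentration, pts$concentration, tolerance = 1e-10)
})

test_that("LOQ/LOD gating flags but retains low concentrations", {
  cal <- exact_curve("zeaxanthin")
  q <- quantify(cal, 150) # 15 ug/ml < LOQ 21
  expect_equal(q$concentration, 15)
  expect_true(q$below_loq)
  q0 <- quantify(cal, 0)
  expect_equal(q0$concentration, 0)
  expect_true(q0$below_lod)
  # negative computed concentration clips to zero with the LOD flag
  cal2 <- fit_calibration(
    data.frame(concentration = c(0, 10, 20), response = c(5, 105, 205)),
    analyte = "zeaxanthin"
  )
  qn <- quantify(cal2, 1)
  expect_equal(qn$concentration, 0)
  expect_true(qn$below_lod)
})

test_that("chlorophyll normalisation divides pigments and rebuilds the pool", {
  d <- tibble::tibble(sample_id = "s", zeaxanthin = 10, antheraxanthin = 5,
                      violaxanthin = 20, lutein = 15,
                      chlorophyll_a = 80, chlorophyll_b = 20)
  out <- normalize_to_chlorophyll(d)
  expect_equal(out$zeaxanthin, 0.10)
  expect_equal(out$vaz_pool, 0.35)
  expect_equal(out$total_chlorophyll, 100)
  # all-zero pigments normalise to zero
  d0 <- dplyr::mutate(d, zeaxanthin = 0, antheraxanthin = 0,
                      violaxanthin = 0, lutein = 0)
  expect_equal(normalize_to_chlorophyll(d0)$vaz_pool, 0)
  expect_error(
    normalize_to_chlorophyll(dplyr::mutate(d, chlorophyll_a = 0,
                                           chlorophyll_b = 0)),
    class = "npqkit_normalization_error"
  )
})

test_that("pool equals sum of components for every generated record", {
  tabs <- simulate_assay_tables(n_reps = 3, seed = 2)
  out <- normalize_to_chlorophyll(tabs$pigments)
  expect_equal(out$vaz_pool,
               out$violaxanthin + out$antheraxanthin + out$zeaxanthin)
})

test_that("delta-delta-Ct matches its defining arithmetic", {
  ct <- tibble::tibble(
    sample_id = c("s", "cal"), target = "ZEP",
    ct_target = c(24, 25), ct_ref1 = 20, ct_ref2 = 22
  )
  out <- relative_expression(ct, calibrator = "cal")
  # sample dCt = 24 - 21 = 3, calibrator dCt = 4 -> 2^1 = 2
  expect_equal(out$rel_expr[out$sample_id == "s"], 2)
  expect_equal(out$rel_expr[out$sample_id == "cal"], 1)
  ct2 <- dplyr::mutate(ct, ct_target = c(26, 24)) # dCt 5 vs 3 -> 0.25
  out2 <- relative_expression(ct2, calibrator = "cal")
  expect_equal(out2$rel_expr[out2$sample_id == "s"], 0.25)
})

test_that("relative expression is invariant to uniform Ct shifts", {
  ct <- tibble::tibble(
    sample_id = c("a", "b"), target = "VDE",
    ct_target = c(23.7, 26.1), ct_ref1 = c(19.9, 20.3),
    ct_ref2 = c(21.8, 22.2)
  )
  base <- relative_expression(ct, calibrator = "b")
  shifted <- relative_expression(
    dplyr::mutate(ct, ct_target = ct_target + 3.3, ct_ref1 = ct_ref1 + 3.3,
                  ct_ref2 = ct_ref2 + 3.3),
    calibrator = "b"
  )
  expect_equal(shifted$rel_expr, base$rel_expr)
})

test_that("relative_expression validates its inputs", {
  ct <- tibble::tibble(sample_id = "a", target = "ZEP", ct_target = 24,
                       ct_ref1 = NA_real_, ct_ref2 = 22)
  expect_error(relative_expression(ct), class = "npqkit_invalid_measurement")
  ct2 <- tibble::tibble(sample_id = "a", target = "ZEP", ct_target = 24,
                        ct_ref1 = 20, ct_ref2 = 22)
  expect_error(relative_expression(ct2, calibrator = "nope"),
               class = "npqkit_missing_reference")
})

test_that("metabolite amounts scale with extract volume over weight", {
  cal <- fit_calibration(
    data.frame(concentration = c(0, 10, 20), response = c(0, 100, 200)),
    analyte = "ascorbate"
  )
  d <- tibble::tibble(sample_id = "s", analyte = "ascorbate",
                      peak_area = 100, sample_weight_mg = 25)
  out <- normalize_metabolite(d, cal)
  # 10 units/ml * 0.05 ml / 25 mg
  expect_equal(out$amount_per_mg, 0.02)
  d2 <- dplyr::mutate(d, sample_weight_mg = 50)
  expect_equal(normalize_metabolite(d2, cal)$amount_per_mg, 0.01)
  dz <- dplyr::mutate(d, peak_area = 0)
  outz <- normalize_metabolite(dz, cal)
  expect_equal(outz$amount_per_mg, 0)
  expect_true(outz$below_lod)
  expect_error(
    normalize_metabolite(dplyr::mutate(d, sample_weight_mg = 0), cal),
    class = "npqkit_normalization_error"
  )
})
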