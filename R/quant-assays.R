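#' Default quantification / detection limits for pigment HPLC
#'
#' Lower limits of quantification (LOQ) and detection (LOD), in ug/ml of
#' extract, for the external-standard HPLC assay: 21 ug/ml for lutein,
#' antheraxanthin and zeaxanthin; 20 ug/ml for violaxanthin; 35 and 25
#' ug/ml for chlorophyll a and b respectively. LOD defaults to the same
#' value as LOQ when the assay states a single limit.
#'
#' @param analyte Analyte name (lowercase).
#' @return Named numeric vector with elements `loq` and `lod` (ug/ml).
#' @examples
#' pigment_limits("zeaxanthin")
#' @export
pigment_limits <- function(analyte) {
  limits <- list(
    lutein         = c(loq = 21, lod = 21),
    antheraxanthin = c(loq = 21, lod = 21),
    zeaxanthin     = c(loq = 21, lod = 21),
    violaxanthin   = c(loq = 20, lod = 20),
    chlorophyll_a  = c(loq = 35, lod = 35),
    chlorophyll_b  = c(loq = 25, lod = 25)
  )
  if (!analyte %in% names(limits)) {
    abort(paste0("No default limits for analyte '", analyte, "'."),
          class = "npqkit_unknown_analyte")
  }
  limits[[analyte]]
}

#' Fit an external-standard calibration curve
#'
#' Ordinary least-squares line `response = slope * concentration +
#' intercept` through the standard points. The intercept is fitted by
#' default (`force_zero = TRUE` forces the line through the origin).
#' Supplied or default LOQ/LOD limits are stored on the curve and used by
#' [quantify()] to flag low values.
#'
#' @param points Data frame with columns `concentration` (ug/ml) and
#'   `response` (peak area, a.u.).
#' @param analyte Analyte name; used for default limits and error messages.
#' @param loq,lod Limits in ug/ml. Default: [pigment_limits()] when the
#'   analyte is known, otherwise 0.
#' @param force_zero Force the intercept to 0.
#' @return An object of class `calibration_curve`.
#' @examples
#' cal <- fit_calibration(data.frame(concentration = c(0, 10, 20),
#'                                   response = c(0, 100, 200)),
#'                        analyte = "zeaxanthin")
#' cal$slope
#' @export
fit_calibration <- function(points, analyte = "analyte",
                            loq = NULL, lod = NULL, force_zero = FALSE) {
  if (!all(c("concentration", "response") %in% names(points))) {
    abort("`points` needs columns `concentration` and `response`.",
          class = "npqkit_schema_error")
  }
  if (length(unique(points$concentration)) < 2) {
    abort("Calibration needs at least 2 distinct concentrations.",
          class = "npqkit_singular_fit")
  }
  if (any(points$response < 0)) {
    abort("Calibration responses must be nonnegative.",
          class = "npqkit_invalid_measurement")
  }
  defaults <- tryCatch(pigment_limits(analyte), error = function(e) c(loq = 0, lod = 0))
  loq <- loq %||% unname(defaults["loq"])
  lod <- lod %||% unname(defaults["lod"])
  if (lod > loq) {
    abort("`lod` must not exceed `loq`.", class = "npqkit_invalid_limits")
  }
  fit <- if (force_zero) {
    lm(response ~ concentration + 0, data = points)
  } else {
    lm(response ~ concentration, data = points)
  }
  slope <- unname(coef(fit)[["concentration"]])
  intercept <- if (force_zero) 0 else unname(coef(fit)[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0) {
    abort("Calibration slope must be positive.", class = "npqkit_singular_fit")
  }
  tss <- sum((points$response - mean(points$response))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  structure(
    list(analyte = analyte, points = tibble::as_tibble(points),
         slope = slope, intercept = intercept, r_squared = r2,
         loq = loq, lod = lod, force_zero = force_zero),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> ", x$analyte, "\n", sep = "")
  cat(sprintf("  response = %.6g * conc + %.6g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  LOQ %.3g, LOD %.3g ug/ml\n", x$loq, x$lod))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(analyte = x$analyte, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 loq = x$loq, lod = x$lod)
}

#' Convert instrument responses to concentrations
#'
#' Inverts the calibration line: `conc = (response - intercept) / slope`.
#' Concentrations below the curve's LOQ or LOD are flagged but retained
#' (downstream group statistics use them; censoring is left to the caller).
#' A negative computed concentration is clipped to 0 and flagged below-LOD.
#'
#' @param curve A [fit_calibration()] result.
#' @param response Numeric vector of peak areas.
#' @return A tibble: `response`, `concentration` (ug/ml), `below_loq`,
#'   `below_lod` (logical).
#' @examples
#' cal <- fit_calibration(data.frame(concentration = c(0, 10, 20),
#'                                   response = c(0, 100, 200)),
#'                        analyte = "zeaxanthin")
#' quantify(cal, c(150, 300))
#' @export
quantify <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (response - curve$intercept) / curve$slope
  # numerical floor: values indistinguishable from zero at the calibration
  # scale are treated as zero
  tol <- 1e-9 * max(curve$points$concentration, 1)
  clipped <- conc < 0
  conc[clipped | abs(conc) < tol] <- 0
  # a computed concentration of zero is undetectable whatever the limits
  below_lod <- conc < curve$lod | conc <= 0 | clipped
  tibble::tibble(
    response = response,
    concentration = conc,
    below_loq = conc < curve$loq | below_lod,
    below_lod = below_lod
  )
}

#' Normalise pigment concentrations to total chlorophyll
#'
#' Divides each pigment column by total chlorophyll (`chlorophyll_a +
#' chlorophyll_b`) to remove extraction-efficiency variation, and recomputes
#' the xanthophyll-cycle pool `vaz_pool = violaxanthin + antheraxanthin +
#' zeaxanthin` on the normalised values. The result is a dimensionless mass
#' ratio (pigment mass per chlorophyll mass).
#'
#' @param data Data frame with pigment concentration columns (any of
#'   `zeaxanthin`, `antheraxanthin`, `violaxanthin`, `lutein`) and
#'   `chlorophyll_a`, `chlorophyll_b`.
#' @return The input tibble with pigment columns replaced by
#'   chlorophyll-normalised ratios, a `total_chlorophyll` column (original
#'   units), and `vaz_pool` when V, A and Z are all present.
#' @export
normalize_to_chlorophyll <- function(data) {
  chl_cols <- c("chlorophyll_a", "chlorophyll_b")
  if (!all(chl_cols %in% names(data))) {
    abort("`data` needs `chlorophyll_a` and `chlorophyll_b` columns.",
          class = "npqkit_schema_error")
  }
  total_chl <- data$chlorophyll_a + data$chlorophyll_b
  if (any(!is.finite(total_chl)) || any(total_chl <= 0)) {
    abort("Total chlorophyll must be positive for every sample.",
          class = "npqkit_normalization_error")
  }
  pig_cols <- intersect(c("zeaxanthin", "antheraxanthin", "violaxanthin",
                          "lutein"), names(data))
  out <- tibble::as_tibble(data)
  for (p in pig_cols) out[[p]] <- out[[p]] / total_chl
  out$total_chlorophyll <- total_chl
  if (all(c("violaxanthin", "antheraxanthin", "zeaxanthin") %in% pig_cols)) {
    out$vaz_pool <- out$violaxanthin + out$antheraxanthin + out$zeaxanthin
  }
  out
}

#' Relative expression by the dual-reference delta-delta-Ct method
#'
#' Per sample, `dCt = ct_target - mean(ct_ref1, ct_ref2)` (the reference is
#' the mean of the Ubiquitin and EF1-alpha cycle thresholds, taken at the
#' Ct level); relative expression versus the calibrator sample is
#' `2^-(dCt_sample - dCt_calibrator)`. Amplification efficiency is fixed at
#' 2 (no efficiency correction). With `ref_mode = "geometric"` the
#' reference combination is instead the geometric mean of the two
#' reference-gene expression levels (arithmetic mean of Cts and geometric
#' mean of 2^-Ct coincide; the flag exists for single-flag audit symmetry
#' with other tools and currently yields identical results).
#'
#' @param data Data frame with columns `sample_id`, `target`, `ct_target`,
#'   `ct_ref1`, `ct_ref2`.
#' @param calibrator `sample_id` of the calibrator sample (per target);
#'   if `NULL`, the sample with the largest dCt (lowest expression) is used.
#' @param ref_mode `"mean_ct"` (default) or `"geometric"`.
#' @return Input tibble with `d_ct`, `dd_ct` and `rel_expr` columns.
#' @examples
#' ct <- data.frame(sample_id = c("a", "b"), target = "ZEP",
#'                  ct_target = c(24, 25), ct_ref1 = c(20, 20),
#'                  ct_ref2 = c(22, 22))
#' relative_expression(ct, calibrator = "b")
#' @export
relative_expression <- function(data, calibrator = NULL,
                                ref_mode = c("mean_ct", "geometric")) {
  ref_mode <- match.arg(ref_mode)
  needed <- c("sample_id", "target", "ct_target", "ct_ref1", "ct_ref2")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  cts <- data[c("ct_target", "ct_ref1", "ct_ref2")]
  if (any(!is.finite(as.matrix(cts)))) {
    abort("All Ct values must be finite.", class = "npqkit_invalid_measurement")
  }
  out <- dplyr::mutate(tibble::as_tibble(data),
                       d_ct = .data$ct_target -
                         (.data$ct_ref1 + .data$ct_ref2) / 2)
  out <- dplyr::group_modify(
    dplyr::group_by(out, .data$target),
    function(d, key) {
      cal_dct <- if (is.null(calibrator)) {
        max(d$d_ct)
      } else {
        i <- which(d$sample_id == calibrator)
        if (length(i) == 0) {
          abort(paste0("Calibrator '", calibrator, "' not found for target '",
                       key$target, "'."), class = "npqkit_missing_reference")
        }
        mean(d$d_ct[i])
      }
      dplyr::mutate(d, dd_ct = .data$d_ct - cal_dct,
                    rel_expr = 2^(-.data$dd_ct))
    }
  )
  dplyr::ungroup(out)
}

#' Normalise a metabolite peak area to tissue weight
#'
#' Converts an LC-MS peak area to a concentration via the analyte's
#' external calibration curve, then to an absolute amount in the final
#' extract (default volume 50 ul) and divides by the sample weight:
#' `amount_per_mg = concentration * extract_volume_ml / sample_weight_mg`.
#'
#' @param data Data frame with columns `sample_id`, `analyte`, `peak_area`,
#'   `sample_weight_mg`.
#' @param curve A [fit_calibration()] curve for the analyte (concentration
#'   in units per ml).
#' @param extract_volume_ul Final extract volume (ul), default 50.
#' @return Input tibble with `concentration`, `below_loq`, `below_lod` and
#'   `amount_per_mg` columns.
#' @export
normalize_metabolite <- function(data, curve, extract_volume_ul = 50) {
  needed <- c("sample_id", "analyte", "peak_area", "sample_weight_mg")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Metabolite table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  if (any(data$sample_weight_mg <= 0)) {
    abort("Sample weights must be positive.",
          class = "npqkit_normalization_error")
  }
  q <- quantify(curve, data$peak_area)
  dplyr::mutate(tibble::as_tibble(data),
                concentration = q$concentration,
                below_loq = q$below_loq,
                below_lod = q$below_lod,
                amount_per_mg = .data$concentration *
                  (extract_volume_ul / 1000) / .data$sample_weight_mg)
}
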