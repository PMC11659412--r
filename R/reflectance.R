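#' Bin sub-nanometre reflectance samples to integer wavelengths
#'
#' Spectrometer output at sub-nm resolution is reduced to one value per
#' integer nanometre: each sample's wavelength is converted to an integer
#' and samples sharing an integer are averaged. "Converted to integers" is
#' read as truncation toward zero by default (530.9 nm contributes to the
#' 530-nm bin); rounding to nearest is available since the convention is
#' not fixed by the instrument protocol — for smooth leaf spectra the
#' difference is below measurement noise.
#'
#' @param data A data frame with columns `wavelength_nm` and `reflectance`
#'   (additional columns are ignored).
#' @param method `"truncate"` (default) or `"round"`.
#' @return A tibble with one row per integer `wavelength_nm` and the mean
#'   `reflectance`, plus an `n_samples` count.
#' @examples
#' bin_spectrum(data.frame(wavelength_nm = c(531.2, 531.7),
#'                         reflectance = c(0.10, 0.20)))
#' @export
bin_spectrum <- function(data, method = c("truncate", "round")) {
  method <- match.arg(method)
  if (!all(c("wavelength_nm", "reflectance") %in% names(data))) {
    abort("`data` needs columns `wavelength_nm` and `reflectance`.",
          class = "npqkit_schema_error")
  }
  if (nrow(data) == 0) {
    abort("Empty spectrum.", class = "npqkit_schema_error")
  }
  if (any(!is.finite(data$reflectance)) || any(!is.finite(data$wavelength_nm))) {
    abort("Reflectance and wavelength values must be finite.",
          class = "npqkit_invalid_measurement")
  }
  wl <- if (method == "truncate") trunc(data$wavelength_nm) else
    round(data$wavelength_nm)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(wavelength_nm = as.integer(wl),
                                   reflectance = data$reflectance),
                    .data$wavelength_nm),
    n_samples = dplyr::n(),
    reflectance = mean(.data$reflectance),
    .groups = "drop"
  )
  dplyr::arrange(out[, c("wavelength_nm", "reflectance", "n_samples")],
                 .data$wavelength_nm)
}

band <- function(spectrum, nm) {
  i <- match(nm, spectrum$wavelength_nm)
  if (is.na(i)) {
    abort(paste0("Band ", nm, " nm is missing from the spectrum."),
          class = "npqkit_missing_band")
  }
  r <- spectrum$reflectance[i]
  if (!is.finite(r) || r <= 0) {
    abort(paste0("Band ", nm, " nm must be positive to compute indices."),
          class = "npqkit_invalid_measurement")
  }
  r
}

#' Leaf reflectance indices
#'
#' Three indices computed from an integer-nm binned spectrum
#' (see [bin_spectrum()]):
#'
#' * `pri()` — photochemical reflectance index,
#'   `(R531 - R570) / (R531 + R570)`; decreases as xanthophylls
#'   de-epoxidise (zeaxanthin/antheraxanthin formation).
#' * `ari()` — anthocyanin reflectance index, computed as printed in the
#'   source protocol: `R800 / R550 - 1 / R700`. This mixes a ratio term
#'   with a reciprocal term; the common literature form
#'   `1 / R550 - 1 / R700` is available via `variant = "canonical"` (the
#'   printed form is the default; the intent of the mixed form is not
#'   second-guessed).
#' * `cri()` — carotenoid reflectance index, `1 / R510 - 1 / R550`.
#'
#' @param spectrum Output of [bin_spectrum()].
#' @return A single numeric value.
#' @examples
#' s <- bin_spectrum(data.frame(wavelength_nm = c(510, 531, 550, 570, 700, 800),
#'                              reflectance = c(0.10, 0.10, 0.20, 0.12, 0.20, 0.50)))
#' pri(s)
#' cri(s)
#' @export
pri <- function(spectrum) {
  r531 <- band(spectrum, 531L)
  r570 <- band(spectrum, 570L)
  (r531 - r570) / (r531 + r570)
}

#' @rdname pri
#' @param variant `"printed"` (default) or `"canonical"`, see Details.
#' @export
ari <- function(spectrum, variant = c("printed", "canonical")) {
  variant <- match.arg(variant)
  r550 <- band(spectrum, 550L)
  r700 <- band(spectrum, 700L)
  if (variant == "printed") {
    band(spectrum, 800L) / r550 - 1 / r700
  } else {
    1 / r550 - 1 / r700
  }
}

#' @rdname pri
#' @export
cri <- function(spectrum) {
  1 / band(spectrum, 510L) - 1 / band(spectrum, 550L)
}

#' Compute reflectance indices for a table of spectra
#'
#' Bins each sample's sub-nm spectrum and computes PRI, ARI and CRI per
#' measurement (indices of per-sample spectra, then summarised across
#' replicates downstream — not indices of an averaged spectrum).
#'
#' @param data Long table with columns `sample_id`, `wavelength_nm`,
#'   `reflectance`, and optionally `ambient_ppfd` and metadata columns
#'   (constant within sample), e.g. from [read_spectrum_csv()] or
#'   [simulate_spectrum()].
#' @inheritParams bin_spectrum
#' @param ari_variant Passed to [ari()].
#' @return A tibble: one row per `sample_id` with `pri`, `ari`, `cri` and
#'   any per-sample metadata.
#' @export
spectral_indices <- function(data, method = "truncate",
                             ari_variant = "printed") {
  if (!"sample_id" %in% names(data)) {
    abort("`data` needs a `sample_id` column.", class = "npqkit_schema_error")
  }
  meta_cols <- setdiff(names(data),
                       c("sample_id", "wavelength_nm", "reflectance"))
  out <- dplyr::group_modify(
    dplyr::group_by(data, .data$sample_id),
    function(d, key) {
      s <- bin_spectrum(d, method = method)
      meta <- dplyr::distinct(d, dplyr::across(dplyr::all_of(meta_cols)))
      dplyr::bind_cols(
        meta[1, , drop = FALSE],
        tibble::tibble(pri = pri(s), ari = ari(s, ari_variant), cri = cri(s))
      )
    }
  )
  dplyr::ungroup(out)
}

#' Read a long-format spectrum CSV
#'
#' Expects columns `sample_id`, `wavelength_nm`, `reflectance`; further
#' columns (e.g. `ambient_ppfd`, accession/treatment metadata) are kept.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_spectrum_csv <- function(path) {
  out <- read_csv_exact(path)
  needed <- c("sample_id", "wavelength_nm", "reflectance")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("Spectrum csv is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  out
}
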