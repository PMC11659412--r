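#' Maximum quantum yield of photosystem II (Fv/Fm)
#'
#' Computes `(f_m - f_o) / f_m` from dark-adapted minimal (`f_o`) and maximal
#' (`f_m`) fluorescence. Vectorised; inputs are recycled by the usual rules.
#'
#' @param f_o,f_m Dark-adapted minimal and maximal fluorescence (a.u.).
#'   Must satisfy `f_m > f_o > 0`.
#' @return Numeric vector of yields in (0, 1).
#' @examples
#' compute_fvfm(200, 1000) # 0.8
#' @export
compute_fvfm <- function(f_o, f_m) {
  if (any(!is.finite(f_o)) || any(!is.finite(f_m))) {
    abort("`f_o` and `f_m` must be finite.", class = "npqkit_invalid_measurement")
  }
  if (any(f_o <= 0) || any(f_m <= f_o)) {
    abort("Dark yields must satisfy f_m > f_o > 0.",
          class = "npqkit_invalid_measurement")
  }
  (f_m - f_o) / f_m
}

validate_trace <- function(data, protocol = NULL,
                           require_dark = TRUE,
                           call = rlang::caller_env()) {
  needed <- c("disc_id", "time_min", "f_m_prime")
  if (require_dark) needed <- c(needed, "f_o", "f_m")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Trace table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error", call = call)
  }
  if (any(!is.finite(data$f_m_prime)) || any(data$f_m_prime <= 0)) {
    abort("All `f_m_prime` values must be finite and positive.",
          class = "npqkit_invalid_measurement", call = call)
  }
  if (require_dark) {
    if (any(!is.finite(data$f_o)) || any(!is.finite(data$f_m)) ||
        any(data$f_o <= 0) || any(data$f_m <= data$f_o)) {
      abort("Dark yields must satisfy f_m > f_o > 0 for every row.",
            class = "npqkit_invalid_measurement", call = call)
    }
  }
  if (!is.null(protocol)) {
    off <- setdiff(unique(data$time_min), protocol$flash_times_min)
    if (length(off) > 0) {
      abort(paste0("Flash times not in protocol '", protocol$label, "': ",
                   paste(signif(off, 6), collapse = ", ")),
            class = "npqkit_schema_error", call = call)
    }
  }
  invisible(data)
}

#' Stern-Volmer non-photochemical quenching from a flash table
#'
#' Computes `npq = f_m / f_m_prime - 1` for every saturating flash of every
#' leaf disc, under the Stern-Volmer quenching model, and labels each flash
#' as light- or dark-phase from the protocol's light window.
#'
#' The input is a tidy flash table: one row per disc per flash with columns
#' `disc_id`, `time_min`, `f_m_prime`, and the per-disc dark pair `f_o`,
#' `f_m` repeated on each row (as produced by [read_pam_csv()] or
#' [simulate_trace()]). Steady-state fluorescence `f_s`, if present, is
#' carried through untouched; no computed quantity uses it.
#'
#' Flashes with `f_m_prime > f_m` give negative NPQ; these are retained
#' (clipping would bias downstream slope estimates) but a warning reports
#' how many occurred.
#'
#' @param data Flash table (data frame), see Details.
#' @param protocol A [flash_protocol()]; defaults to the CF Imager preset.
#' @return The input tibble with `npq`, `phase` and `fvfm` columns added.
#' @examples
#' tr <- simulate_trace(sustained_quenching = 0, noise_cv = 0, seed = 1)
#' compute_npq(tr)
#' @export
compute_npq <- function(data, protocol = protocol_preset("cf_imager")) {
  validate_trace(data, protocol)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    npq = .data$f_m / .data$f_m_prime - 1,
    phase = flash_phase(.data$time_min, protocol),
    fvfm = compute_fvfm(.data$f_o, .data$f_m)
  )
  n_neg <- sum(out$npq < 0)
  if (n_neg > 0) {
    warn(paste0(n_neg, " flash(es) have f_m_prime > f_m (negative NPQ); ",
                "values retained."),
         class = "npqkit_negative_npq")
  }
  out
}

#' Read and write long-format PAM flash tables
#'
#' The on-disk long format has one row per flash (`time_min`, `f_s`,
#' `f_m_prime` set; `f_o`, `f_m` empty) plus one dark row per disc
#' (`time_min` empty; `f_o`, `f_m` set), with metadata columns `accession`,
#' `treatment`, `replicate`. [read_pam_csv()] spreads the dark pair onto the
#' disc's flash rows and returns the tidy flash table that [compute_npq()]
#' consumes; [write_pam_csv()] is its inverse, and the round trip reproduces
#' all values bit-exactly.
#'
#' @param path File path.
#' @return `read_pam_csv()`: a tibble with one row per flash.
#' @export
read_pam_csv <- function(path) {
  raw <- read_csv_exact(path)
  needed <- c("disc_id", "time_min", "f_s", "f_m_prime", "f_o", "f_m")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("PAM csv is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  dark <- dplyr::filter(raw, is.na(.data$time_min))
  if (any(duplicated(dark$disc_id))) {
    abort("More than one dark row for a disc.", class = "npqkit_schema_error")
  }
  flashes <- dplyr::filter(raw, !is.na(.data$time_min))
  bad <- setdiff(unique(flashes$disc_id), dark$disc_id)
  if (length(bad) > 0) {
    abort(paste0("Disc(s) without a dark row: ", paste(bad, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  flashes <- dplyr::select(flashes, -"f_o", -"f_m")
  dark <- dplyr::select(dark, "disc_id", "f_o", "f_m")
  out <- dplyr::left_join(flashes, dark, by = "disc_id")
  dplyr::arrange(out, .data$disc_id, .data$time_min)
}

#' @rdname read_pam_csv
#' @param data Tidy flash table as returned by [read_pam_csv()] (columns
#'   `disc_id`, `time_min`, `f_s`, `f_m_prime`, `f_o`, `f_m`, plus metadata).
#' @export
write_pam_csv <- function(data, path) {
  validate_trace(data)
  meta_cols <- intersect(c("accession", "treatment", "infiltration",
                           "replicate", "well"), names(data))
  per_disc <- dplyr::distinct(
    data, dplyr::across(dplyr::all_of(c("disc_id", meta_cols, "f_o", "f_m")))
  )
  dark_rows <- dplyr::mutate(per_disc,
                             time_min = NA_real_, f_s = NA_real_,
                             f_m_prime = NA_real_)
  flash_rows <- dplyr::mutate(data, f_o = NA_real_, f_m = NA_real_)
  cols <- c("disc_id", meta_cols, "time_min", "f_s", "f_m_prime", "f_o", "f_m")
  long <- dplyr::bind_rows(
    dplyr::select(dark_rows, dplyr::all_of(cols)),
    dplyr::select(flash_rows, dplyr::all_of(cols))
  )
  long <- dplyr::arrange(long, .data$disc_id, !is.na(.data$time_min),
                         .data$time_min)
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a 96-well plate-layout table
#'
#' Maps wells (A1-H12) to disc metadata. Expected columns: `well` plus any
#' metadata (typically `accession`, `treatment`, `replicate`).
#'
#' @param path File path.
#' @return A tibble keyed by `well`.
#' @export
read_plate_layout <- function(path) {
  layout <- read_csv_exact(path)
  if (!"well" %in% names(layout)) {
    abort("Plate layout must have a `well` column.",
          class = "npqkit_schema_error")
  }
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", layout$well)
  if (!all(ok)) {
    abort(paste0("Malformed well id(s): ",
                 paste(unique(layout$well[!ok]), collapse = ", ")),
          class = "npqkit_schema_error")
  }
  if (any(duplicated(layout$well))) {
    abort("Duplicated well ids in plate layout.", class = "npqkit_schema_error")
  }
  tibble::as_tibble(layout)
}
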