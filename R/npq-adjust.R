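#' Adjusted NPQ at the dark point
#'
#' Chilling can induce quenching that persists through the dark period, so
#' the dark-adapted maximal fluorescence `F_m` of a chilled disc
#' underestimates the true unquenched maximum. Using warm-treated discs of
#' the same material as an unquenched reference, the true maximum is
#' reconstructed as `F_m_true = F_o_cold / (1 - Fv_warm/Fm_warm)` and the
#' quenching already present in darkness is
#' `NPQ_A(dark) = F_m_true / F_m_cold - 1`, equivalently
#' `(1 - Fv_cold/Fm_cold) / (1 - Fv_warm/Fm_warm) - 1`.
#'
#' The published transcription of this formula contains an unbalanced
#' parenthesis; read literally it evaluates to
#' `r_warm / (r_cold * (1 - r_warm)) - 1` (with `r` = Fv/Fm), which is
#' nonzero even when the warm and cold yields agree, contradicting its own
#' rationale. The form above is the one forced by the stated purpose
#' ("true value of unquenched fluorescence") and by the identity
#' `F_m_true = F_m_cold * (NPQ_A(dark) + 1)`. The literal transcription
#' is available for audit via `literal = TRUE` and warns when used.
#'
#' @param f_o_cold,f_m_cold Dark yields of the cold-treated disc (a.u.).
#' @param fvfm_warm Warm-reference Fv/Fm, in (0, 1).
#' @param literal If `TRUE`, evaluate the garbled published transcription
#'   instead (audit only; emits a warning).
#' @return Dimensionless sustained-quenching value (vectorised). Zero when
#'   the warm and cold yields are equal; positive when the cold yield is
#'   depressed relative to the warm reference.
#' @examples
#' npq_a_dark_point(f_o_cold = 200, f_m_cold = 800, fvfm_warm = 0.8) # 0.25
#' @export
npq_a_dark_point <- function(f_o_cold, f_m_cold, fvfm_warm, literal = FALSE) {
  compute_fvfm(f_o_cold, f_m_cold) # validates the dark pair
  if (any(!is.finite(fvfm_warm)) || any(fvfm_warm <= 0) || any(fvfm_warm > 1)) {
    abort("`fvfm_warm` must lie in (0, 1].", class = "npqkit_invalid_reference")
  }
  if (any(fvfm_warm == 1)) {
    abort("Warm reference Fv/Fm of exactly 1 makes the unquenched maximum infinite.",
          class = "npqkit_invalid_reference")
  }
  fvfm_cold <- compute_fvfm(f_o_cold, f_m_cold)
  if (isTRUE(literal)) {
    warn("Using the literal (typographically garbled) published transcription.",
         class = "npqkit_literal_formula")
    return(fvfm_warm / (fvfm_cold * (1 - fvfm_warm)) - 1)
  }
  (1 - fvfm_cold) / (1 - fvfm_warm) - 1
}

#' True unquenched maximal fluorescence
#'
#' `F_m_true = F_m_cold * (NPQ_A(dark) + 1)`. Composed with
#' [npq_a_dark_point()] this returns `F_o_cold / (1 - Fv_warm/Fm_warm)`
#' exactly.
#'
#' @param f_m_cold Dark-adapted maximal fluorescence of the cold disc (a.u.).
#' @param npq_a_dark Sustained quenching at the dark point (>= -1).
#' @return Fluorescence (a.u.), vectorised.
#' @examples
#' f_m_true(800, 0.25) # 1000
#' @export
f_m_true <- function(f_m_cold, npq_a_dark) {
  if (any(npq_a_dark < -1)) {
    abort("`npq_a_dark` must be >= -1.", class = "npqkit_invalid_measurement")
  }
  f_m_cold * (npq_a_dark + 1)
}

#' Pool a warm reference Fv/Fm from warm-treated discs
#'
#' Computes the mean Fv/Fm of warm-treated discs, by default pooled within
#' accession (the grouping can be changed or dropped). The result joins onto
#' cold discs in [compute_npq_a()].
#'
#' @param data Flash table or any per-disc table with `disc_id`, `f_o`,
#'   `f_m`, a `treatment` column, and the grouping column(s).
#' @param warm_label Treatment label identifying warm-treated discs.
#' @param by Character vector of grouping columns (default `"accession"`);
#'   use `character()` to pool across everything.
#' @return A tibble with the grouping columns, `fvfm_warm`, `n_discs`, and a
#'   `source` description.
#' @export
warm_reference <- function(data, warm_label = "warm", by = "accession") {
  if (!"treatment" %in% names(data)) {
    abort("`data` needs a `treatment` column to locate warm-treated discs.",
          class = "npqkit_schema_error")
  }
  warm <- dplyr::filter(data, .data$treatment == warm_label)
  if (nrow(warm) == 0) {
    abort(paste0("No discs with treatment '", warm_label,
                 "' to serve as warm reference."),
          class = "npqkit_missing_reference")
  }
  per_disc <- dplyr::distinct(
    warm, dplyr::across(dplyr::all_of(c("disc_id", by, "f_o", "f_m")))
  )
  per_disc <- dplyr::mutate(per_disc, fvfm = compute_fvfm(.data$f_o, .data$f_m))
  out <- dplyr::summarise(
    dplyr::group_by(per_disc, dplyr::across(dplyr::all_of(by))),
    fvfm_warm = mean(.data$fvfm),
    n_discs = dplyr::n_distinct(.data$disc_id),
    .groups = "drop"
  )
  dplyr::mutate(out, source = paste0(
    "mean Fv/Fm of ", .data$n_discs, " '", warm_label, "' disc(s)",
    if (length(by) > 0) paste0(" per ", paste(by, collapse = "/")) else ""
  ))
}

#' Adjusted NPQ (NPQ_A) curves
#'
#' Augments the Stern-Volmer NPQ table with the warm-reference-adjusted
#' quenching: the per-disc dark point `npq_a_dark` (see
#' [npq_a_dark_point()]), the reconstructed maximum `f_m_true`, and
#' `npq_a = f_m_true / f_m_prime - 1` at every flash. When the warm
#' reference equals the disc's own Fv/Fm the adjusted and unadjusted curves
#' coincide exactly; in general the algebraic identity
#' `npq_a + 1 = (npq + 1) * (npq_a_dark + 1)` holds at every flash.
#'
#' @param data Flash table (see [compute_npq()]).
#' @param warm_ref Either a single numeric Fv/Fm in (0, 1), or a tibble from
#'   [warm_reference()] that is joined onto `data` by its grouping columns.
#' @param protocol A [flash_protocol()].
#' @param literal Passed to [npq_a_dark_point()] (audit only).
#' @return Tibble with `npq`, `phase`, `fvfm`, `warm_ref_fvfm`,
#'   `npq_a_dark`, `f_m_true`, and `npq_a` columns.
#' @examples
#' tr <- simulate_trace(sustained_quenching = 0.3, noise_cv = 0, seed = 1)
#' compute_npq_a(tr, warm_ref = 0.8)
#' @export
compute_npq_a <- function(data, warm_ref,
                          protocol = protocol_preset("cf_imager"),
                          literal = FALSE) {
  out <- compute_npq(data, protocol)
  if (is.numeric(warm_ref) && length(warm_ref) == 1) {
    out$warm_ref_fvfm <- warm_ref
  } else if (is.data.frame(warm_ref)) {
    by <- setdiff(names(warm_ref), c("fvfm_warm", "n_discs", "source"))
    missing_by <- setdiff(by, names(out))
    if (length(missing_by) > 0) {
      abort(paste0("Warm-reference grouping column(s) absent from data: ",
                   paste(missing_by, collapse = ", ")),
            class = "npqkit_schema_error")
    }
    ref <- dplyr::select(warm_ref, dplyr::all_of(c(by, "fvfm_warm")))
    out <- dplyr::left_join(out, ref, by = by)
    if (anyNA(out$fvfm_warm)) {
      abort("Some discs have no matching warm reference.",
            class = "npqkit_missing_reference")
    }
    out <- dplyr::rename(out, warm_ref_fvfm = "fvfm_warm")
  } else {
    abort("`warm_ref` must be a single Fv/Fm value or a warm_reference() table.")
  }
  out <- dplyr::mutate(
    out,
    npq_a_dark = npq_a_dark_point(.data$f_o, .data$f_m, .data$warm_ref_fvfm,
                                  literal = literal),
    f_m_true = f_m_true(.data$f_m, .data$npq_a_dark),
    npq_a = .data$f_m_true / .data$f_m_prime - 1
  )
  out
}
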