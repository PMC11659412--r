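#' Fit a rectangular hyperbola to an NPQ induction curve
#'
#' Induction of quenching under actinic light is summarised by the
#' two-parameter rectangular hyperbola `NPQ(t) = A * t / (t + K)`:
#' `A` is the asymptotic quenching (amplitude), `K` the half-saturation time
#' in minutes, and the initial slope `A / K` (the derivative at `t = 0`) is
#' the NPQ induction rate. By default only light-phase flashes are fitted,
#' with times re-zeroed to light onset.
#'
#' For adjusted-NPQ curves the sustained-quenching dark point shifts the
#' whole curve upward; pass that value as `offset` (it is subtracted before
#' fitting) so the hyperbola describes the light-induced rise through the
#' origin.
#'
#' Least squares uses Levenberg-Marquardt ([minpack.lm::nlsLM]) with
#' amplitude bounded in `[0, 3 * max(y)]` and half-time in `[0.01, 100]`
#' min, started from `A0 = max(y)` and `K0` = time to half-maximum by
#' linear interpolation; a bounded Nelder-Mead refinement guards against
#' optimiser failure. A curve with no positive signal is flagged degenerate
#' with amplitude 0.
#'
#' @param data A tibble with at least `time_min` and the response column
#'   (an output of [compute_npq()] or [compute_npq_a()] for a single disc).
#' @param value Column to fit: `"npq"` or `"npq_a"` (any numeric column
#'   name is accepted).
#' @param window Which flashes to fit: `"light"` (default), `"dark"`, or
#'   `"all"`. Ignored if `data` has no `phase` column.
#' @param protocol A [flash_protocol()], used to re-zero times to light
#'   onset.
#' @param offset Constant subtracted from the response before fitting
#'   (e.g. `npq_a_dark` for adjusted curves). Default 0.
#' @return An object of class `hyperbolic_fit` with elements `amplitude`,
#'   `half_time`, `initial_slope`, `rss`, `n_points`, `converged`,
#'   `degenerate`, `curve_type`, `offset`, and the fitted `data`.
#' @examples
#' tr <- simulate_trace(amplitude = 2, half_time = 1, noise_cv = 0, seed = 1)
#' fit <- fit_hyperbolic(compute_npq(tr))
#' fit$initial_slope # 2
#' @export
fit_hyperbolic <- function(data, value = "npq", window = c("light", "dark", "all"),
                           protocol = protocol_preset("cf_imager"),
                           offset = 0) {
  window <- match.arg(window)
  if (!value %in% names(data)) {
    abort(paste0("Column `", value, "` not found in `data`."),
          class = "npqkit_schema_error")
  }
  if (window != "all" && "phase" %in% names(data)) {
    data <- dplyr::filter(data, .data$phase == window)
  }
  t <- data$time_min - protocol$light_on_min
  y <- data[[value]] - offset
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(y) < 4) {
    abort("At least 4 points are required to fit the hyperbola.",
          class = "npqkit_insufficient_data")
  }

  new_fit <- function(A, K, rss, converged, degenerate = FALSE) {
    structure(
      list(amplitude = A, half_time = K, initial_slope = A / K,
           rss = rss, n_points = length(y), converged = converged,
           degenerate = degenerate, curve_type = value, offset = offset,
           data = tibble::tibble(time_min = t, value = y)),
      class = "hyperbolic_fit"
    )
  }

  if (max(y) <= 0) {
    # no positive signal: amplitude 0, K undefined -> report 1 with flag
    return(new_fit(0, 1, sum(y^2), converged = TRUE, degenerate = TRUE))
  }

  rss_fun <- function(p) sum((y - p[1] * t / (t + p[2]))^2)
  a_max <- 3 * max(y)
  A0 <- max(y)
  # time to half-maximum by linear interpolation along the observed curve
  K0 <- suppressWarnings(approx(y, t, xout = A0 / 2, ties = "ordered")$y)
  if (!is.finite(K0) || K0 <= 0) K0 <- max(stats::median(t), 0.01)
  K0 <- min(max(K0, 0.01), 100)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * t / (t + K),
      start = list(A = A0, K = K0),
      lower = c(0, 0.01), upper = c(a_max, 100),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- coef(fit)
    res <- list(par = c(p[["A"]], p[["K"]]), value = rss_fun(c(p[["A"]], p[["K"]])))
  } else {
    res <- list(par = c(A0, K0), value = Inf)
  }
  # bounded quasi-Newton polish (also the fallback when nlsLM errors out)
  polish <- tryCatch(
    optim(res$par, rss_fun, method = "L-BFGS-B",
          lower = c(0, 0.01), upper = c(a_max, 100),
          control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value < res$value) res <- polish
  if (!is.finite(res$value)) {
    return(new_fit(A0, K0, rss_fun(c(A0, K0)), converged = FALSE))
  }
  new_fit(res$par[1], res$par[2], res$value, converged = TRUE)
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat("<hyperbolic_fit> ", x$curve_type,
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  cat(sprintf("  amplitude %.4g, half-time %.4g min, initial slope %.4g min^-1\n",
              x$amplitude, x$half_time, x$initial_slope))
  cat(sprintf("  rss %.4g on %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hyperbolic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "half_time", "initial_slope"),
    estimate = c(x$amplitude, x$half_time, x$initial_slope)
  )
}

#' @exportS3Method generics::glance
glance.hyperbolic_fit <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude, half_time = x$half_time,
    initial_slope = x$initial_slope, rss = x$rss, n_points = x$n_points,
    converged = x$converged, degenerate = x$degenerate,
    curve_type = x$curve_type
  )
}

#' NPQ induction rate from a fitted hyperbola
#'
#' The induction rate is the slope of the fitted curve at light onset,
#' `A / K` per minute. A degenerate (zero-signal) fit returns 0 with a
#' warning.
#'
#' @param fit A `hyperbolic_fit`.
#' @return Rate in min^-1.
#' @export
induction_rate <- function(fit) {
  stopifnot(inherits(fit, "hyperbolic_fit"))
  if (fit$degenerate) {
    warn("Degenerate fit: induction rate reported as 0.",
         class = "npqkit_degenerate_fit")
    return(0)
  }
  if (!fit$converged) {
    abort("Fit did not converge; no induction rate available.",
          class = "npqkit_fit_failure")
  }
  fit$initial_slope
}

#' Fit induction kinetics for every disc in a table
#'
#' Groups an NPQ (or NPQ_A) table by disc and fits [fit_hyperbolic()] to
#' each, returning one row per disc. For `value = "npq_a"` the per-disc
#' `npq_a_dark` column, when present, is used as the fitting offset.
#'
#' @inheritParams fit_hyperbolic
#' @param data Output of [compute_npq()] or [compute_npq_a()] (any number
#'   of discs; metadata columns are carried through).
#' @return A tibble: `disc_id`, metadata, `curve_type`, `amplitude`,
#'   `half_time`, `initial_slope`, `rss`, `n_points`, `converged`,
#'   `degenerate`.
#' @examples
#' exp <- simulate_plate_experiment(seed = 1)
#' npq <- compute_npq(exp$traces)
#' fit_npq_kinetics(npq)
#' @export
fit_npq_kinetics <- function(data, value = "npq",
                             window = "light",
                             protocol = protocol_preset("cf_imager")) {
  meta_cols <- intersect(c("accession", "treatment", "infiltration",
                           "replicate", "well"), names(data))
  fits <- dplyr::group_modify(
    dplyr::group_by(data, .data$disc_id),
    function(d, key) {
      off <- if (value == "npq_a" && "npq_a_dark" %in% names(d)) {
        d$npq_a_dark[1]
      } else 0
      fit <- fit_hyperbolic(d, value = value, window = window,
                            protocol = protocol, offset = off)
      meta <- dplyr::distinct(d, dplyr::across(dplyr::all_of(meta_cols)))
      dplyr::bind_cols(meta[1, , drop = FALSE], glance(fit))
    }
  )
  dplyr::ungroup(fits)
}

#' Induction rate relative to an infiltration control
#'
#' Expresses a treated disc group's NPQ induction rate as a percentage of
#' the corresponding control (e.g. DTT infiltration vs water):
#' `relative_pct = 100 * treated / control`. With `mode = "change"` the
#' percent change `100 * (treated - control) / control` is returned
#' instead.
#'
#' @param treated,control `hyperbolic_fit` objects or plain rates (min^-1).
#' @param mode `"ratio"` (retained fraction, default) or `"change"`.
#' @return A one-row tibble: `treated_rate`, `control_rate`, `relative_pct`.
#' @examples
#' relative_to_control(0.38, 0.50) # 76%
#' @export
relative_to_control <- function(treated, control, mode = c("ratio", "change")) {
  mode <- match.arg(mode)
  as_rate <- function(x, what) {
    if (inherits(x, "hyperbolic_fit")) {
      if (!x$converged) {
        abort(paste0("The ", what, " fit did not converge."),
              class = "npqkit_fit_failure")
      }
      x$initial_slope
    } else if (is.numeric(x) && length(x) == 1 && is.finite(x)) {
      x
    } else {
      abort(paste0("`", what, "` must be a hyperbolic_fit or a single rate."))
    }
  }
  tr <- as_rate(treated, "treated")
  cr <- as_rate(control, "control")
  if (cr == 0) {
    abort("Control rate is zero; relative rate undefined.",
          class = "npqkit_undefined_relative")
  }
  rel <- if (mode == "ratio") 100 * tr / cr else 100 * (tr - cr) / cr
  tibble::tibble(treated_rate = tr, control_rate = cr, relative_pct = rel)
}
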