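#' Flash protocols for PAM leaf-disc assays
#'
#' A flash protocol describes when saturating flashes are fired relative to
#' actinic light-on, the light window, and the actinic / flash intensities.
#' Two presets are built in, matching the schedules of the two imagers used
#' for leaf-disc NPQ kinetics: a CF Imager run (21 flashes, 3200 umol m-2 s-1
#' saturating flashes) and a FluorCam FC 800-C run (20 flashes, 6000
#' umol m-2 s-1). Both expose discs to 2000 umol m-2 s-1 actinic light for
#' 10 min followed by 10 min of darkness.
#'
#' @param label Character label for the protocol.
#' @param flash_times_min Strictly increasing numeric vector of flash times,
#'   in minutes relative to actinic light-on.
#' @param light_on_min,light_off_min Light window, minutes. Flashes with
#'   `light_on_min <= t < light_off_min` are labelled `"light"`; all others
#'   `"dark"` (half-open convention, so a flash at exactly light-off is a
#'   dark-phase flash).
#' @param actinic_ppfd,flash_ppfd Actinic and saturating-flash photon flux
#'   densities (umol m-2 s-1).
#'
#' @return An object of class `flash_protocol` (a named list).
#' @examples
#' p <- protocol_preset("cf_imager")
#' p$flash_times_min
#' @export
flash_protocol <- function(label, flash_times_min,
                           light_on_min = 0, light_off_min = 10,
                           actinic_ppfd = 2000, flash_ppfd = 3200) {
  flash_times_min <- as.numeric(flash_times_min)
  if (length(flash_times_min) == 0 || anyNA(flash_times_min)) {
    abort("`flash_times_min` must be a non-empty numeric vector without NA.")
  }
  if (any(diff(flash_times_min) <= 0)) {
    abort("`flash_times_min` must be strictly increasing.")
  }
  if (!(light_off_min > light_on_min)) {
    abort("`light_off_min` must be greater than `light_on_min`.")
  }
  structure(
    list(
      label = label,
      flash_times_min = flash_times_min,
      light_on_min = as.numeric(light_on_min),
      light_off_min = as.numeric(light_off_min),
      actinic_ppfd = as.numeric(actinic_ppfd),
      flash_ppfd = as.numeric(flash_ppfd)
    ),
    class = "flash_protocol"
  )
}

#' @rdname flash_protocol
#' @param name Preset name, `"cf_imager"` or `"fluorcam"`.
#' @export
protocol_preset <- function(name = c("cf_imager", "fluorcam")) {
  name <- match.arg(name)
  switch(name,
    cf_imager = flash_protocol(
      label = "cf_imager",
      flash_times_min = c(0, 0.33, 0.67, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                          10.33, 10.67, 11, 12, 13, 16, 19, 22),
      light_on_min = 0, light_off_min = 10,
      actinic_ppfd = 2000, flash_ppfd = 6000
    ),
    fluorcam = flash_protocol(
      label = "fluorcam",
      flash_times_min = c(0, 0.263, 0.413, 0.747, 1.08, 2.08, 3.08, 4.08,
                          5.08, 6.08, 7.08, 8.08, 9.08, 10.08, 10.263,
                          10.413, 10.913, 11.913, 15.08, 20.08),
      light_on_min = 0, light_off_min = 10,
      actinic_ppfd = 2000, flash_ppfd = 3200
    )
  )
}

#' @export
print.flash_protocol <- function(x, ...) {
  cat("<flash_protocol> ", x$label, "\n", sep = "")
  cat("  flashes: ", length(x$flash_times_min), " (",
      paste(head(x$flash_times_min, 5), collapse = ", "), ", ...)\n", sep = "")
  cat("  light window: [", x$light_on_min, ", ", x$light_off_min, ") min\n",
      sep = "")
  cat("  actinic ", x$actinic_ppfd, " / flash ", x$flash_ppfd,
      " umol m-2 s-1\n", sep = "")
  invisible(x)
}

#' Label flash times as light- or dark-phase
#'
#' Light phase is the half-open interval `[light_on, light_off)`.
#'
#' @param time_min Numeric vector of flash times (minutes).
#' @param protocol A [flash_protocol()].
#' @return Character vector, `"light"` or `"dark"`.
#' @export
flash_phase <- function(time_min, protocol) {
  stopifnot(inherits(protocol, "flash_protocol"))
  ifelse(time_min >= protocol$light_on_min & time_min < protocol$light_off_min,
         "light", "dark")
}
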