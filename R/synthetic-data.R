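#' Simulate one leaf disc's PAM fluorescence trace
#'
#' The observation model inverts the quenching equations. A disc carries
#' sustained quenching `q_s` out of the night, so its observed dark maximal
#' fluorescence is `f_m_unquenched / (1 + q_s)`; by default the dark
#' minimal fluorescence is unaffected by sustained quenching
#' (`f_o_quench_factor = 1`), the regime in which the warm-reference
#' reconstruction of the unquenched maximum is exact, and the factor is a
#' knob for probing the adjustment's sensitivity to that assumption. Under
#' actinic light total quenching rises along a rectangular hyperbola,
#' `q_s + A t / (t + K)`; after light-off the light-induced part decays
#' toward `q_s`, losing `relaxation_fraction` of its remaining amplitude
#' per minute. Every fluorescence reading gets multiplicative log-normal
#' noise with coefficient of variation `noise_cv` (fluorescence is positive
#' and detector noise roughly proportional). Steady-state `f_s` is emitted
#' as a fixed fraction of `f_m_prime`; no analysis uses it.
#'
#' @param sustained_quenching Dark-retained quenching `q_s` (>= 0).
#' @param amplitude,half_time Hyperbolic induction parameters `A`
#'   (dimensionless) and `K` (minutes).
#' @param f_o_unquenched,f_m_unquenched Unquenched dark yields (a.u.).
#' @param f_o_quench_factor Multiplier applied to `f_o` of quenched discs
#'   (default 1: `f_o` not quenched).
#' @param relaxation_fraction Fraction of light-induced quenching lost per
#'   minute of darkness, in [0, 1].
#' @param noise_cv Relative SD of the multiplicative measurement noise.
#' @param f_s_fraction `f_s` as a fraction of `f_m_prime`.
#' @param protocol A [flash_protocol()].
#' @param disc_id,accession,treatment,replicate Metadata labels.
#' @param seed Integer seed; the trace is a pure function of the arguments
#'   and the seed. `NULL` uses (and advances) the session RNG.
#' @return A flash table (tibble) as consumed by [compute_npq()], with the
#'   ground truth attached as attribute `"ground_truth"`.
#' @examples
#' tr <- simulate_trace(sustained_quenching = 0.3, noise_cv = 0, seed = 1)
#' attr(tr, "ground_truth")
#' @export
simulate_trace <- function(sustained_quenching = 0, amplitude = 2,
                           half_time = 1,
                           f_o_unquenched = 200, f_m_unquenched = 1000,
                           f_o_quench_factor = 1,
                           relaxation_fraction = 0.4, noise_cv = 0.01,
                           f_s_fraction = 0.3,
                           protocol = protocol_preset("cf_imager"),
                           disc_id = "disc_1", accession = NA_character_,
                           treatment = NA_character_,
                           replicate = NA_integer_, seed = NULL) {
  stopifnot(sustained_quenching >= 0, amplitude >= 0, half_time > 0,
            noise_cv >= 0, relaxation_fraction >= 0, relaxation_fraction <= 1)
  gen <- function() {
    q_s <- sustained_quenching
    t <- protocol$flash_times_min
    tl <- t - protocol$light_on_min
    dur <- protocol$light_off_min - protocol$light_on_min
    a_end <- amplitude * dur / (dur + half_time)
    light <- flash_phase(t, protocol) == "light"
    npq_total <- ifelse(
      light,
      q_s + amplitude * tl / (tl + half_time),
      ifelse(t < protocol$light_on_min, q_s,
             q_s + a_end *
               (1 - relaxation_fraction)^(t - protocol$light_off_min))
    )
    noise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    f_m_prime <- f_m_unquenched / (1 + npq_total) * noise(length(t))
    f_m <- f_m_unquenched / (1 + q_s) * noise(1)
    f_o <- f_o_unquenched * f_o_quench_factor * noise(1)
    tibble::tibble(
      disc_id = disc_id, accession = accession, treatment = treatment,
      replicate = replicate, time_min = t,
      f_s = f_s_fraction * f_m_prime, f_m_prime = f_m_prime,
      f_o = f_o, f_m = f_m
    )
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "ground_truth") <- tibble::tibble(
    disc_id = disc_id, q_s = sustained_quenching, amplitude = amplitude,
    half_time = half_time, initial_slope = amplitude / half_time,
    f_o_unquenched = f_o_unquenched, f_m_unquenched = f_m_unquenched,
    noise_cv = noise_cv
  )
  out
}

#' Experiment designs for the synthetic plate generator
#'
#' `experiment_design()` wraps a cell table (one row per accession x
#' treatment combination, with the true sustained quenching `q_s`,
#' induction `amplitude` and `half_time`, and `n_reps` discs) together with
#' the global observation parameters. `default_experiment_design()` encodes
#' a three-accession chilling experiment shaped like the published effect
#' structure: all accessions share warm-night kinetics (A = 2, K = 1, no
#' sustained quenching); after a chilling night the high-tolerance
#' accession MsaRB carries q_s = 0.30 and a 66% faster light-induced rise,
#' the moderate MxgI q_s = 0.15, and the low-tolerance control MsiCR
#' q_s = 0.02 with a slightly slowed rise — so that MsaRB's adjusted
#' induction rate is 133% above MsiCR's and the measured-NPQ rate of the
#' high/moderate pair averages ~44% above MsiCR.
#' `default_infiltration_design()` adds a DTT-vs-water infiltration factor
#' at the chilled condition, with the reductant retaining 76% / 48% / 23%
#' of the water-control induction rate in MsaRB / MxgI / MsiCR and
#' suppressing dark zeaxanthin accumulation (q_s near 0).
#'
#' @param cells Tibble with columns `accession`, `treatment` (plus optional
#'   extra factor columns such as `infiltration`), `q_s`, `amplitude`,
#'   `half_time`, `n_reps`.
#' @param n_reps Default replicate count per cell (used by the two preset
#'   designs; 8 discs, within the published 4-8 range).
#' @param noise_cv Measurement noise CV (default 0.01).
#' @param f_o_unquenched,f_m_unquenched Unquenched dark yields (a.u.); the
#'   defaults give a warm Fv/Fm of 0.8.
#' @param protocol A [flash_protocol()].
#' @param seed Integer seed (mandatory; the design is the unit of
#'   reproducibility).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(cells, noise_cv = 0.01,
                              f_o_unquenched = 200, f_m_unquenched = 1000,
                              protocol = protocol_preset("cf_imager"),
                              seed = 1L) {
  needed <- c("accession", "treatment", "q_s", "amplitude", "half_time",
              "n_reps")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("Design cells missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  if (nrow(cells) == 0 || any(cells$n_reps < 1)) {
    abort("Every design cell must have at least one replicate.",
          class = "npqkit_schema_error")
  }
  if (is.null(seed)) abort("A seed is mandatory for an experiment design.")
  structure(
    list(cells = tibble::as_tibble(cells), noise_cv = noise_cv,
         f_o_unquenched = f_o_unquenched, f_m_unquenched = f_m_unquenched,
         protocol = protocol, seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' @rdname experiment_design
#' @export
default_experiment_design <- function(n_reps = 8, noise_cv = 0.01, seed = 1L,
                                      protocol = protocol_preset("cf_imager")) {
  cells <- tibble::tibble(
    accession = rep(c("MsaRB", "MxgI", "MsiCR"), each = 2),
    treatment = rep(c("warm", "chilling"), 3),
    q_s       = c(0, 0.30, 0, 0.15, 0, 0.02),
    amplitude = c(2, 3.32, 2, 1.687, 2, 1.424),
    half_time = 1,
    n_reps = n_reps
  )
  experiment_design(cells, noise_cv = noise_cv, seed = seed,
                    protocol = protocol)
}

#' @rdname experiment_design
#' @export
default_infiltration_design <- function(n_reps = 8, noise_cv = 0.01,
                                        seed = 1L,
                                        protocol = protocol_preset("cf_imager")) {
  base <- default_experiment_design(n_reps = n_reps)$cells
  water <- dplyr::mutate(base, infiltration = "water")
  retention <- c(MsaRB = 0.76, MxgI = 0.48, MsiCR = 0.23)
  dtt <- dplyr::mutate(
    base,
    infiltration = "dtt",
    amplitude = ifelse(.data$treatment == "chilling",
                       .data$amplitude * retention[.data$accession],
                       .data$amplitude * 0.85),
    q_s = ifelse(.data$treatment == "chilling", 0.02, .data$q_s)
  )
  experiment_design(dplyr::bind_rows(water, dtt), noise_cv = noise_cv,
                    seed = seed, protocol = protocol)
}

#' Simulate a full plate experiment
#'
#' Generates one trace per disc per design cell and returns the stacked
#' flash table, the per-disc ground-truth table for recovery scoring, and
#' the design. Pure function of the design (which carries the seed).
#'
#' @param design An [experiment_design()]; alternatively pass `seed` (and
#'   optionally `n_reps`, `noise_cv`) to use the default design.
#' @param seed,n_reps,noise_cv Convenience overrides applied to
#'   [default_experiment_design()] when `design` is missing.
#' @return A list with elements `traces` (flash tibble), `ground_truth`
#'   (one row per disc), and `design`.
#' @examples
#' exp <- simulate_plate_experiment(seed = 7)
#' dplyr::count(exp$traces, accession, treatment)
#' @export
simulate_plate_experiment <- function(design = NULL, seed = 1L, n_reps = 8,
                                      noise_cv = 0.01) {
  if (is.null(design)) {
    design <- default_experiment_design(n_reps = n_reps, noise_cv = noise_cv,
                                        seed = seed)
  }
  stopifnot(inherits(design, "experiment_design"))
  extra_cols <- setdiff(names(design$cells),
                        c("accession", "treatment", "q_s", "amplitude",
                          "half_time", "n_reps"))
  withr::with_seed(design$seed, {
    traces <- list(); truth <- list()
    for (i in seq_len(nrow(design$cells))) {
      cell <- design$cells[i, ]
      for (r in seq_len(cell$n_reps)) {
        id <- paste(c(cell$accession, cell$treatment,
                      unlist(cell[extra_cols]), r), collapse = "_")
        tr <- simulate_trace(
          sustained_quenching = cell$q_s, amplitude = cell$amplitude,
          half_time = cell$half_time,
          f_o_unquenched = design$f_o_unquenched,
          f_m_unquenched = design$f_m_unquenched,
          noise_cv = design$noise_cv, protocol = design$protocol,
          disc_id = id, accession = cell$accession,
          treatment = cell$treatment, replicate = r, seed = NULL
        )
        for (ec in extra_cols) tr[[ec]] <- cell[[ec]]
        gt <- attr(tr, "ground_truth")
        gt$accession <- cell$accession
        gt$treatment <- cell$treatment
        for (ec in extra_cols) gt[[ec]] <- cell[[ec]]
        traces[[id]] <- tr; truth[[id]] <- gt
      }
    }
    list(traces = dplyr::bind_rows(traces),
         ground_truth = dplyr::bind_rows(truth),
         design = design)
  })
}

#' Simulate a sub-nanometre leaf reflectance spectrum
#'
#' A smooth leaf-like baseline over 400-900 nm at 0.3-nm steps (green bump,
#' red absorption trough, NIR plateau) with a Gaussian depression centred
#' at 531 nm whose depth is proportional to the xanthophyll de-epoxidation
#' level, so the photochemical reflectance index decreases monotonically
#' with that level. Additive Gaussian noise emulates detector noise.
#'
#' @param deepox_level De-epoxidation level in [0, 1].
#' @param sample_id Sample label.
#' @param noise_sd SD of additive reflectance noise (default 0.002).
#' @param step_nm Sampling step (default 0.3 nm).
#' @param seed Integer seed (`NULL`: session RNG).
#' @return Tibble with `sample_id`, `wavelength_nm`, `reflectance`,
#'   `deepox_level`.
#' @export
simulate_spectrum <- function(deepox_level, sample_id = "s1",
                              noise_sd = 0.002, step_nm = 0.3, seed = NULL) {
  stopifnot(deepox_level >= 0, deepox_level <= 1)
  gen <- function() {
    wl <- seq(400, 900, by = step_nm)
    anchors_x <- c(400, 450, 500, 540, 570, 620, 670, 690, 710, 740, 780, 900)
    anchors_y <- c(0.05, 0.05, 0.08, 0.17, 0.14, 0.09, 0.05, 0.06, 0.20,
                   0.40, 0.45, 0.45)
    base <- stats::spline(anchors_x, anchors_y, xout = wl)$y
    dip <- 0.04 * deepox_level * exp(-(wl - 531)^2 / (2 * 8^2))
    r <- pmax(base - dip + rnorm(length(wl), sd = noise_sd), 1e-4)
    tibble::tibble(sample_id = sample_id, wavelength_nm = wl,
                   reflectance = r, deepox_level = deepox_level)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate grouped assay tables (pigments, qPCR, metabolites)
#'
#' Generates the tidy tables the quantification operations consume, from
#' designed group effects, so that each normalisation step can be scored
#' against its ground truth:
#'
#' * pigments — per-replicate extract concentrations (ug/ml) for
#'   zeaxanthin, antheraxanthin, violaxanthin and chlorophyll a/b across
#'   three accessions and three night/light treatments. Defaults encode a
#'   3:1 MsaRB:MsiCR zeaxanthin ratio after a chilling night, an
#'   accession-dependent total xanthophyll pool that chilling redistributes
#'   but does not grow, and low (below-LOQ) zeaxanthin after warm nights.
#' * qPCR — Ct tables for ZEP/VDE/PsbS with dual references (Ubiquitin at
#'   Ct 20, EF1-alpha at 22), generated by inverting the delta-delta-Ct
#'   relation from designed fold changes (ZEP up 4-fold after chilling in
#'   MxgI and MsiCR but flat in MsaRB; VDE flat; PsbS halved everywhere).
#' * metabolites — ascorbate / dehydroascorbate peak areas with sample
#'   weights, from designed amounts per mg (chilling-night
#'   dehydroascorbate 3x higher in MsaRB than MsiCR) and linear response
#'   curves; matching calibration-point tables are included.
#'
#' Replicate noise is multiplicative log-normal on concentrations
#' (`conc_cv`) and additive normal on Cts (`ct_sd`).
#'
#' @param n_reps Replicates per accession x treatment cell (default 8).
#' @param conc_cv CV of concentration noise (default 0.15).
#' @param ct_sd SD of Ct noise in cycles (default 0.15).
#' @param seed Integer seed.
#' @return A list of tibbles: `pigments`, `cts`, `metabolites`,
#'   `calibration_points` (per analyte), and `truth` (the designed means).
#' @export
simulate_assay_tables <- function(n_reps = 8, conc_cv = 0.15, ct_sd = 0.15,
                                  seed = 1L) {
  accs <- c("MsaRB", "MxgI", "MsiCR")
  trts <- c("warm_night", "chilling_night", "chilling_night_light")
  pool <- c(MsaRB = 130, MxgI = 115, MsiCR = 100)
  zea <- rbind(warm_night = c(5, 5, 5),
               chilling_night = c(45, 30, 15),
               chilling_night_light = c(70, 50, 30))
  anth <- rbind(warm_night = c(10, 10, 10),
                chilling_night = c(20, 15, 10),
                chilling_night_light = c(25, 20, 15))
  colnames(zea) <- colnames(anth) <- accs
  fold_zep <- c(MsaRB = 1, MxgI = 4, MsiCR = 4)
  asc <- rbind(warm_night = c(2, 2, 2),
               chilling_night = c(2, 2.5, 2),
               chilling_night_light = c(2, 2.5, 2))
  dha <- rbind(warm_night = c(0.3, 0.3, 0.3),
               chilling_night = c(0.9, 0.6, 0.3),
               chilling_night_light = c(0.9, 0.6, 0.3))
  colnames(asc) <- colnames(dha) <- accs

  grid <- tidyr::expand_grid(accession = accs, treatment = trts,
                             replicate = seq_len(n_reps))
  truth <- list(
    zeaxanthin = zea, antheraxanthin = anth, xanthophyll_pool = pool,
    fold_zep = fold_zep, ascorbate = asc, dehydroascorbate = dha
  )

  withr::with_seed(seed, {
    lnoise <- function(n, cv) {
      if (cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    n <- nrow(grid)
    z <- zea[cbind(grid$treatment, grid$accession)]
    a <- anth[cbind(grid$treatment, grid$accession)]
    v <- pool[grid$accession] - z - a
    pigments <- dplyr::mutate(
      grid,
      sample_id = paste(.data$accession, .data$treatment, .data$replicate,
                        sep = "_"),
      zeaxanthin = z * lnoise(n, conc_cv),
      antheraxanthin = a * lnoise(n, conc_cv),
      violaxanthin = v * lnoise(n, conc_cv),
      lutein = 55 * lnoise(n, conc_cv),
      chlorophyll_a = 800 * lnoise(n, conc_cv),
      chlorophyll_b = 250 * lnoise(n, conc_cv)
    )

    ct_ref1 <- 20; ct_ref2 <- 22
    base_dct <- c(ZEP = 4, VDE = 5, PsbS = 3)
    cts <- purrr::map_dfr(c("ZEP", "VDE", "PsbS"), function(gene) {
      fold <- switch(gene,
        ZEP = ifelse(grid$treatment == "warm_night", 1,
                     fold_zep[grid$accession]),
        VDE = rep(1, n),
        PsbS = ifelse(grid$treatment == "warm_night", 1, 0.5)
      )
      tibble::tibble(
        sample_id = paste(grid$accession, grid$treatment, grid$replicate,
                          sep = "_"),
        accession = grid$accession, treatment = grid$treatment,
        replicate = grid$replicate, target = gene,
        ct_target = (ct_ref1 + ct_ref2) / 2 + base_dct[[gene]] -
          log2(fold) + rnorm(n, sd = ct_sd),
        ct_ref1 = ct_ref1 + rnorm(n, sd = ct_sd),
        ct_ref2 = ct_ref2 + rnorm(n, sd = ct_sd)
      )
    })

    met_slope <- c(ascorbate = 120, dehydroascorbate = 90)
    metabolites <- purrr::map_dfr(
      c("ascorbate", "dehydroascorbate"),
      function(an) {
        amount <- (if (an == "ascorbate") asc else
                     dha)[cbind(grid$treatment, grid$accession)]
        weight <- 25 * lnoise(n, 0.1)
        conc <- amount * weight / 0.05 # units/ml in the 50-ul extract
        tibble::tibble(
          sample_id = paste(grid$accession, grid$treatment, grid$replicate,
                            sep = "_"),
          accession = grid$accession, treatment = grid$treatment,
          replicate = grid$replicate, analyte = an,
          peak_area = conc * met_slope[[an]] * lnoise(n, conc_cv),
          sample_weight_mg = weight
        )
      }
    )

    cal_conc <- c(0, 5, 10, 25, 50, 100)
    pig_slope <- c(zeaxanthin = 12, antheraxanthin = 11, violaxanthin = 10,
                   lutein = 13, chlorophyll_a = 8, chlorophyll_b = 9)
    calibration_points <- purrr::map_dfr(
      names(c(pig_slope, met_slope)),
      function(an) {
        slope <- c(pig_slope, met_slope)[[an]]
        tibble::tibble(analyte = an, concentration = cal_conc,
                       response = slope * cal_conc)
      }
    )

    list(pigments = pigments, cts = cts, metabolites = metabolites,
         calibration_points = calibration_points, truth = truth)
  })
}
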