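#' Normality and homoscedasticity checks
#'
#' Shapiro-Wilk on the residuals of the cell-means model (one cell per
#' factor combination) and the Brown-Forsythe test (Levene's statistic with
#' median centring) across cells. These two p-values drive the routing in
#' [route_and_test()]: if either falls below alpha the data are transformed
#' or sent down the nonparametric branch.
#'
#' @param data Data frame of observations.
#' @param value Name of the numeric response column.
#' @param factors Character vector of grouping columns.
#' @return A one-row tibble: `shapiro_p`, `brown_forsythe_p`, `n`,
#'   `n_groups`, `degenerate` (all-constant data; both p are `NA` and the
#'   caller should route nonparametric).
#' @examples
#' d <- data.frame(y = rnorm(30), g = rep(letters[1:3], each = 10))
#' check_assumptions(d, "y", "g")
#' @export
check_assumptions <- function(data, value, factors) {
  y <- data[[value]]
  if (is.null(y)) {
    abort(paste0("Column `", value, "` not found."),
          class = "npqkit_schema_error")
  }
  cell <- interaction(data[factors], drop = TRUE)
  if (length(y) < 3) {
    abort("At least 3 observations are required.",
          class = "npqkit_insufficient_data")
  }
  res <- y - stats::ave(y, cell)
  if (sd(res) < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    return(tibble::tibble(shapiro_p = NA_real_, brown_forsythe_p = NA_real_,
                          n = length(y), n_groups = nlevels(cell),
                          degenerate = TRUE))
  }
  res_sw <- if (length(res) > 5000) res[seq_len(5000)] else res
  sw <- shapiro.test(res_sw)$p.value
  bf <- if (nlevels(cell) >= 2) {
    car::leveneTest(y, cell, center = median)[["Pr(>F)"]][1]
  } else {
    NA_real_ # homoscedasticity is vacuous with a single group
  }
  tibble::tibble(shapiro_p = sw, brown_forsythe_p = bf,
                 n = length(y), n_groups = nlevels(cell), degenerate = FALSE)
}

#' Dunnett many-to-one comparisons
#'
#' Compares every group mean against a designated control with family-wise
#' error control. Two-sided t statistics use the pooled within-group
#' variance; each adjusted p-value is the probability that the maximum
#' absolute component of the many-to-one multivariate-t vector (correlation
#' `rho_ij = lambda_i * lambda_j`, `lambda_i = sqrt(n_i / (n_i + n_0))`)
#' exceeds the observed |t|. With a single comparison this reduces exactly
#' to the two-sided two-sample pooled t-test. The multivariate-t
#' probability is evaluated by seeded quasi-Monte-Carlo
#' ([mvtnorm::pmvt], up to 2.5e5 points, absolute tolerance 1e-4), so
#' results are reproducible bit-for-bit for a given seed.
#'
#' @param data Data frame of observations.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param control Label of the control group.
#' @param alpha Significance level for the `significant` flag.
#' @param seed Integer seed for the quasi-Monte-Carlo evaluation used when
#'   there are more than three comparisons.
#' @return A tibble, one row per non-control group: `contrast`, `estimate`
#'   (mean difference vs control), `statistic`, `df`, `raw_p` (unadjusted
#'   two-sided t), `adjusted_p`, `significant`.
#' @examples
#' d <- data.frame(y = c(rnorm(8), rnorm(8, 2)), g = rep(c("ctrl", "trt"), each = 8))
#' dunnett_test(d, "y", "g", control = "ctrl")
#' @export
dunnett_test <- function(data, value, group, control, alpha = 0.05, seed = 1L) {
  y <- data[[value]]
  g <- as.character(data[[group]])
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  labs <- unique(g)
  if (!control %in% labs) {
    abort(paste0("Control group '", control, "' not found."),
          class = "npqkit_schema_error")
  }
  if (length(labs) < 2) {
    abort("Need at least two groups.", class = "npqkit_insufficient_data")
  }
  n <- tapply(y, g, length)
  if (any(n < 2)) {
    abort("Every group needs at least 2 observations.",
          class = "npqkit_insufficient_data")
  }
  means <- tapply(y, g, mean)
  ss <- tapply(y, g, function(v) sum((v - mean(v))^2))
  N <- length(y); k <- length(labs)
  df <- N - k
  s2 <- sum(ss) / df
  if (s2 <= 0) {
    abort("Zero pooled variance; comparisons are degenerate.",
          class = "npqkit_degenerate")
  }
  trt <- setdiff(labs, control)
  n0 <- n[[control]]
  est <- means[trt] - means[[control]]
  se <- sqrt(s2 * (1 / n[trt] + 1 / n0))
  tstat <- est / se
  lambda <- sqrt(n[trt] / (n[trt] + n0))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  m <- length(trt)
  p_adj <- vapply(abs(tstat), function(tt) {
    if (!is.finite(tt)) return(NA_real_)
    pr <- if (m == 1) {
      1 - (pt(tt, df) - pt(-tt, df))
    } else {
      withr::with_seed(seed, {
        1 - mvtnorm::pmvt(lower = rep(-tt, m), upper = rep(tt, m), df = df,
                          corr = corr,
                          algorithm = mvtnorm::GenzBretz(maxpts = 250000,
                                                         abseps = 1e-4))[1]
      })
    }
    min(max(pr, 0), 1)
  }, numeric(1))
  tibble::tibble(
    contrast = paste(trt, "-", control),
    estimate = as.numeric(est),
    statistic = as.numeric(tstat),
    df = df,
    raw_p = as.numeric(2 * pt(-abs(tstat), df)),
    adjusted_p = as.numeric(p_adj),
    significant = as.logical(p_adj < alpha)
  )
}

#' Conover-Iman rank comparisons with Benjamini-Hochberg correction
#'
#' Post-hoc many-to-one (or all-pairs) comparisons after a Kruskal-Wallis
#' omnibus test, on the pooled ranks: the Conover-Iman t statistic for
#' groups i, j is `(Rbar_i - Rbar_j) / sqrt(S2 * (N - 1 - H) / (N - k) *
#' (1/n_i + 1/n_j))` with `S2` the variance of the pooled (tie-corrected)
#' ranks and `H` the Kruskal-Wallis statistic, referred to a t distribution
#' on `N - k` degrees of freedom. Raw two-sided p-values are adjusted by
#' Benjamini-Hochberg within the comparison family.
#'
#' @inheritParams dunnett_test
#' @param control Label of the control group; if `NULL`, all pairwise
#'   comparisons are performed.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A tibble: `contrast`, `estimate` (rank-mean difference),
#'   `statistic`, `df`, `raw_p`, `adjusted_p`, `significant`, plus the
#'   Kruskal-Wallis omnibus `kw_p` as an attribute `"kw_p"`.
#' @export
conover_iman_bh <- function(data, value, group, control = NULL,
                            alpha = 0.05, p_adjust = "BH") {
  y <- data[[value]]
  g <- as.character(data[[group]])
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  labs <- unique(g)
  k <- length(labs); N <- length(y)
  if (k < 2) abort("Need at least two groups.",
                   class = "npqkit_insufficient_data")
  if (!is.null(control) && !control %in% labs) {
    abort(paste0("Control group '", control, "' not found."),
          class = "npqkit_schema_error")
  }
  r <- rank(y)
  if (sd(r) == 0) {
    abort("All observations tied; rank comparisons are degenerate.",
          class = "npqkit_degenerate")
  }
  n <- tapply(r, g, length)
  rbar <- tapply(r, g, mean)
  s2 <- sum((r - (N + 1) / 2)^2) / (N - 1) # tie-corrected pooled rank variance
  h <- (sum(n * (rbar - (N + 1) / 2)^2)) / s2 # KW statistic (tie-corrected)
  kw_p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  pairs <- if (is.null(control)) {
    utils::combn(labs, 2, simplify = FALSE)
  } else {
    lapply(setdiff(labs, control), function(a) c(a, control))
  }
  df <- N - k
  denom_scale <- s2 * (N - 1 - h) / df
  rows <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- rbar[[i]] - rbar[[j]]
    se <- sqrt(denom_scale * (1 / n[[i]] + 1 / n[[j]]))
    tt <- d / se
    tibble::tibble(contrast = paste(i, "-", j), estimate = d,
                   statistic = tt, df = df,
                   raw_p = 2 * pt(-abs(tt), df))
  })
  rows$adjusted_p <- p.adjust(rows$raw_p, method = p_adjust)
  rows$significant <- rows$adjusted_p < alpha
  attr(rows, "kw_p") <- kw_p
  rows
}

stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

family_compare <- function(d, value, group, control, branch, alpha, seed) {
  labs <- unique(as.character(d[[group]]))
  if (length(labs) < 2 || !control %in% labs) return(NULL)
  if (branch == "parametric") {
    cmp <- dunnett_test(d, value, group, control, alpha = alpha, seed = seed)
    cmp$method <- "dunnett"
  } else if (length(labs) == 2) {
    other <- setdiff(labs, control)
    w <- suppressWarnings(
      wilcox.test(d[[value]][d[[group]] == other],
                  d[[value]][d[[group]] == control], exact = FALSE)
    )
    cmp <- tibble::tibble(
      contrast = paste(other, "-", control),
      estimate = median(d[[value]][d[[group]] == other]) -
        median(d[[value]][d[[group]] == control]),
      statistic = unname(w$statistic), df = NA_real_,
      raw_p = w$p.value, adjusted_p = w$p.value,
      significant = w$p.value < alpha, method = "wilcoxon"
    )
  } else {
    cmp <- conover_iman_bh(d, value, group, control, alpha = alpha)
    cmp$method <- "conover_iman_bh"
    attr(cmp, "kw_p") <- NULL
  }
  cmp
}

#' Assumption-routed group comparisons
#'
#' The full statistical workflow for grouped assay values: check normality
#' (Shapiro-Wilk on residuals) and homoscedasticity (Brown-Forsythe); if
#' either fails at `alpha`, attempt a natural-log transform (positive data
#' only) and re-check; if the checks still fail, route to the nonparametric
#' branch. The parametric branch runs a factorial ANOVA omnibus followed by
#' Dunnett many-to-one comparisons; the nonparametric branch runs
#' Kruskal-Wallis followed by Conover-Iman comparisons with
#' Benjamini-Hochberg correction (rank-sum for two-group families).
#'
#' Two comparison families are built, mirroring the two annotation colours
#' of the figure convention, and corrected separately:
#' * inter-accession — within each treatment, accessions versus the
#'   low-tolerance control accession;
#' * intra-accession — within each accession, treatments versus the warm
#'   control treatment.
#'
#' @param data Data frame of per-replicate observations.
#' @param value Name of the numeric response column.
#' @param accession,treatment Names of the two factor columns.
#' @param accession_control,treatment_control Control levels (defaults
#'   `"MsiCR"` and `"warm"`).
#' @param extra_factor Optional third factor column included in the ANOVA.
#' @param alpha Routing and significance level (default 0.05).
#' @param transform `"log"` (default; natural log attempted when checks
#'   fail and all values are positive) or `"none"`.
#' @param seed Seed passed to [dunnett_test()].
#' @return An object of class `stat_route`: assumption p-values, the
#'   transform applied, the branch taken, the omnibus table, and the
#'   per-contrast comparison table (`tidy()` returns it; `glance()` returns
#'   the one-row route summary).
#' @examples
#' exp <- simulate_plate_experiment(seed = 1)
#' rates <- fit_npq_kinetics(compute_npq(exp$traces))
#' route_and_test(rates, "initial_slope")
#' @export
route_and_test <- function(data, value,
                           accession = "accession", treatment = "treatment",
                           accession_control = "MsiCR",
                           treatment_control = "warm",
                           extra_factor = NULL,
                           alpha = 0.05, transform = c("log", "none"),
                           seed = 1L) {
  transform <- match.arg(transform)
  factors <- c(accession, treatment, extra_factor)
  missing_cols <- setdiff(c(value, factors), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "npqkit_schema_error")
  }
  data <- data[is.finite(data[[value]]), , drop = FALSE]
  cell <- interaction(data[factors], drop = TRUE)
  if (nlevels(cell) < 2) {
    abort("Need at least two groups to compare.",
          class = "npqkit_insufficient_data")
  }
  if (any(table(cell) < 2)) {
    abort("Every accession x treatment cell needs at least 2 replicates.",
          class = "npqkit_insufficient_data")
  }

  chk <- check_assumptions(data, value, factors)
  fails <- function(c) isTRUE(c$degenerate) ||
    isTRUE(c$shapiro_p < alpha) || isTRUE(c$brown_forsythe_p < alpha)
  transform_applied <- "none"
  work <- data
  if (fails(chk) && transform == "log" && !isTRUE(chk$degenerate) &&
      all(data[[value]] > 0)) {
    work[[value]] <- log(data[[value]])
    chk2 <- check_assumptions(work, value, factors)
    if (!fails(chk2)) {
      transform_applied <- "log"
      chk <- chk2
    } else {
      work <- data
    }
  }
  branch <- if (fails(chk) && transform_applied == "none") "nonparametric"
            else "parametric"

  if (branch == "parametric") {
    fml <- stats::as.formula(paste(value, "~", paste(factors, collapse = " * ")))
    fit <- aov(fml, data = work)
    st <- summary(fit)[[1]]
    omnibus <- tibble::tibble(
      term = trimws(rownames(st)),
      df = st$Df, statistic = st$`F value`, p_value = st$`Pr(>F)`
    )
  } else {
    kw <- kruskal.test(work[[value]], cell)
    omnibus <- tibble::tibble(term = "cells (Kruskal-Wallis)",
                              df = unname(kw$parameter),
                              statistic = unname(kw$statistic),
                              p_value = kw$p.value)
  }

  comparisons <- list()
  for (tr in unique(as.character(work[[treatment]]))) {
    d <- work[work[[treatment]] == tr, , drop = FALSE]
    cmp <- family_compare(d, value, accession, accession_control,
                          branch, alpha, seed)
    if (!is.null(cmp)) {
      cmp$family <- paste0("inter_accession|", tr)
      comparisons <- c(comparisons, list(cmp))
    }
  }
  for (ac in unique(as.character(work[[accession]]))) {
    d <- work[work[[accession]] == ac, , drop = FALSE]
    cmp <- family_compare(d, value, treatment, treatment_control,
                          branch, alpha, seed)
    if (!is.null(cmp)) {
      cmp$family <- paste0("intra_accession|", ac)
      comparisons <- c(comparisons, list(cmp))
    }
  }
  comparisons <- dplyr::bind_rows(comparisons)
  if (nrow(comparisons) > 0) {
    comparisons$stars <- stars(comparisons$adjusted_p)
    comparisons <- dplyr::relocate(comparisons, "family")
  }

  structure(
    list(value = value,
         shapiro_p = chk$shapiro_p, brown_forsythe_p = chk$brown_forsythe_p,
         transform_applied = transform_applied, branch = branch,
         alpha = alpha, omnibus = omnibus, comparisons = comparisons),
    class = "stat_route"
  )
}

#' @export
print.stat_route <- function(x, ...) {
  cat("<stat_route> response:", x$value, "\n")
  cat(sprintf("  Shapiro-Wilk p = %.3g; Brown-Forsythe p = %.3g; transform: %s\n",
              x$shapiro_p, x$brown_forsythe_p, x$transform_applied))
  cat("  branch:", x$branch, "\n")
  cat("  omnibus:\n")
  print(x$omnibus)
  cat("  comparisons:\n")
  print(x$comparisons)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stat_route <- function(x, ...) {
  dplyr::mutate(x$comparisons, method = .data$method, branch = x$branch)
}

#' @exportS3Method generics::glance
glance.stat_route <- function(x, ...) {
  tibble::tibble(
    value = x$value, shapiro_p = x$shapiro_p,
    brown_forsythe_p = x$brown_forsythe_p,
    transform_applied = x$transform_applied, branch = x$branch,
    alpha = x$alpha,
    n_comparisons = nrow(x$comparisons),
    n_significant = sum(x$comparisons$significant %||% logical(0))
  )
}
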