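three_groups <- function(n = 10, shift = c(0, 0, 0), rdist = rnorm) {
  tibble::tibble(
    y = c(rdist(n) + shift[1], rdist(n) + shift[2], rdist(n) + shift[3]),
    g = rep(c("ctrl", "a", "b"), each = n)
  )
}

test_that("assumption checks give uniform p-values under the null", {
  set.seed(101)
  n_sims <- 400
  sw <- bf <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    d <- three_groups(n = 50)
    chk <- check_assumptions(d, "y", "g")
    sw[i] <- chk$shapiro_p; bf[i] <- chk$brown_forsythe_p
  }
  expect_gt(stats::ks.test(sw, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(bf, "punif")$p.value, 0.01)
})

test_that("assumption checks detect their target violations", {
  set.seed(102)
  bf_rej <- mean(replicate(300, {
    d <- tibble::tibble(y = c(rnorm(20), rnorm(20), rnorm(20, sd = 4)),
                        g = rep(c("a", "b", "c"), each = 20))
    check_assumptions(d, "y", "g")$brown_forsythe_p < 0.05
  }))
  expect_gt(bf_rej, 0.9)
  sw_rej <- mean(replicate(300, {
    d <- tibble::tibble(y = stats::rexp(30), g = "a")
    check_assumptions(d, "y", "g")$shapiro_p < 0.05
  }))
  expect_gt(sw_rej, 0.9)
})

test_that("constant data is reported as degenerate", {
  d <- tibble::tibble(y = rep(1, 12), g = rep(c("a", "b"), each = 6))
  chk <- check_assumptions(d, "y", "g")
  expect_true(chk$degenerate)
  expect_true(is.na(chk$shapiro_p))
})

test_that("single-comparison Dunnett reduces exactly to the pooled t-test", {
  set.seed(7)
  for (i in 1:5) {
    d <- tibble::tibble(y = c(rnorm(8), rnorm(9, 0.7)),
                        g = rep(c("ctrl", "trt"), c(8, 9)))
    cmp <- dunnett_test(d, "y", "g", "ctrl")
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(cmp$adjusted_p, tt$p.value, tolerance = 1e-12)
    expect_equal(cmp$raw_p, cmp$adjusted_p, tolerance = 1e-12)
  }
})

test_that("null-centred contrasts give adjusted p of 1", {
  d <- tibble::tibble(y = c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                      g = rep(c("ctrl", "a", "b"), each = 3))
  cmp <- dunnett_test(d, "y", "g", "ctrl")
  expect_equal(cmp$statistic, c(0, 0))
  expect_equal(cmp$adjusted_p, c(1, 1), tolerance = 1e-6)
})

test_that("Dunnett adjusted p agrees with a brute-force oracle (k=3, df=12)", {
  set.seed(55)
  d <- three_groups(n = 5)
  cmp <- dunnett_test(d, "y", "g", "ctrl")
  for (i in seq_len(nrow(cmp))) {
    oracle <- mc_dunnett_p(cmp$statistic[i], k = 3, n_per_group = 5)
    expect_equal(cmp$adjusted_p[i], oracle, tolerance = 0.005)
  }
})

test_that("Dunnett agrees with the multivariate-t reference implementation", {
  set.seed(56)
  d <- three_groups(n = 8, shift = c(0, 0.8, 1.6))
  cmp <- dunnett_test(d, "y", "g", "ctrl")
  fit <- stats::aov(y ~ g, data = within(as.data.frame(d), {
    g <- stats::relevel(factor(g), ref = "ctrl")
  }))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  ref_p <- as.numeric(ref$test$pvalues)
  ref_names <- sub(" == 0", "", names(ref$test$coefficients))
  ord <- match(cmp$contrast, ref_names)
  expect_equal(cmp$adjusted_p, ref_p[ord], tolerance = 2e-3)
})

test_that("Dunnett results are reproducible and adjusted >= raw", {
  set.seed(57)
  d <- three_groups(n = 6, shift = c(0, 1, 2))
  c1 <- dunnett_test(d, "y", "g", "ctrl")
  c2 <- dunnett_test(d, "y", "g", "ctrl")
  expect_identical(c1, c2)
  expect_true(all(c1$adjusted_p >= c1$raw_p - 1e-12))
  expect_true(all(c1$adjusted_p >= 0 & c1$adjusted_p <= 1))
})

test_that("Dunnett validates its inputs", {
  d <- three_groups(n = 3)
  expect_error(dunnett_test(d, "y", "g", "nope"),
               class = "npqkit_schema_error")
  d1 <- tibble::tibble(y = c(1, 2, 3, 4), g = c("ctrl", "ctrl", "ctrl", "a"))
  expect_error(dunnett_test(d1, "y", "g", "ctrl"),
               class = "npqkit_insufficient_data")
})

test_that("Conover-Iman statistics match the from-scratch formula", {
  set.seed(60)
  d <- three_groups(n = 7, shift = c(0, 0.5, 1.2))
  cmp <- conover_iman_bh(d, "y", "g", control = "ctrl")
  for (lab in c("a", "b")) {
    oracle <- conover_oracle(d$y, d$g, lab, "ctrl")
    got <- cmp$statistic[cmp$contrast == paste(lab, "-", "ctrl")]
    expect_equal(got, oracle, tolerance = 1e-10)
  }
  expect_equal(cmp$adjusted_p, p.adjust(cmp$raw_p, "BH"))
  expect_true(all(cmp$adjusted_p >= cmp$raw_p - 1e-12))
})

test_that("Benjamini-Hochberg adjustment is monotone under reordering", {
  p <- c(0.01, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.02, 0.04))
  set.seed(61)
  praw <- runif(6)
  perm <- sample(6)
  expect_equal(p.adjust(praw, "BH")[perm], p.adjust(praw[perm], "BH"))
})

test_that("a stochastically dominant group is detected by Conover-Iman", {
  set.seed(62)
  hits <- mean(replicate(50, {
    d <- three_groups(n = 10, shift = c(0, 0, 2))
    cmp <- conover_iman_bh(d, "y", "g", control = "ctrl")
    cmp$significant[cmp$contrast == "b - ctrl"]
  }))
  expect_gt(hits, 0.9)
})

test_that("identical groups produce no excess Conover-Iman rejections", {
  set.seed(63)
  rej <- mean(replicate(200, {
    d <- three_groups(n = 8)
    any(conover_iman_bh(d, "y", "g", control = "ctrl")$significant)
  }))
  expect_lt(rej, 0.1)
})

test_that("all-tied data is a degenerate rank comparison", {
  d <- tibble::tibble(y = rep(2, 9), g = rep(c("a", "b", "c"), each = 3))
  expect_error(conover_iman_bh(d, "y", "g"), class = "npqkit_degenerate")
})

test_that("route_and_test picks the parametric branch for normal data", {
  set.seed(70)
  d <- tidyr::expand_grid(accession = c("MsaRB", "MxgI", "MsiCR"),
                          treatment = c("warm", "chilling"),
                          replicate = 1:6)
  d$y <- rnorm(nrow(d))
  route <- route_and_test(d, "y")
  expect_equal(route$branch, "parametric")
  expect_equal(route$transform_applied, "none")
  expect_true(all(c("accession", "treatment", "accession:treatment") %in%
                    route$omnibus$term))
  expect_true(all(route$comparisons$method == "dunnett"))
  # both families present, corrected separately
  fams <- unique(route$comparisons$family)
  expect_true(any(grepl("^inter_accession", fams)))
  expect_true(any(grepl("^intra_accession", fams)))
})

test_that("log transform rescues positive skewed data", {
  set.seed(71)
  d <- tidyr::expand_grid(accession = c("MsaRB", "MxgI", "MsiCR"),
                          treatment = c("warm", "chilling"),
                          replicate = 1:8)
  d$y <- exp(rnorm(nrow(d), sd = 1.5))
  route <- route_and_test(d, "y")
  # either the transform restored normality or the data went nonparametric;
  # with lognormal data the transform branch should dominate
  expect_equal(route$transform_applied, "log")
  expect_equal(route$branch, "parametric")
})

test_that("heavy-tailed data routes nonparametric", {
  set.seed(72)
  frac <- mean(replicate(40, {
    d <- tidyr::expand_grid(accession = c("MsaRB", "MsiCR"),
                            treatment = c("warm", "chilling"),
                            replicate = 1:10)
    d$y <- stats::rcauchy(nrow(d))
    route_and_test(d, "y")$branch == "nonparametric"
  }))
  expect_gt(frac, 0.9)
})

test_that("two-group nonparametric families use the rank-sum test", {
  set.seed(73)
  d <- tidyr::expand_grid(accession = c("MsaRB", "MsiCR"),
                          treatment = c("warm", "chilling"),
                          replicate = 1:10)
  d$y <- stats::rcauchy(nrow(d))
  route <- route_and_test(d, "y", transform = "none")
  if (route$branch == "nonparametric") {
    expect_true(all(route$comparisons$method == "wilcoxon"))
  }
})

test_that("route_and_test rejects unusable designs", {
  d <- tibble::tibble(accession = "MsaRB", treatment = "warm",
                      y = rnorm(5), replicate = 1:5)
  expect_error(route_and_test(d, "y"), class = "npqkit_insufficient_data")
  d2 <- tibble::tibble(accession = rep(c("MsaRB", "MsiCR"), c(5, 1)),
                       treatment = "warm", y = rnorm(6), replicate = 1:6)
  expect_error(route_and_test(d2, "y"), class = "npqkit_insufficient_data")
})

test_that("a shifted group is flagged by the routed Dunnett comparisons", {
  set.seed(74)
  hits <- replicate(60, {
    d <- tidyr::expand_grid(accession = c("MsaRB", "MxgI", "MsiCR"),
                            treatment = c("warm", "chilling"),
                            replicate = 1:8)
    d$y <- rnorm(nrow(d)) +
      ifelse(d$accession == "MsaRB" & d$treatment == "chilling", 3, 0)
    route <- route_and_test(d, "y")
    cmp <- route$comparisons
    cmp$significant[cmp$family == "inter_accession|chilling" &
                      cmp$contrast == "MsaRB - MsiCR"]
  })
  expect_gt(mean(hits), 0.95)
})

test_that("tidy and glance expose the route record", {
  set.seed(75)
  d <- tidyr::expand_grid(accession = c("MsaRB", "MsiCR"),
                          treatment = c("warm", "chilling"),
                          replicate = 1:5)
  d$y <- rnorm(nrow(d))
  route <- route_and_test(d, "y")
  td <- tidy(route)
  expect_true(all(c("family", "contrast", "estimate", "raw_p", "adjusted_p",
                    "method", "branch", "stars") %in% names(td)))
  gl <- glance(route)
  expect_equal(gl$branch, route$branch)
  expect_equal(gl$n_comparisons, nrow(route$comparisons))
})
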