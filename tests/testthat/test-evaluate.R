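test_that("targeting errors match hand trigonometry on worked cases", {
  # perfect placement
  d0 <- targeting_errors(c(0, 0, 0), c(0, 0, 100), c(0, 0, 100))
  expect_equal(d0$angular_deg, 0)
  expect_equal(d0$absolute_mm, 0)
  expect_equal(d0$longitudinal_mm, 0)

  # lateral 2 mm at full depth: angle = atan(2/100), |BC| = 2,
  # |CC'| = sqrt(100^2 + 2^2) - 100
  d1 <- targeting_errors(c(0, 0, 0), c(0, 0, 100), c(2, 0, 100))
  expect_equal(d1$angular_deg, atan(2 / 100) * 180 / pi, tolerance = 1e-9)
  expect_equal(d1$absolute_mm, 2, tolerance = 1e-12)
  expect_equal(d1$longitudinal_mm, sqrt(100^2 + 2^2) - 100, tolerance = 1e-9)

  # pure depth error: 5 mm short
  d2 <- targeting_errors(c(0, 0, 0), c(0, 0, 100), c(0, 0, 95))
  expect_equal(d2$angular_deg, 0)
  expect_equal(d2$absolute_mm, 5)
  expect_equal(d2$longitudinal_mm, 5)

  expect_error(targeting_errors(c(0, 0, 0), c(0, 0, 100), c(0, 0, 0)),
               class = "cbctnav_validation")
  expect_error(targeting_errors(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               class = "cbctnav_validation")
})

test_that("targeting errors are invariant under common rigid motion", {
  set.seed(13)
  for (i in 1:100) {
    a <- runif(3, -50, 50)
    b <- a + runif(3, -60, 60)
    cc <- b + rnorm(3, 0, 3)
    if (max(abs(b - a)) < 1e-3 || max(abs(cc - a)) < 1e-3) next
    d0 <- targeting_errors(a, b, cc)
    tf <- random_rigid()
    d1 <- targeting_errors(rt_apply(tf, a), rt_apply(tf, b), rt_apply(tf, cc))
    expect_equal(d1$angular_deg, d0$angular_deg, tolerance = 1e-9)
    expect_equal(d1$absolute_mm, d0$absolute_mm, tolerance = 1e-9)
    expect_equal(d1$longitudinal_mm, d0$longitudinal_mm, tolerance = 1e-9)
  }
})

test_that("moving the tip along its own ray changes only the longitudinal term", {
  a <- c(0, 0, 0); b <- c(0, 0, 100); cc <- c(3, 1, 102)  # beyond planned depth
  d0 <- targeting_errors(a, b, cc)
  u_ac <- (cc - a) / sqrt(sum((cc - a)^2))
  d1 <- targeting_errors(a, b, cc + 7 * u_ac)
  expect_equal(d1$angular_deg, d0$angular_deg, tolerance = 1e-9)
  # tip started beyond planned depth, so moving further out adds exactly 7
  expect_equal(d1$longitudinal_mm, d0$longitudinal_mm + 7, tolerance = 1e-9)
})

test_that("the deviation triple respects the triangle inequality", {
  set.seed(19)
  for (i in 1:100) {
    a <- runif(3, -50, 50)
    b <- a + runif(3, -60, 60)
    cc <- b + rnorm(3, 0, 5)
    if (max(abs(b - a)) < 1e-3 || max(abs(cc - a)) < 1e-3) next
    d <- targeting_errors(a, b, cc)
    nab <- sqrt(sum((b - a)^2)); nac <- sqrt(sum((cc - a)^2))
    c_prime <- a + nab * (cc - a) / nac
    expect_lte(d$absolute_mm,
               d$longitudinal_mm + sqrt(sum((c_prime - b)^2)) + 1e-9)
  }
})

test_that("group summaries use sample statistics with the n-1 denominator", {
  s <- summarize_group(c(2, 2, 2))
  expect_equal(s[c("mean", "std", "min", "max")], list(mean = 2, std = 0, min = 2, max = 2))
  s2 <- summarize_group(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$std, sqrt(sum((c(1, 2, 3, 4) - 2.5)^2) / 3), tolerance = 1e-12)
  expect_equal(round(s2$std, 4), 1.291)
  s3 <- summarize_group(5)
  expect_equal(s3$std, 0)
  expect_true(s3$degenerate)
})

test_that("two-group ANOVA matches hand sums of squares and the t-test identity", {
  r <- one_way_anova(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$f_stat, 13.5, tolerance = 1e-12)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 4L)

  same <- one_way_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)

  degenerate <- one_way_anova(c(1, 1), c(2, 2))
  expect_identical(degenerate$f_stat, Inf)
  expect_equal(degenerate$p_value, 0)

  # F = t^2 for two groups; independent pooled-t oracle
  set.seed(37)
  for (i in 1:20) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- rnorm(na, 1, 2); b <- rnorm(nb, 0.5, 2)
    r <- one_way_anova(a, b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(r$f_stat, t_stat^2, tolerance = 1e-9)
    expect_equal(r$p_value, 2 * pt(-abs(t_stat), na + nb - 2), tolerance = 1e-9)
  }
})

test_that("ANOVA agrees with the built-in linear-model ANOVA", {
  set.seed(53)
  a <- rnorm(8, 2, 1); b <- rnorm(9, 2.7, 1)
  r <- one_way_anova(a, b)
  ref <- anova(lm(v ~ g, data.frame(v = c(a, b),
                                    g = rep(c("a", "b"), c(8, 9)))))
  expect_equal(r$f_stat, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(r$p_value, ref$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("null ANOVA p-values are uniform", {
  set.seed(61)
  pvals <- replicate(2000, one_way_anova(rnorm(8), rnorm(8))$p_value)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a zero-noise study summarises to perfect placement", {
  quiet <- needle_noise(0, 0, time_mean_s = 300, time_sd_s = 0)
  s <- simulate_study(noise_by_group = list(in_plane = quiet, out_of_plane = quiet),
                      seed = 2)
  rep <- study_summary(s)
  expect_equal(rep$n_outcomes, 16)
  expect_equal(rep$success_rate, 1)
  for (m in c("angular_deg", "absolute_mm", "longitudinal_mm"))
    expect_lt(rep$metrics[[m]]$overall$mean, 1e-5)  # acos rounding floor
  expect_equal(rep$metrics$time_s$overall$mean, 300)
})

test_that("the report mirrors the study-table shape", {
  rep <- study_summary(simulate_study(seed = 4))
  # 5 quantities x {overall, in-plane, off-plane} + ANOVA each
  expect_named(rep$metrics, c("angular_deg", "absolute_mm", "longitudinal_mm",
                              "time_s", "iterations"))
  for (m in rep$metrics) {
    expect_equal(m$overall$n, 16)
    expect_equal(m$in_plane$n, 8)
    expect_equal(m$out_of_plane$n, 8)
    expect_true(m$overall$min <= m$overall$mean && m$overall$mean <= m$overall$max)
  }
  expect_true(is.finite(rep$metrics$time_s$anova$p_value))
  txt <- format_study_report(rep)
  expect_true(any(grepl("Angular deviation", txt)))
  expect_true(any(grepl("off-plane", txt)))
})

test_that("large-sample mean angular deviation matches a Monte-Carlo oracle", {
  p <- plan_trajectory(c(0, 0, 0), c(0, 100, 0))
  noise <- needle_noise(time_sd_s = 0)  # defaults: 0.68 deg, 1.55 mm
  sim_mean <- mean(vapply(1:10000, function(i) {
    o <- simulate_needle_outcome(p, noise, seed = 30000 + i)
    targeting_errors(o$entry_A, o$target_B, o$tip_C)$angular_deg
  }, numeric(1)))
  # independent oracle: the angle is the norm of two N(0, 0.68) transverse
  # components; simulate that construction directly
  set.seed(123)
  oracle <- mean(sqrt(rnorm(2e5, 0, 0.68)^2 + rnorm(2e5, 0, 0.68)^2))
  expect_equal(sim_mean, oracle, tolerance = 0.05 * oracle)
})
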