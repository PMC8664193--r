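test_that("pearson screen flags and drops correlated covariates", {
  set.seed(41)
  n <- 1000
  x <- rnorm(n)
  tab <- data.frame(a = x, b = x, c = rnorm(n)) # b duplicates a
  sc <- pearson_screen(tab)
  expect_true(any(sc$flagged_pairs$var1 == "a" & sc$flagged_pairs$var2 == "b"))
  expect_equal(sc$dropped, "b") # later in priority order
  expect_equal(sort(sc$retained), c("a", "c"))
  # independent columns are not flagged
  sc2 <- pearson_screen(data.frame(a = rnorm(n), b = rnorm(n)))
  expect_equal(nrow(sc2$flagged_pairs), 0)
  # priority order decides the member dropped
  sc3 <- pearson_screen(tab, priority = c("b", "a", "c"))
  expect_equal(sc3$dropped, "a")
  # constant columns reported, not correlated
  sc4 <- pearson_screen(data.frame(a = rnorm(10), k = rep(2, 10)))
  expect_equal(sc4$constant, "k")
  expect_error(pearson_screen(tab[, 1, drop = FALSE]), "at least 2")
})

test_that("flagged correlations match the textbook Pearson formula", {
  tab <- data.frame(u = c(1, 2, 3, 4, 5), v = c(1.2, 1.9, 3.4, 3.9, 5.1))
  sc <- pearson_screen(tab, threshold = 0.5)
  expect_equal(sc$flagged_pairs$r, pearson_by_hand(tab$u, tab$v),
               tolerance = 1e-12)
})

test_that("RT-TT correlation handles exact, null and hand-checked cases", {
  rt <- c(3, 7, 11, 15, 20, 26)
  rec <- data.frame(rt_min = rt, tt_min = 2 * rt)
  expect_equal(correlation_rt_tt(rec)$r, 1.0, tolerance = 1e-12)
  set.seed(17)
  rec2 <- data.frame(rt_min = rnorm(1000), tt_min = rnorm(1000))
  c2 <- correlation_rt_tt(rec2)
  expect_lt(abs(c2$r), 0.1)
  expect_gt(c2$p, 0.01)
  rec3 <- data.frame(rt_min = c(5, 9, 12, 7, 14, 21),
                     tt_min = c(11, 13, 25, 9, 30, 41))
  expect_equal(correlation_rt_tt(rec3)$r,
               pearson_by_hand(rec3$rt_min, rec3$tt_min), tolerance = 1e-12)
  expect_error(correlation_rt_tt(data.frame(rt_min = c(1, 1, 1),
                                            tt_min = c(1, 2, 3))),
               "zero variance")
})

test_that("ANOVA by area type: degenerate, two-group and hand-worked cases", {
  # three identical groups -> F = 0, all Tukey p = 1
  v <- rep(c(1, 2, 3, 4), 3)
  ty <- rep(c("urban", "densely_populated", "rural"), each = 4)
  a0 <- anova_by_area_type(v, ty)
  expect_equal(a0$F, 0)
  expect_equal(a0$tukey$p_adj, rep(1, 3))

  # two groups: F equals the pooled-variance t statistic squared
  set.seed(9)
  x <- rnorm(14, 10, 2); y <- rnorm(11, 12, 2)
  a2 <- anova_by_area_type(c(x, y), rep(c("g1", "g2"), c(14, 11)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-8)

  # 12-observation example checked against the explicit decomposition
  vals <- c(7.1, 6.8, 7.9, 8.2, 9.5, 9.1, 10.2, 8.8, 12.0, 13.1, 11.4, 12.6)
  grp <- rep(c("urban", "dense", "rural"), each = 4)
  a3 <- anova_by_area_type(vals, grp)
  gm <- tapply(vals, grp, mean)
  ssb <- sum(4 * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(a3$F, f_hand, tolerance = 1e-8)
  expect_equal(a3$df_between, 2)
  expect_equal(a3$df_within, 9)
  expect_equal(a3$p, pf(f_hand, 2, 9, lower.tail = FALSE), tolerance = 1e-8)
  # Tukey adjusted p from the studentized range distribution, by hand
  mse <- ssw / 9
  for (i in seq_len(nrow(a3$tukey))) {
    pr <- strsplit(a3$tukey$pair[i], "-")[[1]]
    q <- abs(gm[[pr[1]]] - gm[[pr[2]]]) / sqrt(mse / 2 * (1 / 4 + 1 / 4))
    expect_equal(a3$tukey$p_adj[i], ptukey(q, 3, 9, lower.tail = FALSE),
                 tolerance = 1e-8)
  }

  expect_error(anova_by_area_type(c(1, 2, 3), c("a", "a", "b")),
               "fewer than 2 observations: b")
})

test_that("Tukey separates all area types under a strong configured contrast", {
  region <- generate_region(region_config(seed = 23, n_areas = 600))
  rec <- compute_access(region$network, region$stations, region$hospitals,
                        region$areas)
  d <- merge(rec, region$areas[, c("area_id", "area_type")], by = "area_id")
  a <- anova_by_area_type(d$rt_min, d$area_type)
  expect_lt(a$p, 0.01)
  expect_true(all(a$tukey$p_adj < 0.05))
  means <- setNames(a$groups$mean, a$groups$group)
  expect_gt(means["rural"], means["densely_populated"])
  expect_gt(means["densely_populated"], means["urban"])
})

test_that("NB fit handles the degenerate constant-response case", {
  d <- data.frame(y = rep(7, 200))
  m <- fit_nb(y ~ 1, d)
  expect_equal(m$coefficients$estimate[1], log(7), tolerance = 1e-6)
  expect_lt(m$alpha, 1e-4) # dispersion at the Poisson boundary
})

test_that("NB fit with tiny fixed dispersion matches Poisson regression", {
  set.seed(71)
  n <- 500
  d <- data.frame(x = rnorm(n), z = rbinom(n, 1, 0.4))
  d$y <- rpois(n, exp(1 + 0.5 * d$x - 0.7 * d$z))
  nb <- fit_nb(y ~ x + z, d, alpha = 1e-8)
  po <- glm(y ~ x + z, data = d, family = poisson())
  expect_equal(nb$coefficients$estimate, unname(coef(po)), tolerance = 1e-4)
})

test_that("NB fit recovers NB2 generating parameters and reports valid fit stats", {
  set.seed(29)
  n <- 2000
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta <- c(2.0, 0.8, -0.9)
  mu <- exp(beta[1] + beta[2] * d$x1 + beta[3] * d$x2)
  d$y <- rnbinom(n, size = 1 / 0.2, mu = mu)
  m <- fit_nb(y ~ x1 + x2, d)
  ci_lo <- m$coefficients$estimate - 1.96 * m$coefficients$se
  ci_hi <- m$coefficients$estimate + 1.96 * m$coefficients$se
  expect_true(all(beta >= ci_lo - 0.05 & beta <= ci_hi + 0.05))
  expect_equal(m$alpha, 0.2, tolerance = 0.05)
  # information criteria identities (k includes intercept and dispersion)
  expect_equal(m$aic, 2 * m$k - 2 * m$log_likelihood, tolerance = 1e-12)
  expect_equal(m$bic, m$k * log(m$n) - 2 * m$log_likelihood, tolerance = 1e-12)
  expect_equal(m$k, 4)
  expect_true(all(m$coefficients$p >= 0 & m$coefficients$p <= 1))
  # rank-deficient design rejected with the collinear terms named
  d$x3 <- d$x1
  expect_error(fit_nb(y ~ x1 + x3, d), "rank-deficient")
  expect_error(fit_nb(y ~ x1, transform(d, y = y - 100)), "nonnegative")
})

test_that("income rescaling only rescales the income coefficient", {
  region <- generate_region(region_config(seed = 37, n_areas = 400))
  rec <- compute_access(region$network, region$stations, region$hospitals,
                        region$areas)
  m_raw <- fit_disparity_models(region$areas, rec, "tpt")
  m_thd <- fit_disparity_models(region$areas, rec, "tpt",
                                income_scale = 1 / 1000)
  raw <- setNames(m_raw$coefficients$estimate, m_raw$coefficients$term)
  thd <- setNames(m_thd$coefficients$estimate, m_thd$coefficients$term)
  expect_equal(thd[["median_income"]], raw[["median_income"]] * 1000,
               tolerance = 1e-6)
  other <- setdiff(names(raw), "median_income")
  expect_equal(thd[other], raw[other], tolerance = 1e-8)
})

test_that("disparity models build the documented design", {
  region <- generate_region(region_config(seed = 44, n_areas = 300))
  rec <- compute_access(region$network, region$stations, region$hospitals,
                        region$areas)
  m <- fit_disparity_models(region$areas, rec, "rt", with_interaction = TRUE)
  terms <- m$coefficients$term
  expect_true("older_share:rural" %in% terms || "rural:older_share" %in% terms)
  expect_true(any(grepl("^region", terms)))
  # urban is the reference: no 'urban' term appears
  expect_false(any(grepl("urban", terms)))
  q5 <- fit_disparity_models(region$areas, rec, "rt", subset = "quintile5")
  expect_equal(q5$n, nrow(rec) %/% 5)
})
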