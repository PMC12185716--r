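test_that("intercept-only NB fit recovers the sample mean exactly", {
  d <- data.frame(y = rep(c(1L, 2L, 3L), times = 10))
  f <- fit_nb_glm(y ~ 1, d)
  expect_equal(exp(coef(f)[["(Intercept)"]]), mean(d$y), tolerance = 1e-8)
  expect_s3_class(f, "cdnm_fit")
  ci <- confint(f)
  expect_true(ci[1, 1] < coef(f)[1] && coef(f)[1] < ci[1, 2])
})

test_that("NB fit guards degenerate inputs", {
  expect_error(fit_nb_glm(y ~ 1, data.frame(y = rep(0L, 20))), "all-zero")
  expect_error(fit_nb_glm(y ~ 1, data.frame(y = c(1.5, 2, 2, 2, 1, 1, 2, 1, 2, 1))),
               "integer")
  expect_error(fit_nb_glm(y ~ 1, data.frame(y = 1:5)), "too few")
  d <- data.frame(y = rpois(20, 5), x = 1, z = 2)
  expect_error(fit_nb_glm(y ~ x + z, d), "rank deficient")
})

test_that("dispersion estimate grows without bound on Poisson data", {
  set.seed(8)
  d <- data.frame(y = rpois(2000, 5))
  f <- fit_nb_glm(y ~ 1, d)
  expect_gt(f$theta, 100)
  # NB log-likelihood at the fit is no worse than at the Poisson solution
  expect_gte(f$loglik,
             sum(dnbinom(d$y, mu = mean(d$y), size = f$theta, log = TRUE)) - 1e-6)
})

test_that("paternal age effect converts the log slope to both scales", {
  fake <- structure(list(coefficients = data.frame(
    term = "father_age", estimate = log(1.02), se = 0.001,
    ci_lo = log(1.02) - 0.002, ci_hi = log(1.02) + 0.002, p_value = 0)),
    class = "cdnm_fit")
  ae <- paternal_age_effect(fake, ref_count = 70)
  expect_equal(ae$percent_per_year, 2.0, tolerance = 1e-9)
  expect_equal(ae$dnms_per_year, 70 * 0.02, tolerance = 1e-9)
  fake$coefficients$estimate <- 0.02
  expect_equal(paternal_age_effect(fake)$percent_per_year,
               100 * (exp(0.02) - 1), tolerance = 1e-12)
  fake$coefficients$estimate <- 0
  expect_equal(paternal_age_effect(fake)$percent_per_year, 0)
  expect_error(paternal_age_effect(fake, term = "nope"), "no coefficient")
})

test_that("simulated age effect is recovered within the Wald CI", {
  set.seed(15)
  age <- runif(500, 20, 45)
  mu <- 70 * exp(log(1.02) * (age - 30))
  d <- data.frame(n = rnbinom(500, mu = mu, size = 50), father_age = age)
  f <- fit_nb_glm(n ~ father_age, d)
  ci <- confint(f, "father_age")
  expect_true(ci[1] < log(1.02) && log(1.02) < ci[2])
})

test_that("Bonferroni adjustment caps and scales", {
  expect_equal(bonferroni_adjust(0.005, 9), 0.045)
  expect_equal(bonferroni_adjust(0.2, 9), 1)
  expect_equal(bonferroni_adjust(0, 9), 0)
  p <- sort(runif(10))
  adj <- bonferroni_adjust(p, 9)
  expect_true(all(adj >= p) && all(adj <= 1) && all(diff(adj) >= 0))
})

test_that("Clopper-Pearson interval matches binom.test and handles edges", {
  cp <- clopper_pearson(37, 163)
  bt <- binom.test(37, 163)
  expect_equal(cp$lower, bt$conf.int[1], tolerance = 1e-10)
  expect_equal(cp$upper, bt$conf.int[2], tolerance = 1e-10)
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_error(clopper_pearson(11, 10), "k <= n")
  set.seed(30)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    cp <- clopper_pearson(k, n)
    bt <- binom.test(k, n)
    expect_equal(c(cp$lower, cp$upper), as.numeric(bt$conf.int), tolerance = 1e-10)
  }
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(99)
  for (p in c(0.05, 0.23, 0.5)) {
    n <- 60
    k <- rbinom(3000, n, p)
    cover <- vapply(k, function(ki) {
      cp <- clopper_pearson(ki, n)
      cp$lower <= p && p <= cp$upper
    }, logical(1))
    expect_gte(mean(cover), 0.95 - 0.01)
  }
})

test_that("descriptive statistics and PPV adjustment", {
  x <- c(0, 1, 1, 2)
  d <- descriptive_stats(x, ppv = 0.23)
  expect_equal(d$mean, 1)
  expect_equal(d$sd, sd(x))
  expect_equal(d$median, 1)
  expect_equal(d$ppv_adjusted_mean, 0.23)
  d2 <- descriptive_stats(c(1, 2, 3), ppv = 1)
  expect_equal(d2$ppv_adjusted_mean, d2$mean)
  g <- descriptive_stats(c(1, 2, 5, 6), group = c("a", "a", "b", "b"), ppv = 0.5)
  expect_equal(g$group, c("a", "b"))
  expect_equal(g$ppv_adjusted_mean, c(0.75, 2.75))
  expect_error(descriptive_stats(numeric(0)), "empty")
})

test_that("cohort contrast model reports adjusted p per non-reference level", {
  set.seed(44)
  n <- 150
  d <- data.frame(
    cohort = rep(c("ctrl", "caseA", "caseB"), each = n),
    father_age = rnorm(3 * n, 30, 4)
  )
  mu <- c(ctrl = 1, caseA = 2, caseB = 3)[d$cohort]
  d$n_cdnm <- rnbinom(3 * n, mu = mu, size = 2)
  cc <- cohort_contrast_model(d, ref_level = "ctrl")
  expect_setequal(cc$contrasts$group, c("caseA", "caseB"))
  expect_equal(cc$contrasts$p_adj,
               pmin(1, 9 * cc$contrasts$p_nom))
  expect_equal(cc$alpha_adjusted, 0.05 / 9)
  expect_true(all(cc$contrasts$rate_ratio > 1))
  expect_error(cohort_contrast_model(data.frame(cohort = "a", n_cdnm = 1,
                                                father_age = 30)),
               "two levels")
})

test_that("dose-response model restricts to exposed offspring and errors on
           degenerate designs", {
  set.seed(55)
  n <- 400
  dose <- rexp(n, 1 / 365)
  d <- data.frame(dose = c(dose, rep(0, 50)),
                  n_cdnm = c(rnbinom(n, mu = 1.55 * exp(5e-4 * dose), size = 2),
                             rnbinom(50, mu = 1.55, size = 2)))
  dr <- dose_response_model(d)
  expect_equal(dr$n, n)  # dose-0 rows dropped
  expect_true(dr$beta$ci_lo < 5e-4 && 5e-4 < dr$beta$ci_hi)
  expect_true(dr$baseline$ci_lo < 1.55 && 1.55 < dr$baseline$ci_hi)

  d0 <- data.frame(dose = rep(100, 30), n_cdnm = rnbinom(30, mu = 2, size = 2))
  expect_error(dose_response_model(d0), "no variation")
  expect_error(dose_response_model(d[1:5, ]), "retained")
})

test_that("inverse dose model finds signal only when present", {
  set.seed(66)
  d_null <- data.frame(dose = rexp(300, 1 / 100),
                       n_cdnm = rnbinom(300, mu = 2, size = 2))
  f0 <- inverse_dose_model(d_null)
  p0 <- f0$coefficients$p_value[f0$coefficients$term == "n_cdnm"]
  expect_gt(p0, 0.05)
  d_sig <- data.frame(n_cdnm = rpois(300, 3))
  d_sig$dose <- 100 * d_sig$n_cdnm + 1
  f1 <- inverse_dose_model(d_sig)
  row <- f1$coefficients[f1$coefficients$term == "n_cdnm", ]
  expect_lt(row$p_value, 0.001)
  expect_gt(row$estimate, 0)
  expect_error(inverse_dose_model(data.frame(dose = rexp(20, 1), n_cdnm = 1)),
               "constant")
})

test_that("binomial thinning preserves the expected mean and ppv=1 is exact", {
  set.seed(77)
  n <- 120
  d <- data.frame(cohort = rep(c("ctrl", "case"), each = n),
                  father_age = rnorm(2 * n, 30, 4),
                  n_cdnm = rnbinom(2 * n, mu = rep(c(1, 3), each = n), size = 2))
  s1 <- ppv_thinning_simulation(d, ref_level = "ctrl", ppv = 1, reps = 5,
                                seed = 1)
  expect_equal(unique(s1$p_values), s1$unthinned$p_adj)
  expect_equal(unique(s1$estimates), s1$unthinned$estimate)

  s <- ppv_thinning_simulation(d, ref_level = "ctrl", ppv = 0.4, reps = 50,
                               seed = 2)
  expect_equal(s$n_failed, 0L)
  # thinning shrinks counts but not the log rate ratio in expectation
  expect_equal(median(s$estimates), s$unthinned$estimate, tolerance = 0.35)
})
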