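# person-wave analysis frame with oracle predictors merged in
oracle_frame <- function(sim) {
  tp <- sim$truth$persons[, c("person_id", "z_u", "z_s")]
  d <- merge(sim$cohort, tp, by = "person_id", sort = FALSE)
  d$female <- as.numeric(d$sex == "female")
  d
}

test_that("degenerate nesting: zero random-effect variances reduce to OLS", {
  # a realization where both variance components sit at the boundary, so
  # the mixed-model GLS weights collapse to OLS weights exactly
  sim <- simulate_cohort(sim_config(seed = 2, n_families = 150,
                                    n_snps = 40, missing_rate = 0,
                                    var_family = 0, var_person = 0,
                                    var_wave = 25, gwas_noise_sd = 0))
  d <- oracle_frame(sim)
  f <- pvt_score ~ z_u + z_s + age + female + us_born + english_home +
    hispanic + in_school
  fit <- fit_lmm(f, d)
  ols <- lm(f, data = d)
  expect_lt(fit$varcomp[["family"]] + fit$varcomp[["person"]], 1e-8)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("three-level fits report family/person/wave variance components", {
  sim <- simulate_cohort(tiny_config(seed = 22))
  d <- oracle_frame(sim)
  fit <- fit_lmm(pvt_score ~ z_u + z_s, d)
  expect_named(fit$varcomp, c("family", "person", "wave"))
  expect_true(all(fit$varcomp >= 0))
  expect_true(is.finite(fit$m2ll))
  expect_equal(fit$n_obs, nrow(d))

  # two-level (conditional) variant: residual plays the person role
  w3 <- wave3_conditional_data(d)
  fit2 <- fit_lmm(pvt_w3 ~ pvt_w1 + z_u, w3, random = "family_id")
  expect_named(fit2$varcomp, c("family", "person"))
  # lag coefficient positive: wave-1 score predicts wave-3 score
  expect_gt(coef(fit2)[["pvt_w1"]], 0)

  # collinear designs fail loudly, naming the offending column
  d$dup <- d$z_u
  expect_error(fit_lmm(pvt_score ~ z_u + dup, d), "collinear.*dup")
})

test_that("adding a predictor never worsens ML -2LL, and OLS R2 is monotone", {
  sim <- simulate_cohort(tiny_config(seed = 23))
  d <- oracle_frame(sim)
  f0 <- fit_lmm(pvt_score ~ z_s, d, method = "ML")
  f1 <- fit_lmm(pvt_score ~ z_s + z_u, d, method = "ML")
  expect_lte(f1$m2ll, f0$m2ll + 1e-6)
  expect_gte(f1$ols_r2, f0$ols_r2 - 1e-12)

  lt <- lrt(f0, f1)
  expect_equal(lt$df, 1)
  expect_gte(lt$statistic, 0)
})

test_that("likelihood-ratio mechanics on published-style summaries", {
  # printed-fit worked example: -2LL 67,064 (df 22) vs 67,058 (df 24)
  res <- lrt(c(67064, 22), c(67058, 24))
  expect_equal(res$statistic, 6)
  expect_equal(res$df, 2)
  expect_gt(res$statistic, qchisq(0.95, 2))   # 5.991: rejected at 5%
  expect_lt(res$p_value, 0.05)

  same <- lrt(c(100, 3), c(100, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(lrt(c(100, 5), c(101, 7)), "nesting violation")
  expect_error(lrt(c(100, 7), c(90, 5)), "nesting violation")

  sim <- simulate_cohort(tiny_config(seed = 24))
  d <- oracle_frame(sim)
  r1 <- fit_lmm(pvt_score ~ z_s, d, method = "REML")
  r2 <- fit_lmm(pvt_score ~ z_s + z_u, d, method = "REML")
  expect_error(lrt(r1, r2), "REML")
})

test_that("companion OLS R2 behaves as a coefficient of determination", {
  set.seed(11)
  d <- data.frame(x = rnorm(200))
  d$y <- 2 * d$x - 1                       # exact linear response
  expect_equal(suppressWarnings(ols_r2(y ~ x, d)), 1, tolerance = 1e-12)

  d2 <- data.frame(x = rnorm(10000), y = rnorm(10000))
  expect_lt(ols_r2(y ~ x, d2), 0.01)       # null design

  d3 <- d2; d3$x <- d2$x * 1000            # scale invariance
  expect_equal(ols_r2(y ~ x, d3), ols_r2(y ~ x, d2), tolerance = 1e-12)

  d4 <- data.frame(x = 1:5, y = rep(3, 5))
  expect_error(ols_r2(y ~ x, d4), "zero response variance")
})

test_that("G x E fit is invariant to recentering of the SES score", {
  sim <- cached("gxe_sim", simulate_cohort(
    sim_config(seed = 25, n_families = 400, n_snps = 60,
               missing_rate = 0, gwas_noise_sd = 0)))
  d <- oracle_frame(sim)
  d$pgs_edu_z <- d$z_u
  d$pgs_iq_z <- d$z_u * 0.5 + truth_of(sim, "v_person", d$person_id) * 0.01
  d$ses_pc <- d$z_s

  g1 <- fit_gxe(d, covariates = c("age", "female"))
  d2 <- d; d2$ses_pc <- d$ses_pc + 10      # recentering
  g2 <- fit_gxe(d2, covariates = c("age", "female"))
  expect_equal(coef(g1$interaction), coef(g2$interaction),
               tolerance = 1e-6)
  expect_equal(g1$lrt$statistic, g2$lrt$statistic, tolerance = 1e-6)

  # interaction-free generator: LRT should not scream
  expect_named(g1$lrt, c("statistic", "df", "p_value"))
  expect_equal(g1$lrt$df, 2)
})

test_that("G x E recovery: a planted interaction is detected and estimated", {
  simx <- cached("gxe_planted", simulate_cohort(
    sim_config(seed = 26, n_families = 2500, n_snps = 120,
               sibship_mix = c(singleton = 1), missing_rate = 0,
               gwas_noise_sd = 0, gxe_effect = 0.36)))
  d <- oracle_frame(simx)
  d$pgs_edu_z <- d$z_u
  d$pgs_iq_z <- 0.5 * d$z_u +
    0.5 * truth_of(simx, "v_person", d$person_id) / sd(simx$truth$persons$v_person)
  d$ses_pc <- d$z_s
  g <- fit_gxe(d, covariates = c("age", "female"))
  est <- coef(g$interaction)[[".c_pgs_edu_z:.c_ses_pc"]]
  se <- g$interaction$se[[".c_pgs_edu_z:.c_ses_pc"]]
  expect_lt(abs(est - 0.36), 3 * se)
  expect_lt(g$lrt$p_value, 0.05)
})

test_that("sibling fixed effects: demeaning identities and deconfounding", {
  sim <- cached("sib_sim", simulate_cohort(
    sim_config(seed = 27, n_families = 2000, n_snps = 80,
               sibship_mix = c(fullsib = 1), missing_rate = 0,
               gwas_noise_sd = 0)))
  d <- oracle_frame(sim)
  d$pgs_z <- d$z_u
  fe <- sibling_fe(d, predictors = "pgs_z", covariates = "female")

  # family-level constants in the response change nothing
  shift <- d
  bump <- match(shift$family_id, unique(shift$family_id)) * 2.5
  shift$pvt_score <- shift$pvt_score + bump
  fe2 <- sibling_fe(shift, predictors = "pgs_z", covariates = "female")
  expect_equal(fe2$coefficients, fe$coefficients, tolerance = 1e-8)

  # between-family confounding: pooled OLS slope is inflated by the
  # SES path, the within-family slope is not
  b_true <- sim$config$b_child
  pooled <- coef(lm(pvt_score ~ pgs_z, data = d))[["pgs_z"]]
  expect_lt(abs(fe$coefficients[["pgs_z"]] - b_true),
            abs(pooled - b_true))

  # a family with no within-pair score variance carries zero weight:
  # removing it leaves the estimate untouched
  persons <- d[!duplicated(d$person_id), ]
  fam_var <- tapply(persons$pgs_z, persons$family_id, var)
  d_const <- d
  target_fam <- names(fam_var)[1]
  d_const$pgs_z[d_const$family_id == target_fam] <- 1.23
  fe_with <- sibling_fe(d_const, predictors = "pgs_z",
                        covariates = "female")
  fe_without <- sibling_fe(
    d_const[d_const$family_id != target_fam, ],
    predictors = "pgs_z", covariates = "female")
  expect_equal(fe_with$coefficients[["pgs_z"]],
               fe_without$coefficients[["pgs_z"]], tolerance = 1e-8)

  dd <- d
  dd$pgs_z <- ave(dd$pgs_z, dd$family_id)   # no within-family variance
  expect_error(sibling_fe(dd, predictors = "pgs_z"), "within-family")
})

test_that("Falconer arithmetic and twin correlations from the cohort", {
  expect_equal(falconer_h2(0.50, 0.31)$h2, 0.38)
  expect_equal(falconer_h2(0.4, 0.4)$h2, 0)
  expect_equal(falconer_h2(1, 0.5)$h2, 1)
  expect_equal(falconer_h2(0.2, 0.5)$h2, 0)    # truncated at zero
  expect_error(falconer_h2(1.2, 0.3), "\\[-1, 1\\]")

  sim <- small_sim()
  ts <- twin_summary(sim$cohort)
  expect_gte(ts$n_mz_pairs, 2)
  expect_gte(ts$n_dz_pairs, 2)
  expect_true(ts$h2 >= 0 && ts$h2 <= 1)
  # genetically identical twins correlate at least as much as DZ twins
  # in a model with family-shared environment and genetic effects
  expect_gte(ts$r_mz, ts$r_dz - 0.2)
})
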