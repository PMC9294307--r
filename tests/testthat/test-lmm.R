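# simulated longitudinal index data with a planted structure
sim_lmm_data <- function(seed, n_part = 13, n_sess = 4, beta_time = 0,
                         beta_hemi = 0, icc_sd = 1, resid_sd = 1) {
  set.seed(seed)
  d <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_part)),
                   session = seq_len(n_sess),
                   hemisphere = c("left", "right"),
                   stringsAsFactors = FALSE)
  d$time_bin <- factor(time_bin_levels[d$session], levels = time_bin_levels)
  b <- rnorm(n_part, sd = icc_sd)
  names(b) <- sprintf("p%02d", seq_len(n_part))
  cov_tab <- data.frame(participant_id = sprintf("p%02d", seq_len(n_part)),
                        age_ci1 = runif(n_part, 1, 5),
                        inter_implant_delay = runif(n_part, 7, 14))
  d <- merge(d, cov_tab, by = "participant_id")
  d$value <- b[d$participant_id] + beta_time * d$session +
    beta_hemi * (d$hemisphere == "right") + rnorm(nrow(d), sd = resid_sd)
  d
}

test_that("REML fits recover planted fixed effects with honest intervals", {
  covered <- logical(60)
  for (i in seq_along(covered)) {
    d <- sim_lmm_data(1000 + i, beta_time = 0.5)
    fit <- fit_lmm(d, "value", "session + hemisphere")
    est <- lme4::fixef(fit$model)["session"]
    se <- sqrt(diag(as.matrix(vcov(fit$model)))["session"])
    covered[i] <- abs(est - 0.5) <= 1.96 * se
  }
  expect_gte(mean(covered), 0.90)
})

test_that("variance components sit at the boundary when truly zero", {
  d <- sim_lmm_data(7, icc_sd = 0)
  fit <- fit_lmm(d, "value", "hemisphere")
  v <- fit$variance_components
  expect_lt(v$variance[v$term == "intercept (participant)"], 0.05)
  expect_true(all(v$variance >= 0))
})

test_that("duplicating every row leaves fixed effects unchanged", {
  d <- sim_lmm_data(8, beta_hemi = 0.7)
  f1 <- fit_lmm(d, "value", "hemisphere")
  f2 <- fit_lmm(rbind(d, d), "value", "hemisphere")
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f2$model),
               tolerance = 1e-6)
})

test_that("model fits are invariant to row order and participant relabelling", {
  d <- sim_lmm_data(9, beta_time = 0.3)
  f1 <- fit_lmm(d, "value", "session")
  d_shuf <- d[sample(nrow(d)), ]
  f2 <- fit_lmm(d_shuf, "value", "session")
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f2$model),
               tolerance = 1e-8)
  d_rel <- d
  d_rel$participant_id <- chartr("p", "q", d$participant_id)
  f3 <- fit_lmm(d_rel, "value", "session")
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f3$model),
               tolerance = 1e-8)
})

test_that("Type-III F tests are calibrated under the null and powered under effects", {
  pvals <- numeric(150)
  sig <- logical(30)
  for (i in seq_along(pvals)) {
    d <- sim_lmm_data(2000 + i, beta_hemi = 0)
    fit <- fit_lmm(d, "value", "hemisphere", covariates = character(0))
    a <- anova_table(fit)
    pvals[i] <- a$p[a$term == "hemisphere"]
  }
  expect_lt(mean(pvals < 0.05), 0.05 + 0.05)
  expect_gt(mean(pvals < 0.05), 0.05 - 0.045)
  for (i in seq_along(sig)) {
    d <- sim_lmm_data(3000 + i, beta_hemi = 1.5)
    a <- anova_table(fit_lmm(d, "value", "hemisphere",
                             covariates = character(0)))
    sig[i] <- a$p[a$term == "hemisphere"] < 0.05
  }
  expect_gte(mean(sig), 0.95)
  # degenerate single-level factor is dropped with a warning, not an error
  d1 <- sim_lmm_data(4)
  d1$hemisphere <- "left"
  expect_warning(f <- fit_lmm(d1, "value", "session + hemisphere"),
                 "single-level")
  expect_false("hemisphere" %in% anova_table(f)$term)
})

test_that("estimated marginal means reduce to cell means in balanced designs", {
  d <- sim_lmm_data(21, beta_hemi = 1)
  fit <- fit_lmm(d, "value", "hemisphere", covariates = character(0))
  emm <- estimated_marginal_means(fit, "hemisphere")
  cells <- tapply(d$value, d$hemisphere, mean)
  expect_equal(emm$emmean, as.numeric(cells[emm$hemisphere]),
               tolerance = 1e-6)
  # translation equivariance
  d2 <- d; d2$value <- d$value + 5
  emm2 <- estimated_marginal_means(
    fit_lmm(d2, "value", "hemisphere", covariates = character(0)),
    "hemisphere")
  expect_equal(emm2$emmean, emm$emmean + 5, tolerance = 1e-6)
  expect_error(estimated_marginal_means(fit, "age_ci1"), "usage error")
})

test_that("Tukey contrasts reduce to the plain test for two levels and are monotone", {
  d <- sim_lmm_data(22, beta_hemi = 0.8)
  fit <- fit_lmm(d, "value", "hemisphere", covariates = character(0))
  pr <- pairwise_contrasts(fit, "hemisphere")
  expect_equal(nrow(pr), 1L)
  em_kr <- emmeans::emmeans(fit$model, "hemisphere",
                            lmer.df = attr(pr, "df_method"))
  un <- as.data.frame(emmeans::contrast(em_kr, "pairwise", adjust = "none"))
  expect_equal(pr$p_adjusted, un$p.value, tolerance = 1e-8)
  # three levels: every Tukey-adjusted p is >= its unadjusted counterpart
  d3 <- sim_lmm_data(23)
  d3$grp <- sample(c("a", "b", "c"), nrow(d3), replace = TRUE)
  fit3 <- fit_lmm(d3, "value", "grp", covariates = character(0))
  pr3 <- pairwise_contrasts(fit3, "grp")
  em3 <- emmeans::emmeans(fit3$model, "grp")
  un3 <- as.data.frame(emmeans::contrast(em3, "pairwise", adjust = "none"))
  expect_true(all(pr3$p_adjusted >= un3$p.value - 1e-10))
})

test_that("family-wise error of Tukey contrasts stays near the nominal level", {
  fwe <- logical(120)
  for (i in seq_along(fwe)) {
    d <- sim_lmm_data(5000 + i, n_sess = 3)
    d$grp <- c("a", "b", "c")[d$session]  # three equal-mean levels
    d$value <- d$value - 0  # no group effect beyond random structure
    d$session <- NULL
    fit <- fit_lmm(d, "value", "grp", covariates = character(0))
    pr <- pairwise_contrasts(fit, "grp")
    fwe[i] <- any(pr$p_adjusted < 0.05)
  }
  expect_lte(mean(fwe), 0.05 + 0.05)
})

test_that("predictor models report marginal F tests and honest diagnostics", {
  d <- sim_lmm_data(31)[1:26, ]
  d$outcome <- d$value
  fit <- suppressWarnings(fit_predictor_model(d, "outcome", "value",
                                              covariates = character(0)))
  expect_equal(fit$r_squared, 1)
  # planted negative slope is recovered in sign essentially always
  neg <- logical(60)
  for (i in seq_along(neg)) {
    set.seed(6000 + i)
    dd <- data.frame(delay = runif(13, 7, 14), age_ci1 = runif(13, 1, 5))
    dd$repr <- 10 - 5 * dd$delay + rnorm(13, sd = 6)
    f <- fit_predictor_model(dd, "repr", "delay",
                             covariates = "age_ci1")
    neg[i] <- coef(f$model)["delay"] < 0
  }
  expect_gte(mean(neg), 0.95)
  # null predictor rejects at about the nominal rate
  p0 <- numeric(150)
  for (i in seq_along(p0)) {
    set.seed(7000 + i)
    dd <- data.frame(x = rnorm(20), y = rnorm(20))
    f <- fit_predictor_model(dd, "y", "x", covariates = character(0))
    p0[i] <- f$terms$p[f$terms$term == "x"]
  }
  expect_lt(mean(p0 < 0.05), 0.05 + 0.05)
  # exact collinearity is a named error
  dd <- data.frame(y = rnorm(10), x1 = 1:10)
  dd$x2 <- dd$x1
  expect_error(fit_predictor_model(dd, "y", c("x1", "x2"),
                                   covariates = character(0)),
               "collinear|rank")
})
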