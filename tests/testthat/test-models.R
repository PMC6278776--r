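# A small linear cohort generator on the transformed scale: log10(si) =
# b0 + b1*epal + b2*as + noise.
sim_linear_cohort <- function(n, beta, sd) {
  epal <- runif(n, 100, 750)
  as <- runif(n, 20, 60)
  data.frame(patient_id = sprintf("L%03d", seq_len(n)),
             epal = epal, as = as,
             si = 10^(beta[1] + beta[2] * epal + beta[3] * as +
                        rnorm(n, 0, sd)))
}

test_that("noiseless cohorts return the generating coefficients exactly", {
  set.seed(1)
  beta <- c(0.8, 0.0015, 0.006)
  co <- sim_linear_cohort(40, beta, 0)
  fit <- fit_model(default_model_specs()$M8, co)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("permuting the response drives R^2 to its null level", {
  set.seed(2)
  co <- sim_linear_cohort(50, c(0.8, 0.0015, 0.006), 0.05)
  r2 <- replicate(200, {
    co$si <- sample(co$si)
    fit_model(default_model_specs()$M8, co)$r_squared
  })
  # E[R^2] under the null is p/(n-1) for p regressors
  expect_equal(mean(r2), 2 / 49, tolerance = 0.35)
  expect_lt(mean(r2), 0.1)
})

test_that("standardized residuals have mean 0 and SD 1 to 1e-9", {
  set.seed(3)
  co <- sim_linear_cohort(60, c(0.8, 0.0015, 0.006), 0.08)
  fit <- fit_model(default_model_specs()$M8, co)
  expect_lt(abs(mean(fit$std_residuals)), 1e-9)
  expect_lt(abs(sd(fit$std_residuals) - 1), 1e-9)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)

  # invariant to affine rescaling of predictors
  co2 <- co
  co2$epal <- co2$epal * 3 + 100
  co2$as <- co2$as / 7 - 2
  fit2 <- fit_model(default_model_specs()$M8, co2)
  expect_equal(fit2$std_residuals, fit$std_residuals, tolerance = 1e-8)
})

test_that("expected values invert the response transform", {
  set.seed(4)
  co <- sim_linear_cohort(30, c(0.8, 0.0015, 0.006), 0.05)
  fit <- fit_model(default_model_specs()$M8, co)
  # dot-product oracle on 10 random subjects
  for (i in sample(30, 10)) {
    lp <- sum(fit$coefficients * c(1, co$epal[i], co$as[i]))
    expect_equal(predict_expected(fit, co[i, ]), 10^lp)
  }
  # OLS passes through the means
  mid <- data.frame(epal = mean(co$epal), as = mean(co$as))
  expect_equal(log10(predict_expected(fit, mid)),
               mean(log10(co$si)), tolerance = 1e-10)
  expect_error(predict_expected(fit, data.frame(epal = 300)),
               "missing predictor")
})

test_that("fixed-coefficient specs predict without fitting", {
  spec <- model_spec("M8", "si", "log10", c("epal", "as"),
                     fixed_coefficients = c(1, 0.001, 0.01))
  nd <- data.frame(epal = 400, as = 50)
  co <- data.frame(epal = c(300, 400, 500, 350), as = c(30, 40, 50, 45),
                   si = c(80, 120, 200, 100))
  fit <- fit_model(spec, co)
  expect_equal(unname(fit$coefficients), c(1, 0.001, 0.01))
  expect_equal(predict_expected(fit, nd), 10^(1 + 0.4 + 0.5))
})

test_that("model fitting validates its inputs", {
  co <- data.frame(patient_id = c("a", "b", "c", "d"),
                   epal = c(1, 2, 3, 4) * 100, as = c(30, 40, 50, 60),
                   si = c(50, -1, 70, 90))
  expect_error(fit_model(default_model_specs()$M8, co),
               "non-positive response.*b")
  co$si <- abs(co$si)
  co$as <- co$epal / 10  # collinear
  expect_error(fit_model(default_model_specs()$M8, co), "rank-deficient")
  expect_error(fit_model(default_model_specs()$M8, co[1:3, ]),
               "at least 4")
})

test_that("parameter recovery stays within 3 SE for simulated cohorts", {
  set.seed(6)
  beta <- c(0.9, 0.0012, 0.008)
  hits <- replicate(200, {
    co <- sim_linear_cohort(60, beta, 0.08)
    X <- cbind(1, co$epal, co$as)
    fit <- lm(log10(si) ~ epal + as, data = co)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    all(abs(est - beta) <= 3 * se)
  })
  expect_gte(mean(hits), 0.95)
  # and the package fit matches lm on one cohort
  co <- sim_linear_cohort(60, beta, 0.08)
  expect_equal(unname(fit_model(default_model_specs()$M8, co)$coefficients),
               unname(coef(lm(log10(si) ~ epal + as, data = co))),
               tolerance = 1e-10)
})

test_that("adding the SI residual never lowers in-sample R^2", {
  set.seed(7)
  co <- sim_linear_cohort(80, c(0.8, 0.0015, 0.006), 0.08)
  co$ao <- 10^(1.7 - 0.0004 * co$epal + rnorm(80, 0, 0.15))
  fit8 <- fit_model(default_model_specs()$M8, co)
  co <- attach_si_residual(co, fit8)
  f10 <- fit_model(default_model_specs()$M10, co)
  f11 <- fit_model(default_model_specs()$M11, co)
  expect_gte(f11$r_squared, f10$r_squared)
})

test_that("attached SI residuals keep the fit's standardization and order", {
  set.seed(8)
  co <- sim_linear_cohort(50, c(0.8, 0.0015, 0.006), 0.1)
  fit8 <- fit_model(default_model_specs()$M8, co)
  co2 <- attach_si_residual(co, fit8)
  expect_lt(abs(mean(co2$si_resid)), 1e-9)
  expect_lt(abs(sd(co2$si_resid) - 1), 1e-9)
  # a subject sitting exactly on the regression line gets (centred) zero
  on_line <- co[1, ]
  on_line$patient_id <- "online"
  on_line$si <- predict_expected(fit8, on_line)
  co3 <- rbind(co, on_line)
  fit8b <- fit_model(default_model_specs()$M8, co3)
  expect_lt(abs(fit8b$residuals[["online"]]), 0.05)
  # ranks of (observed - expected) match ranks of the residuals
  gap <- log10(co$si) - log10(predict_expected(fit8, co))
  expect_equal(rank(gap), rank(co2$si_resid), ignore_attr = TRUE)
  expect_error(attach_si_residual(data.frame(patient_id = "zz"), fit8),
               "missing from the instability fit")
})

test_that("expected increments are linear in mode and interval", {
  expect_equal(expected_increment(400, 4, coefficients = c(0, 0, 0)), 0)
  expect_equal(expected_increment(400, 4, coefficients = c(0, 0.05, 10)),
               60)
  expect_error(expected_increment(400, 4), "reference")
  # refitting on simulated reference increments recovers the coefficients
  set.seed(9)
  ref <- data.frame(mode = runif(120, 150, 800),
                    interval = runif(120, 2, 11))
  ref$observed_increment <- 5 + 0.04 * ref$mode + 9 * ref$interval +
    rnorm(120, 0, 6)
  fit <- lm(observed_increment ~ mode + interval, data = ref)
  expect_equal(expected_increment(500, 5, reference = ref),
               unname(predict(fit, data.frame(mode = 500, interval = 5))),
               tolerance = 1e-8)
})
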