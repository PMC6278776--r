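test_that("trajectories honour age and progenitor preconditions", {
  cfg <- lean_config(seed = 2)
  set.seed(1)
  pop <- simulate_trajectory(cfg, 300, 0)
  expect_equal(pop, rep(300, cfg$n_lineages))
  expect_error(simulate_trajectory(cfg, 300, -1), "non-negative")
  expect_error(simulate_trajectory(cfg, 40, 10), "at least 50")
})

test_that("stabilization slows the walk: lower mean length at same seed", {
  cfg1 <- lean_config(); cfg1$stabilization_factor <- 1
  cfg0 <- lean_config(); cfg0$stabilization_factor <- 0.3
  wins <- 0L
  means <- matrix(0, 100, 2)
  for (i in 1:100) {
    set.seed(1000 + i)
    m1 <- mean(simulate_trajectory(cfg1, 300, 40))
    set.seed(1000 + i)
    m0 <- mean(simulate_trajectory(cfg0, 300, 40))
    means[i, ] <- c(m1, m0)
    wins <- wins + (m1 > m0)
  }
  expect_equal(wins, 100L)  # strictly greater in every paired replicate
  expect_gt(t.test(means[, 1], means[, 2])$conf.int[1], 0)
})

test_that("mean length increases with age", {
  cfg <- lean_config()
  set.seed(7)
  m <- sapply(c(10, 30, 50), function(a)
    mean(replicate(40, mean(simulate_trajectory(cfg, 300, a)))))
  expect_true(all(diff(m) > 0))
})

test_that("populations are right-skewed after a decade of instability", {
  cfg <- simulation_config(seed = 1)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  set.seed(3)
  for (a in c(10, 25, 40)) {
    pop <- simulate_trajectory(cfg, 300, a)
    expect_gt(skew(pop), 0)
  }
})

test_that("small-pool sampling is a uniform subsample in the clean limit", {
  cfg <- lean_config()
  cfg$sizing_cv <- 0
  cfg$poisson_lambda <- 50
  set.seed(9)
  pop <- runif(500, 100, 800)
  obs <- sample_small_pool(pop, cfg)
  expect_gte(length(obs), cfg$min_alleles)
  expect_true(all(obs %in% pop))
  # p10 of a large observation converges on the population p10
  cfg$min_alleles <- 5000L
  big <- sample_small_pool(pop, cfg)
  expect_equal(oracle_percentile(big, 10), oracle_percentile(pop, 10),
               tolerance = 0.02)
})

test_that("undetectable molecules are censored, not resized", {
  cfg <- lean_config(seed = 1)
  cfg$sizing_cv <- 0
  set.seed(10)
  pop <- c(runif(300, 20, 49), runif(700, 60, 400))  # 30% undetectable
  obs <- sample_small_pool(pop, cfg)
  expect_true(all(obs >= cfg$min_detectable))
  # observed mean matches the conditional (above-threshold) mean
  expect_equal(mean(obs), mean(pop[pop >= cfg$min_detectable]),
               tolerance = 0.05)
  expect_error(sample_small_pool(runif(50, 10, 40), cfg),
               "below the detection limit")
})

test_that("identical seeds reproduce cohorts exactly", {
  spec <- cohort_spec(n_subjects = 5L, n_ao_missing = 1L)
  a <- generate_reference_cohort(spec, lean_config(seed = 42))
  b <- generate_reference_cohort(spec, lean_config(seed = 42))
  expect_identical(a$t1, b$t1)
  expect_identical(a$samples, b$samples)
  c2 <- generate_reference_cohort(spec, lean_config(seed = 43))
  expect_false(identical(a$t1$si, c2$t1$si))
})

test_that("study cohorts carry patterns, pairs and buccal samples", {
  cohort <- generate_study_cohort(cohort_spec(), lean_config(seed = 3),
                                  n_interrupted = 3L, n_control = 2L,
                                  n_buccal = 2L)
  expect_equal(nrow(cohort$patients), 5L)
  expect_equal(sum(cohort$patients$group == "interrupted"), 3L)
  expect_true(all(c("SIM-I1/blood/t1", "SIM-I1/blood/t2",
                    "SIM-I1/buccal/t2") %in% names(cohort$samples)))
  # interrupted subjects have a non-pure pattern and an override
  int_rows <- cohort$patients[cohort$patients$group == "interrupted", ]
  for (i in seq_len(nrow(int_rows))) {
    p <- parse_interruption_pattern(int_rows$pattern[i])
    expect_false(is_pure_pattern(p))
    expect_false(is.na(int_rows$interrupted_block_override[i]))
  }
  # metadata round-trips through the patient-table reader
  tsv <- tempfile(fileext = ".tsv")
  write.table(cohort$patients, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_patient_table(tsv)
  expect_equal(back$patient_id, cohort$patients$patient_id)
  expect_equal(back$interrupted_block_override,
               cohort$patients$interrupted_block_override)
  unlink(tsv)
})

test_that("stabilized study groups show depressed instability residuals", {
  # with f well below 1, interrupted subjects should sit below the
  # reference regression: negative median standardized residual
  cfg <- lean_config()
  set.seed(77)
  neg <- replicate(25, {
    co <- lean_cohort_t1(30, cfg, n_first = 5L, f_first = 0.3)
    fit <- fit_model(default_model_specs()$M8, co)
    median(fit$std_residuals[co$group == "interrupted"]) < 0
  })
  expect_gte(mean(neg), 0.95)
})
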