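test_that("percentiles follow the linear-interpolation convention", {
  s <- as_sample(100:109)
  expect_equal(percentile_length(s, 10), 100.9)  # h = 1.9
  expect_equal(percentile_length(s, 90), 108.1)
  expect_equal(instability_range(s), 7.2)

  deg <- as_sample(rep(300, 25))
  for (q in c(5, 10, 50, 90))
    expect_equal(percentile_length(deg, q), 300)
  expect_equal(instability_range(deg), 0)
  expect_equal(instability_range(as_sample(777)), 0)

  expect_error(percentile_length(s, 0), "between 0 and 100")
  expect_error(percentile_length(s, 100), "between 0 and 100")
})

test_that("percentile, SI and mode agree with brute-force oracles", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(2:80, 1)
    x <- switch(sample(3, 1),
                runif(n, 60, 900),
                rlnorm(n, log(300), 0.4),
                round(runif(n, 100, 400)))
    s <- as_sample(x)
    q <- runif(1, 1, 99)
    expect_equal(percentile_length(s, q), oracle_percentile(x, q))
    expect_equal(instability_range(s),
                 oracle_percentile(x, 90) - oracle_percentile(x, 10))
    expect_equal(modal_length(s, bandwidth = 0), oracle_mode(x))
  }
})

test_that("modal length rounds, smooths and breaks ties downward", {
  expect_equal(modal_length(as_sample(c(rep(445.2, 50), rep(500, 10)))),
               445)
  expect_equal(modal_length(as_sample(rep(c(200, 201), 30)),
                            bandwidth = 0), 200)
  s <- as_sample(rlnorm(400, log(350), 0.2))
  m <- modal_length(s)
  expect_true(m >= min(s$sizes) - 1 && m <= max(s$sizes) + 1)
  expect_equal(modal_length(as_sample(123.4)), 123L)
})

test_that("5' view shifts location but not spread", {
  set.seed(5)
  x <- runif(300, 200, 700)
  s <- as_sample(x)
  expect_equal(five_prime_view(s, 0)$sizes, s$sizes)
  v <- five_prime_view(s, 35)
  expect_true(v$is_five_prime_view)
  expect_equal(instability_range(v), instability_range(s))
  expect_equal(percentile_length(v, 10), percentile_length(s, 10) - 35)
  expect_equal(modal_length(v, bandwidth = 0),
               modal_length(as_sample(x - 35), bandwidth = 0))
  expect_error(five_prime_view(s, min(x)), "smaller")
  expect_error(five_prime_view(s, -1), "non-negative")
})

test_that("shift invariance holds for arbitrary constants", {
  set.seed(8)
  for (i in 1:50) {
    x <- runif(sample(5:200, 1), 150, 800)
    s <- as_sample(x)
    c0 <- runif(1, 0, min(x) - 1)
    v <- five_prime_view(s, c0)
    expect_equal(instability_range(v), instability_range(s))
    expect_equal(percentile_length(v, 10), percentile_length(s, 10) - c0)
  }
})

test_that("metrics are invariant to sample duplication", {
  set.seed(13)
  x <- runif(120, 200, 500)
  s1 <- as_sample(x)
  s3 <- as_sample(rep(x, 3))
  expect_equal(percentile_length(s1, 10), percentile_length(s3, 10),
               tolerance = 1e-2)
  expect_equal(modal_length(s1, bandwidth = 0),
               modal_length(s3, bandwidth = 0))
  expect_equal(instability_range(s1), instability_range(s3),
               tolerance = 2e-2)
})

test_that("adding a largest allele never decreases p90", {
  set.seed(21)
  for (i in 1:50) {
    x <- runif(sample(10:100, 1), 100, 600)
    bigger <- c(x, max(x) + runif(1, 1, 50))
    expect_gte(percentile_length(as_sample(bigger), 90),
               percentile_length(as_sample(x), 90))
  }
})

test_that("observed increments difference the modal lengths", {
  s1 <- summarize_sample(as_sample(c(rep(612, 150), rep(650, 60)),
                                   age = 61.5), bandwidth = 0)
  s2 <- summarize_sample(as_sample(c(rep(720, 150), rep(700, 60)),
                                   timepoint = "t2", age = 65.5),
                         bandwidth = 0)
  inc <- observed_increment(s1, s2)
  expect_equal(inc$observed_increment, 108)
  expect_equal(inc$interval, 4)

  other <- summarize_sample(as_sample(300:420, patient = "q",
                                      timepoint = "t2", age = 44),
                            bandwidth = 0)
  expect_error(observed_increment(s1, other), "same patient")
  expect_error(observed_increment(s2, s1), "ordered")
})

test_that("density export covers the sample's size range", {
  s <- as_sample(rlnorm(250, log(300), 0.3))
  d <- afd_density(s)
  expect_named(d, c("size", "density"))
  expect_true(min(d$size) < min(s$sizes) && max(d$size) > max(s$sizes))
  expect_true(all(d$density >= 0))
})
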