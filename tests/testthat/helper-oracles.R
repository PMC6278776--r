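# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: percentiles by direct sort-and-interpolate,
# Wilcoxon p-values by full enumeration.

# Sort-and-interpolate percentile at rank h = (n - 1) q/100 + 1.
oracle_percentile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q / 100 + 1
  lo <- floor(h)
  if (lo == length(s)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# Raw integer-histogram mode, smallest value on ties.
oracle_mode <- function(x) {
  r <- round(x)
  tab <- table(r)
  as.integer(names(tab)[which.max(tab)][1])
}

# Exact two-tailed signed-rank p by enumeration of all 2^n sign patterns.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  list(V = v_obs, p = p)
}

# Exact two-tailed rank-sum p by enumeration of all C(n1+n2, n1)
# assignments of the pooled sample to the first group. U is the
# Mann-Whitney count of (x, y) pairs with x > y.
oracle_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, u_of)
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(U = u_obs, p = p)
}

# Quick allele-sample construction for metric tests.
as_sample <- function(sizes, patient = "p", tissue = "blood",
                      timepoint = "t1", age = 40) {
  allele_sample(patient, tissue, timepoint, age, sizes)
}

# Lean simulation settings for Monte-Carlo-heavy tests: fewer lineages
# and molecules than the defaults, narrower age span.
lean_config <- function(seed = 1L, ...) {
  simulation_config(n_lineages = 50L, min_alleles = 80L, seed = seed, ...)
}

# Simulate a one-timepoint cohort of uninterrupted subjects and return
# the per-subject table (epal = observed p10, as, si). `f` applies to the
# first `n_first` subjects, emulating an interruption-carrier subgroup.
lean_cohort_t1 <- function(n, config, n_first = 0L, f_first = 1,
                           epal_range = c(150, 600), as_range = c(20, 50)) {
  epal <- runif(n, epal_range[1], epal_range[2])
  as1 <- runif(n, as_range[1], as_range[2])
  rows <- lapply(seq_len(n), function(i) {
    f <- if (i <= n_first) f_first else 1
    cfg <- config
    cfg$stabilization_factor <- f
    pop <- simulate_trajectory(cfg, epal[i], as1[i])
    sizes <- sample_small_pool(pop, cfg)
    p10 <- oracle_percentile(sizes, 10)
    p90 <- oracle_percentile(sizes, 90)
    data.frame(patient_id = sprintf("S%03d", i),
               group = if (i <= n_first) "interrupted" else "reference",
               epal = p10, as = as1[i], si = p90 - p10,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
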