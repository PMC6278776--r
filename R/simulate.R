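#' Configuration of the somatic-instability simulator
#'
#' The somatic process is a per-lineage compound-Poisson length walk with
#' a length-proportional event rate: each cell lineage carries a repeat
#' length that, per year, suffers Poisson(rate * f * length) mutation
#' events, each expanding (with probability 1 - contraction_fraction) or
#' contracting by a geometric step. This is the simplest process
#' consistent with somatic mosaicism that is age-dependent,
#' length-dependent and expansion-biased; it is a generative stand-in,
#' not a mechanistic claim. Repeat interruptions act as a single
#' multiplicative factor f on the event rate of the whole allele,
#' reflecting a stabilising effect in cis that extends beyond the
#' interrupted 3' part.
#'
#' @param expansion_rate mutation events per repeat per year.
#' @param contraction_fraction probability an event contracts; must be
#'   below 0.5 so the walk is expansion-biased.
#' @param step_size_mean mean event step in repeats (geometric, >= 1).
#' @param stabilization_factor rate multiplier f for interrupted alleles,
#'   0 < f <= 1 (1 = uninterrupted).
#' @param n_lineages number of independent cell lineages per tissue.
#' @param poisson_lambda mean molecules per small-pool PCR reaction
#'   (5-10 genome equivalents per reaction).
#' @param sizing_cv fractional (lognormal) gel-sizing noise per molecule.
#' @param min_detectable smallest detectable expanded allele, in repeats;
#'   also the floor of the length walk.
#' @param min_alleles molecules to accumulate per sample.
#' @param buccal_rate_factor tissue effect: event-rate multiplier for
#'   buccal relative to blood.
#' @param buccal_offset tissue effect: additive progenitor offset
#'   (repeats) for buccal lineages.
#' @param seed integer seed from which all randomness flows.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(expansion_rate = 0.02,
                              contraction_fraction = 0.3,
                              step_size_mean = 3,
                              stabilization_factor = 1,
                              n_lineages = 200L,
                              poisson_lambda = 7.5,
                              sizing_cv = 0.02,
                              min_detectable = 50,
                              min_alleles = 200L,
                              buccal_rate_factor = 0.6,
                              buccal_offset = 100,
                              seed = 1L) {
  stopifnot(expansion_rate > 0, step_size_mean >= 1, n_lineages >= 1,
            poisson_lambda > 0, sizing_cv >= 0, min_detectable > 0,
            min_alleles >= 1)
  if (contraction_fraction < 0 || contraction_fraction >= 0.5)
    stop("contraction_fraction must be in [0, 0.5): the walk is ",
         "expansion-biased")
  if (stabilization_factor <= 0 || stabilization_factor > 1)
    stop("stabilization_factor must be in (0, 1]")
  structure(as.list(environment()), class = "simulation_config")
}

# Advance a vector of lineage lengths by `years` (fractional allowed).
.evolve <- function(lengths, years, config, f = config$stabilization_factor,
                    rate = config$expansion_rate) {
  if (years < 0) stop("cannot evolve for negative time")
  m <- config$step_size_mean
  steps <- c(rep(1, floor(years)), years - floor(years))
  steps <- steps[steps > 0]
  for (dt in steps) {
    nev <- stats::rpois(length(lengths), rate * f * lengths * dt)
    nexp <- stats::rbinom(length(lengths), nev,
                          1 - config$contraction_fraction)
    ncon <- nev - nexp
    gain <- loss <- numeric(length(lengths))
    i <- nexp > 0L
    if (any(i))  # sum of k geometric steps (mean m) = NB(k) + k
      gain[i] <- stats::rnbinom(sum(i), size = nexp[i],
                                mu = nexp[i] * (m - 1)) + nexp[i]
    i <- ncon > 0L
    if (any(i))
      loss[i] <- stats::rnbinom(sum(i), size = ncon[i],
                                mu = ncon[i] * (m - 1)) + ncon[i]
    lengths <- pmax(config$min_detectable, lengths + gain - loss)
  }
  lengths
}

#' Simulate a somatic repeat-length population
#'
#' Evolves \code{n_lineages} independent cell lineages from a common
#' progenitor length for \code{age} years under the compound-Poisson
#' length walk (see \code{\link{simulation_config}}).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param progenitor_length inherited repeat length, >= 50.
#' @param age years of somatic history; 0 returns all lineages at the
#'   progenitor length.
#' @return Numeric vector of per-lineage repeat lengths.
#' @export
simulate_trajectory <- function(config, progenitor_length, age) {
  stopifnot(inherits(config, "simulation_config"))
  if (progenitor_length < 50)
    stop("progenitor_length must be at least 50 repeats (expanded range)")
  if (age < 0) stop("age must be non-negative")
  .evolve(rep(progenitor_length, config$n_lineages), age, config)
}

#' Observe a population by single-molecule small-pool PCR
#'
#' Draws small-pool reactions, each contributing Poisson(lambda)
#' molecules sampled uniformly (with replacement) from the cell
#' population, until at least \code{min_alleles} molecules have been
#' retained. Each observed size carries multiplicative lognormal sizing
#' noise with the configured coefficient of variation; sizes below the
#' detection limit are dropped.
#'
#' @param population numeric vector of cell repeat lengths.
#' @param config a \code{\link{simulation_config}}.
#' @return Numeric vector of observed allele sizes (length >=
#'   \code{min_alleles}).
#' @export
sample_small_pool <- function(population, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(population) == 0L) stop("population is empty")
  if (all(population < config$min_detectable))
    stop("population lies entirely below the detection limit")
  sdlog <- sqrt(log(1 + config$sizing_cv^2))
  out <- numeric(0)
  while (length(out) < config$min_alleles) {
    k <- stats::rpois(1L, config$poisson_lambda)
    if (k == 0L) next
    mol <- population[sample.int(length(population), k, replace = TRUE)]
    if (sdlog > 0)
      mol <- mol * stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    out <- c(out, mol[mol >= config$min_detectable])
  }
  out
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param epal_range range of progenitor allele lengths (repeats), drawn
#'   uniformly.
#' @param as_range range of ages at first sampling (years).
#' @param interval_range range of between-sampling intervals (years).
#' @param ao_coefficients numeric (intercept, ePAL slope, SI-residual
#'   slope) of the generative age-at-onset model on the log10 scale.
#' @param ao_noise_sd residual SD of log10 age at onset.
#' @param n_ao_missing subjects with missing age at onset (the
#'   asymptomatic fraction of a reference cohort).
#' @param stabilization_factor event-rate multiplier applied to
#'   interrupted subjects of a study cohort.
#' @return A list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects = 136L,
                        epal_range = c(100, 750),
                        as_range = c(20, 60),
                        interval_range = c(2, 11),
                        ao_coefficients = c(1.72, -0.00033, -0.061),
                        ao_noise_sd = 0.168,
                        n_ao_missing = 15L,
                        stabilization_factor = 0.4) {
  stopifnot(n_subjects >= 3, all(interval_range > 0), ao_noise_sd >= 0,
            n_ao_missing >= 0, n_ao_missing < n_subjects)
  structure(as.list(environment()), class = "cohort_spec")
}

# Simulate one subject's blood samples at two timepoints.
.simulate_subject <- function(id, epal, as1, interval, config, f) {
  pop1 <- .evolve(rep(epal, config$n_lineages), as1, config, f = f)
  s1 <- allele_sample(id, "blood", "t1", as1,
                      sample_small_pool(pop1, config),
                      min_alleles = config$min_alleles)
  pop2 <- .evolve(pop1, interval, config, f = f)
  s2 <- allele_sample(id, "blood", "t2", as1 + interval,
                      sample_small_pool(pop2, config),
                      min_alleles = config$min_alleles)
  list(t1 = s1, t2 = s2, pop2 = pop2)
}

#' Generate a synthetic reference cohort
#'
#' Emulates a large cohort of patients with uninterrupted expansions:
#' per subject, a progenitor length and age at sampling are drawn, the
#' somatic process is simulated and observed by small-pool PCR at two
#' timepoints, and age at onset is drawn from a log-linear model in the
#' subject's estimated progenitor length and its standardized
#' instability residual (so that individual-specific instability
#' genuinely modifies onset). Default parameters are calibrated so that
#' refitting the expected-instability model (M8) on the generated cohort
#' explains about 90 percent of the variance of log10 SI.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param config a \code{\link{simulation_config}}; its \code{seed}
#'   drives all randomness.
#' @return A list with elements \code{t1} and \code{t2} (per-timepoint
#'   cohort data frames: patient_id, group, epal, as, si, mode, ao,
#'   si_resid_true), \code{samples} (named list of
#'   \code{\link{allele_sample}} objects) and \code{increments}
#'   (observed modal increments with interval).
#' @export
generate_reference_cohort <- function(spec = cohort_spec(),
                                      config = simulation_config()) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- spec$n_subjects
  ids <- sprintf("REF%03d", seq_len(n))
  epal <- stats::runif(n, spec$epal_range[1], spec$epal_range[2])
  as1 <- stats::runif(n, spec$as_range[1], spec$as_range[2])
  interval <- stats::runif(n, spec$interval_range[1], spec$interval_range[2])

  samples <- list()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- .simulate_subject(ids[i], epal[i], as1[i], interval[i], config,
                             f = 1)
    samples[[paste(ids[i], "blood", "t1", sep = "/")]] <- sub$t1
    samples[[paste(ids[i], "blood", "t2", sep = "/")]] <- sub$t2
    sm1 <- summarize_sample(sub$t1)
    sm2 <- summarize_sample(sub$t2)
    rows[[i]] <- data.frame(
      patient_id = ids[i], group = "reference",
      epal_t1 = sm1$p10, as_t1 = as1[i], si_t1 = sm1$si, mode_t1 = sm1$mode,
      epal_t2 = sm2$p10, as_t2 = as1[i] + interval[i], si_t2 = sm2$si,
      mode_t2 = sm2$mode, interval = interval[i], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)

  # Standardized instability residual at t1 defines the subject's
  # individual-specific instability level used by the onset model.
  t1 <- data.frame(patient_id = tab$patient_id, group = tab$group,
                   epal = tab$epal_t1, as = tab$as_t1, si = tab$si_t1,
                   mode = tab$mode_t1, stringsAsFactors = FALSE)
  fit8 <- fit_model(default_model_specs()$M8, t1)
  z <- unname(fit8$std_residuals[t1$patient_id])
  b <- spec$ao_coefficients
  ao <- 10^(b[1] + b[2] * t1$epal + b[3] * z +
              stats::rnorm(n, 0, spec$ao_noise_sd))
  if (spec$n_ao_missing > 0)
    ao[sample.int(n, spec$n_ao_missing)] <- NA_real_

  t1$ao <- ao
  t1$si_resid_true <- z
  t2 <- data.frame(patient_id = tab$patient_id, group = tab$group,
                   epal = tab$epal_t2, as = tab$as_t2, si = tab$si_t2,
                   mode = tab$mode_t2, ao = ao, si_resid_true = z,
                   stringsAsFactors = FALSE)
  increments <- data.frame(patient_id = tab$patient_id, group = tab$group,
                           mode = tab$mode_t1, mode_t1 = tab$mode_t1,
                           mode_t2 = tab$mode_t2, interval = tab$interval,
                           observed_increment = tab$mode_t2 - tab$mode_t1,
                           stringsAsFactors = FALSE)
  list(t1 = t1, t2 = t2, samples = samples, increments = increments,
       spec = spec, config = config)
}

# Built-in synthetic interruption patterns for study-cohort subjects;
# block structures representative of described interrupted expansions
# (hexamer runs, a large CCG block with internal pure tracts, small CCG
# blocks, a single CTC). Overrides give the subtraction constant where
# pattern arithmetic is incomplete or superseded.
.study_patterns <- data.frame(
  pattern = c(
    "(CTG)n(CCGCTG)3(CTG)4(CCGCTG)2CTGCCG(CTG)17",
    "(CTG)n(CCGCTG)3(CTG)4(CCGCTG)2CTGCCG(CTG)17",
    "(CTG)n(CCGCTG)3(CTG)4(CCGCTG)2CTGCCG(CTG)17",
    "(CTG)n(CCG)36(CTG)nCCG(CTG)7CCG(CTG)12",
    "(CTG)n(CCG)3(CTG)6(CCG)3(CTG)7CCG(CTG)8CCG(CTG)8",
    "(CTG)n(CCG)3(CTG)6(CCG)3(CTG)7CCG(CTG)8CCG(CTG)8",
    "(CTG)nCTC(CTG)26"),
  override = c(35L, 35L, 35L, 85L, 39L, 39L, 29L),
  stringsAsFactors = FALSE)

#' Generate a synthetic study cohort
#'
#' Emulates a small clinical series: interrupted subjects whose somatic
#' event rate is reduced by the spec's stabilization factor, plus
#' uninterrupted controls (factor 1). All subjects get paired blood
#' samples; a subset also gets a buccal sample at the second timepoint
#' (tissue effect per \code{\link{simulation_config}}). The output
#' round-trips through \code{\link{read_allele_table}} /
#' \code{\link{read_patient_table}}.
#'
#' @param spec a \code{\link{cohort_spec}}; \code{n_subjects} is ignored
#'   (the group sizes below apply), its stabilization factor applies to
#'   the interrupted group.
#' @param config a \code{\link{simulation_config}}.
#' @param n_interrupted,n_control group sizes.
#' @param n_buccal how many interrupted subjects also get a buccal
#'   sample.
#' @return A list with \code{samples} (named list of allele samples),
#'   \code{patients} (metadata data frame in the
#'   \code{\link{read_patient_table}} layout), and \code{alleles} (long
#'   allele table as a data frame).
#' @export
generate_study_cohort <- function(spec = cohort_spec(),
                                  config = simulation_config(),
                                  n_interrupted = 7L, n_control = 4L,
                                  n_buccal = 4L) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(config, "simulation_config"),
            n_buccal <= n_interrupted)
  set.seed(config$seed + 1L)
  n <- n_interrupted + n_control
  ids <- c(sprintf("SIM-I%d", seq_len(n_interrupted)),
           sprintf("SIM-C%d", seq_len(n_control)))
  group <- rep(c("interrupted", "control"), c(n_interrupted, n_control))
  f <- ifelse(group == "interrupted", spec$stabilization_factor, 1)
  epal <- stats::runif(n, spec$epal_range[1], spec$epal_range[2])
  as1 <- stats::runif(n, spec$as_range[1], spec$as_range[2])
  # interrupted subjects are resampled after a shorter interval than
  # controls, as in a short prospective follow-up
  interval <- ifelse(group == "interrupted",
                     stats::runif(n, 2.5, 4),
                     stats::runif(n, spec$interval_range[1],
                                  spec$interval_range[2]))
  pat_idx <- rep_len(seq_len(nrow(.study_patterns)), n_interrupted)

  samples <- list()
  for (i in seq_len(n)) {
    sub <- .simulate_subject(ids[i], epal[i], as1[i], interval[i], config,
                             f = f[i])
    samples[[paste(ids[i], "blood", "t1", sep = "/")]] <- sub$t1
    samples[[paste(ids[i], "blood", "t2", sep = "/")]] <- sub$t2
    if (i <= n_buccal) {
      pop_b <- .evolve(rep(epal[i] + config$buccal_offset,
                           config$n_lineages),
                       as1[i] + interval[i], config, f = f[i],
                       rate = config$expansion_rate *
                         config$buccal_rate_factor)
      samples[[paste(ids[i], "buccal", "t2", sep = "/")]] <-
        allele_sample(ids[i], "buccal", "t2", as1[i] + interval[i],
                      sample_small_pool(pop_b, config),
                      min_alleles = config$min_alleles)
    }
  }

  b <- spec$ao_coefficients
  ao <- 10^(b[1] + b[2] * epal + stats::rnorm(n, 0, spec$ao_noise_sd))
  patients <- data.frame(
    patient_id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE),
    group = group,
    age_at_onset = round(pmin(ao, as1), 1),
    pattern = c(.study_patterns$pattern[pat_idx], rep("(CTG)n", n_control)),
    interrupted_block_override =
      c(.study_patterns$override[pat_idx], rep(NA_integer_, n_control)),
    stringsAsFactors = FALSE)

  alleles <- do.call(rbind, lapply(samples, function(s)
    data.frame(patient_id = s$patient_id, tissue = s$tissue,
               timepoint = s$timepoint, age_at_sampling = s$age_at_sampling,
               size = s$sizes, stringsAsFactors = FALSE)))
  rownames(alleles) <- NULL
  list(samples = samples, patients = patients, alleles = alleles,
       spec = spec, config = config)
}
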