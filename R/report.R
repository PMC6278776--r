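#' Run the full somatic-instability analysis
#'
#' Composes the whole pipeline on a study cohort (allele samples plus
#' patient metadata) against a reference cohort: per-sample allele
#' frequency distribution summaries (with 5'-end views for interrupted
#' expansions), per-timepoint refits of the instability and age-at-onset
#' model suite on reference plus study subjects, expected values and
#' standardized residuals, observed and expected modal increments, and
#' the full nonparametric comparison matrix.
#'
#' @param samples named list of \code{\link{allele_sample}} objects
#'   (\code{"patient/tissue/timepoint"} keys), e.g. from
#'   \code{\link{read_allele_table}} or \code{\link{generate_study_cohort}}.
#' @param patients patient metadata data frame (see
#'   \code{\link{read_patient_table}}).
#' @param reference a reference cohort as returned by
#'   \code{\link{generate_reference_cohort}}, or NULL to generate one
#'   from \code{ref_spec}/\code{config}.
#' @param config a \code{\link{simulation_config}} (used only when a
#'   reference cohort must be generated).
#' @param ref_spec a \code{\link{cohort_spec}} for the generated
#'   reference cohort.
#' @param bandwidth modal-length smoothing bandwidth (see
#'   \code{\link{modal_length}}).
#' @param alpha significance level for the comparison matrix.
#' @return A list of class \code{"report_bundle"}: \code{table1}
#'   (per-patient features), \code{table2} (paired-timepoint modes,
#'   distribution-shift tests and increments), \code{summaries} (all
#'   per-sample statistics), \code{fits}, \code{tests}, \code{skipped},
#'   \code{figure_data}.
#' @export
run_full_analysis <- function(samples, patients, reference = NULL,
                              config = simulation_config(),
                              ref_spec = cohort_spec(),
                              bandwidth = NULL, alpha = 0.05) {
  if (is.null(reference))
    reference <- generate_reference_cohort(ref_spec, config)
  summaries <- summarize_samples(samples, bandwidth = bandwidth)
  rownames(summaries) <- NULL

  # 5'-end views for interrupted patients
  fp_rows <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    if (patients$group[i] != "interrupted") next
    pat <- patients$pattern_parsed[[i]]
    if (is.null(pat)) pat <- parse_interruption_pattern(patients$pattern[i])
    clen <- interrupted_block_length(
      pat, override = patients$interrupted_block_override[i])
    for (s in samples) {
      if (s$patient_id != pid || s$tissue != "blood") next
      fp_rows[[length(fp_rows) + 1L]] <-
        summarize_sample(five_prime_view(s, clen), bandwidth = bandwidth)
    }
  }
  summaries_5p <- if (length(fp_rows)) do.call(rbind, fp_rows) else NULL

  # per-timepoint cohorts: reference rows + study blood rows
  study_row <- function(tp) {
    sm <- summaries[summaries$tissue == "blood" &
                      summaries$timepoint == tp, , drop = FALSE]
    if (nrow(sm) == 0L) return(NULL)
    idx <- match(sm$patient_id, patients$patient_id)
    data.frame(patient_id = sm$patient_id,
               group = patients$group[idx],
               epal = sm$p10, as = sm$age_at_sampling, si = sm$si,
               mode = sm$mode, ao = patients$age_at_onset[idx],
               stringsAsFactors = FALSE)
  }
  cohorts <- list()
  fits <- list()
  specs <- default_model_specs()
  for (tp in c("t1", "t2")) {
    st <- study_row(tp)
    ref <- reference[[tp]][c("patient_id", "group", "epal", "as", "si",
                             "mode", "ao")]
    co <- rbind(ref, st)
    fit8 <- fit_model(specs$M8, co)
    co$expected_si <- predict_expected(fit8, co)
    co <- attach_si_residual(co, fit8)
    fits[[paste0("M8_", tp)]] <- fit8
    ao_rows <- co[!is.na(co$ao), , drop = FALSE]
    if (nrow(ao_rows) >= 4L) {
      fits[[paste0("M9_", tp)]] <- fit_model(specs$M9, ao_rows)
      fits[[paste0("M10_", tp)]] <- fit_model(specs$M10, ao_rows)
      fits[[paste0("M11_", tp)]] <- fit_model(specs$M11, ao_rows)
    }
    cohorts[[tp]] <- co
  }

  # observed and expected increments (blood modes t1 -> t2)
  incr <- list()
  for (pid in unique(summaries$patient_id)) {
    s1 <- summaries[summaries$patient_id == pid &
                      summaries$tissue == "blood" &
                      summaries$timepoint == "t1", , drop = FALSE]
    s2 <- summaries[summaries$patient_id == pid &
                      summaries$tissue == "blood" &
                      summaries$timepoint == "t2", , drop = FALSE]
    if (nrow(s1) == 1L && nrow(s2) == 1L)
      incr[[pid]] <- observed_increment(s1, s2)
  }
  increments <- if (length(incr)) do.call(rbind, incr) else NULL
  if (!is.null(increments)) {
    increments$group <-
      patients$group[match(increments$patient_id, patients$patient_id)]
    increments$mode <- increments$mode_t1
    incr_fit <- fit_model(specs$INCR, reference$increments)
    increments$expected_increment <-
      predict_expected(incr_fit, increments)
    rownames(increments) <- NULL
  }

  matrix_res <- run_comparison_matrix(samples, patients, cohorts = cohorts,
                                      fits = fits, increments = increments,
                                      alpha = alpha)

  # Table 1: per-patient features
  t1_sum <- summaries[summaries$tissue == "blood", , drop = FALSE]
  table1 <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    g1 <- t1_sum[t1_sum$patient_id == pid & t1_sum$timepoint == "t1", ]
    g2 <- t1_sum[t1_sum$patient_id == pid & t1_sum$timepoint == "t2", ]
    data.frame(patient_id = pid, sex = patients$sex[i],
               group = patients$group[i],
               pattern = patients$pattern[i],
               age_at_onset = patients$age_at_onset[i],
               as_t1 = if (nrow(g1)) g1$age_at_sampling else NA,
               p10_t1 = if (nrow(g1)) g1$p10 else NA,
               as_t2 = if (nrow(g2)) g2$age_at_sampling else NA,
               p10_t2 = if (nrow(g2)) g2$p10 else NA,
               stringsAsFactors = FALSE)
  }))

  # Table 2: paired-timepoint modes, AFD shift tests, increments
  table2 <- NULL
  if (!is.null(increments)) {
    shift <- matrix_res$results
    shift <- shift[shift$family == "time_afd", , drop = FALSE]
    table2 <- increments
    m5 <- function(pid, tp) {
      if (is.null(summaries_5p)) return(NA_integer_)
      r <- summaries_5p[summaries_5p$patient_id == pid &
                          summaries_5p$timepoint == tp, ]
      if (nrow(r) == 1L) r$mode else NA_integer_
    }
    table2$mode_5p_t1 <- vapply(table2$patient_id, m5, 0L, tp = "t1")
    table2$mode_5p_t2 <- vapply(table2$patient_id, m5, 0L, tp = "t2")
    ix <- match(table2$patient_id, shift$unit)
    table2$W <- shift$statistic[ix]
    table2$p_shift <- shift$p_two_tailed[ix]
    table2$mode <- NULL
  }

  figure_data <- list(
    afd_densities = do.call(rbind, lapply(samples, function(s) {
      d <- afd_density(s)
      d$patient_id <- s$patient_id; d$tissue <- s$tissue
      d$timepoint <- s$timepoint
      d
    })),
    residual_scatter = do.call(rbind, lapply(names(fits), function(fn) {
      f <- fits[[fn]]
      data.frame(fit = fn, patient_id = names(f$std_residuals),
                 std_residual = unname(f$std_residuals),
                 stringsAsFactors = FALSE)
    })))

  structure(list(table1 = table1, table2 = table2, summaries = summaries,
                 summaries_5p = summaries_5p, cohorts = cohorts,
                 fits = fits, increments = increments,
                 tests = matrix_res$results, skipped = matrix_res$skipped,
                 figure_data = figure_data),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Somatic-instability report bundle\n")
  cat("  patients:   ", nrow(x$table1), "\n")
  cat("  samples:    ", nrow(x$summaries), "\n")
  cat("  model fits: ", paste(names(x$fits), collapse = ", "), "\n")
  cat("  tests:      ", if (is.null(x$tests)) 0L else nrow(x$tests),
      " (", if (is.null(x$skipped)) 0L else nrow(x$skipped),
      " skipped)\n", sep = "")
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits table1.tsv, table2.tsv, summaries.tsv, tests.tsv and a
#' machine-readable JSON sidecar with model coefficients and R-squared
#' values at full precision.
#'
#' @param bundle a \code{"report_bundle"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(bundle$table1, "table1.tsv")
  wr(bundle$table2, "table2.tsv")
  wr(bundle$summaries, "summaries.tsv")
  wr(bundle$tests, "tests.tsv")
  wr(bundle$skipped, "skipped.tsv")
  side <- lapply(bundle$fits, function(f)
    list(model = f$spec$name, n = f$n, r_squared = f$r_squared,
         coefficients = as.list(f$coefficients)))
  jsonlite::write_json(side, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
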