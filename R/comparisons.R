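#' Internal constructor for a test-result row
#' @keywords internal
.test_result <- function(method, statistic, p, n1, n2 = NA_integer_,
                         exact = NA, orientation = NA_character_) {
  data.frame(method = method, statistic = as.numeric(statistic),
             p_two_tailed = as.numeric(p), n1 = as.integer(n1),
             n2 = as.integer(n2), exact = exact,
             orientation = orientation, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test between two samples
#'
#' The reported statistic W is the Mann-Whitney U of the first sample
#' (number of (x, y) pairs with x > y, plus half the ties). The exact
#' two-tailed p-value is used when there are no ties and n1 * n2 is at or
#' below \code{exact_limit}; otherwise the normal approximation with tie
#' and continuity correction applies. Swapping the samples maps W to
#' n1 * n2 - W with the same p, so the orientation is recorded.
#'
#' @param x,y numeric samples (e.g. two allele frequency distributions).
#' @param exact_limit use the exact distribution when n1 * n2 is at or
#'   below this and no ties are present.
#' @param orientation label recording which sample came first.
#' @return One-row data frame: method, statistic (W), p_two_tailed, n1,
#'   n2, exact, orientation.
#' @export
rank_sum_test <- function(x, y, exact_limit = 400, orientation = "x_first") {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= exact_limit
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  .test_result("rank_sum", unname(ht$statistic), ht$p.value,
               length(x), length(y), exact, orientation)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' V is the sum of the ranks of the positive differences after ranking
#' the absolute differences (midranks for ties). Zero differences are
#' dropped before ranking. The exact two-tailed p-value enumerates all
#' 2^n sign patterns when the retained n is at or below
#' \code{exact_limit} and the absolute differences are untied; otherwise
#' the normal approximation with continuity correction is used.
#'
#' @param differences numeric vector of paired differences (observed
#'   minus expected, t2 minus t1, ...).
#' @param exact_limit largest n for the exact distribution.
#' @return One-row data frame: method, statistic (V), p_two_tailed,
#'   n1 (retained pairs), exact.
#' @examples
#' signed_rank_test(rep(-1, 6) * 1:6)  # V = 0, p = 2/2^6 = 0.03125
#' @export
signed_rank_test <- function(differences, exact_limit = 25) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero (or missing)")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- !ties && length(d) <= exact_limit
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  .test_result("signed_rank", unname(ht$statistic), ht$p.value,
               length(d), NA_integer_, exact)
}

#' Shapiro-Wilk normality gate
#'
#' Records whether a sample is compatible with normality at the given
#' level. The comparison matrix logs the gate outcome but proceeds with
#' the nonparametric tests regardless, since allele frequency
#' distributions are typically non-normal.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @param alpha significance level for the normality flag.
#' @return One-row data frame as in \code{\link{rank_sum_test}} plus a
#'   logical \code{normal} column.
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("Shapiro-Wilk needs at least 3 observations")
  if (length(x) > 5000L) x <- sample(x, 5000L)
  if (stats::sd(x) == 0) stop("Shapiro-Wilk undefined for a constant sample")
  ht <- stats::shapiro.test(x)
  out <- .test_result("shapiro_wilk", unname(ht$statistic), ht$p.value,
                      length(x))
  out$normal <- ht$p.value > alpha
  out
}

#' Run the full nonparametric comparison matrix on a summarised cohort
#'
#' Reproduces the comparison families of the analysis, all two-tailed:
#' \describe{
#'   \item{tissue_afd}{per patient, blood vs buccal allele frequency
#'     distributions at the shared timepoint (rank-sum).}
#'   \item{time_afd}{per patient, blood t1 vs t2 distributions
#'     (rank-sum).}
#'   \item{obs_vs_exp_si}{per group and timepoint, observed vs expected
#'     instability (signed-rank on paired differences).}
#'   \item{obs_vs_exp_incr}{per group, observed vs expected modal
#'     increments (signed-rank).}
#'   \item{resid_vs_reference}{per model and timepoint, standardized
#'     residuals of the interrupted and of the control group vs the
#'     reference group (rank-sum).}
#'   \item{m11_vs_m10_resid}{per group, M11 vs M10 standardized
#'     age-at-onset residuals (signed-rank).}
#' }
#' Comparisons whose inputs are missing are skipped with a logged reason.
#'
#' @param samples named list of \code{\link{allele_sample}} objects
#'   (names \code{"patient/tissue/timepoint"}).
#' @param patients patient metadata data frame (see
#'   \code{\link{read_patient_table}}).
#' @param cohorts named list of per-timepoint cohort tables (rows:
#'   patient_id, group, si, expected_si, ...), or NULL to skip
#'   model-based families.
#' @param fits named list of \code{"regression_fit"} objects keyed
#'   \code{"<model>_<timepoint>"} (e.g. \code{"M8_t1"}), or NULL.
#' @param increments data frame with observed and expected increments and
#'   a \code{group} column, or NULL.
#' @param alpha significance level recorded with the results.
#' @return A list with \code{results} (data frame of test rows keyed by
#'   \code{family} and \code{unit}) and \code{skipped} (data frame of
#'   skipped comparisons with reasons).
#' @export
run_comparison_matrix <- function(samples, patients, cohorts = NULL,
                                  fits = NULL, increments = NULL,
                                  alpha = 0.05) {
  rows <- list()
  skipped <- list()
  note_skip <- function(family, unit, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      family = family, unit = unit, reason = reason,
      stringsAsFactors = FALSE)
  }
  add <- function(family, unit, res) {
    res$family <- family
    res$unit <- unit
    res$significant <- res$p_two_tailed < alpha
    rows[[length(rows) + 1L]] <<- res
  }
  key <- function(p, ti, tp) paste(p, ti, tp, sep = "/")
  ids <- unique(vapply(samples, function(s) s$patient_id, ""))

  # (a) blood vs buccal per patient (buccal exists at one timepoint)
  for (p in ids) {
    buccal <- samples[vapply(samples, function(s)
      s$patient_id == p && s$tissue == "buccal", TRUE)]
    if (length(buccal) == 0L) {
      note_skip("tissue_afd", p, "no buccal sample")
      next
    }
    b <- buccal[[1]]
    blood <- samples[[key(p, "blood", b$timepoint)]]
    if (is.null(blood)) {
      note_skip("tissue_afd", p, "no blood sample at matching timepoint")
      next
    }
    add("tissue_afd", p,
        rank_sum_test(blood$sizes, b$sizes, orientation = "blood_first"))
  }

  # (b) blood t1 vs t2 per patient
  for (p in ids) {
    s1 <- samples[[key(p, "blood", "t1")]]
    s2 <- samples[[key(p, "blood", "t2")]]
    if (is.null(s1) || is.null(s2)) {
      note_skip("time_afd", p, "missing blood sample at one timepoint")
      next
    }
    add("time_afd", p,
        rank_sum_test(s1$sizes, s2$sizes, orientation = "t1_first"))
  }

  # (c) observed vs expected SI per group and timepoint
  for (tp in names(cohorts)) {
    co <- cohorts[[tp]]
    if (!all(c("si", "expected_si", "group") %in% names(co))) {
      note_skip("obs_vs_exp_si", tp, "cohort lacks si/expected_si columns")
      next
    }
    for (g in intersect(c("interrupted", "control", "reference"),
                        unique(co$group))) {
      d <- co$si[co$group == g] - co$expected_si[co$group == g]
      if (length(d) < 2L || all(d == 0)) {
        note_skip("obs_vs_exp_si", paste(g, tp), "too few paired differences")
        next
      }
      add("obs_vs_exp_si", paste(g, tp, sep = "_"), signed_rank_test(d))
    }
  }

  # (d) observed vs expected increments per group
  if (!is.null(increments) &&
      all(c("observed_increment", "expected_increment", "group")
          %in% names(increments))) {
    for (g in intersect(c("interrupted", "control"),
                        unique(increments$group))) {
      d <- increments$observed_increment[increments$group == g] -
        increments$expected_increment[increments$group == g]
      if (length(d) < 2L || all(d == 0)) {
        note_skip("obs_vs_exp_incr", g, "too few paired differences")
        next
      }
      add("obs_vs_exp_incr", g, signed_rank_test(d))
    }
  } else if (!is.null(increments)) {
    note_skip("obs_vs_exp_incr", "all", "increment table lacks columns")
  }

  # (e) standardized residuals of study groups vs the reference group
  for (fname in names(fits)) {
    fit <- fits[[fname]]
    groups <- .residual_groups(fit, patients)
    if (is.null(groups)) {
      note_skip("resid_vs_reference", fname,
                "fit subjects not matched to patient groups")
      next
    }
    for (g in c("interrupted", "control")) {
      if (length(groups[[g]]) == 0L || length(groups$reference) == 0L) {
        note_skip("resid_vs_reference", paste(fname, g),
                  "missing group residuals")
        next
      }
      gate <- tryCatch(shapiro_wilk_gate(groups$reference),
                       error = function(e) NULL)
      res <- rank_sum_test(groups[[g]], groups$reference,
                           orientation = paste0(g, "_first"))
      res$reference_normal <- if (is.null(gate)) NA else gate$normal
      add("resid_vs_reference", paste(fname, g, sep = "_"), res)
    }
  }

  # (f) M11 vs M10 age-at-onset residuals within each group
  tps <- unique(sub("^.*_", "", grep("^M1[01]_", names(fits), value = TRUE)))
  for (tp in tps) {
    f10 <- fits[[paste0("M10_", tp)]]
    f11 <- fits[[paste0("M11_", tp)]]
    if (is.null(f10) || is.null(f11)) {
      note_skip("m11_vs_m10_resid", tp, "need both M10 and M11 fits")
      next
    }
    common <- intersect(names(f10$std_residuals), names(f11$std_residuals))
    grp <- .subject_groups(common, patients)
    for (g in c("interrupted", "control", "reference")) {
      subj <- common[grp == g]
      if (length(subj) < 2L) {
        if (length(subj) > 0L || g != "reference")
          note_skip("m11_vs_m10_resid", paste(g, tp), "too few subjects")
        next
      }
      d <- f11$std_residuals[subj] - f10$std_residuals[subj]
      if (all(d == 0)) {
        note_skip("m11_vs_m10_resid", paste(g, tp), "identical residuals")
        next
      }
      add("m11_vs_m10_resid", paste(g, tp, sep = "_"), signed_rank_test(d))
    }
  }

  list(results = if (length(rows)) do.call(rbind, lapply(rows, function(r) {
         r[setdiff(c("family", "unit", "method", "statistic", "p_two_tailed",
                     "n1", "n2", "exact", "orientation", "significant",
                     "reference_normal"), names(r))] <- NA
         r[c("family", "unit", "method", "statistic", "p_two_tailed",
             "n1", "n2", "exact", "orientation", "significant",
             "reference_normal")]
       })) else NULL,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

# Map subject ids to group labels via the patient table; subjects absent
# from the table are treated as reference (the large historical cohort is
# usually not re-listed in study metadata).
.subject_groups <- function(ids, patients) {
  grp <- patients$group[match(ids, patients$patient_id)]
  grp[is.na(grp)] <- "reference"
  grp
}

.residual_groups <- function(fit, patients) {
  ids <- names(fit$std_residuals)
  if (is.null(ids)) return(NULL)
  grp <- .subject_groups(ids, patients)
  list(interrupted = unname(fit$std_residuals[grp == "interrupted"]),
       control = unname(fit$std_residuals[grp == "control"]),
       reference = unname(fit$std_residuals[grp == "reference"]))
}
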