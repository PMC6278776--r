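#' Construct an allele sample
#'
#' One patient/tissue/timepoint's set of sized alleles from single-molecule
#' small-pool PCR, the unit on which all allele-frequency-distribution
#' statistics are computed. Sizes are repeat lengths in trinucleotide units
#' and are kept as reals: gel sizing is continuous and integerisation
#' happens only where a statistic demands it (the mode). Samples with fewer
#' than \code{min_alleles} sizes are flagged (\code{low_count}) but not
#' rejected: the >= 200-allele requirement is a quality criterion, not a
#' validity one.
#'
#' @param patient_id patient identifier.
#' @param tissue \code{"blood"} or \code{"buccal"}.
#' @param timepoint \code{"t1"} or \code{"t2"}.
#' @param age_at_sampling age in years at sampling.
#' @param sizes numeric vector of allele lengths in trinucleotide repeats.
#' @param is_five_prime_view whether sizes are 5'-end lengths (interrupted
#'   3' part already subtracted).
#' @param min_alleles quality threshold on the number of sized alleles.
#' @return An object of class \code{"allele_sample"}.
#' @export
allele_sample <- function(patient_id, tissue, timepoint, age_at_sampling,
                          sizes, is_five_prime_view = FALSE,
                          min_alleles = 200L) {
  tissue <- match.arg(tissue, c("blood", "buccal"))
  timepoint <- match.arg(timepoint, c("t1", "t2"))
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L) stop("sizes must be non-empty")
  if (anyNA(sizes) || any(sizes <= 0))
    stop("all allele sizes must be positive numbers")
  if (!is.na(age_at_sampling) && age_at_sampling < 0)
    stop("age_at_sampling must be non-negative")
  structure(
    list(patient_id = as.character(patient_id), tissue = tissue,
         timepoint = timepoint, age_at_sampling = as.numeric(age_at_sampling),
         sizes = sizes, is_five_prime_view = isTRUE(is_five_prime_view),
         low_count = length(sizes) < min_alleles),
    class = "allele_sample")
}

#' @export
print.allele_sample <- function(x, ...) {
  cat(sprintf("Allele sample %s / %s / %s: %d alleles, range %.1f-%.1f%s%s\n",
              x$patient_id, x$tissue, x$timepoint, length(x$sizes),
              min(x$sizes), max(x$sizes),
              if (x$is_five_prime_view) " [5' view]" else "",
              if (x$low_count) " [low count]" else ""))
  invisible(x)
}

#' Read a sized-allele table
#'
#' Expects a TSV with header columns \code{patient_id}, \code{tissue},
#' \code{timepoint}, \code{age_at_sampling}, \code{size}; one row per
#' sized molecule. Rows are grouped into one \code{\link{allele_sample}}
#' per (patient, tissue, timepoint).
#'
#' @param path path to the TSV file.
#' @param min_alleles quality threshold passed to
#'   \code{\link{allele_sample}}.
#' @return A named list of \code{"allele_sample"} objects, keyed
#'   \code{"patient/tissue/timepoint"}, in order of first appearance.
#' @export
read_allele_table <- function(path, min_alleles = 200L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tissue", "timepoint", "age_at_sampling", "size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("allele table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$size))
    stop("column `size` must be numeric")
  key <- paste(df$patient_id, df$tissue, df$timepoint, sep = "/")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    age <- unique(rows$age_at_sampling)
    if (length(age) != 1L)
      stop("conflicting age_at_sampling within sample ", k)
    out[[k]] <- allele_sample(rows$patient_id[1], rows$tissue[1],
                              rows$timepoint[1], age, rows$size,
                              min_alleles = min_alleles)
  }
  out
}

#' Write a sized-allele table
#'
#' Inverse of \code{\link{read_allele_table}}.
#'
#' @param samples list of \code{"allele_sample"} objects.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_allele_table <- function(samples, path) {
  rows <- lapply(samples, function(s)
    data.frame(patient_id = s$patient_id, tissue = s$tissue,
               timepoint = s$timepoint, age_at_sampling = s$age_at_sampling,
               size = s$sizes, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient metadata table
#'
#' Expects a TSV with columns \code{patient_id}, \code{sex}, \code{group}
#' (\code{interrupted}/\code{control}/\code{reference}),
#' \code{age_at_onset} (years, NA when unknown), \code{pattern}
#' (interruption-pattern string) and \code{interrupted_block_override}
#' (repeats, NA when the pattern arithmetic is authoritative).
#'
#' @param path path to the TSV file.
#' @return A data frame with the pattern column parsed into a list column
#'   \code{pattern_parsed} of \code{"interruption_pattern"} objects.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("patient_id", "sex", "group", "age_at_onset", "pattern",
            "interrupted_block_override")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("patient table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in patient table")
  bad_group <- setdiff(unique(df$group),
                       c("interrupted", "control", "reference"))
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  if (any(!is.na(df$age_at_onset) & df$age_at_onset < 0))
    stop("age_at_onset must be non-negative")
  df$pattern_parsed <- lapply(df$pattern, function(p)
    if (is.na(p)) NULL else parse_interruption_pattern(p))
  df
}

#' Write per-sample mosaicism summaries as a TSV
#'
#' @param summaries data frame of summaries, e.g. from
#'   \code{\link{summarize_samples}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Holds model forms and optional fixed coefficients, test options and
#' simulation parameters. Unknown keys are preserved.
#'
#' @param path path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
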