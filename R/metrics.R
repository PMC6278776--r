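#' Percentile of an allele frequency distribution
#'
#' Order-statistic percentile with linear interpolation at rank
#' h = (n - 1) q/100 + 1 (the common default in statistical software;
#' selectable via \code{type}). The 10th percentile of a small-pool PCR
#' allele frequency distribution estimates the progenitor allele length;
#' the 90th bounds the bulk of the somatic expansion range.
#'
#' @param sample an \code{\link{allele_sample}}.
#' @param q percentile in (0, 100).
#' @param type quantile convention, as in \code{\link[stats]{quantile}}.
#' @return Repeat length (real).
#' @examples
#' s <- allele_sample("p", "blood", "t1", 40, 100:109)
#' percentile_length(s, 10)  # 100.9
#' @export
percentile_length <- function(sample, q, type = 7L) {
  stopifnot(inherits(sample, "allele_sample"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 100)
    stop("q must be a single percentile strictly between 0 and 100")
  unname(stats::quantile(sample$sizes, probs = q / 100, type = type,
                         names = FALSE))
}

#' Somatic instability range of a sample
#'
#' The difference between the 90th and the 10th percentile of the allele
#' frequency distribution — the working measure of the observed level of
#' somatic instability.
#'
#' @inheritParams percentile_length
#' @return SI in repeats (>= 0).
#' @export
instability_range <- function(sample, type = 7L) {
  percentile_length(sample, 90, type = type) -
    percentile_length(sample, 10, type = type)
}

#' Modal allele length of a sample
#'
#' Sizes are rounded to the nearest whole repeat and the mode is the
#' argmax of the integer histogram, optionally Gaussian-smoothed (the
#' smoothing emulates reading the centre of a diffuse band). With
#' \code{bandwidth = 0} the raw histogram is used; \code{bandwidth = NULL}
#' applies Silverman's rule-of-thumb on the raw sizes. Ties are broken
#' toward the smallest length.
#'
#' @param sample an \code{\link{allele_sample}}.
#' @param bandwidth Gaussian smoothing bandwidth in repeats; 0 disables
#'   smoothing, NULL (default) uses Silverman's rule.
#' @return Integer repeat length.
#' @export
modal_length <- function(sample, bandwidth = NULL) {
  stopifnot(inherits(sample, "allele_sample"))
  sizes <- sample$sizes
  if (is.null(bandwidth))
    bandwidth <- if (length(sizes) > 1 && stats::sd(sizes) > 0)
      stats::bw.nrd0(sizes) else 0
  rounded <- as.integer(round(sizes))
  grid <- seq.int(min(rounded), max(rounded))
  counts <- tabulate(rounded - min(rounded) + 1L, nbins = length(grid))
  score <- as.numeric(counts)
  if (bandwidth > 0) {
    # smooth the integer histogram with a Gaussian kernel
    half <- max(1L, ceiling(4 * bandwidth))
    kern <- stats::dnorm(seq.int(-half, half), sd = bandwidth)
    padded <- c(numeric(half), counts, numeric(half))
    score <- as.numeric(stats::filter(padded, kern,
                                      sides = 2))[half + seq_along(grid)]
  }
  as.integer(grid[which.max(score)])  # which.max takes the first maximum
}

#' 5'-end view of a sample
#'
#' Subtracts the interrupted 3' part from every sized allele, yielding the
#' distribution of the remaining pure 5' CTG tract. The instability range
#' is shift-invariant, so SI of the view equals SI of the original; p10
#' and the mode shift down by the subtracted constant.
#'
#' @param sample an \code{\link{allele_sample}}.
#' @param interrupted_len length of the interrupted part in repeats
#'   (see \code{\link{interrupted_block_length}}); must be smaller than
#'   the smallest sized allele.
#' @return A new \code{"allele_sample"} flagged \code{is_five_prime_view}.
#' @export
five_prime_view <- function(sample, interrupted_len) {
  stopifnot(inherits(sample, "allele_sample"))
  if (interrupted_len < 0) stop("interrupted_len must be non-negative")
  if (interrupted_len >= min(sample$sizes))
    stop("interrupted_len (", interrupted_len,
         ") is not smaller than the smallest sized allele (",
         min(sample$sizes), ")")
  out <- sample
  out$sizes <- sample$sizes - interrupted_len
  out$is_five_prime_view <- TRUE
  out
}

#' Summarise one sample's allele frequency distribution
#'
#' @param sample an \code{\link{allele_sample}}.
#' @param bandwidth passed to \code{\link{modal_length}}.
#' @param type percentile convention.
#' @return A one-row data frame: patient_id, tissue, timepoint,
#'   age_at_sampling, n_alleles, p10 (ePAL estimate), p90, si, mode,
#'   is_five_prime_view, low_count.
#' @export
summarize_sample <- function(sample, bandwidth = NULL, type = 7L) {
  stopifnot(inherits(sample, "allele_sample"))
  p10 <- percentile_length(sample, 10, type = type)
  p90 <- percentile_length(sample, 90, type = type)
  data.frame(patient_id = sample$patient_id, tissue = sample$tissue,
             timepoint = sample$timepoint,
             age_at_sampling = sample$age_at_sampling,
             n_alleles = length(sample$sizes),
             p10 = p10, p90 = p90, si = p90 - p10,
             mode = modal_length(sample, bandwidth = bandwidth),
             is_five_prime_view = sample$is_five_prime_view,
             low_count = sample$low_count,
             stringsAsFactors = FALSE)
}

#' Summarise a list of samples
#'
#' @param samples list of \code{\link{allele_sample}} objects.
#' @inheritParams summarize_sample
#' @return A data frame with one row per sample.
#' @export
summarize_samples <- function(samples, bandwidth = NULL, type = 7L) {
  do.call(rbind, lapply(samples, summarize_sample, bandwidth = bandwidth,
                        type = type))
}

#' Observed modal expansion increment between two timepoints
#'
#' The observed expansion-size increment over time is the difference
#' between the modal allele lengths at the second and the first sampling
#' (signed; somatic contraction yields a negative increment).
#'
#' @param summary_t1,summary_t2 one-row summaries (see
#'   \code{\link{summarize_sample}}) of the same patient and tissue at
#'   timepoints t1 and t2.
#' @return A one-row data frame: patient_id, tissue, mode_t1, mode_t2,
#'   interval (years), observed_increment.
#' @export
observed_increment <- function(summary_t1, summary_t2) {
  if (summary_t1$patient_id != summary_t2$patient_id ||
      summary_t1$tissue != summary_t2$tissue)
    stop("increment requires the same patient and tissue at both timepoints")
  if (!(summary_t1$timepoint == "t1" && summary_t2$timepoint == "t2"))
    stop("summaries must be ordered t1 then t2")
  interval <- summary_t2$age_at_sampling - summary_t1$age_at_sampling
  if (!is.na(interval) && interval <= 0)
    stop("sampling interval must be positive")
  data.frame(patient_id = summary_t1$patient_id, tissue = summary_t1$tissue,
             mode_t1 = summary_t1$mode, mode_t2 = summary_t2$mode,
             interval = interval,
             observed_increment = summary_t2$mode - summary_t1$mode,
             stringsAsFactors = FALSE)
}

#' Kernel density curve of an allele frequency distribution
#'
#' Coordinates for density-plot style displays of a sample's allele
#' frequency distribution.
#'
#' @param sample an \code{\link{allele_sample}}.
#' @param ... passed to \code{\link[stats]{density}}.
#' @return A data frame with columns \code{size} and \code{density}.
#' @export
afd_density <- function(sample, ...) {
  stopifnot(inherits(sample, "allele_sample"))
  d <- stats::density(sample$sizes, ...)
  data.frame(size = d$x, density = d$y)
}
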