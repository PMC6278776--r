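#' Variable transforms available in model specifications
#' @keywords internal
.transforms <- list(
  identity = function(x) x,
  log10 = log10,
  ln = log
)

.inverse_transforms <- list(
  identity = function(x) x,
  log10 = function(x) 10^x,
  ln = exp
)

#' Specify a linear model of the instability / age-at-onset suite
#'
#' A model specification names a response (with a transform applied
#' before ordinary least squares) and a set of predictors (each with its
#' own transform). Supplying \code{fixed_coefficients} (intercept first,
#' then one per predictor, on the transformed scale) turns the spec into a
#' closed-form predictor that needs no fitting.
#'
#' @param name model label, e.g. \code{"M8"}.
#' @param response response variable (column name in the cohort table).
#' @param response_transform one of \code{"identity"}, \code{"log10"},
#'   \code{"ln"}.
#' @param predictors character vector of predictor column names.
#' @param predictor_transforms transforms per predictor (recycled).
#' @param fixed_coefficients optional numeric vector, intercept first.
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(name, response, response_transform = "identity",
                       predictors, predictor_transforms = "identity",
                       fixed_coefficients = NULL) {
  response_transform <- match.arg(response_transform, names(.transforms))
  predictor_transforms <- rep_len(
    vapply(predictor_transforms, match.arg, "", choices = names(.transforms)),
    length(predictors))
  if (!is.null(fixed_coefficients) &&
      length(fixed_coefficients) != length(predictors) + 1L)
    stop("fixed_coefficients must have length 1 + number of predictors")
  structure(
    list(name = name, response = response,
         response_transform = response_transform,
         predictors = predictors,
         predictor_transforms = predictor_transforms,
         fixed_coefficients = fixed_coefficients),
    class = "model_spec")
}

#' Default model suite
#'
#' The retested linear-model suite on per-subject summaries:
#' \describe{
#'   \item{M8}{log10 somatic instability ~ progenitor allele length (p10)
#'     + age at sampling; the expected-instability model.}
#'   \item{M8_5prime}{the same form on 5'-end quantities.}
#'   \item{M9}{age at onset ~ progenitor allele length (untransformed
#'     response).}
#'   \item{M10}{log10 age at onset ~ progenitor allele length.}
#'   \item{M11}{M10 plus the standardized instability residual from M8.}
#'   \item{INCR}{observed modal increment ~ modal expansion size + time
#'     interval between samplings.}
#' }
#' Transforms are conventions of this package (the response logs reflect
#' the right-skew of SI and AO) and can be overridden per spec.
#'
#' @return Named list of \code{\link{model_spec}} objects.
#' @export
default_model_specs <- function() {
  list(
    M8 = model_spec("M8", "si", "log10", c("epal", "as")),
    M8_5prime = model_spec("M8_5prime", "si_5p", "log10",
                           c("epal_5p", "as")),
    M9 = model_spec("M9", "ao", "identity", "epal"),
    M10 = model_spec("M10", "ao", "log10", "epal"),
    M11 = model_spec("M11", "ao", "log10", c("epal", "si_resid")),
    INCR = model_spec("INCR", "observed_increment", "identity",
                      c("mode", "interval"))
  )
}

# Build the design matrix (with intercept) and transformed response for a
# spec on a cohort data frame; errors name offending subjects.
.design <- function(spec, data, need_response = TRUE) {
  id <- if ("patient_id" %in% names(data)) as.character(data$patient_id)
        else as.character(seq_len(nrow(data)))
  miss <- setdiff(spec$predictors, names(data))
  if (length(miss))
    stop("model ", spec$name, ": missing predictor column(s): ",
         paste(miss, collapse = ", "))
  vals <- mapply(function(v, tr) .transforms[[tr]](data[[v]]),
                 spec$predictors, spec$predictor_transforms,
                 SIMPLIFY = FALSE)
  X <- cbind(1, matrix(unlist(vals), nrow = nrow(data)))
  colnames(X) <- c("(Intercept)", spec$predictors)
  y <- NULL
  if (need_response) {
    if (!spec$response %in% names(data))
      stop("model ", spec$name, ": missing response column ", spec$response)
    raw <- data[[spec$response]]
    if (spec$response_transform %in% c("log10", "ln") && any(raw <= 0)) {
      stop("model ", spec$name, ": non-positive response under log for ",
           "subject(s) ", paste(id[raw <= 0], collapse = ", "))
    }
    y <- .transforms[[spec$response_transform]](raw)
  }
  list(X = X, y = y, id = id)
}

#' Fit a specified linear model on a cohort table
#'
#' Ordinary least squares on the transformed response and predictors.
#' When the spec carries \code{fixed_coefficients} no fitting occurs: the
#' coefficients are taken as given and residuals/R-squared are evaluated
#' against the supplied data. Residuals live on the transformed scale;
#' standardized residuals are rescaled to mean 0, SD 1.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data cohort data frame with one row per subject (a
#'   \code{patient_id} column, when present, labels residuals).
#' @return An object of class \code{"regression_fit"}: spec, coefficients,
#'   r_squared, residuals, std_residuals (both named by subject), n.
#' @export
fit_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  d <- .design(spec, data)
  p <- length(spec$predictors)
  if (nrow(d$X) < p + 2L)
    stop("model ", spec$name, ": need at least ", p + 2L,
         " complete rows for ", p, " predictor(s)")
  if (is.null(spec$fixed_coefficients)) {
    if (qr(d$X)$rank < ncol(d$X))
      stop("model ", spec$name, ": rank-deficient design matrix")
    fit <- stats::lm.fit(d$X, d$y)
    beta <- fit$coefficients
    res <- fit$residuals
  } else {
    beta <- stats::setNames(spec$fixed_coefficients, colnames(d$X))
    res <- d$y - drop(d$X %*% beta)
  }
  sst <- sum((d$y - mean(d$y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  std <- (res - mean(res)) / stats::sd(res)
  names(res) <- names(std) <- d$id
  structure(
    list(spec = spec, coefficients = beta, r_squared = r2,
         residuals = res, std_residuals = std, n = nrow(d$X)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Model %s: n = %d, R^2 = %.3f\n", x$spec$name, x$n,
              x$r_squared))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Expected response for new subjects under a fitted model
#'
#' Evaluates the linear predictor for each row of \code{newdata} and
#' back-transforms it to the natural scale of the response (e.g.
#' \code{10^} for a log10 response).
#'
#' @param fit a \code{"regression_fit"} from \code{\link{fit_model}}.
#' @param newdata data frame supplying every predictor of the fit.
#' @return Numeric vector of expected responses on the natural scale.
#' @export
predict_expected <- function(fit, newdata) {
  stopifnot(inherits(fit, "regression_fit"))
  spec <- fit$spec
  d <- .design(spec, newdata, need_response = FALSE)
  lp <- drop(d$X %*% fit$coefficients)
  .inverse_transforms[[spec$response_transform]](lp)
}

#' Expected modal expansion increment over a sampling interval
#'
#' Linear prediction beta0 + beta1 * mode + beta2 * interval. The
#' coefficients come either from \code{coefficients} (e.g. a run config)
#' or from fitting the increment model on a reference table of observed
#' increments.
#'
#' @param mode modal expansion size(s) at the first timepoint, in repeats.
#' @param interval time between samplings, in years.
#' @param coefficients numeric (intercept, mode, interval).
#' @param reference data frame with columns \code{mode},
#'   \code{interval}, \code{observed_increment}; used when
#'   \code{coefficients} is NULL.
#' @return Expected increment(s) in repeats.
#' @export
expected_increment <- function(mode, interval, coefficients = NULL,
                               reference = NULL) {
  if (is.null(coefficients)) {
    if (is.null(reference))
      stop("supply either coefficients or a reference increment table")
    fit <- fit_model(default_model_specs()$INCR, reference)
    coefficients <- fit$coefficients
  }
  if (length(coefficients) != 3L)
    stop("increment model needs 3 coefficients (intercept, mode, interval)")
  unname(coefficients[1] + coefficients[2] * mode +
           coefficients[3] * interval)
}

#' Attach standardized instability residuals as a cohort covariate
#'
#' Carries each subject's standardized residual from the fitted
#' expected-instability model (M8) into the cohort table as column
#' \code{si_resid}, the additional predictor of the age-at-onset model
#' M11. Every subject in \code{cohort} must be present in the fit.
#'
#' @param cohort cohort data frame with a \code{patient_id} column.
#' @param fit_m8 a \code{"regression_fit"} of the instability model.
#' @return \code{cohort} with an added/overwritten \code{si_resid} column.
#' @export
attach_si_residual <- function(cohort, fit_m8) {
  stopifnot(inherits(fit_m8, "regression_fit"))
  id <- as.character(cohort$patient_id)
  miss <- setdiff(id, names(fit_m8$std_residuals))
  if (length(miss))
    stop("subject(s) missing from the instability fit: ",
         paste(miss, collapse = ", "))
  cohort$si_resid <- unname(fit_m8$std_residuals[id])
  cohort
}
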