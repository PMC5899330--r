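# Immunogenicity modeling. The response is binary but is fit by ordinary
# least squares (a linear probability model) — deliberately, because that
# is how peptide-specific immune response was modeled in the source
# analyses this package follows; logistic regression is available as a
# clearly labeled alternative.

# The nine standard predictors of the full additive model.
.full_terms <- c("neo_affinity", "novel_flag", "paired_diff",
                 "human_match_diff", "mismatches_paired", "sim_paired",
                 "sim_human", "sim_bacterial", "sim_viral")

# The four predictors of the reduced multiplicative model.
.reduced_terms <- c("neo_affinity", "sim_viral", "human_match_diff",
                    "mismatches_paired")

#' Response binarization rules per source study
#'
#' Maps heterogeneous raw immune-response measurements to one boolean per
#' record, according to the study the record came from:
#' \describe{
#'   \item{carreno}{responder iff the percent neoantigen-specific T cells
#'     in lymph+/CD8+ gated cells (\code{pct_tcell}) is strictly greater
#'     than 10.}
#'   \item{ott, bjerregaard}{binary response passed through
#'     (\code{response_binary}).}
#'   \item{le}{responder iff clonal T-cell expansion was demonstrated
#'     (\code{clonal_expansion}); ELISpot-only reactivity is a
#'     non-responder.}
#'   \item{tran, gros}{responder iff T-cell reactive in co-culture
#'     (\code{tcell_reactive}).}
#' }
#' Records missing the field their rule needs are dropped with a logged
#' count (only complete records are modeled).
#'
#' @param records data.frame with a \code{source_study} column (values
#'   above, case-insensitive) and the per-study raw fields.
#' @return The records with a logical \code{response} column appended;
#'   incomplete rows removed. The number dropped is attached as attribute
#'   \code{"n_dropped"} and reported via \code{message()}.
#' @export
binarize_response <- function(records) {
  stopifnot(is.data.frame(records), "source_study" %in% names(records))
  study <- tolower(records$source_study)
  known <- c("carreno", "ott", "bjerregaard", "le", "tran", "gros")
  if (any(!study %in% known))
    stop("unknown source_study: ",
         paste(unique(study[!study %in% known]), collapse = ", "),
         call. = FALSE)
  field <- function(name) {
    if (name %in% names(records)) records[[name]] else
      rep(NA, nrow(records))
  }
  resp <- rep(NA, nrow(records))
  i <- study == "carreno"
  resp[i] <- as.numeric(field("pct_tcell"))[i] > 10
  i <- study %in% c("ott", "bjerregaard")
  resp[i] <- as.logical(field("response_binary"))[i]
  i <- study == "le"
  resp[i] <- as.logical(field("clonal_expansion"))[i]
  i <- study %in% c("tran", "gros")
  resp[i] <- as.logical(field("tcell_reactive"))[i]
  drop <- is.na(resp)
  if (any(drop))
    message(sum(drop), " record(s) dropped: missing response field")
  out <- records[!drop, , drop = FALSE]
  out$response <- as.logical(resp[!drop])
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Fit the immunogenicity linear model
#'
#' Ordinary least squares of the response (0/1, or a continuous score for
#' calibration experiments) on the requested predictors. Three shapes are
#' supported: a single-predictor model, the full nine-term additive model
#' (the default), and the reduced "multiplicative" model — the four
#' predictors \code{neo_affinity}, \code{sim_viral},
#' \code{human_match_diff} and \code{mismatches_paired} with the full
#' factorial interaction expansion (R's \code{*} operator). Records with
#' missing values in any used column are dropped with a logged count.
#'
#' @param records data.frame carrying a \code{response} column (logical or
#'   numeric) and the predictor columns.
#' @param terms Character vector of predictor column names, or a formula
#'   right-hand side as a string. Default: the nine-term additive set.
#' @param reduced If TRUE, ignore \code{terms} and fit the reduced
#'   four-predictor multiplicative model.
#' @param logistic If TRUE, fit logistic regression instead of the linear
#'   probability model (clearly labeled alternative; default FALSE).
#' @return An object of class \code{neoprior_fit}: list with
#'   \code{coefficients}, \code{std_errors}, \code{p_values} (per-term,
#'   two-sided t tests), \code{adj_r_squared}, \code{model_p_value}
#'   (overall F test; NA for logistic), \code{formula}, \code{n}, and the
#'   underlying \code{fit}.
#' @export
fit_immunogenicity_model <- function(records, terms = NULL,
                                     reduced = FALSE, logistic = FALSE) {
  stopifnot(is.data.frame(records), "response" %in% names(records))
  rhs <- if (reduced) {
    paste(.reduced_terms, collapse = " * ")
  } else if (is.null(terms)) {
    paste(.full_terms, collapse = " + ")
  } else if (length(terms) == 1L && grepl("[*+:]", terms)) {
    terms
  } else {
    paste(terms, collapse = " + ")
  }
  fml <- stats::as.formula(paste("response ~", rhs))
  miss <- setdiff(all.vars(fml), names(records))
  if (length(miss))
    stop("schema error: missing predictor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dat <- records[, all.vars(fml), drop = FALSE]
  dat$response <- as.numeric(dat$response)
  cc <- stats::complete.cases(dat)
  if (any(!cc))
    message(sum(!cc), " record(s) dropped: incomplete predictor data")
  dat <- dat[cc, , drop = FALSE]
  p <- ncol(stats::model.matrix(fml, dat[seq_len(min(nrow(dat), 2L)), ,
                                         drop = FALSE]))
  if (nrow(dat) <= p)
    stop("underdetermined error: n <= number of design columns",
         call. = FALSE)
  fit <- if (logistic)
    stats::glm(fml, data = dat, family = stats::binomial())
  else stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("singular-fit error: rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  coefs <- sm$coefficients
  model_p <- NA_real_
  adj_r2 <- NA_real_
  if (!logistic) {
    adj_r2 <- sm$adj.r.squared
    f <- sm$fstatistic
    if (!is.null(f))
      model_p <- stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)
  }
  structure(list(coefficients = coefs[, 1L],
                 std_errors = coefs[, 2L],
                 p_values = coefs[, 4L],
                 adj_r_squared = adj_r2,
                 model_p_value = unname(model_p),
                 formula = fml, n = nrow(dat), logistic = logistic,
                 fit = fit),
            class = "neoprior_fit")
}

#' @export
print.neoprior_fit <- function(x, ...) {
  cat(sprintf("%s immunogenicity model: %s\n",
              if (x$logistic) "Logistic" else "Linear (OLS)",
              deparse(x$formula)))
  cat(sprintf("n = %d; adjusted R^2 = %s; model p = %s\n", x$n,
              format(x$adj_r_squared, digits = 3),
              format(x$model_p_value, digits = 3)))
  print(data.frame(coefficient = x$coefficients, se = x$std_errors,
                   p = x$p_values))
  invisible(x)
}

#' Predict continuous immunogenicity scores
#'
#' Linear combination of the fitted coefficients with the records' terms;
#' scores are unclipped (they are ranking scores, not probabilities).
#'
#' @param object A [fit_immunogenicity_model()] fit.
#' @param newdata data.frame carrying every term of the fit.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.neoprior_fit <- function(object, newdata, ...) {
  need <- setdiff(all.vars(object$formula), "response")
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("schema error: missing term column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  as.numeric(stats::predict(object$fit, newdata = newdata,
                            type = if (object$logistic) "link"
                                   else "response"))
}

#' Rank-based AUROC (Mann-Whitney, ties counted one half)
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with tied scores contributing 1/2. Computed from
#' midranks, which is exactly the normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) class labels; both classes must occur.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))  # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete and of equal length",
         call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUROC error: need both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
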