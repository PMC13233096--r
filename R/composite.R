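#' Per-subject logistic confidence-RT composite model
#'
#' Fits, for a single subject, the logistic regression
#' \deqn{logit\,P(correct) = \beta_0 + \beta_{conf}\,conf + \beta_{rt}\,rt +
#'   \beta_{int}\,conf \cdot rt}
#' on raw (undiscretized) predictors. The fitted linear predictor — the
#' log-odds of response correctness — is itself a graded secondary variable
#' that pools whatever type-2 information confidence and RT each carry,
#' including their interaction. Typical behaviour yields
#' \eqn{\beta_{conf} > 0} (higher confidence, more accurate),
#' \eqn{\beta_{rt} < 0} (faster, more accurate), and a negative interaction
#' (confidence more diagnostic at fast RTs).
#'
#' Complete or quasi-separation (perfectly predictable correctness) is
#' detected from diverging coefficients or fitted probabilities at 0/1; the
#' model is then refit with a small L2 (ridge) penalty and flagged.
#'
#' @param table a [trial_table()] for one subject.
#' @param confidence the confidence predictor; defaults to the table's
#'   ordinal ratings. Pass \code{table$conf_raw} to use a continuous
#'   confidence signal (as in the simulation pipeline).
#' @param min_trials minimum trial count; below it the fit is refused.
#' @param ridge_lambda L2 penalty used only for the separation fallback.
#' @return An object of class \code{"composite_model"}: list with
#'   \code{beta0}, \code{beta_conf}, \code{beta_rt}, \code{beta_interaction},
#'   \code{se} (named vector, NA under ridge), \code{subject},
#'   \code{fitted}, \code{separation_flag}.
#' @export
fit_composite <- function(table, confidence = table$confidence,
                          min_trials = 20, ridge_lambda = 1e-4) {
  stopifnot(inherits(table, "trial_table"))
  if (length(unique(table$subject)) != 1L) {
    stop("fit_composite expects a single subject's trials", call. = FALSE)
  }
  n <- nrow(table)
  if (n < min_trials) {
    stop(sprintf("too few trials (%d < %d) for a composite fit", n, min_trials),
         call. = FALSE)
  }
  y <- as.integer(table$correct)
  if (all(y == 1L) || all(y == 0L)) {
    stop("composite model unfittable: subject has no correct or no incorrect trials",
         call. = FALSE)
  }
  conf <- as.numeric(confidence)
  rt <- table$rt
  dat <- data.frame(y = y, conf = conf, rt = rt, inter = conf * rt)

  fit <- suppressWarnings(
    stats::glm(y ~ conf + rt + inter, data = dat, family = stats::binomial())
  )
  mu <- stats::fitted(fit)
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)) > 50 / c(1, max(abs(conf)), max(rt), max(abs(dat$inter)))) ||
    any(mu < 1e-8) || any(mu > 1 - 1e-8)

  if (separated) {
    # ridge-stabilized refit: small L2 penalty keeps coefficients finite
    x <- as.matrix(dat[, c("conf", "rt", "inter")])
    rfit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    b <- as.numeric(stats::coef(rfit))
    names(b) <- c("(Intercept)", "conf", "rt", "inter")
    se <- stats::setNames(rep(NA_real_, 4), names(b))
  } else {
    b <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
  }
  structure(list(beta0 = unname(b[1]), beta_conf = unname(b["conf"]),
                 beta_rt = unname(b["rt"]),
                 beta_interaction = unname(b["inter"]),
                 se = se, subject = table$subject[1],
                 fitted = TRUE, separation_flag = separated),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("Composite logistic model (subject %s)%s\n", x$subject,
              if (x$separation_flag) " [separation: ridge-stabilized]" else ""))
  cat(sprintf("  logit(correct) = %.3f %+.4f conf %+.6f rt %+.6f conf:rt\n",
              x$beta0, x$beta_conf, x$beta_rt, x$beta_interaction))
  invisible(x)
}

#' Composite secondary variable from a fitted model
#'
#' Evaluates the model's linear predictor (logit of correctness) on each
#' trial and discretizes the logits into \code{n_bins} quantile levels
#' (ascending: higher predicted correctness = higher level). Because the
#' binning is quantile-based and the logit is affine in its inputs, the
#' resulting levels are invariant to affine rescaling of the RT unit.
#'
#' @param model a \code{composite_model}.
#' @param table the same subject's [trial_table()].
#' @param n_bins number of levels; conventionally the dataset's K for
#'   empirical data, 10 for simulation output.
#' @param confidence confidence predictor values, matching those used in
#'   [fit_composite()].
#' @return a \code{secondary_variable} of kind \code{"composite"}.
#' @export
composite_logits <- function(model, table, n_bins,
                             confidence = table$confidence) {
  stopifnot(inherits(model, "composite_model"), inherits(table, "trial_table"))
  conf <- as.numeric(confidence)
  logit <- model$beta0 + model$beta_conf * conf + model$beta_rt * table$rt +
    model$beta_interaction * conf * table$rt
  sv <- bin_by_quantiles(logit, n_bins, orientation = "ascending",
                         kind = "composite")
  sv
}
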