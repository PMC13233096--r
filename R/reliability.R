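#' Odd/even split-half meta-d' estimates
#'
#' Splits each subject's trials by the parity of \code{trial_index} (input
#' order within subject), rebuilds the secondary variable \emph{within each
#' half} (so RT/composite quantile cutoffs are half-specific), and fits
#' meta-d' independently in each half. The cross-subject correlation of the
#' two half estimates measures the reliability of the index; subjects with
#' a non-convergent half are dropped with a message.
#'
#' @param table a [trial_table()] (one or many subjects).
#' @param sv_kind \code{"confidence"}, \code{"rt"}, or \code{"composite"}.
#' @param n_bins levels for RT/composite binning; default the table's K.
#' @param min_trials minimum trials per half.
#' @param ... passed to [fit_meta_d()].
#' @return data.frame with \code{subject}, \code{meta_d_odd},
#'   \code{meta_d_even} for subjects where both halves converged.
#' @export
split_half_metad <- function(table, sv_kind = c("confidence", "rt", "composite"),
                             n_bins = n_levels(table), min_trials = 20, ...) {
  sv_kind <- match.arg(sv_kind)
  stopifnot(inherits(table, "trial_table"))
  subjects <- unique(table$subject)
  rows <- vector("list", length(subjects))
  n_drop <- 0L
  for (i in seq_along(subjects)) {
    st <- table[table$subject == subjects[i], ]
    halves <- list(odd = st[st$trial_index %% 2L == 1L, ],
                   even = st[st$trial_index %% 2L == 0L, ])
    est <- rep(NA_real_, 2)
    ok <- TRUE
    for (h in 1:2) {
      ht <- halves[[h]]
      if (nrow(ht) < min_trials) { ok <- FALSE; break }
      sv <- half_sv(ht, sv_kind, n_bins)
      if (is.null(sv)) { ok <- FALSE; break }
      fit <- try(fit_meta_d(counts_by_cell(ht, sv), ...), silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) { ok <- FALSE; break }
      est[h] <- fit$meta_d_prime
    }
    if (ok) {
      rows[[i]] <- data.frame(subject = subjects[i], meta_d_odd = est[1],
                              meta_d_even = est[2], stringsAsFactors = FALSE)
    } else {
      n_drop <- n_drop + 1L
    }
  }
  if (n_drop > 0) {
    message(sprintf("split_half_metad: dropped %d subject(s) with an unusable half",
                    n_drop))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(subject = character(0),
                                      meta_d_odd = numeric(0),
                                      meta_d_even = numeric(0))
  out
}

half_sv <- function(ht, sv_kind, n_bins) {
  if (sv_kind == "confidence") return(confidence_sv(ht))
  if (sv_kind == "rt") {
    return(suppressWarnings(bin_by_quantiles(ht$rt, n_bins, "descending", "rt")))
  }
  cm <- try(fit_composite(ht, min_trials = 1), silent = TRUE)
  if (inherits(cm, "try-error")) return(NULL)
  suppressWarnings(composite_logits(cm, ht, n_bins))
}

#' Spearman-Brown full-length reliability from a split-half correlation
#' @param r_half correlation between the two half estimates.
#' @return \eqn{2 r / (1 + r)}.
#' @export
spearman_brown <- function(r_half) 2 * r_half / (1 + r_half)

#' Split-half reliability summary
#'
#' @param half_estimates data.frame from [split_half_metad()].
#' @param threshold Spearman-Brown screening threshold (default 0.45): a
#'   dataset whose corrected reliability falls at or below it is considered
#'   too noisy for disattenuated correlations.
#' @return list of class \code{"reliability_result"}: \code{r_half},
#'   \code{r_sb}, \code{passes_screen}, \code{n}.
#' @export
reliability <- function(half_estimates, threshold = 0.45) {
  stopifnot(all(c("meta_d_odd", "meta_d_even") %in% names(half_estimates)))
  r <- stats::cor(half_estimates$meta_d_odd, half_estimates$meta_d_even)
  rsb <- spearman_brown(r)
  structure(list(r_half = r, r_sb = rsb, passes_screen = rsb > threshold,
                 n = nrow(half_estimates)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Split-half reliability (n = %d): r = %.3f, Spearman-Brown = %.3f (%s)\n",
              x$n, x$r_half, x$r_sb,
              if (x$passes_screen) "passes screen" else "fails screen"))
  invisible(x)
}

#' Disattenuate a correlation for measurement error
#'
#' Classical attenuation correction \eqn{r_{xy} / \sqrt{r_{xx} r_{yy}}}.
#' Ratios exceeding 1 in magnitude (possible with noisy reliability
#' estimates) are clamped to the unit interval and flagged.
#'
#' @param r_xy observed correlation.
#' @param r_xx,r_yy reliabilities of x and y (must be > 0).
#' @return list with \code{r} (clamped), \code{raw_ratio},
#'   \code{over_corrected}.
#' @export
disattenuate <- function(r_xy, r_xx, r_yy) {
  if (r_xx <= 0 || r_yy <= 0) {
    stop("disattenuation undefined for non-positive reliabilities",
         call. = FALSE)
  }
  ratio <- r_xy / sqrt(r_xx * r_yy)
  list(r = max(-1, min(1, ratio)), raw_ratio = ratio,
       over_corrected = abs(ratio) > 1)
}

#' First-order partial correlation with Fisher-z confidence interval
#'
#' \eqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}, with a 95\% CI from the Fisher-z
#' approximation using n - 4 effective degrees of freedom (one controlled
#' variable).
#'
#' @param x,y,z numeric vectors of equal length (>= 5 for a CI).
#' @param conf_level CI coverage.
#' @return list with \code{r}, \code{ci}, \code{n}, \code{p_value}.
#' @export
partial_correlation <- function(x, y, z, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 4)
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("partial correlation degenerate: a control correlation is +/-1",
         call. = FALSE)
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  se <- 1 / sqrt(n - 3 - 1)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  zr <- atanh(r)
  list(r = r, ci = tanh(c(zr - zq * se, zr + zq * se)), n = n,
       p_value = 2 * stats::pnorm(-abs(zr) / se))
}

#' Random-effects meta-analysis of correlations
#'
#' Pools per-study Pearson correlations on the Fisher-z scale with
#' DerSimonian-Laird between-study variance: sampling variances
#' \eqn{v_i = 1/(n_i - 3)}; \eqn{\tau^2 = \max(0, (Q - (k-1)) / c)} with
#' \eqn{Q} the fixed-effect heterogeneity statistic and
#' \eqn{c = \sum w_i - \sum w_i^2 / \sum w_i}; random-effects weights
#' \eqn{1/(v_i + \tau^2)}. The pooled z is back-transformed to r with a
#' 95\% CI and a two-sided normal p-value. A single study is returned
#' as-is with \eqn{\tau^2 = 0}.
#'
#' @param per_study data.frame with columns \code{r} and \code{n} (and
#'   optionally \code{study} labels).
#' @param conf_level CI coverage.
#' @return object of class \code{"meta_analysis_result"}: list with
#'   \code{per_study} (with per-study CIs and weights), \code{pooled_r},
#'   \code{pooled_ci}, \code{tau2}, \code{p_value}, \code{k}.
#' @export
meta_analyze_r <- function(per_study, conf_level = 0.95) {
  stopifnot(all(c("r", "n") %in% names(per_study)), nrow(per_study) >= 1,
            all(per_study$n >= 4))
  if (any(abs(per_study$r) >= 1)) {
    stop("meta-analysis undefined for |r| = 1 (infinite Fisher z)",
         call. = FALSE)
  }
  k <- nrow(per_study)
  study <- if ("study" %in% names(per_study)) per_study$study
           else paste0("study", seq_len(k))
  zi <- atanh(per_study$r)
  vi <- 1 / (per_study$n - 3)
  wi <- 1 / vi
  zbar_fe <- sum(wi * zi) / sum(wi)
  Q <- sum(wi * (zi - zbar_fe)^2)
  tau2 <- if (k > 1) {
    cc <- sum(wi) - sum(wi^2) / sum(wi)
    max(0, (Q - (k - 1)) / cc)
  } else 0
  wr <- 1 / (vi + tau2)
  zbar <- sum(wr * zi) / sum(wr)
  se <- 1 / sqrt(sum(wr))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  per <- data.frame(study = study, r = per_study$r, n = per_study$n,
                    ci_lo = tanh(zi - zq * sqrt(vi)),
                    ci_hi = tanh(zi + zq * sqrt(vi)),
                    weight = wr / sum(wr), stringsAsFactors = FALSE)
  structure(list(per_study = per, pooled_r = tanh(zbar),
                 pooled_ci = tanh(c(zbar - zq * se, zbar + zq * se)),
                 tau2 = tau2, Q = Q,
                 p_value = 2 * stats::pnorm(-abs(zbar / se)), k = k),
            class = "meta_analysis_result")
}

#' @export
print.meta_analysis_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (k = %d): pooled r = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$k, x$pooled_r, x$pooled_ci[1], x$pooled_ci[2]))
  cat(sprintf("  tau^2 (Fisher z) = %.4f, p = %.4g\n", x$tau2, x$p_value))
  invisible(x)
}

#' Forest-plot-ready data frame from a meta-analysis
#' @param x a \code{meta_analysis_result}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return per-study rows plus a pooled row.
#' @export
as.data.frame.meta_analysis_result <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  rbind(x$per_study,
        data.frame(study = "pooled", r = x$pooled_r, n = sum(x$per_study$n),
                   ci_lo = x$pooled_ci[1], ci_hi = x$pooled_ci[2],
                   weight = 1, stringsAsFactors = FALSE))
}
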