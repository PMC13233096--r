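#' Type-1 signal detection fit (equal-variance Gaussian)
#'
#' Computes d' and the criterion c from the response margins of a count
#' matrix. Hit rate is P(response S2 | stimulus S2) and false-alarm rate is
#' P(response S2 | stimulus S1), computed after adding \code{padding} to
#' every response x level cell (so extreme observers with a 0 or 1 rate
#' still yield finite estimates). Then
#' \deqn{d' = z(HR) - z(FAR), \quad c = -\tfrac{1}{2}(z(HR) + z(FAR))}
#' with \eqn{z} the standard normal quantile function.
#'
#' @param counts a \code{count_matrix} from [counts_by_cell()].
#' @param padding non-negative value added to each of the 2K cells per
#'   stimulus class before computing rates. Default \code{1/(2K)}.
#' @return list with \code{d_prime}, \code{c}, \code{hr}, \code{far}.
#' @export
fit_type1 <- function(counts, padding = 1 / (2 * counts$K)) {
  stopifnot(inherits(counts, "count_matrix"))
  K <- counts$K
  n1 <- counts$nR_S1 + padding
  n2 <- counts$nR_S2 + padding
  far <- sum(n1[(K + 1):(2 * K)]) / sum(n1)   # P(resp S2 | S1)
  hr  <- sum(n2[(K + 1):(2 * K)]) / sum(n2)   # P(resp S2 | S2)
  if (padding == 0 && (hr %in% c(0, 1) || far %in% c(0, 1))) {
    stop("hit/false-alarm rate of 0 or 1 with padding = 0; d' undefined",
         call. = FALSE)
  }
  d <- stats::qnorm(hr) - stats::qnorm(far)
  cc <- -(stats::qnorm(hr) + stats::qnorm(far)) / 2
  list(d_prime = d, c = cc, hr = hr, far = far)
}

#' Maximum-likelihood meta-d' (Maniscalco-Lau)
#'
#' Estimates meta-d': the type-1 sensitivity that an ideal equal-variance
#' SDT observer would need in order to produce the observed
#' response-conditional secondary-variable (e.g. confidence) distributions.
#' Under the meta-observer model, evidence is distributed
#' \eqn{N(\mp meta\mbox{-}d'/2, 1)} for S1/S2; the meta-level response
#' criterion is held at the type-1 \emph{relative} criterion
#' \eqn{c' = c/d'} (i.e. \eqn{meta\mbox{-}c = c' \cdot meta\mbox{-}d'});
#' and K-1 free type-2 criteria on each side of meta-c partition evidence
#' into levels. The multinomial likelihood of the level counts,
#' \emph{conditional on the response}, is maximized over meta-d' and the
#' 2K-2 criteria (order-constrained via a log-gap parameterization).
#'
#' meta-d' is unconstrained in sign: an observer whose secondary variable is
#' anti-diagnostic of correctness (e.g. fast errors for an RT-based
#' variable) legitimately yields negative meta-d'; no clamping at 0 is
#' applied.
#'
#' @param counts a \code{count_matrix}.
#' @param padding cell padding added before fitting; default \code{1/(2K)}.
#' @param control list passed to [stats::optim()]; \code{maxit} default 1000.
#' @return An object of class \code{"meta_sdt_fit"}: list with
#'   \code{d_prime}, \code{c}, \code{meta_d_prime}, \code{meta_c},
#'   \code{t2_criteria} (length 2K-2, increasing, excluding meta_c),
#'   \code{m_ratio}, \code{loglik}, \code{converged}, \code{K}.
#' @references Maniscalco & Lau (2012), A signal detection theoretic
#'   approach for estimating metacognitive sensitivity from confidence
#'   ratings. Consciousness and Cognition, 21, 422-430.
#' @export
fit_meta_d <- function(counts, padding = 1 / (2 * counts$K), control = list()) {
  stopifnot(inherits(counts, "count_matrix"))
  K <- counts$K
  if (K < 2) stop("meta-d' requires K >= 2 secondary-variable levels",
                  call. = FALSE)
  n1 <- counts$nR_S1 + padding
  n2 <- counts$nR_S2 + padding
  if (padding == 0) {
    resp_tot <- c(sum(n1[1:K] + n2[1:K]), sum(n1[(K + 1):(2 * K)] + n2[(K + 1):(2 * K)]))
    if (any(resp_tot == 0)) {
      stop("degenerate fit: an entire response side has zero counts",
           call. = FALSE)
    }
  }
  t1 <- fit_type1(counts, padding)
  d_prime <- t1$d_prime
  c_rel <- if (abs(d_prime) < 1e-8) 0 else t1$c / d_prime

  negll <- function(theta) {
    meta_d <- theta[1]
    meta_c <- c_rel * meta_d
    gaps_lo <- exp(theta[2:K])                  # K-1 gaps below meta_c
    gaps_hi <- exp(theta[(K + 1):(2 * K - 1)])  # K-1 gaps above meta_c
    lo <- meta_c - rev(cumsum(rev(gaps_lo)))    # increasing, below meta_c
    hi <- meta_c + cumsum(gaps_hi)
    b <- c(-Inf, lo, meta_c, hi, Inf)           # 2K+1 boundaries
    ll <- 0
    for (s in 1:2) {
      mu <- if (s == 1) -meta_d / 2 else meta_d / 2
      n <- if (s == 1) n1 else n2
      cdf <- stats::pnorm(b - mu)
      p_cell <- diff(cdf) + 1e-10               # length 2K; smoothed so the
      # response-conditional probabilities stay in (0,1) and sum to 1 within
      # each response side even when the Gaussian tails underflow
      p <- c(p_cell[1:K] / sum(p_cell[1:K]),
             p_cell[(K + 1):(2 * K)] / sum(p_cell[(K + 1):(2 * K)]))
      ll <- ll + sum(n * log(p))
    }
    -ll
  }

  theta0 <- meta_d_start(n1, n2, d_prime, c_rel, K)
  ctl <- utils::modifyList(list(maxit = 1000, factr = 1e4), control)
  # box bounds keep the optimizer out of the flat saturated-tail region;
  # |meta-d'| = 10 is far beyond any interpretable estimate
  lower <- c(-10, rep(-8, 2 * K - 2))
  upper <- c(10, rep(4, 2 * K - 2))
  fit1 <- stats::optim(theta0, negll, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = ctl$maxit, factr = ctl$factr))
  # Nelder-Mead polish from the L-BFGS-B optimum; agreement defines convergence
  fit2 <- stats::optim(fit1$par, negll, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
  best <- if (fit2$value < fit1$value) fit2 else fit1
  converged <- (fit1$convergence == 0 || fit2$convergence == 0) &&
    abs(fit1$value - fit2$value) < 1e-4 && is.finite(best$value) &&
    abs(best$par[1]) < 10 - 1e-6

  meta_d <- best$par[1]
  meta_c <- c_rel * meta_d
  lo <- meta_c - rev(cumsum(rev(exp(best$par[2:K]))))
  hi <- meta_c + cumsum(exp(best$par[(K + 1):(2 * K - 1)]))
  structure(list(d_prime = d_prime, c = t1$c,
                 meta_d_prime = meta_d, meta_c = meta_c,
                 t2_criteria = c(lo, hi),
                 m_ratio = if (abs(d_prime) > 0) meta_d / d_prime else NA_real_,
                 loglik = -best$value, converged = converged, K = K),
            class = "meta_sdt_fit")
}

# Deterministic start: meta-d' at the type-1 d'; type-2 criteria at the
# pooled empirical quantile z-scores, re-anchored at meta_c.
meta_d_start <- function(n1, n2, d_prime, c_rel, K) {
  tot <- n1 + n2
  p <- cumsum(tot)[-(2 * K)] / sum(tot)
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  q <- stats::qnorm(p)
  # enforce strict increase
  for (i in seq_along(q)[-1]) if (q[i] <= q[i - 1]) q[i] <- q[i - 1] + 1e-3
  gaps_lo <- diff(q[1:K])
  gaps_hi <- diff(q[K:(2 * K - 1)])
  c(d_prime, log(pmax(gaps_lo, 1e-3)), log(pmax(gaps_hi, 1e-3)))
}

#' @export
print.meta_sdt_fit <- function(x, ...) {
  cat(sprintf("Meta-SDT fit (K = %d): d' = %.3f, c = %.3f\n", x$K,
              x$d_prime, x$c))
  cat(sprintf("  meta-d' = %.3f, m-ratio = %.3f, logLik = %.2f, converged: %s\n",
              x$meta_d_prime, x$m_ratio, x$loglik, x$converged))
  invisible(x)
}

#' Apply the convergence and d'-range exclusion rules to a set of fits
#'
#' A subject is excluded when any of its fits failed to converge, or when a
#' d' or meta-d' falls outside \code{d_range} (endpoints inclusive — only
#' values strictly outside the interval are excluded). The default range
#' [-1, 4] removes degenerate near-chance and near-ceiling observers for
#' whom SDT indices are unstable.
#'
#' @param fits a list of \code{meta_sdt_fit} objects (typically one per
#'   subject, or per subject x secondary variable), possibly named.
#' @param d_range numeric length-2 inclusive interval for d' and meta-d'.
#' @return data.frame with columns \code{id}, \code{d_prime},
#'   \code{meta_d_prime}, \code{m_ratio}, \code{converged}, \code{retained},
#'   \code{reason} (\code{""}, \code{"non-convergence"} or
#'   \code{"out-of-range"}).
#' @export
exclude_subjects <- function(fits, d_range = c(-1, 4)) {
  stopifnot(length(d_range) == 2, d_range[1] < d_range[2])
  ids <- names(fits)
  if (is.null(ids)) ids <- as.character(seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    reason <- ""
    if (!isTRUE(f$converged)) {
      reason <- "non-convergence"
    } else if (f$d_prime < d_range[1] || f$d_prime > d_range[2] ||
               f$meta_d_prime < d_range[1] || f$meta_d_prime > d_range[2]) {
      reason <- "out-of-range"
    }
    data.frame(id = ids[i], d_prime = f$d_prime,
               meta_d_prime = f$meta_d_prime, m_ratio = f$m_ratio,
               converged = isTRUE(f$converged),
               retained = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
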