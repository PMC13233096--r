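#' Discretize a continuous variable into quantile bins
#'
#' Assigns each value an ordinal level \code{1..n_bins} using the
#' \code{i/n_bins} empirical quantiles (type 7) as cutoffs. With
#' \code{orientation = "descending"} the \emph{smallest} values receive the
#' \emph{highest} level — the convention used for response times throughout
#' this package, so that level \code{n_bins} always means "fastest" and a
#' secondary-variable level of "high" reads as "fast". Ties at a cutoff are
#' assigned to the lower level (right-closed bins), which keeps the
#' assignment deterministic.
#'
#' Duplicate cutoffs (fewer distinct values than bins) are merged with a
#' warning; if all values are identical a single level is returned with a
#' warning.
#'
#' @param values numeric vector (RTs, logits, raw confidence signals).
#' @param n_bins number of quantile bins, >= 2.
#' @param orientation \code{"ascending"} (large value = high level) or
#'   \code{"descending"} (small value = high level; use for RT).
#' @param kind tag stored on the result: \code{"confidence"}, \code{"rt"} or
#'   \code{"composite"}.
#'
#' @return An integer vector of levels with class \code{"secondary_variable"}
#'   and attributes \code{K} (number of levels present), \code{kind},
#'   \code{cutoffs}.
#' @export
#' @examples
#' bin_by_quantiles(seq(100, 900, by = 100), 3, "descending")
bin_by_quantiles <- function(values,
                             n_bins,
                             orientation = c("ascending", "descending"),
                             kind = "rt") {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(values), length(values) > 0, n_bins >= 2)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  if (length(unique(values)) == 1L) {
    warning("all values identical; returning a single level", call. = FALSE)
    lev <- rep(1L, length(values))
    return(secondary_variable(lev, K = 1L, kind = kind, cutoffs = numeric(0)))
  }
  cutoffs <- stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                             type = 7, names = FALSE)
  dup <- duplicated(cutoffs)
  if (any(dup)) {
    warning(sprintf("degenerate binning: %d duplicated quantile cutoff(s) merged",
                    sum(dup)), call. = FALSE)
    cutoffs <- cutoffs[!dup]
  }
  # right-closed: value == cutoff stays in the lower bin
  lev <- findInterval(values, cutoffs, left.open = TRUE) + 1L
  # merged bins can leave unused top levels; relabel to consecutive 1..m
  lev <- match(lev, sort(unique(lev)))
  m <- max(lev)
  if (orientation == "descending") lev <- m + 1L - lev
  secondary_variable(as.integer(lev), K = m, kind = kind, cutoffs = cutoffs)
}

secondary_variable <- function(levels, K, kind, cutoffs = NULL) {
  structure(as.integer(levels), K = as.integer(K), kind = kind,
            cutoffs = cutoffs, class = "secondary_variable")
}

#' Use a trial table's ordinal confidence as the secondary variable
#' @param table a [trial_table()].
#' @return a \code{secondary_variable} of kind \code{"confidence"}.
#' @export
confidence_sv <- function(table) {
  secondary_variable(table$confidence, K = n_levels(table),
                     kind = "confidence")
}

#' @export
print.secondary_variable <- function(x, ...) {
  cat(sprintf("Secondary variable (%s): %d trials, K = %d levels\n",
              attr(x, "kind"), length(x), attr(x, "K")))
  invisible(x)
}

#' Stimulus x response x level frequency counts
#'
#' Tabulates trials jointly by stimulus class, response class, and
#' secondary-variable level into the standard \code{nR_S1}/\code{nR_S2}
#' layout used by meta-SDT analysis: for each stimulus class a vector of
#' length \code{2K} ordered as (response S1, level K..1, then response S2,
#' level 1..K), i.e. from "high-level S1 response" through the response
#' criterion to "high-level S2 response".
#'
#' @param table a [trial_table()].
#' @param sv a \code{secondary_variable} of the same length (defaults to the
#'   table's own confidence ratings).
#' @return An object of class \code{"count_matrix"}: list with integer
#'   vectors \code{nR_S1}, \code{nR_S2} (length \code{2K}) and \code{K}.
#' @export
counts_by_cell <- function(table, sv = confidence_sv(table)) {
  stopifnot(inherits(table, "trial_table"))
  if (length(sv) != nrow(table)) {
    stop("secondary variable length does not match trial table", call. = FALSE)
  }
  K <- attr(sv, "K")
  lev <- as.integer(sv)
  # slot 1..K: response S1 with level K..1; slot K+1..2K: response S2 level 1..K
  slot <- ifelse(table$response == "S1", K + 1L - lev, K + lev)
  count_one <- function(stim) {
    tabulate(slot[table$stimulus == stim], nbins = 2L * K)
  }
  structure(list(nR_S1 = count_one("S1"), nR_S2 = count_one("S2"), K = K),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: K = %d levels, %d S1 trials, %d S2 trials\n",
              x$K, sum(x$nR_S1), sum(x$nR_S2)))
  invisible(x)
}

#' Type-2 ROC curve and AUC
#'
#' Plots the proportion of trials on which the secondary variable exceeds a
#' cutoff ("high"), conditional on response correctness:
#' p(SV = high | incorrect) on the x-axis against
#' p(SV = high | correct) on the y-axis. The leftmost point uses the most
#' stringent cutoff (only level K counts as high); subsequent points use
#' progressively more lenient cutoffs. The area under the curve (trapezoidal,
#' including the implicit (0,0) and (1,1) endpoints) exceeds 0.5 to the
#' extent the secondary variable is diagnostic of correctness — for an
#' RT-based variable, to the extent correct responses are faster than errors.
#'
#' @param table a [trial_table()].
#' @param sv a \code{secondary_variable}; defaults to the table's confidence.
#' @return An object of class \code{"type2_curve"}: list with \code{points}
#'   (data.frame \code{cutoff}, \code{far2}, \code{hr2}, most stringent
#'   first) and \code{auc}.
#' @export
type2_roc <- function(table, sv = confidence_sv(table)) {
  stopifnot(inherits(table, "trial_table"))
  if (length(sv) != nrow(table)) {
    stop("secondary variable length does not match trial table", call. = FALSE)
  }
  n_cor <- sum(table$correct)
  n_inc <- sum(!table$correct)
  if (n_cor == 0 || n_inc == 0) {
    stop("type-2 ROC undefined: need at least one correct and one incorrect trial",
         call. = FALSE)
  }
  K <- attr(sv, "K")
  lev <- as.integer(sv)
  cuts <- if (K >= 2) K:2 else integer(0)
  hr2  <- vapply(cuts, function(cc) sum(lev >= cc & table$correct) / n_cor,
                 numeric(1))
  far2 <- vapply(cuts, function(cc) sum(lev >= cc & !table$correct) / n_inc,
                 numeric(1))
  x <- c(0, far2, 1)
  y <- c(0, hr2, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(points = data.frame(cutoff = cuts, far2 = far2, hr2 = hr2),
                 auc = auc, K = K, kind = attr(sv, "kind")),
            class = "type2_curve")
}

#' @export
print.type2_curve <- function(x, ...) {
  cat(sprintf("Type-2 ROC (%s, K = %d): AUC = %.4f\n",
              x$kind, x$K, x$auc))
  invisible(x)
}

#' Export a type-2 curve as a plain data frame
#' @param x a \code{type2_curve}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with \code{cutoff_index}, \code{far2}, \code{hr2}.
#' @export
as.data.frame.type2_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(cutoff_index = x$points$cutoff,
             far2 = x$points$far2, hr2 = x$points$hr2)
}
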