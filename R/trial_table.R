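#' Construct a validated trial table
#'
#' A trial table holds one row per 2AFC trial: subject label, stimulus class
#' (\code{"S1"}/\code{"S2"}), observer response (\code{"S1"}/\code{"S2"}),
#' an ordinal confidence rating in \code{1..K}, and the decision response
#' time in milliseconds. \code{correct} is always derived as
#' \code{stimulus == response}, and \code{trial_index} numbers trials
#' \code{1..n} within each subject in input order (the ordering used for
#' odd/even split-half analyses).
#'
#' @param subject vector of subject labels (coerced to character).
#' @param stimulus stimulus class; \code{"S1"}/\code{"S2"}, or \code{1}/\code{2},
#'   or \code{0}/\code{1} encodings are accepted.
#' @param response response class; same encodings as \code{stimulus}.
#' @param confidence integer confidence ratings, \code{1..K}.
#' @param rt decision response times, strictly positive and finite.
#' @param conf_raw optional auxiliary continuous confidence signal (used by
#'   the 2DSD simulator before discretization); \code{NULL} to omit.
#' @param K number of confidence levels; defaults to \code{max(confidence)}.
#'
#' @return A \code{data.frame} of class \code{"trial_table"} with columns
#'   \code{subject}, \code{stimulus}, \code{response}, \code{confidence},
#'   \code{rt}, \code{correct}, \code{trial_index} (and optionally
#'   \code{conf_raw}), and attribute \code{K}.
#' @export
#' @examples
#' tt <- trial_table(subject = rep("s1", 4),
#'                   stimulus = c(1, 2, 1, 2), response = c(1, 2, 2, 2),
#'                   confidence = c(3, 1, 2, 3), rt = c(540, 610, 700, 480))
#' tt$correct
trial_table <- function(subject, stimulus, response, confidence, rt,
                        conf_raw = NULL, K = NULL) {
  subject  <- as.character(subject)
  stimulus <- coerce_s1s2(stimulus, "stimulus")
  response <- coerce_s1s2(response, "response")
  n <- length(stimulus)
  if (length(subject) == 1L) subject <- rep(subject, n)
  if (length(subject) != n || length(response) != n ||
      length(confidence) != n || length(rt) != n) {
    stop("all trial columns must have the same length", call. = FALSE)
  }
  confidence <- as.integer(confidence)
  if (any(is.na(confidence)) || any(confidence < 1L)) {
    stop("confidence must be integer >= 1", call. = FALSE)
  }
  rt <- as.numeric(rt)
  if (any(!is.finite(rt)) || any(rt <= 0)) {
    stop("rt must be strictly positive and finite", call. = FALSE)
  }
  if (is.null(K)) K <- max(confidence)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (any(confidence > K)) stop("confidence exceeds K", call. = FALSE)

  out <- data.frame(subject = subject, stimulus = stimulus,
                    response = response, confidence = confidence, rt = rt,
                    stringsAsFactors = FALSE)
  out$correct <- out$stimulus == out$response
  out$trial_index <- stats::ave(seq_len(n), out$subject, FUN = seq_along)
  if (!is.null(conf_raw)) {
    if (length(conf_raw) != n) stop("conf_raw length mismatch", call. = FALSE)
    out$conf_raw <- as.numeric(conf_raw)
  }
  attr(out, "K") <- K
  class(out) <- c("trial_table", "data.frame")
  out
}

# Accepts "S1"/"S2", 1/2, 0/1 (and factors thereof); returns "S1"/"S2".
coerce_s1s2 <- function(x, what) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    ux <- unique(x[!is.na(x)])
    if (all(ux %in% c("S1", "S2"))) return(x)
    xn <- suppressWarnings(as.numeric(x))
    if (any(is.na(xn) & !is.na(x))) {
      stop(sprintf("cannot interpret %s values: %s", what,
                   paste(utils::head(setdiff(ux, c("S1", "S2")), 3),
                         collapse = ", ")), call. = FALSE)
    }
    x <- xn
  }
  ux <- sort(unique(x[!is.na(x)]))
  if (all(ux %in% c(1, 2))) {
    ifelse(x == 1, "S1", "S2")
  } else if (all(ux %in% c(0, 1))) {
    ifelse(x == 0, "S1", "S2")
  } else {
    stop(sprintf("%s must be coded S1/S2, 1/2, or 0/1", what), call. = FALSE)
  }
}

#' Number of confidence levels of a trial table
#' @param table a \code{trial_table}.
#' @return integer K.
#' @export
n_levels <- function(table) {
  K <- attr(table, "K")
  if (is.null(K)) max(table$confidence) else K
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, %d subject(s), K = %d confidence levels\n",
              nrow(x), length(unique(x$subject)), n_levels(x)))
  cat(sprintf("  accuracy %.3f, median RT %.0f ms\n",
              mean(x$correct), stats::median(x$rt)))
  NextMethod()
}

#' @export
`[.trial_table` <- function(x, ...) {
  K <- attr(x, "K")
  out <- NextMethod()
  if (is.data.frame(out) && all(c("stimulus", "response") %in% names(out))) {
    attr(out, "K") <- K
    class(out) <- c("trial_table", "data.frame")
  }
  out
}
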