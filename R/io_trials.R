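#' Read a per-trial behavioural CSV into a trial table
#'
#' Reads trial-level 2AFC data in the Confidence Database CSV dialect
#' (columns \code{Subj_idx}, \code{Stimulus}, \code{Response},
#' \code{Confidence}, \code{RT_dec}). Files from different labs name their
#' columns differently, so an explicit \code{column_map} can override the
#' defaults; the reader never guesses, because silently binding the wrong RT
#' column would corrupt every downstream estimate.
#'
#' Rows with a missing stimulus, response, confidence, or RT are dropped and
#' the count is reported via \code{message()}. Stimulus and response codes
#' \code{1/2} or \code{0/1} are coerced to \code{"S1"}/\code{"S2"}.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map named character vector overriding any of
#'   \code{c(subject=, stimulus=, response=, confidence=, rt=)}.
#' @param rt_multiplier scalar applied to the RT column (e.g. 1000 for files
#'   recorded in seconds). No unit auto-detection is attempted.
#' @param K number of confidence levels; default \code{max(confidence)}.
#'
#' @return A [trial_table()].
#' @export
read_trials <- function(path, column_map = NULL, rt_multiplier = 1, K = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cmap <- c(subject = "Subj_idx", stimulus = "Stimulus",
            response = "Response", confidence = "Confidence", rt = "RT_dec")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad)) stop("unknown column_map entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cmap[names(column_map)] <- column_map
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- cmap[!cmap %in% names(raw)]
  if (length(missing_cols)) {
    stop("required column(s) not found in ", path, ": ",
         paste(sprintf("%s (for %s)", missing_cols, names(missing_cols)),
               collapse = ", "), call. = FALSE)
  }
  dat <- raw[, unname(cmap)]
  names(dat) <- names(cmap)
  # treat empty strings as missing, then drop incomplete rows
  for (nm in names(dat)) dat[[nm]][dat[[nm]] == ""] <- NA
  dat$confidence <- suppressWarnings(as.numeric(dat$confidence))
  dat$rt <- suppressWarnings(as.numeric(dat$rt)) * rt_multiplier
  keep <- stats::complete.cases(dat) & is.finite(dat$rt) & dat$rt > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("read_trials: dropped %d of %d rows with missing/invalid fields",
                    n_drop, nrow(dat)))
  }
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) == 0) stop("no valid trials remain after filtering: ", path,
                           call. = FALSE)
  trial_table(subject = dat$subject, stimulus = dat$stimulus,
              response = dat$response, confidence = dat$confidence,
              rt = dat$rt, K = K)
}

#' Write a trial table to CSV
#'
#' Writes the canonical dialect (\code{Subj_idx}, \code{Stimulus},
#' \code{Response}, \code{Confidence}, \code{RT_dec}, with stimulus/response
#' coded 1/2) so that \code{read_trials(write_trials(t))} reproduces \code{t}
#' field for field.
#'
#' @param table a [trial_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  out <- data.frame(
    Subj_idx   = table$subject,
    Stimulus   = ifelse(table$stimulus == "S1", 1L, 2L),
    Response   = ifelse(table$response == "S1", 1L, 2L),
    Confidence = table$confidence,
    RT_dec     = table$rt
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
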