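#' Analysis configuration
#'
#' Bundles the pipeline's tunable constants. Defaults: d'/meta-d' retention
#' range [-1, 4], Spearman-Brown screening threshold 0.45, slow-RT
#' exclusion at 3000 ms, 10 quantile levels for simulation variables, 20
#' equal-width RT bins for accuracy profiles.
#'
#' @param d_range inclusive retention interval for d' and meta-d'.
#' @param reliability_threshold Spearman-Brown screen.
#' @param rt_cutoff slow-RT exclusion, ms.
#' @param sim_levels quantile levels for simulation secondary variables.
#' @param accuracy_bins equal-width RT bins for [accuracy_by_rt_bins()].
#' @param min_trials per-subject floor for composite fits.
#' @param seed default seed.
#' @return list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(d_range = c(-1, 4), reliability_threshold = 0.45,
                            rt_cutoff = 3000, sim_levels = 10,
                            accuracy_bins = 20, min_trials = 20, seed = 1) {
  structure(list(d_range = d_range,
                 reliability_threshold = reliability_threshold,
                 rt_cutoff = rt_cutoff, sim_levels = sim_levels,
                 accuracy_bins = accuracy_bins, min_trials = min_trials,
                 seed = seed),
            class = "analysis_config")
}

# Fit the three secondary-variable variants for one subject's trials.
# Returns a list of meta_sdt_fit objects (confidence, rt, composite) or
# NULL if a stage is unfittable.
fit_subject_variants <- function(st, K, min_trials = 20) {
  svs <- list(confidence = confidence_sv(st))
  svs$rt <- suppressWarnings(bin_by_quantiles(st$rt, K, "descending", "rt"))
  cm <- try(fit_composite(st, min_trials = min_trials), silent = TRUE)
  if (inherits(cm, "try-error")) return(NULL)
  svs$composite <- suppressWarnings(composite_logits(cm, st, K))
  fits <- lapply(svs, function(sv) {
    try(fit_meta_d(counts_by_cell(st, sv)), silent = TRUE)
  })
  if (any(vapply(fits, inherits, logical(1), "try-error"))) return(NULL)
  fits$composite_model <- cm
  fits
}

#' Run the empirical meta-SDT pipeline over one or more datasets
#'
#' For every subject in every dataset: fit meta-d' using (i) the ordinal
#' confidence ratings, (ii) RT discretized into the dataset's K quantile
#' bins, and (iii) the per-subject logistic confidence-RT composite binned
#' into K levels. Subjects with any non-convergent fit, or any d'/meta-d'
#' outside \code{config$d_range}, are excluded. Per-dataset means,
#' cross-subject Pearson correlations between the indices (with 95\% CIs),
#' and — with more than one dataset — random-effects meta-analyses of the
#' correlations are returned.
#'
#' @param tables a named list of [trial_table()] objects (one per dataset),
#'   or a single trial table.
#' @param config an [analysis_config()].
#' @return list of class \code{"empirical_result"} with elements
#'   \code{subject_fits} (long data.frame: dataset, subject, variant,
#'   d_prime, meta_d, m_ratio, converged, retained, reason),
#'   \code{dataset_summary} (per-dataset means over retained subjects),
#'   \code{correlations} (per-dataset r + CI per index pair), and
#'   \code{meta} (list of \code{meta_analysis_result} per pair, or NULL).
#' @export
run_empirical <- function(tables, config = analysis_config()) {
  if (inherits(tables, "trial_table")) tables <- list(dataset1 = tables)
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))

  fit_rows <- list()
  wide_rows <- list()
  for (ds in names(tables)) {
    tab <- tables[[ds]]
    K <- n_levels(tab)
    for (sj in unique(tab$subject)) {
      st <- tab[tab$subject == sj, ]
      fits <- fit_subject_variants(st, K, config$min_trials)
      if (is.null(fits)) {
        message(sprintf("run_empirical: subject %s/%s unfittable, skipped", ds, sj))
        next
      }
      variant_fits <- fits[c("confidence", "rt", "composite")]
      part <- exclude_subjects(variant_fits, config$d_range)
      retained <- all(part$retained)
      reason <- paste(unique(part$reason[part$reason != ""]), collapse = ";")
      for (v in c("confidence", "rt", "composite")) {
        f <- variant_fits[[v]]
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          dataset = ds, subject = sj, variant = v, d_prime = f$d_prime,
          meta_d = f$meta_d_prime, m_ratio = f$m_ratio,
          converged = f$converged, retained = retained, reason = reason,
          stringsAsFactors = FALSE)
      }
      if (retained) {
        wide_rows[[length(wide_rows) + 1L]] <- data.frame(
          dataset = ds, subject = sj,
          d_prime = variant_fits$confidence$d_prime,
          meta_d_conf = variant_fits$confidence$meta_d_prime,
          meta_d_rt = variant_fits$rt$meta_d_prime,
          meta_d_comp = variant_fits$composite$meta_d_prime,
          m_ratio_conf = variant_fits$confidence$m_ratio,
          m_ratio_rt = variant_fits$rt$m_ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  subject_fits <- do.call(rbind, fit_rows)
  wide <- do.call(rbind, wide_rows)
  if (is.null(wide) || nrow(wide) == 0) {
    stop("no retained subjects in any dataset", call. = FALSE)
  }

  agg <- function(df) {
    data.frame(n_subjects = nrow(df),
               d_prime = mean(df$d_prime),
               meta_d_conf = mean(df$meta_d_conf),
               meta_d_rt = mean(df$meta_d_rt),
               meta_d_comp = mean(df$meta_d_comp))
  }
  dataset_summary <- do.call(rbind, lapply(split(wide, wide$dataset), agg))
  dataset_summary$dataset <- rownames(dataset_summary)
  rownames(dataset_summary) <- NULL

  pairs <- list(conf_rt = c("meta_d_conf", "meta_d_rt"),
                conf_comp = c("meta_d_conf", "meta_d_comp"),
                mratio_conf_rt = c("m_ratio_conf", "m_ratio_rt"))
  cor_rows <- list()
  for (ds in unique(wide$dataset)) {
    w <- wide[wide$dataset == ds, ]
    if (nrow(w) < 4) {
      message(sprintf("run_empirical: dataset %s has < 4 retained subjects; correlations skipped", ds))
      next
    }
    for (p in names(pairs)) {
      ct <- stats::cor.test(w[[pairs[[p]][1]]], w[[pairs[[p]][2]]])
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        dataset = ds, pair = p, r = unname(ct$estimate), n = nrow(w),
        ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
        stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(cor_rows)) do.call(rbind, cor_rows) else NULL

  meta <- NULL
  if (!is.null(correlations) && length(unique(correlations$dataset)) > 1) {
    meta <- lapply(names(pairs), function(p) {
      pc <- correlations[correlations$pair == p, ]
      meta_analyze_r(data.frame(study = pc$dataset, r = pc$r, n = pc$n))
    })
    names(meta) <- names(pairs)
  }
  structure(list(subject_fits = subject_fits, retained = wide,
                 dataset_summary = dataset_summary,
                 correlations = correlations, meta = meta,
                 config = config),
            class = "empirical_result")
}

#' @export
print.empirical_result <- function(x, ...) {
  n_tot <- length(unique(paste(x$subject_fits$dataset, x$subject_fits$subject)))
  cat(sprintf("Empirical meta-SDT pipeline: %d dataset(s), %d subjects (%d retained)\n",
              nrow(x$dataset_summary), n_tot, nrow(x$retained)))
  cat(sprintf("  mean d' = %.3f, meta-d' conf/RT/composite = %.3f / %.3f / %.3f\n",
              mean(x$retained$d_prime), mean(x$retained$meta_d_conf),
              mean(x$retained$meta_d_rt), mean(x$retained$meta_d_comp)))
  if (!is.null(x$meta)) {
    cat(sprintf("  pooled r(meta-d' conf, meta-d' RT) = %.3f\n",
                x$meta$conf_rt$pooled_r))
  }
  invisible(x)
}

#' Collapse confidence levels into coarser groups
#'
#' @param confidence integer ratings.
#' @param groups list of integer vectors, each one group (e.g.
#'   \code{list(1:2, 3:4, 5:6)}); defaults to pairing consecutive levels
#'   when the scale has 6 levels, otherwise the identity.
#' @return integer group index per trial.
#' @export
collapse_confidence <- function(confidence, groups = NULL) {
  if (is.null(groups)) {
    K <- max(confidence)
    groups <- if (K == 6) list(1:2, 3:4, 5:6) else as.list(seq_len(K))
  }
  out <- rep(NA_integer_, length(confidence))
  for (g in seq_along(groups)) out[confidence %in% groups[[g]]] <- g
  if (any(is.na(out))) stop("confidence value not covered by groups", call. = FALSE)
  out
}

#' Accuracy profiles over equal-width RT bins
#'
#' Divides each subject's RT range into \code{n_rt_bins} equal-\emph{width}
#' bins (not quantiles — so bin index is comparable across subjects with
#' different RT distributions) and computes mean accuracy per confidence
#' group x RT bin. Empty cells are emitted with \code{NA} accuracy, giving
#' a complete long-format grid ready for external smoothing.
#'
#' @param table a [trial_table()].
#' @param n_rt_bins number of equal-width bins (default 20).
#' @param confidence_grouping passed to [collapse_confidence()] as
#'   \code{groups}.
#' @return data.frame: \code{subject}, \code{conf_group}, \code{rt_bin},
#'   \code{n}, \code{accuracy}.
#' @export
accuracy_by_rt_bins <- function(table, n_rt_bins = 20,
                                confidence_grouping = NULL) {
  stopifnot(inherits(table, "trial_table"), n_rt_bins >= 2)
  grp <- collapse_confidence(table$confidence, confidence_grouping)
  rows <- list()
  for (sj in unique(table$subject)) {
    idx <- table$subject == sj
    rt <- table$rt[idx]
    if (max(rt) == min(rt)) {
      stop(sprintf("degenerate binning: constant RT for subject %s", sj),
           call. = FALSE)
    }
    breaks <- seq(min(rt), max(rt), length.out = n_rt_bins + 1)
    bin <- findInterval(rt, breaks, rightmost.closed = TRUE)
    g <- grp[idx]
    correct <- table$correct[idx]
    for (cg in sort(unique(grp))) {
      for (b in seq_len(n_rt_bins)) {
        sel <- g == cg & bin == b
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sj, conf_group = cg, rt_bin = b, n = sum(sel),
          accuracy = if (any(sel)) mean(correct[sel]) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Export a model-ready long-format trial table
#'
#' One row per trial with the predictors used by trial-level regression
#' models of correctness: dataset, subject, correct, confidence, rt, and
#' the confidence x RT product.
#'
#' @param tables named list of [trial_table()] objects (or one table).
#' @param path optional CSV output path.
#' @return the data.frame, invisibly if written to \code{path}.
#' @export
export_glmm_table <- function(tables, path = NULL) {
  if (inherits(tables, "trial_table")) tables <- list(dataset1 = tables)
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  out <- do.call(rbind, lapply(names(tables), function(ds) {
    t <- tables[[ds]]
    data.frame(dataset = ds, subject = t$subject,
               correct = as.integer(t$correct), confidence = t$confidence,
               rt = t$rt, confidence_rt = t$confidence * t$rt,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Paired comparison of meta-d' variants within a dataset
#'
#' Two-sided paired t-test of one meta-d' index against another across the
#' retained subjects of a dataset.
#'
#' @param retained the \code{retained} data.frame of an
#'   \code{empirical_result}.
#' @param a,b column names, e.g. \code{"meta_d_conf"} vs \code{"meta_d_rt"}.
#' @return data.frame per dataset: mean difference, t, df, p.
#' @export
compare_variants <- function(retained, a = "meta_d_conf", b = "meta_d_rt") {
  do.call(rbind, lapply(split(retained, retained$dataset), function(w) {
    tt <- stats::t.test(w[[a]], w[[b]], paired = TRUE)
    data.frame(dataset = w$dataset[1], mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
}
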