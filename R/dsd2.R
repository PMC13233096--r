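#' 2DSD simulator parameters
#'
#' Parameter container for the two-stage dynamic signal detection model:
#' a drift-diffusion decision stage (single accumulator encoding the
#' evidence difference between the two stimuli, absorbing boundaries at
#' +/- a/2) followed by \code{t_pd} further accumulation steps from which
#' confidence is read out as the relative evidence in favour of the chosen
#' option. One step corresponds to 1 ms.
#'
#' Defaults encode the package's reference condition grid: the decision
#' boundary \code{a} was calibrated so that the grid-average d' equals 1.13
#' and \code{t_pd} so that the grid-average confidence-based meta-d' equals
#' 0.81 (see \code{vignette("metaRT-methods")} and [default_dsd_grid()]).
#'
#' @param nu_target mean target drift rate (evidence units/step).
#' @param nu_distractor mean distractor drift rate.
#' @param eta trial-to-trial SD of each stream's drift rate.
#' @param s within-trial increment SD per stream per step.
#' @param s_z range of the uniform starting-point distribution (centred on
#'   the midpoint; must satisfy \code{0 <= s_z < a}).
#' @param a boundary separation on the relative-evidence axis (boundaries
#'   at +/- a/2).
#' @param t_er non-decision time, ms, added to the decision time.
#' @param t_pd post-decisional accumulation steps feeding confidence.
#' @param max_steps cap on decision steps; trials that never cross are
#'   censored (and excluded downstream together with RT > \code{rt_cutoff}).
#' @return list of class \code{"dsd_params"}.
#' @export
dsd_params <- function(nu_target = 0.02, nu_distractor = 0.01, eta = 0.008,
                       s = 0.1, s_z = 0, a = 2.61, t_er = 300, t_pd = 21,
                       max_steps = 3000) {
  stopifnot(s > 0, a > 0, t_pd >= 0, s_z >= 0, s_z < a, t_er >= 0,
            max_steps >= 1)
  structure(list(nu_target = nu_target, nu_distractor = nu_distractor,
                 eta = eta, s = s, s_z = s_z, a = a, t_er = t_er,
                 t_pd = as.integer(t_pd), max_steps = as.integer(max_steps)),
            class = "dsd_params")
}

#' @export
print.dsd_params <- function(x, ...) {
  cat("2DSD parameters:\n")
  cat(sprintf("  nu_target = %g, nu_distractor = %g, eta = %g, s = %g\n",
              x$nu_target, x$nu_distractor, x$eta, x$s))
  cat(sprintf("  s_z = %g, a = %g, t_er = %g, t_pd = %d, max_steps = %d\n",
              x$s_z, x$a, x$t_er, x$t_pd, x$max_steps))
  invisible(x)
}

#' Simulate one 2DSD condition into a trial table
#'
#' Runs \code{n_trials} trials with the target-distractor assignment
#' counterbalanced between S1 and S2 (exactly half each before exclusion),
#' then removes censored trials and trials with RT > \code{rt_cutoff}
#' (defaults to the conventional 3000 ms slow-RT exclusion, applied to the
#' full RT including non-decision time). The continuous post-decisional
#' confidence signal is carried in the \code{conf_raw} column; the ordinal
#' \code{confidence} column is a placeholder (all 1/2 by correctness) until
#' [discretize_outputs()] is applied.
#'
#' @param params a [dsd_params()] object.
#' @param n_trials even number of trials before exclusion.
#' @param seed integer seed (all randomness flows through R's RNG, so the
#'   same seed reproduces the table bit-for-bit).
#' @param rt_cutoff slow-RT exclusion threshold in ms.
#' @param subject subject label for the output table.
#' @return a [trial_table()] with auxiliary \code{conf_raw} column.
#' @export
simulate_condition <- function(params, n_trials, seed = NULL,
                               rt_cutoff = 3000, subject = "sim") {
  stopifnot(inherits(params, "dsd_params"), n_trials >= 2)
  if (n_trials %% 2L != 0L) {
    stop("n_trials must be even for counterbalancing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- dsd_core(as.integer(n_trials), params$nu_target,
                  params$nu_distractor, params$eta, params$s, params$s_z,
                  params$a, params$t_er, params$t_pd, params$max_steps)
  # counterbalanced target assignment, independent of the dynamics
  stim <- rep_len(c("S1", "S2"), n_trials)
  keep <- !sim$censored & sim$rt <= rt_cutoff
  if (!any(keep)) {
    stop("all trials censored or excluded; pathological parameters",
         call. = FALSE)
  }
  stim <- stim[keep]
  chose_target <- sim$choice_target[keep] == 1L
  resp <- ifelse(chose_target, stim, ifelse(stim == "S1", "S2", "S1"))
  trial_table(subject = rep(subject, sum(keep)), stimulus = stim,
              response = resp,
              confidence = ifelse(chose_target, 2L, 1L),  # placeholder
              rt = sim$rt[keep], conf_raw = sim$conf_raw[keep], K = 2L)
}

#' Discretize simulator output into ordinal confidence and an RT variable
#'
#' Converts the continuous post-decisional evidence (\code{conf_raw}) into
#' \code{n_levels} ordinal confidence levels using its quantiles (ascending:
#' more chosen-option evidence = higher confidence) and bins RT into
#' \code{n_levels} quantile levels (descending: faster = higher level),
#' each computed within the given table (i.e. per condition).
#'
#' @param table a [trial_table()] with a \code{conf_raw} column.
#' @param n_levels number of quantile levels (default 10).
#' @return list with \code{table} (confidence replaced by its discretized
#'   levels, \code{K = n_levels}) and \code{rt_sv} (a
#'   \code{secondary_variable} of kind \code{"rt"}).
#' @export
discretize_outputs <- function(table, n_levels = 10) {
  stopifnot(inherits(table, "trial_table"), !is.null(table$conf_raw))
  conf_sv <- bin_by_quantiles(table$conf_raw, n_levels, "ascending",
                              kind = "confidence")
  rt_sv <- bin_by_quantiles(table$rt, n_levels, "descending", kind = "rt")
  out <- trial_table(subject = table$subject, stimulus = table$stimulus,
                     response = table$response,
                     confidence = as.integer(conf_sv), rt = table$rt,
                     conf_raw = table$conf_raw, K = attr(conf_sv, "K"))
  list(table = out, rt_sv = rt_sv)
}

#' Reference 2DSD condition grid
#'
#' The manipulation grid crossing mean target drift rate (stimulus
#' intensity), trial-to-trial drift variability \code{eta}, and
#' starting-point variability \code{s_z}, with all other parameters fixed.
#' The target drift levels span near-chance to near-perfect type-1
#' performance; the \code{eta} levels move RT type-2 performance from null
#' to strongly positive (slow errors); the \code{s_z} levels push it toward
#' the fast-error regime (negative RT-based meta-d'). Boundary \code{a} and
#' post-decisional duration \code{t_pd} are the calibrated constants
#' described in [dsd_params()].
#'
#' @param nu_target,eta,s_z manipulated values (full crossing is used).
#' @param ... fixed-parameter overrides passed to [dsd_params()].
#' @return data.frame with one row per condition and a \code{params} list
#'   column of [dsd_params()] objects.
#' @export
default_dsd_grid <- function(nu_target = c(0.012, 0.016, 0.020, 0.025, 0.030),
                             eta = c(0.004, 0.008, 0.016),
                             s_z = c(0, 1.05, 2.10), ...) {
  g <- expand.grid(nu_target = nu_target, eta = eta, s_z = s_z,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$s_z, g$eta, g$nu_target), , drop = FALSE]
  rownames(g) <- NULL
  g$condition <- sprintf("nu%g_eta%g_sz%g", g$nu_target, g$eta, g$s_z)
  g$params <- lapply(seq_len(nrow(g)), function(i) {
    dsd_params(nu_target = g$nu_target[i], eta = g$eta[i], s_z = g$s_z[i], ...)
  })
  g
}

#' Simulate a condition grid and fit the three meta-SDT variants
#'
#' For every condition: simulate, apply the slow-RT exclusion, discretize
#' confidence and RT into \code{n_levels} quantile levels, fit meta-d' on
#' (i) discretized confidence, (ii) binned RT, and (iii) the composite
#' logistic logit of correctness on raw confidence, raw RT and their
#' interaction (logits binned into \code{n_levels} levels). Per-condition
#' seeds are spawned deterministically from \code{seed}, so the whole grid
#' is reproducible bit-for-bit.
#'
#' @param grid a grid from [default_dsd_grid()] (or a compatible data.frame
#'   with a \code{params} list column and \code{condition} labels).
#' @param n_trials trials per condition before exclusion (the reference
#'   simulation uses 200,000; 20,000 gives a faster run with wider Monte
#'   Carlo error).
#' @param seed master seed.
#' @param n_levels quantile levels for all three secondary variables.
#' @param rt_cutoff slow-RT exclusion in ms.
#' @return object of class \code{"dsd_grid_result"}: list with
#'   \code{summary} (one row per condition: d', the three meta-d' values,
#'   the three m-ratios, \code{ratio_comp_conf}, trial counts, composite
#'   coefficients) and \code{fits} (per-condition list of the three
#'   \code{meta_sdt_fit} objects).
#' @export
run_grid <- function(grid = default_dsd_grid(), n_trials = 20000, seed = 1,
                     n_levels = 10, rt_cutoff = 3000) {
  stopifnot(is.data.frame(grid), "params" %in% names(grid))
  n_cond <- nrow(grid)
  fits <- vector("list", n_cond)
  rows <- vector("list", n_cond)
  for (i in seq_len(n_cond)) {
    cond_seed <- (seed + 7919L * i) %% 2147483647L
    tab <- simulate_condition(grid$params[[i]], n_trials, seed = cond_seed,
                              rt_cutoff = rt_cutoff,
                              subject = grid$condition[i])
    disc <- discretize_outputs(tab, n_levels)
    fit_conf <- fit_meta_d(counts_by_cell(disc$table))
    fit_rt <- fit_meta_d(counts_by_cell(disc$table, disc$rt_sv))
    cm <- fit_composite(disc$table, confidence = disc$table$conf_raw)
    sv_comp <- composite_logits(cm, disc$table, n_levels,
                                confidence = disc$table$conf_raw)
    fit_comp <- fit_meta_d(counts_by_cell(disc$table, sv_comp))
    all_ok <- fit_conf$converged && fit_rt$converged && fit_comp$converged
    if (!all_ok) {
      message(sprintf("run_grid: non-convergent fit in condition %s",
                      grid$condition[i]))
    }
    fits[[i]] <- list(confidence = fit_conf, rt = fit_rt,
                      composite = fit_comp, composite_model = cm)
    rows[[i]] <- data.frame(
      condition = grid$condition[i], nu_target = grid$nu_target[i],
      eta = grid$eta[i], s_z = grid$s_z[i],
      n_retained = nrow(tab), n_excluded = n_trials - nrow(tab),
      d_prime = fit_conf$d_prime,
      meta_d_conf = fit_conf$meta_d_prime,
      meta_d_rt = fit_rt$meta_d_prime,
      meta_d_comp = fit_comp$meta_d_prime,
      m_ratio_conf = fit_conf$m_ratio, m_ratio_rt = fit_rt$m_ratio,
      m_ratio_comp = fit_comp$m_ratio,
      ratio_comp_conf = fit_comp$meta_d_prime / fit_conf$meta_d_prime,
      beta_conf = cm$beta_conf, beta_rt = cm$beta_rt,
      beta_interaction = cm$beta_interaction,
      converged = all_ok, stringsAsFactors = FALSE)
  }
  names(fits) <- grid$condition
  structure(list(summary = do.call(rbind, rows), fits = fits,
                 n_trials = n_trials, seed = seed, n_levels = n_levels),
            class = "dsd_grid_result")
}

#' @export
print.dsd_grid_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("2DSD grid result: %d conditions, %d trials each (seed %d)\n",
              nrow(s), x$n_trials, x$seed))
  cat(sprintf("  mean d' = %.3f, mean meta-d'_conf = %.3f, mean meta-d'_RT = %.3f\n",
              mean(s$d_prime), mean(s$meta_d_conf), mean(s$meta_d_rt)))
  cat(sprintf("  max composite/confidence meta-d' ratio = %.3f\n",
              max(s$ratio_comp_conf)))
  invisible(x)
}
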