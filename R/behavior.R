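#' Per-trial response time metrics
#'
#' Reaction time (RT) is the time from go signal to movement onset; movement
#' time (MT) from movement onset to handle touch; acquisition time (AT) from
#' touch to the first force sample at or above the condition's band minimum,
#' clipped at 0 when the force is already inside the band at touch (typical
#' for low-force trials, whose band minimum is 0 N). A metric whose events
#' are missing, or whose force never enters the band, is NA rather than 0;
#' trials with undefined AT are flagged unsuccessful in the output.
#'
#' @param trial_table trial table (see [simulate_session()]).
#' @param force_traces list of per-trial [continuous_signal()] force traces
#'   (NULL entries allowed for trials without traces).
#' @param force_bands named list of (min, max) per force level.
#' @return Data frame: trial_id, condition, RT, MT, AT (ms), n_touches,
#'   success.
#' @export
compute_response_times <- function(trial_table, force_traces,
                                   force_bands = task_config()$force_bands) {
  n <- nrow(trial_table)
  RT <- trial_table$t_move - trial_table$t_go
  MT <- trial_table$t_touch - trial_table$t_move
  AT <- rep(NA_real_, n)
  success <- trial_table$success
  for (i in seq_len(n)) {
    tr <- force_traces[[i]]
    if (is.null(tr) || is.na(trial_table$t_touch[i])) next
    bmin <- force_bands[[trial_table$force[i]]][1]
    ts <- tr$t0 + (seq_along(tr$samples) - 1) * 1000 / tr$rate
    post <- which(tr$samples >= bmin & ts >= trial_table$t_touch[i])
    pre <- any(tr$samples >= bmin & ts < trial_table$t_touch[i] & ts >= trial_table$t_move[i])
    if (bmin == 0 || pre) {
      AT[i] <- 0                          # already inside the band at touch
    } else if (length(post)) {
      AT[i] <- ts[post[1]] - trial_table$t_touch[i]
    } else {
      success[i] <- FALSE                 # force never reached the band
    }
  }
  data.frame(trial_id = trial_table$trial_id,
             condition = trial_table$condition,
             RT = RT, MT = MT, AT = AT,
             n_touches = trial_table$n_touches,
             success = success, stringsAsFactors = FALSE)
}

#' Exclude trials with unusually long response times
#'
#' A trial is excluded when RT > `rt_max` (500 ms), MT > `mt_max` (350 ms),
#' AT > `at_max` (1500 ms) -- strict inequalities, so a trial exactly at a
#' threshold is retained -- or when more than one handle touch was
#' registered. Unsuccessful trials are excluded as well. The per-rule
#' exclusion counts are returned alongside the keep mask; applying the rules
#' is idempotent and order-independent because each rule is evaluated on the
#' original metrics.
#'
#' @param metrics data frame from [compute_response_times()].
#' @param rt_max,mt_max,at_max thresholds in ms.
#' @return List: `keep` (logical mask), `log` (per-rule counts, overlaps
#'   counted in every rule they violate), `n_excluded`.
#' @export
exclude_trials <- function(metrics, rt_max = 500, mt_max = 350, at_max = 1500) {
  v_rt <- !is.na(metrics$RT) & metrics$RT > rt_max
  v_mt <- !is.na(metrics$MT) & metrics$MT > mt_max
  v_at <- !is.na(metrics$AT) & metrics$AT > at_max
  v_touch <- metrics$n_touches > 1
  v_fail <- !metrics$success
  keep <- !(v_rt | v_mt | v_at | v_touch | v_fail)
  list(keep = keep,
       log = c(rt = sum(v_rt), mt = sum(v_mt), at = sum(v_at),
               multi_touch = sum(v_touch), unsuccessful = sum(v_fail)),
       n_excluded = sum(!keep))
}

#' Per-condition task performance
#'
#' Two success denominators: trials initiated after cue-epoch onset (an
#' index of condition preference, since fixation is broken more often for
#' less preferred conditions) and trials initiated after the go signal (an
#' index of execution ability). Also reports the eye-fixation-error
#' fraction (failures before go).
#'
#' @param trial_table trial table.
#' @return Data frame per condition: n_after_cue, n_after_go,
#'   success_after_cue, success_after_go, eye_fixation_error.
#' @export
performance_summary <- function(trial_table) {
  conds <- task_conditions()$condition
  pre_go <- c("fixation", "cue", "memory")
  out <- lapply(conds, function(cc) {
    tt <- trial_table[trial_table$condition == cc, ]
    after_cue <- is.na(tt$failure_stage) | tt$failure_stage != "fixation"
    after_go <- is.na(tt$failure_stage) | !(tt$failure_stage %in% pre_go)
    data.frame(condition = cc,
               n_after_cue = sum(after_cue), n_after_go = sum(after_go),
               success_after_cue = if (any(after_cue)) mean(tt$success[after_cue]) else NA,
               success_after_go = if (any(after_go)) mean(tt$success[after_go]) else NA,
               eye_fixation_error = mean(!is.na(tt$failure_stage) &
                                           tt$failure_stage %in% pre_go),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Mean force of each trial over a window after touch.
window_mean_force <- function(trial_table, force_traces, window = c(0, 100)) {
  vapply(seq_len(nrow(trial_table)), function(i) {
    tr <- force_traces[[i]]
    if (is.null(tr) || is.na(trial_table$t_touch[i])) return(NA_real_)
    ts <- tr$t0 + (seq_along(tr$samples) - 1) * 1000 / tr$rate
    sel <- ts >= trial_table$t_touch[i] + window[1] &
      ts < trial_table$t_touch[i] + window[2]
    if (!any(sel)) return(NA_real_)
    mean(tr$samples[sel])
  }, 0)
}

#' Early force divergence between force levels
#'
#' Tests, separately for each grip type, whether the applied force already
#' differs between force levels in the first 100 ms after handle touch:
#' one-way ANOVA on the per-trial mean force in the window, followed by
#' Tukey-Kramer pairwise comparisons (studentized range with unequal group
#' sizes, as implemented by [stats::TukeyHSD()]). The characteristic
#' pattern is an early divergence of the low force condition while medium
#' and high do not yet differ.
#'
#' @param force_traces list of per-trial force traces.
#' @param trial_table trial table (only successful trials are used).
#' @param window (start, end) ms relative to touch.
#' @return Object of class `force_divergence`: per grip, the ANOVA p-value
#'   and the Tukey-Kramer table.
#' @export
compare_force_levels <- function(force_traces, trial_table, window = c(0, 100)) {
  if (diff(window) <= 0) stop("empty comparison window")
  mf <- window_mean_force(trial_table, force_traces, window)
  out <- list()
  for (g in GRIPS) {
    sel <- trial_table$grip == g & trial_table$success & !is.na(mf)
    d <- data.frame(force = factor(trial_table$force[sel], levels = FORCES),
                    y = mf[sel])
    if (any(table(d$force) < 2)) stop("need >= 2 trials per condition")
    fit <- aov(y ~ force, data = d)
    tk <- TukeyHSD(fit)$force
    out[[g]] <- list(anova_p = summary(fit)[[1]][["Pr(>F)"]][1], tukey = tk)
  }
  structure(c(out, list(window = window)), class = "force_divergence")
}

#' @export
print.force_divergence <- function(x, ...) {
  cat(sprintf("Force divergence in (%g, %g) ms after touch\n",
              x$window[1], x$window[2]))
  for (g in GRIPS) {
    cat(sprintf("\n%s grip: ANOVA p = %.3g\n", g, x[[g]]$anova_p))
    print(round(x[[g]]$tukey, 4))
  }
  invisible(x)
}

#' Fraction of trials overshooting the force band
#'
#' Per condition, the fraction of successful trials whose force exceeds the
#' band maximum at any sample between handle touch and reward onset.
#'
#' @param force_traces list of per-trial force traces.
#' @param trial_table trial table.
#' @param force_bands named list of (min, max) per force level.
#' @return Named numeric vector over the six conditions.
#' @export
overshoot_fraction <- function(force_traces, trial_table,
                               force_bands = task_config()$force_bands) {
  conds <- task_conditions()$condition
  over <- vapply(seq_len(nrow(trial_table)), function(i) {
    tr <- force_traces[[i]]
    if (is.null(tr) || is.na(trial_table$t_reward[i])) return(NA)
    bmax <- force_bands[[trial_table$force[i]]][2]
    ts <- tr$t0 + (seq_along(tr$samples) - 1) * 1000 / tr$rate
    sel <- ts >= trial_table$t_touch[i] & ts <= trial_table$t_reward[i]
    any(tr$samples[sel] > bmax)
  }, NA)
  vapply(setNames(conds, conds), function(cc) {
    sel <- trial_table$condition == cc & trial_table$success & !is.na(over)
    if (!any(sel)) return(NA_real_)
    mean(over[sel])
  }, 0)
}
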