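TRIAL_TABLE_COLS <- c("trial_id", "condition", "grip", "force", "t_start",
                      "t_cue_on", "t_cue_off", "t_go", "t_move", "t_touch",
                      "t_acquired", "t_reward", "t_end", "success",
                      "failure_stage", "n_touches")

#' Write / read a trial table as TSV
#'
#' @param trial_table trial table data frame.
#' @param path file path.
#' @return `read_trial_table` returns the data frame.
#' @export
write_trial_table <- function(trial_table, path) {
  write.table(trial_table[, TRIAL_TABLE_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tt <- read.delim(path, stringsAsFactors = FALSE)
  rep <- validate_trial_table(tt)
  if (!rep$ok) stop("invalid trial table: ", paste(rep$errors, collapse = "; "))
  tt
}

validate_trial_table <- function(tt) {
  errors <- character(0)
  missing <- setdiff(TRIAL_TABLE_COLS, names(tt))
  if (length(missing))
    errors <- c(errors, paste("missing columns:", paste(missing, collapse = ", ")))
  if (!length(missing)) {
    bad <- which(!tt$grip %in% GRIPS)
    if (length(bad))
      errors <- c(errors, paste0("row ", bad[1], ": grip label '", tt$grip[bad[1]],
                                 "' not in {", paste(GRIPS, collapse = ", "), "}"))
    badf <- which(!tt$force %in% FORCES)
    if (length(badf))
      errors <- c(errors, paste0("row ", badf[1], ": force label '",
                                 tt$force[badf[1]], "'"))
    ev <- as.matrix(tt[, c("t_cue_on", "t_cue_off", "t_go", "t_move",
                           "t_touch", "t_acquired", "t_reward")])
    ooo <- which(apply(ev, 1, function(r) {
      r <- r[!is.na(r)]; length(r) > 1 && any(diff(r) < 0)
    }))
    if (length(ooo))
      errors <- c(errors, paste0("row ", ooo[1], ": event times out of causal order"))
  }
  list(ok = length(errors) == 0, errors = errors)
}

#' Validate pipeline input/output files
#'
#' Checks a trial-table TSV (column set, grip/force labels, causal event
#' order) and, when given, a signals manifest JSON (each entry must name a
#' file and a positive sampling rate).
#'
#' @param trial_table_path path to a trial table TSV.
#' @param manifest_path optional path to a signals manifest JSON.
#' @return List with `ok` and per-file error messages.
#' @export
validate_io <- function(trial_table_path, manifest_path = NULL) {
  out <- list(ok = TRUE, errors = character(0))
  if (!file.exists(trial_table_path)) {
    return(list(ok = FALSE, errors = paste("missing file:", trial_table_path)))
  }
  tt <- read.delim(trial_table_path, stringsAsFactors = FALSE)
  rep <- validate_trial_table(tt)
  out$ok <- rep$ok
  out$errors <- rep$errors
  if (!is.null(manifest_path)) {
    if (!file.exists(manifest_path)) {
      out$ok <- FALSE
      out$errors <- c(out$errors, paste("missing file:", manifest_path))
    } else {
      man <- jsonlite::read_json(manifest_path)
      for (nm in names(man)) {
        e <- man[[nm]]
        if (is.null(e$rate) || !is.numeric(e$rate) || e$rate <= 0) {
          out$ok <- FALSE
          out$errors <- c(out$errors,
                          paste0("signal '", nm, "': missing or invalid rate attribute"))
        }
      }
    }
  }
  out
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates generator -> behavior -> rates -> tuning -> dPCA ->
#' EMG correlation from one configuration. Each stage seeds the RNG with a
#' hash of the global seed and the stage name, so re-running any stage (or
#' the whole pipeline) with the same seed reproduces its outputs
#' byte-identically. Disabled stages make the stages that depend on them
#' fail with a missing-input error.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [task_config()].
#' @param seed global integer seed.
#' @param stages character vector of enabled stages, in dependency order
#'   from "simulate", "behavior", "rates", "tuning", "dpca", "emgcorr".
#' @param n_permutations permutations for the tuning stage.
#' @param tuning_units optional subset of units to test (indices); NULL for
#'   all.
#' @param cv_iterations,n_shuffles decoding settings.
#' @return Invisibly, a list with the stage results; TSV/JSON reports are
#'   written to `out_dir`.
#' @export
run_pipeline <- function(out_dir, config = task_config(), seed = 1,
                         stages = c("simulate", "behavior", "rates",
                                    "tuning", "dpca", "emgcorr"),
                         n_permutations = 1000, tuning_units = NULL,
                         cv_iterations = 100, n_shuffles = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed)
  path <- function(f) file.path(out_dir, f)
  need <- function(stage, file) {
    if (!file.exists(path(file)))
      stop("stage '", stage, "' needs missing input '", file,
           "'; enable the stage that produces it")
  }

  if ("simulate" %in% stages) {
    session <- simulate_session(config, seed = stage_seed(seed, "simulate"))
    saveRDS(session, path("session.rds"))
    write_trial_table(session$trial_table, path("trial_table.tsv"))
    jsonlite::write_json(
      list(planted_shares = as.list(session$ground_truth$planted_shares),
           overshoot = session$ground_truth$overshoot,
           seed = seed),
      path("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  need("behavior", "session.rds")
  session <- readRDS(path("session.rds"))
  tt <- session$trial_table

  if ("behavior" %in% stages) {
    metrics <- compute_response_times(tt, session$force, config$force_bands)
    excl <- exclude_trials(metrics)
    perf <- performance_summary(tt)
    os <- overshoot_fraction(session$force, tt, config$force_bands)
    div <- compare_force_levels(session$force, tt)
    write.table(metrics, path("behavior_metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(perf, path("performance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(exclusion_counts = as.list(excl$log),
                              n_excluded = excl$n_excluded,
                              overshoot_fraction = as.list(os)),
                         path("behavior_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    saveRDS(list(metrics = metrics, keep = excl$keep), path("behavior.rds"))
    res$behavior <- list(metrics = metrics, exclusions = excl,
                         performance = perf, overshoot = os, divergence = div)
  }

  if ("rates" %in% stages) {
    need("rates", "behavior.rds")
    beh <- readRDS(path("behavior.rds"))
    tt_keep <- tt
    tt_keep$success <- tt$success & beh$keep
    rt <- spikes_to_rates(session$spikes, tt_keep, alignment_spec())
    rt <- mask_and_interpolate(rt, median_at_per_condition(tt_keep))
    saveRDS(rt, path("rates.rds"))
    res$rates <- rt
  }

  if ("tuning" %in% stages) {
    need("tuning", "rates.rds")
    rt <- readRDS(path("rates.rds"))
    set.seed(stage_seed(seed, "tuning"))
    units <- if (is.null(tuning_units)) seq_len(dim(rt$rates)[1]) else tuning_units
    cfg <- cluster_test_config(n_permutations = n_permutations)
    tests <- lapply(units, function(u)
      test_unit(rt$rates[u, , ], rt$trials, cfg, rt$timeline))
    frac <- population_fractions(tests)
    rows <- do.call(rbind, lapply(seq_along(tests), function(i) {
      cl <- do.call(rbind, lapply(EFFECTS, function(e) {
        x <- tests[[i]]$effects[[e]]$clusters
        if (nrow(x)) cbind(unit = units[i], effect = e, x) else NULL
      }))
    }))
    if (is.null(rows))
      rows <- data.frame(unit = integer(0), effect = character(0),
                         start = integer(0), end = integer(0),
                         sum_F = numeric(0), significant = logical(0))
    write.table(rows, path("tuning_clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(bin = seq_len(ncol(frac)), t(frac)),
                path("population_fractions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$tuning <- list(tests = tests, fractions = frac)
  }

  if ("dpca" %in% stages) {
    need("dpca", "rates.rds")
    rt <- readRDS(path("rates.rds"))
    x5 <- as_tensor5d(rt)
    model <- dpca(x5, seed = stage_seed(seed, "dpca"))
    vt <- data.frame(component = seq_along(model$ev), marg = model$marg,
                     ev_pct = 100 * model$ev)
    write.table(vt, path("variance_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    dec <- lapply(c("grip", "force"), function(f)
      decode_over_time(model, x5, f, cv_iterations = cv_iterations,
                       n_shuffles = n_shuffles,
                       seed = stage_seed(seed, paste0("decode_", f))))
    names(dec) <- c("grip", "force")
    ivs <- do.call(rbind, lapply(names(dec), function(f)
      if (nrow(dec[[f]]$intervals))
        cbind(factor = f, dec[[f]]$intervals) else NULL))
    if (is.null(ivs)) ivs <- data.frame(factor = character(0),
                                        start = integer(0), end = integer(0))
    write.table(ivs, path("decoding_intervals.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    saveRDS(model, path("dpca.rds"))
    res$dpca <- list(model = model, decoding = dec)
  }

  if ("emgcorr" %in% stages) {
    need("emgcorr", "dpca.rds")
    model <- readRDS(path("dpca.rds"))
    beh <- readRDS(path("behavior.rds"))
    tt_keep <- tt
    tt_keep$success <- tt$success & beh$keep
    fixwin <- cbind(tt$t_start, tt$t_cue_on)
    fixwin <- fixwin[complete.cases(fixwin), , drop = FALSE]
    margs <- lapply(session$emg, function(m) {
      env <- preprocess_emg(m, fixwin)
      marginalize(signal_to_tensor(env, tt_keep))
    })
    corr <- correlate_components(margs, model)
    write.table(data.frame(factor = rownames(corr$r2), round(corr$r2, 4),
                           shift_ms = corr$shift),
                path("emg_r2.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$emgcorr <- corr
  }

  report <- list(seed = seed,
                 stages = stages,
                 config_hash = stage_seed(seed, paste(
                   c(config$n_trials, config$n_units), collapse = "_")),
                 planted_shares = as.list(session$ground_truth$planted_shares))
  if (!is.null(res$dpca))
    report$fitted_shares <- as.list(res$dpca$model$marg_shares)
  if (!is.null(res$emgcorr)) report$emg_shift <- res$emgcorr$shift
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(res)
}
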