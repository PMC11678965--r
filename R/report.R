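# End-to-end orchestration: simulate -> segment -> extract -> reliability +
# model evaluation -> comparison and paradox tables.

#' Run configuration
#'
#' @param out_dir directory for output artifacts.
#' @param group_n named integer vector: participants per group profile.
#' @param seed master seed.
#' @param ntree trees for the diagnostic forests.
#' @param tasks tasks to simulate and analyze.
#' @param feature_sets feature sets to evaluate.
#' @param profiles named list of [group_params()]; defaults to
#'   [default_group_profiles()].
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("mobilitytrt_run_"),
                       group_n = c(control = 10, mild = 10, moderate = 10,
                                   severe = 10),
                       seed = 1, ntree = 500,
                       tasks = c("TUG", "cogTUG", "walk32ft"),
                       feature_sets = c("trial1", "trial2", "both",
                                        "duration"),
                       profiles = NULL) {
  if (is.null(profiles)) profiles <- default_group_profiles()
  stopifnot(all(names(group_n) %in% names(profiles)),
            length(group_n) >= 1, all(group_n >= 1),
            seed == as.integer(seed))
  structure(list(out_dir = out_dir, group_n = group_n, seed = seed,
                 ntree = ntree, tasks = tasks, feature_sets = feature_sets,
                 profiles = profiles),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys: `out_dir`, `seed`, `ntree`, `tasks`, `feature_sets`,
#' `group_n` (mapping group name to n), and optionally `groups` (profile
#' overrides in the [group_params()] field schema).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profiles <- if (!is.null(raw$groups)) {
    out <- lapply(names(raw$groups), function(nm)
      do.call(group_params, c(list(group_label = nm), raw$groups[[nm]])))
    names(out) <- names(raw$groups)
    out
  } else NULL
  args <- raw[intersect(names(raw),
                        c("out_dir", "seed", "ntree", "tasks",
                          "feature_sets"))]
  if (!is.null(raw$group_n)) args$group_n <- unlist(raw$group_n)
  args$profiles <- profiles
  do.call(run_config, args)
}

measure_tasks_for <- function(tasks) {
  out <- setdiff(tasks, "walk32ft")
  if ("walk32ft" %in% tasks) out <- c(out, "walk16ft")
  out
}

#' Run the full pipeline
#'
#' Simulates the configured cohort, segments every recording, extracts the
#' measure table, computes the per-group reliability table, evaluates the
#' diagnostic models for every PD group and feature set, and writes
#' manifest.csv, segments.csv, measures.csv, reliability.csv, eval/*.json,
#' comparison.csv and paradox.csv under `config$out_dir`. Individual
#' recording failures are logged and skipped, never fatal.
#'
#' @param config a [run_config()].
#' @param write write CSV/JSON artifacts to `config$out_dir`.
#' @return list(manifest, segments, measures, reliability, evaluations,
#'   comparison, paradox), invisibly when `write = TRUE`.
#' @export
run_all <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  specs <- lapply(names(config$group_n), function(nm)
    list(params = config$profiles[[nm]], n = config$group_n[[nm]]))
  message("simulate: ", sum(config$group_n), " participants, tasks: ",
          paste(config$tasks, collapse = ", "))
  recs <- simulate_cohort(specs, seed = config$seed, tasks = config$tasks)
  manifest <- attr(recs, "manifest")
  segments <- segment_cohort(recs)
  message("segment: ", nrow(segments), " segment rows, ",
          length(attr(segments, "failures")), " failures")
  measures <- extract_cohort(recs)
  message("extract: ", nrow(measures), " measure rows")
  rel <- reliability_table(measures)
  message("reliability: ", nrow(rel), " cells")

  pd_groups <- setdiff(names(config$group_n), "control")
  evals <- list()
  acc_rows <- list()
  if ("control" %in% names(config$group_n) && length(pd_groups)) {
    for (task in measure_tasks_for(config$tasks)) {
      for (grp in pd_groups) {
        for (fs_ in config$feature_sets) {
          ev <- tryCatch({
            if (fs_ == "duration") {
              fm <- build_feature_matrix(measures, task, grp,
                                         feature_set = "both")
              md <- fm$X[, "total_duration_mean"]
              duration_only_model(md, fm$y, seed = config$seed)
            } else {
              fm <- build_feature_matrix(measures, task, grp,
                                         feature_set = fs_)
              evaluate(fm$X, fm$y, seed = config$seed,
                       ntree = config$ntree)
            }
          }, error = function(e) e)
          if (inherits(ev, "error")) {
            message("eval skipped ", task, "/", grp, "/", fs_, ": ",
                    conditionMessage(ev))
            next
          }
          key <- paste(task, grp, fs_, sep = "_")
          evals[[key]] <- ev
          acc_rows[[key]] <- data.frame(
            task = task, group = grp, feature_set = fs_,
            accuracy = ev$accuracy, stringsAsFactors = FALSE)
          message(sprintf("eval %s: accuracy %.1f%%", key, ev$accuracy))
        }
      }
    }
  }
  comparison <- if (length(acc_rows) &&
                    "trial1" %in% config$feature_sets) {
    tryCatch(compare_trial_models(do.call(rbind, acc_rows)),
             error = function(e) NULL)
  } else NULL
  paradox <- summarize_icc_vs_rc(rel)

  out <- list(manifest = manifest, segments = segments, measures = measures,
              reliability = rel, evaluations = evals,
              comparison = comparison, paradox = paradox)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(segments, file.path(config$out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(measures, file.path(config$out_dir, "measures.csv"),
                     row.names = FALSE)
    utils::write.csv(rel, file.path(config$out_dir, "reliability.csv"),
                     row.names = FALSE)
    if (length(evals)) {
      evdir <- file.path(config$out_dir, "eval")
      dir.create(evdir, showWarnings = FALSE)
      for (key in names(evals)) {
        ev <- evals[[key]]
        jsonlite::write_json(
          list(accuracy = ev$accuracy, n = ev$n,
               votes = unname(as.data.frame(ev$votes)),
               final = ev$final, truth = ev$y),
          file.path(evdir, paste0(key, ".json")), auto_unbox = TRUE)
      }
    }
    if (!is.null(comparison))
      utils::write.csv(comparison$table,
                       file.path(config$out_dir, "comparison.csv"),
                       row.names = FALSE)
    utils::write.csv(paradox, file.path(config$out_dir, "paradox.csv"),
                     row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' ICC-versus-relative-change paradox table
#'
#' Per task x group: the total-duration ICC, the median signed and absolute
#' relative change, and the between-participant mean square. Groups are
#' flagged when the ICC clears the "good" threshold while the median |RC|
#' simultaneously exceeds `rc_threshold` - the configuration in which ICC
#' alone overstates test-retest reliability.
#'
#' @param rel reliability table from [reliability_table()].
#' @param icc_threshold ICC flag threshold (default 0.75, "good").
#' @param rc_threshold median |RC| flag threshold (default 0.10).
#' @return data.frame with a logical `flagged` column.
#' @export
summarize_icc_vs_rc <- function(rel, icc_threshold = 0.75,
                                rc_threshold = 0.10) {
  sub <- rel[rel$measure == "total_duration", , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(task = character(0), group = character(0),
                      icc = numeric(0), median_rc = numeric(0),
                      median_abs_rc = numeric(0), flagged = logical(0)))
  data.frame(
    task = sub$task, group = sub$group, icc = sub$icc,
    median_rc = sub$median_rc, median_abs_rc = sub$median_abs_rc,
    flagged = sub$icc >= icc_threshold &
      sub$median_abs_rc >= rc_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
}
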