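# End-to-end orchestration: config -> generation/ingestion -> pupil + gaze
# pipelines -> mixed-model statistics -> tables, with a run log. The
# exported functions are the interface; inst/scripts/dyadload-run.R is a
# thin command-line wrapper around run_pipeline().

measure_names <- c("first_gaze_to_target", "gaze_to_target", "gaze_to_other",
                   "gaze_to_person", "joint_attention", "mutual_gaze",
                   "mean_dilation", "peak_dilation", "slope", "duration")

# Measures shared by the dyad (identical on both roles' rows): analysed with
# the fragment factor only, on one role's rows to avoid duplication.
shared_measures <- c("joint_attention", "mutual_gaze", "duration")
pupil_measures <- c("mean_dilation", "peak_dilation", "slope")

#' Run the full statistical battery on a metric table
#'
#' Two mixed-model families and a correlation screen:
#' \describe{
#'   \item{type}{fragmented vs non-fragmented (2-level fragment factor), with
#'     role and their interaction for per-role measures; fragment only for
#'     dyad-shared measures (duration, joint attention, mutual gaze).}
#'   \item{sequence}{fragment ordinal Utt-1..Utt-4 as a 4-level factor, on
#'     fragmented instructions only.}
#'   \item{correlations}{Spearman rho of each per-role measure against the
#'     instruction's fragment count, Bonferroni-adjusted.}
#' }
#' Random intercepts default to interaction and instructed object;
#' participant is added for the pupil measures.
#'
#' @param rows metric data.frame from [compute_metrics_all()].
#' @param tier_units optional combined `units` table (for exact fragment
#'   counts in the correlation screen).
#' @param max_ordinal sequence analysis cap (default 4).
#' @return list with `type` and `sequence` (named lists of `stats_result`),
#'   `correlations`, and `warnings` (singular-fit log).
#' @export
analyze_metrics <- function(rows, tier_units = NULL, max_ordinal = 4L) {
  rows <- as.data.frame(rows)
  rows$fragment <- rows$instruction_type
  seq_rows <- rows[rows$instruction_type == "fragmented" &
                     rows$fragment_ordinal <= max_ordinal, , drop = FALSE]
  seq_rows$fragment <- sprintf("Utt-%d", seq_rows$fragment_ordinal)
  log_warn <- character()
  fit_quiet <- function(data, spec) {
    withCallingHandlers(
      tryCatch(fit_and_test(data, spec),
               error = function(e) {
                 log_warn <<- c(log_warn, conditionMessage(e))
                 NULL
               }),
      warning = function(w) {
        log_warn <<- c(log_warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  run_family <- function(data) {
    res <- list()
    for (m in measure_names) {
      if (m %in% shared_measures) {
        d <- data[data$role == "instructor", , drop = FALSE]
        spec <- model_spec(m, "fragment")
      } else {
        random <- c("interaction_id", "referent_id",
                    if (m %in% pupil_measures) "participant_id")
        spec <- model_spec(m, c("fragment", "role"), interaction = TRUE,
                           random = random)
        d <- data
      }
      res[[m]] <- fit_quiet(d, spec)
    }
    res
  }
  type_res <- run_family(rows)
  seq_res <- run_family(seq_rows)

  inst <- instruction_level_metrics(rows, tier_units)
  screen_cols <- character()
  for (m in setdiff(measure_names, shared_measures)) {
    for (r in c("instructor", "builder")) {
      col <- paste(r, m, sep = ".")
      v <- inst[[m]]
      v[inst$role != r] <- NA
      inst[[col]] <- v
      screen_cols <- c(screen_cols, col)
    }
  }
  inst_shared <- inst[inst$role == "instructor", , drop = FALSE]
  # collapse per-role columns back onto one row per instruction
  per_inst <- stats::aggregate(
    inst[, screen_cols, drop = FALSE],
    by = list(interaction_id = inst$interaction_id,
              instruction_id = inst$instruction_id),
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  idx <- match(paste(per_inst$interaction_id, per_inst$instruction_id),
               paste(inst_shared$interaction_id, inst_shared$instruction_id))
  per_inst$n_fragments <- inst_shared$n_fragments[idx]
  for (m in shared_measures) per_inst[[m]] <- inst_shared[[m]][idx]
  screen_cols <- c(screen_cols, shared_measures)
  correlations <- correlation_screen(per_inst, screen_cols)

  list(type = type_res, sequence = seq_res, correlations = correlations,
       warnings = log_warn)
}

flatten_tests <- function(family) {
  out <- lapply(names(family), function(m) {
    r <- family[[m]]
    if (is.null(r)) return(NULL)
    cbind(response = m, r$terms, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

flatten_cells <- function(family) {
  out <- lapply(names(family), function(m) {
    r <- family[[m]]
    if (is.null(r)) return(NULL)
    cells <- r$cells
    if (!"role" %in% names(cells)) cells$role <- "dyad"
    cbind(response = m, cells[, c("fragment", "role", "mean", "sd", "n")],
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

resolve_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(mode = "simulate", corpus_dirs = NULL, sim = list(),
                   threshold_deg = 10, max_gap_frames = 25,
                   denominator = "segment-time",
                   filter = list(), outlier = list(), max_ordinal = 4,
                   write_audit = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown run-config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, as.list(config))
  cfg$mode <- match.arg(cfg$mode, c("simulate", "corpus"))
  if (cfg$mode == "corpus" && length(cfg$corpus_dirs) == 0) {
    stop("corpus mode needs corpus_dirs")
  }
  cfg
}

#' Run the complete pipeline and write all artifacts
#'
#' In `simulate` mode a synthetic corpus is generated from the embedded
#' [sim_config()] (overridable via `config$sim`); in `corpus` mode
#' recordings are read from `config$corpus_dirs`, and a directory whose
#' sensors cannot be read is excluded with a logged reason rather than
#' aborting the run. The metric table, per-frame gaze audit, statistics
#' tables, model-fit JSON and a run log (seed, versions, every resolved
#' parameter) are written under `out_dir`.
#'
#' @param config a list or a YAML/JSON file path; see
#'   `inst/extdata/run_config_example.yaml` for the schema.
#' @param out_dir output directory.
#' @param seed RNG seed (simulate mode; recorded in the log either way).
#' @return (invisibly) list with `metrics`, `analysis`, `excluded`, and the
#'   resolved config.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  cfg <- resolve_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("dyadload %s | R %s.%s",
                         as.character(utils::packageVersion("dyadload")),
                         R.version$major, R.version$minor),
                 sprintf("seed: %d", seed),
                 sprintf("mode: %s", cfg$mode),
                 paste0("resolved config: ",
                        jsonlite::toJSON(cfg[setdiff(names(cfg), "corpus_dirs")],
                                         auto_unbox = TRUE, digits = NA)))
  excluded <- data.frame(interaction = character(), reason = character(),
                         stringsAsFactors = FALSE)
  if (cfg$mode == "simulate") {
    sim <- do.call(sim_config, cfg$sim)
    gen <- generate_dyads(sim, seed = seed)
    recordings <- gen$recordings
  } else {
    recordings <- list()
    for (d in cfg$corpus_dirs) {
      rec <- tryCatch(suppressWarnings(read_recording(d)),
                      error = function(e) e)
      if (inherits(rec, "error")) {
        excluded <- rbind(excluded,
                          data.frame(interaction = d,
                                     reason = conditionMessage(rec)))
        log_lines <- c(log_lines, sprintf("excluded %s: %s", d,
                                          conditionMessage(rec)))
      } else {
        recordings[[rec$interaction_id]] <- rec
      }
    }
    if (length(recordings) == 0) stop("no readable recordings in corpus_dirs")
  }
  fspec <- do.call(filter_spec, cfg$filter)
  ospec <- do.call(outlier_spec, cfg$outlier)
  rows <- compute_metrics_all(recordings, threshold_deg = cfg$threshold_deg,
                              fspec = fspec, ospec = ospec,
                              max_gap_frames = cfg$max_gap_frames,
                              denominator = cfg$denominator)
  write_metric_table(rows, file.path(out_dir, "metrics.csv"))
  if (isTRUE(cfg$write_audit)) {
    audit <- do.call(rbind, lapply(recordings, function(rec) {
      a <- gaze_audit(rec, cfg$threshold_deg)
      cbind(interaction_id = rec$interaction_id, a)
    }))
    utils::write.csv(audit, file.path(out_dir, "gaze_audit.csv"),
                     row.names = FALSE, na = "")
  }
  units <- do.call(rbind, lapply(recordings, function(r) r$tier$units))
  slice_idx <- do.call(rbind, lapply(recordings, function(r)
    data.frame(interaction_id = r$interaction_id,
               t(slice_counts(r$tier, cfg$max_ordinal)))))
  utils::write.csv(slice_idx, file.path(out_dir, "sequence_slices.csv"),
                   row.names = FALSE)

  analysis <- analyze_metrics(rows, units, cfg$max_ordinal)
  utils::write.csv(flatten_tests(analysis$type),
                   file.path(out_dir, "stats_type_tests.csv"), row.names = FALSE)
  utils::write.csv(flatten_cells(analysis$type),
                   file.path(out_dir, "stats_type_cells.csv"), row.names = FALSE)
  utils::write.csv(flatten_tests(analysis$sequence),
                   file.path(out_dir, "stats_sequence_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(flatten_cells(analysis$sequence),
                   file.path(out_dir, "stats_sequence_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$correlations,
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  fit_log <- lapply(c(type = "type", sequence = "sequence"), function(fam) {
    lapply(analysis[[fam]], function(r) {
      if (is.null(r)) return(NULL)
      list(model = r$model, n_rows = r$n_rows, random = r$random_used,
           terms = r$terms)
    })
  })
  jsonlite::write_json(fit_log, file.path(out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_lines <- c(log_lines,
                 sprintf("recordings analysed: %d", length(recordings)),
                 sprintf("metric rows: %d", nrow(rows)),
                 analysis$warnings)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(metrics = rows, analysis = analysis, excluded = excluded,
                 config = cfg, units = units))
}
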