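#' Run configuration for the screening pipeline
#'
#' Collects paths and analysis options with the screen's defaults:
#' compounds at 10 uM in 0.5% DMSO, significance tiers 0.05 / 0.025 /
#' 0.001, duplicate concordance threshold k = 2 vehicle sds, 26
#' no-effect compounds carried into the secondary screen.
#'
#' @param simulate if `TRUE` the pipeline generates its own screen via
#'   [simulate_screen()]; otherwise the layout/measurement paths below
#'   are required.
#' @param layouts named list `plate_id -> layout path` (file mode).
#' @param measurements measurement CSV path (file mode).
#' @param library library-map TSV path (file mode).
#' @param annotations optional annotation TSV path.
#' @param output_dir where stage outputs are written.
#' @param library_size,params,truth simulation-mode inputs
#'   (see [screen_truth()] and [sim_params()]).
#' @param gfp_floor,rescale_gfp scoring options, see [score_wells()].
#' @param gating_pair,min_band QC options, see [plate_qc()].
#' @param k,call_mode,tiers calling options, see [screen_calls()].
#' @param n_no_effect,seed cascade options, see [triage_cascade()];
#'   `seed` drives every stochastic stage.
#' @param excluded_flags deselection flags, see [deselect()].
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = FALSE, layouts = NULL,
                       measurements = NULL, library = NULL,
                       annotations = NULL, output_dir = tempfile("run_"),
                       library_size = 1200, params = sim_params(),
                       truth = NULL, gfp_floor = NULL,
                       rescale_gfp = FALSE,
                       gating_pair = c("positive_control", "fat_control"),
                       min_band = "marginal", k = 2,
                       call_mode = "threshold",
                       tiers = c(0.05, 0.025, 0.001),
                       n_no_effect = 26, seed = 1L,
                       excluded_flags = c("anthelminthic", "cytotoxic",
                                          "antibiotic", "contraceptive",
                                          "unavailable",
                                          "known_anti_obesity")) {
  stopifnot(all(diff(tiers) < 0))
  cfg <- as.list(environment())
  if (!simulate) {
    for (field in c("layouts", "measurements", "library")) {
      if (is.null(cfg[[field]])) {
        stop("config error: '", field, "' required unless simulate=TRUE",
             call. = FALSE)
      }
    }
    paths <- c(unlist(cfg$layouts), cfg$measurements, cfg$library,
               cfg$annotations)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("config error: missing input path(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file; top-level keys are [run_config()] arguments.
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("config error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$params) && !inherits(raw$params, "sim_params")) {
    raw$params <- do.call(sim_params, raw$params)
  }
  do.call(run_config, raw)
}

#' Run a complete simulated screening cascade
#'
#' Simulates a primary screen over the full library, scores and
#' QC-checks every plate, calls each compound from its duplicate wells,
#' builds the secondary roster (all decreasers and increasers plus a
#' random no-effect sample), simulates and calls the secondary screen,
#' intersects the two call sets into confirmed hits, and computes
#' recovery statistics against the known truth.
#'
#' @param library_size compounds in the library (default 1200).
#' @param params a [sim_params()].
#' @param truth optional pre-built [screen_truth()]; built from
#'   `library_size` and the default effect mix when `NULL`.
#' @param k,call_mode,tiers calling options (see [screen_calls()]).
#' @param n_no_effect no-effect compounds carried to the secondary
#'   screen.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `screen_run` with elements `truth`,
#'   `primary` / `secondary` (each: `screen`, `scores`, `qc`, `calls`),
#'   `triage`, `confirmed`, `summary` (the cascade summary table),
#'   `recovery` (sensitivity and false-discovery proportion for the
#'   decrease direction), `seeds`.
#' @export
run_screen_simulation <- function(library_size = 1200,
                                  params = sim_params(), truth = NULL,
                                  k = 2, call_mode = "threshold",
                                  tiers = c(0.05, 0.025, 0.001),
                                  n_no_effect = 26, seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  if (is.null(truth)) truth <- screen_truth(library_size, seed = seeds[1])
  primary_screen <- simulate_screen(truth, params, seed = seeds[2],
                                    plate_prefix = "P")
  primary_scores <- score_screen(primary_screen)
  primary_qc <- plate_qc(primary_scores)
  primary_calls <- screen_calls(primary_scores,
                                primary_screen$library_map, k = k,
                                mode = call_mode, tiers = tiers)
  triage <- triage_cascade(primary_calls, n_no_effect = n_no_effect,
                           seed = seeds[3])
  truth_sec <- truth[truth$compound_id %in% triage$roster, ]
  secondary_screen <- simulate_screen(truth_sec, params,
                                      seed = seeds[4],
                                      plate_prefix = "S")
  secondary_scores <- score_screen(secondary_screen)
  secondary_qc <- plate_qc(secondary_scores)
  secondary_calls <- screen_calls(secondary_scores,
                                  secondary_screen$library_map, k = k,
                                  mode = call_mode, tiers = tiers)
  confirmed <- confirm_hits(primary_calls, secondary_calls)
  true_dec <- truth$compound_id[truth$class == "decrease"]
  got <- confirmed$confirmed_decrease
  recovery <- list(
    sensitivity = if (length(true_dec))
      length(intersect(got, true_dec)) / length(true_dec) else NA_real_,
    fdp = if (length(got))
      length(setdiff(got, true_dec)) / length(got) else 0)
  structure(list(
    truth = truth,
    primary = list(screen = primary_screen, scores = primary_scores,
                   qc = primary_qc, calls = primary_calls),
    secondary = list(screen = secondary_screen,
                     scores = secondary_scores, qc = secondary_qc,
                     calls = secondary_calls),
    triage = triage, confirmed = confirmed,
    summary = cascade_summary(list(primary = primary_calls,
                                   secondary = secondary_calls)),
    recovery = recovery,
    seeds = seeds), class = "screen_run")
}

# Derive n per-stage seeds from one master seed, all below 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the screening pipeline from a configuration
#'
#' Orchestrates QC -> calls -> cascade -> deselection and writes every
#' stage output plus a run log to the configured output directory:
#' `scores_primary.csv` (and `_secondary` when present), `qc.csv`,
#' `calls_primary.csv` / `calls_secondary.csv`, `cascade_summary.csv`,
#' `confirmed.csv`, `leads.csv` (when annotations are given), and
#' `run.log`. Deterministic given the config's seed.
#'
#' @param config a [run_config()] (or path to a YAML/JSON config).
#' @return the output directory, invisibly; the full in-memory result is
#'   attached as attribute `"run"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("nilescreen %s",
                         as.character(utils::packageVersion("nilescreen"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", config_hash(config)))
  if (config$simulate) {
    run <- run_screen_simulation(
      library_size = config$library_size, params = config$params,
      truth = config$truth, k = config$k, call_mode = config$call_mode,
      tiers = config$tiers, n_no_effect = config$n_no_effect,
      seed = config$seed)
    write_scores(run$primary$scores,
                 file.path(config$output_dir, "scores_primary.csv"))
    write_scores(run$secondary$scores,
                 file.path(config$output_dir, "scores_secondary.csv"))
    qc <- rbind(as.data.frame(run$primary$qc),
                as.data.frame(run$secondary$qc))
    calls_primary <- run$primary$calls
    calls_secondary <- run$secondary$calls
    confirmed <- run$confirmed
    summary_df <- run$summary
    log_lines <- c(log_lines,
                   sprintf("stage simulate: %d compounds, %d plates",
                           nrow(run$truth),
                           length(run$primary$screen$layouts) +
                             length(run$secondary$screen$layouts)),
                   sprintf("recovery: sensitivity %.3f fdp %.3f",
                           run$recovery$sensitivity, run$recovery$fdp))
  } else {
    run <- NULL
    layouts <- lapply(config$layouts, parse_layout)
    if (!is.null(names(config$layouts))) {
      for (pid in names(config$layouts)) {
        layouts[[pid]]$plate_id <- pid
      }
    }
    scores <- do.call(rbind, c(lapply(layouts, function(lay) {
      reads <- read_plate_measurements(config$measurements,
                                       plate_id = lay$plate_id)
      score_wells(reads, lay, gfp_floor = config$gfp_floor,
                  rescale_gfp = config$rescale_gfp)
    }), make.row.names = FALSE))
    class(scores) <- c("fat_scores", class(scores))
    write_scores(scores,
                 file.path(config$output_dir, "scores_primary.csv"))
    qc <- plate_qc(scores, gating_pair = config$gating_pair,
                   min_band = config$min_band)
    libmap <- read_library_map(config$library)
    calls_primary <- screen_calls(scores, libmap, k = config$k,
                                  mode = config$call_mode,
                                  tiers = config$tiers)
    calls_secondary <- NULL
    confirmed <- NULL
    summary_df <- cascade_summary(list(primary = calls_primary))
    log_lines <- c(log_lines,
                   sprintf("stage score: %d wells on %d plates",
                           nrow(scores), length(layouts)))
  }
  utils::write.csv(qc, file.path(config$output_dir, "qc.csv"),
                   row.names = FALSE)
  utils::write.csv(calls_primary,
                   file.path(config$output_dir, "calls_primary.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(calls_secondary)) {
    utils::write.csv(calls_secondary,
                     file.path(config$output_dir, "calls_secondary.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(
      data.frame(compound_id = c(confirmed$confirmed_decrease,
                                 confirmed$confirmed_increase),
                 direction = rep(c("decrease", "increase"),
                                 c(length(confirmed$confirmed_decrease),
                                   length(confirmed$confirmed_increase)))),
      file.path(config$output_dir, "confirmed.csv"), row.names = FALSE)
  }
  utils::write.csv(summary_df,
                   file.path(config$output_dir, "cascade_summary.csv"),
                   row.names = FALSE)
  if (!is.null(config$annotations) && !is.null(confirmed)) {
    libmap <- if (config$simulate) run$primary$screen$library_map
              else read_library_map(config$library)
    ub <- unblind(libmap, config$annotations)
    sel <- deselect(confirmed$confirmed_decrease, ub$resolved,
                    excluded_flags = config$excluded_flags)
    utils::write.csv(data.frame(compound_id = sel$leads),
                     file.path(config$output_dir, "leads.csv"),
                     row.names = FALSE)
    if (nrow(sel$excluded)) {
      utils::write.csv(sel$excluded,
                       file.path(config$output_dir, "exclusions.csv"),
                       row.names = FALSE)
    }
    log_lines <- c(log_lines,
                   sprintf("stage deselect: %d leads, %d excluded",
                           length(sel$leads), nrow(sel$excluded)))
  }
  qc_fail <- unique(qc$plate_id[!qc$qc_pass])
  log_lines <- c(log_lines,
                 sprintf("stage qc: %d plates flagged qc_fail",
                         length(qc_fail)))
  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  out <- config$output_dir
  attr(out, "run") <- run
  invisible(out)
}

config_hash <- function(config) {
  flat <- utils::capture.output(utils::str(
    config[setdiff(names(config), c("params", "truth"))]))
  sprintf("%08x", sum(utf8ToInt(paste(flat, collapse = ""))))
}

#' Render a plain-text digest of a completed run directory
#'
#' Reads the stage CSVs written by [run_pipeline()] and produces a
#' human-readable digest: the cascade summary with hit rates in the
#' printed-rate convention, the QC table with any qc_fail plates called
#' out, and the lead list with its exclusion log. Missing stages yield
#' warnings and a partial report rather than an error.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path optional file to write the digest to
#'   (default `<run_dir>/report.txt`).
#' @return the digest lines, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  lines <- c("== nilescreen run report ==", paste("run dir:", run_dir))
  grab <- function(name) {
    f <- file.path(run_dir, name)
    if (!file.exists(f)) {
      warning("missing stage output: ", name, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  summary_df <- grab("cascade_summary.csv")
  if (!is.null(summary_df)) {
    lines <- c(lines, "", "-- cascade summary --")
    for (i in seq_len(nrow(summary_df))) {
      lines <- c(lines, sprintf(
        "%s: %d screened, %d decrease, %d increase, hit rate %s",
        summary_df$tier[i], summary_df$n_screened[i],
        summary_df$n_decrease[i], summary_df$n_increase[i],
        format_hit_rate(summary_df$hit_rate_pct[i])))
    }
  }
  qc <- grab("qc.csv")
  if (!is.null(qc)) {
    lines <- c(lines, "", "-- plate QC --")
    lines <- c(lines, sprintf("%s %s: Z' = %.3f (%s)%s", qc$plate_id,
                              qc$pair, qc$zprime, qc$band,
                              ifelse(qc$qc_pass, "", "  ** qc_fail **")))
    fails <- unique(qc$plate_id[!qc$qc_pass])
    if (length(fails)) {
      lines <- c(lines, paste("qc_fail plates:",
                              paste(fails, collapse = ", ")))
    }
  }
  leads <- grab_quiet(run_dir, "leads.csv")
  if (!is.null(leads)) {
    lines <- c(lines, "", "-- leads --",
               paste(leads$compound_id, collapse = ", "))
    excl <- grab_quiet(run_dir, "exclusions.csv")
    if (!is.null(excl) && nrow(excl)) {
      lines <- c(lines, "excluded:",
                 sprintf("  %s (%s)", excl$compound_id, excl$flags))
    }
  }
  if (is.null(summary_df) && is.null(qc)) {
    lines <- c(lines, "", "WARNING: no stage outputs found; empty run?")
  }
  writeLines(lines, path)
  invisible(lines)
}

# optional stage files: absence is not worth a warning
grab_quiet <- function(run_dir, name) {
  f <- file.path(run_dir, name)
  if (!file.exists(f)) return(NULL)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
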