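#' GFP-normalised Nile Red fat score for one well
#'
#' The single statistic the whole screen rests on: the Nile Red
#' fluorescence of a well divided by its GFP fluorescence. The body-wall
#' muscle GFP reporter (myo-3::gfp) scales with the number of worms in
#' the well, so the ratio is a per-worm fat proxy that is independent of
#' worm count.
#'
#' @param nile_red Nile Red fluorescence (arbitrary units, >= 0).
#' @param gfp GFP fluorescence (arbitrary units, >= 0).
#' @param gfp_floor wells with GFP below this floor (empty or dead wells)
#'   get an invalid score rather than a wild ratio. Must be > 0.
#' @return data frame with columns `score`, `valid`, `reason`
#'   (`NA` when valid, `"gfp_below_floor"` otherwise). Vectorised.
#' @examples
#' normalize_well(500, 250, gfp_floor = 10) # score 2
#' @export
normalize_well <- function(nile_red, gfp, gfp_floor) {
  stopifnot(is.numeric(gfp_floor), length(gfp_floor) == 1L, gfp_floor > 0)
  valid <- gfp >= gfp_floor
  data.frame(
    score = ifelse(valid, nile_red / gfp, NA_real_),
    valid = valid,
    reason = ifelse(valid, NA_character_, "gfp_below_floor"),
    stringsAsFactors = FALSE)
}

#' Score every well of a plate
#'
#' Joins plate-reader measurements with the plate layout and computes the
#' normalised Nile Red fat score per well.
#'
#' @param reads a [read_plate_measurements()] result (or its `reads`
#'   data frame).
#' @param layout the matching [plate_layout()].
#' @param gfp_floor per-well GFP validity floor; default 5% of the median
#'   GFP of the plate's vehicle wells (guards against empty/dead wells).
#' @param rescale_gfp optional per-plate rescaling: divide each well's GFP
#'   by the median GFP of the plate's vehicle wells before taking the
#'   ratio, making scores comparable across plates. Off by default — the
#'   plain per-well ratio is the primary reading.
#' @return data frame of class `fat_scores` with columns `plate_id`,
#'   `well`, `role`, `strain`, `compound_id`, `score`, `valid`, `reason`.
#' @export
score_wells <- function(reads, layout, gfp_floor = NULL,
                        rescale_gfp = FALSE) {
  if (inherits(reads, "well_reads")) reads <- reads$reads
  stopifnot(inherits(layout, "plate_layout"))
  idx <- match(reads$well, layout$wells$well)
  if (anyNA(idx)) stop("measurement for well absent from layout",
                       call. = FALSE)
  veh <- layout$wells$well[layout$wells$role == "vehicle_control"]
  veh_gfp <- reads$gfp[reads$well %in% veh]
  if (is.null(gfp_floor)) {
    if (!length(veh_gfp)) {
      stop("cannot derive gfp_floor: no vehicle wells measured",
           call. = FALSE)
    }
    gfp_floor <- 0.05 * stats::median(veh_gfp)
    if (gfp_floor <= 0) gfp_floor <- .Machine$double.eps
  }
  gfp <- reads$gfp
  if (rescale_gfp) {
    if (!length(veh_gfp)) stop("rescale_gfp needs vehicle wells",
                               call. = FALSE)
    gfp <- gfp / stats::median(veh_gfp)
    gfp_floor <- gfp_floor / stats::median(veh_gfp)
  }
  ns <- normalize_well(reads$nile_red, gfp, gfp_floor)
  out <- data.frame(
    plate_id = reads$plate_id,
    well = reads$well,
    role = layout$wells$role[idx],
    strain = layout$wells$strain[idx],
    compound_id = layout$wells$compound_id[idx],
    score = ns$score, valid = ns$valid, reason = ns$reason,
    stringsAsFactors = FALSE)
  class(out) <- c("fat_scores", class(out))
  out
}

#' Min/max and Grubbs outlier trimming of replicate scores
#'
#' Replicate well values are trimmed before group statistics: the single
#' maximal and single minimal value are removed first (one instance each,
#' ties broken arbitrarily), then a two-sided Grubbs test is applied
#' iteratively, removing the most extreme remaining point while it is
#' significant at `alpha`. Applied per condition (per compound or control
#' group), not across a whole plate.
#'
#' @param values numeric vector of scores (length >= 4 for trimming to
#'   run; shorter inputs are returned untouched with a warning entry in
#'   the log).
#' @param alpha significance level of the iterative Grubbs test
#'   (default 0.05).
#' @param min_keep stop Grubbs removals once this many values remain
#'   (default 3, the smallest n the test is defined for).
#' @return list with `values` (the trimmed vector) and `log` (data frame
#'   `value`, `reason` — reasons `min`, `max`, `grubbs`, or a single
#'   `too_few_values` warning row).
#' @examples
#' trim_values(c(1, 2, 3, 4, 5, 6))$values # 2 3 4 5
#' @export
trim_values <- function(values, alpha = 0.05, min_keep = 3L) {
  stopifnot(is.numeric(values), !anyNA(values))
  log <- data.frame(value = numeric(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (length(values) < 4L) {
    warning("fewer than 4 values; trimming skipped", call. = FALSE)
    log <- rbind(log, data.frame(value = NA_real_,
                                 reason = "too_few_values"))
    return(list(values = values, log = log))
  }
  i_min <- which.min(values)
  log <- rbind(log, data.frame(value = values[i_min], reason = "min"))
  values <- values[-i_min]
  i_max <- which.max(values)
  log <- rbind(log, data.frame(value = values[i_max], reason = "max"))
  values <- values[-i_max]
  while (length(values) > min_keep) {
    g <- grubbs_statistic(values)
    if (is.na(g$G) || g$G <= grubbs_critical(length(values), alpha)) break
    log <- rbind(log, data.frame(value = values[g$idx], reason = "grubbs"))
    values <- values[-g$idx]
  }
  rownames(log) <- NULL
  list(values = values, log = log)
}

# Two-sided Grubbs statistic: largest absolute deviation from the mean
# in units of the sample sd; idx is the offending point.
grubbs_statistic <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(list(G = NA_real_, idx = NA_integer_))
  d <- abs(x - mean(x))
  idx <- which.max(d)
  list(G = d[idx] / s, idx = idx)
}

# Critical value of the two-sided Grubbs test from the t-distribution:
# G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2)),
# t the upper alpha/(2n) quantile of t with n-2 df.
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3L) return(Inf)
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Mean, standard deviation and standard error of a score group
#'
#' @param values numeric vector (n >= 1), typically the output of
#'   [trim_values()].
#' @return object of class `group_stats`: list with `n`, `mean`, `sd`
#'   (n-1 denominator), `sem` (= sd / sqrt(n)). For n = 1, `sd` and `sem`
#'   are `NA`.
#' @export
summarize_group <- function(values) {
  stopifnot(is.numeric(values))
  if (!length(values)) stop("empty group", call. = FALSE)
  if (anyNA(values)) stop("NA in group values", call. = FALSE)
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else NA_real_
  structure(list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> n=%d mean=%.4g sd=%.4g sem=%.4g\n",
              x$n, x$mean, x$sd, x$sem))
  invisible(x)
}

#' Export fat scores as CSV
#' @param scores a [score_wells()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  invisible(path)
}
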