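#' Call a compound from its duplicate screen wells
#'
#' Primary/secondary screen call rule: a compound run in duplicate is
#' called a fat `decrease` only if every duplicate well score falls below
#' mean_vehicle - k * sd_vehicle, an `increase` only if every duplicate
#' exceeds mean_vehicle + k * sd_vehicle, and `no_effect` otherwise
#' (discordant duplicates are no_effect). Requiring concordance of the
#' duplicates is the screen's replication control.
#'
#' @param compound_id identifier carried into the call.
#' @param dup_scores numeric vector of the compound's duplicate-well fat
#'   scores (invalid wells already removed); `NA`s are dropped.
#' @param vehicle [summarize_group()] of the vehicle-control wells on the
#'   compound's plates (n >= 2).
#' @param k threshold multiplier (default 2 vehicle sds).
#' @return one-row data frame: `compound_id`, `direction` (`decrease`,
#'   `increase`, `no_effect`, or `no_data` when no valid duplicate
#'   remains), `effect_ratio` (mean duplicate score / vehicle mean),
#'   `p_value` (`NA`; threshold mode has none), `tier` (`NA`),
#'   `n_wells`.
#' @export
call_compound_screen <- function(compound_id, dup_scores, vehicle, k = 2) {
  dup_scores <- dup_scores[!is.na(dup_scores)]
  if (!length(dup_scores)) {
    return(data.frame(compound_id = compound_id, direction = "no_data",
                      effect_ratio = NA_real_, p_value = NA_real_,
                      tier = NA_character_, n_wells = 0L,
                      stringsAsFactors = FALSE))
  }
  stopifnot(vehicle$n >= 2L, is.finite(vehicle$sd))
  lo <- vehicle$mean - k * vehicle$sd
  hi <- vehicle$mean + k * vehicle$sd
  direction <- if (all(dup_scores < lo)) "decrease"
               else if (all(dup_scores > hi)) "increase"
               else "no_effect"
  data.frame(compound_id = compound_id, direction = direction,
             effect_ratio = mean(dup_scores) / vehicle$mean,
             p_value = NA_real_, tier = NA_character_,
             n_wells = length(dup_scores), stringsAsFactors = FALSE)
}

#' Map a p-value to the significance tier ladder
#'
#' Tiers follow the screen's convention: `star` p < 0.05,
#' `double_star` p < 0.025, `triple_star` p < 0.001, else `ns`.
#'
#' @param p p-value(s).
#' @param tiers strictly decreasing thresholds for star/double/triple.
#' @return character vector of tiers.
#' @export
significance_tier <- function(p, tiers = c(0.05, 0.025, 0.001)) {
  stopifnot(length(tiers) == 3L, all(diff(tiers) < 0))
  ifelse(p < tiers[3], "triple_star",
         ifelse(p < tiers[2], "double_star",
                ifelse(p < tiers[1], "star", "ns")))
}

#' Confirmation call by Welch two-sample t-test
#'
#' Confirmation mode: treated replicate scores are compared with
#' control scores by a two-tailed two-sample Welch t-test (after
#' [trim_values()] trimming, applied by the caller). Direction is the
#' sign of the mean difference when the test reaches at least the
#' `star` tier; a non-significant lower mean remains `no_effect`.
#'
#' @param compound_id identifier carried into the call.
#' @param treated,control numeric score vectors, each n >= 2.
#' @param tiers significance thresholds, see [significance_tier()].
#' @return one-row data frame with the same columns as
#'   [call_compound_screen()], with `p_value` and `tier` filled in.
#' @export
confirm_compound <- function(compound_id, treated, control,
                             tiers = c(0.05, 0.025, 0.001)) {
  stopifnot(length(treated) >= 2L, length(control) >= 2L,
            !anyNA(treated), !anyNA(control))
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    # t.test is undefined on two constant samples; equal means carry no
    # evidence of an effect, unequal constant means are a degenerate
    # zero-noise separation
    p <- if (mean(treated) == mean(control)) 1 else 0
  } else {
    p <- stats::t.test(treated, control, alternative = "two.sided",
                       var.equal = FALSE)$p.value
  }
  tier <- significance_tier(p, tiers)
  direction <- if (tier == "ns") "no_effect"
               else if (mean(treated) < mean(control)) "decrease"
               else "increase"
  data.frame(compound_id = compound_id, direction = direction,
             effect_ratio = mean(treated) / mean(control),
             p_value = p, tier = tier, n_wells = length(treated),
             stringsAsFactors = FALSE)
}

#' Call every compound of a screen from its scores
#'
#' Orchestrates per-compound calling over a scored screen: for each
#' blinded compound id in the library map, collects its duplicate-well
#' scores, summarises the vehicle wells of the plates those duplicates
#' sit on (pooled), and applies [call_compound_screen()] (threshold
#' mode) or [confirm_compound()] (t-test mode).
#'
#' @param scores a [score_wells()] result covering the screen's plates.
#' @param library_map a [read_library_map()] data frame.
#' @param k threshold multiplier for threshold mode.
#' @param mode `"threshold"` (default, the screen call rule) or
#'   `"ttest"` (Welch confirmation against the pooled vehicle wells).
#' @param tiers significance tiers for t-test mode.
#' @return data frame of calls, one row per compound, class
#'   `compound_calls`.
#' @export
screen_calls <- function(scores, library_map, k = 2,
                         mode = c("threshold", "ttest"),
                         tiers = c(0.05, 0.025, 0.001)) {
  mode <- match.arg(mode)
  scores <- as.data.frame(scores)
  key <- paste(scores$plate_id, scores$well)
  rows <- vector("list", length(unique(library_map$blinded_id)))
  i <- 0L
  for (cid in unique(library_map$blinded_id)) {
    sub <- library_map[library_map$blinded_id == cid, ]
    idx <- match(paste(sub$plate_id, sub$well), key)
    if (anyNA(idx)) {
      stop("library map well not present in scores for compound ", cid,
           call. = FALSE)
    }
    dup <- scores$score[idx][scores$valid[idx]]
    veh <- scores$score[scores$plate_id %in% sub$plate_id &
                        scores$role == "vehicle_control" & scores$valid]
    i <- i + 1L
    if (mode == "threshold") {
      rows[[i]] <- call_compound_screen(cid, dup, summarize_group(veh), k)
    } else {
      rows[[i]] <- if (length(dup) >= 2L) {
        confirm_compound(cid, dup, veh, tiers)
      } else {
        data.frame(compound_id = cid, direction = "no_data",
                   effect_ratio = NA_real_, p_value = NA_real_,
                   tier = NA_character_, n_wells = length(dup),
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("compound_calls", class(out))
  out
}

#' Build the secondary-screen roster from primary calls
#'
#' The cascade carries forward every primary decreaser and increaser,
#' plus a seeded random sample of no-effect compounds that serves as a
#' negative comparison arm in the secondary screen.
#'
#' @param primary_calls a [screen_calls()] result.
#' @param n_no_effect how many no-effect compounds to carry (default 26);
#'   capped at the number available, with a warning.
#' @param seed RNG seed for the no-effect sample, recorded in the result.
#' @return list with `roster` (character vector of compound ids),
#'   `composition` (named counts: decrease/increase/no_effect carried),
#'   and `seed`.
#' @export
triage_cascade <- function(primary_calls, n_no_effect = 26, seed = 1L) {
  dec <- primary_calls$compound_id[primary_calls$direction == "decrease"]
  inc <- primary_calls$compound_id[primary_calls$direction == "increase"]
  ne <- primary_calls$compound_id[primary_calls$direction == "no_effect"]
  if (n_no_effect > length(ne)) {
    warning("requested ", n_no_effect, " no-effect compounds, only ",
            length(ne), " available; capped", call. = FALSE)
    n_no_effect <- length(ne)
  }
  ne_sample <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sample(ne, n_no_effect)
  })
  list(roster = c(dec, inc, ne_sample),
       composition = c(decrease = length(dec), increase = length(inc),
                       no_effect = length(ne_sample)),
       seed = seed)
}

#' Intersect primary and secondary calls into confirmed hit sets
#'
#' A compound is a confirmed decreaser only if it was called `decrease`
#' in both the primary and the secondary screen (and analogously for
#' increasers); the secondary screen is the cascade's false-positive
#' control.
#'
#' @param primary_calls,secondary_calls [screen_calls()] results (the
#'   secondary covering a subset of the primary's compounds).
#' @return list with character vectors `confirmed_decrease` and
#'   `confirmed_increase`.
#' @export
confirm_hits <- function(primary_calls, secondary_calls) {
  extra <- setdiff(secondary_calls$compound_id, primary_calls$compound_id)
  if (length(extra)) {
    stop("secondary-screen compound(s) absent from primary: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  both <- function(dir) {
    p <- primary_calls$compound_id[primary_calls$direction == dir]
    s <- secondary_calls$compound_id[secondary_calls$direction == dir]
    intersect(p, s)
  }
  list(confirmed_decrease = both("decrease"),
       confirmed_increase = both("increase"))
}

#' Positive hit rate as a printed percentage
#'
#' Hit rates are rendered by the convention of the screen's summary
#' table: percentages are truncated toward zero, to one decimal place
#' below 10% and to a whole percent at 10% and above (two significant
#' figures over the range screens produce). So 12/160 -> 7.5,
#' 92/1200 -> 7.6 (not 7.7), 29/160 -> 18 (not 18.1).
#'
#' @param n_hits number of hit compounds (0 <= n_hits <= n_screened).
#' @param n_screened number of compounds screened (> 0).
#' @return the percentage as a number.
#' @export
hit_rate <- function(n_hits, n_screened) {
  stopifnot(length(n_hits) == 1L, length(n_screened) == 1L)
  if (n_screened <= 0) stop("n_screened must be > 0", call. = FALSE)
  stopifnot(n_hits >= 0, n_hits <= n_screened)
  pct <- 100 * n_hits / n_screened
  if (pct < 10) trunc(pct * 10) / 10 else trunc(pct)
}

#' Format a hit rate for reports
#'
#' Whole-number percentages are rendered without a trailing ".0".
#' @param rate a [hit_rate()] value.
#' @return string like `"7.5%"` or `"18%"`.
#' @export
format_hit_rate <- function(rate) {
  num <- if (rate == trunc(rate)) sprintf("%d", as.integer(rate))
         else sprintf("%.1f", rate)
  paste0(num, "%")
}

#' Table-1-style cascade summary
#'
#' @param calls_by_tier named list of [screen_calls()] results, e.g.
#'   `list(primary = ..., secondary = ...)`.
#' @return data frame `tier`, `n_screened`, `n_decrease`, `n_increase`,
#'   `hit_rate_pct` (the positive — fat-reducing — hit rate).
#' @export
cascade_summary <- function(calls_by_tier) {
  rows <- lapply(names(calls_by_tier), function(tier) {
    calls <- calls_by_tier[[tier]]
    nd <- sum(calls$direction == "decrease")
    ni <- sum(calls$direction == "increase")
    data.frame(tier = tier, n_screened = nrow(calls), n_decrease = nd,
               n_increase = ni, hit_rate_pct = hit_rate(nd, nrow(calls)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deselect confirmed hits by annotation flags
#'
#' After unblinding, confirmed compounds carrying undesirable annotations
#' (anthelminthic, cytotoxic, antibiotic, contraceptive activity;
#' unavailability; already-known anti-obesity action) are removed from
#' the lead list, with each removal logged.
#'
#' @param compounds character vector of compound ids (blinded ids).
#' @param annotations the `resolved` data frame of [unblind()] (columns
#'   `blinded_id`, `name`, list column `flags`). Compounds without an
#'   annotation row are flagged `unannotated` and retained.
#' @param excluded_flags flags that trigger removal; default the full
#'   deselection set.
#' @return list with `leads` (retained compound ids), `excluded`
#'   (data frame `compound_id`, `flags`), and `unannotated`.
#' @export
deselect <- function(compounds, annotations,
                     excluded_flags = c("anthelminthic", "cytotoxic",
                                        "antibiotic", "contraceptive",
                                        "unavailable",
                                        "known_anti_obesity")) {
  known_flags <- c("anthelminthic", "cytotoxic", "antibiotic",
                   "contraceptive", "unavailable", "known_anti_obesity")
  bad <- setdiff(excluded_flags, known_flags)
  if (length(bad)) stop("unknown flag(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  idx <- match(compounds, annotations$blinded_id)
  unannotated <- compounds[is.na(idx)]
  hit_flags <- lapply(seq_along(compounds), function(i) {
    if (is.na(idx[i])) character(0)
    else intersect(annotations$flags[[idx[i]]], excluded_flags)
  })
  drop <- vapply(hit_flags, length, 1L) > 0L
  excluded <- data.frame(compound_id = compounds[drop],
                         stringsAsFactors = FALSE)
  excluded$flags <- vapply(hit_flags[drop], paste, "", collapse = ";")
  list(leads = compounds[!drop], excluded = excluded,
       unannotated = unannotated)
}

#' Compare a compound's effect across wild-type and mutant backgrounds
#'
#' For a compound tested in the wild-type reporter strain and in the fat
#' nhr-49 mutant background, reports (i) the wild-type effect
#' (treated vs control Welch t-test), (ii) the mutant effect, and
#' (iii) whether the treated mutant remains fatter than the treated wild
#' type — residual elevation, read as evidence the compound acts via the
#' PPAR pathway the mutant disrupts. A treated mutant pushed below both
#' its own control and the wild-type control indicates a
#' pathway-independent reduction.
#'
#' @param wt_control,wt_treated,mut_control,mut_treated numeric score
#'   vectors, each n >= 2.
#' @param alpha significance level for the classification (default 0.05).
#' @return list of class `background_comparison`: per-comparison p-values
#'   and mean ratios (`wt_effect`, `mut_effect`, `residual`), and a
#'   character vector `classification` that may contain
#'   `"residual_elevation"` and/or `"below_control_reduction"` (empty if
#'   neither applies).
#' @export
compare_backgrounds <- function(wt_control, wt_treated,
                                mut_control, mut_treated, alpha = 0.05) {
  groups <- list(wt_control = wt_control, wt_treated = wt_treated,
                 mut_control = mut_control, mut_treated = mut_treated)
  for (nm in names(groups)) {
    if (is.null(groups[[nm]]) || length(groups[[nm]]) < 2L) {
      stop("missing or undersized group: ", nm, call. = FALSE)
    }
  }
  welch_p <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }
  wt_p <- welch_p(wt_treated, wt_control)
  mut_p <- welch_p(mut_treated, mut_control)
  res_p <- welch_p(mut_treated, wt_treated)
  below_p <- welch_p(mut_treated, wt_control)
  classification <- character(0)
  if (mean(mut_treated) > mean(wt_treated) && res_p < alpha) {
    classification <- c(classification, "residual_elevation")
  }
  if (mean(mut_treated) < mean(mut_control) && mut_p < alpha &&
      mean(mut_treated) < mean(wt_control) && below_p < alpha) {
    classification <- c(classification, "below_control_reduction")
  }
  structure(list(
    wt_effect = list(p_value = wt_p,
                     ratio = mean(wt_treated) / mean(wt_control)),
    mut_effect = list(p_value = mut_p,
                      ratio = mean(mut_treated) / mean(mut_control)),
    residual = list(p_value = res_p,
                    ratio = mean(mut_treated) / mean(wt_treated)),
    classification = classification),
    class = "background_comparison")
}
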