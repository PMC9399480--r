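#' Z'-factor assay quality statistic
#'
#' Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|, computed on a
#' positive and a negative control group. Z' >= 0.5 indicates an
#' excellent assay, 0 < Z' < 0.5 a marginal one, Z' <= 0 a poor one
#' (an assay with no usable separation between controls).
#'
#' @param pos,neg [summarize_group()] results (or lists with `mean` and
#'   `sd`) for the two control groups.
#' @param positive_group,negative_group labels carried into the result.
#' @return object of class `zprime_result`: list with `zprime`, `band`
#'   (`excellent` / `marginal` / `poor`), and the two group labels.
#' @details Z' <= 1 always; Z' = 1 only in the noiseless limit
#'   (both sds zero). Equal group means give zero dynamic range and are
#'   an error. Symmetric in its two arguments.
#' @examples
#' a <- summarize_group(c(90, 100, 110))
#' b <- summarize_group(c(190, 200, 210))
#' compute_zprime(a, b)
#' @export
compute_zprime <- function(pos, neg, positive_group = "positive",
                           negative_group = "negative") {
  for (g in list(pos, neg)) {
    stopifnot(is.numeric(g$mean), is.numeric(g$sd), g$sd >= 0)
  }
  dyn <- abs(pos$mean - neg$mean)
  if (dyn == 0) stop("zero dynamic range: control means are equal",
                     call. = FALSE)
  z <- 1 - 3 * (pos$sd + neg$sd) / dyn
  structure(list(zprime = z, band = zprime_band(z),
                 positive_group = positive_group,
                 negative_group = negative_group),
            class = "zprime_result")
}

#' Band a Z' value
#'
#' `excellent` for 0.5 <= Z' <= 1, `marginal` for 0 < Z' < 0.5,
#' `poor` for Z' <= 0.
#'
#' @param z numeric vector of Z' values.
#' @return character vector of bands.
#' @export
zprime_band <- function(z) {
  stopifnot(all(z <= 1 + 1e-12))
  ifelse(z >= 0.5, "excellent", ifelse(z > 0, "marginal", "poor"))
}

#' @export
print.zprime_result <- function(x, ...) {
  cat(sprintf("<zprime> %s vs %s: Z' = %.3f (%s)\n",
              x$positive_group, x$negative_group, x$zprime, x$band))
  invisible(x)
}

BAND_ORDER <- c(poor = 0L, marginal = 1L, excellent = 2L)

#' Per-plate Z'-factor quality control
#'
#' Computes one Z' per requested control pair per plate and flags plates
#' whose gating pair falls below the minimum band. The two pairs used on
#' the screening plates are (i) vehicle vs AICAR in the wild-type
#' reporter background and (ii) AICAR-treated wild type vs the fat
#' nhr-49 mutant.
#'
#' @param scores a [score_wells()] result (possibly covering several
#'   plates).
#' @param pairs list of 2-element character vectors naming the roles of
#'   (positive, negative) groups; default the two pairs above. Roles are
#'   those of [plate_layout()] well roles.
#' @param gating_pair which pair gates the plate; default
#'   `c("positive_control", "fat_control")` (AICAR vs fat-mutant).
#' @param min_band minimum band for the gating pair; default
#'   `"marginal"` — a plate proceeds on a marginal assay or better.
#' @return data frame of class `qc_report`: `plate_id`, `pair`, `zprime`,
#'   `band`, `qc_pass` (qc_pass is the plate-level gate, repeated on each
#'   of the plate's rows).
#' @export
plate_qc <- function(scores,
                     pairs = list(c("vehicle_control", "positive_control"),
                                  c("positive_control", "fat_control")),
                     gating_pair = c("positive_control", "fat_control"),
                     min_band = "marginal") {
  stopifnot(min_band %in% names(BAND_ORDER))
  scores <- as.data.frame(scores)
  rows <- list()
  for (pid in unique(scores$plate_id)) {
    pl <- scores[scores$plate_id == pid & scores$valid, ]
    groups <- lapply(stats::setNames(nm = unique(unlist(pairs))),
                     function(role) pl$score[pl$role == role])
    for (pair in pairs) {
      for (role in pair) {
        if (length(groups[[role]]) < 2L) {
          stop("plate ", pid, ": control group '", role,
               "' has fewer than 2 valid wells", call. = FALSE)
        }
      }
      zr <- compute_zprime(summarize_group(groups[[pair[1]]]),
                           summarize_group(groups[[pair[2]]]),
                           pair[1], pair[2])
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = pid, pair = paste(pair, collapse = "|"),
        zprime = zr$zprime, band = zr$band, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  gate_name <- paste(gating_pair, collapse = "|")
  pass <- vapply(unique(out$plate_id), function(pid) {
    b <- out$band[out$plate_id == pid & out$pair == gate_name]
    if (!length(b)) {
      stop("gating pair ", gate_name, " not computed for plate ", pid,
           call. = FALSE)
    }
    BAND_ORDER[[b]] >= BAND_ORDER[[min_band]]
  }, logical(1))
  out$qc_pass <- pass[out$plate_id]
  class(out) <- c("qc_report", class(out))
  out
}
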