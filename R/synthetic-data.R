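#' Simulation parameters for synthetic screen data
#'
#' Defaults mirror the screen's stated conditions: wells seeded with 250
#' age-synchronised L1 worms, controls in 4 replicates per plate,
#' compounds at 10 uM in 0.5% DMSO with 0.1 mM AICAR as the positive
#' control, and control strains whose fat content brackets the wild
#' type: the nhr-49 (fat, HBC02) mutant above it, the cebp-1 (thin,
#' HBC04) mutant below it, AICAR-treated wild type reduced.
#'
#' The noise model is multiplicative: GFP scales with the (noisy) worm
#' count, Nile Red with worm count x per-worm fat, each channel carrying
#' independent well-level measurement noise, and each plate one
#' lognormal staining factor applied to the Nile Red channel only (the
#' batch variation the GFP normalisation cannot remove).
#'
#' @param worms_per_well mean worms seeded per well (250).
#' @param worm_count_cv coefficient of variation of the seeded count.
#' @param gfp_per_worm,nr_per_worm_baseline per-worm fluorescence yields
#'   (arbitrary units); their ratio sets the wild-type vehicle score.
#' @param well_noise_cv per-channel well-level multiplicative noise cv.
#' @param plate_effect_cv sdlog of the per-plate Nile Red staining
#'   factor.
#' @param strain_multipliers named per-worm fat multipliers; the fat
#'   control must exceed 1, the thin control must be below 1.
#' @param aicar_multiplier fat multiplier of the AICAR positive control
#'   (< 1).
#' @param compound_uM,aicar_uM,dmso_pct assay concentrations recorded in
#'   the layouts.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(worms_per_well = 250,
                       worm_count_cv = 0.05,
                       gfp_per_worm = 100,
                       nr_per_worm_baseline = 100,
                       well_noise_cv = 0.05,
                       plate_effect_cv = 0.05,
                       strain_multipliers = c(AW306 = 1, HBC02 = 1.6,
                                              HBC04 = 0.6, N2 = 1),
                       aicar_multiplier = 0.6,
                       compound_uM = 10, aicar_uM = 100, dmso_pct = 0.5) {
  stopifnot(worm_count_cv >= 0, well_noise_cv >= 0, plate_effect_cv >= 0,
            all(strain_multipliers > 0),
            strain_multipliers[["HBC02"]] > 1,
            strain_multipliers[["HBC04"]] < 1,
            aicar_multiplier > 0, aicar_multiplier < 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Ground-truth compound effects for a synthetic screen
#'
#' Assigns each compound of a library a true per-worm fat multiplier:
#' 1 for nulls, `mult_decrease` (< 1) for true decreasers,
#' `mult_increase` (> 1) for true increasers. Default fractions put the
#' screen in the regime of a low single-digit positive hit rate
#' (7.5% decreasers, 4% increasers).
#'
#' @param library_size number of compounds.
#' @param frac_decrease,frac_increase fractions of true effects
#'   (sum <= 1).
#' @param mult_decrease,mult_increase true fat multipliers.
#' @param seed RNG seed for assigning which compounds carry effects.
#' @return data frame of class `screen_truth`: `compound_id`,
#'   `multiplier`, `class` (`null`/`decrease`/`increase`).
#' @export
screen_truth <- function(library_size, frac_decrease = 0.075,
                         frac_increase = 0.04, mult_decrease = 0.6,
                         mult_increase = 1.5, seed = 1L) {
  stopifnot(library_size >= 1, frac_decrease >= 0, frac_increase >= 0,
            frac_decrease + frac_increase <= 1,
            mult_decrease > 0, mult_decrease < 1, mult_increase > 1)
  n_dec <- round(frac_decrease * library_size)
  n_inc <- round(frac_increase * library_size)
  cls <- rep("null", library_size)
  pick <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    sample.int(library_size, n_dec + n_inc)
  })
  cls[pick[seq_len(n_dec)]] <- "decrease"
  cls[pick[n_dec + seq_len(n_inc)]] <- "increase"
  out <- data.frame(
    compound_id = sprintf("CPD%04d", seq_len(library_size)),
    multiplier = ifelse(cls == "decrease", mult_decrease,
                        ifelse(cls == "increase", mult_increase, 1)),
    class = cls, stringsAsFactors = FALSE)
  class(out) <- c("screen_truth", class(out))
  out
}

#' Simulate one well's dual-channel readout
#'
#' count ~ round(Normal(worms_per_well, cv * mean)), floored at 0;
#' gfp = gfp_per_worm * count * (1 + e1);
#' nile_red = nr_per_worm_baseline * strain_mult * compound_mult *
#'            count * (1 + e2) * plate_effect;
#' e1, e2 independent zero-mean normals with the configured well cv,
#' both channels clamped at 0. Uses the current RNG state.
#'
#' @param strain one of AW306/HBC02/HBC04/N2.
#' @param compound_multiplier true fat multiplier of whatever is in the
#'   well (1 for vehicle, the AICAR multiplier for the positive
#'   control).
#' @param params a [sim_params()].
#' @param plate_effect the plate's Nile Red staining factor (default 1).
#' @return list with `nile_red`, `gfp`, `count`.
#' @export
simulate_well <- function(strain, compound_multiplier, params,
                          plate_effect = 1) {
  stopifnot(inherits(params, "sim_params"), compound_multiplier > 0)
  count <- max(0, round(stats::rnorm(
    1, params$worms_per_well,
    params$worm_count_cv * params$worms_per_well)))
  e1 <- stats::rnorm(1, 0, params$well_noise_cv)
  e2 <- stats::rnorm(1, 0, params$well_noise_cv)
  gfp <- max(0, params$gfp_per_worm * count * (1 + e1))
  nr <- max(0, params$nr_per_worm_baseline *
              params$strain_multipliers[[strain]] * compound_multiplier *
              count * (1 + e2) * plate_effect)
  list(nile_red = nr, gfp = gfp, count = count)
}

#' Build a screening-plate layout for up to 80 compounds
#'
#' Columns 1-10 hold compound wells (row-major fill); the convention for
#' controls is 4 replicates each in columns 11-12: column 11 rows A-D
#' vehicle, rows E-H AICAR positive control; column 12 rows A-D fat
#' control (HBC02), rows E-H thin control (HBC04). Unused compound wells
#' are empty.
#'
#' @param plate_id plate identifier.
#' @param compound_ids up to 80 blinded compound ids.
#' @param params a [sim_params()] (for recorded concentrations).
#' @return a [plate_layout()].
#' @export
screening_layout <- function(plate_id, compound_ids,
                             params = sim_params()) {
  stopifnot(length(compound_ids) <= 80L)
  comp_wells <- as.vector(t(outer(LETTERS[1:8], 1:10, paste0)))
  rows <- list(
    data.frame(well = comp_wells[seq_along(compound_ids)],
               role = "compound", strain = "AW306",
               compound_id = compound_ids,
               concentration_uM = params$compound_uM,
               dmso_pct = params$dmso_pct, stringsAsFactors = FALSE),
    data.frame(well = paste0(LETTERS[1:4], 11), role = "vehicle_control",
               strain = "AW306", compound_id = NA, concentration_uM = 0,
               dmso_pct = params$dmso_pct, stringsAsFactors = FALSE),
    data.frame(well = paste0(LETTERS[5:8], 11), role = "positive_control",
               strain = "AW306", compound_id = NA,
               concentration_uM = params$aicar_uM,
               dmso_pct = params$dmso_pct, stringsAsFactors = FALSE),
    data.frame(well = paste0(LETTERS[1:4], 12), role = "fat_control",
               strain = "HBC02", compound_id = NA, concentration_uM = 0,
               dmso_pct = params$dmso_pct, stringsAsFactors = FALSE),
    data.frame(well = paste0(LETTERS[5:8], 12), role = "thin_control",
               strain = "HBC04", compound_id = NA, concentration_uM = 0,
               dmso_pct = params$dmso_pct, stringsAsFactors = FALSE))
  plate_layout(plate_id, do.call(rbind, rows))
}

#' Simulate a full duplicate-plate screen
#'
#' Each group of up to 80 compounds gets one layout run on two separate
#' plates (the duplicate), each plate carrying 4 wells each of vehicle,
#' AICAR positive, fat and thin controls and its own staining factor.
#' Fully deterministic under a fixed seed.
#'
#' @param truth a [screen_truth()] (or any data frame with
#'   `compound_id` and `multiplier`).
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param plate_prefix prefix of generated plate ids (plates are named
#'   `<prefix><group><A|B>`).
#' @return list of class `sim_screen`: `layouts` (named list of
#'   [plate_layout()]), `measurements` (long-format data frame
#'   `plate_id`, `well`, `channel`, `value`), `library_map`
#'   ([read_library_map()]-compatible), `truth`, `params`.
#' @export
simulate_screen <- function(truth, params = sim_params(), seed = 1L,
                            plate_prefix = "P") {
  stopifnot(nrow(truth) >= 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  groups <- split(truth$compound_id,
                  (seq_len(nrow(truth)) - 1L) %/% 80L)
  mult <- stats::setNames(truth$multiplier, truth$compound_id)
  layouts <- list()
  meas <- list()
  libmap <- list()
  for (g in seq_along(groups)) {
    for (rep_tag in c("A", "B")) {
      pid <- sprintf("%s%02d%s", plate_prefix, g, rep_tag)
      lay <- screening_layout(pid, groups[[g]], params)
      layouts[[pid]] <- lay
      plate_effect <- stats::rlnorm(1, 0, params$plate_effect_cv)
      wl <- lay$wells[lay$wells$role != "empty", ]
      nr <- gfp <- numeric(nrow(wl))
      for (i in seq_len(nrow(wl))) {
        m <- switch(wl$role[i],
                    compound = mult[[wl$compound_id[i]]],
                    positive_control = params$aicar_multiplier,
                    1)
        sim <- simulate_well(wl$strain[i], m, params, plate_effect)
        nr[i] <- sim$nile_red; gfp[i] <- sim$gfp
      }
      meas[[pid]] <- data.frame(
        plate_id = pid, well = rep(wl$well, 2L),
        channel = rep(c("nile_red", "gfp"), each = nrow(wl)),
        value = c(nr, gfp), stringsAsFactors = FALSE)
      cw <- wl[wl$role == "compound", ]
      libmap[[pid]] <- data.frame(blinded_id = cw$compound_id,
                                  plate_id = pid, well = cw$well,
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(layouts = layouts,
                 measurements = do.call(rbind, c(meas,
                                                 make.row.names = FALSE)),
                 library_map = read_library_map(
                   do.call(rbind, c(libmap, make.row.names = FALSE))),
                 truth = truth, params = params),
            class = "sim_screen")
}

#' Score every plate of a simulated (or ingested) screen
#'
#' @param screen a [simulate_screen()] result.
#' @param ... passed to [score_wells()].
#' @return a combined [score_wells()] data frame over all plates.
#' @export
score_screen <- function(screen, ...) {
  stopifnot(inherits(screen, "sim_screen"))
  parts <- lapply(names(screen$layouts), function(pid) {
    reads <- read_plate_measurements(screen$measurements, plate_id = pid)
    score_wells(reads, screen$layouts[[pid]], ...)
  })
  out <- do.call(rbind, c(parts, make.row.names = FALSE))
  class(out) <- c("fat_scores", class(out))
  out
}

#' Write a simulated screen to the on-disk dialects
#'
#' Emits the exact files the ingestion functions consume: one layout TSV
#' per plate (`layout_<plate>.tsv`), `measurements.csv`,
#' `library_map.tsv`, and `truth.tsv`.
#'
#' @param screen a [simulate_screen()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "sim_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(screen$layouts)) {
    write_layout(screen$layouts[[pid]],
                 file.path(dir, paste0("layout_", pid, ".tsv")))
  }
  utils::write.csv(screen$measurements,
                   file.path(dir, "measurements.csv"), row.names = FALSE)
  utils::write.table(as.data.frame(screen$library_map),
                     file.path(dir, "library_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(screen$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic worm micrograph with known ROI readout
#'
#' Draws a 2584 x 1936 (by default) RGB micrograph of a single worm: an
#' elliptical body anchored at an anterior grinder landmark, a uniform
#' green body-wall GFP signal, and a red Nile Red signal composed of a
#' basal body stain plus Gaussian lipid-droplet blobs (or a uniform fill
#' inside the quantification box). The red channel is rescaled so the
#' box mean lands near `condition_mean`, quantised to 8-bit, and the
#' exact post-quantisation box mean is recorded as ground truth by a
#' direct pixel sum at creation time.
#'
#' @param condition_mean target mean red intensity of the quantification
#'   box, in [0, 255].
#' @param width,height image size in pixels.
#' @param roi_size `(width, height)` of the box the truth refers to.
#' @param pattern `"droplets"` (default) or `"uniform"` (constant red
#'   inside the box only).
#' @param n_droplets,droplet_radius droplet field parameters.
#' @param worm_id,condition labels carried on the image.
#' @return list with `image` (a [worm_image()]) and `true_mean` (the
#'   recorded ground-truth box mean).
#' @export
generate_worm_image <- function(condition_mean, width = 2584L,
                                height = 1936L,
                                roi_size = c(1000L, 1000L),
                                pattern = c("droplets", "uniform"),
                                n_droplets = 400L, droplet_radius = 12,
                                worm_id = NA_character_,
                                condition = NA_character_) {
  pattern <- match.arg(pattern)
  stopifnot(condition_mean >= 0, condition_mean <= 255)
  lx <- min(400L, width - roi_size[1])
  ly <- height %/% 2L
  # quantification box as place_roi() will put it
  rx <- lx + seq_len(roi_size[1])          # 1-based columns
  ry <- floor(ly - roi_size[2] / 2) + seq_len(roi_size[2])
  ry <- ry[ry >= 1 & ry <= height]
  # worm body: ellipse extending right from the landmark (mask cached,
  # the geometry is identical for every image of a given size)
  cx <- lx + 850; cy <- ly; a <- 1000; b <- 450
  key <- paste(width, height, cx, cy, sep = "_")
  body <- .mask_cache[[key]]
  if (is.null(body)) {
    dx2 <- ((seq_len(width) - cx) / a)^2
    dy2 <- ((seq_len(height) - cy) / b)^2
    body <- outer(dy2, dx2, "+") < 1
    .mask_cache[[key]] <- body
  }
  red <- matrix(0, height, width)
  if (pattern == "uniform") {
    red[ry, rx] <- condition_mean
  } else if (condition_mean > 0) {
    red[body] <- 120
    # droplet blobs at random positions inside the body
    th <- stats::runif(n_droplets, 0, 2 * pi)
    rr <- sqrt(stats::runif(n_droplets))
    px <- round(cx + a * rr * cos(th))
    py <- round(cy + b * rr * sin(th))
    s <- droplet_radius / 2
    win <- -ceiling(3 * s):ceiling(3 * s)
    bump <- 60 * exp(-outer(win^2, win^2, "+") / (2 * s^2))
    for (d in seq_len(n_droplets)) {
      yy <- py[d] + win; xx <- px[d] + win
      ok_y <- yy >= 1 & yy <= height; ok_x <- xx >= 1 & xx <= width
      red[yy[ok_y], xx[ok_x]] <- red[yy[ok_y], xx[ok_x]] +
        bump[ok_y, ok_x]
    }
    m0 <- mean(red[ry, rx])
    red <- red * (condition_mean / m0)
  }
  red <- round(red)
  red[red > 255] <- 255   # construction keeps red >= 0
  green <- matrix(0, height, width)
  green[body] <- 120
  pixels <- array(0, c(height, width, 3L))
  pixels[, , 1] <- red
  pixels[, , 2] <- green
  img <- worm_image(pixels, landmark = c(lx, ly), worm_id = worm_id,
                    condition = condition)
  # ground truth: direct sum over the box of the final quantised pixels
  true_mean <- sum(red[ry, rx]) / (length(ry) * length(rx))
  list(image = img, true_mean = true_mean)
}

# package-internal cache of worm body masks keyed by image geometry
.mask_cache <- new.env(parent = emptyenv())
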