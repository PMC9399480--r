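test_that("noiseless wells reproduce the deterministic readout", {
  p0 <- sim_params(worm_count_cv = 0, well_noise_cv = 0,
                   plate_effect_cv = 0)
  w <- simulate_well("AW306", 1, p0)
  expect_identical(w$gfp, p0$gfp_per_worm * 250)
  expect_identical(w$count, 250)
  # a half-fat compound exactly halves the normalised score
  null <- simulate_well("AW306", 1, p0)
  half <- simulate_well("AW306", 0.5, p0)
  expect_identical(half$nile_red / half$gfp,
                   0.5 * (null$nile_red / null$gfp))
})

test_that("noiseless scores factor as strain x compound multipliers", {
  p0 <- sim_params(worm_count_cv = 0, well_noise_cv = 0,
                   plate_effect_cv = 0)
  base <- p0$nr_per_worm_baseline / p0$gfp_per_worm
  for (strain in c("AW306", "HBC02", "HBC04")) {
    for (m in c(0.6, 1, 1.5)) {
      w <- simulate_well(strain, m, p0)
      expect_equal(w$nile_red / w$gfp,
                   base * p0$strain_multipliers[[strain]] * m,
                   tolerance = 1e-15)
    }
  }
})

test_that("control score ordering: fat > wild type > AICAR, thin < wt", {
  p0 <- sim_params(worm_count_cv = 0, well_noise_cv = 0,
                   plate_effect_cv = 0)
  scr <- simulate_screen(screen_truth(4), p0, seed = 1)
  sc <- score_screen(scr)
  grp <- tapply(sc$score, sc$role, mean)
  expect_gt(grp[["fat_control"]], grp[["vehicle_control"]])
  expect_gt(grp[["vehicle_control"]], grp[["positive_control"]])
  expect_lt(grp[["thin_control"]], grp[["vehicle_control"]])
})

test_that("empirical score cv matches an independent re-simulation", {
  params <- sim_params(well_noise_cv = 0.1, worm_count_cv = 0,
                       plate_effect_cv = 0)
  set.seed(40)
  s1 <- replicate(10000, {
    w <- simulate_well("AW306", 1, params)
    w$nile_red / w$gfp
  })
  # independent re-simulation of the same model: ratio of two
  # (1 + eps) factors, eps ~ N(0, 0.1)
  e1 <- rnorm(10000, 0, 0.1); e2 <- rnorm(10000, 0, 0.1)
  s2 <- (1 + e2) / (1 + e1)
  cv1 <- sd(s1) / mean(s1); cv2 <- sd(s2) / mean(s2)
  expect_lt(abs(cv1 - cv2) / cv2, 0.15)
})

test_that("screen geometry: duplicates on two plates, controls on all", {
  truth <- screen_truth(160)
  scr <- simulate_screen(truth, seed = 2)
  expect_length(scr$layouts, 4)  # 2 layout groups x 2 duplicate plates
  lm <- scr$library_map
  per_cpd <- table(lm$blinded_id)
  expect_true(all(per_cpd == 2))
  # each compound's two wells sit on different plates
  plates_per_cpd <- tapply(lm$plate_id, lm$blinded_id,
                           function(p) length(unique(p)))
  expect_true(all(plates_per_cpd == 2))
  ctrl_roles <- c("vehicle_control", "positive_control", "fat_control",
                  "thin_control")
  for (lay in scr$layouts) {
    counts <- table(lay$wells$role)[ctrl_roles]
    expect_equal(unname(as.integer(counts)), rep(4L, 4))
  }
  # measurements cover both channels of every non-empty well
  expect_equal(nrow(scr$measurements), 2 * (4 * 96))
})

test_that("truth assignment respects the configured effect mix", {
  truth <- screen_truth(1200, seed = 9)
  expect_equal(sum(truth$class == "decrease"), 90)  # 7.5% of 1200
  expect_equal(sum(truth$class == "increase"), 48)  # 4% of 1200
  expect_equal(unique(truth$multiplier[truth$class == "decrease"]), 0.6)
  expect_equal(unique(truth$multiplier[truth$class == "increase"]), 1.5)
  expect_true(all(truth$multiplier > 0))
})

test_that("identical seeds give byte-identical screen files", {
  truth <- screen_truth(20, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen(simulate_screen(truth, seed = 3), d1)
  write_screen(simulate_screen(truth, seed = 3), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # and a different seed changes the measurements
  d3 <- withr::local_tempdir()
  write_screen(simulate_screen(truth, seed = 4), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "measurements.csv"))),
    unname(tools::md5sum(file.path(d3, "measurements.csv")))))
})

test_that("written screens re-ingest through the parsing layer", {
  truth <- screen_truth(10, seed = 12)
  scr <- simulate_screen(truth, seed = 12)
  d <- withr::local_tempdir()
  write_screen(scr, d)
  pid <- names(scr$layouts)[1]
  lay <- parse_layout(file.path(d, paste0("layout_", pid, ".tsv")),
                      plate_id = pid)
  expect_identical(lay, scr$layouts[[pid]])
  rd <- read_plate_measurements(file.path(d, "measurements.csv"),
                                plate_id = pid)
  expect_equal(nrow(rd$reads), sum(lay$wells$role != "empty"))
  lm <- read_library_map(file.path(d, "library_map.tsv"))
  expect_equal(sort(unique(lm$blinded_id)), sort(truth$compound_id))
})

test_that("generated worm images record their exact ROI ground truth", {
  set.seed(55)
  g <- suppressWarnings(generate_worm_image(
    80, width = 646L, height = 484L, roi_size = c(250L, 250L),
    n_droplets = 60L))
  roi <- place_roi(g$image, 250, 250)
  expect_equal(roi_mean_red(g$image, roi), g$true_mean,
               tolerance = 1e-12)
  expect_true(all(g$image$pixels >= 0 & g$image$pixels <= 255))
  expect_true(all(g$image$pixels == round(g$image$pixels)))
  # degenerate targets
  z <- suppressWarnings(generate_worm_image(
    0, width = 646L, height = 484L, roi_size = c(250L, 250L)))
  expect_identical(z$true_mean, 0)
  u <- suppressWarnings(generate_worm_image(
    100, width = 646L, height = 484L, roi_size = c(250L, 250L),
    pattern = "uniform"))
  expect_identical(u$true_mean, 100)
  expect_equal(roi_mean_red(u$image, place_roi(u$image, 250, 250)), 100)
})
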