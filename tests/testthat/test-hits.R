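test_that("duplicate-well threshold calls follow the concordance rule", {
  veh <- gs(1.0, 0.1, n = 8)
  at_mean <- call_compound_screen("c1", c(1.0, 1.0), veh, k = 2)
  expect_equal(at_mean$direction, "no_effect")
  expect_equal(at_mean$effect_ratio, 1)

  dec <- call_compound_screen("c2", c(0.6, 0.65), veh, k = 2)
  expect_equal(dec$direction, "decrease")   # both below the 0.8 cut
  expect_lt(dec$effect_ratio, 1)

  disc <- call_compound_screen("c3", c(0.6, 1.0), veh, k = 2)
  expect_equal(disc$direction, "no_effect") # discordant duplicates

  inc <- call_compound_screen("c4", c(1.3, 1.25), veh, k = 2)
  expect_equal(inc$direction, "increase")

  nod <- call_compound_screen("c5", c(NA_real_), veh, k = 2)
  expect_equal(nod$direction, "no_data")
  expect_equal(nod$n_wells, 0L)
})

test_that("significance tiers follow the 0.05/0.025/0.001 ladder", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.02, 5e-4)),
               c("ns", "star", "double_star", "triple_star"))
  expect_error(significance_tier(0.01, tiers = c(0.001, 0.025, 0.05)))
})

test_that("confirmation t-test handles exchangeable and separated groups", {
  same <- confirm_compound("c", c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "no_effect")

  flat <- confirm_compound("c", c(2, 2), c(2, 2))  # zero variance, equal
  expect_equal(flat$p_value, 1)
  expect_equal(flat$direction, "no_effect")

  set.seed(21)
  treated <- rnorm(8, 0.6, 0.05); control <- rnorm(8, 1.0, 0.05)
  conf <- confirm_compound("c", treated, control)
  expect_equal(conf$direction, "decrease")
  expect_equal(conf$tier, "triple_star")
  # brute-force null: exact enumeration of all 12870 label permutations
  pooled <- c(treated, control)
  obs <- abs(mean(treated) - mean(control))
  splits <- utils::combn(16, 8)
  diffs <- apply(splits, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(diffs >= obs - 1e-15)
  expect_lt(p_perm, 0.001)  # permutation oracle agrees with the tier

  # a lower mean without significance stays no_effect
  weak <- confirm_compound("c", c(0.97, 1.01, 0.96, 1.02),
                           c(1.0, 1.03, 0.99, 1.05))
  expect_gte(weak$p_value, 0.05)
  expect_equal(weak$direction, "no_effect")
})

test_that("screen_calls matches per-compound manual calling", {
  set.seed(5)
  truth <- screen_truth(20, frac_decrease = 0.2, frac_increase = 0.1,
                        seed = 5)
  scr <- simulate_screen(truth, sim_params(), seed = 6)
  sc <- score_screen(scr)
  calls <- screen_calls(sc, scr$library_map, k = 2)
  expect_equal(nrow(calls), 20)
  # manual re-derivation for one compound
  cid <- calls$compound_id[1]
  lm <- scr$library_map
  sub <- lm[lm$blinded_id == cid, ]
  dup <- mapply(function(p, w) sc$score[sc$plate_id == p & sc$well == w],
                sub$plate_id, sub$well)
  veh <- sc$score[sc$plate_id %in% sub$plate_id &
                  sc$role == "vehicle_control" & sc$valid]
  lo <- mean(veh) - 2 * sd(veh); hi <- mean(veh) + 2 * sd(veh)
  manual <- if (all(dup < lo)) "decrease" else if (all(dup > hi))
    "increase" else "no_effect"
  expect_equal(calls$direction[1], manual)
  expect_equal(calls$effect_ratio[1], mean(dup) / mean(veh))
})

test_that("null compounds are called at the concordant two-draw rate", {
  # 10,000 effect-free compounds called with k = 2, against a direct
  # Monte-Carlo oracle drawing from the same noise model
  params <- sim_params(plate_effect_cv = 0)
  set.seed(123)
  draw_score <- function(n) {
    counts <- pmax(0, round(rnorm(n, params$worms_per_well,
                                  params$worm_count_cv *
                                    params$worms_per_well)))
    nr <- params$nr_per_worm_baseline * counts *
      (1 + rnorm(n, 0, params$well_noise_cv))
    gf <- params$gfp_per_worm * counts *
      (1 + rnorm(n, 0, params$well_noise_cv))
    nr / gf
  }
  veh_stats <- summarize_group(draw_score(5000))
  n_cpd <- 10000
  d1 <- draw_score(n_cpd); d2 <- draw_score(n_cpd)
  called <- vapply(seq_len(n_cpd), function(i) {
    call_compound_screen("x", c(d1[i], d2[i]), veh_stats,
                         k = 2)$direction
  }, character(1))
  rate <- mean(called == "decrease")
  # independent oracle: same model, plain thresholding
  o1 <- draw_score(n_cpd); o2 <- draw_score(n_cpd)
  cut <- veh_stats$mean - 2 * veh_stats$sd
  rate_oracle <- mean(o1 < cut & o2 < cut)
  se <- sqrt(2 * max(rate, rate_oracle, 1 / n_cpd) / n_cpd)
  expect_lt(abs(rate - rate_oracle), 4 * se + 1e-12)
})

test_that("the cascade roster carries hits plus a seeded null sample", {
  calls <- data.frame(
    compound_id = sprintf("C%03d", 1:170),
    direction = rep(c("decrease", "increase", "no_effect"),
                    c(92, 52, 26)))
  tri <- triage_cascade(calls, n_no_effect = 26, seed = 4)
  expect_length(tri$roster, 170)
  expect_equal(unname(tri$composition),
               c(92L, 52L, 26L))
  # determinism of the seeded sample
  tri2 <- triage_cascade(calls, n_no_effect = 26, seed = 4)
  expect_identical(tri$roster, tri2$roster)

  none <- triage_cascade(
    data.frame(compound_id = "a", direction = "no_effect"),
    n_no_effect = 0)
  expect_length(none$roster, 0)

  expect_warning(
    capped <- triage_cascade(
      data.frame(compound_id = letters[1:5], direction = "no_effect"),
      n_no_effect = 10),
    "capped")
  expect_length(capped$roster, 5)
})

test_that("confirmed hits are the direction-concordant intersection", {
  prim <- data.frame(compound_id = c("A", "B", "C"),
                     direction = c("decrease", "decrease", "increase"))
  sec <- data.frame(compound_id = c("A", "B", "C"),
                    direction = c("decrease", "no_effect", "increase"))
  conf <- confirm_hits(prim, sec)
  expect_equal(conf$confirmed_decrease, "A")
  expect_equal(conf$confirmed_increase, "C")

  disjoint <- confirm_hits(prim, data.frame(compound_id = c("A", "B"),
                                            direction = "no_effect"))
  expect_length(disjoint$confirmed_decrease, 0)

  expect_error(confirm_hits(prim, data.frame(compound_id = "Z",
                                             direction = "decrease")),
               "absent from primary")
})

test_that("hit rates follow the printed truncation convention", {
  expect_equal(hit_rate(12, 160), 7.5)
  expect_equal(hit_rate(92, 1200), 7.6)
  expect_equal(hit_rate(29, 160), 18)
  expect_equal(hit_rate(0, 500), 0)
  expect_error(hit_rate(1, 0))
  expect_error(hit_rate(5, 4))
  expect_equal(format_hit_rate(hit_rate(12, 160)), "7.5%")
  expect_equal(format_hit_rate(hit_rate(29, 160)), "18%")
  # bounded and monotone in n_hits
  prev <- -1
  for (h in 0:25) {
    r <- hit_rate(h, 25)
    expect_gte(r, 0); expect_lte(r, 100); expect_gte(r, prev)
    prev <- r
  }
})

test_that("deselection removes flagged compounds and logs each removal", {
  ann <- data.frame(blinded_id = sprintf("C%d", 1:5),
                    name = letters[1:5])
  ann$flags <- list(character(0), "anthelminthic", "anthelminthic",
                    "known_anti_obesity", character(0))
  sel <- deselect(ann$blinded_id, ann,
                  excluded_flags = "anthelminthic")
  expect_setequal(sel$leads, c("C1", "C4", "C5"))
  expect_setequal(sel$excluded$compound_id, c("C2", "C3"))
  expect_equal(unique(sel$excluded$flags), "anthelminthic")

  sel2 <- deselect(ann$blinded_id, ann)
  expect_false("C4" %in% sel2$leads)  # known anti-obesity removed too

  sel3 <- deselect(ann$blinded_id, ann, excluded_flags = character(0))
  expect_equal(sel3$leads, ann$blinded_id)  # identity

  sel4 <- deselect(c("C1", "C9"), ann)
  expect_equal(sel4$unannotated, "C9")
  expect_true("C9" %in% sel4$leads)  # retained, flagged unannotated
})

test_that("mutant-background comparison classifies the two readings", {
  set.seed(31)
  wt_c <- rnorm(8, 1.0, 0.03);  wt_t <- rnorm(8, 0.7, 0.03)
  mu_c <- rnorm(8, 1.6, 0.03);  mu_t <- rnorm(8, 1.1, 0.03)
  res <- compare_backgrounds(wt_c, wt_t, mu_c, mu_t)
  expect_lt(res$wt_effect$p_value, 0.05)
  expect_lt(res$mut_effect$p_value, 0.05)
  expect_true("residual_elevation" %in% res$classification)
  expect_false("below_control_reduction" %in% res$classification)

  mu_t2 <- rnorm(8, 0.5, 0.03)  # pushed below both controls
  res2 <- compare_backgrounds(wt_c, wt_t, mu_c, mu_t2)
  expect_true("below_control_reduction" %in% res2$classification)
  expect_false("residual_elevation" %in% res2$classification)

  same <- rep(c(1, 1.01, 0.99, 1.02), 2)
  res3 <- compare_backgrounds(same, same, same, same)
  expect_length(res3$classification, 0)

  expect_error(compare_backgrounds(wt_c, wt_t, mu_c, numeric(0)),
               "mut_treated")
})
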