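# Fixtures are built in code: a hand-sized screening layout with the
# conventional control block (columns 11-12), and matching plate-reader
# exports with configurable per-well values.

# 80 compound wells (columns 1-10) + 4 wells each of the four controls.
fixture_layout_df <- function(n_compounds = 80) {
  comp_wells <- as.vector(t(outer(LETTERS[1:8], 1:10, paste0)))
  rbind(
    data.frame(well = comp_wells[seq_len(n_compounds)], role = "compound",
               strain = "AW306",
               compound_id = sprintf("CPD%04d", seq_len(n_compounds)),
               concentration_uM = 10, dmso_pct = 0.5),
    data.frame(well = paste0(LETTERS[1:4], 11), role = "vehicle_control",
               strain = "AW306", compound_id = NA, concentration_uM = 0,
               dmso_pct = 0.5),
    data.frame(well = paste0(LETTERS[5:8], 11), role = "positive_control",
               strain = "AW306", compound_id = NA, concentration_uM = 100,
               dmso_pct = 0.5),
    data.frame(well = paste0(LETTERS[1:4], 12), role = "fat_control",
               strain = "HBC02", compound_id = NA, concentration_uM = 0,
               dmso_pct = 0.5),
    data.frame(well = paste0(LETTERS[5:8], 12), role = "thin_control",
               strain = "HBC04", compound_id = NA, concentration_uM = 0,
               dmso_pct = 0.5))
}

fixture_layout <- function(n_compounds = 80, plate_id = "PX") {
  plate_layout(plate_id, fixture_layout_df(n_compounds))
}

# long-format measurement table with constant channels unless overridden
fixture_measurements <- function(layout, nile_red = 500, gfp = 250) {
  wl <- layout$wells[layout$wells$role != "empty", ]
  n <- nrow(wl)
  data.frame(
    plate_id = layout$plate_id, well = rep(wl$well, 2),
    channel = rep(c("nile_red", "gfp"), each = n),
    value = c(rep_len(nile_red, n), rep_len(gfp, n)))
}

# small in-memory group_stats without going through summarize_group
gs <- function(mean, sd, n = 4) {
  structure(list(n = n, mean = mean, sd = sd, sem = sd / sqrt(n)),
            class = "group_stats")
}
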