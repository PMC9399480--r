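test_that("well addresses are canonicalised and off-grid ones rejected", {
  expect_equal(canonical_well(c("a1", "h12", "B07")), c("A1", "H12", "B7"))
  expect_error(canonical_well("I1"), "address")
  expect_error(canonical_well("A13"), "grid")
  expect_error(canonical_well("11"), "address")
  expect_length(all_wells(), 96)
})

test_that("a full screening layout parses with 80 compound wells", {
  lay <- fixture_layout()
  expect_s3_class(lay, "plate_layout")
  expect_equal(nrow(lay$wells), 96)
  expect_equal(sum(lay$wells$role == "compound"), 80)
  expect_equal(sum(lay$wells$role %in%
                     c("vehicle_control", "positive_control",
                       "fat_control", "thin_control")), 16)
})

test_that("layout invariants are enforced", {
  df <- fixture_layout_df()
  df$well[1] <- "I1"
  expect_error(plate_layout("P", df), "address")
  df <- fixture_layout_df()
  df <- rbind(df, df[1, ])
  expect_error(plate_layout("P", df), "duplicate")
  df <- fixture_layout_df()
  df$compound_id[df$role == "compound"][1] <- NA
  expect_error(plate_layout("P", df), "without compound_id")
  df <- fixture_layout_df()
  df$concentration_uM[1] <- -5
  expect_error(plate_layout("P", df), "negative concentration")
  # screening plates need all four control roles
  df <- fixture_layout_df()
  df <- df[df$role != "thin_control", ]
  expect_error(plate_layout("P", df), "thin_control")
  expect_s3_class(plate_layout("P", df, screening_plate = FALSE),
                  "plate_layout")
})

test_that("layouts round-trip through TSV and JSON identically", {
  lay <- fixture_layout(n_compounds = 10, plate_id = "RT")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_layout(lay, tsv)
  expect_identical(parse_layout(tsv, plate_id = "RT"), lay)

  json <- withr::local_tempfile(fileext = ".json")
  wl <- lay$wells[lay$wells$role != "empty", ]
  obj <- list(plate_id = "RT", wells = lapply(
    stats::setNames(seq_len(nrow(wl)), wl$well), function(i) {
      as.list(wl[i, setdiff(names(wl), "well")])
    }))
  jsonlite::write_json(obj, json, auto_unbox = TRUE, na = "null")
  expect_identical(parse_layout(json), lay)
})

test_that("malformed layout files raise parse/schema errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("well\trole\nI1\tcompound", f)
  expect_error(parse_layout(f), "address")
  writeLines("", f)
  expect_error(parse_layout(f), "empty|schema")
  writeLines("well\tstrain\nA1\tAW306", f)
  expect_error(parse_layout(f), "role")
  expect_error(parse_layout("no/such/file.tsv"), "not found")
})

test_that("a complete 192-row export yields 96 paired well reads", {
  meas <- data.frame(plate_id = "PX", well = rep(all_wells(), 2),
                     channel = rep(c("nile_red", "gfp"), each = 96),
                     value = 100)
  rd <- read_plate_measurements(meas)
  expect_equal(nrow(rd$reads), 96)
  expect_equal(nrow(rd$incomplete), 0)
})

test_that("wells missing a channel are reported, not dropped silently", {
  meas <- data.frame(plate_id = "P", well = rep(all_wells(), 2),
                     channel = rep(c("nile_red", "gfp"), each = 96),
                     value = 100)
  meas <- meas[!(meas$well == "C3" & meas$channel == "gfp"), ]
  rd <- read_plate_measurements(meas)
  expect_equal(nrow(rd$reads), 95)
  expect_equal(rd$incomplete$well, "C3")
  expect_equal(rd$incomplete$missing_channel, "gfp")
  # conservation: complete + incomplete = distinct wells in the file
  expect_equal(nrow(rd$reads) + nrow(rd$incomplete),
               length(unique(meas$well)))
})

test_that("bad measurement values are errors", {
  meas <- data.frame(plate_id = "P", well = c("A1", "A1"),
                     channel = c("nile_red", "gfp"), value = c(-3, 10))
  expect_error(read_plate_measurements(meas), "negative")
  meas <- data.frame(plate_id = "P", well = c("A1", "A1", "A1"),
                     channel = c("nile_red", "nile_red", "gfp"),
                     value = c(1, 2, 3))
  expect_error(read_plate_measurements(meas), "duplicate")
})

test_that("measurement ingestion round-trips through CSV", {
  meas <- data.frame(plate_id = "P", well = rep(c("A1", "B2"), 2),
                     channel = rep(c("nile_red", "gfp"), each = 2),
                     value = c(10, 20, 5, 8))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(meas, f, row.names = FALSE)
  expect_identical(read_plate_measurements(f),
                   read_plate_measurements(meas))
})

test_that("unblinding resolves ids and carries deselection flags", {
  lib <- read_library_map(data.frame(
    blinded_id = rep(c("X1", "X2", "X3"), each = 2),
    plate_id = rep(c("P1", "P2"), 3),
    well = c("A1", "A1", "A2", "A2", "A3", "A3")))
  ann <- data.frame(blinded_id = c("X1", "X2", "X3"),
                    name = c("drugA", "drugB", "drugC"),
                    flags = c("", "anthelminthic", "cytotoxic;antibiotic"))
  ub <- unblind(lib, ann)
  expect_equal(nrow(ub$resolved), 3)
  expect_length(ub$unresolved, 0)
  expect_equal(ub$resolved$flags[[1]], character(0))
  expect_equal(ub$resolved$flags[[2]], "anthelminthic")
  expect_setequal(ub$resolved$flags[[3]], c("cytotoxic", "antibiotic"))

  ub2 <- unblind(lib, ann[ann$blinded_id != "X2", ])
  expect_equal(ub2$unresolved, "X2")
  expect_equal(nrow(ub2$resolved), 2)
})

test_that("the library map refuses two compounds in one well", {
  expect_error(read_library_map(data.frame(
    blinded_id = c("X1", "X2"), plate_id = "P1", well = "A1")),
    "one well")
})
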