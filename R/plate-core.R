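#' Construct and validate a 96-well plate layout
#'
#' A plate layout maps every well of an 8 x 12 plate to a role
#' (compound / vehicle_control / positive_control / fat_control /
#' thin_control / empty), a worm strain, and (for compound wells) a
#' blinded compound identifier with its test concentration.
#'
#' @param plate_id single string identifying the plate.
#' @param wells data frame with columns `well`, `role`, `strain`,
#'   `compound_id`, `concentration_uM`, `dmso_pct`. Wells absent from the
#'   table are filled in as `empty`. Addresses are canonicalised
#'   (see [canonical_well()]).
#' @param screening_plate if `TRUE` (default), validation requires each of
#'   the four control roles (vehicle, AICAR positive, fat-mutant,
#'   thin-mutant) to be present at least once.
#' @return an object of class `plate_layout`: a list with elements
#'   `plate_id` and `wells` (a 96-row data frame in row-major well order).
#' @details Invariants enforced: exactly 96 addressable wells, no
#'   duplicate addresses, every `compound` well carries a `compound_id`,
#'   control and empty wells carry none, concentrations are non-negative.
#' @export
plate_layout <- function(plate_id, wells, screening_plate = TRUE) {
  stopifnot(is.character(plate_id), length(plate_id) == 1L)
  required <- c("well", "role")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("layout schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  wells$well <- canonical_well(wells$well)
  if (anyDuplicated(wells$well)) {
    stop("duplicate well address(es): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  for (col in c("strain", "compound_id")) {
    if (is.null(wells[[col]])) wells[[col]] <- NA_character_
    wells[[col]] <- as.character(wells[[col]])
    wells[[col]][!is.na(wells[[col]]) & wells[[col]] == ""] <- NA_character_
  }
  for (col in c("concentration_uM", "dmso_pct")) {
    if (is.null(wells[[col]])) wells[[col]] <- NA_real_
    wells[[col]] <- as.numeric(wells[[col]])
  }
  bad_strain <- setdiff(stats::na.omit(unique(wells$strain)), WORM_STRAINS)
  if (length(bad_strain)) {
    stop("unknown strain(s): ", paste(bad_strain, collapse = ", "),
         call. = FALSE)
  }
  # fill unlisted wells as empty
  todo <- setdiff(all_wells(), wells$well)
  if (length(todo)) {
    fill <- data.frame(well = todo, role = "empty", strain = NA_character_,
                       compound_id = NA_character_,
                       concentration_uM = NA_real_, dmso_pct = NA_real_,
                       stringsAsFactors = FALSE)
    wells <- rbind(wells[, names(fill)], fill)
  } else {
    wells <- wells[, c("well", "role", "strain", "compound_id",
                       "concentration_uM", "dmso_pct")]
  }
  wells <- wells[match(all_wells(), wells$well), ]
  rownames(wells) <- NULL

  no_id <- wells$role == "compound" & is.na(wells$compound_id)
  if (any(no_id)) {
    stop("compound well(s) without compound_id: ",
         paste(wells$well[no_id], collapse = ", "), call. = FALSE)
  }
  stray_id <- wells$role != "compound" & !is.na(wells$compound_id)
  if (any(stray_id)) {
    stop("non-compound well(s) carrying a compound_id: ",
         paste(wells$well[stray_id], collapse = ", "), call. = FALSE)
  }
  neg_conc <- !is.na(wells$concentration_uM) & wells$concentration_uM < 0
  if (any(neg_conc)) {
    stop("negative concentration in well(s): ",
         paste(wells$well[neg_conc], collapse = ", "), call. = FALSE)
  }
  if (screening_plate) {
    absent <- setdiff(CONTROL_ROLES, wells$role)
    if (length(absent)) {
      stop("screening plate missing control role(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(plate_id = plate_id, wells = wells),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("<plate_layout> plate", x$plate_id, "\n")
  print(table(x$wells$role))
  invisible(x)
}

#' Parse a plate layout file (TSV or JSON)
#'
#' TSV dialect (canonical): one row per well with columns
#' `well`, `role`, `strain`, `compound_id`, `concentration_uM`, `dmso_pct`.
#' JSON dialect: `{"plate_id": ..., "wells": {"A1": {"role": ...}, ...}}`.
#' Format is chosen by file extension (`.json` vs anything else).
#'
#' @param path path to the layout file.
#' @param plate_id plate identifier; for TSV files it must be supplied (or
#'   defaults to the file name without extension), for JSON it is read
#'   from the file.
#' @param screening_plate passed to [plate_layout()].
#' @return a validated [plate_layout()].
#' @export
parse_layout <- function(path, plate_id = NULL, screening_plate = TRUE) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$wells) || !length(obj$wells)) {
      stop("layout schema error: no wells in ", path, call. = FALSE)
    }
    rows <- lapply(names(obj$wells), function(w) {
      spec <- obj$wells[[w]]
      data.frame(
        well = w,
        role = spec$role %||% NA_character_,
        strain = spec$strain %||% NA_character_,
        compound_id = spec$compound_id %||% NA_character_,
        concentration_uM = spec$concentration_uM %||% NA_real_,
        dmso_pct = spec$dmso_pct %||% NA_real_,
        stringsAsFactors = FALSE)
    })
    wells <- do.call(rbind, rows)
    if (anyNA(wells$role)) {
      stop("layout schema error: well(s) without a role in ", path,
           call. = FALSE)
    }
    pid <- plate_id %||% obj$plate_id
    if (is.null(pid)) stop("layout schema error: no plate_id", call. = FALSE)
    return(plate_layout(as.character(pid), wells, screening_plate))
  }
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    stop("layout schema error: empty layout file ", path, call. = FALSE)
  }
  wells <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t"),
    error = function(e) stop("layout parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(wells) == 0L) {
    stop("layout schema error: empty layout file ", path, call. = FALSE)
  }
  if (is.null(wells$role)) {
    stop("layout schema error: missing role column in ", path, call. = FALSE)
  }
  pid <- plate_id %||% tools::file_path_sans_ext(basename(path))
  plate_layout(pid, wells, screening_plate)
}

#' Write a plate layout to the canonical TSV dialect
#'
#' @param layout a [plate_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  utils::write.table(layout$wells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Ingest a dual-channel plate-reader export
#'
#' Reads a long-format CSV with columns `plate_id`, `well`, `channel`,
#' `value`, where channel is `nile_red` (ex 528 / em 580 nm) or `gfp`
#' (ex 482 / em 515 nm), and pairs the two channels per well.
#'
#' @param path CSV path, or a data frame already in that shape.
#' @param plate_id optional filter: keep only rows for this plate.
#' @return an object of class `well_reads`: list with
#'   * `reads` — data frame `plate_id`, `well`, `nile_red`, `gfp`, one row
#'     per well having both channels;
#'   * `incomplete` — data frame `plate_id`, `well`, `missing_channel`
#'     reporting wells lacking a channel (never silently dropped).
#' @details Negative fluorescence values and duplicated (well, channel)
#'   rows are errors.
#' @export
read_plate_measurements <- function(path, plate_id = NULL) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plate_id", "well", "channel", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("measurement schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(plate_id)) df <- df[df$plate_id %in% plate_id, ]
  if (nrow(df) == 0L) stop("no measurement rows", call. = FALSE)
  df$well <- canonical_well(df$well)
  bad_chan <- setdiff(unique(df$channel), c("nile_red", "gfp"))
  if (length(bad_chan)) {
    stop("unknown channel(s): ", paste(bad_chan, collapse = ", "),
         call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("non-numeric fluorescence value", call. = FALSE)
  if (any(df$value < 0)) {
    stop("data error: negative fluorescence value(s) in well(s) ",
         paste(unique(df$well[df$value < 0]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$plate_id, df$well, df$channel)
  if (anyDuplicated(key)) {
    stop("ambiguity error: duplicate (well, channel) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  wide <- stats::reshape(
    df, idvar = c("plate_id", "well"), timevar = "channel",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (is.null(wide$nile_red)) wide$nile_red <- NA_real_
  if (is.null(wide$gfp)) wide$gfp <- NA_real_
  complete <- !is.na(wide$nile_red) & !is.na(wide$gfp)
  incomplete <- wide[!complete, c("plate_id", "well")]
  incomplete$missing_channel <- ifelse(is.na(wide$nile_red[!complete]),
                                       "nile_red", "gfp")
  reads <- wide[complete, c("plate_id", "well", "nile_red", "gfp")]
  rownames(reads) <- rownames(incomplete) <- NULL
  structure(list(reads = reads, incomplete = incomplete),
            class = "well_reads")
}

#' @export
print.well_reads <- function(x, ...) {
  cat("<well_reads>", nrow(x$reads), "complete wells,",
      nrow(x$incomplete), "incomplete\n")
  invisible(x)
}

#' Read a blinded compound library map
#'
#' TSV columns: `blinded_id`, `plate_id`, `well` — one row per assay well,
#' so a compound screened in duplicate has two rows. Duplicate wells are
#' recorded explicitly, never inferred from well position.
#'
#' @param path TSV path or equivalent data frame.
#' @return data frame of class `library_map`.
#' @export
read_library_map <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("blinded_id", "plate_id", "well")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("library map schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$well <- canonical_well(df$well)
  if (anyDuplicated(paste(df$plate_id, df$well))) {
    stop("library map assigns two compounds to one well", call. = FALSE)
  }
  class(df) <- c("library_map", class(df))
  df
}

#' Resolve blinded compound identities against an annotation table
#'
#' Attaches unblinded names and deselection flags (e.g. `anthelminthic`,
#' `cytotoxic`, `antibiotic`, `contraceptive`, `unavailable`,
#' `known_anti_obesity`) to a blinded library map. Compound identities are
#' withheld during measurement and calling; this step is run only after
#' the screen calls are made.
#'
#' @param library a [read_library_map()] result (or compatible data frame
#'   with a `blinded_id` column).
#' @param annotations data frame or TSV path with columns `blinded_id`,
#'   `name`, `flags` (semicolon-separated flag list, may be empty).
#' @return list with
#'   * `resolved` — data frame `blinded_id`, `name`, `flags` (list column
#'     of character vectors) for every id found in the annotations;
#'   * `unresolved` — character vector of blinded ids with no annotation
#'     row (reported, not fatal).
#' @export
unblind <- function(library, annotations) {
  if (!is.data.frame(annotations)) {
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  }
  required <- c("blinded_id", "name")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols)) {
    stop("annotation schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(annotations$flags)) annotations$flags <- ""
  ids <- unique(library$blinded_id)
  hit <- match(ids, annotations$blinded_id)
  resolved <- data.frame(blinded_id = ids[!is.na(hit)],
                         name = annotations$name[hit[!is.na(hit)]],
                         stringsAsFactors = FALSE)
  resolved$flags <- lapply(annotations$flags[hit[!is.na(hit)]], parse_flags)
  list(resolved = resolved, unresolved = ids[is.na(hit)])
}

parse_flags <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
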