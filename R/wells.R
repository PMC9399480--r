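#' Well-address utilities for 96-well plates
#'
#' Wells are addressed row letter (A-H) + column number (1-12),
#' canonicalised to "A1".."H12": upper-case letter, no zero padding.
#' Input is case-insensitive and tolerates zero-padded columns ("a01").
#'
#' @param x character vector of well addresses.
#' @return `canonical_well()` returns the canonical addresses; it errors on
#'   any address that does not fall on the 8 x 12 grid.
#' @examples
#' canonical_well(c("a1", "H12", "b07"))
#' @export
canonical_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-H])0*([0-9]{1,2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well address(es): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[[`, "", 2L)
  col <- as.integer(vapply(m, `[[`, "", 3L))
  if (any(col < 1L | col > 12L)) {
    stop("well address off the 8x12 grid: ",
         paste(x[col < 1L | col > 12L], collapse = ", "), call. = FALSE)
  }
  paste0(row, col)
}

#' All 96 canonical well addresses in row-major order (A1..A12, B1, ..)
#' @return character vector of length 96.
#' @export
all_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

# Roles a well may take on a screening plate.
WELL_ROLES <- c("compound", "vehicle_control", "positive_control",
                "fat_control", "thin_control", "empty")
# Control roles that must each appear at least once on a screening plate.
CONTROL_ROLES <- c("vehicle_control", "positive_control",
                   "fat_control", "thin_control")
WORM_STRAINS <- c("AW306", "HBC02", "HBC04", "N2")
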