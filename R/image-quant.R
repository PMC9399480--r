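#' In-memory fluorescence micrograph of a worm
#'
#' Images are H x W x 3 arrays of 8-bit channel intensities (0-255),
#' channel 1 = red (the Nile Red signal), origin at the top-left pixel,
#' x rightward (columns), y downward (rows), 0-based landmark
#' coordinates. The landmark is the pharyngeal grinder — the anatomical
#' anchor used to place the quantification box. Conformant micrographs
#' are 2584 x 1936 px; other sizes are accepted with a warning.
#'
#' @param pixels numeric H x W x 3 array, values in [0, 255].
#' @param landmark length-2 numeric `(x, y)` pixel coordinate of the
#'   grinder, 0-based, inside the image.
#' @param worm_id identifier.
#' @param condition condition label (e.g. compound name or "control").
#' @return object of class `worm_image`.
#' @export
worm_image <- function(pixels, landmark, worm_id = NA_character_,
                       condition = NA_character_) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L,
            dim(pixels)[3] == 3L, length(landmark) == 2L)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  x <- landmark[1]; y <- landmark[2]
  if (x < 0 || y < 0 || x >= w || y >= h) {
    stop("landmark (", x, ", ", y, ") outside image bounds", call. = FALSE)
  }
  if (!(h == 1936L && w == 2584L)) {
    warning("non-conformant image size ", w, "x", h,
            " (expected 2584x1936)", call. = FALSE)
  }
  structure(list(pixels = pixels, landmark = c(x = x, y = y),
                 worm_id = worm_id, condition = condition),
            class = "worm_image")
}

#' Read a worm micrograph from PNG or TIFF
#'
#' @param path image path; format from the extension. Intensities are
#'   rescaled to the 0-255 range.
#' @param landmark,worm_id,condition passed to [worm_image()]; landmarks
#'   normally come from a sidecar CSV, see [read_landmarks()].
#' @return a [worm_image()].
#' @export
read_worm_image <- function(path, landmark, worm_id = NA_character_,
                            condition = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  worm_image(img * 255, landmark, worm_id, condition)
}

#' Read a landmark sidecar CSV
#'
#' Columns: `image` (file name or path), `x`, `y` (0-based grinder
#' pixel coordinates), `condition`.
#'
#' @param path CSV path.
#' @return data frame with those columns.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image", "x", "y", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("landmark schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Place the quantification box against the grinder landmark
#'
#' The box's left edge abuts the landmark x-coordinate and the box is
#' vertically centred on the landmark, then clamped (with a warning) so
#' it lies fully within the image. Placement is deterministic.
#'
#' @param image a [worm_image()].
#' @param width,height box size in pixels (default 1000 x 1000).
#' @return object of class `roi_box`: list with `origin` (`(x, y)`,
#'   0-based top-left corner), `width`, `height`.
#' @examples
#' img <- worm_image(array(0, c(1936, 2584, 3)), landmark = c(500, 968))
#' place_roi(img)$origin  # x 500, y 468
#' @export
place_roi <- function(image, width = 1000L, height = 1000L) {
  stopifnot(inherits(image, "worm_image"), width >= 1L, height >= 1L)
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  if (width > w || height > h) {
    stop("ROI larger than the image", call. = FALSE)
  }
  ox <- floor(image$landmark[["x"]])
  oy <- floor(image$landmark[["y"]] - height / 2)
  cx <- min(max(ox, 0), w - width)
  cy <- min(max(oy, 0), h - height)
  if (cx != ox || cy != oy) {
    # only warn when clamping was forced by the border, not by centring
    if (ox > w - width || oy < 0 || oy > h - height) {
      warning("ROI clamped to image bounds", call. = FALSE)
    }
  }
  structure(list(origin = c(x = cx, y = cy),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_box")
}

#' Mean red-channel intensity over a quantification box
#'
#' The Nile Red readout of a micrograph: the arithmetic mean of the red
#' channel over every pixel of the box. Depends only on the multiset of
#' pixel values inside the box.
#'
#' @param image a [worm_image()].
#' @param roi a [place_roi()] box (default: placed from the image's
#'   landmark at 1000 x 1000).
#' @return mean intensity (arbitrary units, 0-255 scale).
#' @export
roi_mean_red <- function(image, roi = place_roi(image)) {
  stopifnot(inherits(image, "worm_image"), inherits(roi, "roi_box"))
  rows <- (roi$origin[["y"]] + 1):(roi$origin[["y"]] + roi$height)
  cols <- (roi$origin[["x"]] + 1):(roi$origin[["x"]] + roi$width)
  mean(image$pixels[rows, cols, 1L])
}

#' Quantify a group of worm micrographs
#'
#' Computes the per-worm box-mean red intensity for each image and the
#' group mean, sd and sem. To keep memory bounded with full-size
#' micrographs, each element of `images` may be a [worm_image()], a
#' one-row entry of a landmark table (a list with `image`, `x`, `y`,
#' `condition`, loaded via [read_worm_image()]), or a zero-argument
#' function returning a [worm_image()]; images are reduced to their
#' scalar readout one at a time.
#'
#' @param images list of image sources (n >= 2).
#' @param roi_size length-2 `(width, height)` of the box.
#' @return list with `per_worm` (data frame `worm_id`, `condition`,
#'   `roi_origin_x`, `roi_origin_y`, `mean_red`) and `stats`
#'   (a [summarize_group()] of the per-worm values).
#' @export
quantify_group <- function(images, roi_size = c(1000L, 1000L)) {
  stopifnot(length(images) >= 2L)
  sizes <- NULL
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    src <- images[[i]]
    img <- if (inherits(src, "worm_image")) src
           else if (is.function(src)) src()
           else if (is.list(src) && !is.null(src$image)) {
             read_worm_image(src$image, c(src$x, src$y),
                             worm_id = basename(src$image),
                             condition = src$condition %||% NA_character_)
           } else stop("unrecognised image source at position ", i,
                       call. = FALSE)
    sizes <- unique(rbind(sizes, dim(img$pixels)[1:2]))
    roi <- place_roi(img, roi_size[1], roi_size[2])
    rows[[i]] <- data.frame(
      worm_id = img$worm_id %||% NA_character_,
      condition = img$condition %||% NA_character_,
      roi_origin_x = roi$origin[["x"]], roi_origin_y = roi$origin[["y"]],
      mean_red = roi_mean_red(img, roi), stringsAsFactors = FALSE)
    rm(img)
  }
  if (!is.null(sizes) && nrow(sizes) > 1L) {
    warning("mixed image sizes in group; proceeding", call. = FALSE)
  }
  per_worm <- do.call(rbind, rows)
  list(per_worm = per_worm, stats = summarize_group(per_worm$mean_red))
}
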