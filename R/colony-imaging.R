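#' Construct a condition label
#'
#' Describes one well's experimental condition: which CAF (or `"none"` for
#' non-cocultured controls), whether cisplatin was involved, and the medium
#' kind (see [medium_kinds]). Non-cocultured conditions may only carry
#' `fresh` or `depleted` medium.
#'
#' @param caf_id CAF identifier or `"none"`.
#' @param cisplatin Logical flag.
#' @param medium_kind One of [medium_kinds].
#' @return A list of class `condition_label`.
#' @export
condition_label <- function(caf_id = "none", cisplatin = FALSE,
                            medium_kind = "fresh") {
  medium_kind <- match.arg(medium_kind, medium_kinds)
  stopifnot(is.character(caf_id), length(caf_id) == 1L,
            is.logical(cisplatin), length(cisplatin) == 1L)
  if (caf_id == "none" && !medium_kind %in% c("fresh", "depleted")) {
    stop("non-cocultured conditions (caf_id = \"none\") must use fresh or ",
         "depleted medium, not ", medium_kind, call. = FALSE)
  }
  structure(list(caf_id = caf_id, cisplatin = cisplatin,
                 medium_kind = medium_kind),
            class = "condition_label")
}

#' Construct a plate image
#'
#' Wraps an 8-bit RGB raster (array of dimension height x width x 3, values
#' 0..255) with an optional binary well mask restricting the analyzable
#' region, a well id and a [condition_label()].
#'
#' @param pixels Numeric array `h x w x 3`, values in 0..255.
#' @param well_mask Optional logical matrix of the same height/width; must
#'   contain at least one `TRUE` pixel. `NULL` means the whole image.
#' @param well_id Character label.
#' @param condition Optional [condition_label()].
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, well_mask = NULL, well_id = "well",
                        condition = NULL) {
  if (!(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L))
    stop("pixels must be an RGB array of dimension h x w x 3", call. = FALSE)
  if (any(dim(pixels)[1:2] <= 0))
    stop("image dimensions must be positive", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in 0..255", call. = FALSE)
  if (!is.null(well_mask)) {
    if (!identical(dim(well_mask), dim(pixels)[1:2]))
      stop("well_mask dimensions must match the image", call. = FALSE)
    if (!any(well_mask))
      stop("well_mask is empty: no analyzable pixels", call. = FALSE)
  }
  if (!is.null(condition)) stopifnot(inherits(condition, "condition_label"))
  structure(list(pixels = pixels, well_mask = well_mask, well_id = well_id,
                 condition = condition),
            class = "plate_image")
}

#' Convert an 8-bit sRGB raster to CIELAB
#'
#' Conversion uses [grDevices::convertColor()] with the D65 reference
#' white, so pure white maps to L = 100 and the neutral axis to a = b = 0.
#' Blue-stained pixels land at strongly negative b (the blue pole of the
#' blue-yellow opponent channel), which is what colony segmentation
#' thresholds on.
#'
#' @param raster RGB array `h x w x 3` (0..255), or an `n x 3` matrix of
#'   RGB triples.
#' @return Array (or matrix) of the same shape with L, a, b planes.
#' @examples
#' rgb_to_lab(matrix(c(255, 255, 255), 1))  # ~ (100, 0, 0)
#' @export
rgb_to_lab <- function(raster) {
  if (is.matrix(raster) && ncol(raster) == 3L) {
    return(grDevices::convertColor(raster / 255, from = "sRGB", to = "Lab",
                                   scale.in = 1))
  }
  if (!(is.array(raster) && length(dim(raster)) == 3L && dim(raster)[3] == 3L))
    stop("raster must be an RGB array (h x w x 3) or an n x 3 matrix",
         call. = FALSE)
  d <- dim(raster)
  flat <- matrix(raster, ncol = 3L)  # column k = channel k
  lab <- grDevices::convertColor(flat / 255, from = "sRGB", to = "Lab",
                                 scale.in = 1)
  array(lab, dim = d)
}

#' Circular region-of-interest mask
#'
#' Helper for restricting segmentation to the well of a multi-well plate
#' scan. Coordinates are (row, col) and radii in pixels.
#'
#' @param nrow,ncol Image dimensions.
#' @param center Numeric pair (row, col); defaults to the image center.
#' @param radius Circle radius in pixels.
#' @return Logical matrix, `TRUE` inside the circle.
#' @export
circular_roi <- function(nrow, ncol = nrow, center = c((nrow + 1) / 2, (ncol + 1) / 2),
                         radius = min(nrow, ncol) / 2) {
  stopifnot(nrow >= 1, ncol >= 1, radius > 0)
  rg <- matrix(seq_len(nrow), nrow, ncol)
  cg <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rg - center[1])^2 + (cg - center[2])^2 <= radius^2
}

#' Segment stained colonies by color thresholding
#'
#' Classifies a pixel as colony if its color channel lies on the requested
#' side of a single fixed threshold and it falls inside the well mask, then
#' reports the fraction of the well covered. The default channel is CIELAB
#' b with `direction = "below"` and threshold -5: trypan-blue-stained
#' colonies are far on the blue pole (b around -45 for the default stain)
#' while unstained background sits near b = 0. The raw RGB blue channel is
#' available as an alternative reading (`direction = "above"` is the
#' natural pairing there, since stained pixels have high blue values).
#' No morphological cleanup is applied unless `min_size` is set.
#'
#' @param image A [plate_image()] or an RGB array (0..255).
#' @param threshold Finite threshold on the chosen channel.
#' @param direction `"below"` (colony if channel < threshold) or
#'   `"above"`.
#' @param channel `"lab_b"` (default) or `"rgb_blue"`.
#' @param min_size Optional minimum connected-component size in pixels
#'   (requires the EBImage package); 0 disables filtering.
#' @return List with `mask` (logical matrix) and `measurement` (one-row
#'   data frame: `well_id`, `caf_id`, `cisplatin`, `medium_kind`,
#'   `colony_pixels`, `well_pixels`, `area_fraction`).
#' @export
segment_colonies <- function(image, threshold = -5,
                             direction = c("below", "above"),
                             channel = c("lab_b", "rgb_blue"),
                             min_size = 0) {
  direction <- match.arg(direction)
  channel <- match.arg(channel)
  stopifnot(is.finite(threshold))
  if (!inherits(image, "plate_image")) image <- plate_image(image)

  well <- image$well_mask
  if (is.null(well)) well <- matrix(TRUE, dim(image$pixels)[1], dim(image$pixels)[2])
  if (!any(well)) stop("well mask is empty", call. = FALSE)

  ch <- switch(channel,
    lab_b = rgb_to_lab(image$pixels)[, , 3],
    rgb_blue = image$pixels[, , 3]
  )
  mask <- if (direction == "below") ch < threshold else ch > threshold
  mask <- mask & well

  if (min_size > 0) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("min_size filtering requires the EBImage package", call. = FALSE)
    lab <- EBImage::bwlabel(mask)
    keep <- which(tabulate(lab[lab > 0]) >= min_size)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }

  cond <- image$condition
  if (is.null(cond)) cond <- condition_label()
  measurement <- data.frame(
    well_id = image$well_id,
    caf_id = cond$caf_id,
    cisplatin = cond$cisplatin,
    medium_kind = cond$medium_kind,
    colony_pixels = sum(mask),
    well_pixels = sum(well),
    area_fraction = sum(mask) / sum(well)
  )
  list(mask = mask, measurement = measurement)
}

#' Measure a batch of plate images with one shared threshold
#'
#' Applies [segment_colonies()] with the same single threshold to every
#' image and stacks the per-well measurements in input order.
#'
#' @param images List of [plate_image()] objects.
#' @inheritParams segment_colonies
#' @return Data frame with one row per image (columns as in
#'   [segment_colonies()]'s `measurement`).
#' @export
batch_measure <- function(images, threshold = -5,
                          direction = c("below", "above"),
                          channel = c("lab_b", "rgb_blue"), min_size = 0) {
  direction <- match.arg(direction)
  channel <- match.arg(channel)
  empty <- data.frame(well_id = character(), caf_id = character(),
                      cisplatin = logical(), medium_kind = character(),
                      colony_pixels = integer(), well_pixels = integer(),
                      area_fraction = numeric())
  if (length(images) == 0L) return(empty)
  rows <- lapply(images, function(img) {
    segment_colonies(img, threshold = threshold, direction = direction,
                     channel = channel, min_size = min_size)$measurement
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a plate image from a PNG file
#'
#' @param path PNG path.
#' @inheritParams plate_image
#' @return A [plate_image()] with 0..255 intensities.
#' @export
read_plate_png <- function(path, well_mask = NULL,
                           well_id = tools::file_path_sans_ext(basename(path)),
                           condition = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  plate_image(px * 255, well_mask = well_mask, well_id = well_id,
              condition = condition)
}

#' Write a plate image (or a binary mask) as PNG
#'
#' @param x A [plate_image()], an RGB array (0..255) or a logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(x, path) {
  if (inherits(x, "plate_image")) x <- x$pixels
  if (is.logical(x)) x <- matrix(as.numeric(x) * 255, nrow(x), ncol(x))
  png::writePNG(x / 255, target = path)
  invisible(path)
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<plate_image>", x$well_id, sprintf("(%d x %d px)", d[1], d[2]), "\n")
  if (!is.null(x$condition)) {
    cat("  condition:", x$condition$caf_id,
        if (x$condition$cisplatin) "+cisplatin" else "untreated",
        x$condition$medium_kind, "\n")
  }
  if (!is.null(x$truth)) {
    cat("  true area fraction:",
        format(x$truth$true_area_fraction, digits = 4), "\n")
  }
  invisible(x)
}
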