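#' Organ class codes and display palette
#'
#' Segmentation maps code pixels as 0 = background, 1 = leaf, 2 = stalk,
#' 3 = panicle (the maize tassel occupies the panicle slot). The palette
#' used for colour previews is part of the package contract and bit-exact:
#' background white (255,255,255), leaf green (127,201,127), stalk orange
#' (253,192,134), panicle purple (190,173,212).
#'
#' @format An integer matrix with one row per class code 0-3 and columns
#'   `r`, `g`, `b`.
#' @export
ORGAN_PALETTE <- matrix(
  c(255L, 255L, 255L,
    127L, 201L, 127L,
    253L, 192L, 134L,
    190L, 173L, 212L),
  nrow = 4L, byrow = TRUE,
  dimnames = list(c("background", "leaf", "stalk", "panicle"),
                  c("r", "g", "b")))

#' Default organ class vocabulary
#' @return Named integer vector mapping class names to codes 0-3; "tassel"
#'   aliases to the panicle slot (code 3).
#' @export
organ_classes <- function() {
  c(background = 0L, leaf = 1L, stalk = 2L, panicle = 3L, tassel = 3L)
}

#' Segmentation map container
#'
#' @param labels integer matrix (`H x W`) with values in `{0,1,2,3}`.
#' @param image_id optional source image identifier.
#' @return An integer matrix of class `"segmentation_map"`.
#' @export
segmentation_map <- function(labels, image_id = NULL) {
  if (!is.matrix(labels))
    stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 3L))
    stop("segmentation labels must be integers in {0, 1, 2, 3}",
         call. = FALSE)
  structure(labels, image_id = image_id,
            class = c("segmentation_map", "matrix", "array"))
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d x %d px; counts: %s\n",
              nrow(x), ncol(x),
              paste(names(class_counts(x)), class_counts(x),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Whole-image semantic segmentation
#'
#' Flattens the cube to pixel spectra, classifies every pixel with the
#' fitted model, and reshapes the label vector back to the image grid.
#'
#' @param model a fitted classifier from [train_classifier()].
#' @param cube a [hypercube].
#' @return A [segmentation_map] with the cube's spatial dimensions.
#' @export
segment_image <- function(model, cube) {
  stopifnot(inherits(cube, "hypercube"))
  feats <- flatten_cube(cube)
  pred <- predict_pixels(model, feats)
  reshape_predictions(pred$labels, attr(feats, "dims"),
                      image_id = cube$provenance)
}

#' Colour visualization of a segmentation map
#'
#' Maps each class code to its palette colour, bit-exact. `decolorize()`
#' inverts the mapping and errors on any pixel colour outside the palette.
#'
#' @param map a [segmentation_map].
#' @return `colorize()`: an `H x W x 3` integer array of 0-255 RGB values.
#' @export
colorize <- function(map) {
  m <- unclass(map)
  if (anyNA(m) || any(m < 0L | m > 3L))
    stop("map labels must be in {0, 1, 2, 3}", call. = FALSE)
  idx <- as.integer(m) + 1L
  array(c(ORGAN_PALETTE[idx, "r"], ORGAN_PALETTE[idx, "g"],
          ORGAN_PALETTE[idx, "b"]),
        dim = c(nrow(m), ncol(m), 3L))
}

#' @rdname colorize
#' @param rgb an `H x W x 3` integer array produced by [colorize()].
#' @export
decolorize <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("`rgb` must be an H x W x 3 array", call. = FALSE)
  key <- rgb[, , 1L] * 1e6 + rgb[, , 2L] * 1e3 + rgb[, , 3L]
  pal_key <- ORGAN_PALETTE[, "r"] * 1e6 + ORGAN_PALETTE[, "g"] * 1e3 +
    ORGAN_PALETTE[, "b"]
  lab <- array(match(key, pal_key), dim = dim(key))
  if (anyNA(lab))
    stop("image contains colours outside the organ palette", call. = FALSE)
  segmentation_map(lab - 1L)
}

#' Per-class pixel counts
#'
#' @param map a [segmentation_map] (or plain label matrix).
#' @return Named integer vector of length 4 (background, leaf, stalk,
#'   panicle); entries sum to `H * W`.
#' @export
class_counts <- function(map) {
  m <- unclass(map)
  cnt <- tabulate(as.integer(m) + 1L, nbins = 4L)
  names(cnt) <- rownames(ORGAN_PALETTE)
  cnt
}

#' Write a segmentation map or colour preview to PNG
#'
#' Label maps are written as single-channel PNGs carrying the raw codes 0-3
#' (scaled by 1/255 on disk as PNG stores normalised intensities); colour
#' previews use the exact palette.
#'
#' @param map a [segmentation_map].
#' @param path output file.
#' @export
write_mask_png <- function(map, path) {
  png::writePNG(unclass(map) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  segmentation_map(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)))
}

#' @rdname write_mask_png
#' @export
write_colorized_png <- function(map, path) {
  png::writePNG(colorize(map) / 255, path)
  invisible(path)
}
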