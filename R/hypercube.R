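#' Hyperspectral cube container
#'
#' A hyperspectral cube is an `H x W x B` array of reflectance values in
#' `[0, 1]`: `H` image rows, `W` image columns and `B` spectral bands, with a
#' strictly increasing wavelength grid attached. Row 1 is the top of the
#' image (raster convention).
#'
#' @param values numeric `H x W x B` array of finite reflectance values.
#' @param wavelength_nm strictly increasing numeric vector of length `B`
#'   giving the centre wavelength of each band in nanometres. Defaults to a
#'   linear grid over 546-1700 nm (the shortwave range of the line-scan
#'   cameras this package targets).
#' @param provenance optional character scalar recording where the cube came
#'   from (directory path, image id, ...).
#' @return An object of class `"hypercube"`.
#' @export
hypercube <- function(values, wavelength_nm = NULL, provenance = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (rows x cols x bands)", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all cube dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("cube values must all be finite", call. = FALSE)
  b <- dim(values)[3L]
  if (is.null(wavelength_nm))
    wavelength_nm <- if (b >= 2L) band_wavelengths(b, 546, 1700) else 546
  if (length(wavelength_nm) != b)
    stop("`wavelength_nm` must have one entry per band", call. = FALSE)
  if (b > 1L && any(diff(wavelength_nm) <= 0))
    stop("`wavelength_nm` must be strictly increasing", call. = FALSE)
  structure(
    list(values = values, wavelength_nm = as.numeric(wavelength_nm),
         provenance = provenance),
    class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Linear band-to-wavelength grid
#'
#' Maps band indices to wavelengths on a linear grid from `wl_min_nm` to
#' `wl_max_nm` inclusive, e.g. 243 bands over 546-1700 nm gives a spacing of
#' about 4.77 nm per band.
#'
#' @param n_bands number of bands, at least 2.
#' @param wl_min_nm,wl_max_nm wavelength range endpoints in nanometres.
#' @return Numeric vector of length `n_bands`.
#' @export
band_wavelengths <- function(n_bands, wl_min_nm, wl_max_nm) {
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 2)
    stop("`n_bands` must be a single integer >= 2", call. = FALSE)
  if (wl_min_nm >= wl_max_nm)
    stop("`wl_min_nm` must be < `wl_max_nm`", call. = FALSE)
  seq(wl_min_nm, wl_max_nm, length.out = as.integer(n_bands))
}

#' Stack per-band grayscale images into a hyperspectral cube
#'
#' Hyperspectral line-scan systems commonly emit one grayscale image per
#' wavelength band. `stack_bands()` reads an ordered list of such images
#' (PNG or TIFF) and stacks them along the spectral axis; list order defines
#' band order. Intensities are rescaled to `[0, 1]` by the image dtype's
#' maximum (8- or 16-bit), which the PNG/TIFF readers perform on load.
#'
#' @param band_image_paths character vector of image paths, in band order.
#' @param wavelength_nm optional wavelength grid (length = number of images).
#' @return A [hypercube].
#' @export
stack_bands <- function(band_image_paths, wavelength_nm = NULL) {
  if (length(band_image_paths) == 0L)
    stop("`band_image_paths` must list at least one image", call. = FALSE)
  planes <- lapply(band_image_paths, read_gray_image)
  d1 <- dim(planes[[1L]])
  for (i in seq_along(planes)) {
    if (!identical(dim(planes[[i]]), d1))
      stop(sprintf(
        "band image '%s' has dimensions %d x %d, expected %d x %d",
        band_image_paths[i], dim(planes[[i]])[1], dim(planes[[i]])[2],
        d1[1], d1[2]), call. = FALSE)
  }
  values <- array(unlist(planes, use.names = FALSE),
                  dim = c(d1[1], d1[2], length(planes)))
  hypercube(values, wavelength_nm = wavelength_nm,
            provenance = dirname(band_image_paths[1L]))
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported band image format '%s' for '%s'", ext, path),
         call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse grayscale stored as RGB
  img
}

#' Crop a cube to a spatial window
#'
#' Ranges are half-open `[start, stop)` in 1-based indices: `row_range =
#' c(1, 450)` keeps rows 1..449. Wavelengths are unchanged.
#'
#' @param cube a [hypercube].
#' @param row_range,col_range integer pairs `c(start, stop)`, half-open.
#' @return The cropped [hypercube].
#' @export
crop_cube <- function(cube, row_range, col_range) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  check_range <- function(r, n, what) {
    if (length(r) != 2L || any(is.na(r)))
      stop(sprintf("`%s` must be c(start, stop)", what), call. = FALSE)
    if (r[1] < 1 || r[2] > n + 1 || r[2] <= r[1])
      stop(sprintf("`%s` [%s, %s) is out of bounds or empty for extent %d",
                   what, r[1], r[2], n), call. = FALSE)
  }
  check_range(row_range, d[1], "row_range")
  check_range(col_range, d[2], "col_range")
  rows <- seq.int(row_range[1], row_range[2] - 1L)
  cols <- seq.int(col_range[1], col_range[2] - 1L)
  hypercube(cube$values[rows, cols, , drop = FALSE],
            wavelength_nm = cube$wavelength_nm,
            provenance = cube$provenance)
}

#' Flatten a cube to a pixel-by-band feature array
#'
#' Converts the `H x W x B` cube to an `(H*W) x B` matrix of pixel spectra in
#' row-major pixel order: matrix row `(i-1)*W + j` is image pixel `(i, j)`.
#' The spatial dimensions are kept as an attribute so that
#' [reshape_predictions()] can invert the operation exactly.
#'
#' @param cube a [hypercube].
#' @return A numeric matrix of class `"feature_array"` with attribute
#'   `dims = c(H, W)`.
#' @export
flatten_cube <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  m <- matrix(aperm(cube$values, c(2L, 1L, 3L)), nrow = d[1] * d[2],
              ncol = d[3])
  structure(m, dims = c(d[1], d[2]), wavelength_nm = cube$wavelength_nm,
            class = c("feature_array", class(m)))
}

#' Reshape a flat label vector back into a segmentation map
#'
#' Inverts the row-major flattening of [flatten_cube()]: element
#' `(i-1)*W + j` of `labels` becomes map entry `(i, j)`.
#'
#' @param labels integer vector of length `H*W` with values in `{0,1,2,3}`.
#' @param dims integer pair `c(H, W)`.
#' @param image_id optional id recorded on the map.
#' @return A [segmentation_map].
#' @export
reshape_predictions <- function(labels, dims, image_id = NULL) {
  if (length(dims) != 2L || any(dims < 1))
    stop("`dims` must be c(H, W) with positive entries", call. = FALSE)
  if (length(labels) != prod(dims))
    stop(sprintf("`labels` has length %d; expected H*W = %d",
                 length(labels), prod(dims)), call. = FALSE)
  m <- t(matrix(as.integer(labels), nrow = dims[2L], ncol = dims[1L]))
  segmentation_map(m, image_id = image_id)
}

#' Write / read a cube as a directory of band images
#'
#' The on-disk layout is one 16-bit grayscale TIFF per band, named
#' `band_000.tif`, `band_001.tif`, ..., plus a `wavelengths.csv` with columns
#' `band_index,wavelength_nm`. This mirrors how imaging systems emit raw
#' band stacks and keeps everything plain-file inspectable.
#'
#' @param cube a [hypercube].
#' @param dir output directory (created if absent).
#' @return `write_cube_dir()` returns `dir` invisibly; `read_cube_dir()`
#'   returns a [hypercube].
#' @export
write_cube_dir <- function(cube, dir) {
  stopifnot(inherits(cube, "hypercube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- dim(cube$values)[3L]
  for (k in seq_len(b)) {
    tiff::writeTIFF(cube$values[, , k],
                    file.path(dir, sprintf("band_%03d.tif", k - 1L)),
                    bits.per.sample = 16L)
  }
  utils::write.csv(
    data.frame(band_index = seq_len(b) - 1L,
               wavelength_nm = cube$wavelength_nm),
    file.path(dir, "wavelengths.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cube_dir
#' @export
read_cube_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^band_[0-9]+\\.(tif|tiff|png)$",
                           full.names = TRUE))
  if (length(paths) == 0L)
    stop(sprintf("no band_NNN images found in '%s'", dir), call. = FALSE)
  wl <- NULL
  wl_path <- file.path(dir, "wavelengths.csv")
  if (file.exists(wl_path))
    wl <- utils::read.csv(wl_path)$wavelength_nm
  stack_bands(paths, wavelength_nm = wl)
}
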