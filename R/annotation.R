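#' Labeled pixel annotation set
#'
#' Container for click-style pixel annotations: one record per annotated
#' pixel carrying its image id, 0-based column (`x`) and row (`y`)
#' coordinates, class code 0-3, and the pixel's full reflectance spectrum.
#' `(image_id, x, y)` triples are unique; all spectra share one band count.
#'
#' @param records data frame with columns `image_id`, `x`, `y`, `class`.
#' @param spectra numeric matrix, one row per record.
#' @param class_names named integer vector mapping class names to codes.
#' @param wavelength_nm optional wavelength grid for the spectral axis.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(records, spectra,
                           class_names = organ_classes()[1:4],
                           wavelength_nm = NULL) {
  stopifnot(is.data.frame(records),
            all(c("image_id", "x", "y", "class") %in% names(records)))
  if (nrow(records) != nrow(spectra))
    stop("`records` and `spectra` must have the same number of rows",
         call. = FALSE)
  if (nrow(records) > 0) {
    if (any(records$class < 0L | records$class > 3L))
      stop("class codes must be in {0, 1, 2, 3}", call. = FALSE)
    key <- paste(records$image_id, records$x, records$y)
    if (anyDuplicated(key))
      stop("duplicate (image_id, x, y) records", call. = FALSE)
  }
  structure(list(records = records, spectra = as.matrix(spectra),
                 class_names = class_names, wavelength_nm = wavelength_nm),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d records, %d bands, %d image(s)\n",
              nrow(x$records), ncol(x$spectra),
              length(unique(x$records$image_id))))
  if (nrow(x$records)) print(class_balance(x))
  invisible(x)
}

#' Number of records in an annotation set
#' @param set an [annotation_set].
#' @export
n_annotations <- function(set) nrow(set$records)

#' Convert click records to labeled spectra
#'
#' Turns a table of annotation clicks (as exported by crowdsourced
#' annotation platforms) into an [annotation_set] by reading each clicked
#' pixel's spectrum out of its source cube. Coordinates are 0-based with
#' `x` = column and `y` = row, row 0 at the top of the image; exports from
#' other tools may need converting first.
#'
#' Out-of-bounds clicks are skipped with a warning reporting the count;
#' duplicated `(image_id, x, y)` rows are deduplicated (first kept) with a
#' warning; an unrecognized class string is a hard error.
#'
#' @param click_rows data frame (or path to a CSV) with columns
#'   `image_id`, `x`, `y`, `class`; `class` may be a code 0-3 or a name in
#'   `class_names`.
#' @param cube_lookup named list mapping image ids to [hypercube] objects,
#'   or a function taking an id and returning a cube.
#' @param class_names named integer code mapping; "tassel" aliases to the
#'   panicle slot by default.
#' @return An [annotation_set].
#' @export
parse_click_records <- function(click_rows, cube_lookup,
                                class_names = organ_classes()) {
  if (is.character(click_rows) && length(click_rows) == 1L)
    click_rows <- utils::read.csv(click_rows)
  stopifnot(is.data.frame(click_rows))
  need <- c("image_id", "x", "y", "class")
  if (!all(need %in% names(click_rows)))
    stop("click records need columns image_id, x, y, class", call. = FALSE)
  get_cube <- if (is.function(cube_lookup)) cube_lookup else
    function(id) {
      cb <- cube_lookup[[id]]
      if (is.null(cb)) stop(sprintf("no cube for image id '%s'", id),
                            call. = FALSE)
      cb
    }

  if (nrow(click_rows) == 0L) {
    b <- if (is.function(cube_lookup) || length(cube_lookup) == 0L) 0L else
      dim(cube_lookup[[1L]]$values)[3L]
    return(annotation_set(
      data.frame(image_id = character(), x = integer(), y = integer(),
                 class = integer()),
      matrix(numeric(), 0L, b), class_names = class_names[1:4]))
  }

  cls <- click_rows$class
  if (is.character(cls) || is.factor(cls)) {
    cls <- as.character(cls)
    code <- unname(class_names[tolower(cls)])
    if (anyNA(code))
      stop(sprintf("unknown class label(s): %s",
                   paste(unique(cls[is.na(code)]), collapse = ", ")),
           call. = FALSE)
  } else {
    code <- as.integer(cls)
    if (any(code < 0L | code > 3L))
      stop("numeric class codes must be in {0, 1, 2, 3}", call. = FALSE)
  }
  df <- data.frame(image_id = as.character(click_rows$image_id),
                   x = as.integer(click_rows$x),
                   y = as.integer(click_rows$y), class = code)

  dup <- duplicated(paste(df$image_id, df$x, df$y))
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate (image_id, x, y) record(s)",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }

  ids <- unique(df$image_id)
  keep <- rep(TRUE, nrow(df))
  spectra <- vector("list", nrow(df))
  b <- NULL
  wl <- NULL
  for (id in ids) {
    cube <- get_cube(id)
    d <- dim(cube$values)
    if (is.null(b)) { b <- d[3L]; wl <- cube$wavelength_nm }
    rows <- which(df$image_id == id)
    for (r in rows) {
      i <- df$y[r] + 1L; j <- df$x[r] + 1L
      if (i < 1L || i > d[1L] || j < 1L || j > d[2L]) {
        keep[r] <- FALSE
      } else {
        spectra[[r]] <- cube$values[i, j, ]
      }
    }
  }
  if (any(!keep))
    warning(sprintf("skipped %d out-of-bounds click(s)", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  spec <- do.call(rbind, spectra[keep])
  if (is.null(spec)) spec <- matrix(numeric(), 0L, b)
  annotation_set(df, spec, class_names = class_names[1:4],
                 wavelength_nm = wl)
}

#' Per-class record counts
#'
#' @param set an [annotation_set].
#' @return Named integer vector of counts for the four class codes; entries
#'   sum to the total record count.
#' @export
class_balance <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  cnt <- tabulate(set$records$class + 1L, nbins = 4L)
  names(cnt) <- rownames(ORGAN_PALETTE)
  cnt
}

#' Write / read an annotation set as CSV
#'
#' Columns: `image_id,x,y,class_code,b0,b1,...` with one band column per
#' spectral band.
#'
#' @param set an [annotation_set].
#' @param path CSV file path.
#' @export
write_annotations_csv <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  spec <- set$spectra
  colnames(spec) <- sprintf("b%d", seq_len(ncol(spec)) - 1L)
  df <- cbind(set$records[, c("image_id", "x", "y")],
              class_code = set$records$class, spec)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path)
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  annotation_set(
    data.frame(image_id = as.character(df$image_id), x = df$x, y = df$y,
               class = df$class_code),
    as.matrix(df[, bcols, drop = FALSE]))
}
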