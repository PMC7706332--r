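#' Organ pixel counts from a segmentation map
#'
#' The three size traits are simple pixel counts of the leaf, stalk and
#' panicle classes.
#'
#' @param map a [segmentation_map].
#' @return Named numeric vector `c(leaf_size, stalk_size, panicle_size)`.
#' @export
organ_sizes <- function(map) {
  cnt <- class_counts(map)
  c(leaf_size = unname(cnt["leaf"]), stalk_size = unname(cnt["stalk"]),
    panicle_size = unname(cnt["panicle"]))
}

#' Organ size ratios
#'
#' Ratios are simple quotients of the organ pixel counts. A zero
#' denominator yields `NA` plus a missing-organ flag in batch mode; with
#' `strict = TRUE` it raises an error naming the missing organ (useful when
#' a vegetative plant with no panicle should halt a single-image analysis).
#'
#' @param sizes output of [organ_sizes()].
#' @param strict error on zero denominators instead of flagging.
#' @return A list with `ratios` (named vector `leaf_panicle_ratio`,
#'   `leaf_stalk_ratio`, `panicle_stalk_ratio`) and `missing` (names of
#'   organs with zero pixels).
#' @export
organ_ratios <- function(sizes, strict = FALSE) {
  leaf <- sizes[["leaf_size"]]; stalk <- sizes[["stalk_size"]]
  pan <- sizes[["panicle_size"]]
  missing <- character(0)
  if (pan == 0) missing <- c(missing, "panicle")
  if (stalk == 0) missing <- c(missing, "stalk")
  if (leaf == 0) missing <- c(missing, "leaf")
  if (strict && length(intersect(missing, c("panicle", "stalk"))))
    stop(sprintf("zero pixels for organ(s): %s",
                 paste(intersect(missing, c("panicle", "stalk")),
                       collapse = ", ")), call. = FALSE)
  rat <- c(leaf_panicle_ratio = if (pan > 0) leaf / pan else NA_real_,
           leaf_stalk_ratio = if (stalk > 0) leaf / stalk else NA_real_,
           panicle_stalk_ratio = if (stalk > 0 && pan > 0) pan / stalk
                                 else NA_real_)
  list(ratios = rat, missing = missing)
}

#' Plant height to the top of the panicle
#'
#' Euclidean distance between the stalk base pixel and the panicle apex
#' pixel. In raster coordinates (row 1 at the top of the image) the base is
#' the stalk pixel with the *maximum* row index (lowest point of the stalk)
#' and the apex the panicle pixel with the *minimum* row index (highest
#' point of the inflorescence); this is the "height to apex" definition of
#' plant height, measured bottom-of-stalk to top-of-panicle. Note that
#' under a mathematical y-up axis the base is the smallest-y stalk pixel —
#' descriptions of this trait vary in their axis convention, so the
#' orientation used here is fixed and documented. Ties on the extreme row
#' break to the smallest column index.
#'
#' @param map a [segmentation_map].
#' @param pixel_size_mm optional pixel edge length; when given the distance
#'   is returned in millimetres instead of pixels.
#' @param strict error (rather than `NA`) when the stalk or panicle is
#'   absent.
#' @return Height as a single number (pixels or mm), or `NA` when an organ
#'   is missing and `strict = FALSE`.
#' @export
height_to_apex <- function(map, pixel_size_mm = NULL, strict = FALSE) {
  m <- unclass(map)
  stalk <- which(m == 2L, arr.ind = TRUE)
  pan <- which(m == 3L, arr.ind = TRUE)
  if (nrow(stalk) == 0L || nrow(pan) == 0L) {
    msg <- paste(c("stalk", "panicle")[c(nrow(stalk) == 0L,
                                         nrow(pan) == 0L)],
                 collapse = " and ")
    if (strict)
      stop(sprintf("cannot measure height: no %s pixels", msg),
           call. = FALSE)
    return(NA_real_)
  }
  base_row <- max(stalk[, 1L])
  base_col <- min(stalk[stalk[, 1L] == base_row, 2L])
  apex_row <- min(pan[, 1L])
  apex_col <- min(pan[pan[, 1L] == apex_row, 2L])
  d <- sqrt((base_row - apex_row)^2 + (base_col - apex_col)^2)
  if (!is.null(pixel_size_mm)) d <- d * pixel_size_mm
  d
}

#' Build the seven-trait phenotype table
#'
#' One row per line/image with the seven organ-level traits: three pixel
#' counts (`leaf_size`, `stalk_size`, `panicle_size`), three ratios
#' (`leaf_panicle_ratio`, `leaf_stalk_ratio`, `panicle_stalk_ratio`) and
#' `height_to_apex`. Plants with a missing organ get `NA` ratios/height and
#' a flag rather than an error, since incomplete (e.g. pre-reproductive)
#' plants occur in real populations and are handled by exclusion.
#'
#' @param maps named list of [segmentation_map] objects (names = line ids),
#'   or unnamed with `line_ids` supplied.
#' @param line_ids optional character vector of ids, one per map.
#' @param exclude character vector of line ids to drop (e.g. lines that had
#'   not completed reproductive development).
#' @param pixel_size_mm optional pixel size passed to [height_to_apex()].
#' @return A data frame with one row per retained line: `line_id`, the
#'   seven traits, and a `flags` column listing missing organs
#'   (comma-separated, empty when complete).
#' @export
build_trait_table <- function(maps, line_ids = NULL, exclude = character(0),
                              pixel_size_mm = NULL) {
  if (inherits(maps, "segmentation_map")) maps <- list(maps)
  if (length(maps) == 0L) stop("need at least one map", call. = FALSE)
  if (is.null(line_ids))
    line_ids <- if (!is.null(names(maps))) names(maps) else
      sprintf("line_%04d", seq_along(maps))
  if (anyDuplicated(line_ids))
    stop("duplicate line ids", call. = FALSE)
  keep <- !(line_ids %in% exclude)
  maps <- maps[keep]; line_ids <- line_ids[keep]
  rows <- lapply(seq_along(maps), function(i) {
    s <- organ_sizes(maps[[i]])
    r <- organ_ratios(s)
    h <- height_to_apex(maps[[i]], pixel_size_mm = pixel_size_mm)
    data.frame(line_id = line_ids[i],
               leaf_size = s[["leaf_size"]],
               stalk_size = s[["stalk_size"]],
               panicle_size = s[["panicle_size"]],
               leaf_panicle_ratio = r$ratios[["leaf_panicle_ratio"]],
               leaf_stalk_ratio = r$ratios[["leaf_stalk_ratio"]],
               panicle_stalk_ratio = r$ratios[["panicle_stalk_ratio"]],
               height_to_apex = h,
               flags = paste(r$missing, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a trait table to CSV
#' @param traits a [build_trait_table()] data frame.
#' @param path output CSV path.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
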