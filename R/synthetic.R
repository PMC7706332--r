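#' Spectral signature library for the four organ classes
#'
#' Builds per-class mean reflectance curves and per-band noise standard
#' deviations over a linear wavelength grid. The curves are piecewise-smooth
#' (a logistic red-edge base plus Gaussian bumps and dips) and reproduce the
#' qualitative contrasts that per-pixel organ classifiers exploit in
#' shortwave hyperspectral data of grasses:
#'
#' * leaf and stalk are nearly identical in the visible range (546-700 nm)
#'   but separate strongly in the near infrared, with the leaf NIR plateau
#'   well above the stalk's (separation of at least 3 noise SDs somewhere in
#'   1100-1250 nm);
#' * panicle tracks the stalk curve over 750-1700 nm;
#' * all three plant classes show a water-absorption dip with a local
#'   reflectance minimum inside 1304-1466 nm that the (dry) background
#'   lacks.
#'
#' The seed perturbs the curves with a small smooth jitter so different
#' libraries are distinguishable while all invariants hold.
#'
#' @param n_bands number of spectral bands (>= 2); default 243.
#' @param wl_min_nm,wl_max_nm wavelength range; default 546-1700 nm.
#' @param seed integer RNG seed.
#' @return An object of class `"signature_library"`: a list with
#'   `class_names` (background, leaf, stalk, panicle), `mean_curve`
#'   (`B x 4` matrix, columns per class, values in `[0,1]`), `noise_sd`
#'   (`B x 4`, nonnegative) and `wavelength_nm`.
#' @export
make_signature_library <- function(n_bands = 243, wl_min_nm = 546,
                                   wl_max_nm = 1700, seed = 1) {
  if (length(n_bands) != 1L || is.na(n_bands) || n_bands < 2)
    stop("`n_bands` must be a single integer >= 2", call. = FALSE)
  wl <- band_wavelengths(n_bands, wl_min_nm, wl_max_nm)
  bump <- function(center, width, height) height * exp(-((wl - center) / width)^2)
  red_edge <- function(plateau) plateau / (1 + exp(-(wl - 730) / 14))

  # water absorption features shared by the plant classes; the 1400 nm dip is
  # the local minimum required inside 1304-1466 nm
  water <- function(depth) bump(1400, 55, depth) + bump(1190, 45, depth * 0.25)

  leaf <- 0.08 + bump(600, 60, 0.04) + red_edge(0.72) - water(0.38) -
    bump(1660, 60, 0.12)
  stalk <- 0.08 + bump(600, 60, 0.04) + red_edge(0.42) - water(0.22) -
    bump(1660, 60, 0.07) + bump(980, 300, 0.05)
  panicle <- 0.16 + bump(640, 90, 0.06) + red_edge(0.40) - water(0.22) -
    bump(1660, 60, 0.07) + bump(980, 300, 0.05)
  background <- 0.10 + 0.02 * (wl - wl[1]) / max(wl[length(wl)] - wl[1], 1)

  mean_curve <- cbind(background = background, leaf = leaf, stalk = stalk,
                      panicle = panicle)

  # smooth seeded jitter, small enough to leave every invariant intact
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  # background stays jitter-free (strictly monotone, hence no water dip)
  for (k in 2:4) {
    centers <- stats::runif(3, wl_min_nm, wl_max_nm)
    amps <- stats::runif(3, -0.008, 0.008)
    for (j in 1:3) mean_curve[, k] <- mean_curve[, k] +
        amps[j] * exp(-((wl - centers[j]) / 180)^2)
  }
  mean_curve <- pmin(pmax(mean_curve, 0), 1)

  noise_sd <- cbind(background = rep(0.015, n_bands),
                    leaf = rep(0.045, n_bands),
                    stalk = rep(0.045, n_bands),
                    panicle = rep(0.050, n_bands))

  structure(
    list(class_names = c("background", "leaf", "stalk", "panicle"),
         mean_curve = mean_curve, noise_sd = noise_sd, wavelength_nm = wl),
    class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("<signature_library> %d bands, %.0f-%.0f nm, classes: %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Stylized plant layout
#'
#' Geometry of a single synthetic plant on the image grid: a vertical stalk,
#' alternating leaves leaving the stalk at an angle, and an optional panicle
#' sitting on top of the stalk. `panicle_height = 0` gives a vegetative
#' plant with no panicle; `stalk_width = 0` with `leaf_count = 0` gives an
#' all-background image. Row 1 is the top of the image.
#'
#' Defaults mirror the imaging conditions this package emulates: a portrait
#' 560-row by 320-column frame and a stalk 5 px wide (sorghum stalks span
#' roughly 5-6 px at the zoom level of greenhouse line-scan systems).
#'
#' @param image_height,image_width frame size in pixels.
#' @param stalk_width stalk width in pixels (0 = no stalk).
#' @param stalk_top_row,stalk_base_row first and last stalk row (top < base).
#' @param leaf_count number of leaves.
#' @param leaf_angle leaf inclination from horizontal, degrees.
#' @param leaf_length leaf length in pixels.
#' @param leaf_width leaf thickness in pixels.
#' @param panicle_height,panicle_width panicle bounding box in pixels
#'   (height 0 = vegetative stage).
#' @return An object of class `"plant_layout"`.
#' @export
plant_layout <- function(image_height = 560, image_width = 320,
                         stalk_width = 5, stalk_top_row = 180,
                         stalk_base_row = 540, leaf_count = 6,
                         leaf_angle = 35, leaf_length = 90, leaf_width = 4,
                         panicle_height = 70, panicle_width = 26) {
  lay <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              stalk_width = as.integer(stalk_width),
              stalk_top_row = as.integer(stalk_top_row),
              stalk_base_row = as.integer(stalk_base_row),
              leaf_count = as.integer(leaf_count),
              leaf_angle = leaf_angle, leaf_length = leaf_length,
              leaf_width = as.integer(leaf_width),
              panicle_height = as.integer(panicle_height),
              panicle_width = as.integer(panicle_width))
  validate_layout(lay)
  structure(lay, class = "plant_layout")
}

validate_layout <- function(lay) {
  with(lay, {
    if (image_height < 1 || image_width < 1)
      stop("image dimensions must be positive", call. = FALSE)
    if (stalk_width < 0 || panicle_height < 0 || panicle_width < 0 ||
        leaf_count < 0)
      stop("layout sizes must be nonnegative", call. = FALSE)
    if (stalk_width > 0) {
      if (stalk_top_row < 1 || stalk_base_row > image_height ||
          stalk_top_row > stalk_base_row)
        stop("stalk does not fit inside the image", call. = FALSE)
      if (stalk_width > image_width)
        stop("stalk wider than the image", call. = FALSE)
      if (panicle_height > 0 && stalk_top_row - panicle_height < 1)
        stop("panicle extends above the image", call. = FALSE)
      if (panicle_width > image_width)
        stop("panicle wider than the image", call. = FALSE)
    }
  })
  invisible(lay)
}

#' Render a synthetic hyperspectral plant image
#'
#' Paints the layout onto the pixel grid (every pixel gets exactly one
#' class: leaves first, then stalk, then panicle on top) and draws each
#' pixel's spectrum as its class mean curve plus independent per-band
#' Gaussian noise, clipped to `[0, 1]`.
#'
#' @param layout a [plant_layout].
#' @param lib a [make_signature_library()] library; its band count defines
#'   the cube depth.
#' @param seed integer RNG seed.
#' @return A list with elements `cube` (a [hypercube]) and `map` (the exact
#'   ground-truth [segmentation_map]).
#' @export
render_plant_cube <- function(layout, lib, seed = 1) {
  stopifnot(inherits(layout, "plant_layout"),
            inherits(lib, "signature_library"))
  validate_layout(layout)
  map <- render_mask(layout)
  cube <- spectra_from_mask(map, lib, seed)
  list(cube = cube, map = map)
}

render_mask <- function(layout) {
  h <- layout$image_height; w <- layout$image_width
  m <- matrix(0L, h, w)
  if (layout$stalk_width > 0) {
    cx <- w %/% 2L
    half <- (layout$stalk_width - 1L) %/% 2L
    scols <- max(1L, cx - half):min(w, cx - half + layout$stalk_width - 1L)
    # leaves: alternating sides, attachment points spread along the stalk
    if (layout$leaf_count > 0) {
      att <- round(seq(layout$stalk_top_row + 10,
                       layout$stalk_base_row - 10,
                       length.out = layout$leaf_count))
      theta <- layout$leaf_angle * pi / 180
      for (i in seq_len(layout$leaf_count)) {
        side <- if (i %% 2 == 0) 1 else -1
        for (t in seq(0, layout$leaf_length, by = 0.5)) {
          r <- round(att[i] - t * sin(theta))
          cc <- round(cx + side * t * cos(theta))
          rows <- r:min(h, r + layout$leaf_width - 1L)
          rows <- rows[rows >= 1 & rows <= h]
          if (cc >= 1 && cc <= w && length(rows)) m[rows, cc] <- 1L
        }
      }
    }
    m[layout$stalk_top_row:layout$stalk_base_row, scols] <- 2L
    if (layout$panicle_height > 0 && layout$panicle_width > 0) {
      prow0 <- layout$stalk_top_row - layout$panicle_height
      prows <- prow0:(layout$stalk_top_row - 1L)
      phalf <- (layout$panicle_width - 1L) / 2
      pc <- (prow0 + layout$stalk_top_row - 1L) / 2
      for (r in prows) {
        # elliptical panicle outline
        frac <- sqrt(pmax(0, 1 - ((r - pc) / (layout$panicle_height / 2))^2))
        hw <- max(1L, round(phalf * frac))
        cols <- max(1L, layout$image_width %/% 2L - hw):
          min(w, layout$image_width %/% 2L + hw)
        m[r, cols] <- 3L
      }
    }
  }
  segmentation_map(m)
}

spectra_from_mask <- function(map, lib, seed = 1) {
  h <- nrow(map); w <- ncol(map); b <- nrow(lib$mean_curve)
  lv <- as.integer(t(unclass(map))) + 1L  # row-major pixel order
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  mu <- lib$mean_curve[, lv, drop = FALSE]          # B x N
  sdm <- lib$noise_sd[, lv, drop = FALSE]
  x <- mu + stats::rnorm(length(mu)) * sdm
  x <- pmin(pmax(x, 0), 1)
  values <- aperm(array(t(x), dim = c(w, h, b)), c(2L, 1L, 3L))
  hypercube(values, wavelength_nm = lib$wavelength_nm,
            provenance = "synthetic")
}

#' Sample click-style pixel annotations from ground-truth maps
#'
#' Emulates the crowdsourced annotation protocol: for each image, sample
#' `n_per_class` pixels uniformly without replacement from every class
#' present in its map, and record each pixel's full spectrum. Classes absent
#' from an image (e.g. the panicle of a vegetative plant) are skipped;
#' classes present with fewer than `n_per_class` pixels raise an error
#' naming the class.
#'
#' @param maps a [segmentation_map] or list of them.
#' @param cubes the matching [hypercube] or list of cubes.
#' @param n_per_class pixels to sample per class per image (default 10).
#' @param seed integer RNG seed.
#' @param image_ids optional character ids, one per image.
#' @return An [annotation_set].
#' @export
sample_annotations <- function(maps, cubes, n_per_class = 10, seed = 1,
                               image_ids = NULL) {
  if (inherits(maps, "segmentation_map")) maps <- list(maps)
  if (inherits(cubes, "hypercube")) cubes <- list(cubes)
  stopifnot(length(maps) == length(cubes))
  if (is.null(image_ids))
    image_ids <- sprintf("img_%03d", seq_along(maps))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  recs <- vector("list", length(maps))
  spectra <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- unclass(maps[[i]])
    feats <- flatten_cube(cubes[[i]])
    w <- ncol(m)
    rows_i <- list(); spec_i <- list()
    if (n_per_class > 0) {
      for (cls in 0:3) {
        idx <- which(t(m) == cls)  # row-major linear pixel indices
        if (length(idx) == 0L) next
        if (length(idx) < n_per_class)
          stop(sprintf(
            "image '%s': class '%s' has only %d pixels, need %d",
            image_ids[i], rownames(ORGAN_PALETTE)[cls + 1L], length(idx),
            n_per_class), call. = FALSE)
        take <- idx[sample.int(length(idx), n_per_class)]
        r <- (take - 1L) %/% w + 1L
        cc <- (take - 1L) %% w + 1L
        rows_i[[length(rows_i) + 1L]] <- data.frame(
          image_id = image_ids[i], x = cc - 1L, y = r - 1L, class = cls)
        spec_i[[length(spec_i) + 1L]] <- feats[take, , drop = FALSE]
      }
    }
    recs[[i]] <- if (length(rows_i)) do.call(rbind, rows_i) else NULL
    spectra[[i]] <- if (length(spec_i)) do.call(rbind, spec_i) else NULL
  }
  records <- do.call(rbind, recs)
  spec <- do.call(rbind, spectra)
  b <- dim(cubes[[1L]]$values)[3L]
  if (is.null(records)) {
    records <- data.frame(image_id = character(), x = integer(),
                          y = integer(), class = integer())
    spec <- matrix(numeric(), 0L, b)
  }
  annotation_set(records, spec, wavelength_nm = cubes[[1L]]$wavelength_nm)
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor allele frequency uniformly from `maf_range`, then
#' genotypes 0/1/2 across lines with heterozygote frequency
#' `2 p (1-p) (1-F)`, where `F` is the inbreeding coefficient: `F = 0`
#' (default) is random-mating Hardy-Weinberg, `F = 1` a fully inbred panel
#' with genotypes in `{0, 2}` only — the appropriate setting when emulating
#' a diversity panel of inbred lines. SNPs are independent (no linkage
#' disequilibrium) and spread across 10 chromosomes with increasing
#' positions.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5].
#' @param seed integer RNG seed.
#' @param inbreeding inbreeding coefficient `F` in `[0, 1]`.
#' @return A [genotype_matrix].
#' @export
simulate_genotypes <- function(n_lines, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1, inbreeding = 0) {
  if (inbreeding < 0 || inbreeding > 1)
    stop("`inbreeding` must lie in [0, 1]", call. = FALSE)
  if (n_lines < 2) stop("`n_lines` must be >= 2", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  p <- rep(maf, each = n_lines)
  # genotype frequencies with inbreeding: hom-alt p^2 + Fp(1-p),
  # het 2p(1-p)(1-F), hom-ref the rest
  u <- stats::runif(n_lines * n_snps)
  p2 <- p^2 + inbreeding * p * (1 - p)
  phet <- 2 * p * (1 - p) * (1 - inbreeding)
  g <- matrix(ifelse(u < p2, 2L, ifelse(u < p2 + phet, 1L, 0L)),
              nrow = n_lines, ncol = n_snps)
  chrom <- sort(rep(seq_len(10L), length.out = n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom),
                       function(i) seq_along(i) * 1000L), use.names = FALSE)
  genotype_matrix(g,
                  line_ids = sprintf("line_%04d", seq_len(n_lines)),
                  snp_meta = data.frame(
                    chrom = chrom, pos = pos,
                    id = sprintf("snp_%05d", seq_len(n_snps))))
}

#' Parameters of the additive genetic phenotype model
#'
#' @param h2 target narrow-sense heritability in `[0, 1]`.
#' @param n_causal number of causal SNPs.
#' @param effect_sizes optional numeric vector of causal effects (length
#'   `n_causal`); drawn standard normal if `NULL`.
#' @param seed integer RNG seed.
#' @return An object of class `"geno_pheno_sim"`.
#' @export
geno_pheno_sim <- function(h2 = 0.5, n_causal = 10, effect_sizes = NULL,
                           seed = 1) {
  if (length(h2) != 1L || is.na(h2) || h2 < 0 || h2 > 1)
    stop("`h2` must lie in [0, 1]", call. = FALSE)
  if (!is.null(effect_sizes) && length(effect_sizes) != n_causal)
    stop("`effect_sizes` must have length `n_causal`", call. = FALSE)
  structure(list(h2 = h2, n_causal = as.integer(n_causal),
                 effect_sizes = effect_sizes, seed = as.integer(seed)),
            class = "geno_pheno_sim")
}

#' Simulate phenotypes with a known additive architecture
#'
#' Draws `y = sum_c beta_c g_c + e`, with the environmental noise rescaled
#' so that the realized genetic variance fraction `var(g) / var(y)` equals
#' the target narrow-sense heritability exactly in-sample. `h2 = 1` returns
#' an exact linear function of the causal genotypes; `h2 = 0` returns pure
#' noise independent of the genotypes.
#'
#' @param G a [genotype_matrix].
#' @param sim a [geno_pheno_sim].
#' @return A list with `y` (phenotype vector), `causal_idx`, `effects`, and
#'   `genetic_values`.
#' @export
simulate_phenotype <- function(G, sim) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(sim, "geno_pheno_sim"))
  m <- ncol(G$values); n <- nrow(G$values)
  if (sim$n_causal > m)
    stop("`n_causal` exceeds the number of SNPs", call. = FALSE)
  old <- set_local_seed(sim$seed)
  on.exit(restore_seed(old), add = TRUE)
  causal <- sort(sample.int(m, sim$n_causal))
  beta <- if (is.null(sim$effect_sizes)) stats::rnorm(sim$n_causal) else
    sim$effect_sizes
  g <- as.numeric(G$values[, causal, drop = FALSE] %*% beta)
  e <- stats::rnorm(n)
  vg <- stats::var(g)
  if (sim$h2 == 0 || vg == 0) {
    y <- e
    g <- rep(0, n)
  } else if (sim$h2 == 1) {
    y <- g
  } else {
    # scale noise so the realized variance ratio hits h2 exactly
    e <- e - mean(e)
    e <- e * sqrt(vg * (1 - sim$h2) / (sim$h2 * stats::var(e)))
    y <- g + e
  }
  list(y = y, causal_idx = causal, effects = beta, genetic_values = g)
}

#' Simulate a population of plant images with genetically controlled traits
#'
#' Links causal SNPs to layout parameters (e.g. `panicle_height`,
#' `stalk_base_row`) so that each line's ground-truth organ geometry is an
#' additive function of its genotypes plus Gaussian noise, then renders a
#' cube and ground-truth map per line. This enables end-to-end tests that
#' run segmentation, trait extraction and association scans against a known
#' causal architecture.
#'
#' @param G a [genotype_matrix].
#' @param trait_links data frame with columns `snp` (column index into `G`),
#'   `parameter` (a [plant_layout] field name) and `effect` (change in the
#'   parameter per alternate allele).
#' @param lib a signature library.
#' @param base_layout the layout all lines share before genetic effects.
#' @param layout_noise_sd SD of per-line Gaussian noise added to each linked
#'   parameter (pixels).
#' @param seed integer RNG seed.
#' @return A list with one element per line: `list(line_id, cube, map)`.
#' @export
simulate_population_images <- function(G, trait_links, lib,
                                       base_layout = plant_layout(),
                                       layout_noise_sd = 1, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (any(trait_links$snp < 1 | trait_links$snp > ncol(G$values)))
    stop("`trait_links` references a nonexistent SNP", call. = FALSE)
  bad <- setdiff(trait_links$parameter, names(unclass(base_layout)))
  if (length(bad))
    stop(sprintf("unknown layout parameter(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(G$values)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lay <- unclass(base_layout)
    for (j in seq_len(nrow(trait_links))) {
      p <- trait_links$parameter[j]
      lay[[p]] <- lay[[p]] + trait_links$effect[j] *
        G$values[i, trait_links$snp[j]] + stats::rnorm(1, 0, layout_noise_sd)
    }
    int_fields <- c("image_height", "image_width", "stalk_width",
                    "stalk_top_row", "stalk_base_row", "leaf_count",
                    "leaf_width", "panicle_height", "panicle_width")
    for (p in int_fields) lay[[p]] <- max(0L, as.integer(round(lay[[p]])))
    lay_obj <- do.call(plant_layout, lay)
    rendered <- render_plant_cube(lay_obj, lib,
                                  seed = stats::runif(1) * 1e8)
    out[[i]] <- list(line_id = G$line_ids[i], cube = rendered$cube,
                     map = rendered$map)
  }
  out
}

# seed helpers: scope a seed to one generator call, restoring global state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
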