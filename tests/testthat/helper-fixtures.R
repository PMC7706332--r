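# Shared small fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_lib <- function() fixture("small_lib", function()
  make_signature_library(n_bands = 40, seed = 2))

small_layout <- function() plant_layout(
  image_height = 120, image_width = 84, stalk_top_row = 40,
  stalk_base_row = 110, stalk_width = 5, leaf_count = 4,
  leaf_length = 25, panicle_height = 18, panicle_width = 16)

# eight rendered plants sharing one layout, for classifier tests
small_population <- function() fixture("small_population", function() {
  lib <- small_lib()
  lay <- small_layout()
  lapply(1:8, function(i) render_plant_cube(lay, lib, seed = i))
})

small_annotations <- function() fixture("small_annotations", function() {
  pop <- small_population()
  sample_annotations(lapply(pop, `[[`, "map"),
                     lapply(pop, `[[`, "cube"),
                     n_per_class = 10, seed = 5)
})

# tiny cube with distinctive values for index arithmetic checks
tiny_cube <- function(h = 4, w = 3, b = 2) {
  vals <- array(seq_len(h * w * b), dim = c(h, w, b)) / (h * w * b)
  hypercube(vals, wavelength_nm = seq(546, 1700, length.out = b))
}

random_map <- function(h, w, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  m <- matrix(sample(0:3, h * w, replace = TRUE), h, w)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  segmentation_map(m)
}
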