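#' Pipeline configuration
#'
#' Collects the paths, seeds and parameters the staged pipeline needs.
#' Every stage reads and writes plain-text artifacts (CSV, PNG/TIFF band
#' directories) under `out_dir` and records a JSON manifest with the
#' configuration, seed and input checksums, sufficient to re-run the stage.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed master integer seed.
#' @param n_lines,n_snps,n_causal,h2 synthetic population settings.
#' @param n_images images to simulate for classifier training.
#' @param n_bands spectral bands for synthetic cubes.
#' @param image_height,image_width synthetic frame size.
#' @param n_per_class annotation clicks per class per image.
#' @param classifier a [classifier_spec] (default LDA).
#' @param k_folds cross-validation folds.
#' @param exclude line ids excluded from the trait table.
#' @param alpha,maf_min,het_max,n_pcs,window_bp association-scan settings.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_lines = 40, n_snps = 200,
                            n_causal = 1, h2 = 0.8, n_images = 12,
                            n_bands = 40, image_height = 120,
                            image_width = 84, n_per_class = 10,
                            classifier = classifier_spec("LDA"),
                            k_folds = 5, exclude = character(0),
                            alpha = 0.05, maf_min = 0.01, het_max = 0.05,
                            n_pcs = 5, window_bp = 50000) {
  structure(as.list(environment()), class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "annotate", "train", "crossval", "segment",
                     "traits", "heritability", "gwas", "report")

#' Run one pipeline stage
#'
#' Orchestrates the package's analysis stages over on-disk artifacts:
#'
#' * `simulate` — genotype matrix, signature library and a genetically
#'   controlled image population (panicle height linked to the causal SNP);
#' * `annotate` — click-style annotations sampled from ground-truth masks;
#' * `train` / `crossval` — classifier fitting and image-level k-fold CV;
#' * `segment` — whole-image segmentation of every simulated cube;
#' * `traits` — the seven-trait table from the segmentation maps;
#' * `heritability` — kinship and REML PVE per trait;
#' * `gwas` — filtered single-marker scan with PC covariates and kinship;
#' * `report` — collects the stage outputs into one summary CSV set.
#'
#' Stages assume their predecessors have run (a missing artifact raises an
#' error naming it). Each stage writes `<stage>_manifest.json` recording
#' the stage, seed, configuration and md5 checksums of inputs consumed.
#'
#' @param name stage name, one of `simulate`, `annotate`, `train`,
#'   `crossval`, `segment`, `traits`, `heritability`, `gwas`, `report`.
#' @param config a [pipeline_config].
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (paths written).
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!name %in% PIPELINE_STAGES)
    stop(sprintf("unknown stage '%s'; stages are: %s", name,
                 paste(PIPELINE_STAGES, collapse = ", ")), call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- switch(name,
    simulate = stage_simulate(config),
    annotate = stage_annotate(config),
    train = stage_train(config),
    crossval = stage_crossval(config),
    segment = stage_segment(config),
    traits = stage_traits(config),
    heritability = stage_heritability(config),
    gwas = stage_gwas(config),
    report = stage_report(config))
  invisible(list(status = 0L, artifacts = art))
}

#' Run every pipeline stage in order
#' @param config a [pipeline_config].
#' @return Invisibly, the list of per-stage results.
#' @export
run_pipeline <- function(config) {
  invisible(lapply(PIPELINE_STAGES, run_stage, config = config))
}

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing input artifact '%s'; run the '%s' stage first",
                 path, producer), call. = FALSE)
  path
}

write_manifest <- function(config, stage, inputs = character(0)) {
  # directories contribute every file they contain
  inputs <- unlist(lapply(inputs, function(p)
    if (dir.exists(p)) list.files(p, recursive = TRUE, full.names = TRUE)
    else p))
  if (is.null(inputs)) inputs <- character(0)
  cfg <- unclass(config)
  cfg$classifier <- unclass(cfg$classifier)
  manifest <- list(stage = stage, seed = config$seed,
                   config = cfg,
                   input_md5 = as.list(tools::md5sum(inputs)),
                   written = format(Sys.time(), tz = "UTC"))
  path <- file.path(config$out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

stage_paths <- function(config) {
  o <- config$out_dir
  list(geno = file.path(o, "genotypes.csv"),
       map = file.path(o, "snp_map.csv"),
       pheno_truth = file.path(o, "causal_truth.csv"),
       cube_dir = file.path(o, "cubes"),
       mask_dir = file.path(o, "masks"),
       ann = file.path(o, "annotations.csv"),
       model = file.path(o, "model.rds.csv"),
       cv = file.path(o, "crossval_accuracy.csv"),
       seg_dir = file.path(o, "segmented"),
       counts = file.path(o, "class_counts.csv"),
       traits = file.path(o, "traits.csv"),
       herit = file.path(o, "heritability.csv"),
       gwas = file.path(o, "gwas_results.csv"),
       report = file.path(o, "report_summary.csv"))
}

# in-memory cache for objects too large to re-read cheaply (models, cubes);
# keyed by out_dir so concurrent configs do not collide
pipeline_cache <- new.env(parent = emptyenv())

cache_key <- function(config, what) paste0(config$out_dir, ":", what)

stage_simulate <- function(config) {
  p <- stage_paths(config)
  # inbred panel (F = 1): diversity panels of selfing crops are nearly
  # fully homozygous, which is what the heterozygosity QC filter assumes
  G <- simulate_genotypes(config$n_lines, config$n_snps,
                          seed = config$seed, inbreeding = 1)
  write_genotypes_csv(G, p$geno, p$map)
  lib <- make_signature_library(n_bands = config$n_bands,
                                seed = config$seed)
  base <- plant_layout(image_height = config$image_height,
                       image_width = config$image_width,
                       stalk_top_row = round(config$image_height * 0.35),
                       stalk_base_row = round(config$image_height * 0.92),
                       stalk_width = 5, leaf_count = 4,
                       leaf_length = round(config$image_width * 0.3),
                       panicle_height = round(config$image_height * 0.15),
                       panicle_width = round(config$image_width * 0.2))
  sim <- simulate_phenotype(G, geno_pheno_sim(h2 = config$h2,
                                              n_causal = config$n_causal,
                                              seed = config$seed))
  links <- data.frame(snp = sim$causal_idx, parameter = "panicle_height",
                      effect = 4)
  pop <- simulate_population_images(G, links, lib, base_layout = base,
                                    seed = config$seed)
  dir.create(p$cube_dir, showWarnings = FALSE)
  dir.create(p$mask_dir, showWarnings = FALSE)
  for (entry in pop) {
    write_cube_dir(entry$cube, file.path(p$cube_dir, entry$line_id))
    write_mask_png(entry$map,
                   file.path(p$mask_dir, paste0(entry$line_id, ".png")))
  }
  utils::write.csv(data.frame(snp = sim$causal_idx, effect = sim$effects),
                   p$pheno_truth, row.names = FALSE)
  assign(cache_key(config, "lib"), lib, envir = pipeline_cache)
  c(p$geno, p$map, p$cube_dir, p$mask_dir, p$pheno_truth,
    write_manifest(config, "simulate"))
}

read_population <- function(config) {
  p <- stage_paths(config)
  need_artifact(p$cube_dir, "simulate")
  ids <- sort(list.dirs(p$cube_dir, recursive = FALSE, full.names = FALSE))
  lapply(ids, function(id) list(
    line_id = id,
    cube = read_cube_dir(file.path(p$cube_dir, id)),
    map = read_mask_png(file.path(p$mask_dir, paste0(id, ".png")))))
}

stage_annotate <- function(config) {
  p <- stage_paths(config)
  pop <- read_population(config)
  n <- min(config$n_images, length(pop))
  maps <- lapply(pop[seq_len(n)], `[[`, "map")
  cubes <- lapply(pop[seq_len(n)], `[[`, "cube")
  ann <- sample_annotations(maps, cubes, n_per_class = config$n_per_class,
                            seed = config$seed,
                            image_ids = vapply(pop[seq_len(n)], `[[`, "",
                                               "line_id"))
  write_annotations_csv(ann, p$ann)
  c(p$ann, write_manifest(config, "annotate", p$cube_dir))
}

stage_train <- function(config) {
  p <- stage_paths(config)
  ann <- read_annotations_csv(need_artifact(p$ann, "annotate"))
  model <- train_classifier(config$classifier, ann)
  assign(cache_key(config, "model"), model, envir = pipeline_cache)
  # persist a text summary; the fitted object itself lives in the cache
  utils::write.csv(data.frame(family = model$spec$family,
                              n_bands = model$n_bands,
                              classes = paste(model$classes,
                                              collapse = " ")),
                   p$model, row.names = FALSE)
  c(p$model, write_manifest(config, "train", p$ann))
}

stage_crossval <- function(config) {
  p <- stage_paths(config)
  ann <- read_annotations_csv(need_artifact(p$ann, "annotate"))
  n_img <- length(unique(ann$records$image_id))
  if (config$k_folds > n_img)
    stop(sprintf("k_folds = %d exceeds the %d annotated images",
                 config$k_folds, n_img), call. = FALSE)
  cv <- crossvalidate(config$classifier, ann, k = config$k_folds,
                      seed = config$seed)
  utils::write.csv(as.data.frame(cv$accuracy), p$cv, row.names = FALSE)
  c(p$cv, write_manifest(config, "crossval", p$ann))
}

get_model <- function(config) {
  key <- cache_key(config, "model")
  if (!exists(key, envir = pipeline_cache)) {
    need_artifact(stage_paths(config)$model, "train")
    stage_train(config)
  }
  get(key, envir = pipeline_cache)
}

stage_segment <- function(config) {
  p <- stage_paths(config)
  pop <- read_population(config)
  model <- get_model(config)
  dir.create(p$seg_dir, showWarnings = FALSE)
  counts <- lapply(pop, function(entry) {
    seg <- segment_image(model, entry$cube)
    write_mask_png(seg, file.path(p$seg_dir,
                                  paste0(entry$line_id, ".png")))
    data.frame(line_id = entry$line_id, t(class_counts(seg)))
  })
  utils::write.csv(do.call(rbind, counts), p$counts, row.names = FALSE)
  c(p$seg_dir, p$counts, write_manifest(config, "segment", p$cube_dir))
}

stage_traits <- function(config) {
  p <- stage_paths(config)
  need_artifact(p$seg_dir, "segment")
  files <- sort(list.files(p$seg_dir, pattern = "\\.png$",
                           full.names = TRUE))
  maps <- lapply(files, read_mask_png)
  ids <- sub("\\.png$", "", basename(files))
  tt <- build_trait_table(maps, line_ids = ids, exclude = config$exclude)
  write_trait_table(tt, p$traits)
  c(p$traits, write_manifest(config, "traits", files))
}

trait_columns <- function() c("leaf_size", "stalk_size", "panicle_size",
                              "leaf_panicle_ratio", "leaf_stalk_ratio",
                              "panicle_stalk_ratio", "height_to_apex")

stage_heritability <- function(config) {
  p <- stage_paths(config)
  tt <- utils::read.csv(need_artifact(p$traits, "traits"))
  G <- read_genotypes_csv(need_artifact(p$geno, "simulate"), p$map)
  keep <- match(tt$line_id, G$line_ids)
  Gs <- genotype_matrix(G$values[keep, , drop = FALSE],
                        G$line_ids[keep], G$snp_meta)
  Gs <- filter_snps(Gs, maf_min = config$maf_min,
                    het_max = config$het_max)$genotypes
  K <- kinship_matrix(Gs)
  rows <- lapply(trait_columns(), function(tr) {
    y <- tt[[tr]]
    ok <- !is.na(y)
    if (sum(ok) < 10 || stats::sd(y[ok]) == 0)
      return(data.frame(trait = tr, pve = NA_real_,
                        genetic_var = NA_real_, residual_var = NA_real_))
    vc <- estimate_pve(y[ok], K[ok, ok, drop = FALSE])
    data.frame(trait = tr, pve = vc$pve, genetic_var = vc$genetic_var,
               residual_var = vc$residual_var)
  })
  utils::write.csv(do.call(rbind, rows), p$herit, row.names = FALSE)
  c(p$herit, write_manifest(config, "heritability", c(p$traits, p$geno)))
}

stage_gwas <- function(config) {
  p <- stage_paths(config)
  tt <- utils::read.csv(need_artifact(p$traits, "traits"))
  G <- read_genotypes_csv(need_artifact(p$geno, "simulate"), p$map)
  keep <- match(tt$line_id, G$line_ids)
  Gs <- genotype_matrix(G$values[keep, , drop = FALSE],
                        G$line_ids[keep], G$snp_meta)
  flt <- filter_snps(Gs, maf_min = config$maf_min,
                     het_max = config$het_max)
  K <- kinship_matrix(flt$genotypes)
  pcs <- population_pcs(flt$genotypes,
                        n_components = min(config$n_pcs,
                                           nrow(tt) - 2L))
  y <- tt$panicle_size
  res <- gwas_scan(y, flt$genotypes, covariates = pcs, K = K,
                   alpha = config$alpha)
  utils::write.csv(as.data.frame(res), p$gwas, row.names = FALSE)
  c(p$gwas, write_manifest(config, "gwas", c(p$traits, p$geno)))
}

stage_report <- function(config) {
  p <- stage_paths(config)
  cv <- utils::read.csv(need_artifact(p$cv, "crossval"))
  herit <- utils::read.csv(need_artifact(p$herit, "heritability"))
  gwas <- utils::read.csv(need_artifact(p$gwas, "gwas"))
  top <- gwas[which.min(gwas$p), ]
  summary <- data.frame(
    metric = c("cv_average_accuracy", "panicle_size_pve",
               "top_snp", "top_snp_p", "n_significant"),
    value = c(cv$average, herit$pve[herit$trait == "panicle_size"],
              top$snp_id, top$p, sum(gwas$significant)))
  utils::write.csv(summary, p$report, row.names = FALSE)
  c(p$report, write_manifest(config, "report", c(p$cv, p$herit, p$gwas)))
}
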