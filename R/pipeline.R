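#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]. Any
#' section can be overridden by a named list; omitted entries keep their
#' defaults. The same structure can be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param seed Global integer seed; per-stage child seeds are derived from
#'   it (see [stage_seed()]) so stages are independently reproducible.
#' @param out_dir Output directory for all artifacts.
#' @param simulate List: `scene` (arguments to [make_scene()]), `optical`
#'   (arguments to [optical_model()]), `pc` (arguments to [pc_model()]),
#'   `dose` (photoconversion dose, mJ/mm^2), `n_dark_frames`.
#' @param corrections List: `per_hemisphere_rho`.
#' @param segmentation List: `source` ("ground_truth", "builtin" or
#'   "external"), `external_mask` (label-TIFF path when source is
#'   "external"), `min_area`, `threshold_quantile`, `smooth_sigma`,
#'   `max_match_dist` (um, for region assignment of non-ground-truth masks).
#' @param slab List: arguments to [slab_scheme()] (used by the builtin
#'   segmentation source).
#' @param rgr List: `variant` ("standard" or "paired").
#' @param metrics List: `dprime_groups` (two region labels), `dose`
#'   (arguments to [light_dose()]), `decay` (arguments to
#'   [simulate_decay_cohort()], or NULL to skip the decay-fit demo).
#' @param stats List: `compare` (two region labels), `tests` (subset of
#'   "ranksum", "t2").
#' @return Object of class `campari_config` (a nested list).
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("campariq_run_"),
                            simulate = list(), corrections = list(),
                            segmentation = list(), slab = list(),
                            rgr = list(), metrics = list(), stats = list()) {
  defaults <- list(
    seed = seed, out_dir = out_dir,
    simulate = list(scene = list(), optical = list(), pc = list(),
                    dose = 300, n_dark_frames = 5),
    corrections = list(per_hemisphere_rho = FALSE),
    segmentation = list(source = "ground_truth", external_mask = NULL,
                        min_area = 10, threshold_quantile = 0.5,
                        smooth_sigma = 1, max_match_dist = 9),
    slab = list(group_size = 3, skip = 2),
    rgr = list(variant = "standard"),
    metrics = list(dprime_groups = c("V1", "S1"),
                   dose = list(power = 200, aperture_diameter = 6.5,
                               cycle_duration = 1, n_cycles = 50),
                   decay = list(n_cells = 73)),
    stats = list(compare = c("V1", "S1"), tests = c("ranksum", "t2"))
  )
  cfg <- defaults
  for (sec in c("simulate", "corrections", "segmentation", "slab", "rgr",
                "metrics", "stats")) {
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], get(sec))
  }
  if (!cfg$segmentation$source %in% c("ground_truth", "builtin", "external"))
    stop("segmentation source must be ground_truth, builtin or external")
  if (cfg$segmentation$source == "external" &&
      is.null(cfg$segmentation$external_mask))
    stop("external segmentation source requires external_mask")
  structure(cfg, class = "campari_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `campari_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("seed", "out_dir", "simulate",
                                  "corrections", "segmentation", "slab",
                                  "rgr", "metrics", "stats"))]
  do.call(pipeline_config, args)
}

#' Derive a per-stage child seed from the global seed
#'
#' Deterministic fan-out so each stage has its own stream yet the whole run
#' is reproducible from one integer: `(seed * 131 + index * 7919) mod
#' (2^31 - 1)`, where `index` is the 1-based position of the stage in
#' simulate, correct, segment, rgr, metrics, stats.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (see above) or integer index.
#' @return Integer child seed.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "correct", "segment", "rgr", "metrics", "stats")
  idx <- if (is.numeric(stage)) as.integer(stage) else match(stage, stages)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 131 + idx * 7919) %% 2147483647)
}

#' Run the full snapshot-quantification pipeline
#'
#' Executes the six stages -- simulate, correct, segment, rgr, metrics,
#' stats -- on a synthetic scene and writes every artifact plus a manifest
#' to the output directory. Re-running with an identical configuration and
#' seed reproduces byte-identical tables.
#'
#' Stage outputs: `pre_*`/`post_*` TIFF stacks and `ground_truth.csv`
#' (simulate); `corrections.json` and `qc_cells.csv` (correct);
#' `cell_fluor.csv` (segment); `rgr_table.csv` (rgr); `region_summary.csv`
#' and `metrics.json` (metrics); `stats.csv` (stats); `manifest.json`.
#'
#' @param config A `campari_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each stage and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "campari_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "campariq",
                   version = as.character(utils::packageVersion("campariq")),
                   seed = config$seed, config = unclass(config),
                   stages = list())
  note <- function(stage, params, outputs) {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(stage = stage, seed = stage_seed(config$seed, stage),
           params = params, outputs = outputs)
  }

  ## stage 1: simulate ----------------------------------------------------
  s1 <- stage_seed(config$seed, "simulate")
  scene <- do.call(make_scene, c(config$simulate$scene, list(seed = s1)))
  optical <- do.call(optical_model, config$simulate$optical)
  pc <- do.call(pc_model, config$simulate$pc)
  pre <- render_scene(scene, optical, pc, phase = "pre", seed = s1 + 1L)
  post <- render_scene(scene, optical, pc, dose = config$simulate$dose,
                       phase = "post", seed = s1 + 2L)
  write_image_stack(pre, file.path(out, "pre"))
  write_image_stack(post, file.path(out, "post"))
  write_ground_truth(post, file.path(out, "ground_truth.csv"))
  note("simulate",
       list(dose = config$simulate$dose, n_cells = nrow(scene$cells)),
       c("pre_*", "post_*", "ground_truth.csv"))

  ## stage 2: correct -----------------------------------------------------
  s2 <- stage_seed(config$seed, "correct")
  set.seed(s2)
  nf <- config$simulate$n_dark_frames
  dims <- scene$dim[1:2]
  dark_g_frames <- array(stats::rnorm(prod(dims) * nf, optical$dark_green,
                                      optical$read_noise_sd),
                         c(dims, nf))
  dark_r_frames <- array(stats::rnorm(prod(dims) * nf, optical$dark_red,
                                      optical$read_noise_sd),
                         c(dims, nf))
  darks <- estimate_dark_current(dark_g_frames, dark_r_frames)
  pre_cells <- extract_cell_fluorescence(pre$mask, pre$green, pre$red,
                                         expected_ids = scene$cells$cell_id)
  params <- estimate_corrections(
    pre_cells$mean_green, pre_cells$mean_red,
    hemisphere = rep(scene$hemisphere, nrow(pre_cells)),
    dark_green = darks$dark_green, dark_red = darks$dark_red,
    per_hemisphere_rho = config$corrections$per_hemisphere_rho)
  jsonlite::write_json(
    list(dark_green = params$dark_green, dark_red = params$dark_red,
         rho = as.list(params$rho),
         beta = as.list(params$beta), clamped = params$clamped,
         n_cells = params$n, outlier_cells = params$outliers$index),
    file.path(out, "corrections.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  note("correct",
       list(per_hemisphere_rho = config$corrections$per_hemisphere_rho),
       "corrections.json")

  ## stage 3: segment -----------------------------------------------------
  seg <- config$segmentation
  provenance <- switch(seg$source, ground_truth = "ground_truth",
                       builtin = "builtin", external = "imported")
  if (seg$source == "ground_truth") {
    mask <- post$mask
  } else if (seg$source == "external") {
    mask <- read_label_tiff(seg$external_mask)
    if (!all(dim(mask) == dim(post$mask)))
      stop("external mask geometry does not match the stack")
  } else {
    mask <- builtin_mask_3d(post, config$slab, seg)
  }
  cell_tbl <- extract_cells_3d(mask, post, scene, seg)
  pre_tbl <- extract_cells_3d(mask, pre, scene, seg)
  utils::write.csv(cell_tbl, file.path(out, "cell_fluor.csv"),
                   row.names = FALSE)
  note("segment", list(source = seg$source, provenance = provenance),
       "cell_fluor.csv")

  ## stage 4: rgr ---------------------------------------------------------
  corr_post <- apply_corrections(cell_tbl$mean_green, cell_tbl$mean_red,
                                 params, cell_tbl$hemisphere)
  variant <- config$rgr$variant
  rgr_vals <- if (variant == "paired") {
    pre_match <- pre_tbl[match(cell_tbl$cell_id, pre_tbl$cell_id), ]
    # paired variant: pre-PC red subtraction subsumes the beta offset
    r_pre <- pre_match$mean_red - params$dark_red -
      params$rho[1] * (pre_match$mean_green - params$dark_green)
    r_post <- cell_tbl$mean_red - params$dark_red -
      params$rho[1] * corr_post$g_corr
    compute_rgr(corr_post$g_corr, r_post, r_pre = r_pre, variant = "paired")
  } else {
    compute_rgr(corr_post$g_corr, corr_post$r_corr)
  }
  rgr_tbl <- data.frame(cell_id = cell_tbl$cell_id,
                        region = cell_tbl$region,
                        hemisphere = cell_tbl$hemisphere,
                        depth = cell_tbl$depth,
                        rgr = rgr_vals, variant = variant,
                        qc_pass = corr_post$qc_pass & !is.na(rgr_vals))
  utils::write.csv(rgr_tbl[rgr_tbl$qc_pass, !(names(rgr_tbl) == "qc_pass")],
                   file.path(out, "rgr_table.csv"), row.names = FALSE)
  utils::write.csv(rgr_tbl[!rgr_tbl$qc_pass, ],
                   file.path(out, "qc_cells.csv"), row.names = FALSE)
  note("rgr", list(variant = variant,
                   n_qc_failed = sum(!rgr_tbl$qc_pass)),
       c("rgr_table.csv", "qc_cells.csv"))

  ## stage 5: metrics -----------------------------------------------------
  s5 <- stage_seed(config$seed, "metrics")
  ok <- rgr_tbl[rgr_tbl$qc_pass, ]
  summary_tbl <- summarize_region(ok$rgr, ok$region)
  utils::write.csv(summary_tbl, file.path(out, "region_summary.csv"),
                   row.names = FALSE)
  dg <- config$metrics$dprime_groups
  dp <- if (sum(ok$region == dg[1], na.rm = TRUE) >= 2 &&
            sum(ok$region == dg[2], na.rm = TRUE) >= 2)
    dprime(ok$rgr[ok$region == dg[1]], ok$rgr[ok$region == dg[2]])
  else NA_real_
  dose_calc <- do.call(light_dose, config$metrics$dose)
  metrics_json <- list(dprime = list(groups = dg, value = dp),
                       light_dose = dose_calc)
  if (!is.null(config$metrics$decay)) {
    cohort <- do.call(simulate_decay_cohort,
                      c(config$metrics$decay, list(seed = s5)))
    med <- stats::aggregate(rgr_norm ~ day, cohort, stats::median)
    dfit <- fit_decay(med$day, med$rgr_norm)
    metrics_json$decay_fit <- list(half_life_days = dfit$half_life,
                                   half_life_se = dfit$half_life_se,
                                   r_squared = dfit$r_squared)
  }
  jsonlite::write_json(metrics_json, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("metrics", list(dprime_groups = dg), c("region_summary.csv",
                                              "metrics.json"))

  ## stage 6: stats -------------------------------------------------------
  cmp <- config$stats$compare
  stat_rows <- list()
  if (sum(ok$region == cmp[1], na.rm = TRUE) >= 2 &&
      sum(ok$region == cmp[2], na.rm = TRUE) >= 2) {
    va <- ok$rgr[ok$region == cmp[1]]
    vb <- ok$rgr[ok$region == cmp[2]]
    for (tst in config$stats$tests) {
      row <- compare_groups(va, vb, test = tst)
      row$group_a <- cmp[1]; row$group_b <- cmp[2]
      stat_rows[[length(stat_rows) + 1]] <- row
    }
  }
  depth_groups <- split(ok$rgr, ok$depth)
  depth_groups <- depth_groups[vapply(depth_groups, length, 1L) >= 2]
  if (length(depth_groups) >= 2) {
    row <- anova_oneway(depth_groups)
    row <- data.frame(test = "anova_depth", statistic = row$statistic,
                      p_value = row$p_value, n_a = NA, n_b = NA,
                      paired = FALSE, group_a = "depth", group_b = "depth")
    stat_rows[[length(stat_rows) + 1]] <- row
  }
  stats_tbl <- if (length(stat_rows)) do.call(rbind, stat_rows) else
    data.frame()
  utils::write.csv(stats_tbl, file.path(out, "stats.csv"), row.names = FALSE)
  note("stats", list(compare = cmp, tests = config$stats$tests), "stats.csv")

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(scene = scene, pre = pre, post = post,
                 corrections = params, cells = cell_tbl, rgr = rgr_tbl,
                 region_summary = summary_tbl, dprime = dp,
                 stats = stats_tbl, metrics = metrics_json,
                 manifest = manifest, out_dir = out))
}

# builtin segmentation over slab-averaged images, labels offset per slab;
# the flat acquisition background (dark current + autofluorescence) is
# removed with the slab's median before thresholding
builtin_mask_3d <- function(post, slab_cfg, seg) {
  scheme <- slab_scheme(group_size = slab_cfg$group_size,
                        skip = slab_cfg$skip, z_step = post$meta$z_step)
  total <- post$green + post$red
  sl <- slab_average(total, scheme)
  mask <- array(0L, dim(post$green))
  offset <- 0L
  for (k in seq_along(sl$depth)) {
    img <- sl$slabs[, , k]
    # robust background removal: median + 5 MAD of the slab
    img <- pmax(img - (stats::median(img) + 5 * stats::mad(img)), 0)
    lab <- segment_cells(img, min_area = seg$min_area,
                         threshold_quantile = seg$threshold_quantile,
                         smooth_sigma = seg$smooth_sigma)
    n <- max(lab)
    if (n > 0) {
      lab[lab > 0] <- lab[lab > 0] + offset
      for (s in sl$slices[[k]]) {
        page <- mask[, , s]
        page[lab > 0] <- lab[lab > 0]
        mask[, , s] <- page
      }
      offset <- offset + n
    }
  }
  attr(mask, "slab_depth") <- sl$depth
  attr(mask, "slab_slices") <- sl$slices
  mask
}

# extract per-cell means and attach region/hemisphere/depth labels
extract_cells_3d <- function(mask, stack, scene, seg) {
  tbl <- extract_cell_fluorescence(mask, stack$green, stack$red,
                                   min_area = seg$min_area)
  truth <- scene$cells
  if (identical(dim(mask), dim(stack$mask)) && all(mask == stack$mask)) {
    idx <- match(tbl$cell_id, truth$cell_id)
    tbl$region <- truth$region[idx]
    tbl$hemisphere <- truth$hemisphere[idx]
    tbl$depth <- truth$z[idx]
  } else {
    pairs <- match_cells_pre_post(mask, stack$mask,
                                  max_dist = seg$max_match_dist,
                                  pixel_size = scene$pixel_size,
                                  z_step = scene$z_step)
    idx <- match(tbl$cell_id, pairs$id_pre)
    truth_idx <- match(pairs$id_post[idx], truth$cell_id)
    tbl$region <- truth$region[truth_idx]
    tbl$hemisphere <- scene$hemisphere
    tbl$depth <- truth$z[truth_idx]
    tbl <- tbl[!is.na(tbl$region), , drop = FALSE]
  }
  tbl
}
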