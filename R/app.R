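# Pipeline orchestration: one call from slide images to grade maps, tumor
# tables, slide summaries and a reproducible run manifest.

#' Pipeline configuration
#'
#' Every pipeline constant surfaces as a named key with its standard default:
#' 224-px patches at 0.5022 um/px, half-patch inference stride, 5x5 modal
#' smoothing, the 10% overall-grade rule, 8-connectivity, and the IHC
#' exclusion filters (2000 um^2, 50 cells) with the p < 0.01 G-test level.
#'
#' @param model_path checkpoint path of a trained network (NULL to skip
#'   grading-dependent stages).
#' @param stride inference stride, px.
#' @param smooth_window modal smoothing window, px.
#' @param overall_grade_threshold area share for the overall-grade rule.
#' @param connectivity tumor connectivity (4 or 8).
#' @param min_tumor_area_um2,min_tumor_cells IHC exclusion filters.
#' @param g_test_alpha significance level of the staining G-test.
#' @param positivity_threshold positive-cell fraction calling a tumor
#'   stained.
#' @param microns_per_pixel slide resolution.
#' @param normalize_stains run Macenko normalization before grading.
#' @param out_dir output directory.
#' @param seed run seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(model_path = NULL, stride = NULL,
                            smooth_window = 5,
                            overall_grade_threshold = 0.10,
                            connectivity = 8,
                            min_tumor_area_um2 = 2000,
                            min_tumor_cells = 50,
                            g_test_alpha = 0.01,
                            positivity_threshold = 0.05,
                            microns_per_pixel = REFERENCE_MPP,
                            normalize_stains = TRUE,
                            out_dir = "luadgrader-out", seed = 1) {
  cfg <- list(model_path = model_path, stride = stride,
              smooth_window = smooth_window,
              overall_grade_threshold = overall_grade_threshold,
              connectivity = connectivity,
              min_tumor_area_um2 = min_tumor_area_um2,
              min_tumor_cells = min_tumor_cells,
              g_test_alpha = g_test_alpha,
              positivity_threshold = positivity_threshold,
              microns_per_pixel = microns_per_pixel,
              normalize_stains = normalize_stains,
              out_dir = out_dir, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (overall_grade_threshold <= 0 || overall_grade_threshold > 1)
      stop("overall_grade_threshold must be in (0, 1]")
    if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
    if (smooth_window < 1 || smooth_window %% 2 == 0)
      stop("smooth_window must be odd and >= 1")
    if (min_tumor_area_um2 < 0 || min_tumor_cells < 0)
      stop("exclusion filters must be nonnegative")
    if (g_test_alpha <= 0 || g_test_alpha >= 1)
      stop("g_test_alpha must be in (0, 1)")
  })
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the grading pipeline over a set of slides
#'
#' Per slide: optional stain normalization, whole-slide grading, tumor
#' segmentation and overall grading, per-tumor CSV, slide-summary CSV and
#' stacked-bar composition data. A JSON manifest records config hash, seed,
#' per-slide status and artifact paths. Unreadable slides are recorded as
#' failures and the run continues.
#'
#' @param slides character vector of image paths, or a list of in-memory
#'   `list(image = array, slide_id = chr)` entries.
#' @param config a [pipeline_config()] (`model_path` must point to a trained
#'   checkpoint).
#' @return The manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`. The manifest's `status` field is "ok" or
#'   "failed" per slide.
#' @export
run_pipeline <- function(slides, config) {
  validate_config(config)
  if (is.null(config$model_path)) stop("config$model_path is required")
  net <- load_network(config$model_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  entries <- list()
  for (i in seq_along(slides)) {
    sl <- slides[[i]]
    slide_id <- if (is.character(sl)) tools::file_path_sans_ext(basename(sl))
                else sl$slide_id
    t0 <- proc.time()[["elapsed"]]
    entry <- tryCatch({
      image <- if (is.character(sl)) read_rgb(sl) else sl$image
      if (config$normalize_stains)
        image <- tryCatch(normalize_to_reference(image),
                          error = function(e) image)  # blank slides pass through
      gm <- grade_slide(net, image, stride = config$stride,
                        smooth_window = config$smooth_window,
                        microns_per_pixel = config$microns_per_pixel)
      tumors <- segment_tumors(gm, connectivity = config$connectivity)
      summary <- slide_summary(gm, tumors)

      map_path <- file.path(config$out_dir, paste0(slide_id, "_grademap.png"))
      write_label_raster(gm, map_path)
      tumor_path <- file.path(config$out_dir, paste0(slide_id, "_tumors.csv"))
      tumor_table(tumors, tumor_path)
      comp_path <- file.path(config$out_dir,
                             paste0(slide_id, "_composition.csv"))
      comp <- tumor_table(tumors)[, c("tumor_id", "g1", "g2", "g3", "g4",
                                      "overall_grade")]
      write.csv(comp, comp_path, row.names = FALSE)
      summary_path <- file.path(config$out_dir,
                                paste0(slide_id, "_summary.csv"))
      write.csv(data.frame(
        slide_id = slide_id,
        tumor_count = summary$tumor_count_total,
        lung_area_um2 = summary$lung_area_um2,
        tumor_area_um2 = summary$tumor_area_um2,
        burden_fraction = summary$burden_fraction
      ), summary_path, row.names = FALSE)

      list(slide_id = slide_id, status = "ok",
           artifacts = list(grade_map = map_path, tumors = tumor_path,
                            composition = comp_path, summary = summary_path),
           tumor_count = summary$tumor_count_total,
           burden_fraction = summary$burden_fraction,
           elapsed_s = proc.time()[["elapsed"]] - t0)
    }, error = function(e) {
      list(slide_id = slide_id, status = "failed",
           error = conditionMessage(e),
           elapsed_s = proc.time()[["elapsed"]] - t0)
    })
    entries[[length(entries) + 1L]] <- entry
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("luadgrader")),
    model_version = net$version,
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    n_slides = length(slides),
    n_failed = sum(vapply(entries, function(e) e$status == "failed",
                          logical(1))),
    slides = entries
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# stable hash of the configuration (order-independent via sorted YAML text)
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config)[order(names(config))])
  # small polynomial hash over the serialized text; stable across sessions
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
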