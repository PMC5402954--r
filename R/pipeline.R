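#' Run configuration
#'
#' Bundles every knob of an end-to-end run: simulation, quantification and
#' statistics. Can be built in code or loaded from a YAML file.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed recorded in every output artifact.
#' @param cohort a [cohort_spec()].
#' @param mode cohort generation mode (see [generate_cohort()]).
#' @param image_size_px canvas side for images mode.
#' @param layers layers to simulate and analyse.
#' @param contrasts contrasts for the comparison report.
#' @param n_permutations Monte-Carlo permutations for the trend tests.
#' @param write_images also write the rendered angiograms (TIFF) and ground
#'   truth masks (PNG) in images mode.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = cohort_spec(),
                       mode = "metrics", image_size_px = 256,
                       layers = c("NS-RL", "SRL", "DRL"),
                       contrasts = c("BRVO vs control", "CRVO vs control",
                                     "RVO vs control", "RVO vs fellow",
                                     "fellow vs control"),
                       n_permutations = 0, write_images = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 mode = mode, image_size_px = image_size_px, layers = layers,
                 contrasts = contrasts, n_permutations = n_permutations,
                 write_images = write_images),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with (a subset of) the `run_config` fields;
#'   `cohort` sub-fields are passed to [cohort_spec()] and `pathology`
#'   entries to [pathology_spec()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort %||% list()
  if (!is.null(co$pathology))
    co$pathology <- lapply(co$pathology, function(p) do.call(pathology_spec, p))
  cohort <- do.call(cohort_spec, co)
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- cohort
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' simulate -> quantify -> analyse -> report. Writes four artifacts into
#' `config$out_dir`: `cohort_metrics.csv` (one row per eye x layer),
#' `comparisons.csv` (the group-comparison table), `trends.csv` (ordered
#' trend tests) and `manifest.json` (seed, configuration hash, package
#' version). Identical configuration and seed give byte-identical CSVs. Any
#' stage failure aborts with a stage-tagged error and removes partial
#' outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the cohort table, the two report tables
#'   and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir,
                     c("cohort_metrics.csv", "comparisons.csv", "trends.csv",
                       "manifest.json"))
  names(paths) <- c("metrics", "comparisons", "trends", "manifest")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(paths[file.exists(paths)])
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("simulate", generate_cohort(
    config$cohort, seed = config$seed, mode = config$mode,
    layers = config$layers, image_size_px = config$image_size_px,
    keep_images = config$write_images))
  stage("simulate", write_cohort_csv(cohort, paths["metrics"]))
  if (config$write_images && config$mode == "images")
    stage("simulate", write_eye_images(attr(cohort, "eyes"), config$out_dir))
  comparisons <- stage("analyze", comparison_report(cohort, config$contrasts,
                                                    layers = config$layers))
  stage("analyze", utils::write.csv(comparisons, paths["comparisons"],
                                    row.names = FALSE))
  trends <- stage("analyze", trend_report(cohort, layers = config$layers,
                                          n_permutations = config$n_permutations,
                                          seed = config$seed))
  stage("analyze", utils::write.csv(trends, paths["trends"], row.names = FALSE))
  stage("report", jsonlite::write_json(
    list(seed = config$seed, config_md5 = config_hash(config),
         package = "octaquant",
         version = as.character(utils::packageVersion("octaquant"))),
    paths["manifest"], auto_unbox = TRUE, pretty = TRUE))
  invisible(list(cohort = cohort, comparisons = comparisons, trends = trends,
                 paths = paths))
}

write_eye_images <- function(eyes, out_dir) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (nm in names(eyes)) {
    eye <- eyes[[nm]]
    for (lay in setdiff(names(eye), c("subject_id", "eye"))) {
      stem <- file.path(img_dir, paste0(eye$subject_id, "_", eye$eye, "_",
                                        sub("-", "", lay)))
      write_angiogram(eye[[lay]]$angiogram, paste0(stem, ".tiff"))
      png::writePNG(eye[[lay]]$truth$mask * 1, paste0(stem, "_truth.png"))
    }
  }
  invisible(NULL)
}

#' Quantify a directory of angiogram images
#'
#' Reads every TIFF/PNG in `dir` (filename convention
#' `<subject>_<eye>_<layer>.<ext>`), quantifies each image and returns the
#' metric rows.
#'
#' @param dir input directory.
#' @param ... binarization settings passed to [quantify()].
#' @return data.frame with columns subject_id, eye, layer, fd, vd, sd, vdi,
#'   threshold_used, box_fit_r2.
#' @export
quantify_directory <- function(dir, ...) {
  files <- list.files(dir, pattern = "\\.(tiff?|png)$", full.names = TRUE,
                      ignore.case = TRUE)
  files <- files[!grepl("_truth\\.png$", files)]
  if (!length(files)) stop("no TIFF/PNG images in ", dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    a <- read_angiogram(f)
    toks <- strsplit(sub("\\.[^.]*$", "", basename(f)), "_", fixed = TRUE)[[1]]
    ms <- quantify(a, ...)
    data.frame(subject_id = toks[1],
               eye = if (length(toks) > 1) toks[2] else NA_character_,
               layer = a$layer, as.data.frame(ms))
  })
  do.call(rbind, rows)
}
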