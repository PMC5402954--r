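# Image and table I/O.
#
# Filename convention for angiograms: <subject>_<eye>_<layer>.<tiff|png>,
# e.g. S001_OD_SRL.tiff. The layer token is matched case-insensitively
# against NS-RL/NSRL, SRL, DRL; a missing token falls back to NS-RL with a
# warning. A sidecar JSON (<stem>.json) may override `fov_mm` and `layer`.

parse_layer_token <- function(path) {
  stem <- sub("\\.[^.]*$", "", basename(path))
  tokens <- toupper(strsplit(stem, "_", fixed = TRUE)[[1]])
  if (any(tokens %in% c("NS-RL", "NSRL"))) return("NS-RL")
  if ("SRL" %in% tokens) return("SRL")
  if ("DRL" %in% tokens) return("DRL")
  warning(sprintf("no layer token in '%s'; defaulting to NS-RL", basename(path)))
  "NS-RL"
}

#' Read an en-face angiogram from TIFF or PNG
#'
#' Loads a single-channel 8- or 16-bit grayscale image losslessly (pixel
#' values are returned as the stored integers). Layer and field of view are
#' parsed from the filename convention or an optional sidecar JSON.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param fov_mm field of view, used unless the sidecar overrides it.
#' @return An [enface_angiogram()].
#' @export
read_angiogram <- function(path, fov_mm = 3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
               png = {
                 x <- png::readPNG(path, info = TRUE)
                 depth <- attr(x, "info")$bit.depth
                 if (is.null(depth)) depth <- 8
                 round(unclass(x) * (2^depth - 1))
               },
               stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    else stop(sprintf("multi-channel image not supported: %s", basename(path)),
              call. = FALSE)
  }
  layer <- parse_layer_token(path)
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$fov_mm)) fov_mm <- meta$fov_mm
    if (!is.null(meta$layer)) layer <- meta$layer
  }
  enface_angiogram(px + 0, fov_mm = fov_mm, layer = layer)
}

#' @rdname read_angiogram
#' @param angiogram an [enface_angiogram()] to write; intensities either in
#'   [0, 1] or as integers up to the bit depth.
#' @param bits bit depth (8 or 16).
#' @export
write_angiogram <- function(angiogram, path, bits = 16) {
  stopifnot(inherits(angiogram, "enface_angiogram"), bits %in% c(8, 16))
  px <- angiogram$pixels
  maxv <- 2^bits - 1
  if (max(px) > 1) px <- px / maxv else px <- round(px * maxv) / maxv
  if (max(px) > 1) stop("intensities exceed the requested bit depth", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = bits),
         png = png::writePNG(px, path),
         stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Write and read cohort metric tables
#'
#' CSV dialect: UTF-8, comma separator, `.` decimal, mandatory header.
#'
#' @param cohort a `cohort_table` data.frame.
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "eye", "rvo_status", "rvo_type", "age", "gender",
              "layer", "fd", "vd", "sd", "vdi")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols))
    stop("cohort CSV missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"subject_type" %in% names(out)) {
    # reconstruct the subject's disease type from the affected eye
    aff <- out[out$rvo_status == "RVO", c("subject_id", "rvo_type")]
    aff <- aff[!duplicated(aff$subject_id), ]
    out$subject_type <- aff$rvo_type[match(out$subject_id, aff$subject_id)]
    out$subject_type[is.na(out$subject_type)] <- "control"
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}
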