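# File I/O. Stacks and label volumes travel as multi-page TIFF; because the
# TIFF writer cannot embed resolution tags, physical spacing and units are
# carried in a JSON sidecar (<path>.meta.json) written and read alongside.
# Tables are CSV with a sidecar recording the parameters that produced them.

#' Write an intensity stack or label volume as multi-page TIFF
#'
#' Intensities are written as 32-bit float pages; label volumes as 16-bit
#' integer pages (lossless for labels up to 65535). Spacing and unit go to
#' `<path>.meta.json`.
#'
#' @param x an [intensity_stack()] or [label_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "intensity_stack")) {
    arr <- x$values
    # TIFF pages only hold [0, 1]: store rescaled values, range in the sidecar
    rng <- range(arr)
    if (rng[2] > rng[1]) arr <- (arr - rng[1]) / (rng[2] - rng[1])
    else arr <- arr * 0
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta <- list(kind = "intensity", spacing = as.list(x$spacing),
                 unit = x$unit, channel = x$channel,
                 value_range = as.list(rng))
  } else if (inherits(x, "label_volume")) {
    arr <- x$labels
    if (max(arr) > 65535L) stop("labels exceed 16-bit TIFF range")
    pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
    meta <- list(kind = "labels", spacing = as.list(x$spacing), unit = x$unit)
  } else stop("unsupported object")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_meta_ <- function(path, spacing, unit) {
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    list(spacing = unlist(meta$spacing), unit = meta$unit,
         channel = meta$channel %||% "",
         value_range = unlist(meta$value_range %||% NULL))
  } else if (!is.null(spacing)) {
    list(spacing = spacing, unit = unit %||% "um", channel = "")
  } else {
    stop("unit error: no spacing metadata found for '", path,
         "' and no override supplied")
  }
}

#' Read a multi-page TIFF as an intensity stack
#'
#' @param path TIFF path.
#' @param spacing spacing override `c(y=, x=, z=)` when no sidecar metadata
#'   exists (required in that case; spacing is never silently assumed).
#' @param unit unit override.
#' @return an [intensity_stack()].
#' @export
read_stack <- function(path, spacing = NULL, unit = NULL) {
  meta <- read_meta_(path, spacing, unit)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (!is.null(meta$value_range) && length(meta$value_range) == 2) {
    rng <- meta$value_range
    arr <- arr * (rng[2] - rng[1]) + rng[1]
  }
  intensity_stack(arr, meta$spacing, unit = meta$unit, channel = meta$channel)
}

#' Read a multi-page TIFF as a label volume
#'
#' @inheritParams read_stack
#' @return a [label_volume()].
#' @export
read_labels <- function(path, spacing = NULL, unit = NULL) {
  meta <- read_meta_(path, spacing, unit)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(as.integer(round(unlist(pages) * 65535)),
               dim = c(dim(pages[[1]]), length(pages)))
  label_volume(arr, meta$spacing, unit = meta$unit %||% "nm")
}

#' Write a result table with its provenance sidecar
#'
#' @param rows data.frame.
#' @param path output CSV path.
#' @param params named list of the parameters that produced the table
#'   (recorded, with the package version, in `<path>.meta.json`).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, params = list()) {
  write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(
    list(package = "mcsquant",
         version = as.character(packageVersion("mcsquant")),
         params = params),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a closed-outline ROI polygon
#'
#' CSV with columns `x_um`, `y_um` (one vertex per row) or a JSON array of
#' `[x, y]` pairs.
#'
#' @param path file path.
#' @return matrix (k x 2) of physical (x, y) coordinates.
#' @export
read_roi <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    if (ncol(m) != 2) stop("ROI JSON must be an array of [x, y] pairs")
    return(unname(m))
  }
  d <- read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(d))) {
    stop("ROI CSV needs columns x_um, y_um")
  }
  unname(as.matrix(d[, c("x_um", "y_um")]))
}
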