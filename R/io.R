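#' Write a two-channel stack as multi-page TIFF files
#'
#' Writes the green and red channels of a rendered (or acquired) stack as
#' 32-bit float multi-page TIFFs, one page per z-slice, channel order
#' green then red, plus a JSON sidecar recording the intensity scale,
#' geometry and acquisition metadata. Pixel values are divided by a common
#' scale to fit the TIFF float convention and restored on read (float32
#' precision, ~1e-7 relative).
#'
#' @param stack A `campari_stack` (from [render_scene()]) or a list with
#'   `green`, `red` 3-D arrays and a `meta` list.
#' @param path_prefix Output path prefix; files written are
#'   `<prefix>_green.tif`, `<prefix>_red.tif`, `<prefix>_mask.tif` (if a
#'   mask is present) and `<prefix>_meta.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_image_stack <- function(stack, path_prefix) {
  scale <- max(stack$green, stack$red, 1)
  files <- c(
    green = paste0(path_prefix, "_green.tif"),
    red = paste0(path_prefix, "_red.tif")
  )
  write_float_tiff(stack$green / scale, files["green"])
  write_float_tiff(stack$red / scale, files["red"])
  if (!is.null(stack$mask)) {
    files["mask"] <- paste0(path_prefix, "_mask.tif")
    write_label_tiff(stack$mask, files["mask"])
  }
  meta <- c(stack$meta, list(intensity_scale = scale,
                             channel_order = c("green", "red")))
  files["meta"] <- paste0(path_prefix, "_meta.json")
  jsonlite::write_json(meta, files["meta"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

#' Read a two-channel stack written by [write_image_stack()]
#'
#' @param path_prefix The prefix used when writing.
#' @return List with `green`, `red` (and `mask` if present) arrays and
#'   `meta`.
#' @export
read_image_stack <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, "_meta.json"),
                              simplifyVector = TRUE)
  scale <- meta$intensity_scale
  out <- list(
    green = read_float_tiff(paste0(path_prefix, "_green.tif")) * scale,
    red = read_float_tiff(paste0(path_prefix, "_red.tif")) * scale,
    meta = meta
  )
  maskfile <- paste0(path_prefix, "_mask.tif")
  if (file.exists(maskfile)) out$mask <- read_label_tiff(maskfile)
  out
}

write_float_tiff <- function(arr, path) {
  stopifnot(length(dim(arr)) == 3)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write / read integer label masks as 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly. 2-D masks are written as a single
#' page; 3-D masks one page per slice.
#'
#' @param mask Integer matrix or 3-D array of labels (0 = background).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(mask, path) {
  stopifnot(max(mask) < 65536, min(mask) >= 0)
  dm <- dim(mask)
  pages <- if (length(dm) == 3) {
    lapply(seq_len(dm[3]), function(k) mask[, , k] / 65535)
  } else {
    list(mask / 65535)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_tiff
#' @return `read_label_tiff()` returns the integer label matrix (one page)
#'   or array (several pages).
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lab <- lapply(pages, function(p) matrix(as.integer(round(p * 65535)),
                                          nrow(p), ncol(p)))
  if (length(lab) == 1) lab[[1]] else
    array(unlist(lab), c(dim(lab[[1]]), length(lab)))
}

#' Write the ground-truth cell table of a rendered stack
#'
#' @param stack A `campari_stack`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(stack, path) {
  cols <- c("cell_id", "x", "y", "z", "radius", "region", "hemisphere",
            "activity", "base_green", "true_rgr")
  utils::write.csv(stack$cells[, cols], path, row.names = FALSE)
  invisible(path)
}
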