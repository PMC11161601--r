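#' Calibrated multichannel image
#'
#' A light container for a set of equally shaped 2D intensity grids
#' ("channels", e.g. DAPI / K8 / K14 / Yap / collagen reflection) together
#' with the pixel size in micrometers per pixel. Channels are plain numeric
#' matrices indexed \code{[row, col]}; intensities are non-negative and on
#' an arbitrary linear scale.
#'
#' @param channels named list of numeric matrices, all the same dimension.
#' @param pixel_size_um pixel edge length in micrometers (> 0).
#' @return an object of class \code{multichannel_image}.
#' @export
multichannel_image <- function(channels, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be non-negative")
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("multichannel_image: %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$channels[[1]])

#' Get one channel of a multichannel image
#'
#' @param img a \code{multichannel_image}.
#' @param name channel name (case-insensitive).
#' @return numeric matrix.
#' @export
get_channel <- function(img, name) {
  i <- match(tolower(name), tolower(names(img$channels)))
  if (is.na(i))
    stop(sprintf("channel '%s' not found; available: %s", name,
                 paste(names(img$channels), collapse = ", ")))
  img$channels[[i]]
}

#' Write a multichannel image (or stack) as multipage TIFF
#'
#' One 32-bit float page per channel (or time frame). Channel names and the
#' pixel size are stored in a JSON sidecar \code{<path>.meta.json} so that
#' a round trip through [read_image_tiff()] restores the full object.
#' Intensities are written as-is (not rescaled).
#'
#' @param img a \code{multichannel_image}, or a list of matrices (a time
#'   stack written frame-per-page).
#' @param path output file path (.tif).
#' @param pixel_size_um required when \code{img} is a bare list.
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(img, path, pixel_size_um = NULL) {
  if (inherits(img, "multichannel_image")) {
    pages <- img$channels
    meta <- list(channels = names(img$channels),
                 pixel_size_um = img$pixel_size_um, kind = "channels")
  } else {
    stopifnot(is.list(img), !is.null(pixel_size_um))
    pages <- img
    meta <- list(channels = NULL, pixel_size_um = pixel_size_um,
                 kind = "frames")
  }
  scale <- max(1, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multipage TIFF written by this package (or any plain TIFF)
#'
#' @param path TIFF path.
#' @param channels optional character vector naming the pages, overriding
#'   the sidecar metadata.
#' @param pixel_size_um optional pixel size, overriding the sidecar.
#' @return a \code{multichannel_image} when channel names are known,
#'   otherwise a list with elements \code{frames} and \code{pixel_size_um}.
#' @export
read_image_tiff <- function(path, channels = NULL, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  pages <- lapply(pages, function(p) p * scale)
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(channels) && identical(meta$kind, "channels"))
    channels <- unlist(meta$channels)
  if (is.null(pixel_size_um))
    stop("pixel_size_um not given and no metadata sidecar found")
  if (!is.null(channels)) {
    stopifnot(length(channels) == length(pages))
    multichannel_image(setNames(pages, channels), pixel_size_um)
  } else {
    list(frames = pages, pixel_size_um = pixel_size_um)
  }
}

#' Write an integer label map as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) <= 65535)
  tiff::writeTIFF(matrix(as.numeric(labels) / 65535,
                         nrow(labels), ncol(labels)),
                  path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a 16-bit label TIFF back to an integer matrix
#' @param path TIFF path.
#' @return integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

# CSV with '# key: value' header comments; all tables the package writes
# carry their units in these headers
write_annotated_csv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_annotated_csv <- function(path) {
  read.csv(path, comment.char = "#")
}
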