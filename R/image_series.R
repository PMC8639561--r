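#' Construct an image time series
#'
#' Bundles an ordered stack of equal-size grayscale frames with its acquisition
#' metadata. This is the carrier object for every downstream computation: the
#' structure function is defined on differences of these frames at increasing
#' time lags.
#'
#' @param frames numeric array of dimension `N x H x W` (frame index first), or
#'   a list of `N` numeric `H x W` matrices. Pixel values are intensity counts
#'   and are used as-is: the structure function's rejection of static background
#'   comes from frame differencing, not from preprocessing.
#' @param dt frame interval in seconds (`> 0`).
#' @param pixel_size physical side of one pixel in meters (`> 0`).
#' @param bit_depth integer, informational record of the source bit depth.
#'
#' @return An object of class `image_series`: a list with elements `frames`
#'   (`N x H x W` double array), `dt`, `pixel_size`, `bit_depth`.
#' @examples
#' s <- image_series(array(runif(5 * 8 * 8), c(5, 8, 8)), dt = 0.04,
#'                   pixel_size = 1e-6)
#' dim(s$frames)
#' @export
image_series <- function(frames, dt, pixel_size, bit_depth = 16L) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share the same height and width", call. = FALSE)
    arr <- array(0, c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an N x H x W array or a list of matrices",
         call. = FALSE)
  if (dim(frames)[1] < 2L)
    stop("an image series needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("frames contain non-finite pixel values", call. = FALSE)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  storage.mode(frames) <- "double"
  structure(
    list(frames = frames, dt = dt, pixel_size = pixel_size,
         bit_depth = as.integer(bit_depth)),
    class = "image_series"
  )
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_series> %d frames of %d x %d px, dt = %g s, pixel = %g m\n",
    d[1], d[2], d[3], x$dt, x$pixel_size))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$frames)

# Bit depth lives at byte offset 24 of the IHDR chunk; png::readPNG rescales
# pixels to [0,1], so the header is needed to restore raw counts.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  as.integer(hdr[25L])
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    } else if (ext == "png") {
      depth <- png_bit_depth(path)
      m <- png::readPNG(path)
      list(round(m * (2^depth - 1)))
    } else {
      stop("unsupported image format '", ext, "'")
    }
  }, error = function(e) {
    stop("failed to read image file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  lapply(img, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # grayscale stored with channels
    storage.mode(m) <- "double"
    m
  })
}

# Strict zero-padded numbering: every numeric run in otherwise-identical
# filenames must have one common width, otherwise lexicographic order would
# silently misorder frames (frame_2 after frame_10).
check_zero_padding <- function(files) {
  nums <- regmatches(files, regexpr("[0-9]+", files))
  if (length(nums) == length(files) && length(unique(nchar(nums))) > 1L)
    stop("frame filenames mix numeric field widths (e.g. '2' vs '10'); ",
         "zero-pad the numbering so lexicographic order is frame order",
         call. = FALSE)
  invisible(files)
}

#' Load an image time series from disk
#'
#' Reads either a multi-page TIFF stack or a directory of numbered single-frame
#' TIFF/PNG files. Frames are ordered by page index or by ascending filename;
#' directory numbering must be zero-padded to a common width (mixed widths are
#' rejected rather than guessed, since a silent misordering corrupts every
#' lag). Pixel values are loaded as raw counts without rescaling.
#'
#' @param path a multi-page TIFF file, or a directory of same-size frames.
#' @param dt frame interval in seconds.
#' @param pixel_size pixel side in meters.
#' @return An [image_series].
#' @seealso [save_series()]
#' @export
load_series <- function(path, dt, pixel_size) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE)
    if (length(files) < 2L)
      stop("directory '", path, "' holds fewer than 2 frame images",
           call. = FALSE)
    check_zero_padding(files)
    files <- sort(files)
    frames <- unlist(
      lapply(file.path(path, files), read_frame_file), recursive = FALSE)
  } else if (file.exists(path)) {
    frames <- read_frame_file(path)
  } else {
    stop("no such file or directory: '", path, "'", call. = FALSE)
  }
  if (length(frames) < 2L)
    stop("an image series needs at least 2 frames, got ", length(frames),
         call. = FALSE)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop("frames have mixed sizes: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = ", "),
         call. = FALSE)
  depth <- if (max(vapply(frames, max, 0)) > 255) 16L else 8L
  image_series(frames, dt = dt, pixel_size = pixel_size, bit_depth = depth)
}

#' Save an image time series as a multi-page TIFF
#'
#' Writes 16-bit unsigned integer pages (camera-count convention). Values must
#' lie in `[0, 65535]` and are rounded to integers; a series that was loaded
#' from 8/16-bit data round-trips bit-identically.
#'
#' @param series an [image_series].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  fr <- series$frames
  if (min(fr) < 0 || max(fr) > 65535)
    stop("pixel values outside [0, 65535] cannot be stored as 16-bit TIFF",
         call. = FALSE)
  pages <- lapply(seq_len(dim(fr)[1]), function(n) round(fr[n, , ]) / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e)
                   stop("cannot write '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  invisible(path)
}
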