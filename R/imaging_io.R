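#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix of intensities together with the
#' declared representable range of the scale it lives on (e.g. `c(0, 255)`
#' for 8-bit data, `c(0, 1)` after [normalize_unit()]).  All texture
#' operators in the package take and return this class; most accept a bare
#' matrix as well and coerce it.
#'
#' @param pixels numeric matrix (rows x cols) of finite intensities.
#' @param value_range length-2 numeric, declared (min, max) of the scale.
#'   Defaults to the observed range of `pixels`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, value_range = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values")
  if (is.null(value_range)) value_range <- range(pixels)
  stopifnot(length(value_range) == 2L, value_range[1] <= value_range[2])
  structure(list(pixels = pixels, value_range = as.numeric(value_range)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%g, %g], values in [%g, %g]>\n",
              nrow(x$pixels), ncol(x$pixels),
              x$value_range[1], x$value_range[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Coerce to gray_image
#' @param x matrix or `gray_image`.
#' @param value_range optional declared range when `x` is a matrix.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x, value_range = NULL) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, value_range = value_range)
}

# PNG bit depth lives in the IHDR chunk: bytes 1-8 signature, 9-16 chunk
# length+type, 17-24 width+height, byte 25 is bit depth.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 25L) stop("not a PNG file: ", path)
  as.integer(hdr[25L])
}

#' Load a grayscale raster image
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF into a [gray_image()]
#' whose pixel values reproduce the stored integers exactly (0..255 or
#' 0..65535).  Multi-channel files are refused unless `reduce = TRUE`, in
#' which case channels are averaged.
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @param reduce collapse a multi-channel image to grayscale by channel
#'   averaging instead of raising an error.
#' @return A `gray_image` with `value_range` `c(0, 2^bits - 1)`.
#' @export
load_image <- function(path, reduce = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    bits <- png_bit_depth(path)
    maxval <- 2^bits - 1
    arr <- arr * maxval           # readPNG rescales to [0,1]; undo it
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)   # raw integers
    maxval <- if (max(arr) > 255) 65535 else 255
    if (is.list(arr)) arr <- arr[[1]]
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 1L) {
      arr <- arr[, , 1L]
    } else if (reduce) {
      arr <- apply(arr, c(1, 2), mean)
    } else {
      stop("multi-channel image; pass reduce = TRUE to average channels: ",
           path)
    }
  }
  gray_image(round(arr), value_range = c(0, maxval))
}

#' Write a grayscale image to PNG or TIFF
#'
#' Values are mapped from the image's declared `value_range` onto the file's
#' integer scale.  An 8-bit file is written unless `bits = 16`.
#'
#' @param image `gray_image` or matrix.
#' @param path destination (.png, .tif or .tiff).
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8) {
  image <- as_gray_image(image)
  stopifnot(bits %in% c(8, 16))
  vr <- image$value_range
  den <- if (vr[2] > vr[1]) vr[2] - vr[1] else 1
  x <- (image$pixels - vr[1]) / den
  x[x < 0] <- 0; x[x > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits == 16)
      stop("16-bit output is only supported for TIFF")
    png::writePNG(x, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, where = path, bits.per.sample = bits)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' ROI record
#'
#' A rectangular region of interest inside a named image, with a binary
#' diagnosis label.  Coordinates are 0-based, row-major, and the rectangle
#' is half-open: rows `[row0, row0 + height)`, columns `[col0, col0 + width)`.
#'
#' @param image_id character id of the parent image.
#' @param row0,col0 0-based top-left corner.
#' @param height,width extent in pixels, both >= 2.
#' @param label `"benign"` or `"malignant"`.
#' @return An object of class `roi_record`.
#' @export
roi_record <- function(image_id, row0, col0, height, width, label) {
  label <- match.arg(label, c("benign", "malignant"))
  stopifnot(row0 >= 0, col0 >= 0, height >= 2, width >= 2)
  structure(list(image_id = as.character(image_id),
                 row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width),
                 label = label),
            class = "roi_record")
}

#' Read an ROI table
#'
#' Accepts CSV with header `image_id,row0,col0,height,width,label` or a JSON
#' array of objects with the same fields.
#'
#' @param path CSV or JSON file.
#' @return A list of [roi_record()] objects.
#' @export
read_roi_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("image_id", "row0", "col0", "height", "width", "label")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    roi_record(df$image_id[i], df$row0[i], df$col0[i],
               df$height[i], df$width[i], df$label[i]))
}

#' Extract a rectangular ROI
#'
#' @param image `gray_image` (or matrix).
#' @param roi [roi_record()].
#' @return `gray_image` of dimensions `(height, width)`; the declared
#'   `value_range` of the parent is inherited.
#' @export
extract_roi <- function(image, roi) {
  image <- as_gray_image(image)
  px <- image$pixels
  r1 <- roi$row0 + 1L; r2 <- roi$row0 + roi$height
  c1 <- roi$col0 + 1L; c2 <- roi$col0 + roi$width
  if (r2 > nrow(px) || c2 > ncol(px))
    stop(sprintf("ROI %s [%d:%d, %d:%d] exceeds image %d x %d",
                 roi$image_id, r1, r2, c1, c2, nrow(px), ncol(px)))
  gray_image(px[r1:r2, c1:c2, drop = FALSE], value_range = image$value_range)
}

#' Rescale intensities to the unit interval
#'
#' Affine map `(x - min) / (max - min)` using the observed min and max; a
#' constant image maps to all zeros.  This fixes the scale on which additive
#' noise variance (e.g. the default 0.02) is meaningful.
#'
#' @param image `gray_image` or matrix.
#' @return `gray_image` with values in `[0, 1]` and `value_range` `c(0, 1)`.
#' @export
normalize_unit <- function(image) {
  image <- as_gray_image(image)
  px <- image$pixels
  rng <- range(px)
  px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
        else array(0, dim(px))
  gray_image(px, value_range = c(0, 1))
}

#' Quantize an image to L gray levels
#'
#' Equal-width bins over the quantization range (by default the ROI's own
#' min/max, so each sample is quantized on its own scale; pass `range` to
#' impose a fixed global scale).  Values at interior bin edges go to the
#' higher bin; the maximum maps to level `L`.  A constant image maps to all
#' ones.
#'
#' @param image `gray_image` or matrix.
#' @param L number of gray levels, >= 2 (default 8).
#' @param range optional fixed `(min, max)` quantization range.
#' @return An object of class `quantized_image`: integer matrix `levels`
#'   with entries in `1..L`, plus `L`.
#' @export
quantize <- function(image, L = 8, range = NULL) {
  image <- as_gray_image(image)
  stopifnot(L >= 2)
  L <- as.integer(L)
  px <- image$pixels
  rng <- if (is.null(range)) base::range(px) else as.numeric(range)
  if (rng[2] <= rng[1]) {
    lev <- array(1L, dim(px))
  } else {
    lev <- floor((px - rng[1]) / (rng[2] - rng[1]) * L) + 1L
    lev[lev < 1L] <- 1L
    lev[lev > L] <- L
    storage.mode(lev) <- "integer"
  }
  structure(list(levels = lev, L = L), class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image %d x %d, L = %d>\n",
              nrow(x$levels), ncol(x$levels), x$L))
  invisible(x)
}
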