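# Image and DICOM-metadata IO, and geometry normalization to the pipeline's
# working convention: square 384x384 greyscale images with a single
# pixel-spacing value in mm/pixel.

WORKING_DIM <- 384L

#' Image geometry metadata
#'
#' Bundles the DICOM Pixel Spacing (`ps`, mm/pixel) and Image Dimension
#' (`dm`, pixels, square images only) attributes together with the rescaled
#' spacing `ps' = ps * dm / 384` that applies after the image is resampled to
#' the working 384x384 grid.
#'
#' @param pixel_spacing positive pixel spacing in mm/pixel (identical in x
#'   and y).
#' @param dimension positive integer image dimension in pixels (square).
#' @return an `image_meta` object with fields `pixel_spacing`, `dimension`,
#'   `rescaled_spacing`.
#' @export
image_meta <- function(pixel_spacing, dimension) {
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be a single positive number", call. = FALSE)
  if (!is.numeric(dimension) || length(dimension) != 1L ||
      !is.finite(dimension) || dimension <= 0)
    stop("dimension must be a single positive number", call. = FALSE)
  structure(list(pixel_spacing = as.numeric(pixel_spacing),
                 dimension = as.integer(dimension),
                 rescaled_spacing = rescale_pixel_spacing(pixel_spacing,
                                                          dimension)),
            class = "image_meta")
}

#' @export
print.image_meta <- function(x, ...) {
  cat(sprintf("image_meta: %d x %d px, %.4f mm/px (%.4f mm/px at 384)\n",
              x$dimension, x$dimension, x$pixel_spacing, x$rescaled_spacing))
  invisible(x)
}

#' Rescale a pixel spacing to the 384-pixel working grid
#'
#' `ps' = ps * dm / 384`: resampling a `dm` x `dm` image with spacing `ps`
#' onto 384 x 384 preserves the physical field of view, so the spacing scales
#' by `dm / 384`.
#'
#' @param ps original pixel spacing, mm/pixel (> 0).
#' @param dm original image dimension, pixels (> 0).
#' @return the rescaled spacing in mm/pixel.
#' @examples
#' rescale_pixel_spacing(0.8750, 320) # 0.7292 at 4 decimals
#' @export
rescale_pixel_spacing <- function(ps, dm) {
  if (any(!is.finite(ps)) || any(ps <= 0) || any(!is.finite(dm)) || any(dm <= 0))
    stop("ps and dm must be positive", call. = FALSE)
  ps * dm / WORKING_DIM
}

#' Greyscale image container
#'
#' @param px numeric matrix `[row, col]` of intensities in `[0, 255]`.
#' @param meta an [image_meta()]; defaults to spacing 1 mm/px.
#' @return a `grey_image` object (list with `px`, `meta`).
#' @export
grey_image <- function(px, meta = image_meta(1, nrow(px))) {
  stopifnot(is.matrix(px))
  if (nrow(px) != ncol(px))
    stop("grey_image requires a square pixel grid", call. = FALSE)
  if (any(px < 0 | px > 255, na.rm = TRUE))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  structure(list(px = px, meta = meta), class = "grey_image")
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("grey_image: %d x %d, intensity [%.1f, %.1f], %.4f mm/px\n",
              nrow(x$px), ncol(x$px), min(x$px), max(x$px),
              x$meta$pixel_spacing))
  invisible(x)
}

## ---- minimal DICOM metadata reader -----------------------------------------
## Only the attributes the pipeline needs are parsed (explicit- and
## implicit-VR little endian, uncompressed). There is no DICOM reader in the
## package's R dependency universe, so this small parser is provided here.

.dcm_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1L))

.dcm_parse <- function(path, want_pixels = FALSE) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(bytes) >= 132L &&
      rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  explicit_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                    "LT","OB","OF","OW","PN","SH","SL","SQ","SS","ST","TM",
                    "UI","UL","UN","US","UT")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    group <- .dcm_uint(bytes[pos:(pos + 1L)])
    elem <- .dcm_uint(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (vr %in% explicit_vrs) {
      if (vr %in% long_vrs) {
        len <- .dcm_uint(bytes[(pos + 4L):(pos + 7L)]); pos <- pos + 8L
      } else {
        len <- .dcm_uint(bytes[(pos + 2L):(pos + 3L)]); pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- .dcm_uint(bytes[pos:(pos + 3L)]); pos <- pos + 4L
    }
    if (len > 0 && pos + len - 1L > length(bytes))
      stop("truncated DICOM element", call. = FALSE)
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = val)
    if (key == "7fe0,0010") break
  }
  tags
}

.dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  if (!is.na(el$vr) && el$vr %in% c("DS", "IS", "LO", "SH"))
    return(as.numeric(rawToChar(el$value)))
  .dcm_uint(el$value[1:2])
}

#' Read pixel-spacing and dimension metadata from a DICOM file
#'
#' Parses Pixel Spacing (0028,0030) and Rows/Columns (0028,0010/0011) from a
#' little-endian DICOM file. Non-square geometry (differing row/column counts
#' or x/y spacing) is rejected: the pipeline represents each attribute with a
#' single value.
#'
#' @param path path to a DICOM file.
#' @return an [image_meta()].
#' @export
read_dicom_meta <- function(path) {
  tags <- .dcm_parse(path)
  rows <- .dcm_us(tags[["0028,0010"]])
  cols <- .dcm_us(tags[["0028,0011"]])
  sp <- tags[["0028,0030"]]
  if (is.null(rows) || is.null(cols) || is.null(sp))
    stop("DICOM metadata error: PixelSpacing and Rows/Columns are required",
         call. = FALSE)
  spacing <- as.numeric(strsplit(trimws(rawToChar(sp$value)), "\\\\")[[1]])
  if (length(spacing) != 2L || any(!is.finite(spacing)))
    stop("DICOM metadata error: malformed PixelSpacing", call. = FALSE)
  if (abs(spacing[1] - spacing[2]) > 1e-9)
    stop("unsupported geometry: x and y pixel spacing differ", call. = FALSE)
  if (rows != cols)
    stop("unsupported geometry: non-square image", call. = FALSE)
  image_meta(spacing[1], rows)
}

#' Read a DICOM image as a greyscale image
#'
#' Reads uncompressed little-endian pixel data and windows the stored values
#' to `[0, 255]` by linear min-max scaling (the 8-bit export convention used
#' throughout the pipeline; configurable via `window`).
#'
#' @param path path to a DICOM file.
#' @param window optional `c(lo, hi)` window; defaults to the image min/max.
#' @return a [grey_image()].
#' @export
read_dicom_image <- function(path, window = NULL) {
  meta <- read_dicom_meta(path)
  tags <- .dcm_parse(path, want_pixels = TRUE)
  px_el <- tags[["7fe0,0010"]]
  if (is.null(px_el)) stop("DICOM has no PixelData", call. = FALSE)
  bits <- .dcm_us(tags[["0028,0100"]])
  if (is.null(bits)) bits <- 16L
  n <- meta$dimension^2
  vals <- if (bits > 8L) {
    readBin(px_el$value, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  } else {
    as.integer(px_el$value[seq_len(n)])
  }
  # DICOM pixel data is row-major (row by row); R matrices are column-major.
  m <- matrix(as.numeric(vals), nrow = meta$dimension, byrow = TRUE)
  if (is.null(window)) window <- range(m)
  span <- max(window[2] - window[1], 1e-12)
  m <- pmin(pmax((m - window[1]) / span, 0), 1) * 255
  grey_image(m, meta)
}

## ---- resampling ------------------------------------------------------------

# Sparse 1-D resampling operator (n_out x n_in). Catmull-Rom cubic taps with
# border replication; output/input pixel centers aligned.
.resample_operator <- function(n_in, n_out) {
  i <- seq_len(n_out)
  s <- (i - 0.5) * n_in / n_out + 0.5
  base <- floor(s)
  t <- s - base
  w <- cbind((-t^3 + 2 * t^2 - t) / 2,
             (3 * t^3 - 5 * t^2 + 2) / 2,
             (-3 * t^3 + 4 * t^2 + t) / 2,
             (t^3 - t^2) / 2)
  rows <- rep(i, 4L)
  cols <- pmin(pmax(c(base - 1, base, base + 1, base + 2), 1L), n_in)
  Matrix::sparseMatrix(i = rows, j = cols, x = as.numeric(w),
                       dims = c(n_out, n_in))
}

# Cubic (Catmull-Rom, separable) resampling of a numeric matrix.
resize_cubic <- function(m, n_out_r, n_out_c = n_out_r) {
  Wr <- .resample_operator(nrow(m), n_out_r)
  Wc <- .resample_operator(ncol(m), n_out_c)
  as.matrix(Wr %*% m %*% Matrix::t(Wc))
}

# Nearest-neighbour resampling (used for label images: never invents codes).
resize_nearest <- function(m, n_out_r, n_out_c = n_out_r) {
  src_r <- pmin(pmax(floor((seq_len(n_out_r) - 0.5) * nrow(m) / n_out_r) + 1L,
                     1L), nrow(m))
  src_c <- pmin(pmax(floor((seq_len(n_out_c) - 0.5) * ncol(m) / n_out_c) + 1L,
                     1L), ncol(m))
  m[src_r, src_c, drop = FALSE]
}

#' Resample an image or label map to the 384 x 384 working grid
#'
#' Intensity images are resampled with cubic interpolation (clamped back to
#' `[0, 255]`); label maps with nearest-neighbour interpolation so no new
#' label codes can appear. The metadata's rescaled spacing already reflects
#' the 384-pixel grid, so it becomes the active spacing.
#'
#' @param image a [grey_image()] or [label_map()].
#' @return an object of the same class on the 384 x 384 grid.
#' @export
resample_to_384 <- function(image) {
  UseMethod("resample_to_384")
}

#' @export
resample_to_384.grey_image <- function(image) {
  meta <- image_meta(image$meta$rescaled_spacing, WORKING_DIM)
  if (nrow(image$px) == WORKING_DIM) return(grey_image(image$px, meta))
  px <- pmin(pmax(resize_cubic(image$px, WORKING_DIM), 0), 255)
  grey_image(px, meta)
}

#' @export
resample_to_384.label_map <- function(image) {
  meta <- image_meta(image$meta$rescaled_spacing, WORKING_DIM)
  if (nrow(image$px) == WORKING_DIM) return(label_map(image$px, meta))
  label_map(resize_nearest(image$px, WORKING_DIM), meta)
}

## ---- PNG + JSON sidecar IO -------------------------------------------------

#' Read / write 8-bit greyscale PNG images
#'
#' A JSON metadata sidecar (`<path>.json` with `pixel_spacing`, `dimension`,
#' `rescaled_spacing`) carries the geometry that PNG cannot store.
#'
#' @param path PNG file path.
#' @param image a [grey_image()].
#' @param meta optional [image_meta()] used when no sidecar exists.
#' @return `read_grey_png` returns a [grey_image()]; `write_grey_png`
#'   invisibly returns `path`.
#' @export
read_grey_png <- function(path, meta = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  if (is.null(meta)) meta <- .read_meta_sidecar(path, nrow(a))
  grey_image(round(a * 255), meta)
}

#' @rdname read_grey_png
#' @export
write_grey_png <- function(image, path) {
  png::writePNG(pmin(pmax(image$px, 0), 255) / 255, path)
  .write_meta_sidecar(image$meta, path)
  invisible(path)
}

#' Read / write label maps as single-channel PNG with integer codes
#'
#' Region codes 1-6 are stored directly as 8-bit grey values.
#'
#' @inheritParams read_grey_png
#' @param labels a [label_map()].
#' @return `read_label_png` returns a [label_map()].
#' @export
read_label_png <- function(path, meta = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  if (is.null(meta)) meta <- .read_meta_sidecar(path, nrow(a))
  label_map(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)), meta)
}

#' @rdname read_label_png
#' @export
write_label_png <- function(labels, path) {
  png::writePNG(labels$px / 255, path)
  .write_meta_sidecar(labels$meta, path)
  invisible(path)
}

.sidecar_path <- function(path) paste0(path, ".json")

.write_meta_sidecar <- function(meta, path) {
  jsonlite::write_json(list(pixel_spacing = meta$pixel_spacing,
                            dimension = meta$dimension,
                            rescaled_spacing = meta$rescaled_spacing),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

.read_meta_sidecar <- function(path, dim_fallback) {
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    j <- jsonlite::read_json(sc, simplifyVector = TRUE)
    image_meta(j$pixel_spacing, j$dimension)
  } else {
    image_meta(1, dim_fallback)
  }
}
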