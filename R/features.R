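# Nucleus feature extraction: vertebrae-referenced brightness normalization,
# greyscale capping/quantization, adaptive nucleus detection inside each disc,
# and the self-similar colour correlogram (SSCC) feature.

#' Quantizer configuration
#'
#' Greyscale quantization used by the correlogram: intensities are capped at
#' `gl_max` and binned into `n_gl` bins of width `delta_gl = gl_max / n_gl`
#' (defaults 30 bins, cap 150, bin width 5).
#'
#' @param n_gl number of grey bins.
#' @param gl_max grey cap.
#' @return a `quantizer_config` with fields `n_gl`, `gl_max`, `delta_gl`.
#' @export
quantizer_config <- function(n_gl = 30L, gl_max = 150) {
  stopifnot(n_gl > 0, gl_max > 0)
  structure(list(n_gl = as.integer(n_gl), gl_max = gl_max,
                 delta_gl = gl_max / n_gl),
            class = "quantizer_config")
}

#' Quantize adjusted intensities to bin indices
#'
#' `gl_ind = floor(min(gl, gl_max) / delta_gl)`, clamped to `n_gl - 1` so that
#' exactly `n_gl` bins exist (an intensity equal to the cap would otherwise
#' open a spurious extra bin). Indices are 0-based.
#'
#' @param gl numeric vector or matrix of intensities in `[0, 255]`.
#' @param cfg a [quantizer_config()].
#' @return integer bin indices in `0 .. n_gl - 1`, same shape as `gl`.
#' @export
quantize_grey <- function(gl, cfg = quantizer_config()) {
  idx <- floor(pmin(gl, cfg$gl_max) / cfg$delta_gl)
  idx <- pmin(idx, cfg$n_gl - 1L)
  if (is.matrix(gl)) matrix(as.integer(idx), nrow(gl), ncol(gl))
  else as.integer(idx)
}

#' Brightness model referencing vertebrae intensity
#'
#' @param gl_vert_mean dataset-wide reference mean of the per-image vertebrae
#'   intensity means (default 69).
#' @return a `brightness_model`.
#' @export
brightness_model <- function(gl_vert_mean = 69) {
  stopifnot(gl_vert_mean >= 0, gl_vert_mean <= 255)
  structure(list(gl_vert_mean = gl_vert_mean), class = "brightness_model")
}

#' Adjust image brightness against the vertebrae reference
#'
#' `gl = gl_orig - (gl_vert - gl_vert_mean)`, clamped to `[0, 255]`:
#' radiologists judge nucleus brightness relative to the surrounding
#' vertebrae, so each image is offset so its mean vertebrae intensity matches
#' the dataset reference. Global exposure offsets cancel exactly (up to
#' clamping saturation).
#'
#' @param image a [grey_image()] or a numeric matrix.
#' @param vert_mask logical matrix marking Vertebrae pixels.
#' @param model a [brightness_model()].
#' @return same type as `image`, brightness-adjusted.
#' @export
adjust_brightness <- function(image, vert_mask, model = brightness_model()) {
  px <- if (inherits(image, "grey_image")) image$px else image
  if (!any(vert_mask))
    stop("normalization error: empty vertebrae mask", call. = FALSE)
  gl_vert <- mean(px[vert_mask])
  adj <- pmin(pmax(px - (gl_vert - model$gl_vert_mean), 0), 255)
  if (inherits(image, "grey_image")) grey_image(adj, image$meta) else adj
}

#' Estimate the dataset reference vertebrae mean
#'
#' The mean over studies of each study's mean vertebrae intensity.
#'
#' @param studies list of lists with elements `image` ([grey_image()] or
#'   matrix) and `vert_mask` (logical matrix).
#' @return the reference mean intensity.
#' @export
estimate_reference_mean <- function(studies) {
  if (length(studies) == 0L) stop("empty dataset", call. = FALSE)
  per_study <- vapply(studies, function(s) {
    px <- if (inherits(s$image, "grey_image")) s$image$px else s$image
    mean(px[s$vert_mask])
  }, numeric(1))
  mean(per_study)
}

#' Detect the inner nucleus of a disc
#'
#' Works on the x4-upscaled brightness-adjusted image. The disc mask is first
#' eroded to 80% of its area (dropping stray boundary pixels). A threshold
#' then descends from the region maximum in steps of 5: candidate pixels are
#' those above the threshold; a candidate set is accepted once it covers at
#' least 30% of the shrunk region and its largest 8-connected component,
#' after morphological closing, covers at least 20% of the shrunk region.
#' The accepted component is eroded to 90% of its area to give the inner
#' nucleus. If the threshold reaches the region minimum without success (a
#' uniformly dark disc whose nucleus is not distinguishable from the
#' annulus), the eroded disc itself is returned with `fallback = TRUE`.
#'
#' @param image_up numeric matrix, upscaled adjusted intensities.
#' @param ivd_mask logical matrix (upscaled) of the disc region.
#' @param step threshold decrement per pass.
#' @param closing_radius radius (upscaled px) of the disc-shaped closing
#'   element.
#' @return a `nucleus_mask`: list with `mask` (logical matrix) and `fallback`.
#' @export
detect_nucleus <- function(image_up, ivd_mask, step = 5,
                           closing_radius = 4L) {
  if (!any(ivd_mask)) stop("empty IVD region", call. = FALSE)
  shrunk <- erode_to_fraction(ivd_mask, 0.80)
  area_s <- sum(shrunk)
  vals <- image_up[shrunk]
  lo <- min(vals)
  t <- max(vals)
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
  while (t > lo) {
    t <- t - step
    cand <- shrunk & image_up > t
    if (sum(cand) < 0.30 * area_s) next
    lab <- label_components(cand, connectivity = 8)
    big <- lab == 1L
    big <- binary_morph(big, "closing", brush) & ivd_mask
    if (sum(big) < 0.20 * area_s) next
    inner <- erode_to_fraction(big, 0.90)
    return(structure(list(mask = inner, fallback = FALSE),
                     class = "nucleus_mask"))
  }
  structure(list(mask = shrunk, fallback = TRUE), class = "nucleus_mask")
}

#' Self-similar colour correlogram feature
#'
#' Quantizes the masked pixels and, over every ordered pixel pair `(p, q)`
#' inside the mask at chessboard (L-infinity) distance exactly `d`,
#' accumulates counts `C[i, j]` of bin `i` at `p` co-occurring with bin `j`
#' at `q`. Each row is normalized by its pair count, making `C[i, j]` the
#' probability that a pixel at distance `d` from a bin-`i` pixel carries bin
#' `j` (rows without pairs stay zero). The feature emits the diagonal band
#' `|i - j| <= w` in row-major order; its length is
#' `N * (2w + 1) - w * (w + 1)`.
#'
#' @param image_up numeric matrix of adjusted intensities (upscaled frame).
#' @param mask logical matrix or `nucleus_mask` selecting the pixels.
#' @param cfg a [quantizer_config()] (its `n_gl` is the colour count `N`).
#' @param w band half-width (`0 <= w < N`); `w = 0` is the auto correlogram.
#' @param d correlogram distance in pixels (the x4 scaling factor by default).
#' @return an `sscc_feature`: numeric vector of band probabilities with
#'   attributes `N`, `w`, `d` and `matrix` (the full row-normalized `C`).
#' @export
sscc <- function(image_up, mask, cfg = quantizer_config(), w = 2L, d = 4L) {
  if (inherits(mask, "nucleus_mask")) mask <- mask$mask
  stopifnot(w >= 0, w < cfg$n_gl, d >= 1)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  n <- cfg$n_gl
  bins <- quantize_grey(image_up, cfg)
  bb <- mask_bbox(mask, margin = as.integer(d))
  bins <- crop_bbox(bins, bb)
  msk <- crop_bbox(mask, bb)
  counts <- matrix(0, n, n)
  nr <- nrow(msk); nc <- ncol(msk)
  for (dy in -d:d) {
    dxs <- if (abs(dy) == d) -d:d else c(-d, d)
    for (dx in dxs) {
      r1 <- max(1L, 1L - dy):min(nr, nr - dy)
      c1 <- max(1L, 1L - dx):min(nc, nc - dx)
      if (length(r1) == 0L || length(c1) == 0L) next
      m1 <- msk[r1, c1, drop = FALSE]
      m2 <- msk[r1 + dy, c1 + dx, drop = FALSE]
      both <- m1 & m2
      if (!any(both)) next
      i <- bins[r1, c1, drop = FALSE][both]
      j <- bins[r1 + dy, c1 + dx, drop = FALSE][both]
      tab <- tabulate(i * n + j + 1L, nbins = n * n)
      counts <- counts + matrix(tab, n, n, byrow = TRUE)
    }
  }
  row_tot <- rowSums(counts)
  probs <- counts / ifelse(row_tot == 0, 1, row_tot)
  feat <- numeric(0)
  for (i in 0:(n - 1L)) {
    j <- max(0L, i - w):min(n - 1L, i + w)
    feat <- c(feat, probs[i + 1L, j + 1L])
  }
  structure(feat, class = "sscc_feature",
            N = n, w = as.integer(w), d = as.integer(d), matrix = probs)
}

#' Expected length of the self-similar correlogram feature
#'
#' `len = N * (2w + 1) - w * (w + 1)`: a band of half-width `w` around the
#' diagonal of an `N` x `N` matrix.
#'
#' @param N number of colours (positive integer).
#' @param w band half-width (`0 <= w < N`).
#' @return the band cell count.
#' @export
sscc_length <- function(N, w) {
  stopifnot(N >= 1, w >= 0, w < N)
  N * (2 * w + 1) - w * (w + 1)
}

#' Extract the nucleus correlogram feature of one named disc
#'
#' Composes the feature chain for a single disc: vertebrae-referenced
#' brightness adjustment, Gaussian smoothing and x4 upscaling, nucleus
#' detection inside the disc, and the self-similar correlogram of the inner
#' nucleus.
#'
#' @param image a [grey_image()] on the 384-grid.
#' @param labels the aligned [label_map()].
#' @param named a `named_regions` from [assign_names()].
#' @param ivd_name disc to process, e.g. `"L4/L5"`.
#' @param cfg a [quantizer_config()].
#' @param w band half-width.
#' @param d correlogram distance.
#' @param model a [brightness_model()].
#' @param sigma Gaussian smoothing sigma (original-scale pixels).
#' @param prepared optional precomputed [prepare_images()] result computed
#'   from the brightness-adjusted image (shared across discs of one study).
#' @return an `sscc_feature` with attribute `fallback` from the nucleus
#'   detector.
#' @export
extract_ivd_feature <- function(image, labels, named, ivd_name,
                                cfg = quantizer_config(), w = 2L, d = 4L,
                                model = brightness_model(), sigma = 0.5,
                                prepared = NULL) {
  if (is.null(prepared)) {
    adj <- adjust_brightness(image, labels$px == REGION_CODES[["Vertebrae"]],
                             model)
    prepared <- prepare_images(adj, labels, sigma)
  }
  ivd_mask <- .upscaled_ccr_mask(named, ivd_name, prepared$labels)
  bb <- mask_bbox(ivd_mask, margin = 8L)
  nuc <- detect_nucleus(crop_bbox(prepared$image, bb),
                        crop_bbox(ivd_mask, bb))
  feat <- sscc(crop_bbox(prepared$image, bb), nuc$mask, cfg, w, d)
  attr(feat, "fallback") <- nuc$fallback
  feat
}
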