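# Geometric disc-height measurement. Phase one builds a first estimate of the
# bisecting line segment from the disc's endplate boundaries (points M_T and
# M_B); phase two refines both endpoints toward the strongest intensity
# gradient aligned with the bisecting direction. All geometry runs in the x4
# upscaled frame; points are c(x, y) with y increasing downward.

UPSCALE <- 4L

#' Smooth and upscale an image/label pair for height measurement
#'
#' Applies a low-pass Gaussian filter to the MRI image, upscales it by a
#' factor of four with cubic interpolation, and upscales the label map by the
#' same factor with nearest-neighbour interpolation.
#'
#' @param image a [grey_image()] on the 384-grid.
#' @param labels the aligned [label_map()].
#' @param sigma Gaussian smoothing sigma in original-scale pixels.
#' @return list with `image` (numeric matrix, upscaled), `labels` (integer
#'   matrix, upscaled), `meta` (the shared [image_meta()]).
#' @export
prepare_images <- function(image, labels, sigma = 0.5) {
  if (!identical(dim(image$px), dim(labels$px)))
    stop("image and label map differ in shape", call. = FALSE)
  sm <- as.matrix(EBImage::gblur(image$px, sigma = sigma))
  up <- pmin(pmax(resize_cubic(sm, nrow(sm) * UPSCALE), 0), 255)
  lab_up <- resize_nearest(labels$px, nrow(labels$px) * UPSCALE)
  list(image = up, labels = lab_up, meta = image$meta)
}

# Name of the structure below / above a named disc along the spine.
.inferior_of <- function(ivd_name) {
  switch(ivd_name, "L5/S1" = "Sacrum", "L4/L5" = "L5", "L3/L4" = "L4",
         "L2/L3" = "L3", "L1/L2" = "L2",
         stop("unknown IVD name: ", ivd_name, call. = FALSE))
}
.superior_of <- function(ivd_name) {
  switch(ivd_name, "L5/S1" = "L5", "L4/L5" = "L4", "L3/L4" = "L3",
         "L2/L3" = "L2", "L1/L2" = "L1",
         stop("unknown IVD name: ", ivd_name, call. = FALSE))
}

#' Top and bottom boundary points of a named disc
#'
#' The top boundary set holds the disc pixels 8-adjacent to the superior
#' vertebra; the bottom set those adjacent to the inferior structure (the
#' Sacrum for L5/S1, a vertebra otherwise).
#'
#' @param ivd_name disc name, e.g. `"L5/S1"`.
#' @param labels_up upscaled integer label matrix from [prepare_images()].
#' @param named a `named_regions` from [assign_names()] (original scale) used
#'   to resolve which vertebra CCR is the neighbour.
#' @return list with `top` and `bottom` point matrices (columns `x`, `y`).
#' @export
boundary_points <- function(ivd_name, labels_up, named) {
  ivd_mask <- .upscaled_ccr_mask(named, ivd_name, labels_up)
  inf_name <- .inferior_of(ivd_name)
  sup_name <- .superior_of(ivd_name)
  inf_mask <- if (inf_name == "Sacrum") {
    labels_up == REGION_CODES[["Sacrum"]]
  } else {
    .upscaled_ccr_mask(named, inf_name, labels_up)
  }
  sup_mask <- .upscaled_ccr_mask(named, sup_name, labels_up)
  top <- .mask_points(touching_pixels(ivd_mask, sup_mask))
  bottom <- .mask_points(touching_pixels(ivd_mask, inf_mask))
  if (nrow(top) == 0L || nrow(bottom) == 0L)
    stop(sprintf("geometry error: %s has an empty endplate boundary set",
                 ivd_name), call. = FALSE)
  list(top = top, bottom = bottom)
}

# An original-scale CCR rendered as a mask in the upscaled frame (block
# replication is exact nearest-neighbour x4 upscaling).
.upscaled_ccr_mask <- function(named, name, labels_up) {
  cc <- named$ccrs[[name]]
  if (is.null(cc))
    stop("geometry error: region ", name, " was not named", call. = FALSE)
  nr <- nrow(labels_up) / UPSCALE
  m <- ccr_mask(cc, c(nr, ncol(labels_up) / UPSCALE))
  m[rep(seq_len(nrow(m)), each = UPSCALE),
    rep(seq_len(ncol(m)), each = UPSCALE)]
}

.mask_points <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(x = ((idx - 1L) %/% nr) + 1L, y = ((idx - 1L) %% nr) + 1L)
}

#' Centre and best-fit line of the middle portion of a boundary
#'
#' Sorts the boundary points by x, keeps the central fraction (default the
#' middle 30%), and returns their mean coordinate together with the total
#' least squares (orthogonal regression) line through them. Orthogonal
#' regression is used so steep boundaries remain well conditioned; for
#' near-horizontal endplates it agrees with ordinary regression.
#'
#' @param points matrix with columns `x`, `y`.
#' @param fraction central fraction of points kept (by x order).
#' @return list with `centre` (c(x, y)), `direction` (unit c(x, y) along the
#'   line), `normal` (unit perpendicular).
#' @export
middle_portion_fit <- function(points, fraction = 0.30) {
  if (nrow(points) < 10L)
    stop("geometry error: fewer than 10 boundary points", call. = FALSE)
  ord <- order(points[, "x"], points[, "y"])
  n <- nrow(points)
  keep_n <- ceiling(fraction * n)
  first <- floor((n - keep_n) / 2) + 1L
  mid <- points[ord[first:(first + keep_n - 1L)], , drop = FALSE]
  if (nrow(mid) < 3L)
    stop("geometry error: fewer than 3 points in the middle portion",
         call. = FALSE)
  centre <- colMeans(mid)
  cc <- sweep(mid, 2L, centre)
  sv <- svd(cc)
  direction <- sv$v[, 1L]
  if (direction[1L] < 0) direction <- -direction  # orient +x for stability
  list(centre = c(x = unname(centre["x"]), y = unname(centre["y"])),
       direction = c(x = direction[1L], y = direction[2L]),
       normal = c(x = -direction[2L], y = direction[1L]))
}

# Intersection of the ray p + t*v with the line (q, d); returns c(x, y) or
# NULL when parallel.
.ray_line_intersection <- function(p, v, q, d) {
  det <- v[1L] * (-d[2L]) - v[2L] * (-d[1L])
  if (abs(det) < 1e-12) return(NULL)
  rhs <- q - p
  t <- (rhs[1L] * (-d[2L]) - rhs[2L] * (-d[1L])) / det
  p + t * v
}

#' First estimate of the bisecting line segment
#'
#' Builds the geometry bundle of the disc's bisecting segment: perpendicular
#' vectors v_T and v_B of the two endplate fits (oriented into the disc),
#' the projected points C'_T (ray from C_T along v_T onto the bottom fit line)
#' and C'_B (ray from C_B along v_B onto the top fit line), and the initial
#' endpoints M_T = midpoint(C_T, C'_B), M_B = midpoint(C_B, C'_T).
#'
#' @param top_fit,bottom_fit fits from [middle_portion_fit()].
#' @param interior a point c(x, y) inside the disc (e.g. its centroid), used
#'   to orient the perpendiculars into the disc.
#' @return a `bisect_segment`: list with `C_T`, `C_B`, `Cp_T`, `Cp_B`, `v_T`,
#'   `v_B`, `M_T`, `M_B` (and, after refinement, `Mp_T`, `Mp_B`).
#' @export
initial_bisect <- function(top_fit, bottom_fit, interior) {
  orient <- function(fit) {
    v <- fit$normal
    if (sum(v * (interior - fit$centre)) < 0) -v else v
  }
  v_t <- orient(top_fit)
  v_b <- orient(bottom_fit)
  cp_t <- .ray_line_intersection(top_fit$centre, v_t,
                                 bottom_fit$centre, bottom_fit$direction)
  cp_b <- .ray_line_intersection(bottom_fit$centre, v_b,
                                 top_fit$centre, top_fit$direction)
  if (is.null(cp_t) || is.null(cp_b))
    stop("geometry error: endplate ray parallel to the opposite fit line",
         call. = FALSE)
  structure(list(C_T = top_fit$centre, C_B = bottom_fit$centre,
                 Cp_T = cp_t, Cp_B = cp_b, v_T = v_t, v_B = v_b,
                 M_T = (top_fit$centre + cp_b) / 2,
                 M_B = (bottom_fit$centre + cp_t) / 2),
            class = "bisect_segment")
}

#' Prewitt gradient magnitude and direction field
#'
#' 3x3 Prewitt kernels; the direction `beta` is `atan2(gy, gx)` in degrees
#' wrapped to (-180, 180], in the y-down image convention.
#'
#' @param image numeric matrix (typically the upscaled smoothed MRI).
#' @return a `gradient_field`: list with matrices `magnitude` and `beta`.
#' @export
prewitt_field <- function(image) {
  # sh(dr, dc)[r, c] == image[r + dr, c + dc], border replicated
  sh <- function(dr, dc) {
    nr <- nrow(image); nc <- ncol(image)
    src_r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    src_c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    image[src_r, src_c, drop = FALSE]
  }
  gx <- (sh(-1L, 1L) + sh(0L, 1L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + sh(1L, 0L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + sh(-1L, 0L) + sh(-1L, 1L))
  structure(list(magnitude = sqrt(gx^2 + gy^2),
                 beta = wrap_angle(atan2(gy, gx) * 180 / pi)),
            class = "gradient_field")
}

#' Refine a bisecting-segment endpoint along the gradient field
#'
#' Rasterizes the search segment from `A = M - u` to `B = M + k * u`
#' (`u = v / |v|`) with Bresenham's algorithm and scores every pixel `p` on it
#' by `b_p = cos(beta_p - alpha) * m_p`, where `alpha` is the angle of `u`.
#' The pixel with the highest score is returned; ties go to the pixel closest
#' to `M`. When no pixel scores above `min_score` there is no gradient edge
#' aligned with the search direction anywhere on the segment and the initial
#' geometric estimate `M` is kept; the default floor is the Prewitt response
#' to a one-grey-level step (3), the smallest edge the 8-bit intensity scale
#' can express, so sub-quantization ripple never displaces an endpoint.
#'
#' @param M initial point c(x, y) in the upscaled frame.
#' @param v search direction vector (not necessarily unit length).
#' @param field a `gradient_field` from [prewitt_field()].
#' @param k search range in upscaled pixels (>= 1).
#' @param min_score smallest acceptable aligned-gradient score.
#' @return the refined point c(x, y).
#' @export
refine_endpoint <- function(M, v, field, k = 8L, min_score = 3) {
  stopifnot(k >= 1)
  u <- v / sqrt(sum(v^2))
  alpha <- atan2(u[2L], u[1L]) * 180 / pi
  seg <- bresenham_line(M - u, M + k * u)
  nr <- nrow(field$magnitude); nc <- ncol(field$magnitude)
  ok <- seg[, "x"] >= 1L & seg[, "x"] <= nc &
    seg[, "y"] >= 1L & seg[, "y"] <= nr
  seg <- seg[ok, , drop = FALSE]
  if (nrow(seg) == 0L)
    stop("geometry error: search segment lies outside the image",
         call. = FALSE)
  ind <- cbind(seg[, "y"], seg[, "x"])
  delta <- wrap_angle(field$beta[ind] - alpha)
  b <- cos(delta * pi / 180) * field$magnitude[ind]
  if (max(b) <= min_score) return(c(x = unname(M[1L]), y = unname(M[2L])))
  # pixels scoring within 2% of the maximum straddle the same smoothed edge
  # (a gradient plateau): treat them as tied and resolve toward M
  best <- which(b >= max(b) * 0.98)
  if (length(best) > 1L) {
    d2 <- (seg[best, "x"] - M[1L])^2 + (seg[best, "y"] - M[2L])^2
    best <- best[which.min(d2)]
  }
  c(x = unname(seg[best, "x"]), y = unname(seg[best, "y"]))
}

#' Disc height from a refined bisecting segment
#'
#' `height_mm = ||M'_T - M'_B|| * ps' / 4`: the Euclidean length of the
#' refined segment in upscaled pixels, converted to millimetres with the
#' rescaled pixel spacing and divided by the upscaling factor.
#'
#' @param segment a `bisect_segment` carrying `Mp_T` and `Mp_B`.
#' @param meta an [image_meta()].
#' @return height in millimetres.
#' @export
measure_height <- function(segment, meta) {
  if (is.null(segment$Mp_T) || is.null(segment$Mp_B))
    stop("refined endpoints are not set", call. = FALSE)
  d <- sqrt(sum((segment$Mp_T - segment$Mp_B)^2))
  d * meta$rescaled_spacing / UPSCALE
}

#' Measure the heights of named discs
#'
#' Runs the full two-phase measurement for each requested disc: endplate
#' boundary extraction, middle-portion fits, initial bisecting segment,
#' Prewitt-gradient refinement of both endpoints, and conversion to
#' millimetres.
#'
#' @param image a [grey_image()] on the 384-grid.
#' @param labels the aligned [label_map()].
#' @param named a `named_regions` from [assign_names()].
#' @param which_ivds disc names to measure; defaults to all named discs.
#' @param k gradient search range in upscaled pixels.
#' @param sigma Gaussian smoothing sigma (original-scale pixels).
#' @param prepared optional precomputed [prepare_images()] result.
#' @return a `height_result` data frame: `ivd_name`, `height_mm`, `k`, and
#'   the refined endpoint coordinates (upscaled frame), with the segment
#'   geometry in attribute `segments`.
#' @export
measure_ivd_heights <- function(image, labels, named,
                                which_ivds = NULL, k = 8L, sigma = 0.5,
                                prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_images(image, labels, sigma)
  ivds <- named$table$name[named$table$region == "IVD"]
  if (!is.null(which_ivds)) ivds <- intersect(which_ivds, ivds)
  segments <- list()
  rows <- lapply(ivds, function(nm) {
    seg <- .measure_one_disc(nm, prepared, named, k)
    segments[[nm]] <<- seg
    data.frame(ivd_name = nm,
               height_mm = measure_height(seg, prepared$meta),
               k = as.integer(k),
               mT_x = seg$Mp_T[1L], mT_y = seg$Mp_T[2L],
               mB_x = seg$Mp_B[1L], mB_y = seg$Mp_B[2L])
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("height_result", "data.frame"),
            segments = segments)
}

.measure_one_disc <- function(ivd_name, prepared, named, k) {
  bp <- boundary_points(ivd_name, prepared$labels, named)
  top_fit <- middle_portion_fit(bp$top)
  bottom_fit <- middle_portion_fit(bp$bottom)
  ivd_mask <- .upscaled_ccr_mask(named, ivd_name, prepared$labels)
  centroid <- colMeans(.mask_points(ivd_mask))
  seg <- initial_bisect(top_fit, bottom_fit, centroid)
  # cap the search so the two endpoint searches cannot cross the segment
  # midpoint (matters for discs thinner than 2k upscaled pixels)
  init_len <- sqrt(sum((seg$M_T - seg$M_B)^2))
  k_eff <- max(1L, min(as.integer(k), as.integer(floor(init_len / 2))))
  # gradient field on a crop around the disc: gradients are local
  bb <- mask_bbox(ivd_mask, margin = as.integer(k + 12L))
  field <- prewitt_field(prepared$image[bb$r1:bb$r2, bb$c1:bb$c2,
                                        drop = FALSE])
  shift <- c(x = bb$c1 - 1L, y = bb$r1 - 1L)
  seg$Mp_T <- refine_endpoint(seg$M_T - shift, seg$v_T, field, k_eff) + shift
  seg$Mp_B <- refine_endpoint(seg$M_B - shift, seg$v_B, field, k_eff) + shift
  seg
}
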