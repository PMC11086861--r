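# Low-level binary-image utilities shared by the label-map, topology and
# feature modules. Masks are logical matrices [row, col].

#' Label connected components of a binary mask
#'
#' Components are computed over the pixel-adjacency graph, so the foreground
#' connectivity is explicit: 8-connectivity is used for anatomical regions and
#' 4-connectivity for background/hole detection (standard dual connectivity).
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in decreasing area order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  nr <- nrow(mask)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))             # down, right
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- row_i + o[1L]; c2 <- col_i + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    from <- c(from, id[idx[ok]][hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber components by decreasing area for a stable, useful order
  sizes <- tabulate(memb)
  rank <- integer(length(sizes))
  rank[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  out[idx] <- rank[memb]
  out
}

# Bounding box of a mask: list(r1, r2, c1, c2); NULL for an empty mask.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  list(r1 = max(1L, min(r) - margin), r2 = min(nr, max(r) + margin),
       c1 = max(1L, min(c) - margin), c2 = min(ncol(mask), max(c) + margin))
}

crop_bbox <- function(m, bb) m[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]

#' Find hole pixels of a binary mask
#'
#' Holes are 4-connected background components that do not touch the image
#' border (the dual of 8-connected foreground).
#'
#' @param mask logical matrix.
#' @return logical matrix marking hole pixels.
#' @export
find_holes <- function(mask) {
  bb <- mask_bbox(mask, margin = 1L)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (is.null(bb)) return(out)
  sub <- crop_bbox(mask, bb)
  lab <- label_components(!sub, connectivity = 4)
  if (max(lab) == 0L) return(out)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  hole <- lab > 0L & !(lab %in% border)
  out[bb$r1:bb$r2, bb$c1:bb$c2] <- hole
  out
}

# Dilate/erode wrappers over EBImage working on logical matrices, cropped to
# the mask bounding box for speed.
binary_morph <- function(mask, op = c("dilate", "erode", "closing"),
                         brush = EBImage::makeBrush(3, shape = "box")) {
  op <- match.arg(op)
  pad <- as.integer(max(dim(brush)))
  bb <- mask_bbox(mask, margin = pad)
  if (is.null(bb)) return(mask)
  sub <- crop_bbox(mask, bb) * 1
  f <- switch(op, dilate = EBImage::dilate, erode = EBImage::erode,
              closing = EBImage::closing)
  res <- as.matrix(f(sub, brush)) > 0.5
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[bb$r1:bb$r2, bb$c1:bb$c2] <- res
  out
}

# Pixels of `mask` that are 8-adjacent to `other` (both logical matrices).
touching_pixels <- function(mask, other) {
  mask & binary_morph(other, "dilate")
}

# Erode a mask iteratively with a 3x3 box until its area is <= frac of the
# starting area; never erodes to emptiness (returns the last nonempty mask).
erode_to_fraction <- function(mask, frac) {
  target <- sum(mask) * frac
  cur <- mask
  while (sum(cur) > target) {
    nxt <- binary_morph(cur, "erode")
    if (!any(nxt)) break
    cur <- nxt
  }
  cur
}

# Integer Bresenham rasterization of the segment between points a and b,
# given as c(x, y). Returns a matrix with columns x, y (includes endpoints).
bresenham_line <- function(a, b) {
  x0 <- round(a[1]); y0 <- round(a[2]); x1 <- round(b[1]); y1 <- round(b[2])
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs, y = ys)
}

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}
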