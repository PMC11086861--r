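# Spine centerline topology: morphological thinning of the merged
# Sacrum + Vertebrae + IVD region, bottom-up ordering of the one-pixel line by
# A* pathfinding, and anatomical naming of discs and vertebrae in traversal
# order.

# .shift_mat(m, dr, dc)[r, c] == m[r + dr, c + dc] (FALSE beyond the border)
.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) + dr
  src_c <- seq_len(nc) + dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Zhang-Suen thinning of a logical matrix; preserves 8-connectivity and
# reduces a region to a unit-width skeleton.
zhang_suen_thin <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours in the y-down image convention: P2 = north ... P9 = NW
      p2 <- .shift_mat(m, -1L, 0L); p3 <- .shift_mat(m, -1L, 1L)
      p4 <- .shift_mat(m, 0L, 1L);  p5 <- .shift_mat(m, 1L, 1L)
      p6 <- .shift_mat(m, 1L, 0L);  p7 <- .shift_mat(m, 1L, -1L)
      p8 <- .shift_mat(m, 0L, -1L); p9 <- .shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (pass == 1L) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Count of foreground 8-neighbours for every pixel.
.neighbour_count <- function(mask) {
  .shift_mat(mask, -1L, 0L) + .shift_mat(mask, -1L, 1L) +
    .shift_mat(mask, 0L, 1L) + .shift_mat(mask, 1L, 1L) +
    .shift_mat(mask, 1L, 0L) + .shift_mat(mask, 1L, -1L) +
    .shift_mat(mask, 0L, -1L) + .shift_mat(mask, -1L, -1L)
}

#' Extract the one-pixel spine line of a label map
#'
#' Merges all Sacrum, Vertebrae and IVD pixels into one region and reduces it
#' to a unit-width 8-connected skeleton by morphological thinning
#' (Zhang-Suen). Endpoints are foreground pixels with exactly one foreground
#' 8-neighbour; thinning of a real spine column typically yields two true
#' endpoints plus possible branch endpoints.
#'
#' @param labels a post-processed [label_map()].
#' @return a `spine_skeleton`: list with `mask` (logical matrix) and
#'   `endpoints` (matrix with columns `x`, `y`).
#' @export
extract_skeleton <- function(labels) {
  merged <- labels$px == REGION_CODES["Vertebrae"] |
    labels$px == REGION_CODES["IVD"] |
    labels$px == REGION_CODES["Sacrum"]
  if (!any(merged))
    stop("topology error: merged spine region is empty", call. = FALSE)
  comp <- label_components(merged, connectivity = 8)
  if (max(comp) > 1L)
    stop("topology error: merged spine region is disconnected", call. = FALSE)
  bb <- mask_bbox(merged, margin = 1L)
  sub <- zhang_suen_thin(crop_bbox(merged, bb))
  skel <- matrix(FALSE, nrow(merged), ncol(merged))
  skel[bb$r1:bb$r2, bb$c1:bb$c2] <- sub
  structure(list(mask = skel, endpoints = skeleton_endpoints(skel)),
            class = "spine_skeleton")
}

#' Endpoints of a skeleton mask
#'
#' @param mask logical skeleton matrix.
#' @return matrix with columns `x` (col) and `y` (row), one row per endpoint.
#' @export
skeleton_endpoints <- function(mask) {
  ends <- mask & .neighbour_count(mask) == 1L
  idx <- which(ends)
  nr <- nrow(mask)
  cbind(x = ((idx - 1L) %/% nr) + 1L, y = ((idx - 1L) %% nr) + 1L)
}

#' Order the spine line bottom-up with A* pathfinding
#'
#' The start endpoint is the lowest skeleton endpoint (largest y; ties broken
#' by largest x) and the finish the topmost (smallest y; ties by smallest x).
#' A* runs over foreground pixels with 8-connected moves costing 1 (axial) or
#' sqrt(2) (diagonal) under the Euclidean heuristic. Skeleton pixels off the
#' optimal path (branches) are discarded. On a unit-width skeleton the result
#' equals the unique simple path between the two endpoints, so any complete
#' pathfinding algorithm would give the same sequence.
#'
#' @param skeleton a `spine_skeleton` from [extract_skeleton()].
#' @return a `spine_path`: list with `points` (matrix, columns `x`, `y`,
#'   ordered start to finish), `start`, `finish`.
#' @export
order_path <- function(skeleton) {
  ep <- skeleton$endpoints
  if (is.null(ep) || nrow(ep) < 2L)
    stop("topology error: fewer than two skeleton endpoints", call. = FALSE)
  start <- ep[order(-ep[, "y"], -ep[, "x"])[1L], ]
  finish <- ep[order(ep[, "y"], ep[, "x"])[1L], ]
  pts <- .astar_path(skeleton$mask, start, finish)
  if (is.null(pts))
    stop("topology error: no path between start and finish endpoints",
         call. = FALSE)
  structure(list(points = pts, start = start, finish = finish),
            class = "spine_path")
}

# A* over the foreground pixels of a logical matrix; a and b are c(x, y).
# Returns the ordered point matrix or NULL when unreachable.
.astar_path <- function(mask, a, b) {
  nr <- nrow(mask)
  idx <- which(mask)
  id_of <- matrix(0L, nr, ncol(mask))
  id_of[idx] <- seq_along(idx)
  px <- ((idx - 1L) %/% nr) + 1L  # x = col
  py <- ((idx - 1L) %% nr) + 1L   # y = row
  n <- length(idx)
  sid <- id_of[a["y"], a["x"]]
  fid <- id_of[b["y"], b["x"]]
  if (sid == 0L || fid == 0L) return(NULL)
  g <- rep(Inf, n); f <- rep(Inf, n)
  came <- integer(n)
  open <- rep(FALSE, n); closed <- rep(FALSE, n)
  h <- function(i) sqrt((px[i] - b["x"])^2 + (py[i] - b["y"])^2)
  g[sid] <- 0; f[sid] <- h(sid); open[sid] <- TRUE
  offs <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  step_cost <- ifelse(abs(offs[, 1]) + abs(offs[, 2]) == 2, sqrt(2), 1)
  while (any(open)) {
    cand <- which(open)
    cur <- cand[which.min(f[cand])]
    if (cur == fid) {
      seq_ids <- cur
      while (came[cur] != 0L) {
        cur <- came[cur]
        seq_ids <- c(cur, seq_ids)
      }
      return(cbind(x = px[seq_ids], y = py[seq_ids]))
    }
    open[cur] <- FALSE; closed[cur] <- TRUE
    nx <- px[cur] + offs[, "dx"]
    ny <- py[cur] + offs[, "dy"]
    ok <- nx >= 1L & nx <= ncol(mask) & ny >= 1L & ny <= nr
    for (k in which(ok)) {
      nid <- id_of[ny[k], nx[k]]
      if (nid == 0L || closed[nid]) next
      tg <- g[cur] + step_cost[k]
      if (tg < g[nid]) {
        g[nid] <- tg
        f[nid] <- tg + h(nid)
        came[nid] <- cur
        open[nid] <- TRUE
      }
    }
  }
  NULL
}

IVD_NAMES <- c("L5/S1", "L4/L5", "L3/L4", "L2/L3", "L1/L2")
VERT_NAMES <- c("L5", "L4", "L3", "L2", "L1")

# Runs of `codes == code` along the path, merging runs separated by at most
# `gap` other-coded points (guards against single-pixel label noise on the
# line). Interruptions carrying a `protect` code are never bridged: a run of
# IVD points between two vertebra runs is a real (possibly collapsed) disc,
# not noise, whereas vertebrae are never thin enough to be crossed in two
# points. Returns a list of c(start, end) index pairs.
.code_runs <- function(codes, code, gap = 2L, protect = integer(0)) {
  r <- rle(codes == code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(c, starts[r$values], ends[r$values])
  if (length(runs) <= 1L) return(runs)
  merged <- list(runs[[1L]])
  for (i in 2:length(runs)) {
    last <- merged[[length(merged)]]
    gap_idx <- seq.int(last[2L] + 1L, runs[[i]][1L] - 1L)
    bridgeable <- length(gap_idx) <= gap &&
      !any(codes[gap_idx] %in% protect)
    if (bridgeable) {
      merged[[length(merged)]] <- c(last[1L], runs[[i]][2L])
    } else {
      merged[[length(merged) + 1L]] <- runs[[i]]
    }
  }
  merged
}

#' Assign anatomical names to IVD and vertebra regions
#'
#' Walks the ordered spine path bottom-up and records the region code under
#' each point. Each maximal run of IVD points (runs interrupted by at most two
#' non-IVD points are treated as one) is matched to the IVD CCR containing it
#' and receives the next name in L5/S1, L4/L5, L3/L4, L2/L3, L1/L2 order;
#' vertebra runs likewise receive L5 ... L1. Sacrum points are skipped.
#'
#' @param path a `spine_path` from [order_path()].
#' @param labels the [label_map()] the path was derived from.
#' @return a `named_regions`: list with `table` (data frame: `name`, `region`,
#'   `area_px`, `truncated`) and `ccrs` (list of `ccr` objects keyed by name).
#' @export
assign_names <- function(path, labels) {
  pts <- path$points
  codes <- labels$px[cbind(pts[, "y"], pts[, "x"])]
  ivd_runs <- .code_runs(codes, REGION_CODES[["IVD"]])
  vert_runs <- .code_runs(codes, REGION_CODES[["Vertebrae"]],
                          protect = REGION_CODES[["IVD"]])
  if (length(ivd_runs) == 0L)
    stop("anatomy error: no IVD region encountered along the spine line",
         call. = FALSE)
  if (length(ivd_runs) > 5L)
    stop(sprintf("anatomy error: %d IVD regions encountered, at most 5 named",
                 length(ivd_runs)), call. = FALSE)
  if (length(vert_runs) > 5L)
    stop(sprintf(
      "anatomy error: %d vertebra regions encountered, at most 5 named",
      length(vert_runs)), call. = FALSE)

  dims <- dim(labels$px)
  all_ccrs <- list()
  ccr_for_run <- function(run, code) {
    ccrs <- find_ccrs(labels, code)
    pos <- run[1L]:run[2L]
    pos <- pos[codes[pos] == code]
    pix <- (pts[pos, "x"] - 1L) * dims[1L] + pts[pos, "y"]
    hit <- vapply(ccrs, function(cc) sum(pix %in% cc$pixels), integer(1))
    ccrs[[which.max(hit)]]
  }
  rows <- list()
  add_named <- function(runs, code, names_pool) {
    for (i in seq_along(runs)) {
      cc <- ccr_for_run(runs[[i]], code)
      nm <- names_pool[i]
      truncated <- cc$bbox$r1 == 1L || cc$bbox$r2 == dims[1L] ||
        cc$bbox$c1 == 1L || cc$bbox$c2 == dims[2L]
      rows[[length(rows) + 1L]] <<- data.frame(
        name = nm, region = region_name(code), area_px = cc$area,
        truncated = truncated)
      all_ccrs[[nm]] <<- cc
    }
  }
  add_named(ivd_runs, REGION_CODES[["IVD"]], IVD_NAMES)
  add_named(vert_runs, REGION_CODES[["Vertebrae"]], VERT_NAMES)
  structure(list(table = do.call(rbind, rows), ccrs = all_ccrs),
            class = "named_regions")
}

#' @export
print.named_regions <- function(x, ...) {
  print.data.frame(x$table)
  invisible(x)
}

#' Serialize named regions to JSON
#'
#' @param nr a `named_regions` from [assign_names()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
named_regions_json <- function(nr, path = NULL) {
  items <- lapply(seq_len(nrow(nr$table)), function(i) {
    cc <- nr$ccrs[[nr$table$name[i]]]
    list(name = nr$table$name[i], code = nr$table$region[i],
         area_px = cc$area,
         bbox = unlist(cc$bbox), truncated = nr$table$truncated[i])
  })
  if (is.null(path))
    return(jsonlite::toJSON(items, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(jsonlite::toJSON(items, auto_unbox = TRUE, digits = NA))
}
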