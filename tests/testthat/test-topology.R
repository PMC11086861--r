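test_that("thinning reduces a strip to a unit-width line and keeps thin lines", {
  strip <- matrix(FALSE, 60, 30)
  strip[10:50, 11:19] <- TRUE                    # 9-px-wide vertical strip
  sk <- spinemark:::zhang_suen_thin(strip)
  expect_true(all(strip[sk]))                    # skeleton inside the strip
  # unit width: no row of the skeleton's central section has >1 pixel
  mid_rows <- 20:40
  expect_true(all(rowSums(sk[mid_rows, ]) == 1L))
  # centred in the strip
  expect_true(all(abs(which(sk[30, ]) - 15) <= 1))

  line <- matrix(FALSE, 20, 20)
  line[3:17, 10] <- TRUE
  expect_identical(spinemark:::zhang_suen_thin(line), line)  # already thin
})

test_that("skeleton extraction needs a connected merged region", {
  lm <- toy_label_map()
  sk <- extract_skeleton(lm)
  expect_true(nrow(sk$endpoints) >= 2L)
  expect_true(all(lm$px[sk$mask] %in%
                    c(RC[["Vertebrae"]], RC[["IVD"]], RC[["Sacrum"]])))

  empty <- label_map(matrix(RC[["Anterior"]], 30, 30))
  expect_error(extract_skeleton(empty), "empty")

  split <- toy_label_map()
  split$px[33:34, ] <- RC[["Anterior"]]          # cut the column in two
  expect_error(extract_skeleton(split), "disconnected")
})

test_that("A* ordering matches the unique simple path and prunes branches", {
  mask <- matrix(FALSE, 50, 20)
  mask[5:44, 10] <- TRUE                          # straight 40-px line
  sk <- structure(list(mask = mask, endpoints = skeleton_endpoints(mask)),
                  class = "spine_skeleton")
  p <- order_path(sk)
  expect_equal(nrow(p$points), 40L)
  expect_true(all(diff(p$points[, "y"]) == -1L))  # monotone bottom-up
  expect_equal(unname(p$start), c(10, 44))
  expect_equal(unname(p$finish), c(10, 5))

  # add a 5-px lateral branch: path must exclude exactly those pixels
  branched <- mask
  branched[25, 11:15] <- TRUE
  skb <- structure(list(mask = branched,
                        endpoints = skeleton_endpoints(branched)),
                   class = "spine_skeleton")
  pb <- order_path(skb)
  expect_equal(nrow(pb$points), 40L)
  expect_false(any(pb$points[, "x"] > 10))

  # oracle: dense Dijkstra minimal cost over the same move set; the A* path
  # must be valid (8-adjacent, no repeats) and of minimal total cost
  dijkstra_cost <- function(mask, from, to) {
    pts <- which(mask, arr.ind = TRUE)            # row, col
    n <- nrow(pts)
    id <- function(p) which(pts[, 1] == p[2] & pts[, 2] == p[1])
    dist <- rep(Inf, n); dist[id(from)] <- 0
    done <- rep(FALSE, n)
    repeat {
      open <- which(!done & is.finite(dist))
      if (length(open) == 0) break
      u <- open[which.min(dist[open])]
      done[u] <- TRUE
      dr <- abs(pts[, 1] - pts[u, 1]); dc <- abs(pts[, 2] - pts[u, 2])
      nb <- which(pmax(dr, dc) == 1 & !done)
      step <- ifelse(dr[nb] + dc[nb] == 2, sqrt(2), 1)
      dist[nb] <- pmin(dist[nb], dist[u] + step)
    }
    dist[id(to)]
  }
  path_cost <- function(points) {
    d <- diff(points)
    steps <- pmax(abs(d[, 1]), abs(d[, 2]))
    stopifnot(all(steps == 1))                     # valid 8-adjacent moves
    sum(ifelse(abs(d[, 1]) + abs(d[, 2]) == 2, sqrt(2), 1))
  }
  expect_equal(path_cost(pb$points),
               dijkstra_cost(branched, pb$start, pb$finish),
               tolerance = 1e-9)
  expect_false(any(duplicated(pb$points)))

  lonely <- matrix(FALSE, 10, 10); lonely[5, 5] <- TRUE
  skl <- structure(list(mask = lonely, endpoints = skeleton_endpoints(lonely)),
                   class = "spine_skeleton")
  expect_error(order_path(skl), "fewer than two")
})

test_that("traversal names discs and vertebrae bottom-up from L5/S1 and L5", {
  for (n in c(3L, 5L)) {
    st <- quiet_phantom(seed = 20 + n, n = n, grades = rep_len(c(2, 3, 1), n))
    nm <- assign_names(order_path(extract_skeleton(st$labels)), st$labels)
    ivds <- nm$table$name[nm$table$region == "IVD"]
    verts <- nm$table$name[nm$table$region == "Vertebrae"]
    expect_equal(ivds, st$truth$name)
    expect_equal(verts, st$vertebra_names)
  }
  # five-disc stack ends at L1/L2
  st5 <- quiet_phantom(seed = 33, n = 5, grades = c(1, 2, 3, 4, 2))
  nm5 <- assign_names(order_path(extract_skeleton(st5$labels)), st5$labels)
  expect_equal(nm5$table$name[nm5$table$region == "IVD"][5], "L1/L2")

  # a path that never leaves the Sacrum is an anatomy error
  lm <- toy_label_map()
  sac_path <- structure(list(
    points = cbind(x = rep(30L, 6), y = 56:51),
    start = c(x = 30, y = 56), finish = c(x = 30, y = 51)),
    class = "spine_path")
  expect_error(assign_names(sac_path, lm), "anatomy error")
})

test_that("naming is invariant to skeleton branches from lateral bumps", {
  base <- quiet_phantom(seed = 77, n = 4, grades = c(2, 3, 2, 1), n_bumps = 0)
  bumped <- quiet_phantom(seed = 77, n = 4, grades = c(2, 3, 2, 1),
                          n_bumps = 2)
  name_of <- function(st) {
    nm <- assign_names(order_path(extract_skeleton(st$labels)), st$labels)
    nm$table$name
  }
  expect_equal(name_of(bumped), name_of(base))
})
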