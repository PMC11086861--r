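test_that("connected components follow 8-connectivity", {
  m <- matrix(0L, 12, 12)
  m[2:6, 2:6] <- RC[["IVD"]]
  lm <- label_map(m)
  ccrs <- find_ccrs(lm, RC[["IVD"]])
  expect_length(ccrs, 1L)
  expect_equal(ccrs[[1]]$area, 25L)

  m2 <- matrix(0L, 12, 12)
  m2[2:4, 2:4] <- RC[["IVD"]]
  m2[5:7, 5:7] <- RC[["IVD"]]           # touching only diagonally
  expect_length(find_ccrs(label_map(m2), RC[["IVD"]]), 1L)

  m3 <- matrix(0L, 12, 12)
  m3[1:2, 1:2] <- RC[["Vertebrae"]]
  m3[5:6, 5:6] <- RC[["Vertebrae"]]
  m3[9:10, 9:10] <- RC[["Vertebrae"]]
  expect_length(find_ccrs(label_map(m3), RC[["Vertebrae"]]), 3L)
})

test_that("hole detection uses 4-connected enclosed background", {
  m <- matrix(FALSE, 9, 9)
  m[2:6, 2:6] <- TRUE
  m[4, 4] <- FALSE
  holes <- find_holes(m)
  expect_equal(sum(holes), 1L)
  expect_true(holes[4, 4])
  # an open concavity is not a hole
  cshape <- matrix(FALSE, 9, 9)
  cshape[2:8, 2:4] <- TRUE
  cshape[2:3, 4:8] <- TRUE
  cshape[7:8, 4:8] <- TRUE
  expect_false(any(find_holes(cshape)))
})

test_that("validation flags each labeling-requirement violation", {
  lm <- toy_label_map()
  expect_equal(nrow(validate_labelmap(lm)), 0L)

  two_ant <- lm
  two_ant$px[5:8, 25:30] <- RC[["Anterior"]]   # islands inside Vertebrae band?
  two_ant$px[5:8, 25:30] <- RC[["Anterior"]]
  # put a second Anterior CCR inside PosteriorB, away from the main one
  two_ant <- lm
  two_ant$px[3:5, 55:58] <- RC[["Anterior"]]
  rep1 <- validate_labelmap(two_ant)
  expect_true(1L %in% rep1$rule)

  swapped <- lm
  swapped$px[46:50, 21:40] <- RC[["Vertebrae"]]  # vertebra just above sacrum
  swapped$px[36:45, 21:40] <- RC[["IVD"]]
  rep6 <- validate_labelmap(swapped)
  expect_true(6L %in% rep6$rule)

  holed <- lm
  holed$px[40, 30] <- RC[["IVD"]]  # a 1-px IVD hole inside a vertebra
  repv <- validate_labelmap(holed)
  expect_true(any(repv$rule %in% c(5L, 6L)))
})

test_that("fill_holes closes interior holes and leaves concavities alone", {
  lm <- toy_label_map()
  lm$px[40, 30] <- 0L                           # hole in a vertebra CCR
  cc <- find_ccrs(lm, RC[["Vertebrae"]])
  has_hole <- vapply(cc, function(x) x$bbox$r1 <= 40 && x$bbox$r2 >= 40,
                     logical(1))
  target <- cc[[which(has_hole)[1]]]
  filled <- fill_holes(target, lm)
  expect_equal(filled$px[40, 30], RC[["Vertebrae"]])
  expect_identical(fill_holes(target, filled)$px, filled$px)  # idempotent
})

test_that("merge uses the boundary mode with smallest-code tie-break", {
  # fragment bordered 60/40 by Vertebrae and Anterior -> Vertebrae
  m <- matrix(RC[["Anterior"]], 20, 20)
  m[8:12, 8:12] <- RC[["Vertebrae"]]
  m[9:11, 9:11] <- RC[["IVD"]]
  m[8, 9:11] <- RC[["Anterior"]]  # erode the vertebra above the fragment
  lm <- label_map(m)
  frag <- find_ccrs(lm, RC[["IVD"]])[[1]]
  merged <- merge_ccr_into_surrounding(frag, lm)
  expect_false(any(merged$px == RC[["IVD"]]))
  expect_equal(merged$px[10, 10], RC[["Vertebrae"]])

  # exact 50/50 ring split between codes 1 and 4 -> smallest code (1)
  m2 <- matrix(0L, 7, 7)
  m2[, 1:3] <- RC[["Anterior"]]
  m2[, 5:7] <- RC[["Vertebrae"]]
  m2[, 4] <- RC[["IVD"]]
  lm2 <- label_map(m2)
  frag2 <- find_ccrs(lm2, RC[["IVD"]])[[1]]
  merged2 <- merge_ccr_into_surrounding(frag2, lm2)
  # ring: 7 Anterior + 7 Vertebrae pixels -> tie -> code 1
  expect_true(all(merged2$px[, 4] == RC[["Anterior"]]))
})

test_that("postprocess merges sub-20-px fragments and keeps 20-px CCRs", {
  lm <- toy_label_map()
  frag <- lm
  frag$px[5:8, 5:9] <- RC[["IVD"]]      # 20-px detached IVD inside Anterior
  frag$px[8, 9] <- RC[["Anterior"]]     # now 19 px
  out <- postprocess_labelmap(frag)
  expect_false(any(out$px[5:8, 5:9] == RC[["IVD"]]))

  attached <- lm
  # 4x5 = 20-px IVD block attached to the main column stays
  attached$px[17:20, 25:29] <- RC[["IVD"]]
  out2 <- postprocess_labelmap(attached)
  expect_true(any(out2$px[17:20, 25:29] == RC[["IVD"]]))

  expect_identical(postprocess_labelmap(lm)$px, lm$px)  # fixed point
  expect_error(postprocess_labelmap(label_map(matrix(1L, 10, 10))), "Sacrum")
})

test_that("postprocess repairs a corrupted map to a valid fixed point", {
  st <- quiet_phantom(seed = 9, n = 4, grades = c(1, 2, 3, 4))
  lm <- st$labels
  lm$px[40, 100] <- RC[["IVD"]]               # stray 1-px IVD in Anterior
  lm$px[200, 30:32] <- RC[["PosteriorB"]]     # stray PosteriorB fragment? no:
  lm$px[200, 30:32] <- RC[["Anterior"]]       # keep it simple: revert
  lm$px[150, 150] <- 0L                        # unassigned pinhole
  lm$px[150, 150] <- RC[["Vertebrae"]]         # 1-px vertebra in Anterior
  pp <- postprocess_labelmap(lm)
  expect_equal(nrow(validate_labelmap(pp)), 0L)
  expect_identical(postprocess_labelmap(pp)$px, pp$px)
})

test_that("segmentation scores match a per-pixel oracle and the mean rule", {
  st <- quiet_phantom(seed = 4)
  s <- seg_scores(st$labels, st$labels)
  expect_true(all(abs(s$accuracy - 100) < 1e-9))
  expect_true(all(abs(s$iou - 100) < 1e-9))
  expect_equal(attr(s, "mean_score"), 100)

  # brute-force accuracy/IoU oracle on small random maps
  set.seed(11)
  for (i in 1:5) {
    a <- label_map(matrix(sample(1:6, 256, replace = TRUE), 16, 16))
    b <- label_map(matrix(sample(1:6, 256, replace = TRUE), 16, 16))
    sc <- seg_scores(a, b)
    for (code in 1:6) {
      pm <- a$px == code; tm <- b$px == code
      acc <- 100 * sum(pm & tm) / sum(tm)
      iou <- 100 * sum(pm & tm) / sum(pm | tm)
      expect_equal(sc$accuracy[code], acc)
      expect_equal(sc$iou[code], iou)
    }
  }

  # boundary F1 oracle: direct pairwise distances on a small map
  a <- label_map(rbind(matrix(1L, 8, 16), matrix(4L, 8, 16)))
  b <- label_map(rbind(matrix(1L, 9, 16), matrix(4L, 7, 16)))
  sc <- seg_scores(a, b, theta = 1)
  bf_oracle <- function(pm, tm, theta) {
    bnd <- function(m) {
      out <- matrix(FALSE, nrow(m), ncol(m))
      for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
        if (!m[r, c]) next
        nb <- c(if (r > 1) m[r - 1, c] else FALSE,
                if (r < nrow(m)) m[r + 1, c] else FALSE,
                if (c > 1) m[r, c - 1] else FALSE,
                if (c < ncol(m)) m[r, c + 1] else FALSE)
        if (r == 1 || c == 1 || r == nrow(m) || c == ncol(m) || !all(nb))
          out[r, c] <- TRUE
      }
      which(out, arr.ind = TRUE)
    }
    pb <- bnd(pm); tb <- bnd(tm)
    mind <- function(p, q) apply(p, 1, function(x)
      min(sqrt((q[, 1] - x[1])^2 + (q[, 2] - x[2])^2)))
    pr <- mean(mind(pb, tb) <= theta)
    rc <- mean(mind(tb, pb) <= theta)
    100 * 2 * pr * rc / (pr + rc)
  }
  expect_equal(sc$bfscore[4], bf_oracle(a$px == 4, b$px == 4, 1))

  expect_equal(round(seg_mean_score(c(97.2, 92.4, 99.5, 97.7, 88.2, 99.1)), 1),
               95.7)
  expect_equal(round(seg_mean_score(c(97.0, 92.0, 99.3, 97.7, 87.6, 98.9)), 1),
               95.4)
})
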