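test_that("brightness adjustment implements the vertebrae-offset rule", {
  img <- matrix(100, 10, 10)
  vm <- matrix(FALSE, 10, 10); vm[1:5, ] <- TRUE
  img[vm] <- 89
  out <- adjust_brightness(img, vm)
  expect_equal(out[8, 8], 100 - (89 - 69))      # 80
  expect_equal(mean(out[vm]), 69)

  img69 <- matrix(50, 6, 6); vmask <- matrix(TRUE, 6, 6); img69[] <- 69
  expect_equal(adjust_brightness(img69, vmask), img69)  # zero offset

  bright <- matrix(250, 8, 8)
  vm2 <- matrix(FALSE, 8, 8); vm2[1, ] <- TRUE
  bright[vm2] <- 50
  out2 <- adjust_brightness(bright, vm2)
  expect_equal(out2[5, 5], 255)                 # 269 capped at 255

  expect_error(adjust_brightness(img, matrix(FALSE, 10, 10)),
               "normalization error")
})

test_that("the dataset reference mean averages per-study vertebrae means", {
  s1 <- list(image = matrix(70, 5, 5), vert_mask = matrix(TRUE, 5, 5))
  expect_equal(estimate_reference_mean(list(s1)), 70)
  s2 <- list(image = matrix(60, 5, 5), vert_mask = matrix(TRUE, 5, 5))
  s3 <- list(image = matrix(80, 5, 5), vert_mask = matrix(TRUE, 5, 5))
  expect_equal(estimate_reference_mean(list(s2, s3)), 70)

  # phantoms with symmetric exposure offsets around the nominal vertebrae
  # intensity: the estimate recovers the reference value 69
  offs <- seq(-20, 20, length.out = 9)
  studies <- lapply(seq_along(offs), function(i) {
    st <- quiet_phantom(seed = 100 + i, exposure_offset = offs[i],
                        noise_sd = 0)
    list(image = st$image,
         vert_mask = st$labels$px == RC[["Vertebrae"]])
  })
  expect_lt(abs(estimate_reference_mean(studies) - 69), 2)
})

test_that("greyscale quantization caps, bins, and clamps", {
  cfg <- quantizer_config()
  expect_equal(cfg$delta_gl, 5)
  expect_equal(quantize_grey(0, cfg), 0L)
  expect_equal(quantize_grey(149, cfg), 29L)
  expect_equal(quantize_grey(200, cfg), 29L)    # capped then clamped
  expect_equal(quantize_grey(150, cfg), 29L)    # cap boundary stays in range
  expect_equal(quantize_grey(37, cfg), 7L)
  m <- matrix(c(0, 42, 151, 255), 2, 2)
  expect_identical(quantize_grey(m, cfg),
                   matrix(c(0L, 8L, 29L, 29L), 2, 2))
})

test_that("nucleus detection finds bright cores and falls back when dark", {
  dim <- 120L
  ivd <- matrix(FALSE, dim, dim); ivd[40:80, 20:100] <- TRUE
  img <- matrix(30, dim, dim)
  # bright elliptical core covering ~40% of the disc
  xs <- matrix(seq_len(dim), dim, dim, byrow = TRUE)
  ys <- matrix(seq_len(dim), dim, dim)
  core <- ((xs - 60) / 30)^2 + ((ys - 60) / 15)^2 <= 1
  img[core] <- 150
  nuc <- detect_nucleus(img, ivd)
  expect_false(nuc$fallback)
  expect_true(all(ivd[nuc$mask]))
  expect_gt(mean(img[nuc$mask]), 140)           # mask sits on the bright core

  # uniformly dark disc: threshold loop exhausts, eroded disc returned
  flat <- matrix(22, dim, dim)
  nuc2 <- detect_nucleus(flat, ivd)
  expect_true(nuc2$fallback)
  expect_true(all(ivd[nuc2$mask]))
  expect_lte(sum(nuc2$mask), 0.8 * sum(ivd) + 1)

  # two bright blobs: the larger connected component wins
  img3 <- matrix(30, dim, dim)
  big <- ((xs - 45) / 22)^2 + ((ys - 60) / 14)^2 <= 1
  small <- ((xs - 90) / 6)^2 + ((ys - 60) / 6)^2 <= 1
  img3[big | small] <- 150
  nuc3 <- detect_nucleus(img3, ivd)
  expect_false(nuc3$fallback)
  expect_gt(sum(nuc3$mask & big), 0)
  expect_equal(sum(nuc3$mask & small & !big), 0)
})

test_that("the correlogram length law holds across (N, w)", {
  for (N in 1:32) for (w in 0:(N - 1)) {
    band_cells <- sum(abs(outer(0:(N - 1), 0:(N - 1), "-")) <= w)
    expect_equal(sscc_length(N, w), band_cells)
  }
  expect_equal(sscc_length(10, 2), 44)
})

test_that("sscc equals the brute-force pair-enumeration oracle", {
  sscc_oracle <- function(img, mask, cfg, w, d) {
    n <- cfg$n_gl
    bins <- quantize_grey(img, cfg)
    pts <- which(mask, arr.ind = TRUE)
    counts <- matrix(0, n, n)
    for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
      if (i == j) next
      ch <- max(abs(pts[i, ] - pts[j, ]))
      if (ch != d) next
      bi <- bins[pts[i, 1], pts[i, 2]]; bj <- bins[pts[j, 1], pts[j, 2]]
      counts[bi + 1, bj + 1] <- counts[bi + 1, bj + 1] + 1
    }
    rs <- rowSums(counts)
    probs <- counts / ifelse(rs == 0, 1, rs)
    feat <- numeric(0)
    for (i in 0:(n - 1)) {
      jj <- max(0, i - w):min(n - 1, i + w)
      feat <- c(feat, probs[i + 1, jj + 1])
    }
    feat
  }
  cfg <- quantizer_config(n_gl = 10, gl_max = 150)
  set.seed(42)
  for (rep in 1:4) {
    img <- matrix(sample(c(20, 80, 140, 200), 400, replace = TRUE), 20, 20)
    mask <- matrix(runif(400) < 0.7, 20, 20)
    if (!any(mask)) next
    for (d in c(2, 4)) {
      f <- sscc(img, mask, cfg, w = 2, d = d)
      expect_equal(as.numeric(f), sscc_oracle(img, mask, cfg, 2, d))
    }
  }

  # uniform mask: all pair mass on the single diagonal cell
  uni <- matrix(100, 15, 15)
  mu <- matrix(TRUE, 15, 15)
  fu <- sscc(uni, mu, cfg, w = 2, d = 4)
  expect_equal(sum(fu), 1)
  expect_equal(max(fu), 1)
  expect_length(fu, sscc_length(10, 2))

  # every row of the full correlogram sums to one or is all zero
  rowsums <- rowSums(attr(sscc(img, mask, cfg, w = 2, d = 4), "matrix"))
  expect_true(all(abs(rowsums - 1) < 1e-12 | rowsums == 0))
})

test_that("extracted features separate bright from dark nuclei and cancel exposure", {
  st <- quiet_phantom(seed = 55, n = 3, grades = c(1, 3, 4), noise_sd = 2)
  nm <- assign_names(order_path(extract_skeleton(st$labels)), st$labels)
  f1 <- extract_ivd_feature(st$image, st$labels, nm, "L5/S1")   # grade 1
  f4 <- extract_ivd_feature(st$image, st$labels, nm, "L3/L4")   # grade 4
  centre_of_mass <- function(f) {
    m <- attr(f, "matrix")
    diagm <- diag(m)
    sum(seq_along(diagm) * diagm) / sum(diagm)
  }
  expect_gt(centre_of_mass(f1), centre_of_mass(f4) + 5)

  # a global exposure offset that saturates nothing in the spine leaves the
  # feature untouched (the vertebrae-mean offset cancels it exactly)
  shifted <- st$image
  shifted$px <- pmin(pmax(shifted$px + 30, 0), 255)
  f1b <- extract_ivd_feature(shifted, st$labels, nm, "L5/S1")
  expect_equal(as.numeric(f1b), as.numeric(f1), tolerance = 1e-12)
})
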