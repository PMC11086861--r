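test_that("prepare_images upscales x4 (cubic image, nearest labels)", {
  st <- quiet_phantom(seed = 8)
  prep <- prepare_images(st$image, st$labels)
  expect_equal(dim(prep$image), c(1536L, 1536L))
  expect_equal(dim(prep$labels), c(1536L, 1536L))
  expect_true(all(prep$labels %in% unique(as.vector(st$labels$px))))

  const <- grey_image(matrix(42, 384, 384))
  pc <- prepare_images(const, label_map(matrix(1L, 384, 384)))
  expect_equal(max(abs(pc$image - 42)), 0, tolerance = 1e-6)
})

test_that("middle-portion fit keeps the central 30% and fits exactly", {
  pts <- cbind(x = 1:10, y = rep(5, 10))
  fit <- middle_portion_fit(pts)
  expect_equal(unname(fit$centre["y"]), 5)
  expect_equal(abs(unname(fit$direction["y"])), 0, tolerance = 1e-12)

  x <- seq(0, 20, length.out = 41)
  fit2 <- middle_portion_fit(cbind(x = x, y = 0.5 * x + 1))
  slope <- fit2$direction["y"] / fit2$direction["x"]
  expect_equal(unname(slope), 0.5, tolerance = 1e-6)

  # symmetric arc: centre lands at the arc midpoint; oracle = direct mean
  xa <- seq(-10, 10)
  arc <- cbind(x = xa, y = 0.05 * xa^2)
  fit3 <- middle_portion_fit(arc)
  keep_n <- ceiling(0.3 * nrow(arc))
  first <- floor((nrow(arc) - keep_n) / 2) + 1
  mid <- arc[order(arc[, "x"])[first:(first + keep_n - 1)], ]
  expect_equal(unname(fit3$centre), unname(colMeans(mid)))
  expect_equal(unname(fit3$centre["x"]), 0)

  expect_error(middle_portion_fit(pts[1:5, ]), "fewer than 10")
})

test_that("initial bisect reproduces the symmetric parallel-plate case", {
  horiz <- function(y) list(centre = c(x = 50, y = y),
                            direction = c(x = 1, y = 0),
                            normal = c(x = 0, y = 1))
  seg <- initial_bisect(horiz(0), horiz(40), interior = c(50, 20))
  expect_equal(unname(seg$Cp_T), c(50, 40))
  expect_equal(unname(seg$Cp_B), c(50, 0))
  expect_equal(unname(seg$M_T), c(50, 0))
  expect_equal(unname(seg$M_B), c(50, 40))
  expect_true(seg$v_T["y"] > 0)     # oriented into the disc (downwards)
  expect_true(seg$v_B["y"] < 0)

  # randomly perturbed plates: oracle re-derivation of the construction
  set.seed(5)
  for (i in 1:10) {
    c_t <- c(x = runif(1, 40, 60), y = runif(1, 0, 5))
    c_b <- c(x = runif(1, 40, 60), y = runif(1, 30, 40))
    th_t <- runif(1, -0.3, 0.3); th_b <- runif(1, -0.3, 0.3)
    top <- list(centre = c_t, direction = c(x = cos(th_t), y = sin(th_t)),
                normal = c(x = -sin(th_t), y = cos(th_t)))
    bot <- list(centre = c_b, direction = c(x = cos(th_b), y = sin(th_b)),
                normal = c(x = -sin(th_b), y = cos(th_b)))
    interior <- (c_t + c_b) / 2
    seg <- initial_bisect(top, bot, interior)
    # oracle: solve the ray/line intersections with explicit algebra
    isect <- function(p, v, q, d) {
      A <- cbind(v, -d)
      t <- solve(A, q - p)
      p + t[1] * v
    }
    v_t <- top$normal * sign(sum(top$normal * (interior - c_t)))
    v_b <- bot$normal * sign(sum(bot$normal * (interior - c_b)))
    cp_t <- isect(c_t, v_t, c_b, bot$direction)
    cp_b <- isect(c_b, v_b, c_t, top$direction)
    expect_equal(unname(seg$M_T), unname((c_t + cp_b) / 2), tolerance = 1e-9)
    expect_equal(unname(seg$M_B), unname((c_b + cp_t) / 2), tolerance = 1e-9)
  }

  # ray parallel to the opposite fit line -> geometry error
  top_v <- list(centre = c(x = 0, y = 0), direction = c(x = 0, y = 1),
                normal = c(x = 1, y = 0))
  bot_h <- list(centre = c(x = 5, y = 20), direction = c(x = 1, y = 0),
                normal = c(x = 0, y = 1))
  expect_error(initial_bisect(top_v, bot_h, interior = c(5, 10)),
               "parallel")
})

test_that("Prewitt field has the expected directions and magnitudes", {
  step <- cbind(matrix(0, 20, 10), matrix(100, 20, 10))   # vertical edge
  f <- prewitt_field(step)
  edge <- f$beta[5:15, 10:11][f$magnitude[5:15, 10:11] > 0]
  expect_true(all(abs(edge) < 1e-9 | abs(abs(edge) - 180) < 1e-9))

  const <- matrix(7, 15, 15)
  expect_true(all(prewitt_field(const)$magnitude == 0))

  ramp45 <- outer(1:30, 1:30, function(r, c) r + c)       # rises down-right
  f45 <- prewitt_field(ramp45)
  expect_true(all(abs(f45$beta[5:25, 5:25] - 45) < 1e-6))
})

test_that("endpoint refinement follows aligned gradients and honours ties", {
  mag <- matrix(0, 40, 40)
  beta <- matrix(0, 40, 40)
  mag[30, 20] <- 50            # one strong edge pixel, gradient pointing +y
  beta[30, 20] <- 90
  field <- structure(list(magnitude = mag, beta = beta),
                     class = "gradient_field")
  got <- refine_endpoint(M = c(20, 25), v = c(0, 1), field, k = 8)
  expect_equal(unname(got), c(20, 30))

  # a zero field keeps the original point
  zf <- structure(list(magnitude = matrix(0, 40, 40),
                       beta = matrix(0, 40, 40)), class = "gradient_field")
  expect_equal(unname(refine_endpoint(c(20, 25), c(0, 1), zf, k = 8)),
               c(20, 25))

  # misaligned gradients (cos < 0) never attract the endpoint
  mag2 <- matrix(0, 40, 40); beta2 <- matrix(0, 40, 40)
  mag2[30, 20] <- 50; beta2[30, 20] <- -90
  f2 <- structure(list(magnitude = mag2, beta = beta2),
                  class = "gradient_field")
  expect_equal(unname(refine_endpoint(c(20, 25), c(0, 1), f2, k = 8)),
               c(20, 25))
})

test_that("height arithmetic follows ||M'_T - M'_B|| * ps' / 4", {
  seg <- structure(list(Mp_T = c(x = 10, y = 40), Mp_B = c(x = 10, y = 80)),
                   class = "bisect_segment")
  expect_equal(measure_height(seg, image_meta(0.7292, 384)), 40 * 0.7292 / 4)
  seg0 <- structure(list(Mp_T = c(x = 7, y = 9), Mp_B = c(x = 7, y = 9)),
                    class = "bisect_segment")
  expect_equal(measure_height(seg0, image_meta(0.7292, 384)), 0)
})

test_that("noise-free phantom heights are recovered within half a millimetre", {
  st <- generate_phantom(phantom_config(
    seed = 14, n_ivds = 4, grades = c(1, 2, 3, 4), noise_sd = 0,
    nucleus_sd = rep(0, 5), n_bumps = 0))
  nm <- assign_names(order_path(extract_skeleton(st$labels)), st$labels)
  h <- measure_ivd_heights(st$image, st$labels, nm)
  truth <- st$truth$height_mm[match(h$ivd_name, st$truth$name)]
  expect_true(all(abs(h$height_mm - truth) <= 0.5))
})
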