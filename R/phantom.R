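# Seeded synthetic mid-sagittal phantom studies: a vertical Sacrum -> IVD ->
# Vertebra -> ... stack with curvature and per-disc tilt, a bright nucleus
# ellipse whose brightness and homogeneity fall with Pfirrmann grade, full
# six-region tiling of the frame, exposure offsets and additive noise, plus a
# per-disc ground-truth table. Geometry is anatomically proportioned
# (vertebral bodies ~26 mm tall and ~41 mm wide at 0.7292 mm/px) so the
# centerline, naming and height stages meet the same structure they would on
# clinical data.

#' Phantom study configuration
#'
#' All intensity parameters are on the 0-255 grey scale. Grade-dependent
#' nucleus intensities are brightest and most homogeneous at grade 1 and
#' darken/roughen monotonically; grade-5 discs are generated thinner than the
#' 3.0 mm height threshold.
#'
#' @param n_ivds number of discs (3-5).
#' @param grades integer vector of per-disc Pfirrmann grades (bottom-up), or
#'   `NULL` to draw them from `grade_probs`.
#' @param heights_mm per-disc heights in mm, or `NULL` to draw per grade
#'   (grade 1: 9-12, 2: 8-11, 3: 6.5-9.5, 4: 4.5-7.5, 5: 2.0-2.8).
#' @param grade_probs sampling weights over grades 1-5 used when `grades` is
#'   `NULL`.
#' @param curvature_px amplitude (px) of the sinusoidal horizontal offset of
#'   the spinal column.
#' @param tilt_deg per-disc endplate tilt in degrees, or `NULL` to draw
#'   uniformly from `c(-tilt_max_deg, tilt_max_deg)`.
#' @param tilt_max_deg bound for drawn tilts.
#' @param n_bumps number of lateral bumps attached to vertebrae (each creates
#'   a skeleton branch).
#' @param exposure_offset global intensity offset (emulates scan exposure
#'   variation; the brightness-normalization stage must cancel it).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param nucleus_mean,nucleus_sd per-grade nucleus intensity mean and sd.
#' @param vertebra_intensity,annulus_intensity,sacrum_intensity,background
#'   tissue intensity means.
#' @param anterior_intensity,posterior_a_intensity,posterior_b_intensity
#'   filler-region intensity means.
#' @param pixel_spacing mm/px (default the modal clinical spacing 0.7292).
#' @param dim image dimension in pixels (square).
#' @param seed integer seed; the study is a deterministic function of the
#'   config.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_ivds = 5L, grades = NULL, heights_mm = NULL,
                           grade_probs = c(0.15, 0.35, 0.20, 0.20, 0.10),
                           curvature_px = 6, tilt_deg = NULL,
                           tilt_max_deg = 5, n_bumps = 1L,
                           exposure_offset = 0, noise_sd = 3,
                           nucleus_mean = c(160, 130, 95, 60, 45),
                           nucleus_sd = c(4, 8, 14, 18, 20),
                           vertebra_intensity = 69, annulus_intensity = 35,
                           sacrum_intensity = 50, background = 15,
                           anterior_intensity = 25,
                           posterior_a_intensity = 30,
                           posterior_b_intensity = 20,
                           pixel_spacing = 0.7292, dim = 384L, seed = 1L) {
  if (n_ivds < 3L || n_ivds > 5L)
    stop("n_ivds must be between 3 and 5", call. = FALSE)
  if (!is.null(grades) && length(grades) != n_ivds)
    stop("grades must have one entry per disc", call. = FALSE)
  if (!is.null(heights_mm) && length(heights_mm) != n_ivds)
    stop("heights_mm must have one entry per disc", call. = FALSE)
  cfg <- as.list(environment())
  cfg$n_ivds <- as.integer(n_ivds)
  cfg$dim <- as.integer(dim)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "phantom_config")
}

.height_range_mm <- rbind(c(9, 12), c(8, 11), c(6.5, 9.5), c(4.5, 7.5),
                          c(2.0, 2.8))

#' Generate one phantom study
#'
#' Renders the label map and MRI image described by a [phantom_config()] and
#' returns them with the per-disc ground truth. Output label maps satisfy all
#' six labeling requirements by construction, and the same config (same seed)
#' always yields a bit-identical study.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_study`: list with `image` ([grey_image()]), `labels`
#'   ([label_map()]), `truth` (data frame `name`, `height_mm`, `grade`),
#'   `vertebra_names`, and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_ivds
  ps <- cfg$pixel_spacing
  dm <- cfg$dim

  grades <- cfg$grades
  if (is.null(grades))
    grades <- sample(1:5, n, replace = TRUE, prob = cfg$grade_probs)
  heights <- cfg$heights_mm
  if (is.null(heights))
    heights <- vapply(grades, function(g)
      runif(1, .height_range_mm[g, 1], .height_range_mm[g, 2]), numeric(1))
  if (any(grades == 5L & heights >= 3.0))
    stop("grade-5 discs must be shorter than 3.0 mm", call. = FALSE)
  tilts <- cfg$tilt_deg
  if (is.null(tilts))
    tilts <- runif(n, -cfg$tilt_max_deg, cfg$tilt_max_deg)
  tilts <- rep_len(tilts, n)

  # anatomical block sizes in pixels
  vert_h <- 36L; blk_w <- 56L
  sacrum_h <- 60L; sacrum_w <- 64L; top_extra <- 20L
  h_px <- pmax(2L, as.integer(round(heights / ps)))

  y_bottom <- dm - 30L                      # sacrum base row
  stack_h <- sacrum_h + sum(h_px) + n * vert_h + top_extra
  y_top <- y_bottom - stack_h
  if (y_top < 10L)
    stop("geometry overflow: disc stack does not fit the frame",
         call. = FALSE)

  phase <- runif(1, 0, 2 * pi)
  xc_of <- function(y)
    dm / 2 + cfg$curvature_px * sin(pi * (y - y_top) / stack_h + phase)

  X <- matrix(seq_len(dm), dm, dm, byrow = TRUE)   # column index
  Y <- matrix(seq_len(dm), dm, dm)                 # row index
  XC <- matrix(xc_of(seq_len(dm)), dm, dm)         # column centre per row

  # interface curves: y = anchor_y + tan(tilt) * (x - xc(anchor_y));
  # each is a length-dm vector over x, turned into a matrix by column.
  curve_mat <- function(anchor_y, tilt) {
    v <- anchor_y + tan(tilt * pi / 180) * (seq_len(dm) - xc_of(anchor_y))
    matrix(v, dm, dm, byrow = TRUE)
  }

  lab <- matrix(0L, dm, dm)

  # Hard band membership drives the labels; the image instead accumulates
  # vertical partial-volume coverage: a pixel row spans [y - 0.5, y + 0.5],
  # so its coverage by the band between two face curves is the clipped
  # overlap, as MRI voxels average the tissues they straddle. The spine
  # structures partition vertically, so coverages sum to at most 1 and the
  # remainder is filled with the surrounding tissue intensity at the end.
  # Lateral cuts stay hard (they are never measured).
  band <- function(top_curve, bottom_curve, half_w)
    Y > top_curve & Y <= bottom_curve & abs(X - XC) <= half_w
  coverage <- function(top_curve, bottom_curve, half_w) {
    # centre-sampled labels put the face between pixel rows, i.e. at
    # curve + 0.5 in continuous row coordinates; the coverage band uses the
    # same convention so image and label geometry coincide
    cov <- pmin(Y, bottom_curve) - pmax(Y - 1, top_curve)
    cov <- pmin(pmax(cov, 0), 1)
    cov[abs(X - XC) > half_w] <- 0
    cov
  }
  acc <- matrix(0, dm, dm)      # coverage-weighted intensity sum
  covtot <- matrix(0, dm, dm)   # total spine coverage
  add_cov <- function(cov, value) {
    acc <<- acc + cov * value
    covtot <<- covtot + cov
  }

  # sacrum
  y_cursor <- y_bottom - sacrum_h
  sac_top <- curve_mat(y_cursor, tilts[1L])
  sac_bot <- matrix(y_bottom, dm, dm)
  lab[band(sac_top, sac_bot, sacrum_w / 2)] <- REGION_CODES[["Sacrum"]]
  add_cov(coverage(sac_top, sac_bot, sacrum_w / 2), cfg$sacrum_intensity)

  disc_mid <- numeric(n)
  for (i in seq_len(n)) {
    bot <- curve_mat(y_cursor, tilts[i])
    y_cursor <- y_cursor - h_px[i]
    top <- curve_mat(y_cursor, tilts[i])     # parallel endplates
    lab[band(top, bot, blk_w / 2)] <- REGION_CODES[["IVD"]]
    dcov <- coverage(top, bot, blk_w / 2)
    disc_mid[i] <- y_cursor + h_px[i] / 2

    # nucleus: a superellipse spanning the full disc thickness, flattened
    # against the endplates over the central column (as the nucleus pulposus
    # is on T2 slices); it overfills the band vertically and is clipped by
    # the disc coverage
    x_ctr <- xc_of(disc_mid[i])
    a <- 0.38 * blk_w
    b <- h_px[i] / 2 + 1
    sheared_y <- Y - tan(tilts[i] * pi / 180) * (X - x_ctr)
    ell <- ((X - x_ctr) / a)^4 + ((sheared_y - disc_mid[i]) / b)^4 <= 1
    ncov <- dcov * ell
    nuc_val <- matrix(rnorm(length(acc), cfg$nucleus_mean[grades[i]],
                            cfg$nucleus_sd[grades[i]]), dm, dm)
    add_cov(dcov - ncov, cfg$annulus_intensity)
    add_cov(ncov, nuc_val)

    # vertebra above (the topmost one runs on, leaving the lumbar field)
    vh <- vert_h + if (i == n) top_extra else 0L
    vtop_tilt <- if (i < n) tilts[i + 1L] else 0
    bot_v <- top
    y_cursor <- y_cursor - vh
    top_v <- curve_mat(y_cursor, vtop_tilt)
    lab[band(top_v, bot_v, blk_w / 2)] <- REGION_CODES[["Vertebrae"]]
    add_cov(coverage(top_v, bot_v, blk_w / 2), cfg$vertebra_intensity)
  }

  # lateral bumps on vertebra flanks (create skeleton branches)
  if (cfg$n_bumps > 0L) {
    vert_idx <- sample(seq_len(n), min(cfg$n_bumps, n))
    for (i in vert_idx) {
      yb <- disc_mid[i] - h_px[i] / 2 - vert_h / 2
      side <- sample(c(-1, 1), 1)
      xb <- xc_of(yb) + side * blk_w / 2
      r <- 8
      bump <- (X - xb)^2 + (Y - yb)^2 <= r^2 & lab == 0L
      lab[bump] <- REGION_CODES[["Vertebrae"]]
      acc[bump] <- cfg$vertebra_intensity
      covtot[bump] <- 1
    }
  }

  # tile the rest of the frame: Anterior left of (and over/under) the spine,
  # a PosteriorA band hugging its right flank, PosteriorB beyond that.
  spine <- lab > 0L
  sp_xr <- apply(spine, 1L, function(r) if (any(r)) max(which(r)) else NA)
  rows <- seq_len(dm)
  sp_xr <- round(stats::approx(rows[!is.na(sp_xr)], sp_xr[!is.na(sp_xr)],
                               rows, rule = 2)$y)
  XR <- matrix(sp_xr, dm, dm)
  pa <- lab == 0L & X > XR & X <= XR + 30L
  lab[pa] <- REGION_CODES[["PosteriorA"]]
  pb <- lab == 0L & X > XR + 30L
  lab[pb] <- REGION_CODES[["PosteriorB"]]
  ant <- lab == 0L
  lab[ant] <- REGION_CODES[["Anterior"]]

  # surrounding-tissue intensity completes the partial-volume mix
  filler <- matrix(cfg$background, dm, dm)
  filler[pa] <- cfg$posterior_a_intensity
  filler[pb] <- cfg$posterior_b_intensity
  filler[ant] <- cfg$anterior_intensity
  img <- acc + pmax(1 - covtot, 0) * filler

  img <- img + cfg$exposure_offset
  if (cfg$noise_sd > 0)
    img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img <- pmin(pmax(img, 0), 255)

  meta <- image_meta(ps, dm)
  truth <- data.frame(name = IVD_NAMES[seq_len(n)],
                      height_mm = h_px * cos(tilts * pi / 180) * ps,
                      grade = as.integer(grades))
  cfg$grades <- as.integer(grades)
  cfg$heights_mm <- heights
  cfg$tilt_deg <- tilts
  structure(list(image = grey_image(img, meta),
                 labels = label_map(lab, meta),
                 truth = truth,
                 vertebra_names = VERT_NAMES[seq_len(n)],
                 config = cfg),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("phantom_study: %d discs, seed %d\n", nrow(x$truth),
              x$config$seed))
  print(x$truth)
  invisible(x)
}

#' Generate a batch of phantom studies
#'
#' Draws a grade for every disc from the requested distribution and packs the
#' discs into studies of 3-5 discs each. `n` counts discs, not studies.
#'
#' @param n total number of discs across the batch.
#' @param grade_dist `"balanced"` (equal shares of grades 1-5, via a shuffled
#'   balanced sequence), `"clinical"` (the imbalanced clinical shares
#'   3.9/64.9/10.8/19.0/1.4% for grades 1-5), or a numeric probability vector
#'   over grades 1-5.
#' @param seed batch seed; study `i` uses `seed + i`.
#' @param grades optional explicit per-disc grades (length `n`), overriding
#'   `grade_dist`.
#' @param n_ivds discs per study (3-5), or `"random"` to vary.
#' @param ... further arguments passed to [phantom_config()] (e.g.
#'   `noise_sd`, `exposure_offset`).
#' @return list of `phantom_study` objects covering exactly `n` discs.
#' @export
generate_phantom_batch <- function(n, grade_dist = "balanced", seed = 1L,
                                   grades = NULL, n_ivds = "random", ...) {
  stopifnot(n >= 3L)
  set.seed(seed)
  if (is.null(grades)) {
    grades <- if (identical(grade_dist, "balanced")) {
      sample(rep_len(1:5, n))
    } else {
      probs <- if (identical(grade_dist, "clinical"))
        c(0.039, 0.649, 0.108, 0.190, 0.014) else grade_dist
      sample(1:5, n, replace = TRUE, prob = probs)
    }
  }
  stopifnot(length(grades) == n)
  sizes <- integer(0)
  left <- n
  while (left > 0L) {
    # candidate sizes that leave either nothing or at least one more study
    cand <- if (identical(n_ivds, "random")) 3:5 else as.integer(n_ivds)
    cand <- cand[cand <= left & (left - cand == 0L | left - cand >= 3L)]
    if (length(cand) == 0L)
      stop("cannot pack ", n, " discs into studies of the requested size",
           call. = FALSE)
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    sizes <- c(sizes, s)
    left <- left - s
  }
  offsets <- cumsum(c(0L, sizes))
  lapply(seq_along(sizes), function(i) {
    g <- grades[(offsets[i] + 1L):offsets[i + 1L]]
    generate_phantom(phantom_config(n_ivds = sizes[i], grades = g,
                                    seed = seed + i, ...))
  })
}
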