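# Six-region label maps: representation, the six ground-truth labeling
# requirements, connected-component post-processing, and segmentation quality
# metrics (per-region accuracy, IoU, boundary F1).

#' Region codes of the six-region segmentation
#'
#' Integer codes for the six anatomical regions: Anterior = 1, PosteriorA = 2,
#' PosteriorB = 3, Vertebrae = 4, IVD = 5, Sacrum = 6. Code 0 is reserved for
#' unassigned pixels during editing; validation constrains only codes 1-6.
#'
#' @format named integer vector of length 6.
#' @export
REGION_CODES <- c(Anterior = 1L, PosteriorA = 2L, PosteriorB = 3L,
                  Vertebrae = 4L, IVD = 5L, Sacrum = 6L)

region_name <- function(code) names(REGION_CODES)[match(code, REGION_CODES)]

#' Label map container
#'
#' @param px integer matrix of region codes (0-6).
#' @param meta an [image_meta()].
#' @return a `label_map` object (list with `px`, `meta`).
#' @export
label_map <- function(px, meta = image_meta(1, nrow(px))) {
  stopifnot(is.matrix(px))
  px <- matrix(as.integer(px), nrow(px), ncol(px))
  if (any(px < 0L | px > 6L, na.rm = TRUE))
    stop("label codes must lie in 0..6", call. = FALSE)
  structure(list(px = px, meta = meta), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  present <- sort(unique(as.vector(x$px)))
  cat(sprintf("label_map: %d x %d, codes {%s}\n", nrow(x$px), ncol(x$px),
              paste(present, collapse = ",")))
  invisible(x)
}

#' Find connected component regions (CCRs) of one region code
#'
#' Maximal 8-connected components of the pixels carrying `code`.
#'
#' @param labels a [label_map()].
#' @param code a region code (see [REGION_CODES]).
#' @return list of `ccr` objects, largest first, each with fields `code`,
#'   `pixels` (linear indices into the label matrix), `area`, `bbox`.
#' @export
find_ccrs <- function(labels, code) {
  mask <- labels$px == code
  lab <- label_components(mask, connectivity = 8)
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    pix <- which(lab == i)
    structure(list(code = as.integer(code), pixels = pix,
                   area = length(pix),
                   bbox = mask_bbox(lab == i)),
              class = "ccr")
  })
}

#' @export
print.ccr <- function(x, ...) {
  cat(sprintf("ccr: code %d (%s), %d px\n", x$code,
              region_name(x$code), x$area))
  invisible(x)
}

ccr_mask <- function(ccr, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[ccr$pixels] <- TRUE
  m
}

# Most frequent value; ties broken by the smallest value.
.code_mode <- function(codes) {
  tab <- table(codes)
  as.integer(min(as.integer(names(tab)[tab == max(tab)])))
}

#' Validate a label map against the six labeling requirements
#'
#' Checks, in order: (1) exactly one hole-free Anterior region, (2) exactly
#' one hole-free PosteriorA region, (3) exactly one hole-free Sacrum region,
#' (4) every PosteriorB region is hole-free (any count), (5) exactly one
#' hole-free Vert-IVD union region (union of all Vertebrae and IVD pixels),
#' (6) IVD and Vertebrae alternate along the spine starting with an IVD at
#' the bottom, just above the Sacrum.
#'
#' @param labels a [label_map()].
#' @return a `validation_report`: data frame with columns `rule` (1-6) and
#'   `detail`; zero rows means the map satisfies all six requirements.
#' @export
validate_labelmap <- function(labels) {
  v <- list()
  add <- function(rule, detail) v[[length(v) + 1L]] <<- list(rule = rule,
                                                             detail = detail)
  dims <- dim(labels$px)

  check_single <- function(rule, code) {
    ccrs <- find_ccrs(labels, code)
    nm <- region_name(code)
    if (length(ccrs) == 0L) {
      add(rule, sprintf("no %s region present", nm))
    } else {
      if (length(ccrs) > 1L)
        add(rule, sprintf("%d %s regions found, expected 1", length(ccrs), nm))
      if (any(find_holes(ccr_mask(ccrs[[1L]], dims))))
        add(rule, sprintf("largest %s region has holes", nm))
    }
  }
  check_single(1L, REGION_CODES["Anterior"])
  check_single(2L, REGION_CODES["PosteriorA"])
  check_single(3L, REGION_CODES["Sacrum"])

  for (ccr in find_ccrs(labels, REGION_CODES["PosteriorB"]))
    if (any(find_holes(ccr_mask(ccr, dims))))
      add(4L, "a PosteriorB region has holes")

  union_mask <- labels$px == REGION_CODES["Vertebrae"] |
    labels$px == REGION_CODES["IVD"]
  lab_u <- label_components(union_mask, connectivity = 8)
  if (max(lab_u) == 0L) {
    add(5L, "no Vert-IVD region present")
  } else {
    if (max(lab_u) > 1L)
      add(5L, sprintf("%d Vert-IVD regions found, expected 1", max(lab_u)))
    if (any(find_holes(lab_u == 1L)))
      add(5L, "Vert-IVD region has holes")
    seq_codes <- .spine_stack_codes(labels)
    if (length(seq_codes) > 0L) {
      if (seq_codes[1L] != REGION_CODES["IVD"])
        add(6L, "lowest Vert-IVD element is not an IVD")
      if (length(seq_codes) > 1L &&
          any(seq_codes[-1L] == seq_codes[-length(seq_codes)]))
        add(6L, "IVD and Vertebrae regions do not alternate")
      sac <- labels$px == REGION_CODES["Sacrum"]
      first_ivd <- .nth_stack_mask(labels, 1L)
      if (any(sac) && !any(touching_pixels(first_ivd, sac)))
        add(6L, "bottom IVD is not adjacent to the Sacrum")
    }
  }
  report <- if (length(v) == 0L) {
    data.frame(rule = integer(0), detail = character(0))
  } else {
    data.frame(rule = vapply(v, `[[`, integer(1), "rule"),
               detail = vapply(v, `[[`, character(1), "detail"))
  }
  structure(report, class = c("validation_report", "data.frame"))
}

# Vertebrae/IVD CCRs of the main union component ordered bottom-up by their
# lowest pixel; returns the code sequence.
.spine_stack_codes <- function(labels) {
  st <- .spine_stack(labels)
  vapply(st, `[[`, integer(1), "code")
}

.nth_stack_mask <- function(labels, n) {
  st <- .spine_stack(labels)
  m <- matrix(FALSE, nrow(labels$px), ncol(labels$px))
  if (n <= length(st)) m[st[[n]]$pixels] <- TRUE
  m
}

.spine_stack <- function(labels) {
  ccrs <- c(find_ccrs(labels, REGION_CODES["Vertebrae"]),
            find_ccrs(labels, REGION_CODES["IVD"]))
  if (length(ccrs) == 0L) return(list())
  bottom <- vapply(ccrs, function(cc) cc$bbox$r2, integer(1))
  ccrs[order(bottom, decreasing = TRUE)]
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation_report: all six requirements satisfied\n")
  } else {
    cat(sprintf("validation_report: %d violation(s)\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}

#' Fill the holes of one CCR
#'
#' Interior pixels not reachable from the image border through non-CCR pixels
#' are reassigned to the CCR's own code.
#'
#' @param ccr a `ccr` from [find_ccrs()].
#' @param labels a [label_map()].
#' @return the updated [label_map()].
#' @export
fill_holes <- function(ccr, labels) {
  holes <- find_holes(ccr_mask(ccr, dim(labels$px)))
  labels$px[holes] <- ccr$code
  labels
}

#' Merge a CCR into its surrounding region
#'
#' Every pixel of the CCR is reassigned to the most frequent code among the
#' CCR's external boundary pixels (its 8-neighbourhood ring); ties are broken
#' by the smallest code. Unassigned pixels (code 0) in the ring are ignored
#' unless the ring is entirely unassigned.
#'
#' @inheritParams fill_holes
#' @return the updated [label_map()].
#' @export
merge_ccr_into_surrounding <- function(ccr, labels) {
  mask <- ccr_mask(ccr, dim(labels$px))
  ring <- binary_morph(mask, "dilate") & !mask
  codes <- labels$px[ring]
  if (length(codes) == 0L)
    stop("CCR has no surrounding region to merge into", call. = FALSE)
  nz <- codes[codes > 0L]
  labels$px[mask] <- .code_mode(if (length(nz) > 0L) nz else codes)
  labels
}

#' Post-process a label map to meet the labeling requirements
#'
#' Applies, in order: (1) keep the largest Anterior CCR, merge the rest into
#' their surroundings, and close its holes; (2) the same for PosteriorA and
#' Sacrum; (3) close holes of every PosteriorB CCR (no merging); (4) form the
#' Vert-IVD union, keep its largest CCR, reassign detached Vertebrae/IVD CCRs
#' to their surroundings, and fill union holes (a hole whose vertical
#' neighbours above and below are Vertebrae becomes IVD, otherwise the mode of
#' the hole-adjacent codes); (5) merge any Vertebrae or IVD CCR smaller than
#' 20 pixels into its surrounding region (a 20-pixel CCR is kept).
#'
#' @param labels a [label_map()].
#' @return the post-processed [label_map()].
#' @export
postprocess_labelmap <- function(labels) {
  dims <- dim(labels$px)

  keep_largest <- function(labels, code) {
    ccrs <- find_ccrs(labels, code)
    if (length(ccrs) == 0L) return(labels)
    if (length(ccrs) > 1L)
      for (cc in ccrs[-1L]) labels <- merge_ccr_into_surrounding(cc, labels)
    fill_holes(find_ccrs(labels, code)[[1L]], labels)
  }

  labels <- keep_largest(labels, REGION_CODES["Anterior"])
  labels <- keep_largest(labels, REGION_CODES["PosteriorA"])
  labels <- keep_largest(labels, REGION_CODES["Sacrum"])
  if (!any(labels$px == REGION_CODES["Sacrum"]))
    stop("no Sacrum region present: spine traversal is impossible",
         call. = FALSE)
  for (cc in find_ccrs(labels, REGION_CODES["PosteriorB"]))
    labels <- fill_holes(cc, labels)

  # step 4: the Vert-IVD union
  union_mask <- labels$px == REGION_CODES["Vertebrae"] |
    labels$px == REGION_CODES["IVD"]
  lab_u <- label_components(union_mask, connectivity = 8)
  if (max(lab_u) > 1L) {
    for (i in 2:max(lab_u)) {
      pix <- which(lab_u == i)
      cc <- structure(list(code = 0L, pixels = pix, area = length(pix),
                           bbox = mask_bbox(lab_u == i)), class = "ccr")
      labels <- merge_ccr_into_surrounding(cc, labels)
    }
    union_mask <- labels$px == REGION_CODES["Vertebrae"] |
      labels$px == REGION_CODES["IVD"]
  }
  holes <- label_components(find_holes(union_mask), connectivity = 4)
  if (max(holes) > 0L) {
    nr <- dims[1]
    for (i in seq_len(max(holes))) {
      hm <- holes == i
      hidx <- which(hm)
      rows <- ((hidx - 1L) %% nr) + 1L
      cols <- ((hidx - 1L) %/% nr) + 1L
      vert_nb <- integer(0)
      for (cl in unique(cols)) {
        rr <- rows[cols == cl]
        if (min(rr) > 1L) vert_nb <- c(vert_nb, labels$px[min(rr) - 1L, cl])
        if (max(rr) < nr) vert_nb <- c(vert_nb, labels$px[max(rr) + 1L, cl])
      }
      fill_code <- if (length(vert_nb) > 0L &&
                       all(vert_nb == REGION_CODES["Vertebrae"])) {
        REGION_CODES["IVD"]
      } else {
        ring <- binary_morph(hm, "dilate") & !hm
        .code_mode(labels$px[ring])
      }
      labels$px[hm] <- fill_code
    }
  }

  # step 5: merge undersized Vertebrae/IVD CCRs (strictly below 20 px)
  repeat {
    small <- Filter(function(cc) cc$area < 20L,
                    c(find_ccrs(labels, REGION_CODES["Vertebrae"]),
                      find_ccrs(labels, REGION_CODES["IVD"])))
    if (length(small) == 0L) break
    labels <- merge_ccr_into_surrounding(small[[1L]], labels)
  }
  labels
}

## ---- segmentation quality metrics -------------------------------------------

# Boundary pixels: mask pixels with a 4-neighbour outside the mask or on the
# image border.
.mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[-1L, , drop = FALSE], FALSE)
  down <- rbind(FALSE, mask[-nr, , drop = FALSE])
  left <- cbind(mask[, -1L, drop = FALSE], FALSE)
  right <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mask & !(up & down & left & right)
}

.bf_score <- function(pred_mask, truth_mask, theta) {
  pb <- .mask_boundary(pred_mask)
  tb <- .mask_boundary(truth_mask)
  if (!any(pb) && !any(tb)) return(100)
  if (!any(pb) || !any(tb)) return(0)
  dist_to_tb <- as.matrix(EBImage::distmap(1 - tb))
  dist_to_pb <- as.matrix(EBImage::distmap(1 - pb))
  precision <- mean(dist_to_tb[pb] <= theta)
  recall <- mean(dist_to_pb[tb] <= theta)
  if (precision + recall == 0) return(0)
  100 * 2 * precision * recall / (precision + recall)
}

#' Segmentation quality scores of a predicted label map
#'
#' Per region: accuracy (percentage of ground-truth pixels of the region that
#' are correctly labelled), intersection-over-union, and BFScore (boundary F1
#' at distance tolerance `theta`). The mean score is the average of the six
#' Vertebrae and IVD metric values, the model-selection score used for the
#' segmentation backend.
#'
#' @param predicted,truth [label_map()]s of identical shape.
#' @param theta boundary-match tolerance in pixels; default is 0.75% of the
#'   image diagonal, rounded up.
#' @return a `seg_scores` object: data frame (`region`, `accuracy`, `iou`,
#'   `bfscore`, all percentages) with attribute `mean_score`.
#' @export
seg_scores <- function(predicted, truth, theta = NULL) {
  if (!identical(dim(predicted$px), dim(truth$px)))
    stop("predicted and truth label maps differ in shape", call. = FALSE)
  if (is.null(theta))
    theta <- ceiling(0.0075 * sqrt(sum(dim(truth$px)^2)))
  res <- lapply(REGION_CODES, function(code) {
    p <- predicted$px == code
    t <- truth$px == code
    inter <- sum(p & t)
    uni <- sum(p | t)
    acc <- if (sum(t) == 0L) NA_real_ else 100 * inter / sum(t)
    iou <- if (uni == 0L) NA_real_ else 100 * inter / uni
    c(accuracy = acc, iou = iou, bfscore = .bf_score(p, t, theta))
  })
  df <- data.frame(region = names(REGION_CODES),
                   do.call(rbind, res), row.names = NULL)
  six <- unlist(df[df$region %in% c("Vertebrae", "IVD"),
                   c("accuracy", "iou", "bfscore")])
  structure(df, class = c("seg_scores", "data.frame"),
            mean_score = seg_mean_score(six))
}

#' Mean score of the Vertebrae and IVD segmentation metrics
#'
#' The arithmetic mean of the six metric values (accuracy, IoU and BFScore of
#' the Vertebrae and IVD regions), the single number used to rank candidate
#' segmentation models.
#'
#' @param values numeric vector of the six metric percentages, or a
#'   `seg_scores` object.
#' @return the mean score (percent).
#' @examples
#' seg_mean_score(c(97.2, 92.4, 99.5, 97.7, 88.2, 99.1)) # 95.7 at 1 decimal
#' @export
seg_mean_score <- function(values) {
  if (inherits(values, "seg_scores")) return(attr(values, "mean_score"))
  mean(values)
}

#' @export
print.seg_scores <- function(x, ...) {
  print.data.frame(x)
  cat(sprintf("mean score (Vertebrae+IVD): %.1f\n", attr(x, "mean_score")))
  invisible(x)
}
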