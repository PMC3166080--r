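# Morphology-channel segmentation (neuromeres + neurite segments) and
# reporter-channel aggregate pixel counting.

#' Segmentation configuration
#'
#' @param morph_threshold_method `"otsu"` (default; scale-invariant) or
#'   `"fixed"`.
#' @param fixed_threshold Raw intensity threshold used when
#'   `morph_threshold_method = "fixed"`.
#' @param soma_opening_radius_px Disc radius of the morphological opening
#'   that separates thick somata from thin neurites.
#' @param min_neuromere_area_px Minimum opened-component area to count as a
#'   neuromere.
#' @param min_segment_length_px Minimum skeleton segment length to keep.
#' @param neuromere_dilation_px Dilation of the neuromere mask subtracted
#'   from the binary mask before neurite skeletonisation.
#' @param background_window_px Odd window (px) of the median background
#'   filter. Must comfortably exceed the largest neuromere diameter or the
#'   filter flattens the objects it should preserve.
#' @param aggregate_threshold Raw reporter intensity above which a pixel
#'   counts as aggregate; usually set by [calibrate_aggregate_threshold()].
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(morph_threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                soma_opening_radius_px = 4L,
                                min_neuromere_area_px = 50L,
                                min_segment_length_px = 5L,
                                neuromere_dilation_px = 2L,
                                background_window_px = 95L,
                                aggregate_threshold = NA_real_) {
  morph_threshold_method <- match.arg(morph_threshold_method)
  stopifnot(
    soma_opening_radius_px >= 1L, min_neuromere_area_px >= 1L,
    min_segment_length_px >= 1L, neuromere_dilation_px >= 1L,
    background_window_px >= 3L, background_window_px %% 2L == 1L
  )
  if (morph_threshold_method == "fixed" && !is.finite(fixed_threshold))
    stop("`fixed_threshold` required when morph_threshold_method = 'fixed'",
         call. = FALSE)
  structure(as.list(environment()), class = "segmentation_config")
}

# Cyclic 8-neighbourhood values (N, NE, E, SE, S, SW, W, NW) of the pixels
# `idx` of a zero-padded logical matrix with `nr` rows (column-major).
neigh8 <- function(m, idx, nr) {
  list(m[idx - 1L], m[idx + nr - 1L], m[idx + nr], m[idx + nr + 1L],
       m[idx + 1L], m[idx - nr + 1L], m[idx - nr], m[idx - nr - 1L])
}

pad_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  m
}

# Zhang-Suen binary thinning to a 1-px skeleton. Operates on the sparse
# foreground index set, so cost scales with mask size, not field size.
thin_skeleton <- function(mask) {
  if (!any(mask)) return(mask)
  m <- pad_mask(mask)
  nr <- nrow(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      idx <- which(m)
      if (length(idx) == 0L) break
      p <- neigh8(m, idx, nr)
      b <- p[[1]] + p[[2]] + p[[3]] + p[[4]] + p[[5]] + p[[6]] + p[[7]] + p[[8]]
      a <- (!p[[1]] & p[[2]]) + (!p[[2]] & p[[3]]) + (!p[[3]] & p[[4]]) +
        (!p[[4]] & p[[5]]) + (!p[[5]] & p[[6]]) + (!p[[6]] & p[[7]]) +
        (!p[[7]] & p[[8]]) + (!p[[8]] & p[[1]])
      cond <- if (sub == 1L) {
        b >= 2 & b <= 6 & a == 1 &
          !(p[[1]] & p[[3]] & p[[5]]) & !(p[[3]] & p[[5]] & p[[7]])
      } else {
        b >= 2 & b <= 6 & a == 1 &
          !(p[[1]] & p[[3]] & p[[7]]) & !(p[[1]] & p[[5]] & p[[7]])
      }
      if (any(cond)) {
        m[idx[cond]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

# Branch (junction) pixels of a 1-px skeleton: crossing number >= 3, i.e.
# at least three distinct path arms meet there. A raw neighbour count would
# misclassify interior pixels of diagonal staircases and shatter segments.
junction_pixels <- function(skel) {
  out <- matrix(FALSE, nrow(skel), ncol(skel))
  if (!any(skel)) return(out)
  m <- pad_mask(skel)
  nr <- nrow(m)
  idx <- which(m)
  p <- neigh8(m, idx, nr)
  a <- (!p[[1]] & p[[2]]) + (!p[[2]] & p[[3]]) + (!p[[3]] & p[[4]]) +
    (!p[[4]] & p[[5]]) + (!p[[5]] & p[[6]]) + (!p[[6]] & p[[7]]) +
    (!p[[7]] & p[[8]]) + (!p[[8]] & p[[1]])
  jm <- matrix(FALSE, nr, ncol(m))
  jm[idx[a >= 3]] <- TRUE
  jm[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)]
}

# Per-component path lengths (px) of a 1-px skeleton with junctions removed.
# Orthogonal pixel adjacencies count 1, pure diagonal adjacencies sqrt(2);
# each component gets +1 px for the extent of its pixels. Sparse: works on
# the foreground index set of a zero-padded label matrix.
segment_lengths_px <- function(skel) {
  lab0 <- label8(skel)
  n <- max(lab0)
  if (n == 0L) return(numeric(0))
  lab <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  lab[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- lab0
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  lb <- lab[idx]
  len <- numeric(n)
  edge_add <- function(off, w, off_o1 = NULL, off_o2 = NULL) {
    ok <- lab[idx + off] > 0L
    if (!is.null(off_o1)) {
      # skip diagonals that shortcut an existing orthogonal step
      ok <- ok & !(lab[idx + off_o1] > 0L | lab[idx + off_o2] > 0L)
    }
    if (any(ok)) {
      s <- rowsum(rep(w, sum(ok)), lb[ok])
      ids <- as.integer(rownames(s))
      len[ids] <<- len[ids] + s[, 1]
    }
  }
  edge_add(nr, 1)                        # east
  edge_add(1L, 1)                        # south
  edge_add(nr + 1L, sqrt(2), 1L, nr)     # south-east, pure diagonal only
  edge_add(-nr + 1L, sqrt(2), 1L, -nr)   # south-west, pure diagonal only
  len + 1
}

# Otsu's threshold over the image's own intensity range (256 bins), hence
# exactly invariant to uniform intensity scaling.
otsu_threshold <- function(x, levels = 256L) {
  mx <- max(x)
  h <- tabulate(as.integer(x * ((levels - 1) / mx)) + 1L, levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels * mx
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  bc <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bc[!is.finite(bc)] <- 0
  k <- which.max(bc[-levels])
  mids[k]
}

# Slowly-varying background by median filtering. The median runs on a 4x
# down-sampled copy (window scaled to match) and is resized back: the
# background varies over scales much larger than 4 px, and this keeps the
# filter cost negligible at any window size.
estimate_background <- function(x, window_px) {
  f <- 4L
  nr <- nrow(x); nc <- ncol(x)
  down <- EBImage::resize(EBImage::Image(clamp(x, 0, 1)),
                          w = max(8L, nr %/% f), h = max(8L, nc %/% f))
  size <- max(1L, as.integer(round((window_px - 1L) / 2L / f)))
  size <- min(size, min(dim(down)[1:2]) %/% 2L - 1L)  # filter-size limit
  size <- max(size, 1L)
  med <- EBImage::medianFilter(down, size)
  as.matrix(EBImage::resize(med, w = nr, h = nc))
}

#' Segment neuromeres and neurites from a morphology-channel field
#'
#' Pipeline: (1) median-filter background subtraction and binarisation by
#' Otsu (computed over the image's own intensity range, hence invariant to
#' uniform scaling) or a fixed threshold; (2) morphological opening with a
#' disc of radius `soma_opening_radius_px` separates thick somata from thin
#' neurites; opened components of at least `min_neuromere_area_px` pixels
#' are neuromeres; (3) the neurite mask (binary mask minus dilated
#' neuromeres) is thinned to a 1-px skeleton, split at junction pixels
#' (>= 3 neighbours), and each piece is measured as a path length with
#' diagonal steps counting sqrt(2) pixels. Segments shorter than
#' `min_segment_length_px` are discarded. Areas/lengths are reported in
#' um^2 / um, sorted descending.
#'
#' @param image A morphology-channel [field_image()].
#' @param config A [segmentation_config()].
#' @return A `segmentation_result`: `neuromere_areas` (um^2),
#'   `neurite_segment_lengths` (um), `aggregate_pixel_count` (`NA` until
#'   [count_aggregate_pixels()] fills it), `neuromere_pixel_mask_size`,
#'   `neurite_pixel_mask_size`, `pixel_size_um`.
#' @export
segment_morphology <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "field_image"), image$channel == "morphology",
            inherits(config, "segmentation_config"))
  ps <- image$pixel_size_um
  maxv <- 2^image$bit_depth - 1
  x <- image$pixels / maxv

  empty <- structure(
    list(neuromere_areas = numeric(0), neurite_segment_lengths = numeric(0),
         aggregate_pixel_count = NA_integer_,
         neuromere_pixel_mask_size = 0L, neurite_pixel_mask_size = 0L,
         pixel_size_um = ps),
    class = "segmentation_result"
  )

  xs <- x - estimate_background(x, config$background_window_px)
  xs[xs < 0] <- 0
  if (max(xs) <= 0) return(empty)

  th <- if (config$morph_threshold_method == "otsu") {
    otsu_threshold(xs)
  } else {
    config$fixed_threshold / maxv
  }
  bw <- xs > th
  if (!any(bw)) return(empty)

  brush <- EBImage::makeBrush(2L * config$soma_opening_radius_px + 1L, "disc")
  opened <- as.matrix(EBImage::opening(bw, brush)) > 0
  lbl <- EBImage::bwlabel(opened)
  sizes <- tabulate(lbl[lbl > 0])
  keep <- which(sizes >= config$min_neuromere_area_px)
  neuromere_mask <- matrix(lbl %in% keep, nrow(bw), ncol(bw))
  areas_um2 <- sort(sizes[keep] * ps^2, decreasing = TRUE)

  dil <- if (any(neuromere_mask)) {
    as.matrix(EBImage::dilate(
      neuromere_mask,
      EBImage::makeBrush(2L * config$neuromere_dilation_px + 1L, "disc"))) > 0
  } else neuromere_mask
  neurite_mask <- bw & !dil

  skel <- thin_skeleton(neurite_mask)
  seg_skel <- skel & !junction_pixels(skel)
  len_px <- segment_lengths_px(seg_skel)
  lengths_um <- sort(len_px[len_px >= config$min_segment_length_px] * ps,
                     decreasing = TRUE)

  structure(
    list(neuromere_areas = areas_um2, neurite_segment_lengths = lengths_um,
         aggregate_pixel_count = NA_integer_,
         neuromere_pixel_mask_size = sum(neuromere_mask),
         neurite_pixel_mask_size = sum(neurite_mask),
         pixel_size_um = ps),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d neuromeres (total %.1f um^2), %d neurite segments (total %.1f um), aggregate px: %s\n",
    length(x$neuromere_areas), sum(x$neuromere_areas),
    length(x$neurite_segment_lengths), sum(x$neurite_segment_lengths),
    format(x$aggregate_pixel_count)
  ))
  invisible(x)
}

#' Tidy a segmentation result into one row per object
#'
#' @param x A `segmentation_result`.
#' @param ... Unused.
#' @return Tibble with columns `object_type` (`"neuromere"`/`"neurite"`),
#'   `id`, `value` (um^2 for areas, um for lengths).
#' @export
tidy.segmentation_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(object_type = "neuromere",
                   id = seq_along(x$neuromere_areas),
                   value = as.numeric(x$neuromere_areas)),
    tibble::tibble(object_type = "neurite",
                   id = seq_along(x$neurite_segment_lengths),
                   value = as.numeric(x$neurite_segment_lengths))
  )
}

#' Count reporter pixels above the aggregate threshold
#'
#' The screen's aggregation measure: the number of reporter-channel pixels
#' per image with intensity strictly higher than the calibrated threshold.
#'
#' @param image A reporter-channel [field_image()].
#' @param aggregate_threshold Raw intensity threshold, or a
#'   [segmentation_config()] carrying one.
#' @return Integer pixel count.
#' @export
count_aggregate_pixels <- function(image, aggregate_threshold) {
  stopifnot(inherits(image, "field_image"))
  if (inherits(aggregate_threshold, "segmentation_config"))
    aggregate_threshold <- aggregate_threshold$aggregate_threshold
  if (!is.finite(aggregate_threshold))
    stop("aggregate threshold is not set; run calibrate_aggregate_threshold()",
         call. = FALSE)
  sum(image$pixels > aggregate_threshold)
}

#' Calibrate the aggregate intensity threshold on aggregate-free controls
#'
#' Pools all pixel intensities of the reference reporter fields (vehicle
#' Htt15Q wells, which carry no aggregates) and returns their `q`-quantile.
#' Counting is strict (`>`), so a threshold at the reference maximum gives
#' zero counts on the references by construction.
#'
#' @param reference_images List of reporter-channel [field_image()]s.
#' @param q Quantile in (0, 1); default 0.999.
#' @return Raw intensity threshold.
#' @export
calibrate_aggregate_threshold <- function(reference_images, q = 0.999) {
  if (inherits(reference_images, "field_image"))
    reference_images <- list(reference_images)
  if (length(reference_images) == 0L)
    stop("at least one reference image is required for calibration",
         call. = FALSE)
  stopifnot(q > 0, q < 1)
  pooled <- unlist(lapply(reference_images, function(im) {
    stopifnot(inherits(im, "field_image"))
    as.vector(im$pixels)
  }))
  quantile(pooled, q, names = FALSE)
}

#' Pixel sizes of the neuromere and neurite masks
#'
#' The denominator of the reporter-distribution ratio (reporter pixels per
#' neuronal area).
#'
#' @param seg A `segmentation_result`.
#' @return Named integer vector `c(neuromere = , neurite = )`.
#' @export
neuronal_mask_sizes <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  c(neuromere = seg$neuromere_pixel_mask_size,
    neurite = seg$neurite_pixel_mask_size)
}

#' Count soluble (non-aggregate) reporter pixels
#'
#' Pixels with intensity above the soluble threshold but not above the
#' aggregate threshold: the numerator of the reporter-distribution ratio.
#'
#' @param image A reporter-channel [field_image()].
#' @param soluble_threshold Lower raw-intensity threshold (see
#'   [calibrate_soluble_threshold()]).
#' @param aggregate_threshold Upper threshold excluding aggregate pixels;
#'   `Inf` disables the exclusion.
#' @return Integer pixel count.
#' @export
count_soluble_pixels <- function(image, soluble_threshold,
                                 aggregate_threshold = Inf) {
  stopifnot(inherits(image, "field_image"), is.finite(soluble_threshold))
  sum(image$pixels > soluble_threshold &
        image$pixels <= aggregate_threshold)
}

#' Calibrate the soluble-reporter threshold
#'
#' A second, lower quantile threshold (default the 0.90 quantile of pooled
#' vehicle-Htt15Q reporter pixels) separating diffuse soluble reporter
#' signal from background for the reporter-distribution ratio.
#'
#' @inheritParams calibrate_aggregate_threshold
#' @export
calibrate_soluble_threshold <- function(reference_images, q = 0.90) {
  calibrate_aggregate_threshold(reference_images, q)
}
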