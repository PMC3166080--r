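# Synthetic two-channel culture fields and whole screens with ground truth.
#
# The generator emulates the structure the analysis assumes: sparse bright
# neuromere blobs whose log2 areas follow a three-component normal mixture,
# thin branched neurites with gamma-distributed lengths, punctate reporter
# aggregates over diffuse soluble signal, per-field Gaussian read noise and
# a Gaussian PSF blur. It is not a photorealistic optics model.

#' Parameters of a synthetic culture field
#'
#' Defaults describe the shared acquisition geometry and noise model;
#' phenotype parameters (rates, mixture, lengths) are set by
#' [control_params()] and [mutant_params()].
#'
#' @param field_width_px,field_height_px Field size in pixels. The test
#'   default is 256 x 256; the full acquisition geometry (1392 x 1040) is
#'   available by overriding.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param bit_depth Intensity bit depth.
#' @param neuromere_rate Expected neuromere blobs per field (Poisson mean).
#' @param area_mixture Data frame with columns `weight, mean, sd`: a
#'   three-component normal mixture on the log2 area (um^2) scale, means
#'   strictly increasing, weights summing to 1.
#' @param neurites_per_neuromere Poisson mean of neurites per blob.
#' @param length_shape,length_scale Gamma shape/scale of neurite length (um).
#' @param branch_prob Probability per walk step that a neurite forks.
#' @param heading_jitter Angular sd (radians) of the neurite random walk.
#' @param aggregate_rate Expected reporter puncta per field (Poisson mean).
#' @param aggregate_radius_px Punctum disc radius in pixels (integer >= 1).
#' @param aggregate_intensity Mean punctum intensity (counts); each punctum
#'   draws from a +/-10% band, well above any soluble level so a threshold
#'   separating aggregates from soluble signal exists by construction.
#' @param soluble_reporter_level Diffuse reporter intensity in neuronal
#'   pixels, as a fraction of `signal_level`.
#' @param signal_level Morphology-channel amplitude of neuronal pixels
#'   (counts).
#' @param background_level Additive background (counts).
#' @param noise_sd Gaussian read-noise sd (counts).
#' @param psf_sigma_px PSF blur sd in pixels (0 disables).
#' @return A `culture_params` list.
#' @export
culture_params <- function(field_width_px = 256L,
                           field_height_px = 256L,
                           pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                           bit_depth = 16L,
                           neuromere_rate = 7,
                           area_mixture = data.frame(
                             weight = c(0.35, 0.45, 0.20),
                             mean = c(6.0, 7.5, 9.0),
                             sd = c(0.35, 0.35, 0.35)
                           ),
                           neurites_per_neuromere = 3,
                           length_shape = 5,
                           length_scale = 14,
                           branch_prob = 0.01,
                           heading_jitter = 0.12,
                           aggregate_rate = 0,
                           aggregate_radius_px = 2L,
                           aggregate_intensity = 24000,
                           soluble_reporter_level = 0.5,
                           signal_level = 12000,
                           background_level = 400,
                           noise_sd = 150,
                           psf_sigma_px = 1) {
  p <- as.list(environment())
  validate_culture_params(p)
}

validate_culture_params <- function(p) {
  stopifnot(
    p$field_width_px >= 16, p$field_height_px >= 16,
    p$pixel_size_um > 0,
    p$neuromere_rate >= 0, p$neurites_per_neuromere >= 0,
    p$length_shape > 0, p$length_scale > 0,
    p$branch_prob >= 0, p$branch_prob <= 1,
    p$aggregate_rate >= 0, p$aggregate_radius_px >= 1,
    p$soluble_reporter_level >= 0, p$noise_sd >= 0, p$psf_sigma_px >= 0
  )
  am <- p$area_mixture
  stopifnot(
    nrow(am) == 3L,
    abs(sum(am$weight) - 1) < 1e-9,
    all(diff(am$mean) > 0),
    all(am$sd > 0)
  )
  structure(p, class = "culture_params")
}

#' Phenotype parameter sets for the two genotypes
#'
#' `control_params()` describes Htt15Q cultures: no aggregates, soluble
#' reporter filling neurons, long straight neurites and larger neuromeres.
#' `mutant_params()` describes Htt138Q cultures: numerous bright puncta,
#' little soluble signal, shorter neurites, more branching and a
#' down-shifted neuromere area mixture. `rescue` in `[0, 1]` linearly
#' interpolates every phenotype parameter from the mutant (0) to the
#' control (1) set, so `rescue = 1` reproduces the control exactly.
#'
#' @param base A [culture_params()] carrying geometry/noise settings.
#' @param rescue Mutant-to-control interpolation factor in `[0, 1]`.
#' @return A `culture_params` list.
#' @export
control_params <- function(base = culture_params()) {
  p <- unclass(base)
  p$neuromere_rate <- 7
  p$area_mixture <- data.frame(
    weight = c(0.35, 0.45, 0.20),
    mean = c(6.0, 7.5, 9.0),
    sd = c(0.35, 0.35, 0.35)
  )
  p$neurites_per_neuromere <- 3
  p$length_shape <- 5
  p$length_scale <- 14
  p$branch_prob <- 0.01
  p$aggregate_rate <- 0
  p$soluble_reporter_level <- 0.5
  validate_culture_params(p)
}

#' @rdname control_params
#' @export
mutant_params <- function(base = culture_params(), rescue = 0) {
  stopifnot(rescue >= 0, rescue <= 1)
  p <- unclass(base)
  p$neuromere_rate <- 7
  p$area_mixture <- data.frame(
    weight = c(0.55, 0.33, 0.12),
    mean = c(5.0, 6.5, 8.0),
    sd = c(0.35, 0.35, 0.35)
  )
  p$neurites_per_neuromere <- 3
  p$length_shape <- 5
  p$length_scale <- 6
  p$branch_prob <- 0.04
  p$aggregate_rate <- 30
  p$soluble_reporter_level <- 0.12
  mut <- validate_culture_params(p)
  if (rescue == 0) return(mut)
  interpolate_params(mut, control_params(base), rescue)
}

# Element-wise linear interpolation of the phenotype parameters from `from`
# (r = 0) to `to` (r = 1); geometry and noise settings come from `from`.
interpolate_params <- function(from, to, r) {
  p <- unclass(from)
  for (f in c("neuromere_rate", "neurites_per_neuromere", "length_shape",
              "length_scale", "branch_prob", "heading_jitter",
              "aggregate_rate", "soluble_reporter_level")) {
    p[[f]] <- (1 - r) * from[[f]] + r * to[[f]]
  }
  for (col in c("weight", "mean", "sd")) {
    p$area_mixture[[col]] <-
      (1 - r) * from$area_mixture[[col]] + r * to$area_mixture[[col]]
  }
  validate_culture_params(p)
}

# Linear indices of a filled disc clipped to an nr x nc grid.
disc_indices <- function(ci, cj, r, nr, nc) {
  i <- max(1L, floor(ci - r)):min(nr, ceiling(ci + r))
  j <- max(1L, floor(cj - r)):min(nc, ceiling(cj + r))
  if (length(i) == 0L || length(j) == 0L) return(integer(0))
  d2 <- outer((i - ci)^2, (j - cj)^2, `+`)
  keep <- which(d2 <= r^2)
  ii <- i[((keep - 1L) %% length(i)) + 1L]
  jj <- j[((keep - 1L) %/% length(i)) + 1L]
  (jj - 1L) * nr + ii
}

# Rasterise one neurite as a jittered persistent random walk with forks.
# Returns pixel indices and the planted segment lengths (um) between forks.
walk_neurite <- function(start_i, start_j, heading, n_steps, params, nr, nc) {
  jitter <- params$heading_jitter
  path <- integer(0)   # centreline pixels, in walk order, with NA at arm ends
  thick <- integer(0)  # thickening pixels (2 px width normal to heading)
  # queue of branches: each is (i, j, heading, steps, depth)
  queue <- list(list(i = start_i, j = start_j, h = heading,
                     steps = n_steps, depth = 0L))
  while (length(queue) > 0L) {
    b <- queue[[1L]]; queue <- queue[-1L]
    if (b$steps < 1L) next
    dh <- rnorm(b$steps, 0, jitter)
    h <- b$h + cumsum(dh)
    forks <- if (b$depth < 3L && params$branch_prob > 0) {
      which(runif(b$steps) < params$branch_prob)
    } else integer(0)
    stop_at <- b$steps
    if (length(forks) > 0L) stop_at <- forks[1L]
    h <- h[seq_len(stop_at)]
    di <- cumsum(sin(h)); dj <- cumsum(cos(h))
    ii <- round(b$i + di); jj <- round(b$j + dj)
    inside <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    n_in <- if (all(inside)) stop_at else (which(!inside)[1L] - 1L)
    if (n_in >= 1L) {
      s <- seq_len(n_in)
      path <- c(path, (jj[s] - 1L) * nr + ii[s], NA_integer_)
      # thicken to 2 px normal to the local heading
      i2 <- ii[s] + round(cos(h[s])); j2 <- jj[s] - round(sin(h[s]))
      ok2 <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
      thick <- c(thick, (j2[ok2] - 1L) * nr + i2[ok2])
    }
    # fork: both arms continue from the fork point with the remaining steps
    if (length(forks) > 0L && n_in == stop_at && b$steps > stop_at) {
      rest <- b$steps - stop_at
      fi <- b$i + di[stop_at]; fj <- b$j + dj[stop_at]
      split <- runif(1, 0.4, 0.8)
      queue <- c(queue, list(
        list(i = fi, j = fj, h = h[stop_at] + split, steps = rest,
             depth = b$depth + 1L),
        list(i = fi, j = fj, h = h[stop_at] - split, steps = rest,
             depth = b$depth + 1L)
      ))
    }
  }
  list(path = path, thick = thick)
}

# Planted segment lengths: walked steps split at arm ends (NA markers) and
# wherever the walk passes through a soma blob, which occludes the neurite.
planted_segment_lengths <- function(path, blob_mask, pixel_size_um) {
  if (length(path) == 0L) return(numeric(0))
  visible <- !is.na(path) & !blob_mask[ifelse(is.na(path), 1L, path)]
  r <- rle(visible)
  r$lengths[r$values] * pixel_size_um
}

#' Generate one synthetic two-channel culture field
#'
#' Renders neuromeres as filled discs with log2 areas drawn from the
#' parameter mixture (placed without overlap so planted counts are an exact
#' segmentation oracle on noiseless fields), neurites as 1-px random-walk
#' polylines emanating from blob boundaries, and the reporter channel as
#' bright aggregate puncta over `soluble_reporter_level` times the neuronal
#' mask. Both channels are blurred by the PSF and corrupted with Gaussian
#' noise. Identical seeds give bit-identical output.
#'
#' @param params A [culture_params()].
#' @param seed Integer seed for this field.
#' @param well_id,site_index Identity stamped on the returned images.
#' @return List with elements `morphology` and `reporter` (both
#'   [field_image()]) and `truth`, a list recording everything planted:
#'   neuromere areas (um^2, as rasterised) and their sampled log2 areas and
#'   mixture components, neurite segment lengths (um), aggregate pixel
#'   count, and mask sizes.
#' @export
generate_culture_field <- function(params, seed, well_id = "A01",
                                   site_index = 1L) {
  stopifnot(inherits(params, "culture_params"))
  set.seed(seed)
  nr <- params$field_height_px
  nc <- params$field_width_px
  ps <- params$pixel_size_um

  blob_mask <- matrix(FALSE, nr, nc)
  keep_clear <- matrix(FALSE, nr, nc)  # blobs + separation margin
  n_blobs <- rpois(1, params$neuromere_rate)
  areas_um2 <- numeric(0)
  log2_sampled <- numeric(0)
  comps <- integer(0)
  centers <- matrix(numeric(0), ncol = 2)

  am <- params$area_mixture
  margin_gap <- 12  # px between blob edges; keeps components separable
  for (b in seq_len(n_blobs)) {
    comp <- sample.int(3L, 1L, prob = am$weight)
    l2a <- rnorm(1, am$mean[comp], am$sd[comp])
    r_px <- sqrt((2^l2a / ps^2) / pi)
    placed <- FALSE
    if (2 * r_px + 6 >= min(nr, nc)) {
      warning("synthetic field: neuromere of log2 area ", round(l2a, 2),
              " does not fit the field; skipped", call. = FALSE)
      next
    }
    for (try in 1:30) {
      ci <- runif(1, r_px + 2, nr - r_px - 1)
      cj <- runif(1, r_px + 2, nc - r_px - 1)
      if (ci <= r_px + 1 || cj <= r_px + 1) next
      guard <- disc_indices(ci, cj, r_px + margin_gap, nr, nc)
      if (any(keep_clear[guard])) next
      idx <- disc_indices(ci, cj, r_px, nr, nc)
      blob_mask[idx] <- TRUE
      keep_clear[idx] <- TRUE
      areas_um2 <- c(areas_um2, length(idx) * ps^2)
      log2_sampled <- c(log2_sampled, l2a)
      comps <- c(comps, comp)
      centers <- rbind(centers, c(ci, cj))
      placed <- TRUE
      break
    }
    if (!placed)
      warning("synthetic field: could not place a neuromere of log2 area ",
              round(l2a, 2), "; skipped", call. = FALSE)
  }
  n_placed <- length(areas_um2)

  neurite_mask <- matrix(FALSE, nr, nc)
  seg_lengths <- numeric(0)
  if (n_placed > 0 && params$neurites_per_neuromere > 0) {
    for (b in seq_len(n_placed)) {
      n_neur <- rpois(1, params$neurites_per_neuromere)
      r_px <- sqrt((areas_um2[b] / ps^2) / pi)
      for (k in seq_len(n_neur)) {
        ang <- runif(1, 0, 2 * pi)
        len_um <- rgamma(1, shape = params$length_shape,
                         scale = params$length_scale)
        steps <- max(1L, round(len_um / ps))
        w <- walk_neurite(centers[b, 1] + (r_px + 1) * sin(ang),
                          centers[b, 2] + (r_px + 1) * cos(ang),
                          ang, steps, params, nr, nc)
        neurite_mask[w$path[!is.na(w$path)]] <- TRUE
        neurite_mask[w$thick] <- TRUE
        seg_lengths <- c(seg_lengths,
                         planted_segment_lengths(w$path, blob_mask, ps))
      }
    }
  }
  neurite_only <- neurite_mask & !blob_mask
  neuronal <- blob_mask | neurite_only

  # reporter channel: puncta over diffuse soluble signal
  agg_mask <- matrix(FALSE, nr, nc)
  n_agg <- rpois(1, params$aggregate_rate)
  neuron_idx <- which(neuronal)
  if (n_agg > 0 && length(neuron_idx) > 0) {
    at <- sample(neuron_idx, n_agg, replace = TRUE)
    for (a in at) {
      ci <- ((a - 1L) %% nr) + 1L
      cj <- ((a - 1L) %/% nr) + 1L
      agg_mask[disc_indices(ci, cj, params$aggregate_radius_px, nr, nc)] <- TRUE
    }
  }

  morph <- matrix(params$background_level, nr, nc)
  morph[neurite_only] <- params$background_level + 0.8 * params$signal_level
  morph[blob_mask] <- params$background_level + params$signal_level

  rep_ch <- matrix(params$background_level, nr, nc)
  rep_ch[neuronal] <- params$background_level +
    params$soluble_reporter_level * params$signal_level
  if (any(agg_mask)) {
    rep_ch[agg_mask] <- runif(sum(agg_mask), 0.9, 1.1) *
      params$aggregate_intensity
  }

  maxv <- 2^params$bit_depth - 1
  finish <- function(x) {
    if (params$psf_sigma_px > 0)
      x <- as.matrix(EBImage::gblur(EBImage::Image(x / 65535),
                                    sigma = params$psf_sigma_px)) * 65535
    if (params$noise_sd > 0)
      x <- x + rnorm(length(x), 0, params$noise_sd)
    x <- round(x)
    x[x < 0] <- 0
    x[x > maxv] <- maxv
    storage.mode(x) <- "integer"
    matrix(x, nr, nc)
  }

  truth <- list(
    n_neuromeres = n_placed,
    neuromere_areas_um2 = areas_um2,
    neuromere_log2_areas = log2_sampled,
    neuromere_components = comps,
    neurite_segment_lengths_um = seg_lengths,
    total_neurite_length_um = sum(seg_lengths),
    aggregate_pixel_count = sum(agg_mask),
    n_aggregates = n_agg,
    neuromere_mask_px = sum(blob_mask),
    neurite_mask_px = sum(neurite_only)
  )
  list(
    morphology = field_image(finish(morph), well_id, site_index, "morphology",
                             ps, params$bit_depth),
    reporter = field_image(finish(rep_ch), well_id, site_index, "reporter",
                           ps, params$bit_depth),
    truth = truth
  )
}

#' Build a default screen plate layout
#'
#' Vehicle (DMSO) wells for both genotypes followed by compound-treated
#' Htt138Q wells in duplicate, filling a 96-well plate by default
#' (8 + 8 vehicle wells + 40 treatments x 2 replicates).
#'
#' @param n_treatments Number of distinct treatments.
#' @param n_vehicle_per_genotype Vehicle wells per genotype.
#' @param duplicates Replicate wells per treatment.
#' @param treatment_prefix Prefix for generated treatment ids.
#' @return A `plate_layout` tibble.
#' @export
screen_layout <- function(n_treatments = 40L, n_vehicle_per_genotype = 8L,
                          duplicates = 2L, treatment_prefix = "cmpd") {
  n_wells <- 2L * n_vehicle_per_genotype + n_treatments * duplicates
  rows <- ceiling(n_wells / 12L)
  wells <- as.vector(t(outer(LETTERS[seq_len(max(rows, 1L))], 1:12,
                             function(r, c) sprintf("%s%02d", r, c))))
  if (n_wells > length(wells))
    stop("layout does not fit: ", n_wells, " wells requested", call. = FALSE)
  veh <- tibble::tibble(
    genotype = rep(GENOTYPES, each = n_vehicle_per_genotype),
    treatment_id = "DMSO",
    treatment_kind = "VEHICLE",
    concentration = "0.2",
    unit = "%",
    replicate_group = rep(paste0("rep", seq_len(n_vehicle_per_genotype)), 2L)
  )
  trt <- tibble::tibble(
    genotype = "HTT138Q",
    treatment_id = rep(sprintf("%s%03d", treatment_prefix,
                               seq_len(n_treatments)), each = duplicates),
    treatment_kind = "COMPOUND",
    concentration = "10",
    unit = "uM",
    replicate_group = rep(paste0("rep", seq_len(duplicates)), n_treatments)
  )
  layout <- dplyr::bind_rows(veh, trt)
  layout <- dplyr::bind_cols(tibble::tibble(well = wells[seq_len(nrow(layout))]),
                             layout)
  validate_plate_layout(layout)
}

#' Generate a whole synthetic screen with ground truth
#'
#' Emulates the screen design: 3 sites imaged per well, treatments in
#' duplicate wells, in-plate vehicle controls of both genotypes. Planted
#' effects are applied to Htt138Q treated wells: `AGG_SUPPRESSOR` scales
#' the aggregate rate by `factor` only; `DUAL_RESCUER` additionally
#' interpolates all morphology parameters toward the control by `rescue`;
#' `TOXIC` shrinks neuromere areas and neurite lengths below mutant levels.
#' Every well/site draws from an independent substream derived from
#' `(seed, plate, well, site)`, so output is reproducible independent of
#' generation order.
#'
#' @param layout A `plate_layout` (default [screen_layout()]); must contain
#'   at least 2 vehicle wells per genotype.
#' @param effects Named list keyed by treatment id; each element a list with
#'   `label` in `AGG_SUPPRESSOR, DUAL_RESCUER, TOXIC` and optional `factor`
#'   (aggregate-rate multiplier) and `rescue`. Treatments not named are NULL
#'   (no effect).
#' @param fields_per_well Sites imaged per well (default 3).
#' @param seed Master integer seed.
#' @param base Shared [culture_params()] (geometry/noise).
#' @param plate_id Plate identifier used in substreams and filenames.
#' @param write_dir Optional directory: writes one TIFF per well/site/channel
#'   (`{plate}_{well}_s{site}_{channel}.tif`), the layout CSV and a ground
#'   truth JSON.
#' @return A `synthetic_screen` list: `fields` (named `well_s<site>`, each
#'   holding `morphology`, `reporter`, `truth`), `layout`, `truth`
#'   (per-treatment labels), `plate_id`, `params`.
#' @export
generate_screen <- function(layout = screen_layout(), effects = list(),
                            fields_per_well = 3L, seed = 1L,
                            base = culture_params(), plate_id = "P01",
                            write_dir = NULL) {
  layout <- validate_plate_layout(layout)
  for (g in GENOTYPES) {
    nveh <- sum(layout$genotype == g &
                  layout$treatment_kind %in% c("VEHICLE", "MOCK"))
    if (nveh < 2L)
      stop("need at least 2 vehicle/mock wells for genotype ", g, call. = FALSE)
  }
  trt_ids <- unique(layout$treatment_id[
    !layout$treatment_kind %in% c("VEHICLE", "MOCK")])
  unknown <- setdiff(names(effects), trt_ids)
  if (length(unknown) > 0L)
    stop("effect map names absent from layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  mut <- mutant_params(base)
  ctl <- control_params(base)
  well_params <- function(genotype, treatment_id) {
    p <- if (genotype == "HTT15Q") ctl else mut
    eff <- effects[[treatment_id]]
    if (is.null(eff) || genotype != "HTT138Q") return(p)
    label <- match.arg(eff$label, c("AGG_SUPPRESSOR", "DUAL_RESCUER", "TOXIC"))
    if (label == "AGG_SUPPRESSOR") {
      p$aggregate_rate <- mut$aggregate_rate * (eff$factor %||% 1)
    } else if (label == "DUAL_RESCUER") {
      p <- interpolate_params(mut, ctl, eff$rescue %||% 1)
      if (!is.null(eff$factor))
        p$aggregate_rate <- mut$aggregate_rate * eff$factor
    } else {  # TOXIC: worse than mutant
      p$length_scale <- mut$length_scale * (eff$factor %||% 0.6)
      p$area_mixture$mean <- mut$area_mixture$mean - 0.5
      p$branch_prob <- min(1, mut$branch_prob * 1.5)
    }
    validate_culture_params(p)
  }

  fields <- vector("list", nrow(layout) * fields_per_well)
  names(fields) <- as.vector(vapply(layout$well, function(w) {
    sprintf("%s_s%d", w, seq_len(fields_per_well))
  }, character(fields_per_well)))
  for (w in seq_len(nrow(layout))) {
    p <- well_params(layout$genotype[w], layout$treatment_id[w])
    for (s in seq_len(fields_per_well)) {
      fs <- substream_seed(seed, plate_id, layout$well[w], s)
      fields[[sprintf("%s_s%d", layout$well[w], s)]] <-
        generate_culture_field(p, fs, well_id = layout$well[w],
                               site_index = s)
    }
  }

  labels <- tibble::tibble(
    treatment_id = trt_ids,
    label = vapply(trt_ids, function(id) {
      if (is.null(effects[[id]])) "NULL" else effects[[id]]$label
    }, character(1))
  )
  screen <- structure(
    list(fields = fields, layout = layout, truth = labels,
         plate_id = plate_id, params = base, seed = seed,
         fields_per_well = fields_per_well),
    class = "synthetic_screen"
  )
  if (!is.null(write_dir)) write_screen(screen, write_dir)
  screen
}

#' Write a synthetic screen to disk in the plate I/O formats
#'
#' @param screen A [generate_screen()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(screen$fields)) {
    f <- screen$fields[[key]]
    for (ch in CHANNELS) {
      img <- f[[ch]]
      write_field_image(img, file.path(dir, sprintf(
        "%s_%s_s%d_%s.tif", screen$plate_id, img$well_id, img$site_index, ch)))
    }
  }
  write_plate_layout(screen$layout, file.path(dir, "layout.csv"))
  truths <- lapply(screen$fields, function(f) f$truth)
  jsonlite::write_json(
    list(plate_id = screen$plate_id, seed = screen$seed,
         treatment_labels = screen$truth, per_field = truths),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
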