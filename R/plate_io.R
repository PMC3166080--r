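# Plate/field I/O, acquisition geometry, and image/well exclusion rules.

# Default pixel calibration of the screen's acquisition geometry:
# 1392 x 1040 px fields spanning 897 x 670 um at 10x.
DEFAULT_PIXEL_SIZE_UM <- 897 / 1392

CHANNELS <- c("morphology", "reporter")
GENOTYPES <- c("HTT15Q", "HTT138Q")
TREATMENT_KINDS <- c("COMPOUND", "RNAI", "VEHICLE", "MOCK")

#' Construct a single-channel field image
#'
#' A field image is one channel (morphology = membrane GFP, reporter =
#' Htt-RFP) of one imaged site of one well, together with its pixel
#' calibration. Pixels are non-negative integers within the declared bit
#' depth; coordinates are row-major with the origin at the top left.
#'
#' @param pixels Integer matrix of intensities (rows = image rows).
#' @param well_id Plate coordinate, e.g. `"A01"`.
#' @param site_index Imaged site within the well (integer >= 1).
#' @param channel `"morphology"` or `"reporter"`.
#' @param pixel_size_um Micrometres per pixel edge. Defaults to the
#'   acquisition geometry 897/1392 um/px.
#' @param bit_depth Intensity bit depth (8 or 16).
#' @return A `field_image` object.
#' @export
field_image <- function(pixels, well_id, site_index = 1L,
                        channel = c("morphology", "reporter"),
                        pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                        bit_depth = 16L) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L))
    stop("pixel intensities must be non-negative and finite", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  if (any(pixels > 2^bit_depth - 1))
    stop("pixel intensities exceed the declared bit depth", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (!(is.numeric(site_index) && length(site_index) == 1L && site_index >= 1))
    stop("`site_index` must be a single integer >= 1", call. = FALSE)
  structure(
    list(
      well_id = as.character(well_id),
      site_index = as.integer(site_index),
      channel = channel,
      pixels = pixels,
      pixel_size_um = pixel_size_um,
      bit_depth = as.integer(bit_depth)
    ),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> well %s site %d channel %s: %d x %d px (%.4f um/px, %d-bit)\n",
    x$well_id, x$site_index, x$channel, nrow(x$pixels), ncol(x$pixels),
    x$pixel_size_um, x$bit_depth
  ))
  invisible(x)
}

#' Read a field image from a single-plane grayscale TIFF
#'
#' @param path Path to the TIFF file.
#' @inheritParams field_image
#' @param pixel_size_um Calibration in um/px; when `NULL` the default
#'   897/1392 from the acquisition geometry is used.
#' @return A [field_image()].
#' @export
read_field_image <- function(path, well_id, site_index = 1L,
                             channel = c("morphology", "reporter"),
                             pixel_size_um = NULL) {
  channel <- match.arg(channel)
  if (!file.exists(path))
    stop("cannot read field image: file not found: ", path, call. = FALSE)
  planes <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, all = TRUE),
    error = function(e) stop("cannot decode TIFF: ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(planes) != 1L)
    stop("multi-plane TIFF not supported: ", path, call. = FALSE)
  px <- planes[[1L]]
  if (length(dim(px)) == 3L)
    stop("RGB/multi-channel TIFF not supported (expected grayscale): ", path,
         call. = FALSE)
  bits <- attr(px, "bits.per.sample")
  bit_depth <- if (!is.null(bits) && bits <= 8) 8L else 16L
  if (max(px) > 2^bit_depth - 1) bit_depth <- 16L
  field_image(px, well_id, site_index, channel,
              pixel_size_um = pixel_size_um %||% DEFAULT_PIXEL_SIZE_UM,
              bit_depth = bit_depth)
}

#' Write a field image to a single-plane grayscale TIFF
#'
#' @param image A [field_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  maxv <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$pixels / maxv, path,
                  bits.per.sample = image$bit_depth, compression = "none")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a plate layout from CSV
#'
#' The layout assigns each well a genotype (`HTT15Q` control or `HTT138Q`
#' mutant), a treatment and its kind (`COMPOUND`, `RNAI`, `VEHICLE`, `MOCK`),
#' a concentration (free text value + unit; empty for vehicle/mock), and a
#' replicate group. Required columns: `well, genotype, treatment_id,
#' treatment_kind, concentration, unit, replicate_group`.
#'
#' @param path CSV file path.
#' @return A tibble of class `plate_layout`, one row per well.
#' @export
load_plate_layout <- function(path) {
  if (!file.exists(path))
    stop("plate layout not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("well", "genotype", "treatment_id", "treatment_kind",
                "concentration", "unit", "replicate_group")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("plate layout missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_plate_layout(raw[required])
}

validate_plate_layout <- function(layout) {
  layout <- tibble::as_tibble(layout)
  layout$concentration[is.na(layout$concentration)] <- ""
  layout$unit[is.na(layout$unit)] <- ""
  dup <- layout$well[duplicated(layout$well)]
  if (length(dup) > 0L)
    stop("duplicate well ids in plate layout: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad_g <- which(!layout$genotype %in% GENOTYPES)
  if (length(bad_g) > 0L)
    stop("unknown genotype in layout row(s) ",
         paste(bad_g, collapse = ", "), ": ",
         paste(unique(layout$genotype[bad_g]), collapse = ", "),
         " (expected ", paste(GENOTYPES, collapse = "/"), ")", call. = FALSE)
  bad_k <- which(!layout$treatment_kind %in% TREATMENT_KINDS)
  if (length(bad_k) > 0L)
    stop("unknown treatment_kind in layout row(s) ",
         paste(bad_k, collapse = ", "), ": ",
         paste(unique(layout$treatment_kind[bad_k]), collapse = ", "),
         call. = FALSE)
  class(layout) <- c("plate_layout", class(layout))
  layout
}

#' Write a plate layout to CSV
#'
#' @param layout A plate layout tibble (see [load_plate_layout()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  readr::write_csv(tibble::as_tibble(unclass(layout))[, c(
    "well", "genotype", "treatment_id", "treatment_kind",
    "concentration", "unit", "replicate_group"
  )], path, progress = FALSE)
  invisible(path)
}

#' Image-level quality control for one field
#'
#' Reproduces the screen's image exclusion rules: out-of-focus fields and
#' fields lacking cell profiles are unusable. Focus is scored by the
#' variance of a discrete Laplacian of the min-max-normalised morphology
#' channel (a standard, parameter-light sharpness proxy); presence of cells
#' is taken from the segmentation (at least one neuromere).
#'
#' @param image A morphology-channel [field_image()].
#' @param seg Optional [segment_morphology()] result for the same field;
#'   when absent `has_cells` is `NA`.
#' @param focus_threshold Minimum focus metric to count as in focus.
#' @return One-row tibble: `well_id, site_index, focus_metric, in_focus,
#'   has_cells, usable`.
#' @export
assess_field_quality <- function(image, seg = NULL, focus_threshold = 0) {
  stopifnot(inherits(image, "field_image"))
  fm <- focus_metric(image$pixels)
  in_focus <- fm >= focus_threshold
  has_cells <- if (is.null(seg)) NA else length(seg$neuromere_areas) > 0L
  tibble::tibble(
    well_id = image$well_id,
    site_index = image$site_index,
    focus_metric = fm,
    in_focus = in_focus,
    has_cells = has_cells,
    usable = in_focus & has_cells
  )
}

# Variance of the 4-neighbour discrete Laplacian of the min-max-normalised
# image. Flat images score 0; blur strictly reduces the score.
focus_metric <- function(px) {
  px <- px - min(px)
  mx <- max(px)
  if (mx == 0) return(0)
  x <- px / mx
  lap <- shift_mat(x, 1, 0, 0) + shift_mat(x, -1, 0, 0) +
    shift_mat(x, 0, 1, 0) + shift_mat(x, 0, -1, 0) - 4 * x
  # borders see zero padding; restrict to the interior
  interior <- lap[2:(nrow(x) - 1), 2:(ncol(x) - 1)]
  var(as.vector(interior))
}

#' Apply the minimum-image inclusion rule per treatment
#'
#' A treatment (pooled over its replicate wells) is included when it has at
#' least `min_images` usable images; the screen design of 3 sites per well
#' in duplicate makes 6 the natural default. Exclusion reasons are recorded
#' per treatment rather than raised as errors.
#'
#' @param qc QC table: one row per field as returned by
#'   [assess_field_quality()] (rows bound together).
#' @param layout Plate layout tibble.
#' @param min_images Minimum usable images per treatment (default 6).
#' @param scope Pool images `"treatment"`-wide across replicate wells
#'   (default) or require the count `"well"`-wise in every well.
#' @return Tibble: `genotype, treatment_id, n_images, n_usable, included,
#'   reason`.
#' @export
select_usable_wells <- function(qc, layout, min_images = 6L,
                                scope = c("treatment", "well")) {
  scope <- match.arg(scope)
  stopifnot(min_images >= 1L)
  joined <- dplyr::left_join(
    tibble::as_tibble(unclass(layout)), qc,
    by = c(well = "well_id")
  )
  per_well <- joined |>
    dplyr::group_by(.data$genotype, .data$treatment_id, .data$well) |>
    dplyr::summarise(
      n_images = sum(!is.na(.data$usable)),
      n_usable = sum(.data$usable %in% TRUE),
      .groups = "drop"
    )
  out <- per_well |>
    dplyr::group_by(.data$genotype, .data$treatment_id) |>
    dplyr::summarise(
      n_images = sum(.data$n_images),
      n_usable = sum(.data$n_usable),
      all_wells_ok = all(.data$n_usable >= min_images),
      .groups = "drop"
    )
  out$included <- if (scope == "treatment") {
    out$n_usable >= min_images
  } else {
    out$all_wells_ok & out$n_images > 0L
  }
  out$reason <- dplyr::case_when(
    out$included ~ "",
    out$n_images == 0L ~ "no images",
    TRUE ~ sprintf("fewer than %d usable images (%d)", min_images,
                   out$n_usable)
  )
  out$all_wells_ok <- NULL
  out
}
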