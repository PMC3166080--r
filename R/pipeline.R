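# End-to-end orchestration: QC -> segmentation -> calibration ->
# morphometry -> statistics -> hit calling, with an auditable manifest.

#' Load a screen's images and layout from disk
#'
#' Reads TIFFs written as `{plate}_{well}_s{site}_{channel}.tif` together
#' with the layout CSV, reconstructing the in-memory structure produced by
#' [generate_screen()].
#'
#' @param dir Directory containing the images.
#' @param layout Path to the layout CSV (default `layout.csv` in `dir`).
#' @param plate_id Plate identifier prefix of the filenames; default is
#'   inferred from the first TIFF found.
#' @param pixel_size_um Calibration applied to all images.
#' @return A `synthetic_screen`-shaped list (without ground truth).
#' @export
load_screen_images <- function(dir, layout = file.path(dir, "layout.csv"),
                               plate_id = NULL,
                               pixel_size_um = DEFAULT_PIXEL_SIZE_UM) {
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no TIFF images found in ", dir, call. = FALSE)
  meta <- regmatches(basename(files),
                     regexec("^(.+)_([A-P][0-9]{2})_s([0-9]+)_(morphology|reporter)\\.tif$",
                             basename(files)))
  ok <- lengths(meta) == 5L
  if (!any(ok))
    stop("no files match the {plate}_{well}_s{site}_{channel}.tif pattern",
         call. = FALSE)
  files <- files[ok]; meta <- meta[ok]
  plate_id <- plate_id %||% meta[[1L]][2L]
  fields <- list()
  for (i in seq_along(files)) {
    m <- meta[[i]]
    key <- sprintf("%s_s%s", m[3L], m[4L])
    if (is.null(fields[[key]])) fields[[key]] <- list()
    fields[[key]][[m[5L]]] <- read_field_image(
      files[i], well_id = m[3L], site_index = as.integer(m[4L]),
      channel = m[5L], pixel_size_um = pixel_size_um)
  }
  structure(
    list(fields = fields, layout = load_plate_layout(layout),
         truth = NULL, plate_id = plate_id),
    class = "synthetic_screen"
  )
}

#' Run the full screen analysis
#'
#' Executes every stage in order on a screen's fields: morphology
#' segmentation, focus/cell QC, the minimum-usable-image exclusion rule per
#' treatment, aggregate-threshold calibration on vehicle Htt15Q reporter
#' fields, binning-model fits on the pooled vehicle wells, per-field
#' feature computation, per-treatment aggregation and morphology tests
#' against the in-plate vehicle references, the screen-wide 2-SD cutoff,
#' and two-stage hit classification. All steps are deterministic given the
#' inputs, so reruns reproduce identical outputs.
#'
#' @param screen A [generate_screen()] or [load_screen_images()] result.
#' @param seg_config A [segmentation_config()]; its `aggregate_threshold`
#'   is calibrated in-run when unset.
#' @param alpha Significance level for both stages.
#' @param m Screen-threshold multiplier (default 2 SD).
#' @param min_images Minimum usable images per treatment (default 6).
#' @param agg_quantile Calibration quantile for the aggregate threshold.
#' @param focus_frac The focus threshold is this fraction of the median
#'   vehicle-well focus metric (default 0.25).
#' @param stage1_rule Stage-1 rule passed to [call_hits()].
#' @param rescue_floor Partial-reversion floor passed to [call_hits()].
#' @return A `screen_result` list: `features` (per-field tibble), `hits`
#'   (a `hit_table`), `qc`, `inclusion`, `models`, `threshold`,
#'   `aggregate_threshold`, `baseline`, `manifest`.
#' @export
run_screen <- function(screen, seg_config = segmentation_config(),
                       alpha = 0.05, m = 2, min_images = 6L,
                       agg_quantile = 0.999, focus_frac = 0.25,
                       stage1_rule = c("and", "or", "p"),
                       rescue_floor = 1e-6) {
  stage1_rule <- match.arg(stage1_rule)
  layout <- screen$layout
  stopifnot(!is.null(layout), length(screen$fields) > 0L)
  is_vehicle <- layout$treatment_kind %in% c("VEHICLE", "MOCK")
  for (g in GENOTYPES) {
    if (sum(is_vehicle & layout$genotype == g) < 2L)
      stop("configuration error: need >= 2 vehicle wells for genotype ", g,
           call. = FALSE)
  }
  well_of <- setNames(seq_len(nrow(layout)), layout$well)
  veh_15q <- layout$well[is_vehicle & layout$genotype == "HTT15Q"]
  veh_138q <- layout$well[is_vehicle & layout$genotype == "HTT138Q"]

  # stage 1: segmentation + focus metric for every field
  keys <- names(screen$fields)
  segs <- vector("list", length(keys)); names(segs) <- keys
  focus <- numeric(length(keys))
  wells <- character(length(keys)); sites <- integer(length(keys))
  for (i in seq_along(keys)) {
    f <- screen$fields[[keys[i]]]
    segs[[i]] <- segment_morphology(f$morphology, seg_config)
    focus[i] <- focus_metric(f$morphology$pixels)
    wells[i] <- f$morphology$well_id
    sites[i] <- f$morphology$site_index
  }
  veh_focus <- focus[wells %in% layout$well[is_vehicle]]
  focus_threshold <- focus_frac * median(veh_focus)

  has_cells <- vapply(segs, function(s) length(s$neuromere_areas) > 0L,
                      logical(1))
  in_focus <- focus >= focus_threshold
  qc <- tibble::tibble(
    well_id = wells, site_index = sites, focus_metric = focus,
    in_focus = in_focus, has_cells = has_cells,
    usable = in_focus & has_cells
  )
  inclusion <- select_usable_wells(qc, layout, min_images)
  usable_key <- keys[qc$usable]

  # stage 2: aggregate threshold from usable vehicle-15Q reporter fields
  ref_imgs <- lapply(usable_key[wells[qc$usable] %in% veh_15q],
                     function(k) screen$fields[[k]]$reporter)
  if (length(ref_imgs) == 0L)
    stop("no usable vehicle Htt15Q reporter fields to calibrate on",
         call. = FALSE)
  agg_threshold <- calibrate_aggregate_threshold(ref_imgs, agg_quantile)
  agg_counts <- vapply(keys, function(k) {
    count_aggregate_pixels(screen$fields[[k]]$reporter, agg_threshold)
  }, numeric(1))

  # stage 3: binning models on pooled usable vehicle objects, then frozen
  veh_keys <- usable_key[wells[qc$usable] %in% c(veh_15q, veh_138q)]
  pooled_areas <- unlist(lapply(veh_keys,
                                function(k) segs[[k]]$neuromere_areas))
  pooled_lens <- unlist(lapply(veh_keys,
                               function(k) segs[[k]]$neurite_segment_lengths))
  areas_model <- fit_area_bins(log2(pooled_areas))
  lengths_model <- fit_length_groups(pooled_lens)

  # stage 4: per-field features for usable fields with cells
  features <- dplyr::bind_rows(lapply(usable_key, function(k) {
    fv <- compute_features(segs[[k]], areas_model, lengths_model)
    img <- screen$fields[[k]]$morphology
    row <- layout[well_of[[img$well_id]], ]
    dplyr::bind_cols(
      tibble::tibble(well = img$well_id, site = img$site_index,
                     genotype = row$genotype, treatment_id = row$treatment_id,
                     treatment_kind = row$treatment_kind),
      fv,
      tibble::tibble(aggregate_pixels = agg_counts[[k]])
    )
  }))

  ref_features <- features[features$well %in% veh_15q, ]
  mut_veh_features <- features[features$well %in% veh_138q, ]
  dmso_counts <- features$aggregate_pixels[features$well %in% veh_138q]

  baseline_test <- morphology_rescue_test(mut_veh_features, ref_features)
  baseline <- list(
    morph_combined_p = baseline_test$combined_p,
    mean_neurite_length = mean(mut_veh_features$mean_neurite_length),
    mean_neuromere_area = mean(mut_veh_features$mean_neuromere_area)
  )

  # stage 5: per-treatment tests (treated Htt138Q wells only)
  veh_cond <- unique(paste(layout$genotype[is_vehicle],
                           layout$treatment_id[is_vehicle]))
  trt <- inclusion[!(paste(inclusion$genotype, inclusion$treatment_id) %in%
                       veh_cond), ]
  agg_rows <- list(); morph_rows <- list(); excluded_rows <- list()
  for (r in seq_len(nrow(trt))) {
    id <- trt$treatment_id[r]
    if (!trt$included[r]) {
      excluded_rows[[id]] <- tibble::tibble(treatment_id = id,
                                            reason = trt$reason[r])
      next
    }
    tf <- features[features$treatment_id == id &
                     features$genotype == trt$genotype[r], ]
    res <- tryCatch({
      at <- aggregation_suppression_test(tf$aggregate_pixels, dmso_counts)
      mt <- morphology_rescue_test(tf, ref_features)
      list(at = at, mt = mt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded_rows[[id]] <- tibble::tibble(treatment_id = id,
                                            reason = conditionMessage(res))
      next
    }
    agg_rows[[id]] <- tibble::tibble(
      treatment_id = id, log2_ratio = res$at$log2_ratio,
      agg_p = res$at$p_value, direction = res$at$direction,
      n_fields = nrow(tf))
    morph_rows[[id]] <- tibble::tibble(
      treatment_id = id, morph_combined_p = res$mt$combined_p,
      mean_neurite_length = mean(tf$mean_neurite_length),
      mean_neuromere_area = mean(tf$mean_neuromere_area))
  }
  agg_tab <- dplyr::bind_rows(agg_rows)
  morph_tab <- dplyr::bind_rows(morph_rows)
  excl_tab <- dplyr::bind_rows(excluded_rows)
  if (nrow(agg_tab) == 0L)
    stop("no treatment passed inclusion; nothing to test", call. = FALSE)

  threshold <- screen_threshold(agg_tab$log2_ratio, m)
  hits <- call_hits(agg_tab, morph_tab, threshold, alpha = alpha,
                    rescue_floor = rescue_floor, stage1_rule = stage1_rule,
                    baseline = baseline, excluded = excl_tab)
  # Benjamini-Hochberg column as optional extra output; the original
  # decision rule applies no across-treatment correction.
  hits$agg_p_bh <- NA_real_
  tested <- !is.na(hits$agg_p)
  hits$agg_p_bh[tested] <- stats::p.adjust(hits$agg_p[tested], "BH")

  manifest <- list(
    package_version = as.character(utils::packageVersion("httscreen")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_images = length(keys),
    n_usable_images = sum(qc$usable),
    n_excluded_images = sum(!qc$usable),
    focus_threshold = focus_threshold,
    aggregate_threshold = agg_threshold,
    n_treatments = nrow(trt),
    n_tested = nrow(agg_tab),
    n_excluded_treatments = nrow(trt) - nrow(agg_tab),
    n_hits = sum(hits$classification == "DUAL_HIT"),
    alpha = alpha, multiplier = m, min_images = min_images,
    stage1_rule = stage1_rule
  )
  structure(
    list(features = features, hits = hits, qc = qc, inclusion = inclusion,
         models = list(areas = areas_model, lengths = lengths_model),
         threshold = threshold, aggregate_threshold = agg_threshold,
         baseline = baseline, manifest = manifest),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<screen_result> %d images (%d usable), %d treatments tested, %d dual hits\n",
    m$n_images, m$n_usable_images, m$n_tested, m$n_hits))
  invisible(x)
}

#' Summarise a hit table
#'
#' Prints the cutoff line, per-class counts, and the ranked suppressed
#' treatments, and returns the scatter data for the log2-ratio hit plot.
#'
#' @param hits A `hit_table` from [call_hits()] or `run_screen()$hits`.
#' @param n_top Number of ranked rows to print.
#' @return Invisibly, a list: `scatter` (tibble `treatment_id, log2_ratio,
#'   cutoff`), `class_counts`, `cutoff`.
#' @export
screen_report <- function(hits, n_top = 10L) {
  stopifnot(inherits(hits, "hit_table"))
  threshold <- attr(hits, "threshold")
  cutoff <- threshold$cutoff
  counts <- table(hits$classification)
  cat(sprintf("Screen cutoff (mean - %g sd of log2 ratios): %.4f\n",
              threshold$multiplier, cutoff))
  cat("Classification counts:\n")
  for (cl in names(counts)) cat(sprintf("  %-20s %d\n", cl, counts[[cl]]))
  ranked <- hits[hits$aggregation_suppressed %in% TRUE, ]
  ranked <- ranked[order(ranked$log2_ratio), ]
  if (nrow(ranked) > 0L) {
    cat(sprintf("Top suppressed treatments (up to %d):\n", n_top))
    show <- head(ranked, n_top)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %-12s log2 ratio %8.3f  agg p %-10s morph p %-10s %s\n",
                  show$treatment_id[i], show$log2_ratio[i],
                  format_p(show$agg_p[i]), format_p(show$morph_combined_p[i]),
                  as.character(show$classification[i])))
    }
  } else {
    cat("No treatments suppressed aggregation.\n")
  }
  invisible(list(
    scatter = tibble::tibble(treatment_id = hits$treatment_id,
                             log2_ratio = hits$log2_ratio,
                             cutoff = cutoff),
    class_counts = counts,
    cutoff = cutoff
  ))
}

#' Write the tabular outputs of a screen run
#'
#' Emits the feature table, hit table, QC table and a JSON manifest.
#'
#' @param result A `screen_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_result <- function(result, dir) {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$features, file.path(dir, "features.tsv"),
                   progress = FALSE)
  hits <- result$hits
  hits$classification <- as.character(hits$classification)
  readr::write_tsv(hits, file.path(dir, "hits.tsv"), progress = FALSE)
  qc <- dplyr::rename(result$qc, well = "well_id", site = "site_index")
  readr::write_tsv(qc, file.path(dir, "qc.tsv"), progress = FALSE)
  jsonlite::write_json(
    c(result$manifest,
      list(models = list(
        area_bins = result$models$areas[c("weights", "means", "sds",
                                          "fitted_n")],
        length_groups = result$models$lengths[c("centers", "fitted_n")]
      ),
      threshold = unclass(result$threshold))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
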