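# Label fusion by majority vote: per-pixel consensus maps and thresholded
# consensus segmentations.

#' Build a per-pixel consensus map from a stack of masks
#'
#' The consensus fraction at a pixel is the proportion of the supplied
#' masks that include it, from 0 (no annotator) to 1 (all annotators).
#' The denominator is the number of masks supplied, i.e. the annotators
#' who actually segmented this image — not the full panel roster.
#'
#' @param masks A (possibly named) list of `binary_mask` objects on a
#'   common grid, one per annotator.
#' @return An object of class `consensus_map` with fields `grid`,
#'   `fraction` (numeric matrix in `[0, 1]`, every value a multiple of
#'   `1/n_annotators`) and `n_annotators`.
#' @export
build_consensus_map <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("`masks` must be a non-empty list of binary masks")
  grid <- masks[[1L]]$grid
  for (m in masks) {
    if (!inherits(m, "binary_mask")) stop("all elements must be binary_mask objects")
    if (!same_grid(m$grid, grid)) stop("all masks must share one grid")
  }
  n <- length(masks)
  counts <- Reduce(`+`, lapply(masks, `[[`, "pixels"))
  structure(list(grid = grid, fraction = counts / n, n_annotators = n),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("<consensus_map> ", x$grid$height, " x ", x$grid$width, " px, ",
      x$n_annotators, " annotators, max fraction ",
      format(max(x$fraction)), "\n", sep = "")
  invisible(x)
}

#' Threshold a consensus map into a consensus segmentation
#'
#' A pixel belongs to the consensus segmentation iff its consensus
#' fraction strictly exceeds `threshold` (majority vote at the default
#' 0.5: strictly more than half of the annotators). With an even panel a
#' pixel split exactly 50/50 is therefore excluded, and with a 3-member
#' panel at 0.5 inclusion requires at least 2 votes.
#'
#' @param cmap A [build_consensus_map()] result.
#' @param threshold Vote fraction in the open interval (0, 1); default 0.5.
#'   0.25 and 0.75 are the conventional values for sensitivity analyses.
#' @param source Optional panel label (e.g. `"citizens"`, `"experts"`).
#' @return A `consensus_segmentation`, which is also a `binary_mask`
#'   (fields `grid`, `pixels`) with extra fields `threshold` and `source`.
#' @export
threshold_consensus <- function(cmap, threshold = 0.5, source = NULL) {
  if (!inherits(cmap, "consensus_map")) stop("`cmap` must be a consensus_map")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single number strictly between 0 and 1")
  structure(list(grid = cmap$grid,
                 pixels = cmap$fraction > threshold,
                 threshold = threshold,
                 source = source),
            class = c("consensus_segmentation", "binary_mask"))
}

#' @export
print.consensus_segmentation <- function(x, ...) {
  cat("<consensus_segmentation> ", x$grid$height, " x ", x$grid$width,
      " px, threshold ", x$threshold,
      if (!is.null(x$source)) paste0(", panel ", x$source) else "",
      ", area ", mask_area(x), "\n", sep = "")
  invisible(x)
}

#' Remove repeated (annotator, image) records
#'
#' Annotators occasionally re-segmented an image in a later session.
#' Repeats count toward throughput, but for accuracy analyses only the
#' earliest-session record per (annotator, image) pair is retained;
#' records without a session number rank after numbered sessions, then
#' input order breaks remaining ties.
#'
#' @param records List of `outline_record` objects.
#' @param quiet Suppress the removed-duplicates message.
#' @return The filtered list, in original order, with attribute
#'   `n_removed` giving the number of records dropped.
#' @export
deduplicate_records <- function(records, quiet = FALSE) {
  if (length(records) == 0L) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  aid <- vapply(records, `[[`, character(1), "annotator_id")
  iid <- vapply(records, `[[`, character(1), "image_id")
  ses <- vapply(records, `[[`, integer(1), "session")
  key <- paste(aid, iid, sep = "\r")
  ord <- order(key, ifelse(is.na(ses), .Machine$integer.max, ses),
               seq_along(records))
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  n_removed <- length(records) - length(keep)
  if (n_removed > 0L && !quiet)
    message(n_removed, " duplicate (annotator, image) record(s) removed ",
            "for accuracy analyses")
  out <- records[keep]
  attr(out, "n_removed") <- n_removed
  out
}

#' Consensus maps and segmentations for every image of a panel
#'
#' Convenience wrapper: given per-image stacks of rasterized masks (as
#' produced by [rasterize_annotations()]), builds a consensus map and a
#' thresholded consensus segmentation for each image, and reports images
#' covered by fewer annotators than `min_coverage` (they are still
#' processed, only flagged).
#'
#' @param masks_by_image Named list (by image) of named lists (by
#'   annotator) of `binary_mask` objects.
#' @param threshold Vote-fraction threshold, see [threshold_consensus()].
#' @param source Optional panel label attached to each segmentation.
#' @param min_coverage Minimum annotators per image before the image is
#'   flagged as low-coverage (default 3).
#' @return A list with `maps` (named list of `consensus_map`),
#'   `segmentations` (named list of `consensus_segmentation`) and
#'   `coverage` (data frame: `image_id`, `n_annotators`, `low_coverage`).
#' @export
panel_consensus <- function(masks_by_image, threshold = 0.5, source = NULL,
                            min_coverage = 3L) {
  if (length(masks_by_image) == 0L) stop("no images to fuse")
  maps <- lapply(masks_by_image, build_consensus_map)
  segs <- lapply(maps, threshold_consensus, threshold = threshold,
                 source = source)
  n_ann <- vapply(maps, `[[`, numeric(1), "n_annotators")
  coverage <- data.frame(image_id = names(maps),
                         n_annotators = as.integer(n_ann),
                         low_coverage = n_ann < min_coverage,
                         stringsAsFactors = FALSE, row.names = NULL)
  list(maps = maps, segmentations = segs, coverage = coverage)
}

#' Export a consensus map as portable text
#'
#' Writes the fraction lattice as a tab-separated matrix plus a JSON
#' sidecar (`<path>.json`) recording the image, panel and denominator.
#'
#' @param cmap A `consensus_map`.
#' @param path Output path for the lattice.
#' @param image_id,panel Metadata written to the sidecar.
#' @return `path`, invisibly.
#' @export
write_consensus_map <- function(cmap, path, image_id = NA, panel = NA) {
  utils::write.table(cmap$fraction, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(image_id = image_id, panel = panel,
               n_annotators = cmap$n_annotators,
               height = cmap$grid$height, width = cmap$grid$width)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a consensus map written by [write_consensus_map()]
#'
#' @param path Lattice file path (the `.json` sidecar must sit beside it).
#' @return A `consensus_map`.
#' @export
read_consensus_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frac <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(frac) <- NULL
  structure(list(grid = image_grid(meta$height, meta$width),
                 fraction = frac,
                 n_annotators = as.integer(meta$n_annotators)),
            class = "consensus_map")
}
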