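# Dice similarity and the study-level agreement summaries: individuals vs
# a reference consensus, panel consensus vs panel consensus, pairwise
# within-panel agreement, and threshold sensitivity.

#' Dice similarity coefficient between two masks
#'
#' `Dice(A, B) = 2|A n B| / (|A| + |B|)`: 1 for identical pixel sets,
#' 0 for disjoint ones. By convention two empty masks score 1 and an
#' empty mask against a non-empty one scores 0; real annotation data
#' never hits this, but degenerate synthetic cases stay defined.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return A number in `[0, 1]`.
#' @examples
#' g <- image_grid(4, 4)
#' m <- rasterize_polygon(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)), g)
#' dice(m, m) # 1
#' @export
dice <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    stop("`a` and `b` must be binary_mask objects")
  if (!same_grid(a$grid, b$grid)) stop("masks are on different grids")
  na <- sum(a$pixels)
  nb <- sum(b$pixels)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  2 * sum(a$pixels & b$pixels) / (na + nb)
}

#' Score individual annotators against a per-image reference segmentation
#'
#' The study's headline accuracy analysis: every annotator's mask for
#' every image is compared, by Dice, to that image's reference consensus
#' segmentation (conventionally the expert consensus, treated as ground
#' truth). No leave-one-out correction is applied by default: when the
#' reference panel is disjoint from the scored annotators (citizens vs
#' expert consensus) none is needed. Set `leave_one_out = TRUE` to
#' rebuild the reference without the scored annotator whenever that
#' annotator's own mask contributed to it.
#'
#' @param masks_by_image Per-image stacks of annotator masks, as from
#'   [rasterize_annotations()] (deduplicated records).
#' @param reference Named list (by image) of reference masks
#'   (`consensus_segmentation` or `binary_mask`). Images without a
#'   reference are skipped.
#' @param reference_masks Only with `leave_one_out = TRUE`: the per-image
#'   mask stacks the reference was built from.
#' @param leave_one_out Rebuild the reference without the scored
#'   annotator when they are part of it (default `FALSE`).
#' @param threshold Vote threshold used when rebuilding a leave-one-out
#'   reference (default 0.5).
#' @return A data frame of class `agreement_table` with columns
#'   `image_id`, `subject`, `reference`, `dice`. Annotators with no
#'   scorable image are absent (with a warning).
#' @export
score_individuals <- function(masks_by_image, reference,
                              reference_masks = NULL,
                              leave_one_out = FALSE, threshold = 0.5) {
  if (leave_one_out && is.null(reference_masks))
    stop("`leave_one_out = TRUE` needs `reference_masks`")
  images <- intersect(names(masks_by_image), names(reference))
  skipped <- setdiff(names(masks_by_image), images)
  if (length(skipped))
    warning(length(skipped), " image(s) without a reference skipped")
  rows <- vector("list", length(images))
  for (k in seq_along(images)) {
    img <- images[[k]]
    stack <- masks_by_image[[img]]
    ref <- reference[[img]]
    d <- vapply(names(stack), function(aid) {
      r <- ref
      if (leave_one_out && aid %in% names(reference_masks[[img]])) {
        others <- reference_masks[[img]][names(reference_masks[[img]]) != aid]
        if (length(others) == 0L) return(NA_real_)
        r <- threshold_consensus(build_consensus_map(others), threshold)
      }
      dice(stack[[aid]], r)
    }, numeric(1))
    rows[[k]] <- data.frame(image_id = img, subject = names(stack),
                            reference = "reference_consensus", dice = d,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(image_id = character(), subject = character(),
                                      reference = character(), dice = numeric())
  out <- out[!is.na(out$dice), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' Score one panel's consensus against another's, image by image
#'
#' @param panel_a,panel_b Named lists (by image) of consensus
#'   segmentations (or any `binary_mask`). Only images present in both
#'   are scored; none shared is an error.
#' @param label_a,label_b Labels recorded in the `subject` / `reference`
#'   columns.
#' @return An `agreement_table` data frame with one row per shared image.
#' @export
score_consensus_vs_consensus <- function(panel_a, panel_b,
                                         label_a = "panel_a",
                                         label_b = "panel_b") {
  images <- intersect(names(panel_a), names(panel_b))
  if (length(images) == 0L) stop("the two panels share no images")
  d <- vapply(images, function(img) dice(panel_a[[img]], panel_b[[img]]),
              numeric(1))
  out <- data.frame(image_id = images, subject = label_a,
                    reference = label_b, dice = unname(d),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' Pairwise agreement within one image's annotator stack
#'
#' Dice for every unordered pair of annotators of one image — the
#' inter-expert agreement analysis when applied to the expert stack.
#'
#' @param masks Named list (by annotator) of `binary_mask` objects for
#'   one image.
#' @param image_id Image identifier recorded in the output.
#' @return An `agreement_table` with `choose(n, 2)` rows; fewer than two
#'   annotators gives an empty table with a warning.
#' @export
pairwise_panel_agreement <- function(masks, image_id = NA_character_) {
  empty <- data.frame(image_id = character(), subject = character(),
                      reference = character(), dice = numeric())
  class(empty) <- c("agreement_table", "data.frame")
  if (length(masks) < 2L) {
    warning("fewer than 2 annotators for image ", image_id,
            "; no pairwise agreement computed")
    return(empty)
  }
  ids <- names(masks)
  pairs <- utils::combn(length(masks), 2L)
  out <- data.frame(
    image_id = as.character(image_id),
    subject = ids[pairs[1L, ]],
    reference = ids[pairs[2L, ]],
    dice = apply(pairs, 2L, function(p) dice(masks[[p[1L]]], masks[[p[2L]]])),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' Summarise an agreement table
#'
#' Per-image or per-subject distribution summaries (n, median, mean, SD,
#' min, max) of the Dice scores.
#'
#' @param scores An `agreement_table` data frame.
#' @param by `"image"` or `"subject"`.
#' @return A data frame with columns `level`, `id`, `n`, `median`,
#'   `mean`, `sd`, `min`, `max`.
#' @export
summarize_agreement <- function(scores, by = c("image", "subject")) {
  by <- match.arg(by)
  key <- if (by == "image") scores$image_id else scores$subject
  groups <- split(scores$dice, key)
  out <- data.frame(
    level = by,
    id = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, stats::median, numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Consensus accuracy across vote thresholds
#'
#' Rebuilds both panels' consensus segmentations at each threshold and
#' scores subject consensus against reference consensus per image,
#' reporting the mean and SD of the per-image Dice — the sensitivity
#' analysis for the majority-vote cut-off.
#'
#' @param subject_masks,reference_masks Per-image stacks of masks for
#'   the two panels (see [rasterize_annotations()]).
#' @param thresholds Numeric vector of vote thresholds in (0, 1);
#'   default `c(0.25, 0.5, 0.75)`.
#' @return A data frame with columns `threshold`, `n_images`,
#'   `mean_dice`, `sd_dice`.
#' @export
threshold_sensitivity <- function(subject_masks, reference_masks,
                                  thresholds = c(0.25, 0.5, 0.75)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("all thresholds must lie strictly between 0 and 1")
  rows <- lapply(thresholds, function(t) {
    subj <- panel_consensus(subject_masks, threshold = t)$segmentations
    ref <- panel_consensus(reference_masks, threshold = t)$segmentations
    sc <- score_consensus_vs_consensus(subj, ref)
    data.frame(threshold = t, n_images = nrow(sc),
               mean_dice = mean(sc$dice), sd_dice = stats::sd(sc$dice))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an agreement table or its summary as delimited text
#'
#' @param x An `agreement_table` or a [summarize_agreement()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
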