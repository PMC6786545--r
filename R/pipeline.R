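# One-shot orchestration: deduplicate -> rasterize -> consensus (both
# panels, all thresholds) -> individual scoring -> consensus-vs-consensus
# -> pairwise reference-panel agreement -> annotator statistics, with all
# tables, figures and a markdown summary written to an output directory.

#' Configure a pipeline run
#'
#' @param annotations Annotation table (data frame in the canonical
#'   format) or a path to one.
#' @param metadata Optional annotator metadata (data frame with
#'   `annotator_id`, `age`, `group`) or a path; required to split panels
#'   unless every annotator is a citizen.
#' @param out_dir Output directory (created if needed); `NULL` for none
#'   (results only returned).
#' @param reference_group Annotator group used as the reference panel
#'   (default `"expert"`); the other group is the subject panel.
#' @param thresholds Ascending vote thresholds in (0, 1), default
#'   `c(0.25, 0.5, 0.75)`; the consensus used for scoring is the one at
#'   `main_threshold`.
#' @param main_threshold Majority-vote threshold for the headline
#'   analyses (default 0.5; must be among `thresholds`).
#' @param grid An [image_grid()], or `NULL` to infer one just covering
#'   all outline coordinates.
#' @param min_coverage Minimum annotators per image before flagging
#'   (default 3).
#' @param max_skip_frac Abort when more than this fraction of annotation
#'   rows is malformed (default 0.05).
#' @param seed Integer seed recorded with the run (the pipeline itself
#'   is deterministic; the seed feeds anything downstream that samples).
#' @return An object of class `run_config`.
#' @export
run_config <- function(annotations, metadata = NULL, out_dir = NULL,
                       reference_group = "expert",
                       thresholds = c(0.25, 0.5, 0.75),
                       main_threshold = 0.5,
                       grid = NULL, min_coverage = 3L,
                       max_skip_frac = 0.05, seed = 1L) {
  thresholds <- sort(as.numeric(thresholds))
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("all thresholds must lie strictly in (0, 1)")
  if (!main_threshold %in% thresholds)
    stop("`main_threshold` must be one of `thresholds`")
  structure(list(annotations = annotations, metadata = metadata,
                 out_dir = out_dir, reference_group = reference_group,
                 thresholds = thresholds, main_threshold = main_threshold,
                 grid = grid, min_coverage = as.integer(min_coverage),
                 max_skip_frac = max_skip_frac, seed = as.integer(seed)),
            class = "run_config")
}

infer_grid <- function(annotations) {
  image_grid(max(1, ceiling(max(annotations$y) + 1)),
             max(1, ceiling(max(annotations$x) + 1)))
}

pipeline_log <- function(...) message("[crowdseg] ", ...)

#' Run the full evaluation pipeline
#'
#' Executes every stage of the study analysis on an annotation table and
#' returns (and optionally writes) the full bundle of result tables and
#' figures. Repeated (annotator, image) records count toward throughput
#' but are removed before any accuracy analysis. The reference panel's
#' consensus at `main_threshold` plays the role of ground truth for
#' individual scoring; the subject panel's consensus is scored against
#' the reference consensus per image, at every configured threshold.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with elements
#'   `individual_scores`, `individual_by_annotator`,
#'   `individual_by_image`, `consensus_scores`, `pairwise_reference`,
#'   `sensitivity`, `throughput` (session counts and Mann-Whitney tests
#'   between consecutive sessions), `points_vs_images`,
#'   `age_regression` (or `NULL` without ages), `annotators`,
#'   `coverage`, `n_duplicates_removed`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ann <- config$annotations
  if (is.character(ann)) ann <- read_annotations(ann)
  meta <- config$metadata
  if (is.character(meta)) meta <- read_annotator_metadata(meta)

  n0 <- nrow(ann)
  bad <- is.na(ann$annotator_id) | is.na(ann$image_id) |
    !is.finite(ann$x) | !is.finite(ann$y)
  if (any(bad)) {
    pipeline_log(sum(bad), " malformed vertex row(s) skipped")
    if (sum(bad) / n0 > config$max_skip_frac)
      stop("more than ", 100 * config$max_skip_frac,
           "% of annotation rows malformed; aborting")
    ann <- ann[!bad, , drop = FALSE]
  }
  grid <- if (is.null(config$grid)) infer_grid(ann) else config$grid
  pipeline_log("grid ", grid$height, " x ", grid$width, " px, ",
               nrow(ann), " vertex rows")

  if (is.null(meta)) {
    meta <- data.frame(annotator_id = unique(ann$annotator_id),
                       age = NA_real_, group = "citizen",
                       stringsAsFactors = FALSE)
  }
  ref_ids <- meta$annotator_id[meta$group == config$reference_group]
  subj_ids <- setdiff(unique(ann$annotator_id), ref_ids)
  if (length(ref_ids) == 0L)
    stop("no annotators in reference group '", config$reference_group, "'")

  records <- records_from_table(ann)
  pipeline_log(length(records), " outline records")
  deduped <- deduplicate_records(records, quiet = TRUE)
  n_dup <- attr(deduped, "n_removed")
  pipeline_log(n_dup, " duplicate record(s) excluded from accuracy analyses")

  is_ref <- vapply(deduped, function(r) r$annotator_id %in% ref_ids, logical(1))
  ref_masks <- rasterize_annotations(deduped[is_ref], grid)
  subj_masks <- rasterize_annotations(deduped[!is_ref], grid)
  pipeline_log("rasterized ", sum(is_ref), " reference and ",
               sum(!is_ref), " subject masks")

  ref_cons <- panel_consensus(ref_masks, threshold = config$main_threshold,
                              source = config$reference_group,
                              min_coverage = config$min_coverage)
  subj_cons <- panel_consensus(subj_masks, threshold = config$main_threshold,
                               source = "subject",
                               min_coverage = config$min_coverage)
  coverage <- merge(subj_cons$coverage, ref_cons$coverage,
                    by = "image_id", all = TRUE,
                    suffixes = c("_subject", "_reference"))

  indiv <- score_individuals(subj_masks, ref_cons$segmentations)
  indiv_by_ann <- summarize_agreement(indiv, by = "subject")
  indiv_by_img <- summarize_agreement(indiv, by = "image")
  pipeline_log(nrow(indiv), " individual scores on ",
               nrow(indiv_by_img), " images")

  cons_scores <- score_consensus_vs_consensus(
    subj_cons$segmentations, ref_cons$segmentations,
    label_a = "subject_consensus",
    label_b = paste0(config$reference_group, "_consensus"))

  pw <- do.call(rbind, lapply(names(ref_masks), function(img)
    pairwise_panel_agreement(ref_masks[[img]], image_id = img)))
  class(pw) <- c("agreement_table", "data.frame")

  sens <- threshold_sensitivity(subj_masks, ref_masks,
                                thresholds = config$thresholds)

  ses <- session_counts(ann[ann$annotator_id %in% subj_ids, , drop = FALSE])
  sessions <- sort(unique(ses$session))
  throughput_tests <- list()
  if (length(sessions) >= 2L) {
    for (k in seq_len(length(sessions) - 1L)) {
      a <- ses$n_images[ses$session == sessions[k]]
      b <- ses$n_images[ses$session == sessions[k + 1L]]
      throughput_tests[[paste0("s", sessions[k], "_vs_s", sessions[k + 1L])]] <-
        session_throughput_test(a, b)
    }
  }

  summ <- annotator_summary(ann, metadata = meta, scores = indiv)
  pvi <- tryCatch(
    points_vs_images_correlation(summ[summ$annotator_id %in% subj_ids, ]),
    error = function(e) NULL)
  agereg <- tryCatch(
    covariate_accuracy_regression(summ[summ$annotator_id %in% subj_ids, ]),
    error = function(e) NULL)

  result <- structure(list(
    individual_scores = indiv,
    individual_by_annotator = indiv_by_ann,
    individual_by_image = indiv_by_img,
    consensus_scores = cons_scores,
    pairwise_reference = pw,
    sensitivity = sens,
    throughput = list(session_counts = ses, tests = throughput_tests),
    points_vs_images = pvi,
    age_regression = agereg,
    annotators = summ,
    coverage = coverage,
    n_duplicates_removed = n_dup,
    config = config), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_agreement(result$individual_scores, file.path(dir, "individual_scores.csv"))
  write_agreement(result$individual_by_annotator,
                  file.path(dir, "individual_by_annotator.csv"))
  write_agreement(result$individual_by_image,
                  file.path(dir, "individual_by_image.csv"))
  write_agreement(result$consensus_scores, file.path(dir, "consensus_scores.csv"))
  write_agreement(result$pairwise_reference,
                  file.path(dir, "pairwise_reference.csv"))
  utils::write.table(result$sensitivity, file.path(dir, "sensitivity.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(result$throughput$session_counts,
                     file.path(dir, "session_counts.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(result$annotators, file.path(dir, "annotators.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(result$coverage, file.path(dir, "coverage.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  cfg <- result$config
  jsonlite::write_json(
    list(reference_group = cfg$reference_group, thresholds = cfg$thresholds,
         main_threshold = cfg$main_threshold, min_coverage = cfg$min_coverage,
         seed = cfg$seed,
         package_version = as.character(utils::packageVersion("crowdseg"))),
    file.path(dir, "run_config.json"), auto_unbox = TRUE)
  writeLines(report_markdown(result), file.path(dir, "report.md"))
  save_pipeline_figures(result, dir)
  invisible(dir)
}

fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")

#' Render a pipeline result as a markdown report
#'
#' @param result A [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(result) {
  lines <- c("# Crowd-sourced segmentation evaluation", "")
  ses <- result$throughput$session_counts
  lines <- c(lines, "## Throughput", "")
  for (s in sort(unique(ses$session))) {
    v <- ses$n_images[ses$session == s]
    lines <- c(lines, paste0("- Session ", s, ": median ",
                             stats::median(v), " images per annotator (n = ",
                             length(v), ")"))
  }
  for (nm in names(result$throughput$tests)) {
    t <- result$throughput$tests[[nm]]
    lines <- c(lines, paste0("- Mann-Whitney ", gsub("_", " ", nm), ": U = ",
                             fmt(t$U, 1), ", p = ", fmt(t$p), " (", t$method, ")"))
  }
  if (!is.null(result$points_vs_images)) {
    p <- result$points_vs_images
    lines <- c(lines, "", "## Points versus images analysed", "",
               paste0("- Pearson r = ", fmt(p$r), ", p = ", fmt(p$p, 4),
                      " (n = ", p$n, ")"))
  }
  med <- result$individual_by_image$median
  lines <- c(lines, "", "## Accuracy", "",
             paste0("- Per-image median individual Dice vs reference ",
                    "consensus: mean ", fmt(mean(med)), " (SD ",
                    fmt(stats::sd(med)), "), range ", fmt(min(med)), "-",
                    fmt(max(med))),
             paste0("- Subject consensus vs reference consensus Dice: mean ",
                    fmt(mean(result$consensus_scores$dice)), " (SD ",
                    fmt(stats::sd(result$consensus_scores$dice)), "), range ",
                    fmt(min(result$consensus_scores$dice)), "-",
                    fmt(max(result$consensus_scores$dice))))
  pwm <- summarize_agreement(result$pairwise_reference, by = "image")$median
  lines <- c(lines,
             paste0("- Pairwise reference-panel Dice (per-image median): mean ",
                    fmt(mean(pwm)), " (SD ", fmt(stats::sd(pwm)), ")"))
  if (!is.null(result$age_regression)) {
    a <- result$age_regression
    lines <- c(lines, paste0("- Age vs accuracy: Pearson r = ", fmt(a$r),
                             ", p = ", fmt(a$p), "; slope ",
                             fmt(a$slope_per_decade, 4), " Dice per decade"))
  }
  lines <- c(lines, "", "## Threshold sensitivity", "",
             "| threshold | n images | mean Dice | SD |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(result$sensitivity))) {
    r <- result$sensitivity[i, ]
    lines <- c(lines, paste0("| ", r$threshold, " | ", r$n_images, " | ",
                             fmt(r$mean_dice), " | ", fmt(r$sd_dice), " |"))
  }
  dup <- result$n_duplicates_removed
  lines <- c(lines, "",
             paste0("Duplicate (annotator, image) records excluded from ",
                    "accuracy analyses: ", dup,
                    " (still counted in throughput)."))
  lines
}

# -- figures -----------------------------------------------------------

#' Boxplot of images segmented per session
#' @param session_counts A [session_counts()] data frame.
#' @return A ggplot object.
#' @export
fig_session_throughput <- function(session_counts) {
  ggplot2::ggplot(session_counts,
                  ggplot2::aes(x = factor(.data$session), y = .data$n_images)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Session", y = "Images segmented",
                  title = "Throughput per session")
}

#' Scatter of mean outline points vs images analysed
#' @param summaries An [annotator_summary()] data frame.
#' @return A ggplot object.
#' @export
fig_points_vs_images <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$total_images,
                               y = .data$mean_points_per_image)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Images analysed", y = "Mean points per outline",
                  title = "Point budget versus workload")
}

#' Per-annotator accuracy boxplots
#' @param scores An `agreement_table` of individual scores.
#' @return A ggplot object.
#' @export
fig_accuracy_by_annotator <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$subject, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "Annotator", y = "Dice vs reference consensus",
                  title = "Accuracy by annotator") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-image accuracy: individuals, subject consensus, reference agreement
#' @param individual_scores,consensus_scores,pairwise_reference Agreement
#'   tables from [run_pipeline()].
#' @return A ggplot object.
#' @export
fig_accuracy_by_image <- function(individual_scores, consensus_scores,
                                  pairwise_reference) {
  ind <- data.frame(image_id = individual_scores$image_id,
                    dice = individual_scores$dice, what = "individuals")
  pw <- data.frame(image_id = pairwise_reference$image_id,
                   dice = pairwise_reference$dice, what = "reference pairs")
  cons <- data.frame(image_id = consensus_scores$image_id,
                     dice = consensus_scores$dice, what = "subject consensus")
  ggplot2::ggplot(rbind(ind, pw),
                  ggplot2::aes(x = .data$image_id, y = .data$dice,
                               fill = .data$what)) +
    ggplot2::geom_boxplot(outlier.size = 0.2, linewidth = 0.2) +
    ggplot2::geom_point(data = cons, colour = "darkgreen", size = 0.6,
                        inherit.aes = FALSE,
                        ggplot2::aes(x = .data$image_id, y = .data$dice)) +
    ggplot2::labs(x = "Image", y = "Dice", title = "Accuracy by image") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

save_pipeline_figures <- function(result, dir) {
  figs <- list(
    session_throughput = fig_session_throughput(
      result$throughput$session_counts),
    points_vs_images = fig_points_vs_images(result$annotators),
    accuracy_by_annotator = fig_accuracy_by_annotator(
      result$individual_scores),
    accuracy_by_image = fig_accuracy_by_image(
      result$individual_scores, result$consensus_scores,
      result$pairwise_reference))
  for (nm in names(figs))
    ggplot2::ggsave(file.path(dir, paste0("fig_", nm, ".png")), figs[[nm]],
                    width = 7, height = 4.5, dpi = 120)
  invisible(names(figs))
}
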