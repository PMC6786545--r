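# Annotator behaviour analyses: session throughput (Mann-Whitney U),
# outline point count vs number of images analysed (Pearson), and
# covariate (age) effects on accuracy.

#' Mann-Whitney U test for session throughput
#'
#' Two-sided Mann-Whitney U comparing per-annotator image counts between
#' two sessions (or any two samples). Ties are handled with midranks.
#' U is reported for the first sample under the rank-sum convention
#' `U = R_a - n_a (n_a + 1) / 2`. When both samples have at most
#' `exact_max` observations the p-value is computed by full enumeration
#' of the permutation null (every assignment of the pooled midranks to
#' the two groups), which remains exact under ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param counts_a,counts_b Numeric vectors (non-empty, no NA).
#' @param exact_max Largest per-group size for which the exact
#'   enumeration is used (default 8).
#' @return A list with `U`, `p`, `method` (`"exact"` or `"normal"`),
#'   `n_a`, `n_b`.
#' @examples
#' session_throughput_test(c(18, 25, 12), c(30, 29, 35))
#' @export
session_throughput_test <- function(counts_a, counts_b, exact_max = 8L) {
  a <- as.numeric(counts_a)
  b <- as.numeric(counts_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  if (any(is.na(a)) || any(is.na(b)))
    stop("samples must not contain NA")
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  rk <- rank(c(a, b))            # midranks under ties
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    subsets <- utils::combn(n, na)
    us <- colSums(matrix(rk[subsets], nrow = na)) - na * (na + 1) / 2
    # the permutation null of U is symmetric about n_a n_b / 2 even with
    # ties (swapping group labels maps U to n_a n_b - U)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    tab <- table(rk)
    tie_term <- sum(tab^3 - tab)
    s2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (s2 <= 0) {
      p <- 1                      # all observations tied
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(s2)   # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = u, p = p, method = method, n_a = na, n_b = nb)
}

#' Correlation between outline point budget and workload
#'
#' Pearson product-moment correlation between each annotator's mean
#' number of outline points per image and the total number of images
#' they analysed, with the usual two-sided t-test on `n - 2` degrees of
#' freedom. A negative r is the signature of detail-oriented annotators
#' getting through fewer images.
#'
#' @param summaries A data frame with columns `mean_points_per_image`
#'   and `total_images` (one row per annotator), e.g. from
#'   [annotator_summary()].
#' @return A list with `r`, `p`, `n`.
#' @export
points_vs_images_correlation <- function(summaries) {
  x <- summaries$mean_points_per_image
  y <- summaries$total_images
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 annotators with defined values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in one of the variables")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Age effect on segmentation accuracy
#'
#' Pearson correlation between annotator age and median Dice accuracy,
#' plus the least-squares slope of accuracy on age rescaled to Dice
#' change per decade of age.
#'
#' @param summaries A data frame with columns `age` (years) and
#'   `accuracy_median` (per-annotator median Dice), e.g. from
#'   [annotator_summary()]. Annotators with missing age or accuracy are
#'   excluded with a warning.
#' @return A list with `r`, `p`, `slope_per_decade`, `n`.
#' @export
covariate_accuracy_regression <- function(summaries) {
  age <- summaries$age
  acc <- summaries$accuracy_median
  ok <- is.finite(age) & is.finite(acc)
  if (any(!ok))
    warning(sum(!ok), " annotator(s) without age or accuracy excluded")
  age <- age[ok]; acc <- acc[ok]
  if (length(age) < 3L) stop("need at least 3 annotators with age and accuracy")
  if (stats::sd(age) == 0 || stats::sd(acc) == 0)
    stop("correlation undefined: zero variance in age or accuracy")
  ct <- stats::cor.test(age, acc, method = "pearson")
  fit <- stats::lm(acc ~ age)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope_per_decade = unname(stats::coef(fit)[2L]) * 10,
       n = length(age))
}

#' Per-annotator summary table
#'
#' Builds one row per annotator from an annotation table: number of
#' records (= image segmentations) overall and per session, the number
#' of distinct images, and the mean outline points per image. Repeated
#' (annotator, image) records count toward all throughput tallies —
#' deduplication applies only to accuracy analyses — so `total_images`
#' may exceed `n_unique_images`. Optionally joins annotator metadata
#' (age, group) and per-annotator median accuracy from an agreement
#' table.
#'
#' @param annotations Data frame in the canonical annotation format.
#' @param metadata Optional data frame with `annotator_id`, `age`,
#'   `group`.
#' @param scores Optional `agreement_table` (e.g. individuals vs expert
#'   consensus); its per-subject median Dice becomes `accuracy_median`.
#' @return A data frame with columns `annotator_id`, `total_images`,
#'   `n_unique_images`, `mean_points_per_image`, and (when supplied)
#'   `age`, `group`, `accuracy_median`.
#' @export
annotator_summary <- function(annotations, metadata = NULL, scores = NULL) {
  key <- paste(annotations$annotator_id, annotations$image_id,
               annotations$session, sep = "\r")
  # one row per record with its vertex count
  per_rec <- stats::aggregate(list(n_points = annotations$vertex_index),
                              by = list(key = key,
                                        annotator_id = annotations$annotator_id),
                              FUN = length)
  agg <- stats::aggregate(list(total_images = per_rec$key),
                          by = list(annotator_id = per_rec$annotator_id),
                          FUN = length)
  mp <- stats::aggregate(list(mean_points_per_image = per_rec$n_points),
                         by = list(annotator_id = per_rec$annotator_id),
                         FUN = mean)
  uni <- unique(annotations[c("annotator_id", "image_id")])
  nu <- stats::aggregate(list(n_unique_images = uni$image_id),
                         by = list(annotator_id = uni$annotator_id),
                         FUN = length)
  out <- merge(merge(agg, nu, by = "annotator_id"), mp, by = "annotator_id")
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "annotator_id", all.x = TRUE)
  if (!is.null(scores)) {
    med <- summarize_agreement(scores, by = "subject")
    acc <- data.frame(annotator_id = med$id, accuracy_median = med$median,
                      stringsAsFactors = FALSE)
    out <- merge(out, acc, by = "annotator_id", all.x = TRUE)
  }
  out[order(out$annotator_id), , drop = FALSE]
}

#' Per-annotator, per-session record counts
#'
#' Throughput tallies for the session analysis; repeated images count.
#' Sessions an annotator did not attend (or whose data were lost) are
#' simply absent — never recorded as zero.
#'
#' @param annotations Data frame in the canonical annotation format.
#' @return A data frame with columns `annotator_id`, `session`,
#'   `n_images`.
#' @export
session_counts <- function(annotations) {
  ann <- annotations[!is.na(annotations$session), , drop = FALSE]
  key <- paste(ann$annotator_id, ann$image_id, ann$session, sep = "\r")
  rec <- unique(data.frame(annotator_id = ann$annotator_id,
                           session = ann$session, key = key,
                           stringsAsFactors = FALSE))
  out <- stats::aggregate(list(n_images = rec$key),
                          by = list(annotator_id = rec$annotator_id,
                                    session = rec$session),
                          FUN = length)
  out[order(out$annotator_id, out$session), , drop = FALSE]
}
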