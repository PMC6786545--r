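# The canonical annotation interchange format: delimited text, one row per
# outline vertex, with columns
#   annotator_id, image_id, session, region_index, vertex_index, x, y
# Vertices are ordered by vertex_index within region_index.

ANNOTATION_COLS <- c("annotator_id", "image_id", "session",
                     "region_index", "vertex_index", "x", "y")

#' Read an annotation table
#'
#' Reads the package's vertex-per-row annotation format (see
#' [write_annotations()]). Rows with missing identifiers or non-finite
#' coordinates are dropped with a warning.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A data frame with the canonical annotation columns.
#' @export
read_annotations <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(annotator_id = "character",
                                         image_id = "character"),
                          stringsAsFactors = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing))
    stop("annotation table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[ANNOTATION_COLS]
  bad <- is.na(df$annotator_id) | is.na(df$image_id) |
    !is.finite(df$x) | !is.finite(df$y) |
    is.na(df$region_index) | is.na(df$vertex_index)
  if (any(bad)) {
    warning(sum(bad), " malformed annotation row(s) dropped")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Write an annotation table
#'
#' @param annotations Data frame with the canonical annotation columns.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, sep = ",") {
  missing <- setdiff(ANNOTATION_COLS, names(annotations))
  if (length(missing))
    stop("annotation table is missing columns: ", paste(missing, collapse = ", "))
  utils::write.table(annotations[ANNOTATION_COLS], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an annotation table to outline records
#'
#' Groups vertex rows by (annotator, image, session), orders them by
#' `region_index` then `vertex_index`, and builds one [outline_record()]
#' per group. Regions with fewer than three vertices are dropped with a
#' warning; a group with no usable region is dropped entirely.
#'
#' @param annotations Data frame in the canonical annotation format.
#' @return A list of `outline_record` objects.
#' @export
records_from_table <- function(annotations) {
  df <- annotations[ANNOTATION_COLS]
  key <- paste(df$annotator_id, df$image_id, df$session, sep = "\r")
  idx <- split(seq_len(nrow(df)), key)
  n_short <- 0L
  out <- vector("list", length(idx))
  k <- 0L
  for (rows in idx) {
    g <- df[rows, , drop = FALSE]
    g <- g[order(g$region_index, g$vertex_index), , drop = FALSE]
    regions <- lapply(split(seq_len(nrow(g)), g$region_index), function(i)
      cbind(x = g$x[i], y = g$y[i]))
    ok <- vapply(regions, nrow, integer(1)) >= 3L
    n_short <- n_short + sum(!ok)
    regions <- regions[ok]
    if (length(regions) == 0L) next
    k <- k + 1L
    out[[k]] <- outline_record(g$annotator_id[1L], g$image_id[1L],
                               regions, session = g$session[1L])
  }
  if (n_short > 0L)
    warning(n_short, " region(s) with fewer than 3 vertices dropped")
  out[seq_len(k)]
}

#' Convert outline records to an annotation table
#'
#' Inverse of [records_from_table()].
#'
#' @param records List of `outline_record` objects.
#' @return Data frame in the canonical annotation format.
#' @export
table_from_records <- function(records) {
  parts <- lapply(records, function(rec) {
    reg <- lapply(seq_along(rec$regions), function(j) {
      p <- rec$regions[[j]]
      data.frame(annotator_id = rec$annotator_id,
                 image_id = rec$image_id,
                 session = rec$session,
                 region_index = j,
                 vertex_index = seq_len(nrow(p)),
                 x = p[, 1L], y = p[, 2L],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, reg)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Rasterize a set of records, grouped by image
#'
#' @param records List of `outline_record` objects.
#' @param grid An [image_grid()].
#' @return A named list (by `image_id`) of named lists (by `annotator_id`)
#'   of `binary_mask` objects. If the same annotator appears more than once
#'   for an image (duplicates not removed), the first record wins with a
#'   warning; deduplicate first with [deduplicate_records()].
#' @export
rasterize_annotations <- function(records, grid) {
  out <- list()
  n_dup <- 0L
  for (rec in records) {
    img <- rec$image_id
    if (is.null(out[[img]])) out[[img]] <- list()
    if (!is.null(out[[img]][[rec$annotator_id]])) {
      n_dup <- n_dup + 1L
      next
    }
    out[[img]][[rec$annotator_id]] <- rasterize_record(rec, grid)
  }
  if (n_dup > 0L)
    warning(n_dup, " duplicate (annotator, image) record(s) ignored; ",
            "run deduplicate_records() first to control which is kept")
  out[order(names(out))]
}

#' Write a mask as an 8-bit PNG
#'
#' Background pixels are written as 0 and segment pixels as 255 in a
#' single-channel lossless PNG.
#'
#' @param mask A `binary_mask`.
#' @param path Output path; when `path` is a directory the conventional
#'   name `{image_id}__{annotator_id}.png` is used, built from `image_id`
#'   and `annotator_id`.
#' @param image_id,annotator_id Identifiers used for the conventional
#'   filename when `path` is a directory.
#' @return The file path written, invisibly.
#' @export
write_mask_png <- function(mask, path, image_id = NULL, annotator_id = NULL) {
  if (dir.exists(path)) {
    if (is.null(image_id) || is.null(annotator_id))
      stop("writing into a directory needs `image_id` and `annotator_id`")
    path <- file.path(path, paste0(image_id, "__", annotator_id, ".png"))
  }
  png::writePNG(ifelse(mask$pixels, 1, 0), path)
  invisible(path)
}

#' Read a mask from an 8-bit PNG
#'
#' @param path PNG file path (as written by [write_mask_png()]).
#' @return A `binary_mask`; any strictly positive pixel is a segment pixel.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  binary_mask(img > 0.5, image_grid(nrow(img), ncol(img)))
}

#' Read an annotator metadata table
#'
#' Expected columns: `annotator_id`, `age` (years, may be missing) and
#' `group` (`citizen` or `expert`).
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A data frame with columns `annotator_id`, `age`, `group`.
#' @export
read_annotator_metadata <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(annotator_id = "character"),
                          stringsAsFactors = FALSE)
  need <- c("annotator_id", "age", "group")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("metadata table is missing columns: ", paste(missing, collapse = ", "))
  df[need]
}
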