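# Synthetic study generator: vertebra-like ground-truth shapes and panels
# of imperfect annotators. Stands in for the (undeposited) imaging data so
# the whole pipeline can be exercised and validated end-to-end.
#
# Shapes have a large rounded "body" (a smoothly modulated star-shaped
# blob) and, optionally, a thin "posterior" process attached below it —
# reproducing the large-round vs small-thin structure contrast that drives
# differences in inter-annotator agreement.
#
# All randomness flows from one top-level seed through named substreams
# (shapes, models, assignment, one per outline), so any stage can be
# regenerated independently and reproducibly.

# Deterministic sub-seed from a seed plus arbitrary name/index parts.
# Kept strictly below 2^31 and computed in exact double arithmetic.
substream_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  x <- as.numeric(seed) %% 2147483629
  for (p in c(parts, 97)) x <- (x * 69069 + p) %% 2147483629
  as.integer(x)
}

#' Describe a synthetic study design
#'
#' Captures the design of a crowd-sourced segmentation study: how many
#' images, how many citizen and expert annotators, and how the citizens'
#' workloads (number of images each segments) are distributed. Defaults
#' mirror a study of 150 images, 29 citizens segmenting on average
#' 85 +/- 43 of them, and 3 experts segmenting all images.
#'
#' @param n_images Number of images (default 150).
#' @param n_citizens Number of citizen annotators (default 29).
#' @param n_experts Number of expert annotators; experts segment every
#'   image (default 3).
#' @param workload_mean,workload_sd Mean and SD of the truncated-normal
#'   citizen workload distribution, truncated to `[1, n_images]`
#'   (defaults 85 and 43).
#' @param workload_points_cor Latent (Gaussian-copula) correlation
#'   between a citizen's outline point budget and their workload
#'   (default -0.675: annotators who place many points get through
#'   fewer images). The copula leaves the truncated-normal workload
#'   marginal untouched.
#' @param grid [image_grid()] the synthetic images live on (default
#'   96 x 96).
#' @param radius_frac Range of the body radius as a fraction of the
#'   smaller grid dimension (default `c(0.18, 0.26)`).
#' @param include_posterior Attach a thin posterior process to each body
#'   (default `TRUE`).
#' @param n_sessions Number of annotation sessions the citizen workload
#'   is split across (default 3).
#' @param seed Top-level integer seed (default 1).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_images = 150L, n_citizens = 29L, n_experts = 3L,
                         workload_mean = 85, workload_sd = 43,
                         workload_points_cor = -0.675,
                         grid = image_grid(96L, 96L),
                         radius_frac = c(0.18, 0.26),
                         include_posterior = TRUE,
                         n_sessions = 3L,
                         seed = 1L) {
  stopifnot(n_images >= 1L, n_citizens >= 1L, n_experts >= 1L,
            workload_mean > 0, workload_sd >= 0,
            workload_points_cor >= -1, workload_points_cor <= 1,
            length(radius_frac) == 2L, radius_frac[1L] > 0,
            radius_frac[2L] >= radius_frac[1L], n_sessions >= 1L)
  structure(list(n_images = as.integer(n_images),
                 n_citizens = as.integer(n_citizens),
                 n_experts = as.integer(n_experts),
                 workload_mean = workload_mean,
                 workload_sd = workload_sd,
                 workload_points_cor = workload_points_cor,
                 grid = grid,
                 radius_frac = radius_frac,
                 include_posterior = include_posterior,
                 n_sessions = as.integer(n_sessions),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Describe a synthetic annotator
#'
#' The annotator noise model: each sampled boundary point is displaced by
#' `bias + N(0, sigma)` pixels, radially from the shape centroid for the
#' body (so a positive bias dilates, negative erodes) and along the local
#' outward normal for thin posterior processes. With probability
#' `gross_error_rate` the whole outline is grossly wrong: displaced off
#' the structure and shrunken.
#'
#' @param annotator_id Identifier.
#' @param sigma Boundary noise SD in pixels (>= 0).
#' @param bias Signed radial offset in pixels (dilation > 0).
#' @param n_points Outline point budget per image (>= 3; the study's
#'   per-annotator means ranged over roughly 36-130).
#' @param gross_error_rate Probability of a grossly wrong outline.
#' @param seed Integer seed for the annotator's private substream.
#' @return An object of class `annotator_model`.
#' @export
annotator_model <- function(annotator_id, sigma = 1.5, bias = 0,
                            n_points = 80L, gross_error_rate = 0,
                            seed = 1L) {
  stopifnot(sigma >= 0, n_points >= 3L,
            gross_error_rate >= 0, gross_error_rate <= 1)
  structure(list(annotator_id = as.character(annotator_id),
                 sigma = sigma, bias = bias,
                 n_points = as.integer(n_points),
                 gross_error_rate = gross_error_rate,
                 seed = as.integer(seed)),
            class = "annotator_model")
}

#' Radius of a shape's body boundary at a polar angle
#'
#' The body boundary is star-shaped about the shape centre: the distance
#' from centre to boundary at angle `theta` is an anisotropically scaled,
#' low-frequency-modulated radius. This is the exact function annotator
#' noise is applied around, so boundary deviations of simulated outlines
#' can be measured against it exactly.
#'
#' @param shape A `gt_shape` from [generate_shapes()].
#' @param theta Polar angle(s) in radians (x towards +columns, y towards
#'   +rows).
#' @return Radii in pixels, same length as `theta`.
#' @export
shape_radius <- function(shape, theta) {
  e <- 1 / sqrt((cos(theta) / shape$ax)^2 + (sin(theta) / shape$ay)^2)
  shape$R * e * (1 + shape$a2 * cos(2 * theta + shape$ph2) +
                   shape$a3 * cos(3 * theta + shape$ph3))
}

body_polygon <- function(shape, n = 256L) {
  tt <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rr <- shape_radius(shape, tt)
  cbind(x = shape$center[1L] + rr * cos(tt),
        y = shape$center[2L] + rr * sin(tt))
}

posterior_polygon <- function(shape) {
  p <- shape$posterior
  if (is.null(p)) return(NULL)
  u <- c(cos(p$theta), sin(p$theta))
  nrm <- c(-u[2L], u[1L])
  r0 <- shape_radius(shape, p$theta) - 2      # start just inside the body
  p0 <- shape$center + r0 * u
  p1 <- shape$center + (r0 + p$length + 2) * u
  rbind(p0 + p$width / 2 * nrm,
        p1 + p$width / 2 * nrm,
        p1 - p$width / 2 * nrm,
        p0 - p$width / 2 * nrm)
}

#' Ground-truth polygons of a synthetic shape
#'
#' @param shape A `gt_shape`.
#' @param n Number of vertices used for the body boundary.
#' @return A list of polygons: the body, plus the posterior process when
#'   present.
#' @export
shape_polygons <- function(shape, n = 256L) {
  polys <- list(body = body_polygon(shape, n))
  post <- posterior_polygon(shape)
  if (!is.null(post)) polys$posterior <- post
  polys
}

#' Ground-truth mask of a synthetic shape
#'
#' @param shape A `gt_shape`.
#' @return A `binary_mask` on the shape's grid (union of body and
#'   posterior process).
#' @export
shape_mask <- function(shape) {
  rec <- outline_record("ground_truth", shape$image_id, shape_polygons(shape))
  rasterize_record(rec, shape$grid)
}

#' Generate ground-truth shapes for a study design
#'
#' One vertebra-like shape per image: a rounded body whose radius,
#' anisotropy, boundary modulation and position vary between images,
#' plus (optionally) a thin posterior process. Deterministic given the
#' design seed.
#'
#' @param design A [study_design()].
#' @return A named list (by `image_id`) of `gt_shape` objects.
#' @export
generate_shapes <- function(design) {
  g <- design$grid
  mind <- min(g$height, g$width)
  if (mind < 48L)
    stop("grid too small for the configured shape scale (need >= 48 px)")
  set.seed(substream_seed(design$seed, "shapes"))
  out <- vector("list", design$n_images)
  for (i in seq_len(design$n_images)) {
    image_id <- sprintf("img%03d", i)
    R <- stats::runif(1, design$radius_frac[1L], design$radius_frac[2L]) * mind
    shape <- list(
      image_id = image_id,
      center = c(stats::runif(1, 0.42, 0.58) * g$width,
                 stats::runif(1, 0.36, 0.44) * g$height),
      R = R,
      ax = stats::runif(1, 0.85, 1.2),
      ay = stats::runif(1, 0.85, 1.2),
      a2 = stats::runif(1, 0, 0.08),
      ph2 = stats::runif(1, 0, 2 * pi),
      a3 = stats::runif(1, 0, 0.05),
      ph3 = stats::runif(1, 0, 2 * pi),
      posterior = NULL,
      grid = g)
    if (design$include_posterior) {
      shape$posterior <- list(theta = stats::rnorm(1, pi / 2, 0.15),
                              length = stats::runif(1, 0.45, 0.7) * R,
                              width = stats::runif(1, 3, 5))
    }
    out[[i]] <- structure(shape, class = "gt_shape")
  }
  names(out) <- vapply(out, `[[`, character(1), "image_id")
  out
}

# Resample a closed polyline at n arc-length-uniform positions starting
# from a random phase; returns points and outward unit normals.
resample_boundary <- function(poly, n, phase) {
  closed <- rbind(poly, poly[1L, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1L])^2 + diff(closed[, 2L])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- sort((phase + (seq_len(n) - 1L) / n) %% 1) * total
  px <- stats::approx(cum, closed[, 1L], xout = s)$y
  py <- stats::approx(cum, closed[, 2L], xout = s)$y
  # tangent from neighbouring resampled points (closed loop)
  nx <- c(px[-1L], px[1L]) - c(px[n], px[-n])
  ny <- c(py[-1L], py[1L]) - c(py[n], py[-n])
  len <- sqrt(nx^2 + ny^2)
  len[len == 0] <- 1
  normal <- cbind(ny / len, -nx / len)
  ctr <- c(mean(poly[, 1L]), mean(poly[, 2L]))
  flip <- (px - ctr[1L]) * normal[, 1L] + (py - ctr[2L]) * normal[, 2L] < 0
  normal[flip, ] <- -normal[flip, ]
  list(points = cbind(x = px, y = py), normals = normal)
}

#' Simulate one annotator's outline of one shape
#'
#' Samples the annotator's point budget arc-length-uniformly along the
#' true boundary (split between body and posterior process in proportion
#' to their perimeters) and perturbs each point by `bias + N(0, sigma)`
#' pixels — radially from the centre for the body, along the outward
#' normal for the posterior process. With probability `gross_error_rate`
#' the outline is instead drawn around a displaced, shrunken body.
#' Deterministic given `(shape, model, seed)`.
#'
#' @param shape A `gt_shape`.
#' @param model An [annotator_model()].
#' @param seed Integer seed; defaults to a substream of the model seed
#'   and the image id.
#' @return An [outline_record()] whose first region outlines the body
#'   and whose second (when the shape has one, and the outline is not a
#'   gross error) outlines the posterior process.
#' @export
simulate_outline <- function(shape, model, seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(model$seed, "outline", shape$image_id)
  set.seed(seed)
  gross <- stats::runif(1) < model$gross_error_rate
  ctr <- shape$center
  scale <- 1
  if (gross) {
    ang <- stats::runif(1, 0, 2 * pi)
    ctr <- ctr + stats::runif(1, 0.3, 0.6) * shape$R * c(cos(ang), sin(ang))
    scale <- 0.6
  }
  # split the point budget by perimeter share
  bp <- body_polygon(shape, 256L)
  body_perim <- sum(sqrt(rowSums((bp - bp[c(2:256, 1), ])^2)))
  post <- if (gross) NULL else posterior_polygon(shape)
  post_perim <- if (is.null(post)) 0 else {
    cl <- rbind(post, post[1L, ])
    sum(sqrt(diff(cl[, 1L])^2 + diff(cl[, 2L])^2))
  }
  n_body <- if (post_perim > 0)
    max(8L, round(model$n_points * body_perim / (body_perim + post_perim)))
  else model$n_points
  n_post <- if (post_perim > 0) max(6L, model$n_points - n_body) else 0L

  # arc-length-uniform sampling of the body boundary: map equally spaced
  # arc-length targets (with a random phase) through the cumulative
  # perimeter back to polar angles
  phase <- stats::runif(1)
  dense_t <- seq(0, 2 * pi, length.out = 721L)
  dense_r <- shape_radius(shape, dense_t)
  dx <- diff(dense_r * cos(dense_t))
  dy <- diff(dense_r * sin(dense_t))
  cum <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  s <- sort((phase + (seq_len(n_body) - 1L) / n_body) %% 1) * cum[721L]
  tt <- stats::approx(cum, dense_t, xout = s)$y
  rr <- scale * shape_radius(shape, tt) + model$bias +
    stats::rnorm(n_body, 0, model$sigma)
  regions <- list(cbind(x = ctr[1L] + rr * cos(tt),
                        y = ctr[2L] + rr * sin(tt)))
  if (n_post > 0L) {
    rs <- resample_boundary(post, n_post, stats::runif(1))
    eps <- model$bias + stats::rnorm(n_post, 0, model$sigma)
    regions <- c(regions, list(rs$points + eps * rs$normals))
  }
  outline_record(model$annotator_id, shape$image_id, regions)
}

#' Draw citizen workloads from the design's distribution
#'
#' Truncated-normal workloads rounded to whole images and clamped to
#' `[1, n_images]`. When `n_points` is supplied, workloads are coupled
#' to the point budgets through a Gaussian copula with latent
#' correlation `design$workload_points_cor` — annotators with larger
#' point budgets draw smaller workloads — without changing the
#' truncated-normal marginal.
#'
#' @param design A [study_design()].
#' @param n Number of draws (default `design$n_citizens`).
#' @param n_points Optional vector (length `n`) of the annotators'
#'   outline point budgets to couple the draws to.
#' @return Integer vector of workloads.
#' @export
draw_workloads <- function(design, n = design$n_citizens, n_points = NULL) {
  plo <- stats::pnorm(1, design$workload_mean, design$workload_sd)
  phi <- stats::pnorm(design$n_images, design$workload_mean, design$workload_sd)
  rho <- design$workload_points_cor
  if (is.null(n_points) || rho == 0) {
    u <- stats::runif(n)
  } else {
    stopifnot(length(n_points) == n)
    # normal scores of the point budgets (Blom), mixed with fresh noise
    zp <- stats::qnorm((rank(n_points, ties.method = "average") - 0.375) /
                         (n + 0.25))
    u <- stats::pnorm(rho * zp + sqrt(1 - rho^2) * stats::rnorm(n))
  }
  w <- round(stats::qnorm(plo + u * (phi - plo),
                          design$workload_mean, design$workload_sd))
  as.integer(pmin(design$n_images, pmax(1L, w)))
}

default_citizen_models <- function(design, ages, plant_age_effect = FALSE) {
  n <- design$n_citizens
  sigma <- stats::runif(n, 0.8, 2.8)
  if (plant_age_effect)
    sigma <- 0.8 + 2.0 * (ages - 18) / 55 + stats::runif(n, -0.2, 0.2)
  lapply(seq_len(n), function(i)
    annotator_model(sprintf("c%02d", i),
                    sigma = max(0, sigma[i]),
                    bias = stats::runif(1, -0.5, 0.5),
                    n_points = sample(36:130, 1L),
                    gross_error_rate = 0.02,
                    seed = substream_seed(design$seed, "citizen", i)))
}

default_expert_models <- function(design) {
  lapply(seq_len(design$n_experts), function(i)
    annotator_model(sprintf("e%d", i),
                    sigma = stats::runif(1, 0.5, 1.0),
                    bias = 0,
                    n_points = sample(80:120, 1L),
                    gross_error_rate = 0,
                    seed = substream_seed(design$seed, "expert", i)))
}

#' Simulate a full crowd-sourced segmentation study
#'
#' Generates ground-truth shapes, draws annotator models and citizen
#' workloads, assigns each citizen a random subset of images split
#' across sessions, simulates every outline, and assembles the canonical
#' annotation table plus annotator metadata (synthetic ages) and
#' ground-truth masks. Experts segment every image. Deterministic given
#' the design seed.
#'
#' Default annotator models give experts low boundary noise (sigma
#' 0.5-1 px, no bias) and citizens a wide heterogeneous range (sigma
#' 0.8-2.8 px, small biases, occasional gross errors), chosen so the
#' emergent accuracy statistics land in the range reported for human
#' panels on this kind of task (most individual citizens above 0.8 Dice
#' against the expert consensus; expert pairwise agreement around
#' 0.95+).
#'
#' @param design A [study_design()].
#' @param citizen_models,expert_models Optional lists of
#'   [annotator_model()] objects; lengths must match the design counts.
#'   Defaults are drawn from the design seed.
#' @param plant_age_effect When using default citizen models, make
#'   boundary noise increase with age so the age-accuracy regression
#'   has a recoverable planted effect (default `FALSE`).
#' @return A list of class `synthetic_study` with elements
#'   `annotations` (canonical table), `annotators` (metadata:
#'   `annotator_id`, `age`, `group`), `shapes`, `ground_truth` (named
#'   list of `binary_mask`), `design`, and `coverage` (data frame of
#'   citizen counts per image; images no citizen segmented are listed
#'   with zero).
#' @export
simulate_study <- function(design, citizen_models = NULL,
                           expert_models = NULL, plant_age_effect = FALSE) {
  shapes <- generate_shapes(design)

  set.seed(substream_seed(design$seed, "models"))
  ages <- round(stats::runif(design$n_citizens, 18, 73))
  if (is.null(citizen_models))
    citizen_models <- default_citizen_models(design, ages, plant_age_effect)
  if (is.null(expert_models))
    expert_models <- default_expert_models(design)
  if (length(citizen_models) != design$n_citizens)
    stop("length(citizen_models) must equal design$n_citizens")
  if (length(expert_models) != design$n_experts)
    stop("length(expert_models) must equal design$n_experts")

  set.seed(substream_seed(design$seed, "assignment"))
  workloads <- draw_workloads(
    design, n_points = vapply(citizen_models, `[[`, integer(1), "n_points"))
  assignment <- lapply(workloads, function(k) sort(sample(design$n_images, k)))
  # split each citizen's images across sessions; the first session is a
  # little slower (training effect), mirroring observed throughput
  session_of <- lapply(assignment, function(imgs) {
    k <- length(imgs)
    if (design$n_sessions == 1L) return(rep(1L, k))
    pr <- c(0.28, rep(0.72 / (design$n_sessions - 1L), design$n_sessions - 1L))
    sizes <- round(k * pr)
    sizes[design$n_sessions] <- k - sum(sizes[-design$n_sessions])
    rep(seq_len(design$n_sessions), times = pmax(0L, sizes))[seq_len(k)]
  })

  cols <- list(aid = list(), img = list(), ses = list(), reg = list(),
               vtx = list(), x = list(), y = list())
  k <- 0L
  push <- function(rec, session) {
    for (j in seq_along(rec$regions)) {
      p <- rec$regions[[j]]
      k <<- k + 1L
      n <- nrow(p)
      cols$aid[[k]] <<- rep(rec$annotator_id, n)
      cols$img[[k]] <<- rep(rec$image_id, n)
      cols$ses[[k]] <<- rep(as.integer(session), n)
      cols$reg[[k]] <<- rep(j, n)
      cols$vtx[[k]] <<- seq_len(n)
      cols$x[[k]] <<- p[, 1L]
      cols$y[[k]] <<- p[, 2L]
    }
  }
  image_ids <- names(shapes)
  for (i in seq_along(citizen_models)) {
    m <- citizen_models[[i]]
    imgs <- assignment[[i]]
    for (j in seq_along(imgs)) {
      shp <- shapes[[imgs[j]]]
      rec <- simulate_outline(shp, m,
                              seed = substream_seed(design$seed, "out", i, imgs[j]))
      push(rec, session_of[[i]][j])
    }
  }
  for (i in seq_along(expert_models)) {
    m <- expert_models[[i]]
    for (j in seq_len(design$n_images)) {
      rec <- simulate_outline(shapes[[j]], m,
                              seed = substream_seed(design$seed, "exp", i, j))
      push(rec, 1L)
    }
  }
  annotations <- data.frame(
    annotator_id = unlist(cols$aid), image_id = unlist(cols$img),
    session = unlist(cols$ses), region_index = unlist(cols$reg),
    vertex_index = unlist(cols$vtx),
    x = unlist(cols$x), y = unlist(cols$y),
    stringsAsFactors = FALSE)

  annotators <- data.frame(
    annotator_id = c(vapply(citizen_models, `[[`, character(1), "annotator_id"),
                     vapply(expert_models, `[[`, character(1), "annotator_id")),
    age = c(ages, rep(NA_real_, design$n_experts)),
    group = c(rep("citizen", design$n_citizens),
              rep("expert", design$n_experts)),
    stringsAsFactors = FALSE)

  n_cit <- tabulate(unlist(assignment), nbins = design$n_images)
  coverage <- data.frame(image_id = image_ids, n_citizens = n_cit,
                         stringsAsFactors = FALSE)

  structure(list(annotations = annotations, annotators = annotators,
                 shapes = shapes,
                 ground_truth = lapply(shapes, shape_mask),
                 design = design, coverage = coverage),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", x$design$n_images, " images, ",
      x$design$n_citizens, " citizens, ", x$design$n_experts, " experts, ",
      nrow(x$annotations), " vertex rows\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `annotations.csv`, `annotators.csv`, `design.json` and a
#' `ground_truth/` directory of PNG masks.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations(study$annotations, file.path(dir, "annotations.csv"))
  utils::write.table(study$annotators, file.path(dir, "annotators.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  d <- study$design
  jsonlite::write_json(
    list(n_images = d$n_images, n_citizens = d$n_citizens,
         n_experts = d$n_experts, workload_mean = d$workload_mean,
         workload_sd = d$workload_sd,
         workload_points_cor = d$workload_points_cor,
         grid = c(d$grid$height, d$grid$width),
         radius_frac = d$radius_frac,
         include_posterior = d$include_posterior,
         n_sessions = d$n_sessions, seed = d$seed),
    file.path(dir, "design.json"), auto_unbox = TRUE)
  gt_dir <- file.path(dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  for (img in names(study$ground_truth))
    write_mask_png(study$ground_truth[[img]], gt_dir,
                   image_id = img, annotator_id = "ground_truth")
  invisible(dir)
}

#' Estimate annotator boundary noise from outlines and ground truth
#'
#' For each record's body outline (region 1) the radial deviation of
#' every vertex from the true body boundary is measured:
#' `|p - centre| - rho(theta(p))`. Pooled per annotator, the standard
#' deviation of these residuals estimates the annotator's `sigma` (the
#' mean estimates the bias). Gross-error outlines are not down-weighted,
#' so the estimator is meant for panels simulated without gross errors;
#' posterior-process regions are excluded because their noise is applied
#' along local normals, not radially.
#'
#' @param records List of `outline_record` objects.
#' @param shapes Named list of `gt_shape` objects (by `image_id`).
#' @return A data frame with columns `annotator_id`, `n_points`,
#'   `sigma_hat`, `bias_hat`.
#' @export
estimate_boundary_sigma <- function(records, shapes) {
  dev <- list()
  for (rec in records) {
    shape <- shapes[[rec$image_id]]
    if (is.null(shape)) next
    p <- rec$regions[[1L]]
    dxv <- p[, 1L] - shape$center[1L]
    dyv <- p[, 2L] - shape$center[2L]
    theta <- atan2(dyv, dxv)
    d <- sqrt(dxv^2 + dyv^2) - shape_radius(shape, theta)
    dev[[rec$annotator_id]] <- c(dev[[rec$annotator_id]], d)
  }
  data.frame(
    annotator_id = names(dev),
    n_points = vapply(dev, length, integer(1)),
    sigma_hat = vapply(dev, stats::sd, numeric(1)),
    bias_hat = vapply(dev, mean, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
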