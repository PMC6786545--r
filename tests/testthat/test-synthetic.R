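# The synthetic study generator: shapes, annotator noise model, study
# assembly, and recoverability of the planted parameters.

test_that("shape generation is deterministic and respects the design", {
  d <- study_design(n_images = 5, grid = image_grid(64, 64), seed = 9)
  s1 <- generate_shapes(d)
  s2 <- generate_shapes(d)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  d1 <- study_design(n_images = 1, seed = 9)
  expect_length(generate_shapes(d1), 1)
  # ground-truth masks are non-empty and inside the grid
  for (shape in s1) {
    m <- shape_mask(shape)
    expect_gt(mask_area(m), 0)
    expect_equal(dim(m$pixels), c(64, 64))
  }
  expect_error(generate_shapes(study_design(grid = image_grid(32, 32))),
               "too small")
})

test_that("posterior processes are thinner than the body", {
  d <- study_design(n_images = 6, seed = 15)
  for (shape in generate_shapes(d)) {
    expect_lt(shape$posterior$width, shape$R)
    body <- rasterize_polygon(shape_polygons(shape)$body, shape$grid)
    expect_gt(mask_area(body), 0)
  }
})

test_that("a noiseless generous outline reproduces the ground truth closely", {
  d <- study_design(n_images = 2, include_posterior = FALSE, seed = 3)
  shape <- generate_shapes(d)[[1]]
  model <- annotator_model("a", sigma = 0, bias = 0, n_points = 200,
                           gross_error_rate = 0, seed = 1)
  rec <- simulate_outline(shape, model, seed = 5)
  expect_gt(dice(rasterize_record(rec, shape$grid), shape_mask(shape)), 0.98)
})

test_that("positive radial bias dilates the outline", {
  d <- study_design(n_images = 1, include_posterior = FALSE, seed = 4)
  shape <- generate_shapes(d)[[1]]
  gt_area <- mask_area(shape_mask(shape))
  model <- annotator_model("a", sigma = 0, bias = 2, n_points = 150,
                           gross_error_rate = 0, seed = 1)
  rec <- simulate_outline(shape, model, seed = 5)
  expect_gt(mask_area(rasterize_record(rec, shape$grid)), gt_area)
  erode <- annotator_model("a", sigma = 0, bias = -2, n_points = 150,
                           gross_error_rate = 0, seed = 1)
  rec2 <- simulate_outline(shape, erode, seed = 5)
  expect_lt(mask_area(rasterize_record(rec2, shape$grid)), gt_area)
})

test_that("accuracy decreases monotonically with boundary noise", {
  d <- study_design(n_images = 5, include_posterior = FALSE,
                    grid = image_grid(64, 64), seed = 6)
  shapes <- generate_shapes(d)
  gts <- lapply(shapes, shape_mask)
  mean_dice <- vapply(c(0.5, 1, 2, 4), function(sig) {
    model <- annotator_model("a", sigma = sig, n_points = 80,
                             gross_error_rate = 0, seed = 1)
    reps <- unlist(lapply(1:4, function(r)
      vapply(seq_along(shapes), function(i) {
        rec <- simulate_outline(shapes[[i]], model, seed = 1000 * r + i)
        dice(rasterize_record(rec, d$grid), gts[[i]])
      }, numeric(1))))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
})

test_that("gross errors produce grossly wrong outlines", {
  d <- study_design(n_images = 1, include_posterior = FALSE, seed = 8)
  shape <- generate_shapes(d)[[1]]
  gt <- shape_mask(shape)
  good <- annotator_model("a", sigma = 1, n_points = 80,
                          gross_error_rate = 0, seed = 1)
  bad <- annotator_model("a", sigma = 1, n_points = 80,
                         gross_error_rate = 1, seed = 1)
  d_good <- dice(rasterize_record(simulate_outline(shape, good, seed = 2),
                                  shape$grid), gt)
  d_bad <- dice(rasterize_record(simulate_outline(shape, bad, seed = 2),
                                 shape$grid), gt)
  expect_gt(d_good, 0.9)
  expect_lt(d_bad, 0.75)
})

test_that("outline simulation is deterministic given (shape, model, seed)", {
  d <- study_design(n_images = 1, seed = 12)
  shape <- generate_shapes(d)[[1]]
  model <- annotator_model("a", sigma = 1.5, n_points = 60, seed = 77)
  r1 <- simulate_outline(shape, model, seed = 123)
  r2 <- simulate_outline(shape, model, seed = 123)
  expect_identical(r1, r2)
  r3 <- simulate_outline(shape, model, seed = 124)
  expect_false(identical(r1$regions[[1]], r3$regions[[1]]))
})

test_that("workload draws match the configured truncated normal", {
  d <- study_design(seed = 30)
  set.seed(99)
  w <- draw_workloads(d, n = 1000)
  expect_true(all(w >= 1 & w <= d$n_images))
  # closed-form truncated-normal moments as the oracle
  mu <- d$workload_mean; sg <- d$workload_sd
  al <- (1 - mu) / sg; be <- (d$n_images - mu) / sg
  z <- pnorm(be) - pnorm(al)
  tmean <- mu + sg * (dnorm(al) - dnorm(be)) / z
  tvar <- sg^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z -
                    ((dnorm(al) - dnorm(be)) / z)^2)
  expect_lt(abs(mean(w) - tmean) / tmean, 0.05)
  expect_lt(abs(sd(w) - sqrt(tvar)) / sqrt(tvar), 0.05)
})

test_that("workloads are anticorrelated with point budgets but keep their marginal", {
  d <- study_design(seed = 30)
  set.seed(99)
  np <- sample(36:130, 500, replace = TRUE)
  w <- draw_workloads(d, n = 500, n_points = np)
  expect_lt(cor(np, w), -0.4)
  # coupling must not distort the truncated-normal workload marginal
  mu <- d$workload_mean; sg <- d$workload_sd
  al <- (1 - mu) / sg; be <- (d$n_images - mu) / sg
  z <- pnorm(be) - pnorm(al)
  tmean <- mu + sg * (dnorm(al) - dnorm(be)) / z
  expect_lt(abs(mean(w) - tmean) / tmean, 0.05)
  # a realistically sized study shows the negative points-vs-images trend
  ds <- study_design(n_images = 60, n_citizens = 20, workload_mean = 34,
                     workload_sd = 17, grid = image_grid(64, 64), seed = 13)
  st <- simulate_study(ds)
  summ <- annotator_summary(st$annotations)
  summ <- summ[grepl("^c", summ$annotator_id), ]
  expect_lt(points_vs_images_correlation(summ)$r, -0.3)
})

test_that("a full study is deterministic and matches the design counts", {
  s1 <- small_study()
  d <- s1$design
  s2 <- simulate_study(d)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$annotators, s2$annotators)
  expect_equal(nrow(s1$annotators), d$n_citizens + d$n_experts)
  expect_length(s1$ground_truth, d$n_images)
  # experts segment every image
  for (e in sprintf("e%d", seq_len(d$n_experts)))
    expect_equal(length(unique(
      s1$annotations$image_id[s1$annotations$annotator_id == e])),
      d$n_images)
  # citizens segment subsets; coverage table accounts for every image
  expect_equal(sum(s1$coverage$n_citizens),
               sum(vapply(sprintf("c%02d", seq_len(d$n_citizens)), function(a)
                 length(unique(s1$annotations$image_id[
                   s1$annotations$annotator_id == a])), numeric(1))))
  expect_error(simulate_study(d, citizen_models = list()),
               "n_citizens")
})

test_that("written studies round-trip through disk", {
  s <- small_study()
  dir <- withr::local_tempdir()
  write_study(s, dir)
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(nrow(ann), nrow(s$annotations))
  meta <- read_annotator_metadata(file.path(dir, "annotators.csv"))
  expect_equal(meta$group, s$annotators$group)
  gt <- read_mask_png(file.path(dir, "ground_truth",
                                "img001__ground_truth.png"))
  expect_identical(gt$pixels, s$ground_truth$img001$pixels)
  cfg <- jsonlite::read_json(file.path(dir, "design.json"))
  expect_equal(cfg$seed, s$design$seed)
})

test_that("planted boundary noise is recoverable from the outlines", {
  d <- study_design(n_images = 12, include_posterior = FALSE,
                    grid = image_grid(64, 64), seed = 18)
  shapes <- generate_shapes(d)
  sig <- c(a1 = 1, a2 = 2.5)
  recs <- list()
  for (a in names(sig)) {
    model <- annotator_model(a, sigma = sig[[a]], bias = 0.5, n_points = 80,
                             gross_error_rate = 0, seed = 1)
    for (i in seq_along(shapes))
      recs <- c(recs, list(simulate_outline(shapes[[i]], model,
                                            seed = 7000 + 100 * match(a, names(sig)) + i)))
  }
  est <- estimate_boundary_sigma(recs, shapes)
  for (a in names(sig)) {
    row <- est[est$annotator_id == a, ]
    expect_lt(abs(row$sigma_hat - sig[[a]]) / sig[[a]], 0.15)
    expect_lt(abs(row$bias_hat - 0.5), 0.2)
  }
})

test_that("agreement is lower on thin posterior processes than on bodies", {
  d <- study_design(n_images = 8, grid = image_grid(64, 64), seed = 22)
  shapes <- generate_shapes(d)
  body_d <- c(); post_d <- c()
  for (i in seq_along(shapes)) {
    shape <- shapes[[i]]
    recs <- lapply(1:3, function(a) {
      model <- annotator_model(paste0("a", a), sigma = 1.5, n_points = 90,
                               gross_error_rate = 0, seed = a)
      simulate_outline(shape, model, seed = 5000 + 100 * a + i)
    })
    bodies <- lapply(recs, function(r) rasterize_polygon(r$regions[[1]], d$grid))
    posts <- lapply(recs, function(r) rasterize_polygon(r$regions[[2]], d$grid))
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      body_d <- c(body_d, dice(bodies[[p[1]]], bodies[[p[2]]]))
      post_d <- c(post_d, dice(posts[[p[1]]], posts[[p[2]]]))
    }
  }
  expect_gt(mean(body_d), mean(post_d))
})
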