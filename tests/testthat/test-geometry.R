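# Scanline rasterization, outline records, annotation I/O.

test_that("grid and polygon validation reject bad inputs", {
  expect_error(image_grid(0, 5), "height")
  expect_error(image_grid(5, -1), "width")
  expect_error(image_grid(5, 5, pixel_spacing = c(0.5, -1)), "pixel_spacing")
  expect_error(as_polygon(rbind(c(0, 0), c(1, 1))), "fewer than 3")
  expect_error(as_polygon(cbind(c(0, 1, NA), c(0, 1, 2))), "non-finite")
  expect_error(outline_record("a", "i", list()), "at least one region")
})

test_that("axis-aligned square fills exactly the pixels with interior centres", {
  g <- image_grid(6, 6)
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  m <- rasterize_polygon(sq, g)
  expect_equal(mask_area(m), 16)
  # matches the brute-force point-in-polygon oracle everywhere
  expect_identical(m$pixels, pip_bruteforce(sq, g))
  # filled block is rows/cols 1..4 (centres 0.5..3.5)
  expect_true(all(m$pixels[1:4, 1:4]))
  expect_false(any(m$pixels[5:6, ]))
})

test_that("a centre exactly on an edge is outside (strict interior)", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  m <- rasterize_polygon(tri, image_grid(1, 1))
  expect_equal(mask_area(m), 0)
})

test_that("polygons fully outside the grid rasterize to an empty mask", {
  g <- image_grid(4, 4)
  far <- rbind(c(10, 10), c(14, 10), c(12, 14))
  expect_equal(mask_area(rasterize_polygon(far, g)), 0)
  below <- rbind(c(0, -5), c(3, -5), c(1, -1))
  expect_equal(mask_area(rasterize_polygon(below, g)), 0)
})

test_that("degenerate polygons error or warn as contracted", {
  g <- image_grid(4, 4)
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1)), g), "fewer than 3")
  expect_warning(m <- rasterize_polygon(rbind(c(0, 0), c(1, 1), c(2, 2)), g),
                 "collinear")
  expect_equal(mask_area(m), 0)
  expect_warning(m2 <- rasterize_polygon(rbind(c(1, 1), c(1, 1), c(1, 1)), g),
                 "collinear")
  expect_equal(mask_area(m2), 0)
})

test_that("adjacent polygons tile without double cover (half-open rule)", {
  g <- image_grid(6, 6)
  left <- rbind(c(0, 0), c(3, 0), c(3, 6), c(0, 6))
  right <- rbind(c(3, 0), c(6, 0), c(6, 6), c(3, 6))
  ml <- rasterize_polygon(left, g)
  mr <- rasterize_polygon(right, g)
  expect_equal(mask_area(ml) + mask_area(mr), 36)
  expect_false(any(ml$pixels & mr$pixels))
})

test_that("scanline fill agrees with the brute-force oracle on random simple polygons", {
  set.seed(101)
  for (i in 1:60) {
    h <- sample(8:64, 1)
    w <- sample(8:64, 1)
    g <- image_grid(h, w)
    poly <- random_star_polygon(sample(5:40, 1),
                                center = c(runif(1, 0, w), runif(1, 0, h)),
                                rmin = 1, rmax = runif(1, 3, min(h, w) / 2))
    expect_identical(rasterize_polygon(poly, g)$pixels,
                     pip_bruteforce(poly, g))
  }
})

test_that("self-intersecting polygons fill under even-odd semantics", {
  g <- image_grid(8, 8)
  bowtie <- rbind(c(0, 0), c(6, 6), c(6, 0), c(0, 6))
  expect_identical(rasterize_polygon(bowtie, g)$pixels,
                   pip_bruteforce(bowtie, g))
})

test_that("integer translation shifts the mask identically", {
  set.seed(7)
  g <- image_grid(40, 40)
  poly <- random_star_polygon(12, center = c(12, 12), rmin = 3, rmax = 8)
  m0 <- rasterize_polygon(poly, g)$pixels
  for (shift in list(c(5, 0), c(0, 7), c(9, 11))) {
    m1 <- rasterize_polygon(cbind(poly[, 1] + shift[1], poly[, 2] + shift[2]),
                            g)$pixels
    # compare on the region where both placements are in-grid
    rows0 <- 1:(40 - shift[2]); cols0 <- 1:(40 - shift[1])
    expect_identical(m1[rows0 + shift[2], cols0 + shift[1]], m0[rows0, cols0])
  }
})

test_that("records union their regions", {
  g <- image_grid(8, 8)
  sq1 <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))      # 4 px
  sq2 <- rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6))      # 4 px, disjoint
  rec <- outline_record("a", "i", list(sq1, sq2))
  expect_equal(mask_area(rasterize_record(rec, g)), 8)
  # idempotent union
  rec2 <- outline_record("a", "i", list(sq1, sq1))
  expect_identical(rasterize_record(rec2, g)$pixels,
                   rasterize_polygon(sq1, g)$pixels)
  # overlapping 16-px squares sharing a 2x2 block
  sqa <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  sqb <- rbind(c(2, 2), c(6, 2), c(6, 6), c(2, 6))
  rec3 <- outline_record("a", "i", list(sqa, sqb))
  union_oracle <- pip_bruteforce(sqa, g) | pip_bruteforce(sqb, g)
  expect_equal(mask_area(rasterize_record(rec3, g)), sum(union_oracle)) # 28
  expect_identical(rasterize_record(rec3, g)$pixels, union_oracle)
  # union area is at least the largest region
  expect_gte(mask_area(rasterize_record(rec3, g)),
             max(mask_area(rasterize_polygon(sqa, g)),
                 mask_area(rasterize_polygon(sqb, g))))
})

test_that("a record whose every region is degenerate errors", {
  g <- image_grid(4, 4)
  bad <- outline_record("a", "i", list(rbind(c(0, 0), c(1, 1), c(2, 2))))
  expect_error(suppressWarnings(rasterize_record(bad, g)), "degenerate")
})

test_that("annotation tables round-trip through records and disk", {
  g <- image_grid(10, 10)
  recs <- list(
    outline_record("a1", "imgA", list(rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5)),
                                      rbind(c(6, 6), c(8, 6), c(7, 8))),
                   session = 1L),
    outline_record("a2", "imgA", rbind(c(2, 2), c(6, 2), c(4, 7)), session = 2L))
  tab <- table_from_records(recs)
  expect_equal(nrow(tab), 4 + 3 + 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tab, path)
  back <- records_from_table(read_annotations(path))
  expect_length(back, 2)
  ord <- order(vapply(back, `[[`, character(1), "annotator_id"))
  back <- back[ord]
  for (k in 1:2) {
    expect_identical(rasterize_record(back[[k]], g)$pixels,
                     rasterize_record(recs[[k]], g)$pixels)
    expect_identical(back[[k]]$session, recs[[k]]$session)
  }
})

test_that("malformed annotation rows are dropped on read with a warning", {
  tab <- table_from_records(list(
    outline_record("a1", "imgA", rbind(c(1, 1), c(4, 1), c(2, 4)))))
  tab$x[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(write_annotations(tab, path))
  expect_warning(df <- read_annotations(path), "malformed")
  expect_equal(nrow(df), 2)
})

test_that("masks round-trip through 8-bit PNG export", {
  set.seed(3)
  m <- random_mask(12, 9, 0.4)
  dir <- withr::local_tempdir()
  path <- write_mask_png(m, dir, image_id = "imgX", annotator_id = "a7")
  expect_true(file.exists(file.path(dir, "imgX__a7.png")))
  expect_identical(read_mask_png(path)$pixels, m$pixels)
})
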