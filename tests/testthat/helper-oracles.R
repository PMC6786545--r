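# Independent oracles and small fixture builders shared across tests.

# Brute-force even-odd point-in-polygon test at every pixel centre.
# Per-edge parity accumulation over the whole centre lattice — same
# conventions as the package (half-open in y, strict in x) but a wholly
# different code path from the scanline fill.
pip_bruteforce <- function(poly, grid) {
  h <- grid$height; w <- grid$width
  cxs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  cys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  inside <- matrix(FALSE, h, w)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if (y1 != y2) {
      cross <- (y1 <= cys) != (y2 <= cys)
      xc <- x1 + (x2 - x1) * (cys - y1) / (y2 - y1)
      inside <- xor(inside, cross & (xc > cxs))
    }
    j <- i
  }
  inside
}

# Random star-shaped (hence simple) polygon: sorted random angles, random
# radii about a centre.
random_star_polygon <- function(n, center, rmin, rmax) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# Mann-Whitney U by direct pair counting (ties count one half) — no ranks.
u_paircount <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Full enumeration of the Mann-Whitney permutation null via pair counting:
# returns the observed U and the two-sided p-value P(|U - m| >= |u - m|).
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_obs <- u_paircount(a, b)
  subsets <- utils::combn(n, na)
  us <- apply(subsets, 2, function(s) u_paircount(pooled[s], pooled[-s]))
  m <- na * (n - na) / 2
  list(U = u_obs, p = mean(abs(us - m) >= abs(u_obs - m) - 1e-9))
}

# Binary mask from a 0/1 matrix.
mk_mask <- function(mat) {
  binary_mask(mat == 1, image_grid(nrow(mat), ncol(mat)))
}

# Rectangular mask: rows/cols are 1-based index vectors.
rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  binary_mask(m, image_grid(h, w))
}

# Random mask with given inclusion probability.
random_mask <- function(h, w, p = 0.3) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w), image_grid(h, w))
}

# A small synthetic study reused by several test files (built once).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- study_design(n_images = 12L, n_citizens = 6L, n_experts = 3L,
                        workload_mean = 9, workload_sd = 3,
                        grid = image_grid(64L, 64L), seed = 42L)
      cache <<- simulate_study(d)
    }
    cache
  }
})

# Split per-image mask stacks into citizen and expert sub-stacks by
# annotator-id prefix (simulate_study uses c* and e*).
split_panels <- function(masks) {
  cit <- lapply(masks, function(st) st[grepl("^c", names(st))])
  exp <- lapply(masks, function(st) st[grepl("^e", names(st))])
  list(citizens = cit[vapply(cit, length, integer(1)) > 0],
       experts = exp[vapply(exp, length, integer(1)) > 0])
}
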