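# Independent oracles used to check the package's implementations.
# These deliberately use naive algorithms (explicit loops, all-pairs
# distances, hand-written interpolation) so they share no code path with
# the functions under test.

rand_mask <- function(dims, p = 0.2, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  binary_mask(array(runif(prod(dims)) < p, dims), spacing = spacing)
}

# boundary voxels by explicit 6-neighbour check (out-of-grid = background)
brute_boundary <- function(vox) {
  d <- dim(vox)
  fg <- which(vox != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(fg)
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  is_b <- vapply(seq_len(nrow(fg)), function(r) {
    for (t in 1:6) {
      nb <- fg[r, ] + off[t, ]
      if (any(nb < 1) || any(nb > d)) return(TRUE)
      if (vox[nb[1], nb[2], nb[3]] == 0) return(TRUE)
    }
    FALSE
  }, logical(1))
  fg[is_b, , drop = FALSE]
}

# ASSD/MSSD by all-pairs distances over the two boundary sets
brute_surface_metrics <- function(pred, ref) {
  bp <- brute_boundary(pred$voxels)
  br <- brute_boundary(ref$voxels)
  if (nrow(bp) == 0 || nrow(br) == 0) return(NULL)
  sp <- pred$spacing
  dist2 <- outer(bp[, 1], br[, 1], function(a, b) ((a - b) * sp[1])^2) +
           outer(bp[, 2], br[, 2], function(a, b) ((a - b) * sp[2])^2) +
           outer(bp[, 3], br[, 3], function(a, b) ((a - b) * sp[3])^2)
  d_pr <- sqrt(apply(dist2, 1, min))
  d_rp <- sqrt(apply(dist2, 2, min))
  list(assd = mean(c(d_pr, d_rp)), mssd = max(d_pr, d_rp))
}

# type-7 quantile written out by hand (linear interpolation of order stats)
manual_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# York objective minimised by brute force: profile out the intercept at
# each slope, scan a wide slope grid, then polish with optimize()
york_objective <- function(b, x, y, sx, sy) {
  W <- 1 / (sy^2 + b^2 * sx^2)
  a <- sum(W * (y - b * x)) / sum(W)
  sum(W * (y - a - b * x)^2)
}

york_grid_slope <- function(x, y, sx, sy, lo = -10, hi = 10) {
  grid <- seq(lo, hi, length.out = 4001)
  vals <- vapply(grid, york_objective, numeric(1), x = x, y = y, sx = sx, sy = sy)
  b0 <- grid[which.min(vals)]
  step <- grid[2] - grid[1]
  stats::optimize(york_objective, c(b0 - 2 * step, b0 + 2 * step),
                  x = x, y = y, sx = sx, sy = sy, tol = 1e-12)$minimum
}

# one hand-iterated STAPLE update for a single rater (closed form)
staple_j1_oracle <- function(dvec, prior, init_p, init_q, n_iter = 50) {
  p <- init_p
  q <- init_q
  for (it in seq_len(n_iter)) {
    a <- prior * ifelse(dvec == 1, p, 1 - p)
    b <- (1 - prior) * ifelse(dvec == 1, 1 - q, q)
    W <- a / (a + b)
    p <- sum(W * dvec) / sum(W)
    q <- sum((1 - W) * (1 - dvec)) / sum(1 - W)
    p <- min(max(p, 1e-7), 1 - 1e-7)
    q <- min(max(q, 1e-7), 1 - 1e-7)
  }
  W
}

# tiny deterministic study used by several suites (no catastrophic failures
# unless asked for)
tiny_study <- function(seed = 1, n_images = 4, n_models = 3, shape = 32,
                       p_spurious = 0, p_dropout = 0) {
  spec <- study_spec(
    n_images = n_images, n_models = n_models,
    phantom = phantom_spec(shape = rep(shape, 3), semi_axes = c(7, 6, 5)),
    profiles = model_profile(max_translation_vox = 1.5,
                             p_spurious = p_spurious, p_dropout = p_dropout,
                             spurious_min_dist_mm = 8,
                             spurious_size_range = c(27, 81)),
    seed = seed)
  simulate_study(spec)
}
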