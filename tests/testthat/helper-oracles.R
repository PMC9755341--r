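# Independent oracles used to validate the package's own implementations.
# Each oracle takes a deliberately different computational route from the
# code under test.

# scalar pixel-center enumeration for ovals (loops, no vectorized geometry)
oracle_oval_mask <- function(cx, cy, rx, ry, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      x <- j - 1
      y <- i - 1
      m[i, j] <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1 + 1e-12
    }
  }
  m
}

# polygon membership via mgcv's independent point-in-polygon routine
oracle_polygon_mask <- function(vx, vy, nr, nc) {
  pts <- cbind(
    rep(seq_len(nc) - 1, each = nr),
    rep(seq_len(nr) - 1, times = nc)
  )
  inside <- mgcv::in.out(cbind(c(vx, vx[1]), c(vy, vy[1])), pts)
  matrix(inside, nr, nc)
}

# random simple (star-shaped) polygon with vertices off the pixel lattice;
# consecutive angular gaps are kept below pi so the polygon cannot wrap
# around its own kernel and self-intersect
random_star_polygon <- function(n_vertices, cx, cy, rmin, rmax) {
  base <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  theta <- base + stats::runif(n_vertices, 0, 0.45 * 2 * pi / n_vertices)
  r <- stats::runif(n_vertices, rmin, rmax)
  list(x = cx + r * cos(theta) + 1e-4, y = cy + r * sin(theta) + 1e-4)
}

# two-way ANOVA mean squares by stats::aov, an independent route to the ICC
oracle_icc_a1 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

oracle_icc_c1 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3])
}

# Fleiss kappa via the category-count table route
oracle_fleiss <- function(mat) {
  lev <- sort(unique(as.vector(mat)))
  n <- nrow(mat); k <- ncol(mat)
  cnt <- t(apply(mat, 1, function(r) table(factor(r, levels = lev))))
  P_i <- (rowSums(cnt^2) - k) / (k * (k - 1))
  p_j <- colSums(cnt) / (n * k)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# small phantom for fast tests: same organs at quarter resolution scale
fast_params <- function(...) {
  phantom_params(matrix_size = 128L, ...)
}

# one cached noise-free record reused across tests
local_noisefree_record <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_params(poisson_noise = FALSE),
                                 seed = 1L, subject = "T001")
    }
    cache
  }
})
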