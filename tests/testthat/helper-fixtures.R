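# Shared fixtures and small independent oracles used across tests.

# star-shaped polygon in polar form about `center`; containment is then
# analytically decidable (radius interpolation), independent of the
# package's point-in-polygon routine
make_star_polygon <- function(center, r_base, n = 24, jitter = 0.3) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r_base * (1 + runif(n, -jitter, jitter))
  list(poly = cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
       center = center, theta = th, r = r)
}

# analytic containment oracle for a polar star polygon: the boundary radius
# at angle a interpolates linearly between vertices in polar coordinates
star_contains <- function(star, px, py) {
  dx <- px - star$center[1]; dy <- py - star$center[2]
  a <- atan2(dy, dx) %% (2 * pi)
  rp <- sqrt(dx^2 + dy^2)
  n <- length(star$theta)
  i <- findInterval(a, star$theta)
  i[i == 0] <- n
  j <- ifelse(i == n, 1L, i + 1L)
  th_i <- star$theta[i]
  span <- (star$theta[ifelse(i == n, 1, j)] - th_i) %% (2 * pi)
  span[span == 0] <- 2 * pi / n
  w <- ((a - th_i) %% (2 * pi)) / span
  rb <- (1 - w) * star$r[i] + w * star$r[j]
  rp <= rb
}

# brute-force distance oracle: minimum distance to a dense sampling of the
# polygon boundary
dense_boundary_distance <- function(px, py, poly, n_samples = 1e4) {
  n <- nrow(poly)
  per_edge <- ceiling(n_samples / n)
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    t <- seq(0, 1, length.out = per_edge)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  min(sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2))
}

rotate_points <- function(x, y, angle, center = c(0, 0)) {
  dx <- x - center[1]; dy <- y - center[2]
  list(x = center[1] + dx * cos(angle) - dy * sin(angle),
       y = center[2] + dx * sin(angle) + dy * cos(angle))
}

# adjusted Rand index between two labelings (closed-form pair counting),
# kept independent of any clustering package
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_all <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_idx <- (s_a + s_b) / 2
  (s_all - expected) / (max_idx - expected)
}

# small two-group survival data frame
toy_survival <- function(time, event, ...) {
  data.frame(patient_id = sprintf("p%02d", seq_along(time)),
             time = time, event = event, ...)
}
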