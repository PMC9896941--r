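# Independent oracles used to check the package's computational paths.
# Each is a deliberately naive implementation (loops, enumeration) kept
# separate from the code it validates.

# --- FRC ring sums by explicit loop over integer frequency coordinates ---
oracle_frc <- function(img1, img2, bin_width = 1L) {
  n <- nrow(img1)
  f1 <- stats::fft(img1)
  f2 <- stats::fft(img2)
  nring <- floor((n / 2) / bin_width)
  num <- p1 <- p2 <- rep(0, nring + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ky <- i - 1L; if (ky > n / 2) ky <- ky - n
      kx <- j - 1L; if (kx > n / 2) kx <- kx - n
      ring <- round(sqrt(ky^2 + kx^2) / bin_width)
      if (ring > nring) next
      num[ring + 1L] <- num[ring + 1L] + Re(f1[i, j] * Conj(f2[i, j]))
      p1[ring + 1L] <- p1[ring + 1L] + Mod(f1[i, j])^2
      p2[ring + 1L] <- p2[ring + 1L] + Mod(f2[i, j])^2
    }
  }
  num / sqrt(p1 * p2)
}

# --- structural SSIM of one full window by direct covariance sums ---
oracle_ssim_window <- function(x, y, c3 = 0) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * cxy + 2 * c3) / (vx + vy + 2 * c3)
}

# --- convex hull by plane enumeration (O(n^4); tiny inputs only) ---
oracle_hull_planes <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  eps <- 1e-9 * max(1, max(pts) - min(pts))
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- pts[j, ] - pts[i, ]; v <- pts[k, ] - pts[i, ]
    nn <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    nl <- sqrt(sum(nn^2))
    if (nl < eps) next
    nn <- nn / nl
    d <- as.vector(pts %*% nn) - sum(nn * pts[i, ])
    if (all(d <= eps)) planes[[length(planes) + 1L]] <-
        c(nn, sum(nn * pts[i, ]))
    else if (all(d >= -eps)) planes[[length(planes) + 1L]] <-
        c(-nn, -sum(nn * pts[i, ]))
  }
  pl <- unique(t(vapply(planes, function(p) round(p, 7), numeric(4))))
  list(normals = pl[, 1:3, drop = FALSE], offsets = pl[, 4], pts = pts)
}

oracle_hull_volume <- function(pts) {
  h <- oracle_hull_planes(pts)
  c0 <- colMeans(h$pts)
  eps <- 1e-6 * max(1, max(h$pts) - min(h$pts))
  vol <- 0
  for (k in seq_len(nrow(h$normals))) {
    nn <- h$normals[k, ]; b <- h$offsets[k]
    on_plane <- abs(as.vector(h$pts %*% nn) - b) < eps
    facet <- h$pts[on_plane, , drop = FALSE]
    if (nrow(facet) < 3L) next
    # project onto the plane, 2D hull, shoelace area
    basis1 <- facet[2, ] - facet[1, ]
    basis1 <- basis1 / sqrt(sum(basis1^2))
    basis2 <- c(nn[2] * basis1[3] - nn[3] * basis1[2],
                nn[3] * basis1[1] - nn[1] * basis1[3],
                nn[1] * basis1[2] - nn[2] * basis1[1])
    uv <- cbind(as.vector(sweep(facet, 2, facet[1, ]) %*% basis1),
                as.vector(sweep(facet, 2, facet[1, ]) %*% basis2))
    ch <- grDevices::chull(uv)
    poly <- uv[ch, , drop = FALSE]
    m <- nrow(poly)
    area <- abs(sum(poly[, 1] * poly[c(2:m, 1), 2] -
                      poly[c(2:m, 1), 1] * poly[, 2])) / 2
    vol <- vol + area * (b - sum(nn * c0)) / 3
  }
  vol
}

# solidity with the same rasterized-hull convention, but hull membership
# decided by the enumerated supporting planes
oracle_solidity <- function(coords) {
  h <- oracle_hull_planes(coords)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  grid <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  eps <- 1e-7 * max(1, max(abs(h$offsets)))
  inside <- rep(TRUE, nrow(grid))
  for (k in seq_len(nrow(h$normals)))
    inside <- inside & (as.vector(grid %*% h$normals[k, ]) <=
                          h$offsets[k] + eps)
  nrow(coords) / sum(inside)
}

# --- circular autocorrelation by explicit modular indexing ---
oracle_circular_autocorr <- function(x, k) {
  n <- length(x)
  idx <- ((seq_len(n) - 1 + k) %% n) + 1
  stats::cor(x, x[idx])
}

# --- digital shape builders (voxel index matrices) ---
digital_ball <- function(r, spacing = c(1, 1, 1)) {
  ext <- ceiling(r / spacing)
  g <- as.matrix(expand.grid(z = -ext[1]:ext[1], y = -ext[2]:ext[2],
                             x = -ext[3]:ext[3]))
  keep <- rowSums(sweep(g, 2, spacing, `*`)^2) <= r^2
  sweep(g[keep, , drop = FALSE], 2, ext + 1L, `+`)
}

digital_ellipsoid <- function(semi_axes_zyx, angle_xy = 0,
                              spacing = c(1, 1, 1)) {
  # ellipsoid with given semi-axes, optionally rotated in the xy plane
  ext <- ceiling(max(semi_axes_zyx) / spacing) + 1L
  g <- as.matrix(expand.grid(z = -ext[1]:ext[1], y = -ext[2]:ext[2],
                             x = -ext[3]:ext[3]))
  phys <- sweep(g, 2, spacing, `*`)
  ca <- cos(angle_xy); sa <- sin(angle_xy)
  xr <- ca * phys[, 3] + sa * phys[, 2]
  yr <- -sa * phys[, 3] + ca * phys[, 2]
  inside <- (phys[, 1] / semi_axes_zyx[1])^2 +
    (yr / semi_axes_zyx[2])^2 + (xr / semi_axes_zyx[3])^2 <= 1
  sweep(g[inside, , drop = FALSE], 2, ext + 1L, `+`)
}

digital_cuboid <- function(nz, ny, nx) {
  as.matrix(expand.grid(z = seq_len(nz), y = seq_len(ny),
                        x = seq_len(nx)))
}

digital_plus <- function() {
  unique(rbind(as.matrix(expand.grid(z = 4:5, y = 4:5, x = 1:9)),
               as.matrix(expand.grid(z = 4:5, y = 1:9, x = 4:5))))
}

# wrap angle difference into [-pi, pi)
wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi
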