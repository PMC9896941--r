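# Shape quantifiers in 3D physical units.
#
# Elongation: sqrt(lambda_max / lambda_min) of the second-moment
# (covariance) tensor of voxel coordinates in nm, i.e. the major/minor
# principal-axis ratio; 1 for a sphere, rotation-invariant by construction.
# Each voxel contributes its own box moment (edge^2 / 12 per axis), which
# removes most of the discretization bias for small regions.
#
# Solidity: region volume / volume of the rasterized 3D convex hull, i.e.
# the count of voxels whose centers fall inside the convex hull of the
# region's voxel centers (the regionprops convention); 1 for convex
# shapes, exactly 1 for a filled cuboid. The hull is an own incremental
# quickhull (no qhull binding is assumed installed).

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Volume of the 3D convex hull of a point set
#'
#' Incremental quickhull; errors on degenerate (collinear or coplanar)
#' input naming the degeneracy.
#'
#' @param pts numeric matrix, one point per row, 3 columns.
#' @return hull volume (in the cube of the coordinate unit).
#' @export
convex_hull_volume <- function(pts) {
  convex_hull_3d(pts)$volume
}

# Full quickhull: returns volume plus outward facet planes (unit normals N
# and offsets b such that interior points satisfy N x <= b).
convex_hull_3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (is.null(n) || n < 4L || ncol(pts) != 3L)
    stopf("degenerate hull: need >= 4 distinct 3D points, got %s", n)
  eps <- 1e-9 * max(1, max(pts) - min(pts))

  i1 <- which.min(pts[, 1L])
  d2 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d2)
  if (sqrt(d2[i2]) < eps) stopf("degenerate hull: all points coincide")
  u <- pts[i2, ] - pts[i1, ]
  w <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(u[2L] * w[, 3L] - u[3L] * w[, 2L],
              u[3L] * w[, 1L] - u[1L] * w[, 3L],
              u[1L] * w[, 2L] - u[2L] * w[, 1L])
  a2 <- rowSums(cr^2)
  i3 <- which.max(a2)
  if (sqrt(a2[i3]) < eps * sqrt(sum(u^2)))
    stopf("degenerate hull: points are collinear")
  nrm <- cross3(u, pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dd <- abs(as.vector(w %*% nrm))
  i4 <- which.max(dd)
  if (dd[i4] < eps) stopf("degenerate hull: points are coplanar")

  c0 <- colMeans(pts[c(i1, i2, i3, i4), ])
  make_face <- function(a, b, c_) {
    nn <- cross3(pts[b, ] - pts[a, ], pts[c_, ] - pts[a, ])
    nn <- nn / sqrt(sum(nn^2))
    off <- sum(nn * pts[a, ])
    if (sum(nn * c0) > off) { nn <- -nn; off <- -off; tmp <- b; b <- c_
                              c_ <- tmp }
    list(v = c(a, b, c_), n = nn, off = off, outside = integer(),
         alive = TRUE)
  }
  assign_outside <- function(face, cand) {
    if (length(cand) == 0L) return(face)
    dist <- as.vector(pts[cand, , drop = FALSE] %*% face$n) - face$off
    face$outside <- cand[dist > eps]
    face
  }
  faces <- list(make_face(i1, i2, i3), make_face(i1, i2, i4),
                make_face(i1, i3, i4), make_face(i2, i3, i4))
  all_idx <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  claimed <- integer()
  for (fi in seq_along(faces)) {
    faces[[fi]] <- assign_outside(faces[[fi]], setdiff(all_idx, claimed))
    claimed <- c(claimed, faces[[fi]]$outside)
  }

  repeat {
    fi <- which(vapply(faces, function(f)
      f$alive && length(f$outside) > 0L, TRUE))
    if (length(fi) == 0L) break
    fi <- fi[1L]
    f <- faces[[fi]]
    dist <- as.vector(pts[f$outside, , drop = FALSE] %*% f$n) - f$off
    p <- f$outside[which.max(dist)]
    visible <- which(vapply(faces, function(g)
      g$alive && sum(g$n * pts[p, ]) - g$off > eps, TRUE))
    # horizon: undirected edges of visible faces that appear exactly once
    edges <- do.call(rbind, lapply(visible, function(vi) {
      v <- faces[[vi]]$v
      rbind(v[c(1L, 2L)], v[c(2L, 3L)], v[c(3L, 1L)])
    }))
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), ,
                     drop = FALSE]
    pool <- setdiff(unique(unlist(lapply(faces[visible],
                                         `[[`, "outside"))), p)
    for (vi in visible) faces[[vi]]$alive <- FALSE
    for (ei in seq_len(nrow(horizon))) {
      nf <- make_face(horizon[ei, 1L], horizon[ei, 2L], p)
      nf <- assign_outside(nf, pool)
      pool <- setdiff(pool, nf$outside)
      faces[[length(faces) + 1L]] <- nf
    }
  }

  vol <- 0
  alive <- Filter(function(f) f$alive, faces)
  for (f in alive) {
    a <- pts[f$v[1L], ]; b <- pts[f$v[2L], ]; c_ <- pts[f$v[3L], ]
    area <- sqrt(sum(cross3(b - a, c_ - a)^2)) / 2
    vol <- vol + area * (f$off - sum(f$n * c0)) / 3
  }
  list(volume = vol,
       normals = do.call(rbind, lapply(alive, `[[`, "n")),
       offsets = vapply(alive, `[[`, 0, "off"))
}

#' Elongation of a voxel region
#'
#' Principal-axis ratio sqrt(lambda_max / lambda_min) of the physical-unit
#' covariance of voxel coordinates, with per-voxel box moments added
#' (edge^2/12 per axis). Coplanar/collinear regions are computed on the
#' non-degenerate subspace and flagged via the `"degenerate"` attribute.
#'
#' @param coords integer matrix of voxel indices (z, y, x), one per row.
#' @param voxel_size_nm numeric c(z, y, x) voxel edges in nm.
#' @return elongation >= 1, with attribute `degenerate` (logical).
#' @export
elongation <- function(coords, voxel_size_nm) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4L) stopf("region must have >= 4 voxels")
  stopifnot(ncol(coords) == 3L, length(voxel_size_nm) == 3L)
  phys <- sweep(coords, 2L, as.numeric(voxel_size_nm), `*`)
  cc <- sweep(phys, 2L, colMeans(phys))
  cv <- crossprod(cc) / nrow(cc)
  rank_eps <- 1e-9 * max(diag(cv), 1)
  rank <- sum(eigen(cv, symmetric = TRUE, only.values = TRUE)$values >
                rank_eps)
  cv_corr <- cv + diag(as.numeric(voxel_size_nm)^2 / 12)
  ev <- eigen(cv_corr, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- rank < 3L
  k <- max(rank, 2L)
  val <- sqrt(ev[1L] / ev[k])
  structure(max(1, val), degenerate = degenerate)
}

#' Solidity of a voxel region
#'
#' Region voxel count divided by the number of voxels whose centers lie
#' inside the convex hull of the region's voxel centers (rasterized hull,
#' the regionprops convention). 1 for convex regions; exactly 1 for a
#' filled cuboid. The voxel aspect ratio cancels, so anisotropic voxels
#' need no special handling.
#'
#' @inheritParams elongation
#' @export
solidity <- function(coords, voxel_size_nm = c(1, 1, 1)) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4L) stopf("region must have >= 4 voxels")
  vs <- as.numeric(voxel_size_nm)
  # hull from boundary voxels only (interior voxels carry no hull vertex)
  bnd <- boundary_voxels(coords)
  phys <- sweep(bnd, 2L, vs, `*`)
  hull <- convex_hull_3d(phys)
  nrow(coords) / count_voxels_in_hull(coords, vs, hull)
}

count_voxels_in_hull <- function(coords, vs, hull) {
  lo <- apply(coords, 2L, min); hi <- apply(coords, 2L, max)
  grid <- as.matrix(expand.grid(lo[1L]:hi[1L], lo[2L]:hi[2L],
                                lo[3L]:hi[3L]))
  gphys <- sweep(grid, 2L, vs, `*`)
  eps <- 1e-7 * max(abs(hull$offsets), 1)
  inside <- rep(TRUE, nrow(grid))
  for (k in seq_len(nrow(hull$normals))) {
    inside <- inside &
      (gphys %*% hull$normals[k, ] <= hull$offsets[k] + eps)
    if (!any(inside)) break
  }
  sum(inside)
}

# 6-neighbor interior of a voxel set (one erosion step)
interior_voxels <- function(coords) {
  coords[!boundary_flags(coords), , drop = FALSE]
}

# voxels with at least one missing 6-neighbor
boundary_voxels <- function(coords) {
  coords[boundary_flags(coords), , drop = FALSE]
}

boundary_flags <- function(coords) {
  lo <- apply(coords, 2L, min) - 1L
  d <- apply(coords, 2L, max) - lo + 1L
  occ <- array(FALSE, dim = d)
  sh <- sweep(coords, 2L, lo)
  occ[sh] <- TRUE
  get <- function(dz, dy, dx) {
    s2 <- sweep(sh, 2L, c(dz, dy, dx), `+`)
    ok <- s2[, 1L] >= 1L & s2[, 1L] <= d[1L] &
      s2[, 2L] >= 1L & s2[, 2L] <= d[2L] &
      s2[, 3L] >= 1L & s2[, 3L] <= d[3L]
    res <- rep(FALSE, nrow(sh))
    res[ok] <- occ[s2[ok, , drop = FALSE]]
    res
  }
  interior <- get(1, 0, 0) & get(-1, 0, 0) & get(0, 1, 0) &
    get(0, -1, 0) & get(0, 0, 1) & get(0, 0, -1)
  !interior
}
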