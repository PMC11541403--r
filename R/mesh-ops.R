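# Geometric operators built on the Rcpp kernel: signed distance, implicit
# (signed-distance-field) offsets and booleans with marching-tetrahedra
# extraction, targeted Laplacian smoothing, midpoint densification, and the
# measurement utilities (thickness ray casting, Hausdorff distance).
#
# Offsets and booleans deliberately go through a resampled distance field
# rather than per-vertex displacement: the result is watertight by
# construction, also on concave regions, at the cost of resampling accuracy
# (controlled by `resolution`, in mm).

#' Signed distance from a watertight mesh
#'
#' Negative inside, positive outside; magnitude is the distance to the
#' closest surface point. The sign comes from the angle-weighted
#' pseudonormal of the closest feature, which is exact for watertight
#' meshes; a query lying exactly on the surface reports a non-negative sign.
#'
#' @param mesh a watertight TriangleMesh
#' @param points numeric \code{k x 3} matrix (mm)
#' @return numeric vector of signed distances (mm)
#' @export
signedDistance <- function(mesh, points) {
  if (!isWatertight(mesh)) stop("signedDistance requires a watertight mesh")
  points <- asPointMatrix(points)
  q <- meshQuery(mesh)
  res <- cpp_closest(q, points)
  res$distance * res$sign
}

asPointMatrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

# Side-signed distance from an open sheet: positive on the +normal side.
# Queries whose closest feature is on the open rim carry boundary = TRUE.
sheetDistance <- function(mesh, points, query = NULL) {
  points <- asPointMatrix(points)
  q <- if (is.null(query)) meshQuery(mesh) else query
  res <- cpp_closest(q, points)
  list(s = res$distance * res$sign, d = res$distance, boundary = res$boundary,
       point = res$point, normal = res$normal, tri = res$tri)
}

# ---- regular grids and isosurface extraction ------------------------------

# A grid specification over [lo, hi] padded by `pad`, with an irrational
# origin shift so grid nodes do not coincide with mesh vertices or axis
# planes (which would put field samples exactly on the surface).
gridSpec <- function(lo, hi, spacing, pad = NULL) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (is.null(pad)) pad <- 3 * max(spacing)
  origin <- lo - pad - spacing * 0.2371023
  dims <- as.integer(ceiling((hi + pad - origin) / spacing)) + 2L
  nTotal <- prod(as.numeric(dims))
  if (nTotal > 6e7) stop(sprintf("grid too large (%g nodes); increase resolution", nTotal))
  list(origin = origin, spacing = spacing, dims = dims)
}

gridFromMeshes <- function(meshes, spacing, pad = NULL) {
  vs <- do.call(rbind, lapply(meshes, meshVertices))
  gridSpec(apply(vs, 2, min), apply(vs, 2, max), spacing, pad)
}

# Field of a mesh on a grid. Returns list(field, boundary).
gridField <- function(mesh, grid, query = NULL) {
  q <- if (is.null(query)) meshQuery(mesh) else query
  cpp_grid_field(q, grid$origin, grid$spacing, grid$dims)
}

# Grid node coordinates as an n x 3 matrix (x fastest), for analytic fields.
gridCoords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3]
  cbind(rep(xs, times = length(ys) * length(zs)),
        rep(rep(ys, each = length(xs)), times = length(zs)),
        rep(zs, each = length(xs) * length(ys)))
}

# Isosurface of a scalar field at 0 by marching tetrahedra. The outermost
# node layer is clamped outside so any solid is closed by the grid border.
extractIso <- function(field, grid) {
  big <- sum(grid$spacing * grid$dims) + 1
  field[!is.finite(field)] <- big
  dims <- grid$dims
  arr <- array(field, dim = dims)
  h <- max(grid$spacing)
  arr[c(1, dims[1]), , ] <- pmax(arr[c(1, dims[1]), , ], h)
  arr[, c(1, dims[2]), ] <- pmax(arr[, c(1, dims[2]), ], h)
  arr[, , c(1, dims[3])] <- pmax(arr[, , c(1, dims[3])], h)
  arr[arr == 0] <- 1e-12
  res <- cpp_marching_tets(as.vector(arr), dims, grid$origin, grid$spacing, 0)
  if (nrow(res$faces) == 0) return(TriangleMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  m <- cleanMesh(TriangleMesh(res$vertices, res$faces), tol = 1e-9)
  if (meshVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2), drop = FALSE]
  m
}

# ---- offsets / solidify ----------------------------------------------------

#' Solidify an open surface into a watertight shell of given thickness
#'
#' The shell is the set of points between the surface and its offset at
#' \code{thickness} on the chosen side, bounded at the open rim by the
#' surface's boundary normals (no rounded bead is added beyond the rim). The
#' outer sheet coincides with the input surface; implemented by
#' signed-distance resampling and isosurface extraction so the result is
#' watertight also on concave regions.
#'
#' @param surface an open TriangleMesh (manifold with boundary); normals
#'   define the "outward" side
#' @param thickness wall thickness in mm, > 0
#' @param side \code{"inward"} (against the normals, the default) or
#'   \code{"outward"}
#' @param resolution sampling pitch in mm; defaults to \code{thickness / 12}
#'   capped at 0.6 mm
#' @return a watertight TriangleMesh
#' @export
solidifyShell <- function(surface, thickness, side = c("inward", "outward"),
                          resolution = NULL) {
  side <- match.arg(side)
  if (!is.numeric(thickness) || thickness <= 0) stop("thickness must be positive")
  if (nFaces(surface) == 0) stop("cannot solidify an empty mesh")
  if (is.null(resolution)) resolution <- min(thickness / 12, 0.6)
  grid <- gridFromMeshes(list(surface), resolution, pad = thickness + 3 * resolution)
  fl <- gridField(surface, grid)
  s <- fl$field
  d <- abs(s)
  F <- if (side == "inward") pmax(s, -thickness - s) else pmax(-s, s - thickness)
  F[fl$boundary] <- pmax(F[fl$boundary], d[fl$boundary], resolution * 1e-3)
  out <- extractIso(F, grid)
  if (nFaces(out) == 0) stop("solidify produced an empty result")
  if (!isWatertight(out)) stop("solidify produced a non-watertight result")
  out
}

# ---- booleans --------------------------------------------------------------

#' Boolean difference of two watertight solids
#'
#' Computes closure(a minus b) by combining signed-distance fields
#' (\code{max(d_a, -d_b)}) on a regular grid and extracting the zero
#' isosurface. Sharp features are chamfered at the sampling pitch.
#'
#' @param a,b watertight TriangleMesh solids
#' @param resolution grid pitch in mm; default scales with the bounding box
#'   of \code{a} (diagonal / 200)
#' @return a watertight TriangleMesh (possibly empty when \code{b} covers
#'   \code{a})
#' @export
booleanSubtract <- function(a, b, resolution = NULL) {
  for (m in list(a, b)) if (!isWatertight(m)) stop("boolean operands must be watertight")
  bb <- apply(a@vertices, 2, range)
  if (is.null(resolution)) resolution <- sqrt(sum((bb[2, ] - bb[1, ])^2)) / 200
  grid <- gridSpec(bb[1, ], bb[2, ], resolution)
  fa <- gridField(a, grid)$field
  fb <- gridField(b, grid)$field
  out <- extractIso(pmax(fa, -fb), grid)
  if (nFaces(out) > 0 && !isWatertight(out)) stop("boolean produced a non-watertight result")
  out
}

#' Boolean intersection volume fraction helper (a inside b)
#' @keywords internal
booleanIntersect <- function(a, b, resolution = NULL) {
  for (m in list(a, b)) if (!isWatertight(m)) stop("boolean operands must be watertight")
  bb <- apply(a@vertices, 2, range)
  if (is.null(resolution)) resolution <- sqrt(sum((bb[2, ] - bb[1, ])^2)) / 200
  grid <- gridSpec(bb[1, ], bb[2, ], resolution)
  fa <- gridField(a, grid)$field
  fb <- gridField(b, grid)$field
  extractIso(pmax(fa, fb), grid)
}

# ---- smoothing -------------------------------------------------------------

#' Laplacian smoothing restricted to a vertex region
#'
#' Umbrella-operator smoothing in which only the region's interior vertices
#' move; vertices on the region border (or on the mesh boundary) stay fixed,
#' so the smoothed patch blends continuously into its surroundings. A planar
#' region is a fixed point.
#'
#' @param mesh a TriangleMesh
#' @param region a RegionMask on the mesh's topology
#' @param iterations non-negative iteration count
#' @param strength step size in (0, 1]
#' @return the smoothed TriangleMesh
#' @export
regionSmooth <- function(mesh, region, iterations = 10, strength = 0.5) {
  if (iterations < 0) stop("iterations must be >= 0")
  stopifnot(is(region, "RegionMask"))
  flags <- region@flags
  if (length(flags) != nVertices(mesh)) stop("region mask does not match mesh topology")
  if (iterations == 0 || !any(flags)) return(mesh)
  f <- mesh@faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  n <- nVertices(mesh)
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(n, n))
  A <- methods::as(A > 0, "dMatrix") * 1
  deg <- Matrix::rowSums(A)
  # region interior: all neighbours inside the region, and not on the mesh boundary
  inRegion <- as.vector(A %*% as.numeric(flags)) >= deg - 1e-9
  movable <- flags & inRegion & deg > 0
  bl <- boundaryLoops(mesh)
  movable[bl$vertices] <- FALSE
  if (!any(movable)) return(mesh)
  v <- mesh@vertices
  for (i in seq_len(iterations)) {
    avg <- as.matrix(A %*% v) / deg
    v[movable, ] <- (1 - strength) * v[movable, , drop = FALSE] +
      strength * avg[movable, , drop = FALSE]
  }
  TriangleMesh(v, f, mesh@vertexLabels)
}

# ---- densification ---------------------------------------------------------

#' Densify a mesh to a target edge length
#'
#' Midpoint 1-to-4 subdivision (geometry-preserving: the surface is
#' unchanged, so the Hausdorff distance to the input is zero) repeated until
#' at least 95 percent of edges are no longer than the target. A mesh whose
#' edges already satisfy the target is returned unchanged.
#'
#' @param mesh a TriangleMesh
#' @param targetEdgeLength mm, > 0
#' @return the densified TriangleMesh
#' @export
densifyMesh <- function(mesh, targetEdgeLength) {
  if (!is.numeric(targetEdgeLength) || targetEdgeLength <= 0)
    stop("targetEdgeLength must be positive")
  for (round in 1:8) {
    el <- edgeLengths(mesh)
    if (length(el) == 0 || max(el) <= targetEdgeLength) return(mesh)
    if (mean(el > targetEdgeLength) <= 0.05) return(mesh)
    mesh <- subdivideMidpoint(mesh)
  }
  mesh
}

edgeLengths <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- ed[!duplicated(key), , drop = FALSE]
  sqrt(rowSums((v[ed[, 1], , drop = FALSE] - v[ed[, 2], , drop = FALSE])^2))
}

# ---- measurements ----------------------------------------------------------

#' Sampled two-sided Hausdorff distance between surfaces (mm)
#'
#' Deterministic sampling: vertices, face centroids and edge midpoints of
#' each mesh against the exact closest point on the other.
#'
#' @param a,b TriangleMesh objects
#' @return the larger of the two directed sampled Hausdorff distances
#' @export
hausdorffDistance <- function(a, b) {
  sampleSet <- function(m) {
    v <- m@vertices; f <- m@faces
    rbind(v,
          (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3,
          (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE]) / 2)
  }
  qa <- meshQuery(a); qb <- meshQuery(b)
  dab <- max(cpp_closest(qb, sampleSet(a))$distance)
  dba <- max(cpp_closest(qa, sampleSet(b))$distance)
  max(dab, dba)
}

#' Random area-weighted surface samples
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param mesh a TriangleMesh
#' @param n number of samples
#' @return list with \code{points} (n x 3) and \code{normals} (n x 3)
#' @export
sampleSurfacePoints <- function(mesh, n) {
  ar <- faceAreas(mesh)
  fi <- sample.int(nFaces(mesh), n, replace = TRUE, prob = ar)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  v <- mesh@vertices; f <- mesh@faces
  p <- w[, 1] * v[f[fi, 1], , drop = FALSE] +
       w[, 2] * v[f[fi, 2], , drop = FALSE] +
       w[, 3] * v[f[fi, 3], , drop = FALSE]
  list(points = p, normals = faceNormals(mesh)[fi, , drop = FALSE], face = fi)
}

#' Median wall thickness by inward-normal ray casting
#'
#' Samples the surface (area-weighted), casts a ray from each sample along
#' the inward normal and records the distance to the first opposite surface
#' crossing. The median over samples is the reported thickness; an optional
#' predicate excludes samples (e.g. near the rim).
#'
#' @param mesh a watertight TriangleMesh
#' @param nSamples number of surface samples (>= 1000 recommended)
#' @param exclude optional function taking the sample point matrix and
#'   returning a logical exclusion vector
#' @return list with \code{median} (mm) and the per-sample \code{thickness}
#' @export
measureThickness <- function(mesh, nSamples = 2000, exclude = NULL) {
  sp <- sampleSurfacePoints(mesh, nSamples)
  keep <- rep(TRUE, nSamples)
  if (!is.null(exclude)) keep <- !exclude(sp$points)
  p <- sp$points[keep, , drop = FALSE]
  nrm <- sp$normals[keep, , drop = FALSE]
  q <- meshQuery(mesh)
  hit <- cpp_raycast(q, p, -nrm, 1e-4)
  th <- hit$t[is.finite(hit$t)]
  list(median = stats::median(th), thickness = th)
}

#' Root-mean-square distance from sample points to a surface (mm)
#' @param points k x 3 matrix
#' @param mesh target TriangleMesh
#' @export
rmsDistance <- function(points, mesh) {
  q <- meshQuery(mesh)
  sqrt(mean(cpp_closest(q, asPointMatrix(points))$distance^2))
}
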