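#' Construct a TriangleMesh
#'
#' @param vertices numeric \code{n x 3} matrix (mm)
#' @param faces integer \code{m x 3} matrix of 1-based vertex indices
#' @param vertexLabels optional integer vector of per-vertex tags
#' @return a validated \linkS4class{TriangleMesh}
#' @export
TriangleMesh <- function(vertices, faces, vertexLabels = integer(0)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) == 0) faces <- matrix(integer(0), 0, 3)
  if (nrow(vertices) == 0) vertices <- matrix(numeric(0), 0, 3)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriangleMesh", vertices = vertices, faces = faces,
      vertexLabels = as.integer(vertexLabels))
}

#' @rdname TriangleMesh-class
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname TriangleMesh-class
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname TriangleMesh-class
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @rdname TriangleMesh-class
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

#' @rdname TriangleMesh-class
#' @export
setMethod("vertexLabels", "TriangleMesh", function(x) x@vertexLabels)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces", nVertices(object), nFaces(object)))
  if (nFaces(object) > 0) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("\n  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
    cat(sprintf("\n  watertight: %s", isWatertight(object)))
  }
  cat("\n")
  invisible(object)
})

#' @rdname isWatertight
#' @export
setMethod("isWatertight", "TriangleMesh", function(x) {
  if (nFaces(x) == 0) return(FALSE)
  a <- cpp_edge_audit(x@faces, nVertices(x))
  a$n_boundary == 0 && a$n_nonmanifold == 0 && a$n_mismatched == 0
})

#' @rdname meshVolume
#' @export
setMethod("meshVolume", "TriangleMesh", function(x) {
  if (nFaces(x) == 0) return(0)
  v <- x@vertices; f <- x@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # divergence theorem: sum of signed tetra volumes against the origin
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
})

#' Clean a mesh
#'
#' Merges duplicate vertices (within \code{tol} mm), drops degenerate and
#' duplicate faces, and removes unreferenced vertices. Applied on every file
#' read.
#'
#' @param mesh a TriangleMesh
#' @param tol vertex merge tolerance in mm
#' @param dropUnreferenced drop vertices no face uses
#' @return a cleaned TriangleMesh
#' @export
cleanMesh <- function(mesh, tol = 1e-6, dropUnreferenced = TRUE) {
  v <- mesh@vertices
  f <- mesh@faces
  lab <- mesh@vertexLabels
  if (nrow(v) == 0) return(mesh)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])  # compact index of each vertex's representative
  v2 <- v[first, , drop = FALSE]
  lab2 <- if (length(lab)) lab[first] else integer(0)
  if (nrow(f) > 0) {
    f2 <- matrix(remap[f], ncol = 3)
    keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
    f2 <- f2[keep, , drop = FALSE]
    # zero-area faces (collinear vertices)
    if (nrow(f2) > 0) {
      e1 <- v2[f2[, 2], , drop = FALSE] - v2[f2[, 1], , drop = FALSE]
      e2 <- v2[f2[, 3], , drop = FALSE] - v2[f2[, 1], , drop = FALSE]
      cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
      cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
      cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
      area2 <- cx^2 + cy^2 + cz^2
      f2 <- f2[area2 > (tol * tol) * 1e-12, , drop = FALSE]
    }
    if (nrow(f2) > 1) {
      key <- paste(pmin(f2[, 1], pmin(f2[, 2], f2[, 3])),
                   f2[, 1] + f2[, 2] + f2[, 3],
                   pmax(f2[, 1], pmax(f2[, 2], f2[, 3])))
      f2 <- f2[!duplicated(key), , drop = FALSE]
    }
  } else {
    f2 <- f
  }
  if (dropUnreferenced && nrow(f2) > 0) {
    used <- sort(unique(as.vector(f2)))
    remap2 <- integer(nrow(v2))
    remap2[used] <- seq_along(used)
    v2 <- v2[used, , drop = FALSE]
    lab2 <- if (length(lab2)) lab2[used] else integer(0)
    f2 <- matrix(remap2[f2], ncol = 3)
  }
  TriangleMesh(v2, f2, lab2)
}

#' Per-face unit normals
#' @param mesh a TriangleMesh
#' @return numeric \code{m x 3} matrix
#' @export
faceNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Area-weighted per-vertex unit normals
#' @param mesh a TriangleMesh
#' @return numeric \code{n x 3} matrix
#' @export
vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  acc <- rowsum(rbind(n, n, n), group = c(f[, 1], f[, 2], f[, 3]))
  out <- matrix(0, nrow(v), 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  len[len == 0] <- 1
  out / len
}

#' Per-face areas (mm^2)
#' @param mesh a TriangleMesh
#' @export
faceAreas <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(n^2)) / 2
}

#' Boundary edges and loops of an open mesh
#'
#' @param mesh a TriangleMesh
#' @return list with \code{edges} (2-column matrix of vertex indices),
#'   \code{vertices} (indices on any boundary) and \code{nLoops}
#' @export
boundaryLoops <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0)
    return(list(edges = matrix(integer(0), 0, 2), vertices = integer(0), nLoops = 0L))
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1]
  bed <- ed[key %in% bkey, , drop = FALSE]
  bv <- sort(unique(as.vector(bed)))
  # count loops by walking successor edges
  nLoops <- 0L
  if (nrow(bed) > 0) {
    nxt <- split(seq_len(nrow(bed)), bed[, 1])
    visited <- rep(FALSE, nrow(bed))
    for (i in seq_len(nrow(bed))) {
      if (visited[i]) next
      nLoops <- nLoops + 1L
      j <- i
      repeat {
        visited[j] <- TRUE
        cand <- nxt[[as.character(bed[j, 2])]]
        cand <- cand[!visited[cand]]
        if (length(cand) == 0) break
        j <- cand[1]
      }
    }
  }
  list(edges = bed, vertices = bv, nLoops = nLoops)
}

# Internal: persistent BVH query structure for a mesh.
meshQuery <- function(mesh) {
  if (nFaces(mesh) == 0) stop("cannot build a query structure on an empty mesh")
  cpp_bvh_build(mesh@vertices, mesh@faces)
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "TriangleMesh"),
  function(transform, x) {
    v <- transformPoints(transform, x@vertices)
    TriangleMesh(v, x@faces, x@vertexLabels)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "LandmarkSet"),
  function(transform, x) {
    co <- transformPoints(transform, x@coords)
    rownames(co) <- rownames(x@coords)
    new("LandmarkSet", coords = co)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, x) transformPoints(transform, x))

transformPoints <- function(tr, pts) {
  sweep(pts %*% t(tr@rotation) * tr@scale, 2, tr@translation, "+")
}

#' Construct a LandmarkSet
#' @param coords named list of length-3 numeric vectors, or a \code{k x 3}
#'   matrix with rownames
#' @export
LandmarkSet <- function(coords) {
  if (is.list(coords)) {
    nm <- names(coords)
    coords <- do.call(rbind, lapply(coords, as.numeric))
    rownames(coords) <- nm
  }
  storage.mode(coords) <- "double"
  new("LandmarkSet", coords = as.matrix(coords))
}

#' Construct a RegionMask
#' @param flags logical vector (or integer vertex indices with \code{n} given)
#' @param n vertex count of the target topology, when \code{flags} is an
#'   index vector
#' @export
RegionMask <- function(flags, n = NULL) {
  if (!is.logical(flags)) {
    stopifnot(!is.null(n))
    idx <- as.integer(flags)
    flags <- rep(FALSE, n)
    flags[idx] <- TRUE
  }
  new("RegionMask", flags = flags)
}

setMethod("show", "MoldAssembly", function(object) {
  cat(sprintf("MoldAssembly: anterior %d faces, posterior %d faces, closure gap %.2f mm\n",
              nFaces(object@anteriorShell), nFaces(object@posteriorShell), object@closureGap))
  invisible(object)
})

setMethod("show", "MorphableModel", function(object) {
  cat(sprintf("MorphableModel: %d vertices, rank %d", length(object@mean) / 3,
              ncol(object@basis)))
  if (ncol(object@basis) > 0)
    cat(sprintf(", mode SD %.3f .. %.3f mm", object@modeSD[1], tail(object@modeSD, 1)))
  cat("\n")
  invisible(object)
})

# ---- analytic test/primitive surfaces -------------------------------------

#' Axis-aligned box mesh
#' @param lo,hi opposite corners (mm)
#' @return a watertight TriangleMesh (12 triangles)
#' @export
meshBox <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # corner ids follow bit order x,y,z (1-based)
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(1, 3, 4, 2),  # z = lo (normal -z)
    quad(5, 6, 8, 7),  # z = hi (+z)
    quad(1, 2, 6, 5),  # y = lo (-y)
    quad(3, 7, 8, 4),  # y = hi (+y)
    quad(1, 5, 7, 3),  # x = lo (-x)
    quad(2, 4, 8, 6))  # x = hi (+x)
  TriangleMesh(v, f)
}

#' Sphere mesh by icosahedron subdivision
#' @param radius mm
#' @param center length-3 numeric (mm)
#' @param subdivisions number of 1-to-4 refinement rounds (4 gives 5120 faces)
#' @export
meshSphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- TriangleMesh(v / sqrt(1 + phi^2), f)
  for (i in seq_len(subdivisions)) {
    m <- subdivideMidpoint(m)
    vv <- m@vertices
    m@vertices <- vv / sqrt(rowSums(vv^2))
  }
  vv <- m@vertices * radius
  TriangleMesh(sweep(vv, 2, center, "+"), m@faces)
}

#' Open hemisphere mesh (z >= 0 half of a sphere)
#' @param radius mm
#' @param center length-3 numeric (mm)
#' @param n angular resolution (rings and segments scale with n)
#' @return an open TriangleMesh whose boundary is the equator circle
#' @export
meshHemisphere <- function(radius = 20, center = c(0, 0, 0), n = 48) {
  # polar grid: rings of latitude from pole to equator
  nr <- max(4, round(n / 2))
  verts <- c(0, 0, radius)
  faces <- NULL
  ringStart <- integer(nr)
  ringLen <- integer(nr)
  for (i in seq_len(nr)) {
    th <- i / nr * pi / 2       # polar angle
    k <- max(6, round(n * sin(th)))
    ringStart[i] <- length(verts) / 3 + 1
    ringLen[i] <- k
    ang <- (seq_len(k) - 1) / k * 2 * pi
    verts <- c(verts, rbind(radius * sin(th) * cos(ang),
                            radius * sin(th) * sin(ang),
                            radius * cos(th)))
  }
  v <- matrix(verts, ncol = 3, byrow = TRUE)
  # stitch rings with triangles
  stitch <- function(sa, ka, sb, kb) {
    # connect ring a (inner) to ring b (outer)
    out <- NULL
    ia <- 0; ib <- 0
    while (ia < ka || ib < kb) {
      pa <- sa + (ia %% ka); pa2 <- sa + ((ia + 1) %% ka)
      pb <- sb + (ib %% kb); pb2 <- sb + ((ib + 1) %% kb)
      advanceA <- (ia + 1) / ka <= (ib + 1) / kb
      if (ia >= ka) advanceA <- FALSE
      if (ib >= kb) advanceA <- TRUE
      if (advanceA) {
        out <- rbind(out, c(pa, pb, pa2)); ia <- ia + 1
      } else {
        out <- rbind(out, c(pa, pb, pb2)); ib <- ib + 1
      }
    }
    out
  }
  # pole fan
  s1 <- ringStart[1]; k1 <- ringLen[1]
  for (j in seq_len(k1))
    faces <- rbind(faces, c(1, s1 + (j - 1), s1 + (j %% k1)))
  for (i in seq_len(nr - 1))
    faces <- rbind(faces, stitch(ringStart[i], ringLen[i], ringStart[i + 1], ringLen[i + 1]))
  TriangleMesh(sweep(v, 2, center, "+"), faces)
}

#' Closed cylinder mesh
#' @param p0 center of the base disk (mm)
#' @param axis direction of the cylinder axis (normalized internally)
#' @param radius mm
#' @param height mm, extent along axis from p0
#' @param n segments around the circumference
#' @export
meshCylinder <- function(p0, axis, radius, height, n = 48) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame
  up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- up - sum(up * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ang <- (seq_len(n) - 1) / n * 2 * pi
  ring <- outer(cos(ang), u) + outer(sin(ang), w)
  bot <- sweep(radius * ring, 2, p0, "+")
  top <- sweep(bot, 2, axis * height, "+")
  v <- rbind(p0, p0 + axis * height, bot, top)
  fb <- cbind(1, 2 + (seq_len(n) %% n) + 1, 2 + seq_len(n))          # base fan (normal -axis)
  ft <- cbind(2, 2 + n + seq_len(n), 2 + n + (seq_len(n) %% n) + 1)  # top fan (+axis)
  side <- NULL
  for (j in seq_len(n)) {
    j2 <- j %% n + 1
    a <- 2 + j; b <- 2 + j2; c_ <- 2 + n + j; d <- 2 + n + j2
    side <- rbind(side, c(a, b, d), c(a, d, c_))
  }
  TriangleMesh(v, rbind(fb, ft, side))
}

#' Flat rectangular plate mesh (open surface in the z = z0 plane)
#' @param xlim,ylim extents (mm)
#' @param z0 plane height (mm)
#' @param nx,ny grid resolution
#' @return an open TriangleMesh with normals along +z
#' @export
meshPlate <- function(xlim = c(-60, 60), ylim = c(-60, 60), z0 = 0, nx = 60, ny = 60) {
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  ys <- seq(ylim[1], ylim[2], length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  v <- cbind(g$x, g$y, z0)
  f <- gridFaces(nx, ny)
  TriangleMesh(v, f)
}

# Triangulation of an nx x ny vertex grid (x fastest), CCW seen from +z.
gridFaces <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1), ny - 1)
  iy <- rep(seq_len(ny - 1), each = nx - 1)
  a <- (iy - 1) * nx + ix
  b <- a + 1
  c_ <- a + nx
  d <- c_ + 1
  rbind(cbind(a, b, d), cbind(a, d, c_))
}

# One round of midpoint 1-to-4 subdivision (no smoothing).
subdivideMidpoint <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- unique(key)
  eidx <- match(key, uk)
  firsts <- match(uk, key)
  mid <- (v[ed[firsts, 1], , drop = FALSE] + v[ed[firsts, 2], , drop = FALSE]) / 2
  nv <- nrow(v)
  m12 <- nv + eidx[seq_len(nrow(f))]
  m23 <- nv + eidx[nrow(f) + seq_len(nrow(f))]
  m31 <- nv + eidx[2 * nrow(f) + seq_len(nrow(f))]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  lab <- mesh@vertexLabels
  lab2 <- if (length(lab)) c(lab, rep(0L, nrow(mid))) else integer(0)
  TriangleMesh(rbind(v, mid), f2, lab2)
}
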