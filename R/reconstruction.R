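# Reconstruction of the missing nose: erase the affected region from the
# face model, align the morphable model via landmarks, then iterate
# closest-point correspondences with a regularized (ridge) coefficient
# solve and a coupled rigid refinement. Cropping the fitted face to the
# nasal region yields the nose model (NM).

#' Construct a FitConfig
#' @param maxIterations iteration cap
#' @param corrMaxDistance mm, correspondence rejection distance
#' @param corrMaxNormalAngle degrees, correspondence rejection normal angle
#' @param regularizationWeight ridge penalty on standardized coefficients
#' @param coeffBound coefficient clip in SD units
#' @param convergenceTol mm, RMS-change stopping tolerance
#' @param withScale estimate a uniform scale during alignment updates
#' @export
fitConfig <- function(maxIterations = 50, corrMaxDistance = 5, corrMaxNormalAngle = 60,
                      regularizationWeight = 0.1, coeffBound = 3, convergenceTol = 0.01,
                      withScale = FALSE) {
  new("FitConfig", maxIterations = as.integer(maxIterations),
      corrMaxDistance = corrMaxDistance, corrMaxNormalAngle = corrMaxNormalAngle,
      regularizationWeight = regularizationWeight, coeffBound = coeffBound,
      convergenceTol = convergenceTol, withScale = withScale)
}

#' Erase a masked region from a face model
#'
#' Removes the flagged vertices and every face incident to them, preventing
#' the affected geometry from influencing the later morphing. Unflagged
#' vertices are all retained (the output vertex count is the input count
#' minus the masked count); the remainder is a manifold mesh with boundary.
#'
#' @param fm a TriangleMesh
#' @param defect a RegionMask on fm's topology
#' @return the defect-masked TriangleMesh
#' @export
eraseRegion <- function(fm, defect) {
  stopifnot(is(defect, "RegionMask"))
  flags <- defect@flags
  if (length(flags) != nVertices(fm)) stop("defect mask does not match the mesh topology")
  if (!any(flags)) return(fm)
  if (all(flags)) stop("defect mask removes every vertex")
  keep <- !flags
  remap <- integer(length(keep))
  remap[keep] <- seq_len(sum(keep))
  f <- fm@faces
  fkeep <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  f2 <- matrix(remap[f[fkeep, , drop = FALSE]], ncol = 3)
  lab <- fm@vertexLabels
  TriangleMesh(fm@vertices[keep, , drop = FALSE], f2,
               if (length(lab)) lab[keep] else integer(0))
}

#' Rigid landmark alignment
#'
#' Least-squares rigid (optionally similarity) transform mapping the model
#' landmarks onto the scan landmarks, by the closed-form orthogonal
#' Procrustes solution. Requires at least three shared, non-collinear
#' landmark names.
#'
#' @param modelLandmarks,fmLandmarks LandmarkSet objects sharing names
#' @param withScale estimate a uniform scale factor
#' @return a \linkS4class{RigidTransform}
#' @export
rigidAlign <- function(modelLandmarks, fmLandmarks, withScale = FALSE) {
  a <- modelLandmarks@coords; b <- fmLandmarks@coords
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3) stop("at least 3 shared landmark names are required")
  X <- a[shared, , drop = FALSE]
  Y <- b[shared, , drop = FALSE]
  sv <- svd(sweep(X, 2, colMeans(X)))
  if (sv$d[2] < max(sv$d[1] * 1e-8, 1e-12)) stop("landmarks are collinear")
  tr <- kabsch(X, Y, withScale = withScale)
  new("RigidTransform", rotation = tr$R, translation = tr$t, scale = tr$s)
}

#' Fit a morphable model to a defect-masked scan
#'
#' Iterates: (a) for every model vertex, find the closest point on the
#' scan; reject pairs farther than \code{corrMaxDistance}, with normals
#' disagreeing by more than \code{corrMaxNormalAngle}, or whose closest
#' point lies on an open boundary (the defect rim or the scan border);
#' (b) solve the ridge-regularized least squares in standardized
#' coefficient space and clip to \code{coeffBound} SD; (c) refine the rigid
#' transform on the accepted pairs. Stops when the correspondence RMS
#' changes by less than \code{convergenceTol} or at \code{maxIterations}.
#'
#' @param model a MorphableModel
#' @param fmPartial the defect-masked scan (TriangleMesh)
#' @param config a \linkS4class{FitConfig}
#' @param init rigid initialization, usually from \code{\link{rigidAlign}}
#' @param excludeRegion optional RegionMask on the reference topology:
#'   model vertices in the region to be reconstructed (e.g. the nose) take
#'   no part in the correspondence search, so the erased area cannot drag
#'   the fit toward the surrounding skin
#' @return a \linkS4class{FitResult}
#' @export
fitModel <- function(model, fmPartial, config = fitConfig(), init = new("RigidTransform"),
                     excludeRegion = NULL) {
  if (nFaces(fmPartial) == 0) stop("scan mesh is empty")
  validObject(config)
  r <- modelRank(model)
  mu <- model@mean
  W <- sweep(model@basis, 2, model@modeSD, "*")
  faces <- model@faces
  scanQ <- meshQuery(fmPartial)
  nModelV <- length(mu) / 3
  usable <- rep(TRUE, nModelV)
  if (!is.null(excludeRegion)) {
    if (length(excludeRegion@flags) != nModelV)
      stop("excludeRegion does not match the model topology")
    usable[excludeRegion@flags] <- FALSE
  }
  # open rims of the scan (defect boundary and outer border), for the
  # boundary-band correspondence rejection
  scanBnd <- fmPartial@vertices[boundaryLoops(fmPartial)$vertices, , drop = FALSE]
  bndBand <- 1.5  # mm
  nearBoundary <- function(pts) {
    if (nrow(scanBnd) == 0) return(rep(FALSE, nrow(pts)))
    d2 <- outer(rowSums(pts^2), rowSums(scanBnd^2), "+") - 2 * pts %*% t(scanBnd)
    sqrt(pmax(apply(d2, 1, min), 0)) < bndBand
  }
  R <- init@rotation; tt <- init@translation; sc <- init@scale
  coeffs <- rep(0, r)
  cosTol <- cos(config@corrMaxNormalAngle * pi / 180)
  trace <- numeric(0)
  lambda <- config@regularizationWeight
  for (iter in seq_len(config@maxIterations)) {
    x <- mu + if (r > 0) as.vector(W %*% coeffs) else 0
    Vm <- matrix(x, ncol = 3, byrow = TRUE)
    Vw <- sweep(Vm %*% t(R) * sc, 2, tt, "+")
    cl <- cpp_closest(scanQ, Vw)
    nrm <- vertexNormals(unflattenMesh(x, faces)) %*% t(R)
    agree <- rowSums(nrm * cl$normal)
    sel <- which(usable & cl$distance <= config@corrMaxDistance & !cl$boundary &
                   agree >= cosTol)
    sel <- sel[!nearBoundary(cl$point[sel, , drop = FALSE])]
    if (length(sel) < max(10, r)) {
      if (iter == 1) stop("no valid correspondences; check the landmark alignment")
      break
    }
    Y <- cl$point[sel, , drop = FALSE]
    # targets mapped into model space (R orthonormal: residuals are isometric)
    Ym <- sweep(Y, 2, tt) %*% R / sc
    rows <- as.vector(t(outer(3 * (sel - 1), 1:3, "+")))
    if (r > 0) {
      A <- W[rows, , drop = FALSE]
      b <- as.vector(t(Ym)) - mu[rows]
      if (iter > 3) {
        # point-to-plane refinement: penalize displacement along the target
        # normal only, removing the tangential-sliding bias of the
        # point-to-point warmup
        Nm <- cl$normal[sel, , drop = FALSE] %*% R
        m <- length(sel)
        i3 <- 3 * (seq_len(m) - 1)
        App <- Nm[, 1] * A[i3 + 1, , drop = FALSE] +
               Nm[, 2] * A[i3 + 2, , drop = FALSE] +
               Nm[, 3] * A[i3 + 3, , drop = FALSE]
        bpp <- Nm[, 1] * b[i3 + 1] + Nm[, 2] * b[i3 + 2] + Nm[, 3] * b[i3 + 3]
        coeffs <- solve(crossprod(App) + diag(lambda, r), crossprod(App, bpp))
      } else {
        coeffs <- solve(crossprod(A) + diag(lambda, r), crossprod(A, b))
      }
      coeffs <- pmin(pmax(as.vector(coeffs), -config@coeffBound), config@coeffBound)
    }
    x <- mu + if (r > 0) as.vector(W %*% coeffs) else 0
    Vm <- matrix(x, ncol = 3, byrow = TRUE)
    # coupled rigid refinement on the accepted pairs
    tr <- kabsch(Vm[sel, , drop = FALSE], Y, withScale = config@withScale)
    R <- tr$R; tt <- tr$t; sc <- tr$s
    Vw <- sweep(Vm %*% t(R) * sc, 2, tt, "+")
    rms <- sqrt(mean(rowSums((Vw[sel, , drop = FALSE] - Y)^2)))
    trace <- c(trace, rms)
    if (length(trace) > 1 && abs(diff(tail(trace, 2))) < config@convergenceTol) break
  }
  fitted <- TriangleMesh(Vw, faces)
  new("FitResult", coefficients = as.numeric(coeffs), fittedMesh = fitted,
      residualTrace = trace,
      transform = new("RigidTransform", rotation = R, translation = tt, scale = sc))
}

#' Crop a fitted face to the nasal region
#'
#' Sub-mesh of the vertices flagged in the nose region (faces whose three
#' vertices are all flagged), preserving the open boundary. Because the
#' region is defined once on the reference topology, it transfers to any
#' fitted instance.
#'
#' @param fitted a TriangleMesh on the reference topology
#' @param noseRegion a RegionMask on the reference topology
#' @return the nose model (open TriangleMesh)
#' @export
cropNose <- function(fitted, noseRegion) {
  stopifnot(is(noseRegion, "RegionMask"))
  flags <- noseRegion@flags
  if (length(flags) != nVertices(fitted)) stop("nose region does not match the mesh topology")
  if (!any(flags)) stop("nose region is empty")
  remap <- integer(length(flags))
  remap[flags] <- seq_len(sum(flags))
  f <- fitted@faces
  fkeep <- flags[f[, 1]] & flags[f[, 2]] & flags[f[, 3]]
  f2 <- matrix(remap[f[fkeep, , drop = FALSE]], ncol = 3)
  lab <- fitted@vertexLabels
  TriangleMesh(fitted@vertices[flags, , drop = FALSE], f2,
               if (length(lab)) lab[flags] else integer(0))
}
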