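# The morphable face model: generalized-Procrustes alignment + PCA over a
# training population in vertex-wise correspondence, Gaussian-process
# flexibility augmentation via a low-rank (Nystrom) squared-exponential
# kernel, Gaussian posterior conditioning on point constraints, and
# standardized-coefficient sampling.
#
# Shapes are stacked as 3N vectors in vertex-major order (x1,y1,z1,x2,...).
# Coefficients are standardized: coefficient k multiplies modeSD[k] mm of
# deformation along basis column k.

#' Smooth deformation kernel specification
#'
#' Squared-exponential covariance for the deformation-field augmentation:
#' \code{variance * exp(-r^2 / (2 * lengthScale^2))}, applied independently
#' per coordinate axis. \code{approxRank} is the number of low-rank modes
#' appended to the model.
#'
#' @slot variance mm^2, >= 0 (0 disables the augmentation)
#' @slot lengthScale mm, > 0
#' @slot approxRank integer >= 1
#' @export
setClass("SmoothDeformationKernel",
  representation(variance = "numeric", lengthScale = "numeric", approxRank = "integer"),
  prototype(variance = 1, lengthScale = 30, approxRank = 50L))

setValidity("SmoothDeformationKernel", function(object) {
  if (object@variance < 0) return("variance must be >= 0")
  if (object@lengthScale <= 0) return("lengthScale must be positive")
  if (object@approxRank < 1) return("approxRank must be >= 1")
  TRUE
})

#' @rdname SmoothDeformationKernel-class
#' @param variance kernel variance in mm^2
#' @param lengthScale kernel length scale in mm
#' @param approxRank number of modes to append
#' @export
smoothDeformationKernel <- function(variance = 1, lengthScale = 30, approxRank = 50) {
  new("SmoothDeformationKernel", variance = variance, lengthScale = lengthScale,
      approxRank = as.integer(approxRank))
}

flattenMesh <- function(mesh) as.vector(t(mesh@vertices))
unflattenMesh <- function(x, faces) TriangleMesh(matrix(x, ncol = 3, byrow = TRUE), faces)

#' Build a morphable model from meshes in vertex-wise correspondence
#'
#' Generalized Procrustes alignment (translation + rotation; uniform scale
#' optionally, off by default because prosthesis work is metric) followed by
#' PCA of the stacked vertex coordinates. By default the retained rank is
#' the smallest one carrying 99.9 percent of the population variance
#' (degenerate tail modes are numerical noise and harm the identifiability
#' of the later fit); the retained rank is always at most \code{n - 1}.
#'
#' @param training list of TriangleMesh with identical topology
#' @param rank maximum retained rank, or NULL for the variance-based default
#' @param withScale normalize scale during alignment
#' @return a \linkS4class{MorphableModel}
#' @export
buildModel <- function(training, rank = NULL, withScale = FALSE) {
  n <- length(training)
  if (n < 2) stop("at least 2 training meshes are required")
  f0 <- training[[1]]@faces
  nv <- nVertices(training[[1]])
  for (m in training)
    if (nVertices(m) != nv || !identical(m@faces, f0))
      stop("training meshes must share an identical topology")
  X <- vapply(training, function(m) as.vector(t(m@vertices)), numeric(3 * nv))
  # generalized Procrustes: translate to common centroid, then iterate
  # rotation (and scale) alignment to the evolving mean
  shapes <- lapply(seq_len(n), function(i) {
    v <- matrix(X[, i], ncol = 3, byrow = TRUE)
    sweep(v, 2, colMeans(v))
  })
  ref <- shapes[[1]]
  for (iter in 1:5) {
    shapes <- lapply(shapes, function(v) {
      tr <- kabsch(v, ref, withScale = withScale)
      v %*% t(tr$R) * tr$s
    })
    newRef <- Reduce(`+`, shapes) / n
    if (max(abs(newRef - ref)) < 1e-9) { ref <- newRef; break }
    ref <- newRef
  }
  Xa <- vapply(shapes, function(v) as.vector(t(v)), numeric(3 * nv))
  mu <- rowMeans(Xa)
  C <- Xa - mu
  sv <- svd(C, nu = min(n, 3 * nv))
  sdev <- sv$d / sqrt(n - 1)
  nondeg <- sdev > max(sdev[1] * 1e-7, 1e-10)
  if (is.null(rank)) {
    # default truncation: keep the modes carrying 99.9 percent of the
    # population variance; degenerate tail modes are numerical noise
    cv <- cumsum(sdev^2) / sum(sdev^2)
    r <- which(cv >= 0.999)[1]
  } else {
    r <- min(sum(nondeg), rank)
  }
  r <- min(r, sum(nondeg), n - 1)
  new("MorphableModel", faces = f0, mean = mu,
      basis = sv$u[, seq_len(r), drop = FALSE], modeSD = sdev[seq_len(r)])
}

# Least-squares rigid (optionally similarity) transform mapping X onto Y.
kabsch <- function(X, Y, withScale = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (withScale) sum(sv$d * c(1, 1, d)) / sum(Xc^2) else 1
  t <- cy - s * as.vector(R %*% cx)
  list(R = R, s = s, t = t)
}

#' @rdname modelRank
#' @export
setMethod("modelRank", "MorphableModel", function(x) ncol(x@basis))

#' @rdname modelRank
#' @export
setMethod("modeSD", "MorphableModel", function(x) x@modeSD)

#' @rdname meanMesh
#' @export
setMethod("meanMesh", "MorphableModel", function(x) unflattenMesh(x@mean, x@faces))

#' Sample a model instance at given standardized coefficients
#'
#' Returns \code{mean + basis (coeffs * modeSD)} reshaped onto the
#' reference topology; zero coefficients give the mean mesh exactly.
#'
#' @param model a MorphableModel
#' @param coeffs numeric vector of length \code{modelRank(model)}, in SD units
#' @return a TriangleMesh
#' @export
sampleInstance <- function(model, coeffs) {
  r <- modelRank(model)
  if (length(coeffs) != r) stop("coefficient length must equal the model rank")
  if (any(!is.finite(coeffs))) stop("coefficients must be finite")
  x <- model@mean
  if (r > 0) x <- x + as.vector(model@basis %*% (coeffs * model@modeSD))
  unflattenMesh(x, model@faces)
}

#' Project a shape onto the model, returning standardized coefficients
#'
#' @param model a MorphableModel
#' @param mesh a TriangleMesh on the reference topology (or a 3N vector)
#' @return numeric coefficient vector (SD units)
#' @export
projectShape <- function(model, mesh) {
  x <- if (is(mesh, "TriangleMesh")) flattenMesh(mesh) else as.numeric(mesh)
  if (length(x) != length(model@mean)) stop("shape does not match the model topology")
  if (modelRank(model) == 0) return(numeric(0))
  as.vector(crossprod(model@basis, x - model@mean)) / model@modeSD
}

#' Augment a model with smooth deformation modes
#'
#' Appends \code{approxRank} low-rank eigenmodes of a squared-exponential
#' deformation covariance (independent per axis), computed by a Nystrom
#' approximation on a vertex subsample, then jointly re-orthonormalizes.
#' The base model's span is preserved exactly: every base-model sample
#' remains representable, and the augmented rank is
#' \code{modelRank + approxRank}.
#'
#' @param model a MorphableModel
#' @param kernel a \linkS4class{SmoothDeformationKernel}
#' @param subsampleSize vertex subsample for the Nystrom approximation
#' @return the augmented MorphableModel
#' @export
augmentModel <- function(model, kernel, subsampleSize = 400) {
  validObject(kernel)
  if (kernel@variance == 0) return(model)
  n3 <- length(model@mean)
  N <- n3 / 3
  k <- kernel@approxRank
  if (k > n3 - modelRank(model)) stop("approxRank exceeds the available dimensions")
  P <- matrix(model@mean, ncol = 3, byrow = TRUE)
  m <- min(subsampleSize, N)
  idx <- unique(round(seq(1, N, length.out = m)))
  m <- length(idx)
  Ps <- P[idx, , drop = FALSE]
  D2 <- as.matrix(stats::dist(Ps))^2
  Kmm <- kernel@variance * exp(-D2 / (2 * kernel@lengthScale^2))
  eg <- eigen(Kmm, symmetric = TRUE)
  q <- min(ceiling(k / 3), sum(eg$values > max(eg$values) * 1e-10))
  lam <- eg$values[seq_len(q)] * (N / m)  # Nystrom covariance-operator scaling
  # out-of-sample extension of the eigenfunctions to every vertex
  cross2 <- outer(rowSums(P^2), rowSums(Ps^2), "+") - 2 * P %*% t(Ps)
  Knm <- kernel@variance * exp(-pmax(cross2, 0) / (2 * kernel@lengthScale^2))
  Phi <- Knm %*% eg$vectors[, seq_len(q), drop = FALSE] %*%
    diag(1 / eg$values[seq_len(q)], q)
  Phi <- sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")  # unit scalar fields
  # one displacement mode per (eigenfunction, axis); take the top approxRank
  modes <- matrix(0, n3, 3 * q)
  msd <- numeric(3 * q)
  for (j in seq_len(q)) {
    for (a in 1:3) {
      col <- 3 * (j - 1) + a
      modes[seq(a, n3, by = 3), col] <- Phi[, j]
      msd[col] <- sqrt(lam[j])
    }
  }
  ord <- order(msd, decreasing = TRUE)[seq_len(min(k, 3 * q))]
  modes <- modes[, ord, drop = FALSE]
  msd <- msd[ord]
  # joint subspace: orthonormalize [base | new], eigendecompose the combined
  # covariance inside it (keeps the base span exactly)
  B <- model@basis
  r <- ncol(B)
  Mperp <- modes - B %*% crossprod(B, modes)
  Q <- qr.Q(qr(cbind(B, Mperp)))[, seq_len(r + ncol(modes)), drop = FALSE]
  W <- cbind(sweep(B, 2, model@modeSD, "*"), sweep(modes, 2, msd, "*"))
  Msub <- crossprod(Q, W)
  eg2 <- eigen(tcrossprod(Msub), symmetric = TRUE)
  vals <- pmax(eg2$values, 0)
  keep <- seq_len(r + ncol(modes))
  new("MorphableModel", faces = model@faces, mean = model@mean,
      basis = Q %*% eg2$vectors[, keep, drop = FALSE],
      modeSD = sqrt(vals[keep]))
}

#' Gaussian posterior model given point constraints
#'
#' Conditions the coefficient distribution on observed positions of
#' reference vertices with isotropic Gaussian noise. The returned model's
#' mean is the regression posterior mean and its modes are the posterior
#' covariance eigenmodes; every posterior mode variance is bounded by the
#' corresponding prior variance.
#'
#' @param model a MorphableModel
#' @param vertexIds integer vector of constrained reference vertices
#' @param points numeric \code{k x 3} matrix of observed positions (mm)
#' @param noiseSd observation noise SD in mm, > 0
#' @return the posterior MorphableModel
#' @export
posteriorModel <- function(model, vertexIds, points, noiseSd) {
  if (length(vertexIds) == 0) return(model)
  if (noiseSd <= 0) stop("noiseSd must be positive")
  points <- asPointMatrix(points)
  if (nrow(points) != length(vertexIds)) stop("vertexIds and points must align")
  N <- length(model@mean) / 3
  if (any(vertexIds < 1 | vertexIds > N)) stop("constraint vertex id out of range")
  rows <- as.vector(t(outer(3 * (vertexIds - 1), 1:3, "+")))
  r <- modelRank(model)
  A <- sweep(model@basis[rows, , drop = FALSE], 2, model@modeSD, "*")
  b <- as.vector(t(points)) - model@mean[rows]
  P <- crossprod(A) / noiseSd^2 + diag(r)
  Sc <- solve(P)
  mc <- as.vector(Sc %*% crossprod(A, b)) / noiseSd^2
  W <- sweep(model@basis, 2, model@modeSD, "*")
  newMean <- model@mean + as.vector(W %*% mc)
  # eigenmodes of the posterior shape covariance B S Sc S B'
  S <- diag(model@modeSD, r)
  eg <- eigen(S %*% Sc %*% S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  keep <- vals > max(vals[1] * 1e-12, 1e-300)
  new("MorphableModel", faces = model@faces, mean = newMean,
      basis = model@basis %*% eg$vectors[, keep, drop = FALSE],
      modeSD = sqrt(vals[keep]))
}

#' Persist a model archive
#'
#' Stores the reference topology, mean, basis and mode SDs with a format
#' version tag, plus (optionally) the nose region mask and the named
#' landmark vertex indices that accompany the model through the pipeline.
#'
#' @param model a MorphableModel
#' @param path output file
#' @param noseMask optional RegionMask on the reference topology
#' @param landmarkIndices optional named integer vector of landmark vertices
#' @export
saveModel <- function(model, path, noseMask = NULL, landmarkIndices = NULL) {
  obj <- list(format = "noseforge-model", version = 1L,
              faces = model@faces, mean = model@mean, basis = model@basis,
              modeSD = model@modeSD,
              noseMask = if (!is.null(noseMask)) noseMask@flags,
              landmarkIndices = landmarkIndices)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model archive written by \code{\link{saveModel}}
#' @param path archive path
#' @return list with \code{model}, \code{noseMask}, \code{landmarkIndices}
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "noseforge-model")) stop("not a model archive: ", path)
  list(model = new("MorphableModel", faces = obj$faces, mean = obj$mean,
                   basis = obj$basis, modeSD = obj$modeSD),
       noseMask = if (!is.null(obj$noseMask)) new("RegionMask", flags = obj$noseMask),
       landmarkIndices = obj$landmarkIndices)
}

#' Landmarks of a model's mean shape
#' @param model a MorphableModel
#' @param landmarkIndices named integer vector of reference vertex indices
#' @return a LandmarkSet at the mean-shape positions
#' @export
modelLandmarks <- function(model, landmarkIndices) {
  v <- matrix(model@mean, ncol = 3, byrow = TRUE)
  co <- v[landmarkIndices, , drop = FALSE]
  rownames(co) <- names(landmarkIndices)
  new("LandmarkSet", coords = co)
}
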