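# The prosthesis/mold protocol: blend the nose-model border into the face,
# solidify to the prosthesis wall thickness, subtract the face solid to
# obtain the prosthesis model (PM), sculpt nostrils, and split the PM into
# two flanged mold shells with a closure gap.
#
# The two traditionally manual steps (border sculpting, nostrils) are
# parameterized operations; externally edited meshes can be injected in
# their place at the pipeline level.

#' Construct a DesignParams
#'
#' Protocol defaults: 6 mm prosthesis wall, 0.3 mm mold closure gap, 4 mm
#' mold shell wall. See \linkS4class{DesignParams} for the remaining knobs.
#'
#' @param prosthesisWall,moldGap,moldWall,blendWidth,blendDepth,densifyEdge
#'   geometric parameters in mm
#' @param smoothIterations smoothing iterations for protocol steps 4 and 6
#' @param backingDepth mm, depth of the face-solid backing
#' @param flangeExtent mm, radial extent of the mold flanges
#' @param resolution mm, implicit-surface sampling pitch
#' @export
designParams <- function(prosthesisWall = 6, moldGap = 0.3, moldWall = 4,
                         blendWidth = 3, blendDepth = 0.5, densifyEdge = 0.5,
                         smoothIterations = 10, backingDepth = 30,
                         flangeExtent = 10, resolution = 0.4) {
  new("DesignParams", prosthesisWall = prosthesisWall, moldGap = moldGap,
      moldWall = moldWall, blendWidth = blendWidth, blendDepth = blendDepth,
      densifyEdge = densifyEdge, smoothIterations = as.integer(smoothIterations),
      backingDepth = backingDepth, flangeExtent = flangeExtent,
      resolution = resolution)
}

#' Construct a NostrilSpec
#' @param entry k x 3 matrix of entry points (mm), k in 0..2
#' @param axis k x 3 matrix of drilling directions
#' @param radius,depth numeric vectors (mm)
#' @export
nostrilSpec <- function(entry = matrix(numeric(0), 0, 3), axis = entry,
                        radius = numeric(0), depth = numeric(0)) {
  entry <- asPointMatrix(entry)
  axis <- asPointMatrix(axis)
  if (nrow(axis) > 0) axis <- axis / sqrt(rowSums(axis^2))
  new("NostrilSpec", entry = entry, axis = axis,
      radius = as.numeric(radius), depth = as.numeric(depth))
}

#' Blend the nose-model border inward of the face
#'
#' Within \code{blendWidth} of the NM's open boundary, vertices are
#' displaced along the face normal so that the boundary ring comes to lie
#' \code{blendDepth} on the inner (negative signed-distance) side of the
#' face, with a smooth cosine falloff to zero displacement at the band's
#' inner edge. This guarantees that the later subtraction produces a thin,
#' feathered prosthesis edge seated on the skin.
#'
#' @param nm the open nose model
#' @param fm the face surface (open sheet or watertight solid)
#' @param params a DesignParams
#' @return the blended nose model
#' @export
blendBorder <- function(nm, fm, params = designParams()) {
  bl <- boundaryLoops(nm)
  if (length(bl$vertices) == 0) stop("nose model has no open boundary to blend")
  v <- nm@vertices
  bv <- v[bl$vertices, , drop = FALSE]
  # distance of every vertex to the boundary ring
  d2 <- outer(rowSums(v^2), rowSums(bv^2), "+") - 2 * v %*% t(bv)
  dRing <- sqrt(pmax(apply(d2, 1, min), 0))
  band <- dRing < params@blendWidth
  if (all(band))
    stop("blend band covers the whole nose model; blendWidth must be a proper subset")
  sd_ <- sheetDistance(fm, v[band, , drop = FALSE])
  ringRows <- match(bl$vertices, which(band))
  uncovered <- sd_$d[ringRows] > 5 * params@blendWidth + params@prosthesisWall
  if (any(uncovered))
    stop(sprintf("face model not found under %d border sample(s); cannot blend",
                 sum(uncovered)))
  w <- (1 + cos(pi * dRing[band] / params@blendWidth)) / 2
  delta <- w * (-params@blendDepth - sd_$s)
  v[band, ] <- v[band, , drop = FALSE] + delta * sd_$normal
  TriangleMesh(v, nm@faces, nm@vertexLabels)
}

# Crop a mesh to faces whose centroid lies inside an axis-aligned box.
cropToBox <- function(mesh, lo, hi) {
  v <- mesh@vertices; f <- mesh@faces
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
  keep <- cen[, 1] >= lo[1] & cen[, 1] <= hi[1] &
          cen[, 2] >= lo[2] & cen[, 2] <= hi[2] &
          cen[, 3] >= lo[3] & cen[, 3] <= hi[3]
  cleanMesh(TriangleMesh(v, f[keep, , drop = FALSE]), dropUnreferenced = TRUE)
}

#' Close a face surface into a watertight solid
#'
#' The subtraction step needs the face as a volume; an open scan sheet is
#' backed to \code{backingDepth} behind the skin (against the surface
#' normals). The face is first cropped to the nose neighbourhood to keep
#' the resampling tractable.
#'
#' @param fm face surface
#' @param nm nose model whose neighbourhood is needed
#' @param params a DesignParams
#' @return a watertight TriangleMesh
#' @export
solidifyFace <- function(fm, nm, params = designParams()) {
  if (isWatertight(fm)) return(fm)
  bb <- apply(nm@vertices, 2, range)
  pad <- params@moldWall + params@flangeExtent + 5
  fmCrop <- cropToBox(fm, bb[1, ] - pad, bb[2, ] + pad)
  if (nFaces(fmCrop) == 0) stop("face model does not cover the nose neighbourhood")
  # a coarser pitch suffices here: on the smooth skin the extraction error
  # is ~ h^2 * curvature (about 0.01 mm at 1 mm), and a lean face solid
  # keeps the later field evaluations fast
  solidifyShell(fmCrop, params@backingDepth, "inward",
                resolution = max(2.5 * params@resolution, 1))
}

#' Build the prosthesis model from the blended nose model
#'
#' Protocol steps 3 to 6: solidify the NM to \code{prosthesisWall}; smooth
#' the inner sheet (cleaning comfort); subtract the face solid, giving the
#' prosthesis model with a seamless connection to the skin; smooth the
#' connecting surface. Every intermediate is watertight.
#'
#' @param nm blended nose model (step 2 done)
#' @param fmSolid watertight face solid (see \code{\link{solidifyFace}})
#' @param params a DesignParams
#' @return the prosthesis model (watertight TriangleMesh)
#' @export
buildProsthesisSolid <- function(nm, fmSolid, params = designParams()) {
  if (!isWatertight(fmSolid)) stop("step 5 (subtract FM): face solid must be watertight")
  shell <- withStage("step 3 (wall thickness)",
    solidifyShell(nm, params@prosthesisWall, "inward", resolution = params@resolution))
  # step 4: smooth the inner sheet (vertices nearer the inner offset)
  nmQ <- meshQuery(nm)
  dn <- cpp_closest(nmQ, shell@vertices)$distance
  inner <- RegionMask(dn > 0.55 * params@prosthesisWall)
  shell <- withStage("step 4 (smooth inner surface)",
    regionSmooth(shell, inner, iterations = params@smoothIterations, strength = 0.5))
  pm <- withStage("step 5 (subtract FM)",
    booleanSubtract(shell, fmSolid, resolution = params@resolution))
  if (nFaces(pm) == 0) stop("step 5 (subtract FM): empty prosthesis model")
  # step 6: smooth the connecting surface (vertices on the face solid),
  # then re-seat it: smoothing regularizes the triangulation but must not
  # lift the skin-facing surface off the face, so seat-like vertices are
  # projected back onto the face solid
  fmQ <- meshQuery(fmSolid)
  dfm <- abs(cpp_closest(fmQ, pm@vertices)$distance)
  conn <- RegionMask(dfm < 1.5 * params@resolution)
  pm <- withStage("step 6 (smooth connecting surface)",
    regionSmooth(pm, conn, iterations = params@smoothIterations, strength = 0.5))
  vn <- vertexNormals(pm)
  cl <- cpp_closest(fmQ, pm@vertices)
  seat <- which(cl$distance < 1.5 * params@resolution &
                  rowSums(vn * cl$normal) < -0.7)
  pm@vertices[seat, ] <- cl$point[seat, , drop = FALSE]
  if (!isWatertight(pm)) stop("prosthesis model is not watertight")
  pm
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stop(stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Sculpt the nostrils
#'
#' Subtracts up to two capped cylinders (radius, depth along the axis from
#' the entry point) from the prosthesis model. An empty specification
#' returns the model unchanged; a cylinder that misses the model entirely
#' is an error.
#'
#' @param pm watertight prosthesis model
#' @param nostrils a \linkS4class{NostrilSpec}
#' @param resolution boolean sampling pitch (mm); defaults to the cylinder
#'   radius / 10
#' @return the sculpted prosthesis model
#' @export
sculptNostrils <- function(pm, nostrils, resolution = NULL) {
  validObject(nostrils)
  k <- nrow(nostrils@entry)
  if (k == 0) return(pm)
  if (!isWatertight(pm)) stop("prosthesis model must be watertight")
  for (i in seq_len(k)) {
    cyl <- meshCylinder(nostrils@entry[i, ], nostrils@axis[i, ],
                        nostrils@radius[i], nostrils@depth[i], n = 64)
    if (min(signedDistance(pm, cyl@vertices)) > 0)
      stop(sprintf("nostril %d does not intersect the prosthesis model", i))
    res <- if (is.null(resolution)) min(nostrils@radius[i] / 10, 0.4) else resolution
    volBefore <- meshVolume(pm)
    pm <- booleanSubtract(pm, cyl, resolution = res)
    if (nFaces(pm) == 0 || meshVolume(pm) < 0.1 * volBefore)
      stop(sprintf("nostril %d removes the prosthesis shell", i))
  }
  pm
}

#' Generate the two-part mold
#'
#' Protocol steps 8 to 10. The prosthesis surface is separated into the
#' outer (anterior, visible) and inner (posterior, skin-facing) sheets
#' along the prosthesis edge curve; each sheet is thickened outward by
#' \code{moldWall} and extended by a flat flange ring following the edge
#' curve, with the two flanges held \code{moldGap} apart along the parting
#' normal so the closed mold clamps tight. Both shells are watertight with
#' disjoint interiors, and the assembled cavity reproduces the prosthesis
#' model (excluding the flange ring).
#'
#' The parting classification needs the geometric context in which the PM
#' was built, so the face solid and the blended nose model are passed
#' alongside the PM.
#'
#' @param pm watertight prosthesis model
#' @param fmSolid the watertight face solid used to build the PM
#' @param nm the blended nose model used to build the PM
#' @param params a DesignParams
#' @return a \linkS4class{MoldAssembly}
#' @export
generateMold <- function(pm, fmSolid, nm, params = designParams()) {
  if (!isWatertight(pm)) stop("prosthesis model must be watertight")
  gap <- params@moldGap
  wall <- params@moldWall
  # parting field u: negative behind the skin-facing surface of the PM
  # (inside the face solid, or deeper than the prosthesis wall under the
  # nose sheet), positive on the visible side
  fmQ <- meshQuery(fmSolid)
  nmQ <- meshQuery(nm)
  # prosthesis edge curve: the blended rim of the nose sheet, which by
  # construction lies just inside the face and bounds the feathered edge
  rim <- boundaryLoops(nm)
  if (length(rim$vertices) < 10)
    stop("no closed prosthesis edge curve found; PM is not separable")
  edgePts <- nm@vertices[rim$vertices, , drop = FALSE]
  # parting plane: least-squares plane through the edge curve, oriented
  # toward the visible (anterior) side of the nose sheet
  cen <- colMeans(edgePts)
  sv <- svd(sweep(edgePts, 2, cen))
  nrm <- sv$v[, 3]
  fn <- faceNormals(nm)
  meanNm <- colSums(fn * faceAreas(nm))
  if (sum(nrm * meanNm) < 0) nrm <- -nrm
  # in-plane frame for the flange ring
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  toPlane <- function(pts) {
    rel <- sweep(pts, 2, cen)
    cbind(rel %*% e1, rel %*% e2, rel %*% nrm)  # (p, q, h)
  }
  ep <- toPlane(edgePts)
  rho <- sqrt(ep[, 1]^2 + ep[, 2]^2)
  theta <- atan2(ep[, 2], ep[, 1])
  nb <- 90
  bin <- pmin(floor((theta + pi) / (2 * pi) * nb) + 1, nb)
  rhoEdge <- rep(NA_real_, nb)
  agg <- tapply(rho, bin, max)
  rhoEdge[as.integer(names(agg))] <- agg
  # circular fill + light smoothing of the per-angle edge radius
  if (anyNA(rhoEdge)) {
    ok <- which(!is.na(rhoEdge))
    if (length(ok) == 0) stop("degenerate prosthesis edge curve")
    for (i in which(is.na(rhoEdge))) {
      dd <- pmin(abs(ok - i), nb - abs(ok - i))
      rhoEdge[i] <- rhoEdge[ok[which.min(dd)]]
    }
  }
  rhoEdge <- stats::filter(c(tail(rhoEdge, 1), rhoEdge, head(rhoEdge, 1)),
                           rep(1 / 3, 3), sides = 2)[1 + seq_len(nb)]
  rhoAt <- function(th) {
    pos <- (th + pi) / (2 * pi) * nb + 0.5
    i0 <- floor(pos)
    fr <- pos - i0
    i0 <- ((i0 - 1) %% nb) + 1
    i1 <- (i0 %% nb) + 1
    rhoEdge[i0] * (1 - fr) + rhoEdge[i1] * fr
  }

  # flanges extend only within the parting plane, so pad per axis
  pad <- wall + 3 * params@resolution + params@flangeExtent * sqrt(pmax(1 - nrm^2, 0))
  grid <- gridFromMeshes(list(pm), params@resolution, pad = pad)
  dPm <- gridField(pm, grid)$field
  fl <- gridField(nm, grid, query = nmQ)
  sn <- fl$field
  sn[fl$boundary] <- abs(sn[fl$boundary])
  dFm <- gridField(fmSolid, grid, query = fmQ)$field
  u <- pmin(dFm, sn + params@prosthesisWall)
  co <- gridCoords(grid)
  pl <- toPlane(co)
  rhoG <- sqrt(pl[, 1]^2 + pl[, 2]^2)
  hG <- pl[, 3]
  re <- rhoAt(atan2(pl[, 2], pl[, 1]))
  ringSlab <- function(h0, h1) {
    pmax(h0 - hG, hG - h1, (re - wall) - rhoG, rhoG - (re + params@flangeExtent))
  }
  B <- pmin(pmax(dPm - wall, -dPm, u),              # shell behind the skin-facing sheet
            pmax(ringSlab(-wall, 0), -dPm))          # posterior flange ring
  posterior <- extractIso(B, grid)
  if (nFaces(posterior) == 0) stop("mold generation produced an empty posterior shell")
  # carve the anterior against the extracted posterior's true distance
  # field: unlike the raw parting field it is 1-Lipschitz, so the closure
  # gap holds by construction also across the feather-edge discontinuity
  dB <- gridField(posterior, grid)$field
  A <- pmin(pmax(dPm - wall, -dPm),                  # shell over the visible sheet
            pmax(ringSlab(gap, gap + wall), gap - dPm))
  A <- pmax(A, gap - dB)                             # enforce the closure gap
  anterior <- extractIso(A, grid)
  if (nFaces(anterior) == 0)
    stop("mold generation produced an empty shell")
  # isosurface interpolation can undercut the gap by a fraction of the
  # pitch near field creases; project any short-clearance anterior vertex
  # back out to the exact gap distance
  qPost <- meshQuery(posterior)
  for (pass in 1:3) {
    clv <- cpp_closest(qPost, anterior@vertices)
    short <- which(clv$distance < gap - 1e-9)
    if (length(short) == 0) break
    dirs <- anterior@vertices[short, , drop = FALSE] - clv$point[short, , drop = FALSE]
    nn <- sqrt(rowSums(dirs^2))
    deg <- nn < 1e-9
    dirs[deg, ] <- clv$normal[short, , drop = FALSE][deg, , drop = FALSE]
    nn[deg] <- 1
    anterior@vertices[short, ] <- clv$point[short, , drop = FALSE] + dirs / nn * gap
  }
  if (!isWatertight(anterior) || !isWatertight(posterior))
    stop("mold shells are not watertight")
  new("MoldAssembly", anteriorShell = anterior, posteriorShell = posterior,
      closureGap = gap,
      parting = list(center = cen, normal = nrm, e1 = e1, e2 = e2,
                     rhoEdge = as.numeric(rhoEdge), nBins = nb,
                     flangeExtent = params@flangeExtent, moldWall = wall))
}

#' Export the mold shells for 3D printing
#'
#' Writes exactly two binary STL files, \code{mold_anterior.stl} and
#' \code{mold_posterior.stl}, into \code{outDir}.
#'
#' @param assembly a MoldAssembly
#' @param outDir output directory (created if absent)
#' @return character vector of the two paths
#' @export
exportMold <- function(assembly, outDir) {
  stopifnot(is(assembly, "MoldAssembly"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- file.path(outDir, c("mold_anterior.stl", "mold_posterior.stl"))
  writeMesh(assembly@anteriorShell, paths[1], "stl")
  writeMesh(assembly@posteriorShell, paths[2], "stl")
  paths
}

#' Achieved flange-to-flange closure distance (mm)
#'
#' Minimum distance from the anterior shell's flange region (the stretched
#' border beyond the prosthesis edge curve) to the posterior shell, i.e.
#' the clearance that remains when the mold is clamped shut.
#'
#' @param assembly a MoldAssembly with parting information
#' @return the minimum flange-to-flange distance in mm
#' @export
moldClosureGap <- function(assembly) {
  p <- assembly@parting
  if (length(p) == 0) stop("assembly lacks parting information")
  v <- assembly@anteriorShell@vertices
  rel <- sweep(v, 2, p$center)
  pq <- cbind(rel %*% p$e1, rel %*% p$e2)
  rho <- sqrt(rowSums(pq^2))
  nb <- p$nBins
  pos <- (atan2(pq[, 2], pq[, 1]) + pi) / (2 * pi) * nb + 0.5
  i0 <- ((floor(pos) - 1) %% nb) + 1
  fr <- pos - floor(pos)
  re <- p$rhoEdge[i0] * (1 - fr) + p$rhoEdge[(i0 %% nb) + 1] * fr
  h <- as.vector(rel %*% p$normal)
  # the flange ring proper: beyond the shell collar around the prosthesis
  # edge, within the flange slab height
  onFlange <- rho > re + p$moldWall + 1 & rho < re + p$flangeExtent &
    h > 0 & h < assembly@closureGap + p$moldWall + 0.5
  if (!any(onFlange)) stop("no anterior flange vertices found")
  qb <- meshQuery(assembly@posteriorShell)
  min(cpp_closest(qb, v[onFlange, , drop = FALSE])$distance)
}

#' Seating error of the prosthesis connecting surface
#'
#' The connecting surface is the skin-facing part of the PM created by the
#' face subtraction: faces lying within \code{band} mm of the face solid
#' with normals opposing the skin. Samples it and reports the signed
#' distance to the face solid; a seamless fit keeps at least 95 percent of
#' samples within 0.2 mm.
#'
#' @param pm the prosthesis model
#' @param fmSolid the watertight face solid it was built against
#' @param nSamples surface samples
#' @param band selection band in mm
#' @return list with \code{fraction02} (samples within 0.2 mm), \code{q95}
#'   and the signed \code{distances}
#' @export
seamlessFit <- function(pm, fmSolid, nSamples = 2000, band = 0.5) {
  sp <- sampleSurfacePoints(pm, 4 * nSamples)
  q <- meshQuery(fmSolid)
  cl <- cpp_closest(q, sp$points)
  opposing <- rowSums(sp$normals * cl$normal) < -0.9
  sel <- which(cl$distance < band & opposing)
  if (length(sel) < 50) stop("no connecting surface found within the band")
  sel <- sel[seq_len(min(nSamples, length(sel)))]
  d <- cl$distance[sel] * cl$sign[sel]
  list(fraction02 = mean(abs(d) < 0.2), q95 = as.numeric(quantile(abs(d), 0.95)),
       distances = d)
}

#' How faithfully the mold cavity reproduces the prosthesis model
#'
#' Samples the PM surface and measures the distance to the nearest mold
#' shell surface; the cavity walls of a faithful mold coincide with the PM
#' everywhere except the thin closure band at the prosthesis edge.
#'
#' @param assembly a MoldAssembly
#' @param pm the prosthesis model
#' @param nSamples surface samples
#' @return list with the 95th percentile distance (mm) and all samples
#' @export
cavityFidelity <- function(assembly, pm, nSamples = 2000) {
  sp <- sampleSurfacePoints(pm, nSamples)
  qa <- meshQuery(assembly@anteriorShell)
  qb <- meshQuery(assembly@posteriorShell)
  d <- pmin(cpp_closest(qa, sp$points)$distance, cpp_closest(qb, sp$points)$distance)
  list(q95 = as.numeric(quantile(d, 0.95)), distances = d)
}

#' Casting simulation: the cavity enclosed by the closed mold
#'
#' Extracts the region that is outside both shells but within the
#' prosthesis neighbourhood, i.e. the volume the silicone fills when the
#' mold is clamped; it should reproduce the PM (plus a sub-gap flash film
#' at the parting line).
#'
#' @param assembly a MoldAssembly
#' @param pm the prosthesis model (defines the casting neighbourhood)
#' @param resolution sampling pitch in mm
#' @return a watertight TriangleMesh of the cast volume
#' @export
castingCavity <- function(assembly, pm, resolution = 0.4) {
  grid <- gridFromMeshes(list(pm), resolution, pad = 2)
  dA <- gridField(assembly@anteriorShell, grid)$field
  dB <- gridField(assembly@posteriorShell, grid)$field
  dP <- gridField(pm, grid)$field
  extractIso(pmax(-dA, -dB, dP - 0.5), grid)
}
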