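#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Units are assumed to be millimetres (the package-wide convention). Every
#' read applies \code{\link{cleanMesh}}: duplicate vertices within 1e-6 mm
#' are merged and degenerate faces dropped, so an STL file (which stores
#' unshared triangle soup) comes back with shared topology.
#'
#' @param path file path
#' @param format one of \code{"stl"}, \code{"ply"}, \code{"obj"};
#'   defaults to the file extension
#' @return a \linkS4class{TriangleMesh}
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj"))
      stop("cannot infer mesh format from extension: ", path)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  mesh <- switch(format,
    stl = readSTL(path),
    ply = readPLY(path),
    obj = readOBJ(path))
  cleanMesh(mesh)
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' STL is written as binary (the printer-facing dialect); PLY is ascii and
#' carries the per-vertex label as a \code{region} property when present;
#' OBJ stores geometry only.
#'
#' @param mesh a non-empty TriangleMesh
#' @param path output file path
#' @param format as in \code{\link{readMesh}}
#' @return the path, invisibly
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj"))
      stop("cannot infer mesh format from extension: ", path)
  }
  stopifnot(is(mesh, "TriangleMesh"))
  if (nFaces(mesh) == 0) stop("refusing to write an empty mesh")
  switch(format,
    stl = writeSTL(mesh, path),
    ply = writePLY(mesh, path),
    obj = writeOBJ(mesh, path))
  invisible(path)
}

# ---- STL -------------------------------------------------------------------

readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (length(header) < 80) stop("malformed STL: truncated header in ", path)
  # ascii STL starts with "solid" and contains "facet" text
  headTxt <- rawToChar(header[header != as.raw(0)])
  probe <- readBin(con, "raw", 512)
  isAscii <- grepl("^\\s*solid", headTxt) &&
    grepl("facet", rawToChar(probe[probe != as.raw(0) & probe <= as.raw(127)]), fixed = TRUE)
  if (isAscii) return(readSTLascii(path))
  seek(con, 80)
  nTri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(nTri) == 0 || is.na(nTri) || nTri < 0)
    stop("malformed STL: bad triangle count in ", path)
  expect <- 80 + 4 + nTri * 50
  if (file.size(path) < expect)
    stop(sprintf("malformed STL: %s declares %d triangles but is truncated", path, nTri))
  raw <- readBin(con, "raw", nTri * 50)
  m <- matrix(raw, nrow = 50)
  vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * nTri, endian = "little")
  vals <- matrix(vals, nrow = 12)  # per-tri: normal, v1, v2, v3
  v <- matrix(as.vector(vals[4:12, ]), ncol = 3, byrow = TRUE)
  f <- matrix(seq_len(3 * nTri), ncol = 3, byrow = TRUE)
  TriangleMesh(v, f)
}

readSTLascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ascii STL: vertex count not a multiple of 3 in ", path)
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 4)
  if (length(bad))
    stop("malformed ascii STL: bad vertex record '", vl[bad[1]], "'")
  v <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3, byrow = TRUE)
  if (anyNA(v)) stop("malformed ascii STL: non-numeric vertex in ", path)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  TriangleMesh(v, f)
}

writeSTL <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  n <- faceNormals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw(sprintf("%-79s", "noseforge binary STL (mm)")), as.raw(0)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  tri <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  # interleave 12 floats + 2-byte attribute per record
  floats <- writeBin(as.vector(t(tri)), raw(), size = 4, endian = "little")
  fm <- matrix(floats, nrow = 48)
  rec <- rbind(fm, matrix(as.raw(0), 2, ncol(fm)))
  writeBin(as.vector(rec), con)
}

# ---- PLY -------------------------------------------------------------------

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readHeaderLine <- function() {
    chars <- raw(0)
    repeat {
      ch <- readBin(con, "raw", 1)
      if (length(ch) == 0) stop("malformed PLY: unterminated header in ", path)
      if (ch == as.raw(10)) break
      chars <- c(chars, ch)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (readHeaderLine() != "ply") stop("malformed PLY: missing magic in ", path)
  fmt <- NULL; nV <- NULL; nF <- NULL
  vprops <- character(0)
  inVertex <- FALSE
  repeat {
    ln <- readHeaderLine()
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      inVertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nV <- as.integer(tok[3])
      if (tok[2] == "face") nF <- as.integer(tok[3])
    } else if (tok[1] == "property" && inVertex && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || is.null(nV) || is.null(nF))
    stop("malformed PLY: incomplete header in ", path)
  need <- match(c("x", "y", "z"), vprops)
  if (anyNA(need)) stop("malformed PLY: vertex element lacks x/y/z in ", path)
  regCol <- match("region", vprops)
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nV + nF) stop("malformed PLY: truncated body in ", path)
    vm <- matrix(as.numeric(unlist(strsplit(trimws(txt[seq_len(nV)]), "\\s+"))),
                 nrow = nV, byrow = TRUE)
    if (anyNA(vm)) stop("malformed PLY: non-numeric vertex record in ", path)
    v <- vm[, need, drop = FALSE]
    lab <- if (!is.na(regCol)) as.integer(vm[, regCol]) else integer(0)
    frows <- strsplit(trimws(txt[nV + seq_len(nF)]), "\\s+")
    cnt <- vapply(frows, function(x) as.integer(x[1]), 1L)
    if (any(cnt != 3)) stop("malformed PLY: only triangular faces supported (", path, ")")
    f <- matrix(as.integer(unlist(lapply(frows, `[`, 2:4))), ncol = 3, byrow = TRUE) + 1L
  } else if (fmt == "binary_little_endian") {
    v <- matrix(NA_real_, nV, length(vprops))
    raw <- readBin(con, "raw", nV * 4 * length(vprops))
    if (length(raw) < nV * 4 * length(vprops)) stop("malformed PLY: truncated body in ", path)
    vals <- readBin(raw, "numeric", size = 4, n = nV * length(vprops), endian = "little")
    vm <- matrix(vals, nrow = nV, byrow = TRUE)
    v <- vm[, need, drop = FALSE]
    lab <- if (!is.na(regCol)) as.integer(vm[, regCol]) else integer(0)
    f <- matrix(NA_integer_, nF, 3)
    for (i in seq_len(nF)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (length(cnt) == 0 || cnt != 3) stop("malformed PLY: non-triangular face in ", path)
      f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format '", fmt, "' in ", path)
  TriangleMesh(v, f, lab)
}

writePLY <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  lab <- mesh@vertexLabels
  hasLab <- length(lab) == nrow(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment noseforge (mm)",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               if (hasLab) "property int region",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  if (hasLab) {
    writeLines(sprintf("%.9g %.9g %.9g %d", v[, 1], v[, 2], v[, 3], lab), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# ---- OBJ -------------------------------------------------------------------

readOBJ <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) stop("malformed OBJ: no geometry in ", path)
  v <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"), `[`, 2:4))),
              ncol = 3, byrow = TRUE)
  if (anyNA(v)) stop("malformed OBJ: bad vertex record in ", path)
  fparts <- strsplit(trimws(fl), "\\s+")
  if (any(vapply(fparts, length, 1L) != 4))
    stop("malformed OBJ: only triangular faces supported (", path, ")")
  idx <- vapply(fparts, function(x) as.integer(sub("/.*", "", x[2:4])), integer(3))
  f <- t(idx)
  if (anyNA(f)) stop("malformed OBJ: bad face record in ", path)
  TriangleMesh(v, f)
}

writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# noseforge OBJ (mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

#' Read landmarks from a JSON file
#'
#' Expected layout: \code{{"name": [x, y, z], ...}} in mm.
#' @param path JSON file path
#' @return a \linkS4class{LandmarkSet}
#' @export
readLandmarks <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  LandmarkSet(lapply(lst, as.numeric))
}

#' Write landmarks to JSON
#' @param landmarks a LandmarkSet
#' @param path output path
#' @export
writeLandmarks <- function(landmarks, path) {
  co <- landmarks@coords
  lst <- lapply(seq_len(nrow(co)), function(i) unname(co[i, ]))
  names(lst) <- rownames(co)
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
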