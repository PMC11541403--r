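# One-command orchestration: erase -> align -> fit -> crop -> protocol
# steps 1-11 -> export, with a reproducible run manifest (input/output
# hashes, config snapshot, per-stage timings).

#' Read a defect mask JSON file
#'
#' Layout: \code{{"n": vertex_count, "indices": [1-based vertex ids]}}.
#' @param path JSON file
#' @return a RegionMask
#' @export
readDefectMask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$n) || is.null(obj$indices)) stop("malformed defect mask: ", path)
  RegionMask(as.integer(obj$indices), n = as.integer(obj$n))
}

#' Write a defect mask JSON file
#' @param mask a RegionMask
#' @param path output file
#' @export
writeDefectMask <- function(mask, path) {
  jsonlite::write_json(list(n = length(mask@flags), indices = which(mask@flags)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a flat YAML run configuration
#'
#' Recognized keys are the \code{\link{fitConfig}} and
#' \code{\link{designParams}} argument names (snake_case or camelCase).
#' Unknown keys are an error, so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file, or NULL for all-default configuration
#' @return list with \code{fit} (FitConfig) and \code{design} (DesignParams)
#' @export
readRunConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  toCamel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(raw) <- toCamel(names(raw))
  fitArgs <- names(formals(fitConfig))
  desArgs <- names(formals(designParams))
  unknown <- setdiff(names(raw), c(fitArgs, desArgs))
  if (length(unknown)) stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  list(fit = do.call(fitConfig, raw[intersect(names(raw), fitArgs)]),
       design = do.call(designParams, raw[intersect(names(raw), desArgs)]),
       snapshot = raw)
}

#' Run the full prosthesis-design pipeline
#'
#' Executes erase, align, fit, crop, the 11-step prosthesis/mold protocol
#' and the STL export, writing \code{nm.ply}, \code{pm.ply}, the two mold
#' STLs and \code{manifest.json} into \code{outDir}. Any stage error aborts
#' with the stage name; outputs of completed stages are preserved.
#'
#' @param scan path to the face scan (PLY/STL/OBJ, mm)
#' @param defectMask path to the defect mask JSON (on the scan's topology)
#' @param landmarks path to the scan landmark JSON
#' @param model path to a model archive from \code{\link{saveModel}}
#'   (carrying the nose region and landmark indices)
#' @param config optional YAML configuration path
#' @param outDir output directory
#' @param nostrils optional \linkS4class{NostrilSpec} (or JSON path with
#'   fields entry/axis/radius/depth)
#' @return list with the mold assembly, fit result and manifest, invisibly
#' @export
runFullPipeline <- function(scan, defectMask, landmarks, model, config = NULL,
                            outDir = ".", nostrils = NULL) {
  inputs <- c(scan = scan, defectMask = defectMask, landmarks = landmarks, model = model)
  if (!is.null(config)) inputs["config"] <- config
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  cfg <- readRunConfig(config)
  manifest <- list(inputs = as.list(tools::md5sum(inputs)),
                   config = cfg$snapshot, stages = list())
  t0 <- proc.time()[["elapsed"]]
  stageTimes <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stageTimes[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  run <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    tick(stage)
    out
  }

  fmFull <- run("read_scan", readMesh(scan))
  mask <- run("read_mask", readDefectMask(defectMask))
  lmScan <- run("read_landmarks", readLandmarks(landmarks))
  arch <- run("read_model", loadModel(model))
  if (is.null(arch$noseMask) || is.null(arch$landmarkIndices))
    stop("model archive lacks the nose region or landmark indices")
  if (is.character(nostrils)) {
    nj <- jsonlite::read_json(nostrils, simplifyVector = TRUE)
    nostrils <- nostrilSpec(entry = matrix(unlist(nj$entry), ncol = 3, byrow = TRUE),
                            axis = matrix(unlist(nj$axis), ncol = 3, byrow = TRUE),
                            radius = nj$radius, depth = nj$depth)
  }

  fmPartial <- run("erase_region", eraseRegion(fmFull, mask))
  lmModel <- modelLandmarks(arch$model, arch$landmarkIndices)
  init <- run("rigid_align", rigidAlign(lmModel, lmScan))
  fit <- run("fit_model",
             fitModel(arch$model, fmPartial, cfg$fit, init, excludeRegion = arch$noseMask))
  nmRaw <- run("crop_nose", cropNose(fit@fittedMesh, arch$noseMask))

  params <- cfg$design
  nm <- run("step1_densify", densifyMesh(nmRaw, params@densifyEdge))
  nm <- run("step2_blend_border", blendBorder(nm, fmPartial, params))
  fmSolid <- run("solidify_face", solidifyFace(fmPartial, nm, params))
  pm <- run("steps3_6_prosthesis", buildProsthesisSolid(nm, fmSolid, params))
  if (!is.null(nostrils) && nrow(nostrils@entry) > 0)
    pm <- run("step7_nostrils", sculptNostrils(pm, nostrils))
  mold <- run("steps8_10_mold", generateMold(pm, fmSolid, nm, params))

  nmPath <- file.path(outDir, "nm.ply")
  pmPath <- file.path(outDir, "pm.ply")
  writeMesh(nm, nmPath, "ply")
  writeMesh(pm, pmPath, "ply")
  moldPaths <- exportMold(mold, outDir)
  tick("step11_export")

  outputs <- c(nmPath, pmPath, moldPaths)
  manifest$stages <- as.list(stageTimes)
  manifest$outputs <- as.list(tools::md5sum(outputs))
  manifest$fit <- list(rank = length(fit@coefficients),
                       finalRMS = unname(tail(fit@residualTrace, 1)),
                       iterations = length(fit@residualTrace))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(mold = mold, fit = fit, pm = pm, nm = nm, manifest = manifest))
}
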