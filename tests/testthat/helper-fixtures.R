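# Shared fixtures, built once per test run. Geometry-heavy objects (the
# toy hemisphere-on-plate prosthesis and its mold, the synthetic face
# population and its morphable model) are cached so independent test files
# can reuse them.

fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixtureCache)) {
    assign(name, force(expr), envir = fixtureCache)
  }
  get(name, envir = fixtureCache)
}

# toy case: hemisphere nose on a flat plate face, protocol defaults
toyCase <- function() {
  cached("toy", {
    hemi <- meshHemisphere(radius = 20, n = 64)
    plate <- meshPlate(c(-45, 45), c(-45, 45), z0 = 0, nx = 70, ny = 70)
    params <- designParams(resolution = 0.5)
    nm <- blendBorder(hemi, plate, params)
    fmSolid <- solidifyFace(plate, nm, params)
    pm <- buildProsthesisSolid(nm, fmSolid, params)
    list(hemi = hemi, plate = plate, params = params, nm = nm,
         fmSolid = fmSolid, pm = pm)
  })
}

toyMold <- function() {
  cached("toyMold", {
    toy <- toyCase()
    generateMold(toy$pm, toy$fmSolid, toy$nm, toy$params)
  })
}

# synthetic population and morphable model (fixed seed)
popModel <- function() {
  cached("popModel", {
    topo <- faceTopology(96, 96)
    pop <- generatePopulation(40, seed = 11, topology = topo)
    model <- buildModel(pop)
    list(topo = topo, pop = pop, model = model,
         landmarkIdx = faceLandmarkIndices(topo),
         noseMask = referenceNoseMask(topo))
  })
}

# a held-out patient face (parameters about 1 SD from the means)
patientFace <- function() {
  cached("patient", {
    pm <- popModel()
    generateFace(faceParams(noseLength = 54, noseWidth = 36, bridgeHeight = 9,
                            tipProjection = 20, nostrilRadius = 5.2,
                            faceBreadth = 144), pm$topo)
  })
}

expect_watertight <- function(mesh) {
  expect_true(isWatertight(mesh))
}
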