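# Shared fixtures for the test suite; everything is generated in code.

sphereCoeffs <- function() {
  stereologyCoefficients(1, sqrt(6 / pi), sqrt(6 / pi), 1)
}

# A small bank of glomeruli with identical geometry but independent
# nucleus placements.
glomBank <- function(n = 10, R = 50, npod = 200, rho = 3, seed = 11) {
  lapply(seq_len(n), function(i)
    makeGlomerulus(R, npod, rho, seed = seed + i))
}

# Tiny two-group, two-age count experiment with three programmed 8-fold
# genes, for exact DEG recovery at tight dispersion.
toyCountSE <- function(nGenes = 20L, dispersion = 1e-3, n = 4L,
                       seed = 5L) {
  design <- studyDesign(agesWeeks = c(12, 41), nPerCohort = n,
                        endpointParams = list(),
                        fibrosisParams = list(
                          severity = matrix(1, 2, 2,
                                            dimnames = list(c("lean", "obese"),
                                                            c(12, 41))),
                          severitySd = 0.1,
                          couplings = list(uC3M = list(a = 0, b = 1, sd = 0.1)),
                          couplingUnits = c(uC3M = "ug/dL"),
                          trichromeThresholds = 1:4,
                          creatinine = list(logMean = log(50), logSd = 0.1)
                        ),
                        seed = seed)
  params <- countSimParams(
    nGenes = nGenes, dispersion = dispersion,
    degSpec = list(up8 = list(genes = sprintf("g%04d", 1:3),
                              log2fc = c(3, 3))),
    podocyteGenes = character(), podocyteTrajectory = numeric(),
    nAges = 2L, librarySize = 2e6, seed = seed)
  simulateCounts(params, design)
}

# A low-noise, globally coupled study design: both uC3M and microalbumin
# share one affine coupling to the latent severity, so the pooled R^2 has
# a closed form.
lowNoiseDesign <- function(sdU = 0.05, sdM = 2, severitySd = 0.3,
                           nPerCohort = 5L, seed = 3L) {
  sev <- rbind(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0),
               c(0.8, 1.2, 1.6, 2.2, 3.2, 4.2))
  dimnames(sev) <- list(c("lean", "obese"), c(12, 20, 24, 29, 34, 41))
  studyDesign(
    nPerCohort = nPerCohort,
    endpointParams = list(),
    fibrosisParams = list(
      severity = sev, severitySd = severitySd,
      couplings = list(
        uC3M = list(a = 0.2, b = 1.1, sd = sdU),
        microalbumin = list(a = 5, b = 120, sd = sdM)
      ),
      couplingUnits = c(uC3M = "ug/dL", microalbumin = "ug/dL"),
      trichromeThresholds = c(1.25, 2.0, 2.75, 3.5),
      creatinine = list(logMean = log(50), logSd = 0.1)
    ),
    seed = seed
  )
}
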