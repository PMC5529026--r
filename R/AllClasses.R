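#' @import methods
#' @importFrom stats rnorm runif rnbinom rlnorm aov TukeyHSD cor prcomp
#'   pt phyper setNames complete.cases var sd lm coef
NULL

#' Glomerulus3D: a synthetic glomerulus with known podocyte ground truth
#'
#' Models a glomerulus as a sphere of radius `radiusGlom` containing
#' `nPod` equal spherical podocyte nuclei of radius `radiusNuc`, all fully
#' interior (centre norm at most `radiusGlom - radiusNuc`, so no nucleus is
#' clipped by the glomerular surface). The true nucleus count is the
#' ground truth against which stereological estimators are scored.
#'
#' @slot radiusGlom glomerular radius, micrometres.
#' @slot radiusNuc nuclear radius, micrometres (`radiusNuc < radiusGlom`).
#' @slot centers numeric matrix (n x 3) of nucleus centres, micrometres,
#'   relative to the glomerular centre.
#' @slot seed integer seed the object was generated with.
#'
#' @seealso [makeGlomerulus()], [sectionProfile()], [sampleProfiles()]
#' @export
setClass("Glomerulus3D",
  representation(
    radiusGlom = "numeric",
    radiusNuc = "numeric",
    centers = "matrix",
    seed = "integer"
  )
)

setValidity("Glomerulus3D", function(object) {
  msg <- character()
  if (length(object@radiusGlom) != 1L || object@radiusGlom <= 0)
    msg <- c(msg, "radiusGlom must be a single positive number")
  if (length(object@radiusNuc) != 1L || object@radiusNuc <= 0)
    msg <- c(msg, "radiusNuc must be a single positive number")
  if (length(object@radiusNuc) == 1L && length(object@radiusGlom) == 1L &&
      object@radiusNuc >= object@radiusGlom)
    msg <- c(msg, "radiusNuc must be smaller than radiusGlom")
  if (ncol(object@centers) != 3L && nrow(object@centers) > 0L)
    msg <- c(msg, "centers must have 3 columns")
  if (nrow(object@centers) > 0L) {
    norms <- sqrt(rowSums(object@centers^2))
    if (any(norms > object@radiusGlom - object@radiusNuc + 1e-9))
      msg <- c(msg, "all nucleus centres must lie within radiusGlom - radiusNuc")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Glomerulus3D number of podocyte nuclei (ground truth).
#' @param object,x a `Glomerulus3D`.
#' @export
setGeneric("nPod", function(object) standardGeneric("nPod"))

#' @rdname Glomerulus3D
#' @export
setMethod("nPod", "Glomerulus3D", function(object) nrow(object@centers))

#' @describeIn Glomerulus3D glomerular radius (micrometres).
#' @export
setGeneric("radiusGlom", function(object) standardGeneric("radiusGlom"))

#' @rdname Glomerulus3D
#' @export
setMethod("radiusGlom", "Glomerulus3D", function(object) object@radiusGlom)

#' @describeIn Glomerulus3D nuclear radius (micrometres).
#' @export
setGeneric("radiusNuc", function(object) standardGeneric("radiusNuc"))

#' @rdname Glomerulus3D
#' @export
setMethod("radiusNuc", "Glomerulus3D", function(object) object@radiusNuc)

#' @describeIn Glomerulus3D nucleus centre coordinates (n x 3 matrix).
#' @export
setGeneric("nucleusCenters", function(object) standardGeneric("nucleusCenters"))

#' @rdname Glomerulus3D
#' @export
setMethod("nucleusCenters", "Glomerulus3D", function(object) object@centers)

setMethod("show", "Glomerulus3D", function(object) {
  cat("Glomerulus3D: R =", object@radiusGlom, "um,",
      nPod(object), "podocyte nuclei of radius", object@radiusNuc,
      "um (seed", object@seed, ")\n")
})

#' Coefficients for Weibel-Gomez model-based stereology
#'
#' Bundles the four dimensionless coefficients of the Weibel-Gomez chain:
#' a size-distribution coefficient `kNuc` and shape coefficient `betaNuc`
#' for the nuclear numerical-density step, and a shape coefficient
#' `betaGlom` with distribution coefficient `kGlom` for the glomerular
#' volume step. Defaults are the values conventionally used for podocyte
#' nuclei (K = 1.1, beta = 1.45) and for a near-spherical glomerulus
#' (beta = 1.38, K = 1.01). For an exactly spherical monodisperse particle
#' the theoretical values are K = 1 and beta = sqrt(6/pi) ~ 1.382.
#'
#' @slot kNuc,betaNuc nuclear distribution and shape coefficients.
#' @slot betaGlom,kGlom glomerular shape and distribution coefficients.
#' @seealso [stereologyCoefficients()], [estimatePodocytes()]
#' @export
setClass("StereologyCoefficients",
  representation(
    kNuc = "numeric", betaNuc = "numeric",
    betaGlom = "numeric", kGlom = "numeric"
  )
)

setValidity("StereologyCoefficients", function(object) {
  v <- c(object@kNuc, object@betaNuc, object@betaGlom, object@kGlom)
  if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
    "all four coefficients must be single, finite, strictly positive numbers"
  else TRUE
})

#' Construct stereology coefficients
#'
#' @param kNuc,betaNuc nuclear distribution / shape coefficients
#'   (defaults 1.1 and 1.45).
#' @param betaGlom,kGlom glomerular shape / distribution coefficients
#'   (defaults 1.38 and 1.01).
#' @return a [StereologyCoefficients-class] object.
#' @examples
#' stereologyCoefficients()                       # conventional values
#' stereologyCoefficients(1, sqrt(6 / pi), sqrt(6 / pi), 1)  # sphere-exact
#' @export
stereologyCoefficients <- function(kNuc = 1.1, betaNuc = 1.45,
                                   betaGlom = 1.38, kGlom = 1.01) {
  new("StereologyCoefficients", kNuc = kNuc, betaNuc = betaNuc,
      betaGlom = betaGlom, kGlom = kGlom)
}

setMethod("show", "StereologyCoefficients", function(object) {
  cat("StereologyCoefficients: nuclei K =", object@kNuc,
      "beta =", object@betaNuc,
      "| volume beta =", object@betaGlom, "K =", object@kGlom, "\n")
})

#' PodocyteEstimate: output of the Weibel-Gomez estimation chain
#'
#' Holds every intermediate of the chain from pooled 2D profile
#' measurements to the estimated number of podocytes per glomerulus:
#' profile count density `N_A` (nuclei / um^2 of tuft), nuclear areal
#' fraction `A_A` (dimensionless), numerical density `N_V` (nuclei /
#' um^3), glomerular volume `V_glom` (um^3), the estimated podocyte number
#' `N_pod = N_V * V_glom`, podocyte density per 10^6 um^3, and the mean
#' WT-1 stained area per nucleus (um^2).
#'
#' @slot NA_ nuclear profiles per um^2 of tuft.
#' @slot AA stained areal fraction (dimensionless, in `[0, 1]`).
#' @slot NV nuclei per um^3.
#' @slot Vglom glomerular tuft volume, um^3.
#' @slot Npod estimated podocytes per glomerulus.
#' @slot density podocytes per 10^6 um^3 (`NV * 1e6`).
#' @slot meanNuclearSize mean stained area per WT-1 positive nucleus, um^2
#'   (`NA_real_` when no nuclei were counted).
#' @slot nProfiles number of profiles pooled into the estimate.
#' @seealso [estimatePodocytes()]
#' @export
setClass("PodocyteEstimate",
  representation(
    NA_ = "numeric", AA = "numeric", NV = "numeric",
    Vglom = "numeric", Npod = "numeric", density = "numeric",
    meanNuclearSize = "numeric", nProfiles = "integer"
  )
)

setValidity("PodocyteEstimate", function(object) {
  msg <- character()
  nonneg <- c(object@NA_, object@AA, object@NV, object@Vglom,
              object@Npod, object@density)
  if (any(nonneg < 0, na.rm = TRUE))
    msg <- c(msg, "all estimates must be non-negative")
  if (abs(object@density - object@NV * 1e6) > 1e-6 * max(1, object@density))
    msg <- c(msg, "density must equal NV * 1e6")
  if (abs(object@Npod - object@NV * object@Vglom) >
      1e-6 * max(1, object@Npod))
    msg <- c(msg, "Npod must equal NV * Vglom")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PodocyteEstimate", function(object) {
  cat("PodocyteEstimate (", object@nProfiles, " profiles)\n", sep = "")
  cat(sprintf("  N_A    %.4g nuclei/um^2\n", object@NA_))
  cat(sprintf("  A_A    %.4g (areal fraction)\n", object@AA))
  cat(sprintf("  N_V    %.4g nuclei/um^3\n", object@NV))
  cat(sprintf("  V_glom %.4g um^3\n", object@Vglom))
  cat(sprintf("  N_pod  %.4g podocytes/glomerulus\n", object@Npod))
  cat(sprintf("  density %.4g podocytes/10^6 um^3\n", object@density))
  if (is.finite(object@meanNuclearSize))
    cat(sprintf("  mean nuclear size %.4g um^2\n", object@meanNuclearSize))
})

#' @describeIn PodocyteEstimate estimated podocytes per glomerulus.
#' @param object a `PodocyteEstimate`.
#' @export
setGeneric("npodGlomEstimate", function(object) standardGeneric("npodGlomEstimate"))

#' @rdname PodocyteEstimate
#' @export
setMethod("npodGlomEstimate", "PodocyteEstimate", function(object) object@Npod)

#' Coerce a PodocyteEstimate to a one-row data.frame
#'
#' @param x a [PodocyteEstimate-class].
#' @param row.names,optional,... passed for S3 compatibility, ignored.
#' @return one-row `data.frame` with columns `n_a`, `a_a`, `n_v`,
#'   `v_glom_um3`, `n_pod`, `density_per_1e6um3`, `mean_nuclear_size_um2`,
#'   `n_profiles`.
#' @export
as.data.frame.PodocyteEstimate <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    n_a = x@NA_, a_a = x@AA, n_v = x@NV, v_glom_um3 = x@Vglom,
    n_pod = x@Npod, density_per_1e6um3 = x@density,
    mean_nuclear_size_um2 = x@meanNuclearSize, n_profiles = x@nProfiles
  )
}

#' StudyDesign: the longitudinal two-group preclinical design
#'
#' Describes a lean vs obese two-group design with terminal cohorts at a
#' set of ages (weeks), `nPerCohort` animals per group x age cell, per-
#' analyte log-normal endpoint parameters, and a latent fibrosis process
#' that drives the urinary collagen-III fragment biomarker (uC3M), the
#' microalbumin/creatinine ratio, and the ordinal 1-5 trichrome fibrosis
#' score. Construct with [studyDesign()].
#'
#' @slot groups character, the two group labels (`lean`, `obese`).
#' @slot agesWeeks strictly increasing integer ages in weeks.
#' @slot nPerCohort animals per group x age cohort (>= 2).
#' @slot endpointParams named list: per analyte a list with `logMean`
#'   (group x age matrix) and `logSd` (scalar > 0).
#' @slot fibrosisParams list: `severity` (group x age matrix of latent
#'   mean severities), `severitySd`, `couplings` (per coupled analyte an
#'   intercept/slope/noise-sd spec, optionally per group), and
#'   `trichromeThresholds` (4 increasing cut points on the latent scale).
#' @slot seed integer seed.
#' @seealso [studyDesign()], [simulateStudy()]
#' @export
setClass("StudyDesign",
  representation(
    groups = "character",
    agesWeeks = "numeric",
    nPerCohort = "integer",
    endpointParams = "list",
    fibrosisParams = "list",
    seed = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@groups) != 2L)
    msg <- c(msg, "exactly two groups are required")
  if (any(diff(object@agesWeeks) <= 0))
    msg <- c(msg, "agesWeeks must be strictly increasing")
  if (object@nPerCohort < 2L)
    msg <- c(msg, "nPerCohort must be at least 2")
  for (an in names(object@endpointParams)) {
    p <- object@endpointParams[[an]]
    if (!is.matrix(p$logMean) ||
        !identical(dim(p$logMean),
                   c(length(object@groups), length(object@agesWeeks))))
      msg <- c(msg, sprintf("endpointParams[['%s']]$logMean must be a group x age matrix", an))
    if (!is.numeric(p$logSd) || p$logSd <= 0)
      msg <- c(msg, sprintf("endpointParams[['%s']]$logSd must be > 0", an))
  }
  fp <- object@fibrosisParams
  if (!is.matrix(fp$severity) ||
      !identical(dim(fp$severity),
                 c(length(object@groups), length(object@agesWeeks))))
    msg <- c(msg, "fibrosisParams$severity must be a group x age matrix")
  if (!is.null(fp$couplings)) {
    sds <- unlist(lapply(fp$couplings, function(cc) {
      if (!is.null(cc$sd)) cc$sd
      else vapply(cc, function(z) z$sd, 0)
    }))
    if (any(sds < 0))
      msg <- c(msg, "coupling noise sd must be non-negative")
  }
  if (!is.null(fp$trichromeThresholds) &&
      any(diff(fp$trichromeThresholds) <= 0))
    msg <- c(msg, "trichromeThresholds must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", paste(object@groups, collapse = " vs "),
      "| ages (weeks):", paste(object@agesWeeks, collapse = ", "),
      "| n =", object@nPerCohort, "per cohort\n")
  cat("  analytes:",
      paste(c(names(object@endpointParams),
              names(object@fibrosisParams$couplings)), collapse = ", "), "\n")
})

#' CountSimParams: parameters of the negative-binomial count simulator
#'
#' Construct with [countSimParams()]. Programmed differential expression
#' is expressed as per-age obese/lean fold-change trajectories; the five
#' designated podocyte-specific genes carry a programmed decline
#' trajectory (obese/lean expression ratio per age).
#'
#' @slot nGenes number of genes.
#' @slot baselineLogMeanSd meanlog/sdlog of the log-normal distribution of
#'   relative gene abundances.
#' @slot dispersion scalar negative-binomial dispersion phi
#'   (variance = m + phi * m^2).
#' @slot degSpec list of programmed DE blocks, each
#'   `list(genes =, log2fc = per-age numeric)`.
#' @slot podocyteGenes character(5) gene identifiers.
#' @slot podocyteTrajectory obese/lean expression ratio per age.
#' @slot geneLengths gene lengths in bp.
#' @slot librarySize expected reads per sample.
#' @slot seed integer seed.
#' @seealso [countSimParams()], [simulateCounts()]
#' @export
setClass("CountSimParams",
  representation(
    nGenes = "integer",
    baselineLogMeanSd = "numeric",
    dispersion = "numeric",
    degSpec = "list",
    podocyteGenes = "character",
    podocyteTrajectory = "numeric",
    geneLengths = "numeric",
    librarySize = "numeric",
    seed = "integer"
  )
)

setValidity("CountSimParams", function(object) {
  msg <- character()
  if (any(object@dispersion <= 0))
    msg <- c(msg, "dispersion must be > 0")
  if (any(object@geneLengths < 1))
    msg <- c(msg, "gene lengths must be >= 1 bp")
  if (length(object@geneLengths) != object@nGenes)
    msg <- c(msg, "geneLengths must have one entry per gene")
  if (length(object@podocyteGenes) &&
      length(object@podocyteTrajectory) == 0L)
    msg <- c(msg, "podocyte genes require a decline trajectory")
  if (object@librarySize <= 0)
    msg <- c(msg, "librarySize must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CountSimParams", function(object) {
  cat("CountSimParams:", object@nGenes, "genes, dispersion",
      object@dispersion, ", library size", format(object@librarySize),
      "\n  programmed DE blocks:", length(object@degSpec),
      "| podocyte genes:", paste(object@podocyteGenes, collapse = ", "), "\n")
})
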