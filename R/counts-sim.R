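#' Default podocyte-specific marker genes
#'
#' The five podocyte-specific transcripts tracked by the composite
#' statistic: Nephrin (Nphs1), Podocin (Nphs2), WT-1 (Wt1), Synaptopodin
#' (Synpo) and GLEPP1 (Ptpro).
#' @export
podocyteMarkerGenes <- c("Nphs1", "Nphs2", "Wt1", "Synpo", "Ptpro")

#' Construct parameters for the negative-binomial count simulator
#'
#' Gene relative abundances are log-normal; each programmed
#' differential-expression block carries a per-age log2 fold-change
#' trajectory (obese over lean). By default four blocks are programmed —
#' 40 genes 4-fold up and 40 genes 4-fold down at every age, plus 15
#' genes each whose log2 fold change ramps up (or down) progressively
#' with age — and the
#' five podocyte marker genes decline along the obese/lean expression
#' ratio trajectory `(1, 0.9, 0.8, 0.7, 0.35, 0.25)`, i.e. a ~75 percent
#' reduction by the final age.
#'
#' @param nGenes number of genes (the five podocyte genes occupy the last
#'   five slots).
#' @param baselineLogMeanSd length-2 numeric: meanlog and sdlog of the
#'   log-normal relative-abundance distribution.
#' @param dispersion negative-binomial dispersion phi
#'   (variance = m + phi m^2).
#' @param degSpec list of programmed blocks, each
#'   `list(genes = character, log2fc = per-age numeric)`; `NULL` installs
#'   the default blocks above.
#' @param podocyteGenes character(5) podocyte marker gene ids.
#' @param podocyteTrajectory per-age obese/lean expression ratio for the
#'   podocyte genes.
#' @param geneLengths per-gene length in bp, or `NULL` to draw uniformly
#'   from 500-5000 bp.
#' @param librarySize expected reads per sample.
#' @param nAges number of study ages the trajectories must cover.
#' @param seed integer seed.
#' @return a [CountSimParams-class].
#' @examples
#' countSimParams(nGenes = 500)
#' @export
countSimParams <- function(nGenes = 2000L,
                           baselineLogMeanSd = c(0, 1.2),
                           dispersion = 0.1,
                           degSpec = NULL,
                           podocyteGenes = podocyteMarkerGenes,
                           podocyteTrajectory = c(1, 0.9, 0.8, 0.7, 0.35, 0.25),
                           geneLengths = NULL,
                           librarySize = 2e7,
                           nAges = length(podocyteTrajectory),
                           seed = 1L) {
  nGenes <- as.integer(nGenes)
  stopifnot(nGenes > length(podocyteGenes))
  if (is.null(degSpec)) {
    # default blocks occupy genes g0001-g0110; up- and down-regulated
    # blocks are kept comparable in size so programmed DE perturbs the
    # library composition (and hence RPKM fold changes) only mildly
    stopifnot(nGenes >= 110L + length(podocyteGenes))
    gid <- function(i) sprintf("g%04d", i)
    ramp <- seq(0.3, by = 0.5, length.out = nAges)
    degSpec <- list(
      up4 = list(genes = gid(1:40), log2fc = rep(2, nAges)),
      down4 = list(genes = gid(41:80), log2fc = rep(-2, nAges)),
      prog_up = list(genes = gid(81:95), log2fc = ramp),
      prog_down = list(genes = gid(96:110), log2fc = -ramp)
    )
  }
  if (is.null(geneLengths)) {
    geneLengths <- with_seed(deriveSeed(seed, "gene_lengths"),
                             round(runif(nGenes, 500, 5000)))
  }
  new("CountSimParams",
      nGenes = nGenes, baselineLogMeanSd = baselineLogMeanSd,
      dispersion = dispersion, degSpec = degSpec,
      podocyteGenes = podocyteGenes,
      podocyteTrajectory = podocyteTrajectory,
      geneLengths = as.numeric(geneLengths),
      librarySize = librarySize, seed = as.integer(seed))
}

#' Simulate a gene x sample count matrix with programmed DE
#'
#' Draws negative-binomial counts for the full group x age x replicate
#' design: `count[g, s] ~ NB(mean = librarySize * p_g * FC(g, cohort(s)),
#' dispersion)`, where `p_g` are normalized log-normal relative
#' abundances, lean cohorts carry `FC = 1`, and obese cohorts carry the
#' programmed per-age fold changes (including the podocyte-gene decline).
#' Gene names are `g0001 ...` with the podocyte marker genes occupying
#' the final rows under their own symbols.
#'
#' @param params a [CountSimParams-class].
#' @param design a [StudyDesign-class] supplying groups, ages and
#'   replicates.
#' @param seed optional integer overriding `params@seed`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowData(x)$gene_length`, colData `group` / `age_week`,
#'   and `metadata(x)$truth`, a `data.frame(gene, age_week,
#'   log2_fc_programmed)` listing every non-null gene (the module's
#'   parameter-recovery contract).
#' @examples
#' se <- simulateCounts(countSimParams(nGenes = 400), studyDesign(nPerCohort = 3L))
#' dim(se)
#' @export
simulateCounts <- function(params, design, seed = NULL) {
  stopifnot(is(params, "CountSimParams"), is(design, "StudyDesign"))
  validObject(params)
  if (is.null(seed)) seed <- params@seed
  nG <- params@nGenes
  ages <- design@agesWeeks
  nAges <- length(ages)
  np <- length(params@podocyteGenes)
  if (np && length(params@podocyteTrajectory) != nAges)
    stop("podocyte trajectory must define a ratio for every study age")
  for (bl in params@degSpec) {
    if (length(bl$log2fc) != nAges)
      stop("every programmed fold-change trajectory must cover all ",
           nAges, " study ages")
  }

  genes <- sprintf("g%04d", seq_len(nG))
  if (np) genes[(nG - np + 1L):nG] <- params@podocyteGenes

  # relative abundances; podocyte markers pinned at a high-expression level
  p <- with_seed(deriveSeed(seed, "abundance"), {
    a <- rlnorm(nG, params@baselineLogMeanSd[1], params@baselineLogMeanSd[2])
    if (np) a[(nG - np + 1L):nG] <-
      exp(params@baselineLogMeanSd[1] + 2 * params@baselineLogMeanSd[2])
    a / sum(a)
  })
  if (any(p == 0))
    stop("zero baseline abundance is not allowed")

  # obese/lean fold change per gene x age (lean is the FC = 1 reference)
  fc <- matrix(1, nG, nAges, dimnames = list(genes, ages))
  truth <- list()
  for (bn in names(params@degSpec)) {
    bl <- params@degSpec[[bn]]
    miss <- setdiff(bl$genes, genes)
    if (length(miss))
      stop("programmed genes absent from the matrix: ",
           paste(utils::head(miss, 3), collapse = ", "))
    fc[bl$genes, ] <- matrix(2^bl$log2fc, length(bl$genes), nAges,
                             byrow = TRUE)
    truth[[bn]] <- data.frame(
      gene = rep(bl$genes, each = nAges), age_week = rep(ages, length(bl$genes)),
      log2_fc_programmed = rep(bl$log2fc, length(bl$genes)), block = bn
    )
  }
  if (np) {
    fc[params@podocyteGenes, ] <-
      matrix(params@podocyteTrajectory, np, nAges, byrow = TRUE)
    truth[["podocyte"]] <- data.frame(
      gene = rep(params@podocyteGenes, each = nAges),
      age_week = rep(ages, np),
      log2_fc_programmed = rep(log2(params@podocyteTrajectory), np),
      block = "podocyte"
    )
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))

  groups <- design@groups
  n <- design@nPerCohort
  meta <- expand.grid(rep = seq_len(n), age_week = ages, group = groups,
                      stringsAsFactors = FALSE)[, c("group", "age_week", "rep")]
  meta$sample_id <- sprintf("%s_%gw_%d", meta$group, meta$age_week, meta$rep)

  counts <- with_seed(deriveSeed(seed, "counts"), {
    m <- matrix(0L, nG, nrow(meta), dimnames = list(genes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      ai <- match(meta$age_week[j], ages)
      f <- if (meta$group[j] == groups[1]) rep(1, nG) else fc[, ai]
      mu <- params@librarySize * p * f
      m[, j] <- rnbinom(nG, mu = mu, size = 1 / params@dispersion)
    }
    m
  })

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = params@geneLengths,
                                   row.names = genes),
    colData = S4Vectors::DataFrame(
      sample_id = meta$sample_id, group = meta$group,
      age_week = meta$age_week, row.names = meta$sample_id
    ),
    metadata = list(truth = truth, seed = as.integer(seed))
  )
}

#' Programmed differential-expression truth table of a simulated matrix
#'
#' @param se a `SummarizedExperiment` from [simulateCounts()].
#' @return the truth `data.frame(gene, age_week, log2_fc_programmed,
#'   block)`.
#' @export
degTruth <- function(se) S4Vectors::metadata(se)$truth
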