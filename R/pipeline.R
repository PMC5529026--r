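#' Build a pipeline run configuration
#'
#' Collects every stage parameter with its conventional default into a
#' single list that round-trips losslessly through JSON. One master seed
#' fans out to independent per-stage substreams by stable hashing, so
#' toggling one stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param nGlomeruliPerAnimal,sectionsPerGlomerulus,glomRadius,nPodTrue,nucRadius
#'   stereology-simulation settings (per-animal glomeruli, sections per
#'   glomerulus, sphere radius um, true podocyte count, nuclear radius um).
#' @param minRelArea grazing-profile exclusion threshold (see
#'   [sampleProfiles()]).
#' @param coefficients a [StereologyCoefficients-class].
#' @param nGenes,dispersion,librarySize count-simulation settings.
#' @param fcThresh,rpkmThresh,alpha DEG-calling thresholds.
#' @param pseudocount RPKM pseudocount.
#' @param nPerCohort animals per group x age cohort.
#' @return a named list (class `podometricsConfig`).
#' @export
runConfig <- function(seed = 1L,
                      nGlomeruliPerAnimal = 4L,
                      sectionsPerGlomerulus = 11L,
                      glomRadius = 50, nPodTrue = 200L, nucRadius = 3,
                      minRelArea = 0,
                      coefficients = stereologyCoefficients(),
                      nGenes = 2000L, dispersion = 0.1, librarySize = 2e6,
                      fcThresh = 2, rpkmThresh = 0.5, alpha = 0.05,
                      pseudocount = 0.25,
                      nPerCohort = 5L) {
  cfg <- list(
    seed = as.integer(seed),
    nGlomeruliPerAnimal = as.integer(nGlomeruliPerAnimal),
    sectionsPerGlomerulus = as.integer(sectionsPerGlomerulus),
    glomRadius = glomRadius, nPodTrue = as.integer(nPodTrue),
    nucRadius = nucRadius, minRelArea = minRelArea,
    coefficients = list(kNuc = coefficients@kNuc,
                        betaNuc = coefficients@betaNuc,
                        betaGlom = coefficients@betaGlom,
                        kGlom = coefficients@kGlom),
    nGenes = as.integer(nGenes), dispersion = dispersion,
    librarySize = librarySize,
    fcThresh = fcThresh, rpkmThresh = rpkmThresh, alpha = alpha,
    pseudocount = pseudocount,
    nPerCohort = as.integer(nPerCohort)
  )
  class(cfg) <- c("podometricsConfig", "list")
  cfg
}

#' Read / write a pipeline configuration
#'
#' @param cfg a configuration from [runConfig()].
#' @param path JSON file path.
#' @return `readConfig` returns the configuration; `writeConfig` returns
#'   `path` invisibly.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("podometricsConfig", "list")
  cfg
}

.cfgCoeffs <- function(cfg) {
  with(cfg$coefficients,
       stereologyCoefficients(kNuc, betaNuc, betaGlom, kGlom))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: simulate the study (glomerular
#' profiles per animal, endpoint table with latent-fibrosis truth, count
#' matrix with programmed DE), then run stereology (per-animal
#' Weibel-Gomez estimates), morphometry (trichrome score vs latent
#' severity), the transcriptome stage (per-age DEG calls, podocyte
#' composite, PCA), and endpoint statistics (creatinine normalization,
#' week-41 microalbumin fold change, ANOVA/Tukey families, uC3M
#' correlations). Every table is written as TSV with a seed-bearing
#' comment line, and a JSON manifest records the seed, a parameter hash
#' and per-file checksums.
#'
#' @param config a configuration from [runConfig()].
#' @param outDir output directory (created if absent).
#' @param stages character subset of
#'   `c("simulate", "stereology", "morphometry", "degs", "endpoints")`;
#'   the consolidated report and manifest are always written.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = runConfig(), outDir,
                        stages = c("simulate", "stereology", "morphometry",
                                   "degs", "endpoints")) {
  stopifnot(inherits(config, "podometricsConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  tag <- sprintf("seed=%d", seed)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeTsv(df, p, tag)
    written <<- c(written, p)
    p
  }
  msg <- function(...) message(format(Sys.time(), "%H:%M:%S"), " INFO ", ...)
  res <- list()

  design <- studyDesign(nPerCohort = config$nPerCohort, seed = seed)

  if ("simulate" %in% stages) {
    msg("simulate: study endpoints, glomerular profiles, counts")
    study <- simulateStudy(design, seed = deriveSeed(seed, "study"))
    res$study <- study
    emit(study$endpoints, "endpoints.tsv")
    emit(study$truth, "truth_animals.tsv")

    animals <- unique(study$truth$animal_id)
    prof <- do.call(rbind, lapply(seq_along(animals), function(i) {
      gl <- lapply(seq_len(config$nGlomeruliPerAnimal), function(j)
        makeGlomerulus(config$glomRadius, config$nPodTrue, config$nucRadius,
                       seed = deriveSeed(seed, paste0("glom", i, "_", j))))
      p <- sampleProfiles(gl, config$sectionsPerGlomerulus,
                          config$minRelArea,
                          seed = deriveSeed(seed, paste0("sections", i)))
      p$animal_id <- animals[i]
      p
    }))
    res$profiles <- prof
    emit(prof, "profiles.tsv")

    se <- simulateCounts(
      countSimParams(nGenes = config$nGenes, dispersion = config$dispersion,
                     librarySize = config$librarySize,
                     seed = deriveSeed(seed, "counts")),
      design)
    res$counts <- se
    cm <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
    emit(cbind(gene = rownames(se), cm), "counts.tsv")
    emit(data.frame(gene = rownames(se),
                    length_bp = SummarizedExperiment::rowData(se)$gene_length),
         "gene_lengths.tsv")
    emit(as.data.frame(SummarizedExperiment::colData(se)), "samples.tsv")
    emit(degTruth(se), "truth_degs.tsv")
  }

  if ("stereology" %in% stages) {
    if (is.null(res$profiles)) {
      p <- file.path(outDir, "profiles.tsv")
      if (!file.exists(p)) stop("missing input: ", p)
      res$profiles <- readTsv(p)
    }
    msg("stereology: Weibel-Gomez per-animal estimates")
    est <- podocytesByAnimal(res$profiles, .cfgCoeffs(config))
    res$stereology <- est
    emit(est, "podocyte_estimates.tsv")
  }

  if ("morphometry" %in% stages && !is.null(res$study)) {
    msg("morphometry: trichrome score vs latent severity")
    tr <- res$study$truth
    rho <- scoreVsSeverity(
      data.frame(animal_id = tr$animal_id, score = tr$trichrome_score),
      tr)
    res$morphometry <- data.frame(metric = "spearman_score_vs_severity",
                                  value = rho)
    emit(res$morphometry, "morphometry.tsv")
  }

  if ("degs" %in% stages && !is.null(res$counts)) {
    msg("degs: per-age DEG calls, podocyte composite, PCA")
    degs <- callDEGsByAge(res$counts, config$fcThresh, config$rpkmThresh,
                          config$alpha, config$pseudocount)
    res$degs <- degs
    degTab <- do.call(rbind, lapply(names(degs), function(a)
      cbind(age_week = as.numeric(a), degs[[a]])))
    emit(degTab, "degs.tsv")
    comp <- podocyteComposite(res$counts)
    res$composite <- comp
    emit(comp$composite, "podocyte_composite.tsv")
    pca <- pcaExpressed(res$counts)
    res$pca <- pca
    emit(pca$scores[, seq_len(min(ncol(pca$scores), 7L))], "pca_scores.tsv")
  }

  if ("endpoints" %in% stages && !is.null(res$study)) {
    msg("endpoints: normalization, fold change, ANOVA/Tukey, correlations")
    ep <- res$study$endpoints
    ua <- ep[!is.na(ep$urine_creatinine), ]
    ratios <- normalizeToCreatinine(ua)
    emit(ratios, "endpoint_ratios.tsv")
    malb <- ratios[ratios$analyte == "microalbumin", ]
    lastAge <- max(malb$age_week)
    fc <- groupFoldChange(malb$ratio, malb$group, malb$age_week, lastAge)
    stat <- anovaTukey(malb$ratio, malb$group, malb$age_week,
                       alpha = config$alpha)
    uc3m <- ratios[ratios$analyte == "uC3M", ]
    m <- merge(uc3m[, c("animal_id", "ratio")],
               malb[, c("animal_id", "ratio")], by = "animal_id",
               suffixes = c("_uc3m", "_malb"))
    m <- merge(m, res$study$truth[, c("animal_id", "trichrome_score")],
               by = "animal_id")
    corAlb <- correlateEndpoints(m$ratio_uc3m, m$ratio_malb)
    corTri <- correlateEndpoints(m$ratio_uc3m, m$trichrome_score)
    res$endpoints <- list(fold_change = fc, anova = stat,
                          cor_uc3m_malb = corAlb, cor_uc3m_trichrome = corTri)
    emit(data.frame(
      comparison = c("uC3M_vs_microalbumin", "uC3M_vs_trichrome"),
      rbind(corAlb, corTri)), "correlations.tsv")
    emit(cbind(family = rep(names(stat), vapply(stat, nrow, 0L)),
               do.call(rbind, stat)), "anova_tukey.tsv")
    emit(data.frame(age_week = lastAge, fold = fc$fold,
                    headline = fc$headline), "fold_change.tsv")
  }

  # consolidated report + manifest
  report <- list(seed = seed, stages = stages)
  if (!is.null(res$stereology))
    report$mean_n_pod <- mean(res$stereology$n_pod)
  if (!is.null(res$composite))
    report$composite_last_age_pct <-
      utils::tail(res$composite$composite$composite_pct, 1)
  if (!is.null(res$endpoints)) {
    report$microalbumin_fold_last_age <- res$endpoints$fold_change$fold
    report$r2_uc3m_microalbumin <- res$endpoints$cor_uc3m_malb$r_squared
  }
  if (!is.null(res$morphometry))
    report$spearman_trichrome_severity <- res$morphometry$value
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfgPath <- file.path(outDir, "config.json")
  writeConfig(config, cfgPath)
  manifest <- list(
    seed = seed,
    parameter_hash = unname(tools::md5sum(cfgPath)),
    files = as.list(tools::md5sum(sort(c(written, cfgPath,
                                         file.path(outDir, "report.json")))))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$report <- report
  invisible(res)
}
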