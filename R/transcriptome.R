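#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm[g, s] = counts[g, s] * 1e9 / (length[g] * librarySize[s])`,
#' with the library size taken as the raw column sum.
#'
#' @param counts gene x sample non-negative count matrix, or a
#'   `SummarizedExperiment` with assay `counts` and
#'   `rowData(x)$gene_length`.
#' @param geneLengths per-gene length in bp (ignored for the
#'   `SummarizedExperiment` input).
#' @return RPKM matrix of the same shape.
#' @examples
#' rpkm(matrix(500, 1, 1, dimnames = list("g", "s")) , 2000)  # needs library
#' @export
rpkm <- function(counts, geneLengths = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    geneLengths <- SummarizedExperiment::rowData(counts)$gene_length
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  stopifnot(is.matrix(counts), length(geneLengths) == nrow(counts))
  if (any(geneLengths <= 0)) stop("zero-length gene")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  counts * 1e9 / outer(as.numeric(geneLengths), lib)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: order the m p-values increasingly, compute
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down
#' (running minimum), cap at 1, and return in the original order.
#'
#' @param p numeric p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv)
  adj <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out[ok][o] <- pmin(adj, 1)
  out
}

# Vectorised Welch two-sample t-test over matrix rows.
# Returns two-sided p-values; rows with zero variance in both groups get
# p = 1 when the means agree and p = 0 otherwise.
welchRows <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- apply(x[, idx1, drop = FALSE], 1, var)
  v2 <- apply(x[, idx2, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Call differentially expressed genes at one age
#'
#' Compares the obese cohort with the age-matched lean cohort. The
#' per-gene fold change is computed from cohort mean RPKM with a
#' pseudocount; the p-value comes from a Welch two-sample test on
#' `log2(RPKM + pseudocount)`; Benjamini-Hochberg adjustment runs across
#' all genes (no expression prefilter before testing). A gene is a DEG
#' iff fold change exceeds `fcThresh` (either direction), its mean RPKM
#' across the two cohorts exceeds `rpkmThresh`, and the adjusted p-value
#' is below `alpha`.
#'
#' @param se `SummarizedExperiment` with assay `counts`,
#'   `rowData(se)$gene_length` and colData `group` / `age_week`.
#' @param ageWeek the age (weeks) at which to compare cohorts.
#' @param fcThresh fold-change threshold (default 2).
#' @param rpkmThresh mean-expression threshold in RPKM (default 0.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param pseudocount RPKM pseudocount for fold change and log transform
#'   (default 0.25).
#' @param groups length-2 character: reference group then test group.
#' @return `data.frame(gene_id, log2_fc, mean_rpkm, p_value, adj_p,
#'   is_deg)`; `log2_fc` is test (obese) over reference (lean).
#' @export
callDEGs <- function(se, ageWeek, fcThresh = 2, rpkmThresh = 0.5,
                     alpha = 0.05, pseudocount = 0.25,
                     groups = c("lean", "obese")) {
  stopifnot(is(se, "SummarizedExperiment"))
  cd <- SummarizedExperiment::colData(se)
  idxRef <- which(cd$group == groups[1] & cd$age_week == ageWeek)
  idxTest <- which(cd$group == groups[2] & cd$age_week == ageWeek)
  if (length(idxRef) < 2L || length(idxTest) < 2L)
    stop("at least two samples per cohort are required at age ", ageWeek)
  r <- rpkm(se)
  lr <- log2(r + pseudocount)
  meanRef <- rowMeans(r[, idxRef, drop = FALSE])
  meanTest <- rowMeans(r[, idxTest, drop = FALSE])
  lfc <- log2((meanTest + pseudocount) / (meanRef + pseudocount))
  p <- welchRows(lr, idxTest, idxRef)
  adj <- bhAdjust(p)
  meanRpkm <- (meanRef + meanTest) / 2
  data.frame(
    gene_id = rownames(se),
    log2_fc = lfc,
    mean_rpkm = meanRpkm,
    p_value = p,
    adj_p = adj,
    is_deg = abs(lfc) > log2(fcThresh) & meanRpkm > rpkmThresh & adj < alpha,
    row.names = NULL
  )
}

#' Call DEGs at every study age
#'
#' @inheritParams callDEGs
#' @return named list of per-age DEG `data.frame`s (names are the ages).
#' @export
callDEGsByAge <- function(se, fcThresh = 2, rpkmThresh = 0.5, alpha = 0.05,
                          pseudocount = 0.25, groups = c("lean", "obese")) {
  ages <- sort(unique(SummarizedExperiment::colData(se)$age_week))
  setNames(lapply(ages, function(a)
    callDEGs(se, a, fcThresh, rpkmThresh, alpha, pseudocount, groups)),
    ages)
}

#' Podocyte-specific mRNA composite
#'
#' For each of the marker genes, the cohort value is the geometric mean
#' of `RPKM + eps` over the cohort's samples, normalized to the
#' youngest-age reference-group cohort of the same gene (fold change
#' relative to 12-week lean). The composite per test-group age is
#' `100 * mean over genes of geomean_test(age) / geomean_ref(age)` —
#' 100 percent means no reduction relative to age-matched reference
#' animals.
#'
#' @param se `SummarizedExperiment` with counts, gene lengths and
#'   colData `group` / `age_week`.
#' @param genes marker gene ids (default [podocyteMarkerGenes]); all must
#'   be present in the matrix.
#' @param eps small positive constant added before the geometric mean.
#' @param groups length-2 character: reference group then test group.
#' @return list with `perGene` (`data.frame(gene, group, age_week,
#'   rel_to_reference)`, the per-cohort normalized levels) and
#'   `composite` (`data.frame(age_week, composite_pct)`).
#' @export
podocyteComposite <- function(se, genes = podocyteMarkerGenes, eps = 0.01,
                              groups = c("lean", "obese")) {
  stopifnot(is(se, "SummarizedExperiment"))
  missing <- setdiff(genes, rownames(se))
  if (length(missing))
    stop("podocyte genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  cd <- SummarizedExperiment::colData(se)
  ages <- sort(unique(cd$age_week))
  r <- rpkm(se)[genes, , drop = FALSE]
  geo <- function(v) exp(mean(log(v + eps)))
  cohort <- expand.grid(group = groups, age_week = ages,
                        stringsAsFactors = FALSE)
  gm <- sapply(seq_len(nrow(cohort)), function(i) {
    idx <- which(cd$group == cohort$group[i] & cd$age_week == cohort$age_week[i])
    apply(r[, idx, drop = FALSE], 1, geo)
  })  # genes x cohorts
  refCol <- which(cohort$group == groups[1] & cohort$age_week == ages[1])
  perGene <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    data.frame(gene = genes, group = cohort$group[i],
               age_week = cohort$age_week[i],
               rel_to_reference = gm[, i] / gm[, refCol], row.names = NULL)
  }))
  composite <- vapply(ages, function(a) {
    ci <- which(cohort$group == groups[2] & cohort$age_week == a)
    cr <- which(cohort$group == groups[1] & cohort$age_week == a)
    100 * mean(gm[, ci] / gm[, cr])
  }, 0)
  list(perGene = perGene,
       composite = data.frame(age_week = ages, composite_pct = composite))
}

#' PCA of detectably expressed genes
#'
#' Retains genes whose overall mean RPKM exceeds `minMeanRpkm`, applies
#' `log2(x + 1)`, centres each gene, and computes sample scores by
#' singular-value decomposition (via `prcomp`, no scaling).
#'
#' @param se `SummarizedExperiment` (counts + gene lengths + colData).
#' @param minMeanRpkm expression threshold (default 0.5).
#' @return list with `scores` (`data.frame` of sample metadata plus PC
#'   columns) and `varExplained` (per-component variance fractions,
#'   summing to 1).
#' @export
pcaExpressed <- function(se, minMeanRpkm = 0.5) {
  stopifnot(is(se, "SummarizedExperiment"))
  if (ncol(se) < 3L) stop("at least three samples are required")
  r <- rpkm(se)
  keep <- rowMeans(r) > minMeanRpkm
  if (sum(keep) < 2L) stop("fewer than two genes pass the expression filter")
  x <- t(log2(r[keep, , drop = FALSE] + 1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  list(scores = cbind(cd, as.data.frame(pc$x)), varExplained = ve,
       nGenes = sum(keep))
}

#' Classify longitudinal DEG trajectories
#'
#' Two classes are extracted from per-age DEG calls:
#' \describe{
#'   \item{early_sustained}{significant (adjusted p < `alpha`) at every
#'     age, with fold change of at least `fcAll` (either direction) at
#'     every age.}
#'   \item{progressive}{significant at every age from the second onward,
#'     with a log2 fold-change sequence over those ages that is
#'     non-strictly monotone up to a tolerance of `tol` log2 units per
#'     step.}
#' }
#'
#' @param degByAge named list of per-age DEG `data.frame`s from
#'   [callDEGsByAge()] (one entry per study age, in age order).
#' @param fcAll stringent fold-change cut for the sustained class
#'   (default 3).
#' @param tol monotonicity tolerance in log2 units (default 0.1).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return list with character vectors `early_sustained` and
#'   `progressive`.
#' @export
classifyLongitudinal <- function(degByAge, fcAll = 3, tol = 0.1,
                                 alpha = 0.05) {
  if (length(degByAge) < 2L) stop("DEG calls at all study ages are required")
  genes <- degByAge[[1]]$gene_id
  for (d in degByAge) {
    if (!identical(d$gene_id, genes))
      stop("all per-age DEG tables must cover the same genes in order")
  }
  lfc <- sapply(degByAge, `[[`, "log2_fc")
  sig <- sapply(degByAge, function(d) !is.na(d$adj_p) & d$adj_p < alpha)
  sustained <- rowSums(sig) == ncol(sig) &
    apply(abs(lfc) >= log2(fcAll), 1, all)
  later <- seq(2L, ncol(sig))
  sigLater <- rowSums(sig[, later, drop = FALSE]) == length(later)
  mono <- apply(lfc[, later, drop = FALSE], 1, function(x) {
    d <- diff(x)
    all(d >= -tol) || all(d <= tol)
  })
  list(early_sustained = genes[sustained],
       progressive = genes[sigLater & mono])
}

#' Over-representation of a gene set among DEGs
#'
#' Right-tailed Fisher (hypergeometric upper-tail) test of the overlap
#' between the DEG list and a gene set within a fixed universe, plus a
#' simple signed direction score
#' `(n_up - n_down) / sqrt(overlap)` (0 for an empty overlap). The
#' direction score is a simplified summary of concordance and is not
#' equivalent to any proprietary pathway activation score.
#'
#' @param degGenes character vector of DEG identifiers (subset of
#'   `universe`).
#' @param degSigns optional named numeric (+1/-1 per DEG, names matching
#'   `degGenes`) giving each DEG's direction; `NULL` yields
#'   `direction_z = NA`.
#' @param geneSet character vector, the set to test (subset of
#'   `universe`).
#' @param universe character vector of all genes considered.
#' @return `data.frame(overlap, p_right, direction_z)`.
#' @examples
#' oraFisher(paste0("g", 1:4), NULL, paste0("g", c(1:3, 10, 11)),
#'           paste0("g", 1:20))  # p ~ 0.032
#' @export
oraFisher <- function(degGenes, degSigns = NULL, geneSet, universe) {
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (!all(geneSet %in% universe) || !all(degGenes %in% universe))
    stop("geneSet and degGenes must be subsets of the universe")
  ov <- intersect(degGenes, geneSet)
  k <- length(ov)
  pRight <- phyper(k - 1, length(geneSet),
                   length(universe) - length(geneSet),
                   length(degGenes), lower.tail = FALSE)
  dz <- if (k == 0L) 0 else if (is.null(degSigns)) NA_real_ else {
    s <- degSigns[ov]
    (sum(s > 0) - sum(s < 0)) / sqrt(k)
  }
  data.frame(overlap = k, p_right = pRight, direction_z = dz)
}
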