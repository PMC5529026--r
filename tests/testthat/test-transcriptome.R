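test_that("rpkm matches the hand-evaluated definition", {
  # two genes so the library size is under control
  counts <- matrix(c(500, 9999500), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  r <- rpkm(counts, c(2000, 1000))
  expect_equal(r["a", 1], 500 * 1e9 / (2000 * 1e7))  # 25
  expect_equal(r["a", 1], 25)
  # zero count gives zero
  counts["a", 1] <- 0
  expect_equal(rpkm(counts, c(2000, 1000))["a", 1], 0)
  expect_error(rpkm(counts, c(0, 1000)), "zero-length")
  # doubling all counts in a sample leaves its RPKM unchanged
  m <- matrix(rpois(20, 100), 10, 2)
  lens <- rep(1000, 10)
  expect_equal(rpkm(m * 2L, lens)[, 1], rpkm(m, lens)[, 1])
})

test_that("BH adjustment does textbook step-up and edge cases", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bhAdjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})

test_that("BH adjustment equals the independent reference on random vectors", {
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  }
})

test_that("DEG calling is null on self-comparisons and monotone in fc cut", {
  se <- toyCountSE()
  # duplicated cohorts: compare lean against itself by relabelling
  se2 <- se
  cd <- SummarizedExperiment::colData(se2)
  lean <- which(cd$group == "lean" & cd$age_week == 41)
  cd$group[lean[1:2]] <- "obese"  # split one cohort into two pseudo-groups
  keep <- c(lean, which(cd$group == "lean" & cd$age_week == 12))
  SummarizedExperiment::colData(se2) <- cd
  degsNull <- callDEGs(se2[, keep], 41)
  expect_equal(sum(degsNull$is_deg), 0L)

  degs1 <- callDEGs(se, 41, fcThresh = 2)
  degs2 <- callDEGs(se, 41, fcThresh = 1.2)
  expect_gte(sum(degs2$is_deg), sum(degs1$is_deg))

  expect_error(callDEGs(se[, 1:3], 41), "two samples")
})

test_that("podocyte composite recovers uniform scalings exactly", {
  se <- toyCountSE(nGenes = 200L)
  # construct a deterministic RPKM scenario: obese = lean * 0.5 on five genes
  counts <- SummarizedExperiment::assay(se)
  cd <- SummarizedExperiment::colData(se)
  genes <- sprintf("g%04d", 10:14)
  obese <- cd$group == "obese"
  counts[genes, obese] <- counts[genes, obese] %/% 2L
  # rebuild with near-deterministic counts: equal cohorts elsewhere
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = SummarizedExperiment::rowData(se),
    colData = cd)
  comp <- podocyteComposite(se2, genes = genes, eps = 1e-6)
  expect_true(all(abs(comp$composite$composite_pct - 50) < 2.5))
  # identical cohorts give ~100% (only sampling noise separates them)
  compSame <- podocyteComposite(
    se, genes = sprintf("g%04d", 15:19), eps = 1e-6)
  expect_true(all(abs(compSame$composite$composite_pct - 100) < 10))
  expect_error(podocyteComposite(se, genes = "absent_gene"), "absent")
})

test_that("composite is invariant to gene lengths and sample order", {
  d <- studyDesign(nPerCohort = 3L)
  se <- simulateCounts(countSimParams(nGenes = 400L, seed = 6L), d)
  comp <- podocyteComposite(se)
  # perturb lengths: pure ratio statistic is unchanged
  se2 <- se
  SummarizedExperiment::rowData(se2)$gene_length <-
    SummarizedExperiment::rowData(se)$gene_length * 3
  # invariance is exact up to the epsilon in the geometric mean
  expect_equal(podocyteComposite(se2)$composite, comp$composite,
               tolerance = 1e-3)
  # permute samples
  se3 <- se[, sample(ncol(se))]
  expect_equal(podocyteComposite(se3)$composite, comp$composite)
})

test_that("PCA of expressed genes is well normalized and separates groups", {
  d <- studyDesign(nPerCohort = 3L)
  se <- simulateCounts(countSimParams(nGenes = 400L, seed = 7L), d)
  pc <- pcaExpressed(se)
  expect_equal(sum(pc$varExplained), 1)
  expect_true(all(c("group", "age_week", "PC1") %in% names(pc$scores)))
  # identical samples land on identical scores
  cm <- SummarizedExperiment::assay(se)
  cm[, 2] <- cm[, 1]
  seDup <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cm),
    rowData = SummarizedExperiment::rowData(se),
    colData = SummarizedExperiment::colData(se))
  pcDup <- pcaExpressed(seDup)
  expect_equal(pcDup$scores$PC1[1], pcDup$scores$PC1[2])
  # strong programmed separation at the late ages shows up on PC1/PC2
  late <- pc$scores[pc$scores$age_week == 41, ]
  d12 <- dist(late[, c("PC1", "PC2")])
  sameGroup <- outer(late$group, late$group, "==")[lower.tri(diag(nrow(late)))]
  # silhouette-like check: between-group distances exceed within-group
  expect_gt(mean(as.vector(d12)[!sameGroup]), mean(as.vector(d12)[sameGroup]))
})

test_that("longitudinal classification applies the sustained and progressive rules", {
  ages <- c(12, 20, 24, 29, 34, 41)
  mk <- function(lfc, sig) {
    lapply(seq_along(ages), function(i)
      data.frame(gene_id = c("sust", "prog", "late", "flat"),
                 log2_fc = lfc[, i],
                 adj_p = ifelse(sig[, i], 0.01, 0.5),
                 mean_rpkm = 10, p_value = 0.01, is_deg = sig[, i]))
  }
  lfc <- rbind(
    sust = rep(2, 6),                      # |FC| = 4 >= 3 everywhere
    prog = c(0.2, 1.2, 1.8, 2.3, 3.0, 3.4),
    late = c(0.1, 0.2, 2.5, 2.2, 2.6, 2.7),  # non-monotone beyond tol
    flat = rep(0.5, 6)
  )
  sig <- rbind(
    sust = rep(TRUE, 6),
    prog = c(FALSE, rep(TRUE, 5)),         # significant from the 2nd age
    late = c(FALSE, rep(TRUE, 5)),
    flat = rep(FALSE, 6)
  )
  cl <- classifyLongitudinal(mk(lfc, sig))
  expect_true("sust" %in% cl$early_sustained)
  expect_true("prog" %in% cl$progressive)
  expect_true("sust" %in% cl$progressive)  # constant-high is monotone too
  expect_false("late" %in% cl$progressive)
  expect_false("flat" %in% cl$progressive)
  expect_false("prog" %in% cl$early_sustained)
})

test_that("programmed sustained and progressive genes are recovered", {
  d <- studyDesign(nPerCohort = 4L)
  se <- simulateCounts(countSimParams(nGenes = 600L, dispersion = 0.01,
                                      seed = 11L), d)
  degs <- callDEGsByAge(se)
  cl <- classifyLongitudinal(degs)
  tr <- degTruth(se)
  up4 <- unique(tr$gene[tr$block == "up4"])
  down4 <- unique(tr$gene[tr$block == "down4"])
  prog <- unique(tr$gene[tr$block %in% c("prog_up", "prog_down")])
  expect_gt(mean(c(up4, down4) %in% cl$early_sustained), 0.95)
  expect_gt(mean(prog %in% cl$progressive), 0.9)
})

test_that("over-representation matches exact hypergeometric probabilities", {
  uni <- paste0("g", 1:20)
  res <- oraFisher(paste0("g", 1:4), NULL, paste0("g", c(1:3, 10, 11)), uni)
  expect_equal(res$overlap, 3L)
  # C(5,3) C(15,1) / C(20,4) + C(5,4) C(15,0) / C(20,4)
  expect_equal(res$p_right, (choose(5, 3) * 15 + choose(5, 4)) / choose(20, 4))
  expect_equal(res$p_right, 0.0319917, tolerance = 1e-5)

  # zero overlap: p = 1, direction 0
  res0 <- oraFisher(paste0("g", 1:4), NULL, paste0("g", 15:18), uni)
  expect_equal(res0$p_right, 1)
  expect_equal(res0$direction_z, 0)

  # all overlapping genes up: direction = sqrt(overlap)
  signs <- setNames(rep(1, 4), paste0("g", 1:4))
  resUp <- oraFisher(paste0("g", 1:4), signs, paste0("g", 1:6), uni)
  expect_equal(resUp$direction_z, sqrt(4))
  expect_lte(abs(resUp$direction_z), sqrt(resUp$overlap))

  expect_error(oraFisher("g1", NULL, "g1", character()), "universe")
  expect_error(oraFisher("x", NULL, "g1", uni), "subsets")
})

test_that("over-representation agrees with fisher.test across small tables", {
  set.seed(42)
  for (i in 1:30) {
    N <- sample(8:30, 1)
    uni <- paste0("g", 1:N)
    set <- sample(uni, sample(1:(N - 1), 1))
    deg <- sample(uni, sample(1:(N - 1), 1))
    ours <- oraFisher(deg, NULL, set, uni)$p_right
    k <- length(intersect(deg, set))
    tab <- matrix(c(k, length(deg) - k, length(set) - k,
                    N - length(deg) - length(set) + k), 2)
    ref <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})
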