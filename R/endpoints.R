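#' Normalize urinary analytes to urine creatinine
#'
#' Divides each urinary analyte value by the animal's urine creatinine
#' (mg/dL); for concentrations measured per dL the resulting ratio units
#' are analyte mass per mg creatinine (e.g. ug/mg).
#'
#' @param records endpoint `data.frame` with columns `value` and
#'   `urine_creatinine` (plus any identifier columns, carried through).
#' @return the input with an added `ratio` column (`value /
#'   urine_creatinine`).
#' @examples
#' normalizeToCreatinine(data.frame(value = 100, urine_creatinine = 50))
#' @export
normalizeToCreatinine <- function(records) {
  stopifnot(all(c("value", "urine_creatinine") %in% names(records)))
  if (any(is.na(records$urine_creatinine)))
    stop("urine creatinine is missing for ",
         sum(is.na(records$urine_creatinine)), " record(s)")
  if (any(records$urine_creatinine <= 0))
    stop("urine creatinine must be positive")
  records$ratio <- records$value / records$urine_creatinine
  records
}

#' Cohort fold change of an endpoint at one age
#'
#' Ratio of the obese-cohort arithmetic mean to the lean-cohort mean,
#' with a headline value rounded to the nearest ten (matching the
#' convention of reporting e.g. a "90-fold" difference).
#'
#' @param values numeric endpoint values (typically creatinine-normalized
#'   ratios).
#' @param group group label per value.
#' @param ageWeek age per value (weeks).
#' @param atAge the age at which to compare.
#' @param groups length-2 character: reference group then test group.
#' @return list with `fold` (raw ratio of means), `headline` (rounded to
#'   nearest ten), and the two cohort means.
#' @examples
#' groupFoldChange(c(47121, 526), c("obese", "lean"), c(41, 41), 41)
#' @export
groupFoldChange <- function(values, group, ageWeek, atAge,
                            groups = c("lean", "obese")) {
  sel <- ageWeek == atAge
  leanMean <- mean(values[sel & group == groups[1]])
  obeseMean <- mean(values[sel & group == groups[2]])
  if (!is.finite(leanMean) || !is.finite(obeseMean))
    stop("both cohorts must be non-empty at age ", atAge)
  if (leanMean == 0) stop("reference cohort mean is zero")
  fold <- obeseMean / leanMean
  list(fold = fold, headline = round(fold / 10) * 10,
       mean_reference = leanMean, mean_test = obeseMean)
}

#' Two-way ANOVA with Tukey comparison families
#'
#' Fits an ANOVA over the group x age cell means (equivalently a two-way
#' layout with interaction) and applies Tukey's multiple-comparisons
#' adjustment over all cell pairs. Two comparison families are
#' extracted, mirroring the standard longitudinal reporting convention:
#' \describe{
#'   \item{obese_vs_lean}{test group vs the age-matched reference group
#'     at each age (the `*` comparisons).}
#'   \item{obese_vs_baseline}{each test-group cohort vs the test group at
#'     the first age (the dagger comparisons).}
#' }
#'
#' @param values numeric endpoint values.
#' @param group,ageWeek group label and age per value.
#' @param alpha significance threshold on the Tukey-adjusted p
#'   (default 0.05).
#' @param groups length-2 character: reference group then test group.
#' @return list of two `data.frame`s (`obese_vs_lean`,
#'   `obese_vs_baseline`), each with `age_week`, `p_adj`, `significant`.
#' @export
anovaTukey <- function(values, group, ageWeek, alpha = 0.05,
                       groups = c("lean", "obese")) {
  stopifnot(length(values) == length(group),
            length(values) == length(ageWeek))
  tab <- table(group, ageWeek)
  if (any(tab < 2))
    stop("at least two animals are required in every group x age cell")
  cell <- factor(paste(group, ageWeek, sep = "@"))
  fit <- aov(values ~ cell)
  tk <- TukeyHSD(fit)$cell
  ages <- sort(unique(ageWeek))
  lookup <- function(a, b) {
    i <- match(paste(a, b, sep = "-"), rownames(tk))
    if (is.na(i)) i <- match(paste(b, a, sep = "-"), rownames(tk))
    tk[i, "p adj"]
  }
  fam1 <- data.frame(
    age_week = ages,
    p_adj = vapply(ages, function(a)
      lookup(paste(groups[2], a, sep = "@"),
             paste(groups[1], a, sep = "@")), 0)
  )
  fam1$significant <- fam1$p_adj <= alpha
  base <- paste(groups[2], ages[1], sep = "@")
  laterAges <- ages[-1]
  fam2 <- data.frame(
    age_week = laterAges,
    p_adj = vapply(laterAges, function(a)
      lookup(paste(groups[2], a, sep = "@"), base), 0)
  )
  fam2$significant <- fam2$p_adj <= alpha
  list(obese_vs_lean = fam1, obese_vs_baseline = fam2)
}

#' Linear correlation between two endpoint series
#'
#' Ordinary least-squares regression of `y` on `x` over all animals
#' pooled (both groups), reporting slope, intercept and the coefficient
#' of determination.
#'
#' @param x,y paired numeric vectors (one value per animal).
#' @return one-row `data.frame(slope, intercept, r_squared, n)`.
#' @examples
#' correlateEndpoints(1:10, 2 * (1:10))  # r_squared = 1
#' @export
correlateEndpoints <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least three paired observations are required")
  if (var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  # a perfect fit is a legitimate input here, not a modelling mistake
  r2 <- if (var(y) == 0) 0
        else suppressWarnings(summary(fit)$r.squared)
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             r_squared = r2, n = length(x))
}
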