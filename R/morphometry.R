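#' Systematic checkerboard quadrat selection
#'
#' Implements "every other quadrat" selection of glomerular tufts: the
#' image plane is tiled from the origin into squares of side
#' `quadratSize`, and a centroid at (x, y) is selected iff
#' `floor(x/q) + floor(y/q)` is even (a checkerboard). Deterministic and
#' unbiased under random tuft placement (half the plane is selected).
#'
#' @param x,y centroid coordinates (same length).
#' @param quadratSize quadrat side length (> 0), same units as `x`, `y`.
#' @return logical vector: `TRUE` for selected centroids.
#' @examples
#' quadratSelect(c(50, 150, 50, 150), c(50, 50, 150, 150), 100)
#' @export
quadratSelect <- function(x, y, quadratSize) {
  if (quadratSize <= 0) stop("quadratSize must be positive")
  stopifnot(length(x) == length(y))
  (floor(x / quadratSize) + floor(y / quadratSize)) %% 2 == 0
}

#' Stain-positive area summaries per glomerular tuft
#'
#' Summarizes per-tuft stain measurements into (i) the mean stain area
#' per tuft (unweighted over tufts), (ii) percent of tuft area (pooled
#' totals: `100 * sum(stain) / sum(tuft)`), and (iii) percent of
#' whole-kidney section area when a reference area is supplied.
#'
#' @param measurements `data.frame` with columns `tuft_area_um2` and
#'   `stain_area_um2` (0 <= stain <= tuft).
#' @param referenceArea whole-kidney section area (um^2) for the
#'   whole-kidney percentage, or `NULL` (the percentage is then `NA`).
#' @param perTuftPercent if `TRUE`, percent-of-tuft is instead the mean
#'   of per-tuft percentages (exposed as an alternative; pooled totals
#'   are the default because they are robust to tiny tufts).
#' @return list with `mean_stain_area_um2`, `pct_of_tuft`,
#'   `pct_of_kidney`, `n_tufts`.
#' @examples
#' stainSummary(data.frame(tuft_area_um2 = c(4000, 6000),
#'                         stain_area_um2 = c(400, 900)))
#' @export
stainSummary <- function(measurements, referenceArea = NULL,
                         perTuftPercent = FALSE) {
  req <- c("tuft_area_um2", "stain_area_um2")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "))
  if (nrow(measurements) == 0L) stop("at least one tuft is required")
  with(measurements, {
    if (any(stain_area_um2 < 0) || any(stain_area_um2 > tuft_area_um2 + 1e-9))
      stop("stain area must lie in [0, tuft area]")
    NULL
  })
  pct <- if (perTuftPercent) {
    mean(100 * measurements$stain_area_um2 / measurements$tuft_area_um2)
  } else {
    100 * sum(measurements$stain_area_um2) / sum(measurements$tuft_area_um2)
  }
  list(
    mean_stain_area_um2 = mean(measurements$stain_area_um2),
    pct_of_tuft = pct,
    pct_of_kidney = if (is.null(referenceArea)) NA_real_
                    else 100 * sum(measurements$stain_area_um2) / referenceArea,
    n_tufts = nrow(measurements)
  )
}

#' Areas from binary tuft and stain masks
#'
#' Converts a pair of binary rasters (tuft region, stain-positive
#' region) into a tuft measurement; stain pixels outside the tuft are
#' excluded before counting, and areas are pixel counts times
#' `pixelSize^2`.
#'
#' @param tuftMask,stainMask logical/0-1 matrices of identical shape.
#' @param pixelSize pixel edge length, micrometres.
#' @return list with `tuft_area_um2` and `stain_area_um2`.
#' @export
maskAreas <- function(tuftMask, stainMask, pixelSize) {
  if (!identical(dim(tuftMask), dim(stainMask)))
    stop("tuft and stain masks must have the same shape")
  if (pixelSize <= 0) stop("pixelSize must be positive")
  tuft <- sum(tuftMask != 0)
  stain <- sum(tuftMask != 0 & stainMask != 0)
  list(tuft_area_um2 = tuft * pixelSize^2,
       stain_area_um2 = stain * pixelSize^2)
}

#' Rank agreement between ordinal fibrosis scores and latent severity
#'
#' Spearman rank correlation between pathologist-style ordinal 1-5
#' trichrome scores and the simulator's latent fibrosis severity,
#' used to validate the scoring contract (the score is only required to
#' be a monotone discretization of severity).
#'
#' @param scores `data.frame(animal_id, score)` with ordinal scores.
#' @param truth `data.frame(animal_id, severity)` latent ground truth.
#' @return Spearman rho, or `NA` when either side is constant (ties-only
#'   degenerate input).
#' @export
scoreVsSeverity <- function(scores, truth) {
  stopifnot(all(c("animal_id", "score") %in% names(scores)),
            all(c("animal_id", "severity") %in% names(truth)))
  m <- merge(scores, truth[, c("animal_id", "severity")], by = "animal_id")
  if (nrow(m) < 2L) stop("at least two paired animals are required")
  if (length(unique(m$score)) < 2L || length(unique(m$severity)) < 2L)
    return(NA_real_)
  cor(m$score, m$severity, method = "spearman")
}
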