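#' Summarize glomerular profiles into areal statistics
#'
#' Pools a set of 2D glomerular cross-sectional profiles into the four
#' areal statistics the Weibel-Gomez chain consumes. Ratios of unweighted
#' means over profiles are used (equivalently, ratios of totals), which
#' is unbiased under unequal profile areas:
#' \deqn{N_A = \bar{n}_{WT1} / \bar{A}_{tuft}, \quad
#'       A_A = \bar{A}_{WT1} / \bar{A}_{tuft}}
#' The mean nuclear size is total stained area over total nuclei counted,
#' reported as `NA` when no nuclei were counted at all.
#'
#' @param profiles `data.frame` with columns `tuft_area_um2`, `n_wt1`,
#'   `wt1_area_um2` (as produced by [sampleProfiles()] or read from a
#'   profiles TSV).
#' @return list with `N_A` (nuclei/um^2), `A_A` (areal fraction),
#'   `mean_tuft_area` (um^2), `mean_nuclear_size` (um^2, `NA` when the
#'   total count is zero), and `n_profiles`.
#' @examples
#' profileSummary(data.frame(tuft_area_um2 = 5000, n_wt1 = 10,
#'                           wt1_area_um2 = 250))
#' @export
profileSummary <- function(profiles) {
  req <- c("tuft_area_um2", "n_wt1", "wt1_area_um2")
  if (!all(req %in% names(profiles)))
    stop("profiles must have columns ", paste(req, collapse = ", "))
  if (nrow(profiles) == 0L) stop("at least one profile is required")
  if (any(profiles$tuft_area_um2 <= 0))
    stop("all tuft areas must be positive")
  if (any(profiles$wt1_area_um2 > profiles$tuft_area_um2 + 1e-9))
    stop("stained area cannot exceed tuft area")
  mt <- mean(profiles$tuft_area_um2)
  totN <- sum(profiles$n_wt1)
  list(
    N_A = mean(profiles$n_wt1) / mt,
    A_A = mean(profiles$wt1_area_um2) / mt,
    mean_tuft_area = mt,
    mean_nuclear_size = if (totN > 0) sum(profiles$wt1_area_um2) / totN
                        else NA_real_,
    n_profiles = nrow(profiles)
  )
}

#' Weibel-Gomez numerical density from areal statistics
#'
#' \deqn{N_V = (K/\beta) \sqrt{N_A^3 / A_A}}
#' with the nuclear distribution coefficient `K` and shape coefficient
#' `beta`. `N_A = 0` returns 0 regardless of `A_A` (an empty glomerulus
#' has zero density).
#'
#' @param N_A nuclear profiles per um^2.
#' @param A_A stained areal fraction (> 0 whenever `N_A > 0`).
#' @param coeffs a [StereologyCoefficients-class]; defaults to the
#'   conventional podocyte values (K = 1.1, beta = 1.45).
#' @return numerical density, nuclei per um^3.
#' @examples
#' nvWeibelGomez(0.002, 0.05)  # 3.0345e-4
#' @export
nvWeibelGomez <- function(N_A, A_A, coeffs = stereologyCoefficients()) {
  stopifnot(is(coeffs, "StereologyCoefficients"))
  if (N_A < 0) stop("N_A must be non-negative")
  if (N_A == 0) return(0)
  if (!is.finite(A_A) || A_A <= 0)
    stop("A_A must be positive when N_A > 0")
  (coeffs@kNuc / coeffs@betaNuc) * sqrt(N_A^3 / A_A)
}

#' Weibel-Gomez glomerular volume from mean tuft area
#'
#' \deqn{V_{glom} = \bar{A}_{tuft}^{3/2} \cdot \beta / K}
#' with shape coefficient `beta` (1.38 for a near-sphere) and
#' distribution coefficient `K` (1.01).
#'
#' @param meanTuftArea mean tuft profile area, um^2 (>= 0).
#' @param coeffs a [StereologyCoefficients-class].
#' @return glomerular volume, um^3.
#' @examples
#' vglomWeibelGomez(10000)  # 1.3663e6
#' @export
vglomWeibelGomez <- function(meanTuftArea, coeffs = stereologyCoefficients()) {
  stopifnot(is(coeffs, "StereologyCoefficients"))
  if (meanTuftArea < 0) stop("mean tuft area must be non-negative")
  meanTuftArea^1.5 * coeffs@betaGlom / coeffs@kGlom
}

#' Podocytes per glomerulus from density and volume
#'
#' \deqn{N_{pod} = N_V \cdot V_{glom}}
#'
#' @param N_V numerical density, nuclei per um^3 (>= 0).
#' @param V_glom glomerular volume, um^3 (>= 0).
#' @return estimated podocytes per glomerulus.
#' @export
npodGlom <- function(N_V, V_glom) {
  if (N_V < 0 || V_glom < 0) stop("inputs must be non-negative")
  N_V * V_glom
}

#' Estimate podocyte number per glomerulus from 2D profiles
#'
#' Runs the full Weibel-Gomez chain: [profileSummary()] to obtain
#' `N_A`, `A_A` and the mean tuft area, [nvWeibelGomez()] for the
#' numerical density, [vglomWeibelGomez()] for the glomerular volume,
#' and [npodGlom()] for the estimated podocyte number. Podocyte density
#' is reported per 10^6 um^3.
#'
#' @param profiles profile `data.frame` (see [profileSummary()]).
#' @param coeffs a [StereologyCoefficients-class].
#' @return a [PodocyteEstimate-class].
#' @examples
#' g <- makeGlomerulus(50, 200, 3, seed = 1)
#' p <- sampleProfiles(g, 500, seed = 2)
#' estimatePodocytes(p, stereologyCoefficients(1, sqrt(6/pi), sqrt(6/pi), 1))
#' @export
estimatePodocytes <- function(profiles, coeffs = stereologyCoefficients()) {
  s <- profileSummary(profiles)
  nv <- nvWeibelGomez(s$N_A, s$A_A, coeffs)
  vg <- vglomWeibelGomez(s$mean_tuft_area, coeffs)
  new("PodocyteEstimate",
      NA_ = s$N_A, AA = s$A_A, NV = nv, Vglom = vg,
      Npod = npodGlom(nv, vg), density = nv * 1e6,
      meanNuclearSize = s$mean_nuclear_size,
      nProfiles = as.integer(s$n_profiles))
}

#' Per-animal and per-cohort podocyte estimates from a profiles table
#'
#' Pools each animal's profiles into one [estimatePodocytes()] call
#' (matching a design in which ~44 glomerular profiles are analysed per
#' animal); cohort values are means of the per-animal estimates.
#'
#' @param profiles profile `data.frame` with an `animal_id` column plus
#'   the measurement columns of [profileSummary()]; optional `group` /
#'   `age_week` columns are carried through.
#' @param coeffs a [StereologyCoefficients-class].
#' @return `data.frame` of per-animal estimates (one row per animal).
#' @export
podocytesByAnimal <- function(profiles, coeffs = stereologyCoefficients()) {
  stopifnot("animal_id" %in% names(profiles))
  ids <- unique(profiles$animal_id)
  rows <- lapply(ids, function(id) {
    sub <- profiles[profiles$animal_id == id, , drop = FALSE]
    est <- as.data.frame(estimatePodocytes(sub, coeffs))
    meta <- sub[1, intersect(c("group", "age_week"), names(sub)), drop = FALSE]
    cbind(data.frame(animal_id = id, row.names = NULL), meta, est,
          row.names = NULL)
  })
  do.call(rbind, rows)
}
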