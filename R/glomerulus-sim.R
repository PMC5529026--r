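#' Generate a synthetic glomerulus with known podocyte count
#'
#' Places `nPod` equal spherical nuclei of radius `radiusNuc` uniformly at
#' random inside the sphere of radius `radiusGlom - radiusNuc`, so every
#' nucleus lies fully interior to the glomerulus. The uniform-in-sphere
#' draw uses the inverse-CDF radial law `r = R * u^(1/3)` with an
#' isotropic direction.
#'
#' @param radiusGlom glomerular radius, micrometres (> 0).
#' @param nPod number of podocyte nuclei (>= 0).
#' @param radiusNuc nuclear radius, micrometres (0 < radiusNuc < radiusGlom).
#' @param seed integer seed; results are bit-reproducible given
#'   `(arguments, seed)`.
#' @return a [Glomerulus3D-class] object.
#' @examples
#' g <- makeGlomerulus(50, 200, 3, seed = 1)
#' nPod(g)
#' @export
makeGlomerulus <- function(radiusGlom, nPod, radiusNuc, seed = 1L) {
  if (!is.numeric(radiusGlom) || radiusGlom <= 0)
    stop("radiusGlom must be positive")
  if (!is.numeric(radiusNuc) || radiusNuc <= 0)
    stop("radiusNuc must be positive")
  if (radiusNuc >= radiusGlom)
    stop("radiusNuc must be smaller than radiusGlom")
  if (nPod < 0) stop("nPod must be non-negative")
  nPod <- as.integer(nPod)
  centers <- with_seed(seed, {
    if (nPod == 0L) {
      matrix(numeric(0), ncol = 3)
    } else {
      rmax <- radiusGlom - radiusNuc
      # isotropic direction from a standard normal triple
      z <- matrix(rnorm(nPod * 3L), ncol = 3)
      z <- z / sqrt(rowSums(z^2))
      r <- rmax * runif(nPod)^(1 / 3)
      z * r
    }
  })
  new("Glomerulus3D", radiusGlom = radiusGlom, radiusNuc = radiusNuc,
      centers = centers, seed = as.integer(seed))
}

#' Section a glomerulus with a plane and measure the resulting profile
#'
#' A plane at signed offset `offset` from the glomerular centre (by
#' spherical symmetry the canonical axis is used) produces a circular
#' tuft profile of area `pi * (R^2 - h^2)`. A nucleus is counted as a
#' WT-1 positive nuclear profile iff the plane cuts it
#' (`|h - z_i| < radiusNuc`), and its stained profile area is
#' `pi * (radiusNuc^2 - (h - z_i)^2)`; overlap between nuclear profiles
#' is ignored (nuclei occupy a small volume fraction, so overlap is a
#' second-order effect).
#'
#' @param glom a [Glomerulus3D-class].
#' @param offset signed plane offset h from the centre, micrometres.
#' @return a one-row `data.frame` with columns `tuft_area_um2`, `n_wt1`,
#'   `wt1_area_um2`, or `NULL` when `|offset| >= radiusGlom` (the plane
#'   misses the glomerulus).
#' @examples
#' g <- makeGlomerulus(50, 200, 3, seed = 1)
#' sectionProfile(g, 0)$tuft_area_um2   # 2500 * pi
#' @export
sectionProfile <- function(glom, offset) {
  stopifnot(is(glom, "Glomerulus3D"), is.numeric(offset), length(offset) == 1L)
  R <- glom@radiusGlom
  if (abs(offset) >= R) return(NULL)
  rho <- glom@radiusNuc
  tuft <- pi * (R^2 - offset^2)
  if (nPod(glom) == 0L) {
    return(data.frame(tuft_area_um2 = tuft, n_wt1 = 0L, wt1_area_um2 = 0))
  }
  d <- abs(offset - glom@centers[, 3])
  hit <- d < rho
  data.frame(
    tuft_area_um2 = tuft,
    n_wt1 = as.integer(sum(hit)),
    wt1_area_um2 = sum(pi * (rho^2 - d[hit]^2))
  )
}

#' Draw random sections through a set of glomeruli
#'
#' For each glomerulus, `sectionsPerGlom` plane offsets are drawn
#' uniformly on `(-R, R)`. Profiles whose tuft area falls below
#' `minRelArea * pi * R^2` are dropped (not resampled), emulating the
#' exclusion of grazing sections during manual profile selection; the
#' dropped count is attached as the `"dropped"` attribute and a warning
#' is raised when more than half of all profiles are dropped.
#'
#' @param gloms a [Glomerulus3D-class] or a list of them.
#' @param sectionsPerGlom sections to draw per glomerulus.
#' @param minRelArea minimum tuft area relative to the equatorial area
#'   `pi * R^2`, in `[0, 1)`; default 0 (keep everything).
#' @param seed integer seed.
#' @return `data.frame` with columns `glom_id`, `section_id`,
#'   `tuft_area_um2`, `n_wt1`, `wt1_area_um2`; attribute `dropped` holds
#'   the number of discarded profiles and attribute `offsets` the signed
#'   plane offsets of the retained rows (useful for validation).
#' @examples
#' g <- makeGlomerulus(50, 200, 3, seed = 1)
#' p <- sampleProfiles(g, 100, seed = 2)
#' nrow(p)
#' @export
sampleProfiles <- function(gloms, sectionsPerGlom, minRelArea = 0,
                           seed = 1L) {
  if (is(gloms, "Glomerulus3D")) gloms <- list(gloms)
  stopifnot(length(gloms) >= 1L, sectionsPerGlom >= 1L)
  if (minRelArea < 0 || minRelArea >= 1)
    stop("minRelArea must lie in [0, 1)")
  out <- with_seed(seed, {
    res <- vector("list", length(gloms))
    for (i in seq_along(gloms)) {
      g <- gloms[[i]]
      R <- g@radiusGlom
      rho <- g@radiusNuc
      z <- g@centers[, 3]
      h <- runif(sectionsPerGlom, -R, R)
      nw <- integer(sectionsPerGlom)
      wa <- numeric(sectionsPerGlom)
      # chunked so the offset x nucleus distance matrix stays small
      for (block in split(seq_along(h), ceiling(seq_along(h) / 1e4))) {
        if (length(z)) {
          D <- abs(outer(h[block], z, "-"))
          hit <- D < rho
          nw[block] <- as.integer(rowSums(hit))
          wa[block] <- rowSums(pi * (rho^2 - D^2) * hit)
        }
      }
      res[[i]] <- data.frame(
        glom_id = i, section_id = seq_len(sectionsPerGlom),
        tuft_area_um2 = pi * (R^2 - h^2), n_wt1 = nw, wt1_area_um2 = wa,
        offset = h
      )
    }
    do.call(rbind, res)
  })
  keep <- out$tuft_area_um2 >= minRelArea * pi *
    vapply(gloms, radiusGlom, 0)[out$glom_id]^2
  dropped <- sum(!keep)
  offsets <- out$offset[keep]
  out <- out[keep, c("glom_id", "section_id", "tuft_area_um2",
                     "n_wt1", "wt1_area_um2")]
  rownames(out) <- NULL
  if (dropped > nrow(out))
    warning("more than 50% of sampled profiles were dropped by the ",
            "minimum-area filter")
  attr(out, "dropped") <- dropped
  attr(out, "offsets") <- offsets
  out
}
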