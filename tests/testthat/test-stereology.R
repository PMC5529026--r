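test_that("profile summary does single-profile and degenerate arithmetic", {
  s <- profileSummary(data.frame(tuft_area_um2 = 5000, n_wt1 = 10,
                                 wt1_area_um2 = 250))
  expect_equal(s$N_A, 0.002)
  expect_equal(s$A_A, 0.05)
  expect_equal(s$mean_nuclear_size, 25)

  z <- profileSummary(data.frame(tuft_area_um2 = c(4000, 6000),
                                 n_wt1 = c(0L, 0L),
                                 wt1_area_um2 = c(0, 0)))
  expect_equal(z$N_A, 0)
  expect_equal(z$A_A, 0)
  expect_true(is.na(z$mean_nuclear_size))

  expect_error(profileSummary(data.frame(tuft_area_um2 = numeric(),
                                         n_wt1 = integer(),
                                         wt1_area_um2 = numeric())),
               "at least one")
  expect_error(profileSummary(data.frame(tuft_area_um2 = -1, n_wt1 = 0,
                                         wt1_area_um2 = 0)), "positive")
})

test_that("pooled summary equals brute-force ratio of totals", {
  g <- makeGlomerulus(50, 120, 3, seed = 13)
  p <- sampleProfiles(g, 44, seed = 14)
  s <- profileSummary(p)
  # independent brute-force totals
  expect_equal(s$N_A, sum(p$n_wt1) / sum(p$tuft_area_um2))
  expect_equal(s$A_A, sum(p$wt1_area_um2) / sum(p$tuft_area_um2))
  expect_equal(s$mean_nuclear_size, sum(p$wt1_area_um2) / sum(p$n_wt1))
})

test_that("the Weibel-Gomez formulas match arbitrary-precision values", {
  expect_equal(nvWeibelGomez(0, 0.05), 0)
  expect_equal(nvWeibelGomez(0, 0), 0)  # empty glomerulus, A_A irrelevant
  expect_equal(nvWeibelGomez(0.002, 0.05), 3.034483e-4, tolerance = 1e-6)
  expect_error(nvWeibelGomez(0.002, 0), "positive")

  expect_equal(vglomWeibelGomez(0), 0)
  expect_equal(vglomWeibelGomez(10000), 1.366337e6, tolerance = 1e-6)
  expect_error(vglomWeibelGomez(-5), "non-negative")

  expect_equal(npodGlom(0, 123), 0)
  expect_equal(npodGlom(3.034483e-4, 1.366337e6), 414.6, tolerance = 1e-3)
})

test_that("sphere volume identity: exact mean area recovers 0.9886 V", {
  R <- 50
  ratio <- vglomWeibelGomez((2 / 3) * pi * R^2) / ((4 / 3) * pi * R^3)
  expect_equal(ratio, 1.38 / (1.01 * sqrt(6 / pi)), tolerance = 1e-12)
  expect_equal(ratio, 0.9886, tolerance = 1e-3)
})

test_that("the chain equals the manual composition of its three steps", {
  g <- makeGlomerulus(45, 180, 2.8, seed = 17)
  p <- sampleProfiles(g, 60, seed = 18)
  co <- stereologyCoefficients()
  est <- estimatePodocytes(p, co)
  s <- profileSummary(p)
  nv <- nvWeibelGomez(s$N_A, s$A_A, co)
  vg <- vglomWeibelGomez(s$mean_tuft_area, co)
  expect_equal(npodGlomEstimate(est), npodGlom(nv, vg))
  expect_equal(as.data.frame(est)$density_per_1e6um3, nv * 1e6)
  expect_equal(as.data.frame(est)$n_profiles, nrow(p))
})

test_that("all-zero profiles yield an all-zero estimate", {
  p <- data.frame(tuft_area_um2 = c(3000, 5000), n_wt1 = 0L,
                  wt1_area_um2 = 0)
  est <- estimatePodocytes(p)
  expect_equal(npodGlomEstimate(est), 0)
  expect_equal(as.data.frame(est)$n_v, 0)
  expect_gt(as.data.frame(est)$v_glom_um3, 0)  # volume is still defined
})

test_that("scale covariance: areas x c^2 scales V by c^3, N_pod consistently", {
  p <- data.frame(tuft_area_um2 = c(4000, 6000, 5000),
                  n_wt1 = c(8L, 12L, 10L),
                  wt1_area_um2 = c(200, 300, 260))
  c2 <- 4  # areas scaled by c^2 with c = 2
  p2 <- transform(p, tuft_area_um2 = tuft_area_um2 * c2,
                  wt1_area_um2 = wt1_area_um2 * c2)
  e1 <- as.data.frame(estimatePodocytes(p))
  e2 <- as.data.frame(estimatePodocytes(p2))
  expect_equal(e2$v_glom_um3, e1$v_glom_um3 * 8)     # c^3
  expect_equal(e2$n_v, e1$n_v / 8)                   # density falls as c^-3
  expect_equal(e2$n_pod, e1$n_pod)                   # count is scale-free
})

test_that("N_pod is monotone in the nuclear count, all else fixed", {
  base <- data.frame(tuft_area_um2 = 5000, wt1_area_um2 = 250)
  ests <- vapply(c(5L, 10L, 20L, 40L), function(n)
    npodGlomEstimate(estimatePodocytes(cbind(base, n_wt1 = n))), 0)
  expect_true(all(diff(ests) > 0))
})

test_that("sphere-exact coefficients recover the true podocyte count", {
  gl <- glomBank(10, R = 50, npod = 200, rho = 3, seed = 100)
  p <- sampleProfiles(gl, 400, seed = 101)  # 4000 sections
  est <- estimatePodocytes(p, sphereCoeffs())
  expect_equal(npodGlomEstimate(est), 200, tolerance = 0.05)
})

test_that("identical profile tables give bit-identical estimates", {
  g <- makeGlomerulus(50, 200, 3, seed = 1)
  p <- sampleProfiles(g, 100, seed = 2)
  e1 <- as.data.frame(estimatePodocytes(p))
  e2 <- as.data.frame(estimatePodocytes(p))
  expect_identical(e1, e2)
})

test_that("per-animal estimates pool each animal's profiles", {
  gl <- glomBank(4, seed = 200)
  p <- sampleProfiles(gl, 20, seed = 7)
  p$animal_id <- ifelse(p$glom_id <= 2, "a1", "a2")
  tab <- podocytesByAnimal(p)
  expect_equal(nrow(tab), 2L)
  direct <- estimatePodocytes(p[p$animal_id == "a1", ])
  expect_equal(tab$n_pod[tab$animal_id == "a1"],
               npodGlomEstimate(direct))
})
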