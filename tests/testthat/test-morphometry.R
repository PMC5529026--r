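test_that("checkerboard quadrat selection follows parity", {
  # four centroids at the centres of a 2x2 quadrat grid: exactly 2 selected
  sel <- quadratSelect(c(50, 150, 50, 150), c(50, 50, 150, 150), 100)
  expect_equal(sum(sel), 2L)
  expect_equal(sel, c(TRUE, FALSE, FALSE, TRUE))
  # all centroids inside one even quadrat: all selected
  expect_true(all(quadratSelect(c(10, 20, 30), c(10, 20, 30), 100)))
  expect_error(quadratSelect(1, 1, 0), "positive")
})

test_that("selection is translation-invariant by a full period", {
  set.seed(31)
  x <- runif(200, 0, 1000); y <- runif(200, 0, 1000)
  q <- 37
  expect_identical(quadratSelect(x, y, q), quadratSelect(x + 2 * q, y, q))
  expect_identical(quadratSelect(x, y, q), quadratSelect(x, y + 2 * q, q))
})

test_that("uniform random centroids are selected at rate 1/2", {
  set.seed(32)
  n <- 20000
  sel <- quadratSelect(runif(n, 0, 5000), runif(n, 0, 5000), 25)
  expect_equal(mean(sel), 0.5, tolerance = 3 / sqrt(n))  # ~3 binomial SDs
})

test_that("stain summaries match spreadsheet-style totals", {
  m <- data.frame(tuft_area_um2 = c(4000, 6000, 5000),
                  stain_area_um2 = c(400, 900, 0))
  s <- stainSummary(m, referenceArea = 1e6)
  expect_equal(s$mean_stain_area_um2, mean(m$stain_area_um2))
  expect_equal(s$pct_of_tuft, 100 * 1300 / 15000)
  expect_equal(s$pct_of_kidney, 100 * 1300 / 1e6)
  # ordering invariance
  s2 <- stainSummary(m[c(3, 1, 2), ], referenceArea = 1e6)
  expect_equal(s2$pct_of_tuft, s$pct_of_tuft)

  full <- stainSummary(data.frame(tuft_area_um2 = 500, stain_area_um2 = 500))
  expect_equal(full$pct_of_tuft, 100)
  none <- stainSummary(data.frame(tuft_area_um2 = c(10, 20),
                                  stain_area_um2 = 0))
  expect_equal(none$mean_stain_area_um2, 0)
  expect_equal(none$pct_of_tuft, 0)
  expect_true(is.na(none$pct_of_kidney))
  expect_error(stainSummary(data.frame(tuft_area_um2 = 10,
                                       stain_area_um2 = 20)), "tuft")
})

test_that("per-tuft percentage alternative averages individual tufts", {
  m <- data.frame(tuft_area_um2 = c(100, 10000),
                  stain_area_um2 = c(50, 100))
  expect_equal(stainSummary(m, perTuftPercent = TRUE)$pct_of_tuft,
               mean(c(50, 1)))
  expect_equal(stainSummary(m)$pct_of_tuft, 100 * 150 / 10100)
})

test_that("mask areas count pixels inside the tuft only", {
  tuft <- matrix(0L, 10, 10); tuft[3:7, 3:7] <- 1L
  stain <- matrix(0L, 10, 10); stain[5:9, 5:9] <- 1L
  a <- maskAreas(tuft, stain, pixelSize = 2)
  expect_equal(a$tuft_area_um2, 25 * 4)
  expect_equal(a$stain_area_um2, 9 * 4)  # 3x3 intersection
  same <- maskAreas(tuft, tuft, 1)
  expect_equal(same$stain_area_um2, same$tuft_area_um2)
  disjoint <- matrix(0L, 10, 10); disjoint[9:10, 9:10] <- 1L
  expect_equal(maskAreas(tuft, disjoint, 1)$stain_area_um2, 0)
  expect_error(maskAreas(tuft, matrix(0, 5, 5), 1), "shape")
})

test_that("mask areas are additive over disjoint tiles", {
  set.seed(33)
  tuft <- matrix(rbinom(400, 1, 0.5), 20, 20)
  stain <- matrix(rbinom(400, 1, 0.3), 20, 20)
  whole <- maskAreas(tuft, stain, 1.5)
  top <- maskAreas(tuft[1:10, ], stain[1:10, ], 1.5)
  bottom <- maskAreas(tuft[11:20, ], stain[11:20, ], 1.5)
  expect_equal(whole$tuft_area_um2, top$tuft_area_um2 + bottom$tuft_area_um2)
  expect_equal(whole$stain_area_um2,
               top$stain_area_um2 + bottom$stain_area_um2)
})

test_that("score-severity agreement behaves across noise regimes", {
  truth <- data.frame(animal_id = paste0("a", 1:40),
                      severity = seq(0.1, 4, length.out = 40))
  # noiseless discretization: perfect rank agreement up to ties
  scores <- data.frame(animal_id = truth$animal_id,
                       score = 1L + findInterval(truth$severity,
                                                 c(1.25, 2, 2.75, 3.5)))
  expect_gt(scoreVsSeverity(scores, truth), 0.95)
  # independent scores: near-zero agreement on average
  set.seed(34)
  rhos <- replicate(50, {
    sc <- data.frame(animal_id = truth$animal_id,
                     score = sample(1:5, 40, replace = TRUE))
    scoreVsSeverity(sc, truth)
  })
  expect_lt(abs(mean(rhos)), 0.1)
  # matches a direct rank-correlation computation
  set.seed(35)
  sc <- data.frame(animal_id = truth$animal_id,
                   score = 1L + findInterval(truth$severity + rnorm(40, 0, 0.8),
                                             c(1.25, 2, 2.75, 3.5)))
  m <- merge(sc, truth, by = "animal_id")
  expect_equal(scoreVsSeverity(sc, truth),
               cor(rank(m$score), rank(m$severity)))
  # ties-only degenerate input
  allSame <- data.frame(animal_id = truth$animal_id, score = 3L)
  expect_true(is.na(scoreVsSeverity(allSame, truth)))
})
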