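# Colocalization pipeline: preprocessing, Otsu binarization, mask scoring,
# grid search, and overlap metrics.

test_that("identity parameters reduce preprocessing to min-max rescaling", {
  set.seed(1)
  img <- matrix(runif(400, 2, 9), 20, 20)
  out <- preprocess(img, sigma = 0, gamma = 1)
  expect_equal(out, (img - min(img)) / (max(img) - min(img)))
  expect_equal(range(out), c(0, 1))
})

test_that("the power step acts elementwise on rescaled values", {
  img <- matrix(c(0, 0.5, 1, 0, 0.5, 1, 0, 0.5, 1), 3, 3)
  out <- preprocess(img, sigma = 0, gamma = 2)
  expect_equal(sort(unique(as.numeric(out))), c(0, 0.25, 1))
})

test_that("preprocessing preserves the intensity ordering of the blur", {
  set.seed(2)
  img <- matrix(runif(1024), 32, 32)
  for (gamma in c(0.5, 2, 3)) {
    blurred <- preprocess(img, sigma = 1.5, gamma = 1)
    powered <- preprocess(img, sigma = 1.5, gamma = gamma)
    expect_equal(which.max(powered), which.max(blurred))
    expect_equal(order(blurred), order(powered))
  }
})

test_that("constant images are flagged degenerate, not an error", {
  flat <- matrix(3, 10, 10)
  out <- preprocess(flat, 1, 1)
  expect_true(is_degenerate(out))
  expect_true(all(out == 0))
  expect_error(otsu_threshold(flat), "constant")
})

test_that("preprocess validates its parameters", {
  img <- matrix(runif(64), 8, 8)
  expect_error(preprocess(img, -1, 1), "sigma")
  expect_error(preprocess(img, 1, 0), "gamma")
  expect_error(preprocess(matrix(c(-1, 1, 2, 3), 2, 2), 0, 1), "nonnegative")
})

test_that("a perfectly bimodal image splits at the obvious threshold", {
  img <- matrix(c(rep(0, 5), rep(255, 4)), 3, 3)
  ot <- otsu_threshold(img)
  expect_equal(sum(ot$mask), 4)
  expect_identical(ot$mask, matrix(img == 255, 3, 3))
})

test_that("Otsu matches the exhaustive between-class-variance maximizer", {
  set.seed(3)
  for (i in 1:25) {
    nr <- sample(8:32, 1)
    img <- matrix(sample(0:255, nr * nr, replace = TRUE), nr, nr)
    expect_equal(otsu_threshold(img)$level, brute_force_otsu_level(img))
  }
})

test_that("Otsu masks are invariant to positive affine intensity maps", {
  set.seed(4)
  img <- matrix(runif(900), 30, 30)
  ref <- otsu_threshold(img)
  scaled <- otsu_threshold(3.7 * img + 11)
  expect_identical(ref$mask, scaled$mask)
  expect_equal(ref$level, scaled$level)
})

test_that("mask scores count raw pixels above the raw 90th percentile", {
  img <- matrix(1:100, 10, 10)          # P90 = 90.1 by linear interpolation
  mask <- matrix(FALSE, 10, 10)
  mask[img %in% c(95:100, 10, 20, 30, 40)] <- TRUE
  expect_equal(score_mask(mask, img), 60)
  # a mask of exactly the above-P90 pixels scores 100
  exact <- matrix(img > quantile(img, 0.9), 10, 10)
  expect_equal(score_mask(exact, img), 100)
})

test_that("empty masks score zero with a degenerate flag", {
  img <- matrix(runif(64), 8, 8)
  s <- score_mask(matrix(FALSE, 8, 8), img)
  expect_equal(as.numeric(s), 0)
  expect_true(is_degenerate(s))
  expect_error(score_mask(matrix(TRUE, 4, 4), img), "shape")
})

test_that("singleton grids return the single candidate", {
  p <- simulate_puncta_pair(48, 48, 5, 1, noise_sd = 0.03, seed = 21)
  got <- optimize_mask(p$fish, sigma_grid = 1, gamma_grid = 2)
  pre <- preprocess(p$fish, 1, 2)
  ot <- otsu_threshold(pre)
  expect_identical(got$foreground, ot$mask)
  expect_equal(got$sigma, 1)
  expect_equal(got$gamma, 2)
  expect_equal(got$score, score_mask(ot$mask, p$fish))
})

test_that("grid search returns the exhaustive-best parameter pair", {
  sg <- c(0.5, 1, 2, 4)
  gg <- c(0.5, 1, 2, 3)
  for (seed in c(31, 32)) {
    p <- simulate_puncta_pair(64, 64, 8, 1, seed = seed)
    got <- optimize_mask(p$fish, sg, gg)
    # oracle: evaluate every cell independently, first-best with ascending
    # sigma-major order implements the smallest-sigma/gamma tie break
    best <- list(score = -Inf)
    for (s in sg) for (g in gg) {
      pre <- preprocess(p$fish, s, g)
      if (is_degenerate(pre)) next
      sc <- score_mask(otsu_threshold(pre)$mask, p$fish)
      if (sc > best$score) best <- list(score = sc, sigma = s, gamma = g)
    }
    expect_equal(got$sigma, best$sigma)
    expect_equal(got$gamma, best$gamma)
    expect_equal(got$score, best$score)
  }
})

test_that("optimized masks cover the spot centers of clean images", {
  p <- simulate_puncta_pair(64, 64, 6, 1, noise_sd = 0, seed = 41)
  mask <- optimize_mask(p$fish)$foreground
  centers <- round(p$truth$spot_centers_fish)
  expect_true(all(mask[cbind(centers[, 1], centers[, 2])]))
})

test_that("metric identities hold on constructed masks", {
  base <- matrix(FALSE, 20, 20)
  f <- base; f[1:100] <- TRUE
  s <- base; s[41:120] <- TRUE          # |F|=100, |S|=80, |F n S|=60
  m <- coloc_metrics(f, s)
  expect_equal(m$labeling_efficiency, 60)
  expect_equal(m$specificity, 75)
  expect_equal(m$jaccard, 0.5)
  expect_equal(m$n_union, 120)

  id <- coloc_metrics(f, f)
  expect_equal(id$labeling_efficiency, 100)
  expect_equal(id$specificity, 100)
  expect_equal(id$jaccard, 1)

  disj <- base; disj[201:260] <- TRUE
  z <- coloc_metrics(f, disj)
  expect_equal(z$jaccard, 0)
  expect_equal(z$labeling_efficiency, 0)
  expect_equal(z$specificity, 0)
})

test_that("metric algebra holds on random mask pairs", {
  set.seed(5)
  for (i in 1:50) {
    f <- random_mask(15, 15, runif(1, 0.1, 0.6))
    s <- random_mask(15, 15, runif(1, 0.1, 0.6))
    m <- coloc_metrics(f, s)
    expect_equal(m$labeling_efficiency * m$n_fish_fg, 100 * m$n_intersection)
    expect_equal(m$specificity * m$n_strep_fg, 100 * m$n_intersection)
    expect_equal(m$n_union, m$n_fish_fg + m$n_strep_fg - m$n_intersection)
    expect_lte(m$n_intersection, min(m$n_fish_fg, m$n_strep_fg))
    # Jaccard is symmetric; efficiency and specificity swap
    sw <- coloc_metrics(s, f)
    expect_equal(sw$jaccard, m$jaccard)
    expect_equal(sw$labeling_efficiency, m$specificity)
  }
})

test_that("empty masks degrade metrics gracefully", {
  e <- matrix(FALSE, 5, 5)
  f <- matrix(TRUE, 5, 5)
  m <- coloc_metrics(e, f)
  expect_true(is_degenerate(m))
  expect_equal(m$labeling_efficiency, 0)
  expect_error(coloc_metrics(f, matrix(TRUE, 4, 4)), "shape")
})

test_that("identical channels give Jaccard 1 through the full pipeline", {
  p <- simulate_puncta_pair(64, 64, 8, 1, seed = 51)
  q <- quantify_pair(p$fish, p$fish)
  expect_equal(q$metrics$jaccard, 1)
  expect_equal(q$metrics$labeling_efficiency, 100)
})

test_that("the pipeline separates full from zero planted overlap", {
  hi <- simulate_puncta_pair(96, 96, 12, 1, seed = 61)
  q_hi <- quantify_pair(hi$fish, hi$strep)
  expect_gte(q_hi$metrics$jaccard, 0.8)

  lo <- simulate_puncta_pair(96, 96, 12, 0, seed = 61)
  q_lo <- quantify_pair(lo$fish, lo$strep)
  expect_lte(q_lo$metrics$specificity, 20)
})

test_that("positive rescaling of a channel changes nothing downstream", {
  p <- simulate_puncta_pair(48, 48, 5, 1, seed = 71)
  a <- optimize_mask(p$fish)
  b <- optimize_mask(unclass(p$fish) * 250)
  expect_identical(a$foreground, b$foreground)
  expect_equal(a$sigma, b$sigma)
  expect_equal(a$gamma, b$gamma)
  expect_equal(a$score, b$score)
})
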