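test_that("point-mass density yields a single P-site peak", {
  dens <- rep(0, 100); dens[40] <- 1
  fp <- generate_synthetic_footprints(dens, depth = 1000,
                                      read_length_dist = 30, noise = 0,
                                      seed = 7)
  expect_equal(nrow(fp), 1000)
  expect_true(all(fp$psite == 40))
  h <- psite_histogram(fp, 100)
  expect_equal(which(h > 0), 40L)
})

test_that("uniform density stays within binomial error", {
  L <- 50; depth <- 20000
  fp <- generate_synthetic_footprints(rep(1, L), depth = depth,
                                      read_length_dist = 30, seed = 3)
  h <- psite_histogram(fp, L)
  expect_equal(sum(h), depth)
  p <- 1 / L
  sd <- sqrt(depth * p * (1 - p))
  expect_true(all(abs(h - depth / L) < 4 * sd))
})

test_that("empirical distribution converges to the truth (chi-square)", {
  set.seed(1)
  dens <- runif(40) + 0.1
  fp <- generate_synthetic_footprints(dens, depth = 1e5,
                                      read_length_dist = 30, seed = 21)
  h <- psite_histogram(fp, 40)
  pval <- suppressWarnings(chisq.test(h, p = dens / sum(dens))$p.value)
  expect_gt(pval, 0.001)
})

test_that("two point masses 60 nt apart give disome-read peaks spaced 60", {
  dens <- rep(0, 200); dens[c(80, 140)] <- 1
  fp <- generate_synthetic_footprints(dens, depth = 2000,
                                      read_length_dist = 60, noise = 0,
                                      seed = 9)
  dr <- disome_read_profile(fp, disome_length = 60)
  expect_equal(as.integer(dr$peak_spacing), 60L)
})

test_that("generator is deterministic per seed and validates inputs", {
  dens <- c(1, 2, 3)
  a <- generate_synthetic_footprints(dens, 100, 30, seed = 5)
  b <- generate_synthetic_footprints(dens, 100, 30, seed = 5)
  expect_identical(a, b)
  expect_error(generate_synthetic_footprints(c(1, -1), 10, 30), "negative")
  expect_error(generate_synthetic_footprints(c(0, 0), 10, 30), "zero")
  expect_error(generate_synthetic_footprints(dens, 0, 30), "depth")
})
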