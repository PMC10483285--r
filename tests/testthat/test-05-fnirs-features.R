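test_that("HbO2 preprocessing removes trends and keeps exactly 3 minutes", {
  ramp <- recording(matrix(rep(seq(0, 100, length.out = 3600), each = 8), 8,
                           byrow = FALSE),
                    paste0("ch", 1:8), 10, "control", "T01")
  h <- preprocess_hbo2(ramp)
  expect_equal(ncol(h$data), 1800)
  # the retained 3-min window of the filtered series carries a small local
  # slope from filter transients; the input trend itself is removed
  slope_in <- 100 / 3600
  fit <- coef(lm(h$data[1, ] ~ seq_len(1800)))[2]
  expect_lt(abs(fit) / slope_in, 1e-2)
  expect_lt(abs(mean(h$data[1, ])) / mean(seq(0, 100, length.out = 3600)), 1e-2)
})

test_that("HbO2 passband keeps slow oscillations and rejects fast ones", {
  t <- seq_len(3600) / 10
  mk <- function(f) recording(matrix(rep(sin(2 * pi * f * t), each = 8), 8,
                                     byrow = FALSE),
                              paste0("ch", 1:8), 10, "control", "T01")
  slow <- preprocess_hbo2(mk(0.05))
  expect_gt(sd(slow$data[1, ]) / sd(sin(2 * pi * 0.05 * t)), 0.9)
  fast <- preprocess_hbo2(mk(0.5))
  expect_lt(20 * log10(sd(fast$data[1, ]) / sd(sin(2 * pi * 0.5 * t))), -20)
})

test_that("wavelet transform reconstructs perfectly without thresholding", {
  set.seed(30)
  x <- rnorm(512)
  st <- neurofuse:::dwt_step(x)
  back <- neurofuse:::idwt_step(st$a, st$d)
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("sample entropy is zero for periodic series and matches the oracle", {
  x <- rep(c(1, 2, 3), 40)
  # under the classical convention every m-match extends, so exactly zero;
  # the printed-denominator mode leaves only an O(1/N) edge-template residue
  expect_equal(sample_entropy(x, m = 2, tau = 1, classical = TRUE), 0)
  expect_lt(abs(sample_entropy(x, m = 2, tau = 1)), 1e-3)

  set.seed(31)
  for (rep in 1:5) {
    y <- round(rnorm(12), 2)
    r <- sd(y)          # wide tolerance so hand-sized sequences have matches
    expect_equal(sample_entropy(y, m = 2, r = r, tau = 2),
                 oracle_sampen(y, m = 2, r = r, tau = 2), tolerance = 1e-12)
  }
  y <- rnorm(200)
  r <- 0.2 * sd(y)
  expect_equal(sample_entropy(y, m = 2, r = r, tau = 2),
               oracle_sampen(y, m = 2, r = r, tau = 2), tolerance = 1e-12)
})

test_that("noise has higher sample entropy than a slow oscillation", {
  t <- seq_len(1800) / 10
  tone <- sin(2 * pi * 0.05 * t)
  se_tone <- sample_entropy(tone)
  set.seed(32)
  for (s in 1:20) {
    expect_gt(sample_entropy(rnorm(1800)), se_tone)
  }
})

test_that("sample entropy is invariant under affine amplitude scaling", {
  set.seed(33)
  x <- rnorm(500)
  expect_equal(sample_entropy(x), sample_entropy(5 * x + 3), tolerance = 1e-12)
})

test_that("constant series yields zero entropy with a warning", {
  expect_warning(se <- sample_entropy(rep(1, 100)), "constant")
  expect_equal(se, 0)
})

test_that("ROI connectivity hits the clamp, zero and null scales", {
  t <- seq_len(1800) / 10
  base <- sin(2 * pi * 0.05 * t)
  h <- make_hbo2(matrix(rep(base, each = 8), 8, byrow = FALSE))
  rc <- roi_connectivity(h)
  expect_equal(nrow(rc), 6)
  expect_equal(rc$z, rep(atanh(1 - 1e-7), 6), tolerance = 1e-6)
  expect_gt(min(rc$z), 8)

  # orthogonal constructed ROI series -> z = 0
  d <- matrix(0, 8, 1800)
  d[c(1, 3), ] <- rep(sin(2 * pi * 0.05 * t), each = 2)
  d[c(2, 4), ] <- rep(cos(2 * pi * 0.05 * t), each = 2)
  d[5:8, ] <- rep(sin(2 * pi * 0.03 * t), each = 4)
  rc2 <- roi_connectivity(make_hbo2(d))
  expect_equal(rc2$z[rc2$pair == "roi1-roi2"], 0, tolerance = 1e-6)

  set.seed(34)
  d3 <- matrix(rnorm(8 * 1800), 8)
  rc3 <- roi_connectivity(make_hbo2(d3))
  expect_lt(max(abs(rc3$z)), 0.1)
})

test_that("laterality index obeys symmetry, limits and the 1/3 construction", {
  t <- seq_len(1800) / 10
  base <- 1 + sin(2 * pi * 0.05 * t)
  same <- make_hbo2(matrix(rep(base, each = 8), 8, byrow = FALSE))
  expect_equal(laterality_index(same), 0)

  # constant left side -> LI = 1
  d <- matrix(rep(base, each = 8), 8, byrow = FALSE)
  d[5:8, ] <- 2.5
  expect_equal(laterality_index(make_hbo2(d)), 1)

  # right = 2 * (left - min(left)) + const -> LI = 1/3 by direct summation
  l <- base
  r <- 2 * (l - min(l)) + 0.7
  d2 <- rbind(matrix(rep(r, each = 4), 4, byrow = FALSE),
              matrix(rep(l, each = 4), 4, byrow = FALSE))
  expect_equal(laterality_index(make_hbo2(d2)), 1 / 3, tolerance = 1e-12)

  # swapping the side map flips the sign
  swapped <- setNames(rep(c("left", "right"), each = 4), paste0("ch", 1:8))
  expect_equal(laterality_index(make_hbo2(d2), side_map = swapped), -1 / 3,
               tolerance = 1e-12)
  expect_true(abs(laterality_index(make_hbo2(d2))) <= 1)
})
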