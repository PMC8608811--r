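test_that("sample ACF matches its defining arithmetic", {
  # lag 0 is exactly 1 for any non-degenerate series
  set.seed(1)
  a <- sample_acf(rnorm(50), max_lag = 10)
  expect_identical(a$values[1], 1)

  # alternating series: every lag-1 product of the centred series is -1,
  # so ACF(1) = -(T-1)/T
  x <- rep(c(1, -1), 500)
  a <- sample_acf(x, max_lag = 3)
  expect_equal(a$values[2], -(1000 - 1) / 1000)

  # AR(1): theoretical ACF is phi^k (Monte-Carlo at large T, frozen seed)
  s <- simulate_series(0.5, 100000, seed = 42)
  a <- sample_acf(s, max_lag = 3)
  expect_lt(abs(a$values[2] - 0.5), 0.01)
  expect_lt(abs(a$values[3] - 0.25), 0.01)

  # constant series is degenerate, not an error
  d <- sample_acf(rep(3, 100), max_lag = 5)
  expect_true(d$degenerate)
  expect_equal(int_index(d, tr = 2), 0)

  expect_error(sample_acf(rnorm(10), max_lag = 10), "max_lag")
})

test_that("int_index implements the first-negative summation rule", {
  mk <- function(v) structure(list(lags = 0:length(v), values = c(1, v),
                                   degenerate = FALSE),
                              class = "acf_sequence")
  expect_equal(int_index(mk(c(0.5, 0.2, 0.1, -0.05)), tr = 2), 1.6)
  expect_equal(int_index(mk(c(0.5, 0.2, 0.1, -0.05)), tr = 2,
                         include_lag0 = TRUE), 3.6)
  # ACF(1) < 0: empty positive run
  expect_equal(int_index(mk(c(-0.2, 0.5)), tr = 2), 0)
  # exactly-zero values are included and scanning continues
  expect_equal(int_index(mk(c(0.3, 0, 0.2, -0.1)), tr = 2), 1.0)
  # no negative value within max_lag: sum everything, warn
  expect_warning(v <- int_index(mk(c(0.5, 0.4, 0.3)), tr = 1),
                 "truncated")
  expect_equal(v, 1.2)
})

test_that("int_from_series recovers AR(1) timescales and session rules", {
  # white noise: most positive runs stop at lag 1
  ints <- vapply(1:50, function(i)
    int_from_series(simulate_series(0, 1000, seed = i)), numeric(1))
  expect_lt(median(ints), 0.2 * 2)

  # two identical sessions average to the single-session value exactly
  s1 <- simulate_series(0.5, 200, seed = 9)
  s2 <- bold_series(rep(s1$values, 2), tr = 2, session_bounds = c(200, 200))
  expect_equal(int_from_series(s2), int_from_series(s1))

  # sessions are never concatenated: a level shift between sessions must
  # not leak into the ACF, so per-session analysis of two flat-plus-noise
  # halves equals analysis of either half
  set.seed(11)
  half <- rnorm(300)
  shifted <- bold_series(c(half, half + 100), tr = 2,
                         session_bounds = c(300, 300))
  expect_equal(int_from_series(shifted),
               int_from_series(bold_series(half, tr = 2)))
})

test_that("INT is invariant to scale/offset and linear in TR", {
  set.seed(4)
  x <- as.vector(arima.sim(list(ar = 0.6), 500))
  base <- int_from_series(bold_series(x, tr = 2))
  expect_equal(int_from_series(bold_series(5.5 * x, tr = 2)), base)
  expect_equal(int_from_series(bold_series(x + 17, tr = 2)), base)
  expect_equal(int_from_series(bold_series(x, tr = 4)), 2 * base)
})

test_that("estimator bias shrinks with series length (consistency)", {
  med <- function(T) median(vapply(1:30, function(i)
    int_from_series(simulate_series(0.5, T, seed = 100 + i)), numeric(1)))
  true <- 2 * 0.5 / 0.5
  expect_lt(abs(med(20000) - true), abs(med(200) - true))
})

test_that("int_map equals the scalar estimator voxel by voxel", {
  set.seed(21)
  dims <- c(5, 4, 3)
  nt <- 80
  vol <- array(rnorm(prod(dims) * nt), dim = c(dims, nt))
  mask <- array(runif(prod(dims)) < 0.7, dim = dims)
  m <- int_map(vol, mask, tr = 2)
  lin <- sample(which(mask), 10)
  for (v in lin) {
    ijk <- arrayInd(v, dims)
    s <- bold_series(vol[ijk[1], ijk[2], ijk[3], ], tr = 2)
    expect_equal(m$grid[v], int_from_series(s))
  }
  expect_true(all(is.na(m$grid[!mask])))

  # a volume whose every voxel holds the same series is a constant map
  s <- simulate_series(0.4, nt, seed = 5)
  vol2 <- array(rep(s$values, each = prod(dims)), dim = c(dims, nt))
  m2 <- int_map(vol2, mask, tr = 2)
  expect_equal(unname(range(m2$grid[mask])),
               rep(int_from_series(s), 2))
})

test_that("int_map rejects malformed inputs and flags degenerate voxels", {
  vol <- array(rnorm(4 * 4 * 4 * 60), dim = c(4, 4, 4, 60))
  expect_error(int_map(vol, array(FALSE, c(4, 4, 4)), tr = 2), "no voxels")
  expect_error(int_map(vol, array(TRUE, c(5, 4, 4)), tr = 2), "5x4x4")
  expect_error(int_map(vol, array(TRUE, c(4, 4, 4)), tr = 2,
                       session_bounds = c(30, 31)), "session_bounds")
  vol[1, 1, 1, ] <- 7   # constant voxel
  expect_message(m <- int_map(vol, array(TRUE, c(4, 4, 4)), tr = 2),
                 "degenerate")
  expect_equal(m$grid[1, 1, 1], 0)
  expect_equal(m$n_degenerate, 1)
})

test_that("bold_series validates its invariants", {
  expect_error(bold_series(rnorm(10), tr = 0), "tr")
  expect_error(bold_series(rnorm(10), tr = 2, session_bounds = c(5, 4)),
               "sum")
  expect_error(bold_series(rnorm(3), tr = 2, session_bounds = c(2, 1)),
               "at least 2 frames")
  expect_error(bold_series(c(1, NA, 3), tr = 2), "non-finite")
})
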