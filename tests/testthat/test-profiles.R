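test_that("gap profile counts valid returns below each height", {
  grid <- c(0, 5, 10)
  # 100 shots: 50 valid below 5 m, 50 gaps
  s <- make_scan(c(rep(2 / cos(57.5 * pi / 180), 50), rep(0, 50)))
  p <- gap_profile(s, grid = grid)
  expect_equal(p$pgap, c(1, 0.5, 0.5))
  # hits at heights {2, 2, 8} plus 97 gaps
  cz <- cos(57.5 * pi / 180)
  s2 <- make_scan(c(2 / cz, 2 / cz, 8 / cz, rep(0, 97)))
  p2 <- gap_profile(s2, grid = c(0, 5, 10))
  expect_equal(p2$pgap, c(1, 0.98, 0.97))
  # no valid returns: Pgap = 1 everywhere
  p3 <- gap_profile(make_scan(rep(0, 40)), grid = grid)
  expect_equal(p3$pgap, rep(1, 3))
})

test_that("the below-height count is strictly less-than", {
  # zenith 60 so heights are exact binary fractions: z = 0.5 * d
  s <- make_scan(rep(10, 10), zenith = 60)  # all hits exactly at h = 5
  g60 <- instrument_geometry(zenith = 60)
  p <- gap_profile(s, geom = g60, grid = c(0, 5, 5.0001))
  expect_equal(p$pgap, c(1, 1, 0))  # z = 5 not counted below h = 5
})

test_that("gap profile agrees exactly with a brute-force recount", {
  # 200 random scans of <= 50 shots against an independent per-shot loop
  withr::with_seed(2024, {
    for (i in 1:200) {
      n <- sample(1:50, 1)
      ranges <- ifelse(runif(n) < 0.4, 0, round(runif(n, 0.3, 70), 3))
      scan <- make_scan(ranges)
      grid <- sort(c(0, runif(sample(3:12, 1), 0, 40)))
      expect_identical(gap_profile(scan, grid = grid)$pgap,
                       brute_force_pgap(scan, grid))
    }
  })
})

test_that("the literal gap-inclusive counting rule is available but non-physical", {
  s <- make_scan(c(10, rep(0, 9)))
  lit <- gap_profile(s, grid = c(0, 5, 10), literal = TRUE)
  phys <- gap_profile(s, grid = c(0, 5, 10))
  # gaps coded 0.000 count as "returns below h" under the literal reading,
  # so a gap-heavy scan looks almost fully occluded
  expect_equal(lit$pgap, c(1, 0.1, 0.0))
  expect_equal(phys$pgap, c(1, 1.0, 0.9))
})

test_that("PAI inversion follows -1.1 log(Pgap)", {
  p <- tibble::tibble(height = 0:3,
                      pgap = c(1, 0.5, exp(-1), exp(-1)))
  out <- pai_profile(p)
  expect_equal(out$pai, c(0, 1.1 * log(2), 1.1, 1.1))
  expect_equal(out$pai[2], 0.7625, tolerance = 1e-4)
  expect_error(pai_profile(tibble::tibble(pgap = c(1, 1.2))), "\\[0, 1\\]")
})

test_that("saturated bins (Pgap = 0) are clipped to 1/(2N) and flagged", {
  s <- make_scan(rep(1, 100))  # every shot intercepted below 1 m
  prof <- gap_profile(s, grid = c(0, 5, 10)) |> pai_profile()
  expect_true(attr(prof, "saturated"))
  expect_true(all(is.finite(prof$pai)))
  expect_equal(max(prof$pai), -1.1 * log(1 / 200))
  clean <- gap_profile(make_scan(c(rep(1, 50), rep(0, 50))), grid = c(0, 5)) |>
    pai_profile()
  expect_false(attr(clean, "saturated"))
})

test_that("PAVD is the finite-difference derivative of cumulative PAI", {
  # linear PAI ramp 0 -> 1.5 over 15 m at 0.5 m bins: constant 0.1 m2/m3
  grid <- seq(0, 15, by = 0.5)
  prof <- tibble::tibble(height = grid, pai = 0.1 * grid)
  out <- pavd_profile(prof)
  expect_true(is.na(out$pavd[1]))
  expect_equal(out$pavd[-1], rep(0.1, 30))
  # flat PAI segment -> zero PAVD there
  prof2 <- tibble::tibble(height = grid,
                          pai = pmin(0.2 * grid, 1))
  out2 <- pavd_profile(prof2)
  expect_equal(out2$pavd[grid > 6], rep(0, sum(grid > 6)))
  # non-uniform grids are refused
  expect_error(pavd_profile(tibble::tibble(height = c(0, 1, 3), pai = c(0, 1, 2))),
               "uniform")
})

test_that("profile chain conserves total plant area to 1e-9", {
  cm <- canopy_model(c(8, 18, 25), c(0.06, 0.085, 0.035))
  for (seed in 1:5) {
    p <- compute_profile(simulate_scan(cm, n_shots = 920, seed = seed))
    bw <- diff(p$height)[1]
    expect_lt(abs(bw * sum(p$pavd, na.rm = TRUE) - top_of_canopy_pai(p)), 1e-9)
    expect_true(all(diff(p$pgap) <= 0))
    expect_true(all(diff(p$pai) >= 0))
    expect_equal(p$pgap[1], 1)
    expect_equal(p$pai[1], 0)
  }
})

test_that("two-layer canopy PAVD peaks are recovered at the true layers", {
  cm <- canopy_model(c(6, 10, 14, 18), c(0.02, 0.25, 0.02, 0.3))
  s <- simulate_scan(cm, n_shots = 10000, seed = 314)
  p <- compute_profile(s, grid = height_grid(25, 1))
  dense <- p$height[-1][p$pavd[-1] > 0.1]
  # recovered dense bins fall within the true dense layers (within one bin)
  in_layer <- (dense > 6 - 1 & dense <= 10 + 1) | (dense > 14 - 1 & dense <= 18 + 1)
  expect_true(mean(in_layer) > 0.9)
  # mean recovered PAVD in dense layers exceeds sparse layers
  dense_mean <- mean(p$pavd[p$height > 6.5 & p$height <= 10], na.rm = TRUE)
  sparse_mean <- mean(p$pavd[p$height > 10.5 & p$height <= 14], na.rm = TRUE)
  expect_gt(dense_mean, 3 * sparse_mean)
})

test_that("top-of-canopy PAI recovery across canopy densities", {
  K <- extinction_coefficient(57.5, 1)
  ests <- sapply(c(0.5, 1.0, 1.5, 2.0), function(L) {
    s <- simulate_scan(slab_canopy(L), n_shots = 10000, seed = round(100 * L))
    top_of_canopy_pai(compute_profile(s))
  })
  expect_true(all(diff(ests) > 0))  # monotone in true density
  expect_equal(top_of_canopy_pai(
    compute_profile(make_scan(rep(0, 100)))), 0)  # all-gap scan
})
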