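# deterministic trajectory whose (x, z) histogram equals a given count matrix
traj_from_counts <- function(counts, centers_x, centers_z) {
  top <- topology(particles("BB", 1, "CARGO", group = "cargo",
                            polarity = "polar_uncharged", quiet = TRUE))
  frames <- list()
  for (i in seq_along(centers_x)) {
    for (j in seq_along(centers_z)) {
      for (k in seq_len(counts[i, j])) {
        frames[[length(frames) + 1]] <-
          frame(matrix(c(centers_x[i], 0, centers_z[j]), 1, 3),
                box = c(1000, 1000, 1000), time = length(frames))
      }
    }
  }
  trajectory(top, frames, temperature = 310)
}

test_that("bin_probability matches a brute-force per-frame binning loop", {
  pot <- potential_harmonic(k = c(0.5, 0.5), dim = 2)
  tr <- sample_boltzmann_mc(pot, 310, n_steps = 5000, seed = 2, dims = c("x", "z"))
  g <- bin_probability(tr, "cargo", c("x", "z"), bin_width = c(1, 1))
  xs <- vapply(tr$frames, function(f) f$xyz[1, 1], numeric(1))
  zs <- vapply(tr$frames, function(f) f$xyz[1, 3], numeric(1))
  for (r in sample(nrow(g$bins), 25)) {
    b <- g$bins[r, ]
    e1 <- g$edges[[1]]; e2 <- g$edges[[2]]
    manual <- sum(xs >= e1[b$i] & (xs < e1[b$i + 1] | (b$i == length(e1) - 1 & xs == e1[b$i + 1])) &
                  zs >= e2[b$j] & (zs < e2[b$j + 1] | (b$j == length(e2) - 1 & zs == e2[b$j + 1])))
    expect_equal(b$count, manual)
  }
  expect_equal(sum(g$bins$p), 1)
})

test_that("a point trajectory occupies a single bin with P = 1", {
  tr <- traj_from_counts(matrix(5, 1, 1), 3, -2)
  g <- bin_probability(tr, "cargo", c("x", "z"), bin_width = c(2, 2))
  expect_equal(sum(g$bins$p > 0), 1)
  expect_equal(max(g$bins$p), 1)
})

test_that("free energy matches the hand-evaluated two-bin inversion", {
  counts <- matrix(c(73, 27), 1, 2)
  tr <- traj_from_counts(counts, 0, c(-5, 5))
  g <- free_energy(bin_probability(tr, "cargo", c("x", "z"), bin_width = c(2, 10)),
                   temperature = 310, reference = "global_min")
  occ <- g$bins[g$bins$sampled, ]
  occ <- occ[order(occ$z), ]
  # RT(310) = 0.61597; ln(0.73/0.27) = 0.99462
  expect_equal(occ$f[2] - occ$f[1], 0.6126, tolerance = 1e-3)
})

test_that("free energy reference conventions behave and differences are invariant", {
  counts <- matrix(c(40, 10, 0, 50), 2, 2)
  tr <- traj_from_counts(counts, c(-1, 1), c(-1, 1))
  g <- bin_probability(tr, "cargo", c("x", "z"), bin_width = c(2, 2))
  pl <- free_energy(g, reference = "plateau")
  gm <- free_energy(g, reference = "global_min")
  expect_true(all(pl$bins$f[!pl$bins$sampled] == 0))
  expect_true(all(pl$bins$f[pl$bins$sampled] <= 0))
  expect_equal(min(gm$bins$f, na.rm = TRUE), 0)
  d_pl <- diff(pl$bins$f[pl$bins$sampled])
  d_gm <- diff(gm$bins$f[gm$bins$sampled])
  expect_equal(d_pl, d_gm, tolerance = 1e-12)
  # uniform occupancy with global_min reference gives F == 0 everywhere
  u <- free_energy(bin_probability(traj_from_counts(matrix(4, 2, 2), c(-1, 1), c(-1, 1)),
                                   "cargo", c("x", "z"), c(2, 2)),
                   reference = "global_min")
  expect_equal(u$bins$f, rep(0, 4), tolerance = 1e-12)
  # doubling all counts leaves free-energy differences unchanged
  g2 <- free_energy(bin_probability(traj_from_counts(2 * counts, c(-1, 1), c(-1, 1)),
                                    "cargo", c("x", "z"), c(2, 2)))
  expect_equal(diff(g2$bins$f[g2$bins$sampled]), d_pl, tolerance = 1e-12)
  expect_error(free_energy(g, temperature = -5), "positive")
})

test_that("deeper-sampled bins always get lower free energy", {
  counts <- matrix(c(5, 50, 17, 120, 3, 80), 2, 3)
  tr <- traj_from_counts(counts, c(-1, 1), c(-2, 0, 2))
  g <- free_energy(bin_probability(tr, "cargo", c("x", "z"), c(2, 2)))
  b <- g$bins[g$bins$sampled, ]
  expect_true(all(diff(b$f[order(b$count)]) <= 1e-12))
})

test_that("1D PMF of a separable distribution equals inversion of the marginal", {
  a <- c(3, 9, 6); b <- c(2, 8, 4, 1)
  counts <- outer(a, b)
  tr <- traj_from_counts(counts, c(-2, 0, 2), c(-3, -1, 1, 3))
  g <- free_energy(bin_probability(tr, "cargo", c("x", "z"), c(2, 2)))
  prof <- pmf_1d(g, axis = "z")
  rt <- 1.987e-3 * 310
  f_direct <- -rt * log(b / sum(b))
  f_direct <- f_direct - max(f_direct)
  expect_equal(prof$f, f_direct, tolerance = 1e-9)
  # a region covering the whole grid changes nothing
  whole <- pmf_1d(g, axis = "z",
                  regions = list(region_spec("w", x = c(-10, 10), z = c(-10, 10))))
  expect_equal(whole$f, prof$f, tolerance = 1e-12)
})

test_that("regions outside the grid warn and produce empty segments", {
  tr <- traj_from_counts(matrix(10, 1, 1), 0, 0)
  g <- free_energy(bin_probability(tr, "cargo", c("x", "z"), c(2, 2)))
  expect_warning(prof <- pmf_1d(g, "z", regions = list(region_spec("far", x = c(90, 99)))),
                 "outside")
  expect_equal(nrow(prof), 0)
})

test_that("the shipped stage regions match the release-pathway windows", {
  rg <- stage_regions()
  expect_equal(rg[[1]]$windows, list(xy = c(25, 40), z = c(15, 30)))
  expect_equal(rg[[2]]$windows, list(xy = c(0, 10), z = c(-5, 5)))
  expect_equal(rg[[3]]$windows, list(xy = c(10, 25), z = c(-30, -20)))
  expect_error(region_spec("bad", xy = c(5, 5)), "non-degenerate")
})

test_that("basin detection finds wells and symmetric barriers", {
  mk_prof <- function(f) {
    out <- tibble::tibble(region = "all", center = seq_along(f), count = 100L,
                          p = 1 / length(f), f = f, sampled = TRUE)
    structure(out, class = c("pmf_profile", class(out)),
              axis = "z", temperature = 310, reference = "plateau")
  }
  single <- basin_barriers(mk_prof(c(0, -1, -2, -1, 0) - 0))
  expect_equal(nrow(single$basins), 1)
  expect_equal(nrow(single$barriers), 0)

  dbl <- basin_barriers(mk_prof(c(0, -3, -1, 0, -1, -3, 0)))
  expect_equal(nrow(dbl$basins), 2)
  expect_equal(sort(dbl$barriers$barrier), c(3, 3))
})

test_that("Boltzmann inversion recovers a 1D harmonic potential up to a constant", {
  pot <- potential_harmonic(k = 0.5, dim = 1)
  tr <- sample_boltzmann_mc(pot, 310, n_steps = 2e5, seed = 14, dims = "z")
  g <- free_energy(bin_probability(tr, "cargo", c("x", "z"), c(2, 0.5)))
  b <- g$bins[g$bins$count >= 100, ]
  u <- 0.5 * 0.5 * b$z^2
  d <- b$f - u
  expect_lt(sqrt(mean((d - mean(d))^2)), 0.25)
})
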