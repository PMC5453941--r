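test_that("Metropolis sampling reproduces the harmonic Boltzmann variance", {
  pot <- potential_harmonic(k = 1, dim = 1)
  tr <- sample_boltzmann_mc(pot, 310, n_steps = 1e6, seed = 42)
  x <- vapply(tr$frames, function(f) f$xyz[1, 1], numeric(1))
  expect_equal(var(x), 1.987e-3 * 310 / 1, tolerance = 0.05)
})

test_that("a flat potential samples uniformly and chains are seed-deterministic", {
  flat <- potential_tabulated(c(-10, 10), c(0, 0))
  tr <- sample_boltzmann_mc(flat, 310, n_steps = 2e5, step_size = 10,
                            thin = 5, seed = 9)
  x <- vapply(tr$frames, function(f) f$xyz[1, 1], numeric(1))
  h <- table(cut(x, seq(-10, 10, by = 1)))
  p_hat <- as.numeric(h) / length(x)
  sigma <- sqrt(0.05 * 0.95 / length(x))
  # 4.5 sigma: allows the residual autocorrelation of the thinned chain
  expect_true(all(abs(p_hat - 0.05) < 4.5 * sigma))
  expect_true(all(x >= -10 & x <= 10))

  a <- sample_boltzmann_mc(flat, 310, n_steps = 500, seed = 7)
  b <- sample_boltzmann_mc(flat, 310, n_steps = 500, seed = 7)
  expect_identical(lapply(a$frames, `[[`, "xyz"), lapply(b$frames, `[[`, "xyz"))
})

test_that("sampled harmonic histogram passes a chi-square test against exp(-U/RT)", {
  pot <- potential_harmonic(k = 1, dim = 1)
  tr <- sample_boltzmann_mc(pot, 310, n_steps = 1e6, step_size = 2,
                            thin = 20, seed = 12)
  x <- vapply(tr$frames, function(f) f$xyz[1, 1], numeric(1))
  s <- sqrt(1.987e-3 * 310)
  edges <- c(-Inf, qnorm(seq(0.05, 0.95, by = 0.05), sd = s), Inf)
  obs <- as.numeric(table(cut(x, edges)))
  expected <- rep(length(x) / 20, 20)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 19))
})

test_that("non-finite start is an initialization error", {
  flat <- potential_tabulated(c(-10, 10), c(0, 0))
  expect_error(sample_boltzmann_mc(flat, 310, n_steps = 10, x0 = 50),
               "[Nn]on-finite")
})

test_that("replica exchange accepts every swap at equal temperatures", {
  re <- run_replica_exchange(potential_harmonic(1, dim = 1), c(310, 310),
                             n_steps = 2e4, swap_interval = 500, seed = 3)
  expect_equal(re$acceptance$ratio, 1)
})

test_that("a single-temperature ladder is rejected", {
  expect_error(run_replica_exchange(potential_harmonic(1, dim = 1), 310,
                                    n_steps = 100), "[Dd]egenerate")
})

test_that("lowest-T replica marginal matches direct sampling at the same T", {
  pot <- potential_harmonic(k = 1, dim = 1)
  re <- run_replica_exchange(pot, replica_ladder(309, 380, 4),
                             n_steps = 2.2e5, swap_interval = 500,
                             step_size = 1.5, thin = 20, seed = 5)
  direct <- sample_boltzmann_mc(pot, re$temperatures[1], n_steps = 2.2e5,
                                step_size = 1.5, thin = 20, seed = 6)
  xa <- vapply(re$analysis$frames, function(f) f$xyz[1, 1], numeric(1))
  xb <- vapply(direct$frames, function(f) f$xyz[1, 1], numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(xa, xb)$p.value), 0.01)
})

test_that("swap acceptance does not increase with wider ladder spacing", {
  pot <- potential_double_well(barrier = 4, well = 5, dim = 1)
  mean_acc <- vapply(c(380, 500, 700), function(tmax) {
    re <- run_replica_exchange(pot, replica_ladder(309, tmax, 4),
                               n_steps = 6e4, swap_interval = 300, seed = 8)
    mean(re$acceptance$ratio)
  }, numeric(1))
  expect_true(all(diff(mean_acc) <= 0.02))
})

test_that("bilayer generator hits its geometric and orientational targets", {
  b <- make_bilayer(50, headgroup_z = 24, z_sigma = 0, tilt_kappa = Inf, seed = 1)
  po4 <- b$topology$particles$name == "PO4"
  expect_equal(sort(unique(b$frame$xyz[po4, 3])), c(-24, 24))
  op <- chain_order_parameter(as_traj(b))
  expect_identical(op$mean, 1)

  # kappa from quadrature inversion of <P2>(kappa) recovers the target
  target <- 0.60
  mean_p2 <- function(k) {
    z <- integrate(function(w) exp(k * w), -1, 1)$value
    integrate(function(w) 0.5 * (3 * w^2 - 1) * exp(k * w), -1, 1)$value / z
  }
  k_oracle <- uniroot(function(k) mean_p2(k) - target, c(0.1, 100))$root
  expect_equal(kappa_for_order(target), k_oracle, tolerance = 1e-6)
  b2 <- make_bilayer(500, tilt_kappa = k_oracle, seed = 2)
  expect_equal(chain_order_parameter(as_traj(b2))$mean, 0.60, tolerance = 0.02)
})

test_that("pore assembly geometry matches closed-form ellipse chords", {
  pa <- make_pore_assembly(6, ring_radius = 24, stretch = 1)
  coms <- t(sapply(pa$topology$dimers, function(r) colMeans(pa$frame$xyz[r, ])))
  d <- sapply(1:3, function(i) sqrt(sum((coms[i, ] - coms[i + 3, ])^2)))
  expect_equal(d, rep(48, 3), tolerance = 1e-9)
  expect_equal(pore_ellipticity(pa$frame, pa$topology), 0, tolerance = 1e-9)

  s <- 1.37
  pa2 <- make_pore_assembly(6, ring_radius = 24, stretch = s)
  theta <- 2 * pi * (0:2) / 6
  chords <- 2 * 24 * sqrt(s^2 * cos(theta)^2 + sin(theta)^2)
  expect_equal(pore_ellipticity(pa2$frame, pa2$topology),
               max(chords) - min(chords), tolerance = 1e-9)
  expect_gt(pore_ellipticity(make_pore_assembly(6, 24, 1.2)$frame,
                             make_pore_assembly(6, 24, 1.2)$topology), 0)
  expect_error(make_pore_assembly(5), "even")
})

test_that("cargo replica placement spans 6 axial positions x 8 orientations", {
  cargo <- ideal_helix(6, group = "cargo")
  reps <- place_cargo_replicas(cargo, seed = 1)
  expect_equal(nrow(reps), 48)
  zs <- sort(unique(reps$z))
  expect_equal(diff(zs), rep(13, 5))
  expect_equal(mean(zs), 0)
  coms <- t(sapply(reps$frame, function(f) colMeans(f$xyz)))
  expect_equal(coms[, 3], reps$z, tolerance = 1e-9, ignore_attr = TRUE)

  one <- place_cargo_replicas(cargo, n_axial = 1, n_orientations = 1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$z, 0)

  a <- place_cargo_replicas(cargo, seed = 9)
  b <- place_cargo_replicas(cargo, seed = 9)
  expect_identical(a$frame[[10]]$xyz, b$frame[[10]]$xyz)
})

test_that("ion counts follow round(c N_A V) and the system stays neutral", {
  s <- toy_protein("ALA")
  s$frame <- frame(s$frame$xyz, box = c(100, 100, 100))
  out <- add_ions(s$topology, s$frame, c("NA" = 0.035, "CA" = 0.035), seed = 1)
  expect_equal(unname(out$counts[c("NA", "CA")]), c(21, 21))
  expect_equal(unname(out$counts[["CL"]]), 21 + 2 * 21)
  expect_equal(out$charge, 0)
  expect_error(add_ions(s$topology, s$frame, c("NA" = -0.01)), "negative|non-negative")

  # no enrichment: flat z histogram within loose multinomial bounds
  big <- add_ions(s$topology, frame(s$frame$xyz, box = c(60, 60, 120)),
                  c("NA" = 0.4), surface_enrichment = 1, seed = 3)
  z <- big$frame$xyz[big$topology$particles$group == "ion", 3]
  h <- as.numeric(table(cut(z, seq(-60, 60, by = 20))))
  p_hat <- h / length(z)
  expect_true(all(abs(p_hat - 1 / 6) < 4 * sqrt((1 / 6) * (5 / 6) / length(z))))
})

test_that("calcium surface enrichment concentrates ions at the leaflet slabs", {
  s <- toy_protein("ALA")
  out <- add_ions(s$topology, frame(s$frame$xyz, box = c(80, 80, 120)),
                  c("CA" = 0.2), surface_enrichment = 8, headgroup_z = 24,
                  slab_halfwidth = 5, seed = 4)
  ion <- out$topology$particles$group == "ion" &
         out$topology$particles$name == "CA"
  z <- out$frame$xyz[ion, 3]
  in_slab <- mean(abs(abs(z) - 24) <= 5)
  # slabs cover 20/120 of the box; x8 enrichment predicts 8*20/(8*20+100)
  expect_equal(in_slab, 160 / 260, tolerance = 0.1)
})
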