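#' Sample a single-particle Boltzmann distribution by Metropolis Monte Carlo
#'
#' Random-walk Metropolis chain targeting `exp(-U/RT)`, the synthetic
#' stand-in used to verify Boltzmann inversion: a histogram of the
#' returned positions, inverted with [free_energy()], must recover the
#' input potential up to an additive constant.  Kinetics are not
#' meaningful; only the stationary distribution is.
#'
#' @param pot A [potential_harmonic()]-family `potential_spec`.
#' @param temperature Temperature, K.
#' @param n_steps Number of Metropolis steps (after which a
#'   `burn_in` fraction is discarded).
#' @param step_size Half-width of the uniform proposal, Angstrom.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param burn_in Fraction of initial samples discarded (default 0.1).
#' @param thin Keep every `thin`-th step.
#' @param x0 Start point (defaults to the potential's first center/node).
#' @param dims Cartesian axes the potential dimensions live on, e.g.
#'   `c("x", "z")`; unused axes are zero.
#' @return A single-particle [trajectory()] tagged with `temperature`.
#' @export
sample_boltzmann_mc <- function(pot, temperature = 310, n_steps = 1e5,
                                step_size = 0.5, seed = NULL, burn_in = 0.1,
                                thin = 1L, x0 = NULL,
                                dims = c("x", "y", "z")[seq_len(pot$dim)]) {
  stopifnot(inherits(pot, "potential_spec"), n_steps >= 1)
  if (length(dims) != pot$dim) abort("`dims` must name one axis per potential dimension.")
  axis_idx <- match(dims, c("x", "y", "z"))
  if (any(is.na(axis_idx)) || anyDuplicated(axis_idx)) abort("`dims` must be distinct axes among x, y, z.")
  if (is.null(x0)) x0 <- default_start(pot)
  run <- function() {
    mc_chain_cpp(form_code(pot), pot$dim, pot$params, pot$grid$x, pot$grid$y,
                 pot$grid$v, as.numeric(x0), as.integer(n_steps),
                 step_size, R_KCAL * temperature, as.integer(thin))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  s <- res$samples
  keep <- seq.int(floor(nrow(s) * burn_in) + 1L, nrow(s))
  s <- s[keep, , drop = FALSE]
  top <- topology(particles(name = "BB", resid = 1, resname = "CARGO",
                            group = "cargo", polarity = "polar_uncharged",
                            quiet = TRUE))
  frames <- lapply(seq_len(nrow(s)), function(i) {
    xyz <- matrix(0, 1, 3)
    xyz[1, axis_idx] <- s[i, ]
    frame(xyz, box = c(1000, 1000, 1000), time = (keep[i] - 1) * thin)
  })
  out <- trajectory(top, frames, temperature = temperature)
  attr(out, "mc_acceptance") <- res$acceptance
  out
}

default_start <- function(pot) {
  switch(pot$form,
    harmonic = pot$params[pot$dim + seq_len(pot$dim)],
    double_well = {
      d <- pot$dim
      ctr <- pot$params[3 + d + seq_len(d)]
      ctr[pot$params[1] + 1] <- ctr[pot$params[1] + 1] + pot$params[3]
      ctr
    },
    tabulated = {
      x <- mean(range(pot$grid$x))
      if (pot$dim == 2) c(x, mean(range(pot$grid$y))) else x
    }
  )
}

#' Build a replica temperature ladder
#'
#' Geometrically spaced temperatures between `t_min` and `t_max`
#' (default 309-380 K, the range used for the pore/cargo sampling).
#'
#' @param t_min,t_max Temperature bounds, K.
#' @param n Number of replicas (>= 2).
#' @return Ascending numeric vector of temperatures.
#' @export
replica_ladder <- function(t_min = 309, t_max = 380, n = 8) {
  if (n < 2) abort("A replica ladder needs at least 2 temperatures.")
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Replica-exchange Metropolis Monte Carlo
#'
#' Runs one Metropolis chain per temperature and attempts neighbor
#' configuration swaps every `swap_interval` steps with the exchange
#' criterion `min(1, exp[(beta_i - beta_j)(U_i - U_j)])` (alternating
#' even/odd neighbor pairs).  The lowest-temperature trajectory is the
#' analysis trajectory (analyses are run at the bottom of the ladder,
#' 310 K body temperature in the emulated setup, where the default ladder
#' spans 309-380 K with swaps every 1000 steps).
#'
#' @param pot A `potential_spec`.
#' @param temperatures Ascending ladder, K (>= 2 entries).
#' @param n_steps Steps per replica.
#' @param swap_interval Steps between swap attempts (default 1000).
#' @param step_size,seed,burn_in,thin,x0,dims As in [sample_boltzmann_mc()].
#' @return Object of class `replica_exchange`: list with `trajectories`
#'   (one [trajectory()] per temperature), `acceptance` (tibble of
#'   per-pair swap statistics), `analysis` (the lowest-T trajectory) and
#'   `temperatures`.
#' @export
run_replica_exchange <- function(pot, temperatures = replica_ladder(),
                                 n_steps = 1e5, swap_interval = 1000,
                                 step_size = 0.5, seed = NULL, burn_in = 0.1,
                                 thin = 1L, x0 = NULL,
                                 dims = c("x", "y", "z")[seq_len(pot$dim)]) {
  stopifnot(inherits(pot, "potential_spec"))
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L) {
    abort("Degenerate ladder: replica exchange needs at least 2 temperatures.")
  }
  if (is.unsorted(temperatures)) abort("`temperatures` must be ascending.")
  run <- function() re_run(pot, temperatures, n_steps, swap_interval,
                           step_size, thin, x0)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  axis_idx <- match(dims, c("x", "y", "z"))
  trajs <- purrr::map2(res$samples, seq_along(temperatures), function(s, i) {
    keep <- seq.int(floor(nrow(s) * burn_in) + 1L, nrow(s))
    s <- s[keep, , drop = FALSE]
    top <- topology(particles(name = "BB", resid = 1, resname = "CARGO",
                              group = "cargo", polarity = "polar_uncharged",
                              quiet = TRUE))
    frames <- lapply(seq_len(nrow(s)), function(k) {
      xyz <- matrix(0, 1, 3)
      xyz[1, axis_idx] <- s[k, ]
      frame(xyz, box = c(1000, 1000, 1000), time = (keep[k] - 1) * thin)
    })
    trajectory(top, frames, temperature = temperatures[i])
  })
  acc <- tibble(
    pair = sprintf("%d-%d", seq_len(length(temperatures) - 1L), 2:length(temperatures)),
    t_low = temperatures[-length(temperatures)], t_high = temperatures[-1],
    attempts = res$attempts, accepted = res$accepted,
    ratio = ifelse(res$attempts > 0, res$accepted / res$attempts, NA_real_)
  )
  structure(list(trajectories = trajs, acceptance = acc,
                 analysis = trajs[[1]], temperatures = temperatures),
            class = "replica_exchange")
}

re_run <- function(pot, temperatures, n_steps, swap_interval, step_size, thin, x0) {
  n_rep <- length(temperatures)
  beta <- 1 / (R_KCAL * temperatures)
  if (is.null(x0)) x0 <- default_start(pot)
  states <- replicate(n_rep, as.numeric(x0), simplify = FALSE)
  energies <- rep(potential_energy(pot, matrix(x0, 1)), n_rep)
  samples <- replicate(n_rep, NULL, simplify = FALSE)
  attempts <- accepted <- integer(n_rep - 1L)
  n_seg <- ceiling(n_steps / swap_interval)
  fc <- form_code(pot)
  for (seg in seq_len(n_seg)) {
    len <- min(swap_interval, n_steps - (seg - 1L) * swap_interval)
    for (r in seq_len(n_rep)) {
      res <- mc_chain_cpp(fc, pot$dim, pot$params, pot$grid$x, pot$grid$y,
                          pot$grid$v, states[[r]], as.integer(len),
                          step_size, 1 / beta[r], as.integer(thin))
      states[[r]] <- res$state
      energies[r] <- res$energy
      samples[[r]] <- c(samples[[r]], list(res$samples))
    }
    first <- if (seg %% 2L == 1L) 1L else 2L
    pairs <- if (first <= n_rep - 1L) seq(first, n_rep - 1L, by = 2L) else integer(0)
    for (i in pairs) {
      attempts[i] <- attempts[i] + 1L
      delta <- (beta[i] - beta[i + 1L]) * (energies[i] - energies[i + 1L])
      if (delta >= 0 || runif(1) < exp(delta)) {
        accepted[i] <- accepted[i] + 1L
        tmp <- states[[i]]; states[[i]] <- states[[i + 1L]]; states[[i + 1L]] <- tmp
        energies[c(i, i + 1L)] <- energies[c(i + 1L, i)]
      }
    }
  }
  list(samples = lapply(samples, function(s) do.call(rbind, s)),
       attempts = attempts, accepted = accepted)
}

#' @export
print.replica_exchange <- function(x, ...) {
  cat(sprintf("<replica_exchange> %d replicas, %g-%g K, %d frames at the analysis temperature\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              n_frames(x$analysis)))
  invisible(x)
}

#' @export
glance.replica_exchange <- function(x, ...) {
  tibble(
    n_replicas = length(x$temperatures),
    t_min = min(x$temperatures), t_max = max(x$temperatures),
    mean_swap_ratio = mean(x$acceptance$ratio, na.rm = TRUE),
    min_swap_ratio = min(x$acceptance$ratio, na.rm = TRUE),
    n_frames = n_frames(x$analysis)
  )
}

#' @export
tidy.replica_exchange <- function(x, ...) x$acceptance
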