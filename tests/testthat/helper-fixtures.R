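# Fixtures are built in code; nothing binary ships with the tests.

# toy protein structure: one bead per residue on a line, mixed polarity
toy_protein <- function(resnames = c("GLY", "LYS", "ASP", "LEU"),
                        group = "pore", chain = "A", spacing = 4) {
  n <- length(resnames)
  p <- particles(name = "CA", resid = seq_len(n), resname = resnames,
                 chain = chain, group = group, quiet = TRUE)
  list(topology = topology(p),
       frame = frame(cbind(seq_len(n) * spacing, 0, 0), box = c(100, 100, 120)))
}

# deterministic single-frame trajectory from a topology/frame pair
as_traj <- function(s, temperature = 310) {
  trajectory(s$topology, list(s$frame), temperature = temperature)
}

# brute-force O(N^2) residue-residue minimum-distance contact oracle
naive_contact_matrix <- function(xyz, resid_a, rows_a, resid_b, rows_b,
                                 cutoff, box = NULL) {
  ua <- unique(resid_a)
  ub <- unique(resid_b)
  m <- matrix(0, length(ua), length(ub))
  for (i in seq_along(ua)) {
    for (j in seq_along(ub)) {
      best <- Inf
      for (a in rows_a[resid_a == ua[i]]) {
        for (b in rows_b[resid_b == ub[j]]) {
          d <- xyz[a, ] - xyz[b, ]
          if (!is.null(box)) d <- d - box * round(d / box)
          best <- min(best, sqrt(sum(d^2)))
        }
      }
      m[i, j] <- as.numeric(best < cutoff)
    }
  }
  m
}

# random rigid transform (proper rotation + translation)
random_transform <- function(seed = 1) {
  withr::with_seed(seed, {
    a <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])), 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, byrow = TRUE)
    list(R = Rz %*% Ry %*% Rx, t = runif(3, -20, 20))
  })
}

# two-helix CG fixture with known geometry (chain A, residues 1-12 / 17-28)
two_helix_cg <- function() {
  h1 <- ideal_helix(12, chain = "A")
  h2 <- ideal_helix(12, chain = "A")
  tr <- random_transform(4)
  h2$frame$xyz <- sweep(h2$frame$xyz %*% t(tr$R), 2, c(15, 4, 2), `+`)
  h2$topology$particles$resid <- h2$topology$particles$resid + 16L
  ptab <- rbind(h1$topology$particles, h2$topology$particles)
  ptab$index <- seq_len(nrow(ptab)) - 1L
  list(topology = topology(ptab),
       frame = frame(rbind(h1$frame$xyz, h2$frame$xyz)),
       helix_rows = list(1:12, 13:24))
}
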