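two_bead_system <- function(separation) {
  p <- particles("BB", 1:2, c("LYS", "ASP"), group = c("pore", "cargo"),
                 quiet = TRUE)
  top <- topology(p)
  fr <- frame(rbind(c(0, 0, 0), c(separation, 0, 0)), box = c(100, 100, 100))
  trajectory(top, list(fr))
}

test_that("contact entries flip at the 6.5 A cutoff", {
  expect_equal(as.numeric(contact_matrix(two_bead_system(5))$matrix), 1)
  expect_equal(as.numeric(contact_matrix(two_bead_system(7))$matrix), 0)
})

test_that("contact matrix equals the naive O(N^2) oracle exactly", {
  set.seed(17)
  n_res <- 60
  beads_per <- sample(1:3, n_res, replace = TRUE)
  resid <- rep(seq_len(n_res), beads_per)
  grp <- ifelse(resid <= n_res / 2, "pore", "cargo")
  p <- particles("BB", resid, "ALA", group = grp, quiet = TRUE)
  top <- topology(p)
  box <- c(40, 40, 40)
  xyz <- cbind(runif(nrow(p), 0, 40), runif(nrow(p), 0, 40), runif(nrow(p), 0, 40))
  tr <- trajectory(top, list(frame(xyz, box = box)))
  cm <- contact_matrix(tr, "pore", "cargo", cutoff = 6.5)
  ra <- which(grp == "pore"); rb <- which(grp == "cargo")
  oracle <- naive_contact_matrix(xyz, resid[ra], ra, resid[rb], rb, 6.5, box)
  expect_identical(unname(cm$matrix), oracle)
})

test_that("contact matrices transpose and grow monotonically with the cutoff", {
  set.seed(18)
  p <- particles("BB", 1:30, "ALA", group = rep(c("pore", "cargo"), each = 15),
                 quiet = TRUE)
  tr <- trajectory(topology(p),
                   list(frame(matrix(runif(90, 0, 25), 30, 3), box = c(25, 25, 25))))
  cm_ab <- contact_matrix(tr, "pore", "cargo")
  cm_ba <- contact_matrix(tr, "cargo", "pore")
  expect_identical(unname(cm_ab$matrix), unname(t(cm_ba$matrix)))
  for (co in c(3, 5, 8, 12)) {
    small <- contact_matrix(tr, "pore", "cargo", cutoff = co)$matrix
    large <- contact_matrix(tr, "pore", "cargo", cutoff = co + 2)$matrix
    expect_true(all(large >= small))
  }
  expect_error(contact_matrix(tr, "pore", "pore"), "disjoint|overlap")
})

test_that("contact-number profiles count partners and match recounts", {
  z <- two_bead_system(20)
  cm0 <- contact_matrix(z)
  prof0 <- contact_number_profiles(cm0)
  expect_equal(prof0$rows$n_contacts, 0L)
  expect_equal(prof0$cols$n_contacts, 0L)

  cm1 <- contact_matrix(two_bead_system(4))
  prof1 <- contact_number_profiles(cm1)
  expect_equal(prof1$rows$n_contacts, 1L)
  expect_equal(prof1$cols$n_contacts, 1L)

  set.seed(19)
  p <- particles("BB", 1:40, "ALA", group = rep(c("pore", "cargo"), each = 20),
                 quiet = TRUE)
  tr <- trajectory(topology(p),
                   list(frame(matrix(runif(120, 0, 30), 40, 3), box = c(30, 30, 30))))
  cm <- contact_matrix(tr)
  prof <- contact_number_profiles(cm)
  expect_equal(prof$rows$n_contacts, unname(rowSums(cm$matrix > 0)))
  expect_equal(prof$cols$n_contacts, unname(colSums(cm$matrix > 0)))
})

test_that("polarity contact fractions classify interfaces correctly", {
  mk <- function(res_a, res_b) {
    n <- length(res_a) + length(res_b)
    p <- particles("BB", 1:n, c(res_a, res_b),
                   group = rep(c("pore", "cargo"), c(length(res_a), length(res_b))),
                   quiet = TRUE)
    xyz <- cbind(c(seq_along(res_a), seq_along(res_b)) * 2,
                 rep(c(0, 1), c(length(res_a), length(res_b))), 0)
    trajectory(topology(p), list(frame(xyz, box = c(100, 100, 100))))
  }
  all_philic <- polarity_contact_fractions(contact_matrix(mk(rep("LYS", 4), rep("ASP", 4))))
  expect_equal(all_philic$percent[all_philic$category == "hydrophilic_hydrophilic"], 100)
  all_phobic <- polarity_contact_fractions(contact_matrix(mk(rep("LEU", 4), rep("VAL", 4))))
  expect_equal(all_phobic$percent[all_phobic$category == "hydrophobic_hydrophobic"], 100)

  set.seed(20)
  res_pool <- c("LYS", "GLU", "SER", "LEU", "VAL", "ALA")
  ra <- sample(res_pool, 8, replace = TRUE)
  rb <- sample(res_pool, 8, replace = TRUE)
  tr <- mk(ra, rb)
  cm <- contact_matrix(tr)
  got <- polarity_contact_fractions(cm)
  # hand tally over contacting pairs
  philic <- c("LYS", "GLU", "SER")
  inc <- which(cm$matrix > 0, arr.ind = TRUE)
  hand <- table(factor(
    ifelse(ra[inc[, 1]] %in% philic & rb[inc[, 2]] %in% philic, "hh",
           ifelse(!ra[inc[, 1]] %in% philic & !rb[inc[, 2]] %in% philic, "bb", "mx")),
    levels = c("hh", "bb", "mx")))
  expect_equal(got$n_pairs, as.integer(hand), ignore_attr = TRUE)
  expect_equal(sum(got$percent), 100)
})

test_that("interface counts reproduce constructed geometric fixtures", {
  # ideal N-H...O hydrogen bond: D-A 2.9 A, angle 180 deg
  p <- particles(name = c("N", "H", "O"), resid = c(1, 1, 2),
                 resname = c("SER", "SER", "GLY"), group = c("pore", "pore", "cargo"),
                 quiet = TRUE)
  fr <- frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))
  out <- interface_counts(topology(p), fr, "pore", "cargo")
  expect_equal(out$h_bonds, 1L)

  # Lys NZ 3.5 A from Glu OE1 is one salt bridge
  p2 <- particles(name = c("NZ", "OE1"), resid = c(1, 2),
                  resname = c("LYS", "GLU"), group = c("pore", "cargo"),
                  quiet = TRUE)
  fr2 <- frame(rbind(c(0, 0, 0), c(3.5, 0, 0)))
  out2 <- suppressWarnings(interface_counts(topology(p2), fr2, "pore", "cargo"))
  expect_equal(out2$salt_bridges, 1L)
  # no hydrogens: distance-only fallback warns
  expect_warning(interface_counts(topology(p2), fr2, "pore", "cargo"), "fallback")

  # two opposite unit charges at 10 A: Coulomb = -332.06/10
  p3 <- particles(name = c("Q1", "Q2"), resid = c(1, 2), resname = c("XXA", "XXB"),
                  group = c("pore", "cargo"), quiet = TRUE)
  fr3 <- frame(rbind(c(0, 0, 0), c(10, 0, 0)))
  tab <- data.frame(name = c("Q1", "Q2"), charge = c(1, -1),
                    sigma = c(0, 0), epsilon = c(0, 0))
  out3 <- suppressWarnings(
    interface_counts(topology(p3), fr3, "pore", "cargo", params = tab))
  expect_equal(out3$elec_energy, -33.206, tolerance = 1e-6)
  expect_equal(out3$vdw_energy, 0)
  expect_equal(out3$elec_fraction, 1)
})

test_that("hydrophobic side-chain contacts are counted per residue pair", {
  p <- particles(name = c("CB", "CG", "CB"), resid = c(1, 1, 2),
                 resname = c("LEU", "LEU", "VAL"), group = c("pore", "pore", "cargo"),
                 quiet = TRUE)
  fr <- frame(rbind(c(0, 0, 0), c(1.5, 0, 0), c(4, 0, 0)))
  out <- suppressWarnings(interface_counts(topology(p), fr, "pore", "cargo"))
  expect_equal(out$hydrophobic_contacts, 1L)  # one residue pair despite 2 atom pairs
})
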