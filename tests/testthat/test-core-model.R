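test_that("polarity classification follows the shipped table, unknowns fall back", {
  expect_equal(classify_polarity(c("LYS", "ARG", "HIS")), rep("positive", 3))
  expect_equal(classify_polarity(c("ASP", "GLU")), rep("negative", 3 - 1))
  expect_equal(classify_polarity(c("GLY", "TRP", "CYS")), rep("polar_uncharged", 3))
  expect_equal(classify_polarity("HEM"), "hydrophobic")
  expect_warning(cls <- classify_polarity(c("DSPC", "LEU")), "DSPC")
  expect_equal(cls, c("hydrophobic", "hydrophobic"))
})

test_that("topology enforces unique indices and dimer partition", {
  p <- particles("BB", 1:4, "ALA", quiet = TRUE)
  bad <- p; bad$index[2] <- bad$index[1]
  expect_error(topology(bad), "unique")
  expect_error(topology(p, dimers = list("1" = 1:2)), "partition")
  expect_silent(topology(p, dimers = list("1" = 1:2, "2" = 3:4)))
})

test_that("PDB and GRO files round-trip within format precision", {
  fixtures <- list(
    toy_protein(c("GLY", "LYS")),
    make_bilayer(5, seed = 1),
    { s <- toy_protein(c("SER", "GLU", "PHE")); s$frame$box <- c(100, 100, 120); s }
  )
  for (fmt in c("pdb", "gro")) {
    for (s in fixtures) {
      # the PDB resName field cannot carry 4-character CG lipid names
      if (fmt == "pdb" && any(nchar(s$topology$particles$resname) > 3)) next
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_structure(s$topology, s$frame, path)
      r <- read_structure(path, quiet = TRUE)
      expect_equal(nrow(r$topology$particles), n_particles(s$topology))
      expect_equal(r$topology$particles$resid, s$topology$particles$resid)
      expect_equal(r$topology$particles$name, s$topology$particles$name)
      expect_equal(r$frame$xyz, s$frame$xyz, tolerance = 1e-3,
                   ignore_attr = TRUE)
      expect_equal(r$frame$box, s$frame$box, tolerance = 1e-3)
    }
  }
})

test_that("two-residue PDB fixture classifies LYS as positive on read", {
  s <- toy_protein(c("GLY", "LYS"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s$topology, s$frame, path)
  r <- read_structure(path, quiet = TRUE)
  expect_equal(r$topology$particles$polarity, c("polar_uncharged", "positive"))
})

test_that("GRO box field is carried through (nm converted to Angstrom)", {
  s <- toy_protein("ALA")
  s$frame <- frame(s$frame$xyz, box = c(100, 100, 120))
  path <- withr::local_tempfile(fileext = ".gro")
  write_structure(s$topology, s$frame, path)
  expect_equal(read_structure(path, quiet = TRUE)$frame$box, c(100, 100, 120))
})

test_that("text trajectories round-trip, order by time, and reject truncation", {
  pot <- potential_harmonic(1, dim = 1)
  tr <- sample_boltzmann_mc(pot, 310, n_steps = 100, seed = 3, burn_in = 0)
  expect_equal(n_frames(tr), 100)
  path <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(tr, path)
  r <- read_trajectory(path, tr$topology)
  expect_equal(n_frames(r), 100)
  times <- vapply(r$frames, function(f) f$time, numeric(1))
  expect_true(all(diff(times) > 0))
  expect_lt(max(abs(r$frames[[5]]$xyz - tr$frames[[5]]$xyz)), 1e-3)

  one <- trajectory(tr$topology, tr$frames[1])
  write_trajectory(one, path)
  expect_equal(n_frames(read_trajectory(path, tr$topology)), 1)

  lines <- readLines(path)
  writeLines(head(lines, length(lines) - 1), path)
  expect_error(read_trajectory(path, tr$topology), "[Tt]runcated")

  big <- topology(particles("BB", 1:2, "ALA", quiet = TRUE))
  write_trajectory(one, path)
  expect_error(read_trajectory(path, big), "expected 2")
})

test_that("recenter zeroes the pore xy-COM and maps the leaflet midplane to z = 0", {
  pore <- particles("BB", 1:4, "ALA", group = "pore", quiet = TRUE)
  po4 <- particles("PO4", 5:8, "DSPC", group = "lipid", quiet = TRUE)
  top <- topology(rbind(pore, dplyr::mutate(po4, index = 4:7)))
  xyz <- rbind(
    cbind(c(4, 6, 5, 5), c(-4, -2, -3, -3), c(0, 0, 1, -1)),  # pore COM (5,-3,0)
    cbind(0, 0, c(40, 40, 88, 88))                            # leaflets at 40 and 88
  )
  tr <- trajectory(top, list(frame(xyz, box = c(200, 200, 200))))
  rc <- recenter(tr, "pore", "lipid")
  com <- colMeans(rc$frames[[1]]$xyz[1:4, ])
  expect_equal(com[1:2], c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sort(unique(rc$frames[[1]]$xyz[5:8, 3])), c(-24, 24))
  # idempotency
  rc2 <- recenter(rc, "pore", "lipid")
  expect_equal(rc2$frames[[1]]$xyz, rc$frames[[1]]$xyz, tolerance = 1e-9)
  expect_error(recenter(tr, integer(0)), "empty")
})

test_that("minimum-image COM matches the unwrapped copy for a boundary-split pore", {
  set.seed(21)
  box <- c(50, 50, 50)
  base <- cbind(runif(20, -6, 6), runif(20, -6, 6), runif(20, -6, 6))
  shifted <- sweep(base, 2, c(48, 25, 10), `+`)       # straddles x boundary
  wrapped <- shifted - sweep(floor(sweep(shifted, 2, box, `/`)), 2, box, `*`)
  top <- topology(particles("BB", 1:20, "ALA", group = "pore", quiet = TRUE))
  tr_w <- trajectory(top, list(frame(wrapped, box = box)))
  rc <- recenter(tr_w, "pore")
  com_unwrapped <- colMeans(shifted)
  # after recentering, the bead cloud should sit at (original - unwrapped COM),
  # modulo whole box lengths
  expect_d <- sweep(shifted, 2, com_unwrapped)
  got <- rc$frames[[1]]$xyz
  diff <- got - expect_d
  diff <- diff - sweep(round(sweep(diff, 2, box, `/`)), 2, box, `*`)
  expect_lt(max(abs(diff)), 1e-6)
})

test_that("Rg and RMSD behave as the formulas dictate", {
  sq <- frame(cbind(c(0, 10, 0, 10), c(0, 0, 10, 10), 0))
  top <- topology(particles("BB", 1:4, "ALA", group = "pore", quiet = TRUE))
  tr <- trajectory(top, list(sq))
  out <- rg_rmsd_series(tr, "pore")
  expect_equal(out$rg, sqrt(50))
  expect_equal(out$rmsd, 0)

  tf <- random_transform(2)
  moved <- frame(sweep(sq$xyz %*% t(tf$R), 2, tf$t, `+`))
  tr2 <- trajectory(top, list(sq, moved))
  out2 <- rg_rmsd_series(tr2, "pore", reference = 1L)
  expect_lt(out2$rmsd[2], 1e-6)
  expect_equal(out2$rg[2], sqrt(50), tolerance = 1e-9)

  expect_error(rg_rmsd_series(tr, "pore", reference = frame(matrix(0, 2, 3))),
               "size")
})

test_that("rmsd_matrix is symmetric, zero-diagonal, and matches pairwise fits", {
  set.seed(8)
  top <- topology(particles("BB", 1:6, "ALA", group = "pore", quiet = TRUE))
  frames <- lapply(1:3, function(i) frame(matrix(rnorm(18, sd = 3), 6, 3)))
  tr <- trajectory(top, c(frames[1], frames[1], frames[2], frames[3]))
  m <- rmsd_matrix(tr, "pore")
  expect_equal(m[1, 2], 0)
  expect_equal(diag(m), rep(0, 4), ignore_attr = TRUE)
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_equal(m[3, 4], rmsd_fit(frames[[2]]$xyz, frames[[3]]$xyz))
  expect_error(rmsd_matrix(trajectory(top, frames[1]), "pore"), "2 frames")
})

test_that("triclinic-style invalid boxes are rejected", {
  expect_error(frame(matrix(0, 1, 3), box = c(100, 100)), "orthorhombic")
  expect_error(frame(matrix(0, 1, 3), box = c(100, -1, 100)), "orthorhombic")
})
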