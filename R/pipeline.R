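#' Generate the bundled end-to-end demo system
#'
#' Builds a self-contained synthetic pore/bilayer/cargo/ion system that
#' exercises every analysis stage: a six-dimer pore ring whose x-stretch
#' responds to the cargo position (so the shape coordinate is
#' informative), a bilayer with headgroup planes at +-24 A and a chain
#' tilt targeting a mean order parameter of 0.60, a cargo whose center of
#' mass follows a Metropolis chain on a double-well axial potential with
#' a 3 kcal/mol barrier, and 0.035 M NaCl + CaCl2 counter ions.  All
#' randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @param n_frames Number of trajectory frames.
#' @param n_lipids_per_leaflet Lipids per leaflet.
#' @param mc_thin Metropolis steps between stored frames.
#' @return List with `trajectory` (pore-centered), `potential` (the
#'   ground-truth axial potential) and `pore`, `cargo` (component
#'   structures).
#' @export
generate_demo <- function(seed = 1, n_frames = 120, n_lipids_per_leaflet = 64,
                          mc_thin = 200) {
  seed <- as.integer(seed)
  pore <- make_pore_assembly(n_dimers = 6, ring_radius = 24,
                             beads_per_dimer = 12)
  bil0 <- make_bilayer(n_lipids_per_leaflet, headgroup_z = 24, z_sigma = 1,
                       tilt_kappa = kappa_for_order(0.60), seed = seed + 101L)
  cargo <- ideal_helix(8, resnames = c("LYS", "GLU", "SER", "LEU"),
                       chain = "Z", group = "cargo")
  # axial double well (wells at the two pore mouths) with the cargo held
  # off-axis so it samples the pore wall region
  pot <- potential_double_well(barrier = 3, well = 13, axis = 2, dim = 2,
                               k_other = 0.02, center = c(10, 0))
  mc <- sample_boltzmann_mc(pot, temperature = 310,
                            n_steps = n_frames * mc_thin, seed = seed + 202L,
                            burn_in = 0, thin = mc_thin, dims = c("x", "z"))
  cpos <- t(vapply(mc$frames, function(f) f$xyz[1, ], numeric(3)))
  # box wide enough that the pore ring stays within half the box (the
  # minimum-image unwrapping in recenter() requires it)
  box <- c(130, 130, 120)
  ions <- add_ions(topology(particles(name = character(0), resid = integer(0),
                                      resname = character(0), quiet = TRUE)),
                   frame(matrix(0, 0, 3), box = box), seed = seed + 303L)
  cargo_base <- sweep(cargo$frame$xyz, 2, colMeans(cargo$frame$xyz))
  n_pore <- nrow(pore$frame$xyz)
  ptab <- dplyr::bind_rows(pore$topology$particles, bil0$topology$particles,
                           cargo$topology$particles, ions$topology$particles)
  ptab$index <- seq_len(nrow(ptab)) - 1L
  top <- topology(ptab, dimers = pore$topology$dimers)
  frames <- lapply(seq_len(n_frames), function(i) {
    # pore stretches along x when the cargo sits mid-cavity
    s <- 1 + 0.15 * max(0, 1 - (cpos[i, 3] / 13)^2)
    pxyz <- pore$frame$xyz
    pxyz[, 1] <- pxyz[, 1] * s
    bil <- make_bilayer(n_lipids_per_leaflet, headgroup_z = 24, z_sigma = 1,
                        tilt_kappa = kappa_for_order(0.60),
                        box = box, seed = seed + 1000L + i)
    cxyz <- sweep(cargo_base, 2, cpos[i, ], `+`)
    frame(rbind(pxyz, bil$frame$xyz, cxyz, ions$frame$xyz), box = box,
          time = (i - 1) * 30)
  })
  list(trajectory = trajectory(top, frames, temperature = 310),
       potential = pot, pore = pore, cargo = cargo, n_pore = n_pore)
}

.pipeline_stages <- c("simulate", "membrane", "landscape", "pmf", "contacts",
                      "shape", "surface", "backmap")

#' Run the configured analysis pipeline
#'
#' Config-driven orchestration of all stages over the bundled synthetic
#' demo system, writing plot-ready CSV tables and JSON metadata into
#' `outdir`.  Every output is deterministic given the config: all
#' randomness is seeded from `seed`, and the run metadata (config hash,
#' package version, seed) is written to `meta.json`.
#'
#' The config is a YAML file (or an R list) with optional keys: `seed`
#' (integer), `outdir` (path), `stages` (subset of `simulate, membrane,
#' landscape, pmf, contacts, shape, surface, backmap`), `demo`
#' (`n_frames`, `n_lipids_per_leaflet`), `landscape` (`bin_width`,
#' `shape_bin_width`), `pmf` (`axis`, `regions`: "all" or "stages"),
#' `contacts` (`cutoff`, `threshold`), `membrane` (`bin_width`), `shape`
#' (`probe_step`, `slab_halfwidth`), `surface` (`n_points`).  Unknown
#' keys or stages are a validation error.
#'
#' @param config Path to a YAML config or a named list (`NULL` for all
#'   defaults).
#' @param outdir Output directory (overrides the config).
#' @param seed Seed (overrides the config; default 1).
#' @return Invisibly, a named list of the produced file paths.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else (config %||% list())
  known <- c("seed", "outdir", "stages", "demo", "landscape", "pmf",
             "contacts", "membrane", "shape", "surface")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    abort(sprintf("Config validation failed; unknown key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  outdir <- outdir %||% cfg$outdir %||% abort("No `outdir` given (argument or config).")
  stages <- cfg$stages %||% .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) {
    abort(sprintf("Config validation failed; unknown stage(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  logf <- file.path(outdir, "run.log")
  cat(sprintf("porescape pipeline, seed %d\n", seed), file = logf)
  note <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  meta <- list(package = "porescape",
               version = as.character(utils::packageVersion("porescape")),
               seed = seed, config = cfg,
               config_md5 = unname(tools::md5sum(tmp)),
               stages = stages)
  jsonlite::write_json(meta, file.path(outdir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  files$meta <- file.path(outdir, "meta.json")

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  out_csv <- function(x, name) {
    path <- file.path(outdir, name)
    readr::write_csv(as.data.frame(x), path)
    files[[name]] <<- path
    path
  }
  out_json <- function(x, name) {
    path <- file.path(outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[[name]] <<- path
    path
  }

  demo_args <- cfg$demo %||% list()
  demo <- run_stage("simulate", function() {
    do.call(generate_demo, c(list(seed = seed), demo_args))
  })
  traj <- recenter(demo$trajectory, pore_sel = "pore",
                   leaflet_sel = function(p) p$group == "lipid" & p$name == "PO4")
  if ("simulate" %in% stages) {
    note("simulate: %d frames, %d particles", n_frames(traj),
         n_particles(traj$topology))
    write_structure(traj$topology, traj$frames[[1]],
                    file.path(outdir, "system.gro"))
    files$system <- file.path(outdir, "system.gro")
    write_trajectory(traj, file.path(outdir, "trajectory.trj"))
    files$trajectory <- file.path(outdir, "trajectory.trj")
  }

  if ("membrane" %in% stages) run_stage("membrane", function() {
    bw <- cfg$membrane$bin_width %||% 1
    po4 <- axial_density(traj, function(p) p$group == "lipid" & p$name == "PO4",
                         bin_width = bw, species = "PO4")
    out_csv(po4, "po4_profile.csv")
    ion <- axial_density(traj, "ion", bin_width = bw, species = "ion")
    out_csv(ion, "ion_profile.csv")
    pk <- profile_peaks(po4)
    out_json(list(peaks = pk$peaks, thickness = pk$thickness), "po4_peaks.json")
    op <- chain_order_parameter(traj)
    out_csv(op$per_frame, "order_parameter.csv")
    out_json(list(mean_px = op$mean), "order_parameter.json")
    note("membrane: thickness %.1f A, mean Px %.3f", pk$thickness, op$mean)
  })

  fel <- NULL
  if (any(c("landscape", "pmf") %in% stages)) {
    fel <- run_stage("landscape", function() {
      bw <- cfg$landscape$bin_width %||% 2
      free_energy(bin_probability(traj, "cargo", c("xy", "z"),
                                  bin_width = c(bw, bw)))
    })
  }
  if ("landscape" %in% stages) run_stage("landscape", function() {
    out_csv(tidy(fel), "fel_xy_z.csv")
    sbw <- cfg$landscape$shape_bin_width %||% 1
    fel_shape <- free_energy(bin_probability(traj, "cargo", c("shape", "z"),
                                             bin_width = c(sbw, 2)))
    out_csv(tidy(fel_shape), "fel_shape_z.csv")
    out_json(list(temperature = fel$temperature, reference = fel$reference,
                  n_samples = fel$n_samples), "fel_meta.json")
    note("landscape: %d samples over %d bins", fel$n_samples, nrow(fel$bins))
  })

  if ("pmf" %in% stages) run_stage("pmf", function() {
    axis <- cfg$pmf$axis %||% "z"
    regions <- if (identical(cfg$pmf$regions, "stages")) stage_regions() else NULL
    prof <- pmf_1d(fel, axis = axis, regions = regions)
    out_csv(prof, "pmf.csv")
    bb <- basin_barriers(prof)
    out_json(list(basins = bb$basins, barriers = bb$barriers), "basins.json")
    note("pmf: %d basins", nrow(bb$basins))
  })

  if ("contacts" %in% stages) run_stage("contacts", function() {
    cm <- contact_matrix(traj, "pore", "cargo",
                         cutoff = cfg$contacts$cutoff %||% 6.5)
    out_csv(tidy(cm), "contact_matrix.csv")
    prof <- contact_number_profiles(cm, cfg$contacts$threshold %||% 0)
    out_csv(dplyr::bind_rows(pore = prof$rows, cargo = prof$cols, .id = "side"),
            "contact_profiles.csv")
    out_csv(polarity_contact_fractions(cm, cfg$contacts$threshold %||% 0),
            "polarity_fractions.csv")
    note("contacts: %d residue pairs in contact", sum(cm$matrix > 0))
  })

  if ("shape" %in% stages) run_stage("shape", function() {
    es <- ellipticity_series(traj)
    out_csv(es, "ellipticity.csv")
    cd <- cavity_diameter(traj$frames[[1]], traj$topology, "pore",
                          probe_step = cfg$shape$probe_step %||% 0.5,
                          slab_halfwidth = cfg$shape$slab_halfwidth %||% Inf)
    out_json(list(cavity_diameter = cd,
                  ellipticity_range = range(es$ellipticity)), "shape.json")
    note("shape: cavity %.1f A", cd)
  })

  if ("surface" %in% stages) run_stage("surface", function() {
    np <- cfg$surface$n_points %||% 480
    prot <- select_particles(traj$topology, c("pore", "cargo"))
    sa <- sasa(traj$topology, traj$frames[[1]], sel = prot,
               resolution = "cg", n_points = np)
    out_csv(sa, "sasa_residues.csv")
    dec <- surface_decomposition(sa)
    out_csv(dec, "surface_decomposition.csv")
    bf <- buried_fraction(
      topology(traj$topology$particles[prot, ]),
      frame(traj$frames[[1]]$xyz[prot, , drop = FALSE],
            box = traj$frames[[1]]$box),
      function(p) p$group == "cargo", resolution = "cg", n_points = np)
    out_json(list(hydrophilic_fraction = attr(dec, "hydrophilic_fraction"),
                  cargo_buried_percent = bf), "surface.json")
    note("surface: hydrophilic %.1f%%", 100 * attr(dec, "hydrophilic_fraction"))
  })

  if ("backmap" %in% stages) run_stage("backmap", function() {
    # forward-map two synthetic reference helices to CG and back-map them
    h1 <- ideal_helix(12, chain = "A")
    h2 <- ideal_helix(12, chain = "A")
    h2$frame$xyz <- sweep(h2$frame$xyz %*% t(rot_z(pi / 3)), 2, c(15, 0, 2), `+`)
    h2$topology$particles$resid <- h2$topology$particles$resid + 16L
    ptab <- dplyr::bind_rows(h1$topology$particles, h2$topology$particles)
    ptab$index <- seq_len(nrow(ptab)) - 1L
    cg <- list(topology = topology(ptab),
               frame = frame(rbind(h1$frame$xyz, h2$frame$xyz)))
    lib <- fragment_library(list(helixA = ideal_helix(12)))
    segs <- list(helix_segment(c(1, 12), fragment = "helixA"),
                 helix_segment(c(17, 28), fragment = "helixA"))
    bm <- backmap_assembly(cg$topology, cg$frame, segs, lib)
    out_csv(bm$report, "backmap_report.csv")
    out_csv(bm$clashes, "backmap_clashes.csv")
    write_structure(bm$topology, bm$frame, file.path(outdir, "backmapped.pdb"))
    files[["backmapped.pdb"]] <<- file.path(outdir, "backmapped.pdb")
    note("backmap: max per-segment RMSD %.3f A", max(bm$report$rmsd))
  })

  invisible(files)
}

rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
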