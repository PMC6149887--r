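# Deterministic fixtures: toy chain ligands docked into synthetic grid maps
# whose global optimum is known by construction, plus the analytic landscape
# suite.  Every fixture is reproducible bit-exactly from its seed.

# zig-zag chain ligand with one rotatable bond per interior torsion;
# small seeded jitter breaks planarity and symmetry
make_chain_ligand <- function(n_torsions, jitter = 0.15) {
  n_atoms <- n_torsions + 3L
  coords <- matrix(0, n_atoms, 3)
  bond <- 1.5
  ang <- 2 * pi * 70.5 / 360  # supplement of a tetrahedral-ish bond angle
  dirs <- c(1, -1)
  for (i in 2:n_atoms) {
    step <- c(cos(ang / 2), dirs[(i %% 2) + 1] * sin(ang / 2), 0) * bond
    coords[i, ] <- coords[i - 1, ] + step
  }
  coords <- coords + matrix(stats::rnorm(3 * n_atoms, 0, jitter), n_atoms, 3)
  atoms <- data.frame(
    id = seq_len(n_atoms),
    name = paste0("C", seq_len(n_atoms)),
    element = "C",
    type = LETTERS[seq_len(n_atoms)],
    charge = 0,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  bonds <- cbind(seq_len(n_atoms - 1L), 2:n_atoms)
  branches <- lapply(seq_len(n_torsions), function(k) {
    list(bond = c(k + 1L, k + 2L), moves = seq.int(k + 3L, n_atoms))
  })
  ligand_topology(atoms, bonds, root = c(1L, 2L), branches = branches)
}

#' Build a toy docking complex with a known global optimum
#'
#' Constructs a chain ligand with `n_torsions` rotatable bonds and a
#' synthetic grid-map set: each atom gets its own atom type whose map is a
#' Gaussian well of depth `depth` (width `sigma`) centered on that atom's
#' position in a randomly drawn target pose, plus a weak harmonic funnel
#' (`lambda` per square Angstrom) that guides the search from anywhere in
#' the box.  The joint minimum over all maps is attained exactly when the
#' decoded pose reproduces the target coordinates, so the global-optimum
#' genome, pose and energy are known by construction.  For `n_torsions > 0`
#' the wells act on decoded atom positions, so torsion genes genuinely
#' matter.  The stored optimum energy is verified by direct scoring at
#' construction time.
#'
#' @param n_torsions number of rotatable bonds, 0..15.
#' @param seed fixture seed (construction is bit-reproducible).
#' @param spacing grid spacing in Angstrom.
#' @param depth Gaussian well depth per atom (kcal/mol).
#' @param sigma Gaussian well width (Angstrom).
#' @param lambda harmonic funnel strength (kcal/mol per square Angstrom).
#' @return object of class `toy_complex`: a list with `topo`, `maps`,
#'   `bounds`, `optimum_genome`, `optimum_pose`, `optimum_energy`, `seed`.
#' @export
make_toy_complex <- function(n_torsions, seed = 1L, spacing = 0.6,
                             depth = 5, sigma = 2, lambda = 0.05) {
  stopifnot(n_torsions >= 0, n_torsions <= 15)
  with_run_seed(seed, {
    topo <- make_chain_ligand(n_torsions)
    n_atoms <- nrow(topo$atoms)
    ctr <- colMeans(topo$coords[topo$root, , drop = FALSE])
    # worst-case reach of any atom from the rotation center
    reach <- max(sqrt(rowSums(sweep(topo$coords, 2, ctr)^2)))
    tra_max <- 3
    half <- reach + tra_max + 2
    npts <- 2L * ceiling(half / spacing) + 1L
    box_center <- c(0, 0, 0)
    bounds <- pose_gene_bounds(n_torsions,
                               tra_lower = rep(-tra_max, 3) - ctr + box_center,
                               tra_upper = rep(tra_max, 3) - ctr + box_center)

    # draw a target pose whose atoms sit well inside the box
    half_box <- (npts - 1) / 2 * spacing
    for (try in 1:100) {
      tgt <- c(stats::runif(3, -2, 2) - ctr + box_center,
               stats::rnorm(4),
               stats::runif(n_torsions, -180, 180))
      tgt <- repair_genome(tgt, bounds)
      pose <- decode_pose(tgt, topo)
      if (all(abs(pose) < half_box - 1)) break
    }
    stopifnot(all(abs(pose) < half_box - 1))

    # one map per atom type: Gaussian well + harmonic funnel at the target
    ax <- box_center[1] + (seq_len(npts) - 1 - (npts - 1) / 2) * spacing
    gx <- as.matrix(expand.grid(x = ax, y = ax, z = ax))  # x fastest
    maps <- vector("list", n_atoms)
    names(maps) <- topo$atoms$type
    for (j in seq_len(n_atoms)) {
      d2 <- (gx[, 1] - pose[j, 1])^2 + (gx[, 2] - pose[j, 2])^2 +
        (gx[, 3] - pose[j, 3])^2
      maps[[j]] <- array(-depth * exp(-d2 / (2 * sigma^2)) + lambda * d2,
                         dim = rep(npts, 3))
    }
    gms <- grid_map_set(box_center, spacing, rep(npts, 3), maps)
    energy <- grid_score(tgt, topo, gms, w_tors = 0)
    structure(list(topo = topo, maps = gms, bounds = bounds,
                   optimum_genome = tgt, optimum_pose = pose,
                   optimum_energy = energy, depth = depth, sigma = sigma,
                   lambda = lambda, seed = seed),
              class = "toy_complex")
  })
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("<toy_complex> ", nrow(x$topo$atoms), " atoms, ",
      length(x$topo$branches), " torsions, optimum energy ",
      format(x$optimum_energy), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Counted objective for a toy complex
#' @param tc a `toy_complex`.
#' @return a `dock_objective` (torsional penalty disabled so the stored
#'   optimum energy is exact).
#' @export
toy_objective <- function(tc) {
  obj <- grid_objective(tc$topo, tc$maps, bounds = tc$bounds, w_tors = 0)
  obj$optimum <- tc$optimum_genome
  obj$optimum_value <- tc$optimum_energy
  obj
}

#' The analytic landscape suite
#'
#' Named set of the three benchmark landscapes with recorded optima and
#' bounds.  The surfaces are deterministic; `seed` is accepted for API
#' symmetry with the other fixtures and recorded on the result.
#'
#' @param seed recorded fixture seed.
#' @param dimension genome length for every landscape.
#' @return named list of `dock_objective`: `sphere`, `rastrigin-like`,
#'   `double-funnel`.
#' @export
make_landscape_suite <- function(seed = 1L, dimension = 2L) {
  suite <- list(
    "sphere" = benchmark_landscape("sphere", dimension),
    "rastrigin-like" = benchmark_landscape("rastrigin-like", dimension),
    "double-funnel" = benchmark_landscape("double-funnel", dimension)
  )
  attr(suite, "seed") <- seed
  suite
}

#' Write a toy complex to PDBQT + map files
#'
#' Emits `ligand.pdbqt` and one `.map` file per atom type (plus `e.map`)
#' into `dir`, consumable by [read_pdbqt()] and [read_map_set()].
#'
#' @param tc a `toy_complex`.
#' @param dir output directory.
#' @export
write_toy_complex <- function(tc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdbqt(tc$topo, path = file.path(dir, "ligand.pdbqt"))
  write_map_set(tc$maps, dir)
  invisible(dir)
}
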