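# Independent brute-force oracles and tiny fixture builders shared across
# the suite.  Oracles deliberately re-derive each quantity from first
# principles and never call the implementation path they check.

# explicit Rodrigues rotation of points about the axis through `a` toward
# `b`, by `angle` radians
oracle_rotate <- function(points, a, b, angle) {
  u <- (b - a) / sqrt(sum((b - a)^2))
  t(apply(points, 1, function(p) {
    v <- p - b
    v * cos(angle) + pracma_cross(u, v) * sin(angle) +
      u * sum(u * v) * (1 - cos(angle)) + b
  }))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# direct eight-term trilinear blend at one point
oracle_trilinear <- function(lattice, center, spacing, p) {
  np <- dim(lattice)
  origin <- center - (np - 1) / 2 * spacing
  f <- (p - origin) / spacing
  i0 <- pmin(floor(f), np - 2)
  t <- f - i0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    val <- val + w * lattice[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  val
}

# plain pair-loop Lennard-Jones + Coulomb energy
oracle_pairwise <- function(lig_xyz, lig_q, rec) {
  e <- 0
  for (i in seq_len(nrow(lig_xyz))) {
    for (j in seq_len(nrow(rec))) {
      r <- sqrt(sum((lig_xyz[i, ] - c(rec$x[j], rec$y[j], rec$z[j]))^2))
      r <- max(r, 0.5)
      s6 <- (rec$r_eq[j] / r)^6
      e <- e + rec$eps[j] * (s6^2 - 2 * s6) +
        332.06 * lig_q[i] * rec$charge[j] / (4 * r * r)
    }
  }
  e
}

# exhaustive nearest-unvisited-cell scan over a full cell enumeration;
# returns the minimal normalized distance (ties not broken)
oracle_nearest_unvisited_dist <- function(genome, visited, bounds, ncells) {
  qn <- (genome - bounds$lower) / (bounds$upper - bounds$lower)
  qn <- pmin(pmax(qn, 0), 1)
  grid <- as.matrix(expand.grid(lapply(ncells, function(n) 0:(n - 1))))
  vis_key <- apply(visited, 1, paste, collapse = ",")
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    if (paste(cell, collapse = ",") %in% vis_key) next
    a <- cell / ncells; b <- (cell + 1) / ncells
    d <- sum((pmax(a - qn, 0) + pmax(qn - b, 0))^2)
    if (d < best) best <- d
  }
  best
}

# reference leader clustering in ascending energy order
oracle_cluster <- function(poses, energies, tol) {
  ord <- order(energies, seq_along(energies))
  seeds <- integer(0)
  member_of <- integer(length(poses))
  for (i in ord) {
    hit <- 0L
    for (s in seq_along(seeds)) {
      if (rmsd(poses[[i]], poses[[seeds[s]]]) <= tol) { hit <- s; break }
    }
    if (hit == 0L) {
      seeds <- c(seeds, i)
      hit <- length(seeds)
    }
    member_of[i] <- hit
  }
  member_of
}

# recursively verify that every internal node's children exactly partition
# its box; returns the number of nodes
walk_bsp_check <- function(node) {
  if (node$leaf) return(1L)
  same_lo_l <- all(node$l$lo == node$lo)
  same_hi_r <- all(node$r$hi == node$hi)
  d <- node$dim
  ok <- same_lo_l && same_hi_r &&
    node$l$hi[d] == node$split && node$r$lo[d] == node$split &&
    all(node$l$hi[-d] == node$hi[-d]) && all(node$r$lo[-d] == node$lo[-d]) &&
    node$lo[d] < node$split && node$split < node$hi[d]
  if (!ok) stop("BSP partition invariant violated")
  1L + walk_bsp_check(node$l) + walk_bsp_check(node$r)
}

# four-atom near-linear chain with one rotatable bond (B-C moving D)
make_test_chain4 <- function() {
  atoms <- data.frame(
    id = 1:4, name = paste0("C", 1:4), element = "C",
    type = c("A", "B", "C", "D"), charge = 0,
    x = c(0, 1.5, 2.4, 3.9),
    y = c(0, 0, 1.2, 1.3),
    z = c(0, 0, 0, 0.4)
  )
  ligand_topology(atoms, cbind(1:3, 2:4), root = c(1L, 2L),
                  branches = list(list(bond = c(2L, 3L), moves = 4L)))
}

# small PDBQT ligand text: 4 atoms, one branch moving atom 4
pdbqt_chain4_text <- function() {
  c("REMARK test ligand",
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 A ",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.120 B ",
    "ENDROOT",
    "BRANCH 2 3",
    "ATOM      3  C3  LIG A   1       2.400   1.200   0.000  1.00  0.00    -0.080 C ",
    "ATOM      4  C4  LIG A   1       3.900   1.300   0.400  1.00  0.00     0.050 D ",
    "ENDBRANCH 2 3",
    "TORSDOF 1")
}

# deterministic random rotation genome
random_pose_genome <- function(n_torsions, seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  c(stats::runif(3, -2, 2), q, stats::runif(n_torsions, -180, 180))
}
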