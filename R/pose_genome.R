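# Pose genome: encoding a ligand pose as a fixed-length real vector and
# decoding it to Cartesian coordinates through the ligand's torsion tree.
#
# Genome layout (length 7 + n_torsions):
#   [1:3]  translation tx, ty, tz (Angstrom, offset from the reference pose)
#   [4:7]  orientation quaternion qw, qx, qy, qz (unit norm)
#   [8:..] torsion angles in degrees, wrapped to [-180, 180)

#' Construct a ligand topology
#'
#' A ligand topology holds the atoms, bonds and the torsion tree that a pose
#' genome is decoded against.  The torsion tree is a rooted decomposition of
#' the ligand into a rigid core (the root set) and rotatable branches; each
#' branch angle corresponds to one torsion gene.
#'
#' @param atoms data.frame with columns `id` (integer, unique), `name`
#'   (atom name), `element`, `type` (AutoDock atom type string), `charge`
#'   (partial charge, e), `x`, `y`, `z` (reference coordinates, Angstrom).
#' @param bonds two-column integer matrix of bonded atom-id pairs (may be
#'   empty for single-atom ligands).
#' @param root integer vector of atom ids forming the rigid root set.
#' @param branches list of branches, each a list with `bond` (length-2
#'   integer vector `c(a, b)`: the rotatable bond, rotation axis a -> b) and
#'   `moves` (integer vector of atom ids displaced by this torsion,
#'   including atoms of any nested branch).  Branches must be ordered from
#'   the root outward (a nested branch after its parent).
#' @param torsdof number of active torsions; defaults to `length(branches)`.
#' @return An object of class `ligand_topology`.
#' @export
ligand_topology <- function(atoms, bonds = NULL, root, branches = list(),
                            torsdof = length(branches)) {
  stopifnot(is.data.frame(atoms),
            all(c("id", "type", "charge", "x", "y", "z") %in% names(atoms)))
  if (anyDuplicated(atoms$id)) {
    stop("atom ids must be unique")
  }
  if (!all(root %in% atoms$id)) {
    stop("root set refers to unknown atom ids")
  }
  for (br in branches) {
    if (length(br$bond) != 2L || !all(br$bond %in% atoms$id)) {
      stop("branch bond must name two known atoms")
    }
    if (any(br$moves %in% root)) {
      stop("a branch's moving set must exclude the root set")
    }
    if (length(br$moves) < 1L) {
      stop("a branch must move at least one atom")
    }
  }
  if (torsdof != length(branches)) {
    warning("TORSDOF (", torsdof, ") differs from branch count (",
            length(branches), ")")
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  # cache row lookups so decoding avoids repeated id matching
  for (i in seq_along(branches)) {
    branches[[i]]$bond_rows <- match(branches[[i]]$bond, atoms$id)
    branches[[i]]$move_rows <- match(branches[[i]]$moves, atoms$id)
  }
  structure(list(
    atoms = atoms,
    bonds = bonds,
    root = as.integer(root),
    root_rows = match(as.integer(root), atoms$id),
    branches = branches,
    torsdof = as.integer(torsdof),
    coords = coords
  ), class = "ligand_topology")
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat("<ligand_topology> ", nrow(x$atoms), " atoms, ",
      length(x$branches), " rotatable bonds (TORSDOF ", x$torsdof, ")\n",
      sep = "")
  invisible(x)
}

#' Number of genes for a topology
#' @param topo a `ligand_topology`.
#' @return integer: 7 + number of torsions.
#' @export
n_genes <- function(topo) 7L + length(topo$branches)

# row index of an atom id within topo$atoms / topo$coords
atom_rows <- function(topo, ids) match(ids, topo$atoms$id)

#' Per-gene search bounds
#'
#' Bounds carry a `kind` label per gene so stochastic operators know which
#' repair applies after perturbation: plain clipping (`"plain"`, `"tra"`),
#' quaternion renormalization (`"quat"`) or angular wrapping (`"tor"`).
#'
#' @param lower,upper numeric vectors, `lower < upper` elementwise.
#' @param kind character vector of per-gene kinds
#'   (`"plain"`, `"tra"`, `"quat"`, `"tor"`).
#' @return object of class `gene_bounds`.
#' @export
gene_bounds <- function(lower, upper, kind = rep("plain", length(lower))) {
  stopifnot(length(lower) == length(upper), length(kind) == length(lower))
  if (!all(lower < upper)) {
    stop("gene_bounds: lower must be strictly below upper in every dimension")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 kind = kind,
                 clip = which(kind %in% c("plain", "tra")),
                 quat_idx = which(kind == "quat"),
                 tor_idx = which(kind == "tor")),
            class = "gene_bounds")
}

#' Standard pose bounds for a docking genome
#'
#' Translation bounds are the search-box extents expressed as offsets from
#' the reference root center; quaternion components live in [-1, 1] and are
#' renormalized after every operator; torsions in [-180, 180) degrees.
#'
#' @param n_torsions number of torsion genes.
#' @param tra_lower,tra_upper length-3 translation bounds (Angstrom).
#' @return a `gene_bounds` covering the full genome.
#' @export
pose_gene_bounds <- function(n_torsions, tra_lower = rep(-5, 3),
                             tra_upper = rep(5, 3)) {
  gene_bounds(
    lower = c(tra_lower, rep(-1, 4), rep(-180, n_torsions)),
    upper = c(tra_upper, rep(1, 4), rep(180, n_torsions)),
    kind  = c(rep("tra", 3), rep("quat", 4), rep("tor", n_torsions))
  )
}

#' Wrap angles in degrees to the half-open interval [-180, 180)
#' @param x numeric vector of angles in degrees.
#' @export
wrap_degrees <- function(x) ((x + 180) %% 360) - 180

#' Repair a genome in place after an operator application
#'
#' Clips plain and translation genes to their bounds, renormalizes the
#' quaternion block to unit length (degenerate all-zero block becomes the
#' identity rotation) and wraps torsion genes to [-180, 180).
#'
#' @param genome numeric genome vector.
#' @param bounds a `gene_bounds`.
#' @return repaired genome vector.
#' @export
repair_genome <- function(genome, bounds) {
  cl <- bounds$clip; qi <- bounds$quat_idx; ti <- bounds$tor_idx
  if (is.null(cl)) {  # bounds built by hand rather than gene_bounds()
    k <- bounds$kind
    cl <- which(k %in% c("plain", "tra"))
    qi <- which(k == "quat")
    ti <- which(k == "tor")
  }
  g <- genome[cl]
  lo <- bounds$lower[cl]; hi <- bounds$upper[cl]
  low <- g < lo; g[low] <- lo[low]
  high <- g > hi; g[high] <- hi[high]
  genome[cl] <- g
  if (length(qi) == 4L) {
    nrm <- sqrt(sum(genome[qi]^2))
    genome[qi] <- if (nrm < 1e-12) c(1, 0, 0, 0) else genome[qi] / nrm
  }
  if (length(ti)) genome[ti] <- wrap_degrees(genome[ti])
  genome
}

#' Identity pose genome
#'
#' Zero translation, identity quaternion and zero torsions: decodes to the
#' reference coordinates unchanged.
#'
#' @param n_torsions number of torsion genes.
#' @export
identity_genome <- function(n_torsions) {
  c(rep(0, 3), c(1, 0, 0, 0), rep(0, n_torsions))
}

# 3x3 rotation matrix from a unit quaternion (w, x, y, z)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

# Rodrigues rotation matrix: angle (radians) about unit axis
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Decode a pose genome to atom coordinates
#'
#' Applies torsion rotations branch-by-branch from the root outward (each
#' branch rotates its moving set about the current position of its rotatable
#' bond), then the rigid-body rotation about the root-set centroid, then the
#' translation offset.
#'
#' @param genome numeric genome vector of length `n_genes(topo)`.
#' @param topo a `ligand_topology`.
#' @return numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @export
decode_pose <- function(genome, topo) {
  nt <- length(topo$branches)
  if (length(genome) != 7L + nt) {
    stop("genome length ", length(genome), " does not match topology (",
         7L + nt, " genes expected)")
  }
  coords <- topo$coords
  if (nt > 0L) {
    tors <- genome[8:(7 + nt)] * pi / 180
    for (i in seq_len(nt)) {
      br <- topo$branches[[i]]
      ab <- br$bond_rows
      a <- coords[ab[1L], ]
      b <- coords[ab[2L], ]
      R <- rotation_about_axis(b - a, tors[i])
      m <- coords[br$move_rows, , drop = FALSE]
      m[, 1] <- m[, 1] - b[1]; m[, 2] <- m[, 2] - b[2]
      m[, 3] <- m[, 3] - b[3]
      m <- m %*% t(R)
      m[, 1] <- m[, 1] + b[1]; m[, 2] <- m[, 2] + b[2]
      m[, 3] <- m[, 3] + b[3]
      coords[br$move_rows, ] <- m
    }
  }
  q <- genome[4:7]
  nrm <- sqrt(sum(q^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm < 1e-12) stop("degenerate zero quaternion")
    q <- q / nrm
  }
  ctr <- colMeans(topo$coords[topo$root_rows, , drop = FALSE])
  R <- quat_to_matrix(q)
  off <- ctr + genome[1:3]
  coords[, 1] <- coords[, 1] - ctr[1]
  coords[, 2] <- coords[, 2] - ctr[2]
  coords[, 3] <- coords[, 3] - ctr[3]
  coords <- coords %*% t(R)
  coords[, 1] <- coords[, 1] + off[1]
  coords[, 2] <- coords[, 2] + off[2]
  coords[, 3] <- coords[, 3] + off[3]
  coords
}

#' Root-mean-square positional deviation between two conformations
#'
#' Plain atom-order-matched RMSD with no superposition: both coordinate sets
#' are assumed to already live in the receptor frame, the docking
#' convention.  No symmetry correction is applied.
#'
#' @param coords_a,coords_b numeric matrices (n x 3), matched atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    stop("rmsd: coordinate sets must have identical dimensions")
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}
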