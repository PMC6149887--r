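# Non-revisiting archive: a binary space partition over discretized genome
# cells.  Every evaluated cell is stored; a candidate falling in a visited
# cell is redirected to the nearest unvisited neighbor subspace, so no cell
# is ever evaluated twice.
#
# Nodes are mutable environments.  A leaf holds at most one visited cell;
# an internal node splits its box on one dimension, the two children's
# boxes are disjoint and their union is exactly the parent box.  Boxes are
# half-open integer cell ranges [lo, hi) per gene.

new_bsp_node <- function(lo, hi, ncells, cell = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$leaf <- TRUE
  nd$lo <- lo
  nd$hi <- hi
  nd$nlo <- lo / ncells   # normalized box, cached for the distance search
  nd$nhi <- hi / ncells
  nd$cell <- cell
  nd
}

# clamp negatives to zero without pmax dispatch overhead
pos_part <- function(x) {
  x[x < 0] <- 0
  x
}

#' Create an empty non-revisiting BSP archive
#'
#' The root node represents the entire search space.  Genomes are
#' discretized to integer cells (gene value quantized at `resolution`)
#' before identity testing, since equality on continuous vectors would
#' never fire.
#'
#' @param bounds a `gene_bounds` describing the search space.
#' @param resolution per-gene cell width, recycled to genome length.  The
#'   conventional defaults for pose genomes are 0.25 Angstrom for
#'   translation, 1/64 for quaternion components and 2 degrees for
#'   torsions (see [pose_resolution()]).
#' @return object of class `bsp_tree`.
#' @export
bsp_tree <- function(bounds, resolution) {
  stopifnot(inherits(bounds, "gene_bounds"))
  d <- length(bounds$lower)
  resolution <- rep_len(resolution, d)
  stopifnot(all(resolution > 0))
  ncells <- pmax(1, ceiling((bounds$upper - bounds$lower) / resolution))
  tr <- new.env(parent = emptyenv())
  tr$bounds <- bounds
  tr$resolution <- resolution
  tr$ncells <- ncells
  tr$total <- prod(ncells)  # double: may exceed integer range
  tr$root <- new_bsp_node(rep(0, d), ncells, ncells)
  tr$count <- 0
  tr$nodes <- 1
  class(tr) <- "bsp_tree"
  tr
}

#' Default cell resolution for a pose genome
#'
#' Translation genes 0.25 Angstrom, quaternion components 1/64, torsions
#' 2 degrees, other genes 1/128 of the gene range.
#'
#' @param bounds a `gene_bounds` with per-gene kinds.
#' @return numeric resolution vector.
#' @export
pose_resolution <- function(bounds) {
  span <- bounds$upper - bounds$lower
  res <- span / 128
  res[bounds$kind == "tra"] <- 0.25
  res[bounds$kind == "quat"] <- 1 / 64
  res[bounds$kind == "tor"] <- 2
  res
}

#' Discretize a genome to its integer cell
#' @param tree a `bsp_tree`.
#' @param genome numeric genome vector.
#' @return numeric vector of 0-based cell indices.
#' @export
bsp_cell_of <- function(tree, genome) {
  idx <- floor((genome - tree$bounds$lower) / tree$resolution)
  pmin(pmax(idx, 0), tree$ncells - 1)
}

#' @export
print.bsp_tree <- function(x, ...) {
  cat("<bsp_tree> ", format(x$count), " visited cells of ",
      format(x$total), " (", format(x$nodes), " nodes)\n", sep = "")
  invisible(x)
}

# normalized squared distance from a point (normalized coords in [0,1]) to
# the normalized image of integer box [lo, hi)
norm_box_sqdist <- function(qn, lo, hi, ncells) {
  d <- pos_part(lo / ncells - qn) + pos_part(qn - hi / ncells)
  sum(d * d)
}

# as above but with the node's cached normalized box
node_sqdist <- function(qn, node) {
  a <- node$nlo - qn
  b <- qn - node$nhi
  a[a < 0] <- 0
  b[b < 0] <- 0
  d <- a + b
  sum(d * d)
}

# per-dimension squared cost of a cell index vector relative to qn
cell_cost <- function(qn, cell, ncells) {
  a <- cell / ncells - qn
  b <- qn - (cell + 1) / ncells
  a[a < 0] <- 0
  b[b < 0] <- 0
  d <- a + b
  d * d
}

# store `cell` in the subtree rooted at `node`, splitting occupied leaves;
# assumes the cell is unvisited and inside node's box
bsp_store <- function(tree, node, cell) {
  repeat {
    if (!node$leaf) {
      node <- if (cell[node$dim] < node$split) node$l else node$r
      next
    }
    if (is.null(node$cell)) {
      node$cell <- cell
      tree$count <- tree$count + 1
      return(invisible(NULL))
    }
    old <- node$cell
    gap <- abs(cell - old) / tree$ncells
    dim <- which.max(gap)
    if (gap[dim] == 0) stop("bsp_store: duplicate cell")  # contract guard
    pair <- sort(c(cell[dim], old[dim]))
    split <- ceiling((pair[1] + pair[2]) / 2)
    llo <- node$lo; lhi <- node$hi
    lhi[dim] <- split
    rlo <- node$lo; rlo[dim] <- split
    l <- new_bsp_node(llo, lhi, tree$ncells)
    r <- new_bsp_node(rlo, node$hi, tree$ncells)
    if (old[dim] < split) l$cell <- old else r$cell <- old
    node$leaf <- FALSE
    node$dim <- dim
    node$split <- split
    node$cell <- NULL
    node$l <- l
    node$r <- r
    tree$nodes <- tree$nodes + 2
    node <- if (cell[dim] < split) l else r
  }
}

# locate the leaf whose box contains `cell`, Table-8 style descent:
# at an internal node go to the child whose box is nearer (distance zero
# for the child containing the cell; ties go left)
bsp_find_leaf <- function(tree, cell) {
  node <- tree$root
  while (!node$leaf) {
    node <- if (cell[node$dim] < node$split) node$l else node$r
  }
  node
}

#' Query-and-insert a genome into the non-revisiting archive
#'
#' Descends to the leaf subspace containing the genome's cell.  An
#' unvisited cell is stored and returned unchanged (revisit flag 0).  A
#' visited cell raises the revisit flag and the genome mutates to a point
#' sampled in the nearest unvisited neighbor subspace, which is itself
#' stored, so the returned genome is always safe to evaluate.
#'
#' @param tree a `bsp_tree`.
#' @param genome numeric genome vector within bounds.
#' @return list with `genome` (possibly redirected), `revisit` (0 or 1)
#'   and `cell` (the stored cell).
#' @export
bsp_query_insert <- function(tree, genome) {
  if (tree$count >= tree$total) {
    stop(errorCondition(
      "BSP archive saturated: every cell at the current resolution has been visited",
      class = c("bsp_saturated", "error")))
  }
  cell <- bsp_cell_of(tree, genome)
  leaf <- bsp_find_leaf(tree, cell)
  if (is.null(leaf$cell) || any(leaf$cell != cell)) {
    bsp_store(tree, leaf, cell)
    return(list(genome = genome, revisit = 0L, cell = cell))
  }
  redirected <- bsp_nearest_unvisited(tree, genome)
  list(genome = redirected$genome, revisit = 1L, cell = redirected$cell)
}

#' Redirect a genome to the nearest unvisited subspace
#'
#' Branch-and-bound search over the tree for the unvisited cell minimizing
#' the bounds-normalized Euclidean distance to the query point (zero when
#' the query lies inside the cell).  The winning cell is marked visited and
#' a uniform point inside it is returned.
#'
#' @param tree a `bsp_tree` with at least one unvisited cell.
#' @param genome query genome.
#' @return list with `genome` (a uniform sample inside the chosen cell) and
#'   `cell`.
#' @export
bsp_nearest_unvisited <- function(tree, genome) {
  if (tree$count >= tree$total) {
    stop(errorCondition("BSP archive saturated",
                        class = c("bsp_saturated", "error")))
  }
  qn <- (genome - tree$bounds$lower) /
    (tree$bounds$upper - tree$bounds$lower)
  qn <- pmin(pmax(qn, 0), 1)
  nc <- tree$ncells
  qcell <- bsp_cell_of(tree, genome)

  best_d <- Inf
  best_cell <- NULL

  visit <- function(node, lb) {
    if (lb >= best_d) return()
    if (!node$leaf) {
      dl <- node_sqdist(qn, node$l)
      dr <- node_sqdist(qn, node$r)
      if (dl <= dr) {
        visit(node$l, dl)
        visit(node$r, dr)
      } else {
        visit(node$r, dr)
        visit(node$l, dl)
      }
      return()
    }
    # capacity: number of cells in the box minus the occupant
    occ <- node$cell
    if (!is.null(occ) && prod(node$hi - node$lo) <= 1) return()
    near <- qcell
    low <- near < node$lo
    near[low] <- node$lo[low]
    high <- near >= node$hi
    near[high] <- node$hi[high] - 1
    if (!is.null(occ) && all(near == occ)) {
      # second-nearest cell in the box: change one coordinate to its
      # next-best value (squared distance is separable across genes)
      base <- cell_cost(qn, near, nc)
      alt_d <- Inf; alt <- NULL
      for (k in seq_along(near)) {
        for (step in c(-1, 1)) {
          v <- near[k] + step
          if (v < node$lo[k] || v >= node$hi[k]) next
          cand <- near; cand[k] <- v
          dd <- sum(base) - base[k] + cell_cost(qn, cand, nc)[k]
          if (dd < alt_d) { alt_d <- dd; alt <- cand }
        }
      }
      if (is.null(alt)) return()
      near <- alt
      d <- alt_d
    } else {
      d <- sum(cell_cost(qn, near, nc))
    }
    if (d < best_d) {
      best_d <<- d
      best_cell <<- near
    }
  }
  visit(tree$root, node_sqdist(qn, tree$root))
  if (is.null(best_cell)) {
    stop(errorCondition("BSP archive saturated",
                        class = c("bsp_saturated", "error")))
  }
  leaf <- bsp_find_leaf(tree, best_cell)
  bsp_store(tree, leaf, best_cell)
  lo <- tree$bounds$lower + best_cell * tree$resolution
  g <- lo + stats::runif(length(best_cell)) * tree$resolution
  g <- pmin(g, tree$bounds$upper - 1e-12 * pmax(1, abs(tree$bounds$upper)))
  list(genome = g, cell = best_cell)
}

#' All visited cells of the archive
#' @param tree a `bsp_tree`.
#' @return numeric matrix, one visited cell per row.
#' @export
bsp_cells <- function(tree) {
  out <- vector("list", tree$count)
  i <- 0L
  walk <- function(node) {
    if (node$leaf) {
      if (!is.null(node$cell)) {
        i <<- i + 1L
        out[[i]] <<- node$cell
      }
    } else {
      walk(node$l); walk(node$r)
    }
  }
  walk(tree$root)
  do.call(rbind, out[seq_len(i)])
}

#' Dump the visited cells to a line-oriented text file
#'
#' One visited cell per line, indices separated by single spaces, for
#' post-run diagnostics.
#'
#' @param tree a `bsp_tree`.
#' @param path output file path.
#' @export
bsp_dump <- function(tree, path) {
  cells <- bsp_cells(tree)
  lines <- if (is.null(cells)) character(0) else
    apply(cells, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}
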