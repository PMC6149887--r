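# Genetic operators and the running-history archive.
#
# Populations are passed between operators as a list with
#   genomes : n x g numeric matrix (one row per individual)
#   fitness : length-n numeric (energy; lower is better; NA = not evaluated)
#   parents : length-n list of list(father =, mother =) genome vectors --
#             the two genomes whose crossover produced the individual
#             (copies of the individual itself when it was never crossed).

new_population <- function(genomes, fitness = rep(NA_real_, nrow(genomes)),
                           parents = NULL) {
  if (is.null(parents)) {
    parents <- lapply(seq_len(nrow(genomes)), function(i) {
      list(father = genomes[i, ], mother = genomes[i, ])
    })
  }
  list(genomes = genomes, fitness = fitness, parents = parents)
}

# ---------------------------------------------------------------------------
# History archive

#' Create an empty running-history archive
#'
#' Tracks the historic best solution (`M_optimum`), the historic second-best
#' distinct solution (`M_sub`) and the per-generation elite records (each
#' elite with the parents whose crossover produced it).  Both best solutions
#' update online as evaluations occur.
#'
#' @return object of class `dock_archive` (a mutable environment).
#' @export
history_archive <- function() {
  a <- new.env(parent = emptyenv())
  a$best_genome <- NULL
  a$best_fit <- Inf
  a$sub_genome <- NULL
  a$sub_fit <- Inf
  a$elites <- list()
  class(a) <- "dock_archive"
  a
}

#' Record one evaluated genome in the archive
#' @param archive a `dock_archive`.
#' @param genome evaluated genome vector.
#' @param fitness its energy.
#' @export
archive_update <- function(archive, genome, fitness) {
  if (fitness < archive$best_fit) {
    if (!is.null(archive$best_genome) &&
        any(archive$best_genome != genome)) {
      archive$sub_genome <- archive$best_genome
      archive$sub_fit <- archive$best_fit
    }
    archive$best_genome <- genome
    archive$best_fit <- fitness
  } else if (fitness < archive$sub_fit &&
             any(genome != archive$best_genome)) {
    archive$sub_genome <- genome
    archive$sub_fit <- fitness
  }
  invisible(archive)
}

#' Does the archive hold both a historic best and second-best solution?
#' @param archive a `dock_archive`.
#' @export
archive_ready <- function(archive) {
  !is.null(archive$best_genome) && !is.null(archive$sub_genome)
}

#' @export
print.dock_archive <- function(x, ...) {
  cat("<dock_archive> best ", format(x$best_fit), ", second-best ",
      format(x$sub_fit), ", ", length(x$elites), " elite records\n",
      sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Crossover

#' Two-point crossover
#'
#' Genes strictly after `cuts[1]` and up to `cuts[2]` swap between the two
#' parents; the multiset of gene values at every locus is conserved across
#' the pair.
#'
#' @param parent_a,parent_b equal-length genome vectors.
#' @param cuts optional integer vector `c(c1, c2)` with
#'   `0 <= c1 <= c2 <= n`; drawn uniformly when `NULL`.
#' @return list with `child_a` and `child_b`.
#' @export
two_point_crossover <- function(parent_a, parent_b, cuts = NULL) {
  n <- length(parent_a)
  if (length(parent_b) != n) stop("parents must have equal genome lengths")
  if (is.null(cuts)) {
    cuts <- sample.int(n + 1L, 2L, replace = TRUE) - 1L
    if (cuts[1] > cuts[2]) cuts <- cuts[2:1]
  }
  seg <- seq_len(n) > cuts[1] & seq_len(n) <= cuts[2]
  child_a <- parent_a; child_b <- parent_b
  child_a[seg] <- parent_b[seg]
  child_b[seg] <- parent_a[seg]
  list(child_a = child_a, child_b = child_b)
}

#' CE crossover: elite-parent-preserving crossover
#'
#' Performs pairwise two-point crossover on randomly mated pairs, then
#' preserves into the output, for each of the `ceiling(elite_fraction * n)`
#' best (lowest-energy) individuals, the elite itself together with its
#' recorded parents `M_father` and `M_mother`.  The population size is
#' restored to `n` by truncating children of the worst-fitness mated pairs.
#' Preserved individuals keep their cached fitness; fresh children carry
#' `NA` fitness until the engine evaluates them.
#'
#' @param population a population list (see package internals); `fitness`
#'   must be known for all individuals.
#' @param archive a `dock_archive`; the generation's elite records are
#'   appended to it.
#' @param elite_fraction fraction of the population preserved as elites,
#'   in (0, 0.5]; the conventional default is 0.1.
#' @param generation generation index stored on the elite records.
#' @return the next population (size `n`).
#' @export
ce_crossover <- function(population, archive, elite_fraction = 0.1,
                         generation = NA_integer_) {
  g <- population$genomes
  n <- nrow(g)
  if (n < 2L) stop("CE crossover needs a population of at least 2")
  if (elite_fraction <= 0 || elite_fraction > 0.5) {
    stop("elite_fraction must lie in (0, 0.5]")
  }
  fit <- population$fitness
  if (anyNA(fit)) stop("CE crossover requires evaluated fitness")

  k <- ceiling(elite_fraction * n)
  if (3L * k > n) {
    stop("elite_fraction too large: the ", k, " preserved triples exceed ",
         "the population size ", n)
  }
  elite_idx <- order(fit)[seq_len(k)]

  # random mating; odd population size passes the leftover through unchanged
  perm <- sample.int(n)
  n_pairs <- n %/% 2L
  child_genomes <- matrix(NA_real_, n, ncol(g))
  child_parents <- vector("list", n)
  pair_fit <- numeric(n)  # mean parental fitness, used for truncation
  for (p in seq_len(n_pairs)) {
    ia <- perm[2L * p - 1L]; ib <- perm[2L * p]
    kids <- two_point_crossover(g[ia, ], g[ib, ])
    rows <- c(2L * p - 1L, 2L * p)
    child_genomes[rows[1], ] <- kids$child_a
    child_genomes[rows[2], ] <- kids$child_b
    pr <- list(father = g[ia, ], mother = g[ib, ])
    child_parents[[rows[1]]] <- pr
    child_parents[[rows[2]]] <- pr
    pair_fit[rows] <- (fit[ia] + fit[ib]) / 2
  }
  child_fit <- rep(NA_real_, n)
  if (n %% 2L == 1L) {
    io <- perm[n]
    child_genomes[n, ] <- g[io, ]
    child_parents[[n]] <- population$parents[[io]]
    child_fit[n] <- fit[io]
    pair_fit[n] <- fit[io]
  }

  # preserved block: each elite plus its recorded parents
  records <- vector("list", k)
  pres_genomes <- matrix(NA_real_, 3L * k, ncol(g))
  pres_fit <- rep(NA_real_, 3L * k)
  pres_parents <- vector("list", 3L * k)
  for (j in seq_len(k)) {
    ei <- elite_idx[j]
    pr <- population$parents[[ei]]
    records[[j]] <- elite_record(g[ei, ], fit[ei], pr$father, pr$mother,
                                 generation)
    rows <- (3L * j - 2L):(3L * j)
    pres_genomes[rows[1], ] <- g[ei, ]
    pres_fit[rows[1]] <- fit[ei]
    pres_parents[[rows[1]]] <- pr
    pres_genomes[rows[2], ] <- pr$father
    pres_genomes[rows[3], ] <- pr$mother
    pres_parents[[rows[2]]] <- list(father = pr$father, mother = pr$father)
    pres_parents[[rows[3]]] <- list(father = pr$mother, mother = pr$mother)
  }
  archive$elites <- c(archive$elites, list(records))

  # truncate children from the worst mated pairs to restore size n
  keep <- order(pair_fit)[seq_len(n - 3L * k)]
  out_genomes <- rbind(pres_genomes, child_genomes[keep, , drop = FALSE])
  out_fit <- c(pres_fit, child_fit[keep])
  out_parents <- c(pres_parents, child_parents[keep])
  list(genomes = out_genomes, fitness = out_fit, parents = out_parents,
       elite_records = records)
}

#' Construct an elite record
#'
#' @param genome elite genome; @param fitness its cached energy;
#' @param father,mother the genomes whose crossover produced the elite
#'   (copies of the elite itself when it was never crossed);
#' @param generation generation index.
#' @return object of class `elite_record`.
#' @export
elite_record <- function(genome, fitness, father, mother,
                         generation = NA_integer_) {
  structure(list(genome = genome, fitness = fitness, father = father,
                 mother = mother, generation = generation),
            class = "elite_record")
}

# ---------------------------------------------------------------------------
# Mutation

#' ED mutation: history-directed mutation
#'
#' For each gene a uniform deviate `theta` is drawn.  When `theta < beta`
#' the gene is resampled uniformly within its bounds (exploration branch);
#' otherwise the gene moves by
#' `theta * (M_optimum - M_sub) + delta * (M_optimum - m)`,
#' a vector-addition step directed from the historic second-best towards
#' the historic best solution (exploitation branch).  The result is clipped
#' to bounds, the quaternion block renormalized and torsions wrapped.
#' An archive that does not yet hold both historic solutions forces the
#' exploration branch.
#'
#' @param genome genome vector `m`.
#' @param archive a `dock_archive` supplying `M_optimum` and `M_sub`.
#' @param bounds a `gene_bounds` (`M_min`, `M_max` of the exploration
#'   branch).
#' @param beta balance factor in \[0, 1\]: probability of the exploration
#'   branch per gene.
#' @param scope `"gene"` (default: independent theta/delta per gene) or
#'   `"genome"` (one theta/delta pair for the whole vector).
#' @param rate per-gene application probability.  The default 1 mutates the
#'   whole genome (the operator's own contract); the engine passes its
#'   configured per-gene mutation rate here, so that the operator replaces
#'   the host GA's mutation at the host GA's rate rather than rewriting
#'   every gene every generation.
#' @param theta,delta optional injected deviates (recycled to genome
#'   length) for deterministic verification; drawn uniform(0,1) when NULL.
#' @return mutated genome.
#' @export
ed_mutation <- function(genome, archive, bounds, beta = 0.1,
                        scope = c("gene", "genome"), rate = 1,
                        theta = NULL, delta = NULL) {
  scope <- scope[[1L]]
  if (!scope %in% c("gene", "genome")) stop("scope must be gene or genome")
  stopifnot(beta >= 0, beta <= 1)
  n <- length(genome)
  hit <- if (rate >= 1) rep(TRUE, n) else stats::runif(n) < rate
  if (!any(hit)) return(genome)
  if (is.null(theta)) {
    theta <- if (scope == "gene") stats::runif(n) else rep(stats::runif(1), n)
  } else theta <- rep_len(theta, n)
  if (is.null(delta)) {
    delta <- if (scope == "gene") stats::runif(n) else rep(stats::runif(1), n)
  } else delta <- rep_len(delta, n)

  lo <- bounds$lower; hi <- bounds$upper
  if (!archive_ready(archive)) {
    explore <- hit
  } else {
    explore <- hit & theta < beta
  }
  out <- genome
  out[explore] <- lo[explore] + theta[explore] * (hi[explore] - lo[explore])
  exploit <- hit & !explore
  if (any(exploit)) {
    i <- exploit
    mo <- archive$best_genome; ms <- archive$sub_genome
    out[i] <- genome[i] + theta[i] * (mo[i] - ms[i]) +
      delta[i] * (mo[i] - genome[i])
  }
  repair_genome(out, bounds)
}

#' Gaussian mutation (baseline GA/LGA operator)
#'
#' Each gene mutates with probability `rate`; a mutated gene receives a
#' Gaussian perturbation with standard deviation `sd_frac` of its range.
#'
#' @param genome genome vector.
#' @param bounds a `gene_bounds`.
#' @param rate per-gene mutation probability.
#' @param sd_frac perturbation scale as a fraction of each gene's range.
#' @return mutated genome, repaired to bounds.
#' @export
gaussian_mutation <- function(genome, bounds, rate = 0.1, sd_frac = 0.1) {
  n <- length(genome)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    span <- bounds$upper - bounds$lower
    genome[hit] <- genome[hit] +
      stats::rnorm(sum(hit), 0, sd_frac * span[hit])
  }
  repair_genome(genome, bounds)
}

# ---------------------------------------------------------------------------
# Selection

#' Rank-proportional selection
#'
#' Maps energies to linear-ranking weights (selection pressure 1.5: the
#' best individual receives weight 1.5, the worst 0.5, interpolated by
#' rank) and samples `size` individuals with replacement.  Rank weights
#' avoid the sign and scale problems of raw negative energies; all-equal
#' fitness degenerates to uniform sampling.
#'
#' @param fitnesses numeric energies (lower is better), all finite.
#' @param size number of draws (defaults to `length(fitnesses)`).
#' @param pressure linear-ranking selection pressure in (1, 2].
#' @return integer vector of selected indices.
#' @export
proportional_selection <- function(fitnesses, size = length(fitnesses),
                                   pressure = 1.5) {
  n <- length(fitnesses)
  if (n == 1L) return(rep(1L, size))
  if (!all(is.finite(fitnesses))) stop("fitnesses must be finite")
  # rank 1 = best (lowest energy); ties share averaged weights via rank()
  rk <- rank(fitnesses, ties.method = "average")
  w <- pressure - (rk - 1) / (n - 1) * (2 * (pressure - 1))
  sample.int(n, size, replace = TRUE, prob = w)
}

# ---------------------------------------------------------------------------
# Solis-Wets local search

#' Solis-Wets local search with Lamarckian writeback
#'
#' Adaptive random walk: at each step a Gaussian deviate (scaled per gene by
#' `rho` times the gene range) plus an accumulated bias is tried in the
#' forward and, failing that, the reverse direction.  Four consecutive
#' successes double `rho`; four consecutive failures halve it.  The
#' returned genome is at least as fit as the input (the improved genome
#' replaces the individual: acquired traits are inherited).
#'
#' @param genome starting genome.
#' @param objective a `dock_objective` (evaluations are counted).
#' @param max_steps maximum number of objective evaluations to spend.
#' @param rho_init initial step scale as a fraction of each gene range.
#' @param rho_min terminate when `rho` contracts below this value.
#' @param fitness cached fitness of `genome`; evaluated (and counted) when
#'   `NA`.
#' @param filter optional function(genome) -> genome applied to every probe
#'   before evaluation (used to route probes through the non-revisiting
#'   archive).
#' @param on_eval optional function(genome, fitness) invoked after every
#'   counted evaluation (used by the engine to keep the history archive
#'   current).
#' @return list with `genome`, `fitness` and `evals` (evaluations spent).
#' @export
solis_wets_search <- function(genome, objective, max_steps = 300,
                              rho_init = 1.0, rho_min = 1e-3,
                              fitness = NA_real_, filter = NULL,
                              on_eval = NULL) {
  bounds <- objective$bounds
  span <- bounds$upper - bounds$lower
  evals <- 0
  note <- function(g, f) if (!is.null(on_eval)) on_eval(g, f)
  if (is.na(fitness)) {
    fitness <- obj_eval(objective, genome)
    note(genome, fitness)
    evals <- evals + 1
  }
  if (max_steps <= 0) {
    return(list(genome = genome, fitness = fitness, evals = evals))
  }
  rho <- rho_init
  bias <- numeric(length(genome))
  succ <- 0L; fail <- 0L
  while (evals < max_steps && rho >= rho_min) {
    dev <- stats::rnorm(length(genome), 0, rho * 0.05 * span)
    cand <- repair_genome(genome + bias + dev, bounds)
    if (!is.null(filter)) cand <- filter(cand)
    f1 <- obj_eval(objective, cand); evals <- evals + 1
    note(cand, f1)
    if (f1 < fitness) {
      genome <- cand; fitness <- f1
      bias <- 0.2 * bias + 0.4 * dev
      succ <- succ + 1L; fail <- 0L
    } else if (evals < max_steps) {
      cand2 <- repair_genome(genome - bias - dev, bounds)
      if (!is.null(filter)) cand2 <- filter(cand2)
      f2 <- obj_eval(objective, cand2); evals <- evals + 1
      note(cand2, f2)
      if (f2 < fitness) {
        genome <- cand2; fitness <- f2
        bias <- bias - 0.4 * dev
        succ <- succ + 1L; fail <- 0L
      } else {
        bias <- 0.5 * bias   # decay a stale bias so it cannot pin the walk
        succ <- 0L; fail <- fail + 1L
      }
    } else break
    if (succ >= 4L) { rho <- rho * 2; succ <- 0L }
    if (fail >= 4L) { rho <- rho * 0.5; fail <- 0L }
  }
  list(genome = genome, fitness = fitness, evals = evals)
}
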