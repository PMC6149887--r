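# Post-run analytics: RMSD success rates, energy-ordered conformation
# clustering with rank-1 counting, convergence tables and distribution
# summaries.

#' Cluster docked conformations by RMSD, ranked by energy
#'
#' Energy-ordered leader clustering: poses are processed by ascending
#' energy (ties broken by pose index); a pose joins the first existing
#' cluster whose seed pose lies within `rmsd_tol`, otherwise it seeds a new
#' cluster.  Clusters are reported in order of increasing lowest member
#' energy; rank 1 is the lowest-energy cluster and its size measures how
#' often the lowest-energy structure was found.
#'
#' @param poses list of coordinate matrices (matched atom order).
#' @param energies numeric energies, one per pose.
#' @param rmsd_tol clustering tolerance in Angstrom (default 2.0).
#' @return object of class `cluster_report`: a list with `clusters` (each
#'   with `members`, `seed`, `lowest_energy`, `size`), `n_poses` and
#'   `rmsd_tol`.
#' @export
cluster_conformations <- function(poses, energies, rmsd_tol = 2.0) {
  stopifnot(rmsd_tol > 0)
  if (length(poses) != length(energies)) {
    stop("poses and energies must have equal length")
  }
  n <- length(poses)
  clusters <- list()
  if (n > 0) {
    ord <- order(energies, seq_len(n))
    for (i in ord) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        seed <- clusters[[ci]]$seed
        if (rmsd(poses[[i]], poses[[seed]]) <= rmsd_tol) {
          clusters[[ci]]$members <- c(clusters[[ci]]$members, i)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        clusters[[length(clusters) + 1L]] <-
          list(seed = i, members = i, lowest_energy = energies[i])
      }
    }
    for (ci in seq_along(clusters)) {
      clusters[[ci]]$size <- length(clusters[[ci]]$members)
    }
    # seeds are visited in ascending energy, so clusters are already ranked
  }
  structure(list(clusters = clusters, n_poses = n, rmsd_tol = rmsd_tol),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> ", length(x$clusters), " clusters over ",
      x$n_poses, " poses (tol ", x$rmsd_tol, " A)\n", sep = "")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  rank %d: %d member(s), lowest energy %.4f\n",
                i, cl$size, cl$lowest_energy))
  }
  invisible(x)
}

#' Cluster table as a data.frame
#' @param report a `cluster_report`.
#' @return data.frame with columns rank, size, lowest_energy.
#' @export
cluster_table <- function(report) {
  data.frame(
    rank = seq_along(report$clusters),
    size = vapply(report$clusters, `[[`, integer(1), "size"),
    lowest_energy = vapply(report$clusters, `[[`, numeric(1),
                           "lowest_energy")
  )
}

#' Docking success summary against a reference pose
#'
#' A run is successful when the RMSD between its best pose and the
#' reference is strictly below `rmsd_tol` (the conventional threshold is
#' 2.0 Angstrom).  Reports the success count, the mean RMSD over all runs
#' and the mean RMSD over the successful subset only (`NA` when there are
#' no successes, never 0).
#'
#' @param results list of `run_result` carrying a `pose`, or a numeric
#'   vector of precomputed RMSD values.
#' @param reference_pose coordinate matrix of the reference conformation
#'   (ignored when `results` is already numeric).
#' @param rmsd_tol success threshold in Angstrom.
#' @return list with `n`, `success`, `rmsd` (per-run values),
#'   `mean_rmsd_all`, `mean_rmsd_success`.
#' @export
success_summary <- function(results, reference_pose = NULL, rmsd_tol = 2.0) {
  if (is.numeric(results)) {
    r <- as.numeric(results)
  } else {
    if (is.null(reference_pose)) stop("reference_pose is required")
    r <- vapply(results, function(res) {
      if (is.null(res$pose)) stop("run_result carries no pose")
      rmsd(res$pose, reference_pose)
    }, numeric(1))
  }
  ok <- r < rmsd_tol
  list(
    n = length(r),
    success = sum(ok),
    rmsd = r,
    mean_rmsd_all = if (length(r)) mean(r) else NA_real_,
    mean_rmsd_success = if (any(ok)) mean(r[ok]) else NA_real_
  )
}

#' Five-number summary with Tukey outlier flags
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles computed by linear interpolation between order statistics
#' (R's default quantile type 7).  Outliers are the points beyond the
#' 1.5 x IQR whiskers.
#'
#' @param energies nonempty numeric vector.
#' @return list with `summary` (named length-5 vector), `outliers` (values)
#'   and `whiskers` (the fences).
#' @export
distribution_summary <- function(energies) {
  if (!length(energies)) stop("distribution_summary: empty input")
  qs <- stats::quantile(energies, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                        type = 7)
  iqr <- qs[4] - qs[2]
  lo <- qs[2] - 1.5 * iqr
  hi <- qs[4] + 1.5 * iqr
  out <- energies[energies < lo | energies > hi]
  list(
    summary = c(min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
                max = qs[5]),
    outliers = out,
    whiskers = c(lower = lo, upper = hi)
  )
}

#' One-sided rank-sum comparison of two energy samples
#'
#' Generic utility for pairwise algorithm comparison: a one-sided
#' Mann-Whitney (Wilcoxon rank-sum) test of whether sample `a` tends to
#' lower energies than sample `b`.  This is an interpretation layer over
#' unnamed published test matrices, not a reproduction of any specific
#' procedure.
#'
#' @param a,b numeric energy samples.
#' @return the `htest` object from [stats::wilcox.test()] with
#'   `alternative = "less"`.
#' @export
compare_energies <- function(a, b) {
  stats::wilcox.test(a, b, alternative = "less", exact = FALSE)
}

#' Convergence table across a batch of runs
#'
#' Stacks the per-generation best-so-far traces of a batch into one long
#' data.frame for convergence analysis.
#'
#' @param results list of `run_result`.
#' @param labels optional run labels (defaults to the seeds).
#' @return data.frame with columns run, generation, best, evals.
#' @export
convergence_table <- function(results, labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(results, function(r) as.character(r$seed), character(1))
  }
  do.call(rbind, lapply(seq_along(results), function(i) {
    tr <- results[[i]]$trace
    data.frame(run = labels[i], generation = tr$generation, best = tr$best,
               evals = tr$evals)
  }))
}
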