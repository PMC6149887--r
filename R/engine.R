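# Engine: the generational loop shared by the plain GA, the Lamarckian GA
# and the history-guided hybrid (HIGA).
#
# Generation structure (history-guided mode):
#   crossover (CE) -> mutation (ED) -> non-revisiting archive -> fitness
#   evaluation -> Lamarckian local search on the best fraction -> selection
# The plain GA uses two-point crossover + Gaussian mutation and skips local
# search; the LGA adds local search; neither consults the history archive.

#' Build a run configuration
#'
#' Defaults mirror the conventional docking protocol (population 50,
#' 27,000 generations, 1.5e6 evaluation cap); tests and examples scale the
#' budgets down.
#'
#' @param algorithm `"GA"`, `"LGA"` or `"HIGA"`.
#' @param pop_size population size (>= 2).
#' @param max_generations generation cap (the protocol's "iterations").
#' @param max_evaluations energy-evaluation cap.
#' @param elite_fraction CE elite fraction (HIGA), in (0, 0.5].
#' @param beta ED exploration probability per gene, in \[0, 1\].
#' @param ed_scope `"gene"` or `"genome"` (see [ed_mutation()]).
#' @param mutation_rate,mutation_sd per-gene Gaussian mutation rate and
#'   scale (GA/LGA baselines).
#' @param ls_fraction fraction of the population receiving local search
#'   each generation (LGA/HIGA); the conventional value is 0.06.
#' @param ls_max_steps Solis-Wets evaluation budget per invocation.
#' @param ls_rho_init initial Solis-Wets step scale.
#' @param archive_resolution per-gene BSP cell width, or `NULL` for
#'   [pose_resolution()] on the objective's bounds.
#' @param archive_local_search should Solis-Wets probe points pass through
#'   the non-revisiting archive?  Default `FALSE`: only operator-produced
#'   individuals are archived.
#' @param record_evaluations keep the full matrix of evaluated genomes on
#'   the result (memory-heavy; used by diagnostics and audits).
#' @param verbose print one structured log line per generation (generation,
#'   best, mean, evaluations, redirects).
#' @param seed integer RNG seed for the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(algorithm = c("HIGA", "GA", "LGA"),
                       pop_size = 50L,
                       max_generations = 27000L,
                       max_evaluations = 1.5e6,
                       elite_fraction = 0.1,
                       beta = 0.1,
                       ed_scope = "gene",
                       mutation_rate = 0.1,
                       mutation_sd = 0.1,
                       ls_fraction = 0.06,
                       ls_max_steps = 300L,
                       ls_rho_init = 1.0,
                       archive_resolution = NULL,
                       archive_local_search = FALSE,
                       record_evaluations = FALSE,
                       verbose = FALSE,
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(pop_size >= 2, max_generations >= 1, max_evaluations >= 1,
            beta >= 0, beta <= 1)
  structure(list(
    algorithm = algorithm, pop_size = as.integer(pop_size),
    max_generations = as.integer(max_generations),
    max_evaluations = max_evaluations,
    elite_fraction = elite_fraction, beta = beta, ed_scope = ed_scope,
    mutation_rate = mutation_rate, mutation_sd = mutation_sd,
    ls_fraction = ls_fraction, ls_max_steps = as.integer(ls_max_steps),
    ls_rho_init = ls_rho_init,
    archive_resolution = archive_resolution,
    archive_local_search = isTRUE(archive_local_search),
    record_evaluations = isTRUE(record_evaluations),
    verbose = isTRUE(verbose),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> ", x$algorithm, ": pop ", x$pop_size, ", ",
      x$max_generations, " generations, ", format(x$max_evaluations),
      " evaluations, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# run the global RNG at a given seed, restoring the caller's state
with_run_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Run one optimization
#'
#' Executes the generational loop of the configured algorithm against a
#' counted objective until either budget cap is reached.  The convergence
#' trace records the best-so-far energy after every generation and is
#' monotone non-increasing by construction.
#'
#' @param config a `run_config`.
#' @param objective a `dock_objective`.
#' @param topo optional `ligand_topology`; when supplied the best genome is
#'   also decoded to a pose (coordinate matrix) on the result.
#' @return object of class `run_result` with fields `best_genome`,
#'   `best_energy`, `trace` (data.frame: generation, best, mean, evals,
#'   revisits), `evaluations`, `generations`, `pose`, `wall_time`.
#' @export
dock_run <- function(config, objective, topo = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(objective, "dock_objective"))
  t0 <- proc.time()[["elapsed"]]
  res <- with_run_seed(config$seed, run_loop(config, objective))
  res$wall_time <- proc.time()[["elapsed"]] - t0
  if (!is.null(topo)) res$pose <- decode_pose(res$best_genome, topo)
  res
}

run_loop <- function(config, objective) {
  bounds <- objective$bounds
  d <- length(bounds$lower)
  n <- config$pop_size
  eval0 <- obj_count(objective)
  budget_left <- function() config$max_evaluations -
    (obj_count(objective) - eval0)

  use_history <- config$algorithm == "HIGA"
  use_ls <- config$algorithm %in% c("LGA", "HIGA")

  archive <- history_archive()
  tree <- NULL
  revisits <- 0
  if (use_history) {
    res <- config$archive_resolution
    if (is.null(res)) res <- pose_resolution(bounds)
    tree <- bsp_tree(bounds, res)
  }
  eval_log <- if (config$record_evaluations) vector("list", 1024) else NULL
  n_logged <- 0L
  log_eval <- function(g) {
    if (is.null(eval_log)) return()
    n_logged <<- n_logged + 1L
    if (n_logged > length(eval_log)) {
      length(eval_log) <<- 2L * length(eval_log)
    }
    eval_log[[n_logged]] <<- g
  }

  # route a genome through the archive (history-guided mode only)
  gate <- function(g) {
    if (is.null(tree)) return(g)
    qi <- bsp_query_insert(tree, g)
    if (qi$revisit) revisits <<- revisits + 1
    qi$genome
  }

  evaluate_one <- function(g) {
    f <- obj_eval(objective, g)
    archive_update(archive, g, f)
    log_eval(g)
    f
  }

  # ---- initial population ------------------------------------------------
  init <- matrix(stats::runif(n * d, rep(bounds$lower, each = n),
                              rep(bounds$upper, each = n)), n, d)
  for (i in seq_len(n)) {
    init[i, ] <- repair_genome(init[i, ], bounds)
    init[i, ] <- gate(init[i, ])
  }
  pop <- new_population(init)

  trace_gen <- integer(0); trace_best <- numeric(0)
  trace_mean <- numeric(0); trace_evals <- numeric(0)
  trace_rev <- numeric(0)
  best_so_far <- Inf; best_genome <- NULL

  finalize <- function(gen) {
    tr <- data.frame(generation = trace_gen, best = trace_best,
                     mean = trace_mean, evals = trace_evals,
                     revisits = trace_rev)
    structure(list(
      algorithm = config$algorithm, seed = config$seed,
      best_genome = best_genome, best_energy = best_so_far,
      trace = tr,
      evaluations = obj_count(objective) - eval0,
      generations = gen,
      revisits = revisits,
      evaluated = if (!is.null(eval_log))
        do.call(rbind, eval_log[seq_len(n_logged)]) else NULL,
      config = config, pose = NULL, wall_time = NA_real_
    ), class = "run_result")
  }

  record_gen <- function(gen) {
    trace_gen <<- c(trace_gen, gen)
    trace_best <<- c(trace_best, best_so_far)
    ok <- is.finite(pop$fitness)
    trace_mean <<- c(trace_mean, if (any(ok)) mean(pop$fitness[ok]) else NA)
    trace_evals <<- c(trace_evals, obj_count(objective) - eval0)
    trace_rev <<- c(trace_rev, revisits)
    if (config$verbose) {
      message(sprintf("gen=%d best=%.6g mean=%.6g evals=%d revisits=%d",
                      gen, best_so_far, trace_mean[length(trace_mean)],
                      as.integer(obj_count(objective) - eval0),
                      as.integer(revisits)))
    }
  }

  # evaluate all NA-fitness individuals, respecting the budget; returns
  # FALSE when the budget ran out before finishing
  evaluate_population <- function() {
    for (i in seq_len(n)) {
      if (!is.na(pop$fitness[i])) next
      if (budget_left() <= 0) return(FALSE)
      f <- evaluate_one(pop$genomes[i, ])
      pop$fitness[i] <<- f
      if (f < best_so_far) {
        best_so_far <<- f
        best_genome <<- pop$genomes[i, ]
      }
    }
    TRUE
  }

  if (!evaluate_population()) {
    # budget exhausted before the first generation completed: partial trace
    pop$fitness[is.na(pop$fitness)] <- Inf
    record_gen(1L)
    return(finalize(1L))
  }

  gen <- 0L
  repeat {
    gen <- gen + 1L

    # ---- Lamarckian local search on the best fraction --------------------
    if (use_ls && config$ls_fraction > 0 && config$ls_max_steps > 0 &&
        budget_left() > 0) {
      n_ls <- max(1L, floor(config$ls_fraction * n))
      for (i in order(pop$fitness)[seq_len(n_ls)]) {
        steps <- min(config$ls_max_steps, budget_left())
        if (steps <= 0) break
        sw <- solis_wets_search(
          pop$genomes[i, ], objective, max_steps = steps,
          rho_init = config$ls_rho_init, fitness = pop$fitness[i],
          filter = if (use_history && config$archive_local_search) {
            function(g) gate(g)
          } else NULL,
          on_eval = function(g, f) {
            archive_update(archive, g, f)
            log_eval(g)
          })
        pop$genomes[i, ] <- sw$genome
        pop$fitness[i] <- sw$fitness
        if (sw$fitness < best_so_far) {
          best_so_far <- sw$fitness
          best_genome <- sw$genome
        }
      }
    }

    record_gen(gen)
    if (gen >= config$max_generations || budget_left() <= 0) break

    # ---- variation -------------------------------------------------------
    if (use_history) {
      pop <- ce_crossover(pop, archive, config$elite_fraction, gen)
      for (i in seq_len(n)) {
        # history-directed mutation supplements the host GA's Gaussian
        # mutation: ED supplies direction, the Gaussian supplies the
        # medium-scale moves neither ED branch can make
        g <- ed_mutation(pop$genomes[i, ], archive, bounds,
                         beta = config$beta, scope = config$ed_scope,
                         rate = config$mutation_rate)
        g <- gaussian_mutation(g, bounds, rate = config$mutation_rate,
                               sd_frac = config$mutation_sd)
        if (any(g != pop$genomes[i, ])) {
          pop$genomes[i, ] <- g
          pop$fitness[i] <- NA_real_
        }
        gi <- gate(pop$genomes[i, ])
        if (any(gi != pop$genomes[i, ])) {
          pop$genomes[i, ] <- gi
          pop$fitness[i] <- NA_real_
        } else if (is.na(pop$fitness[i])) {
          # unchanged by the gate but mutated: still needs evaluation
        }
      }
    } else {
      idx <- proportional_selection(pop$fitness, n)
      mated <- pop$genomes[idx, , drop = FALSE]
      nxt <- matrix(NA_real_, n, d)
      for (p in seq_len(n %/% 2L)) {
        kids <- two_point_crossover(mated[2L * p - 1L, ], mated[2L * p, ])
        nxt[2L * p - 1L, ] <- kids$child_a
        nxt[2L * p, ] <- kids$child_b
      }
      if (n %% 2L == 1L) nxt[n, ] <- mated[n, ]
      for (i in seq_len(n)) {
        nxt[i, ] <- gaussian_mutation(nxt[i, ], bounds,
                                      rate = config$mutation_rate,
                                      sd_frac = config$mutation_sd)
      }
      # the Lamarckian GA keeps the incumbent (writeback preserves acquired
      # improvements); the plain GA does not, and is monotone only in
      # best-so-far terms
      pop_new <- new_population(nxt)
      if (config$algorithm == "LGA") {
        bi <- which.min(pop$fitness)
        pop_new$genomes[1L, ] <- pop$genomes[bi, ]
        pop_new$fitness[1L] <- pop$fitness[bi]
      }
      pop <- pop_new
    }

    if (!evaluate_population()) {
      pop$fitness[is.na(pop$fitness)] <- Inf
      record_gen(gen + 1L)
      return(finalize(gen + 1L))
    }

    # ---- selection (history-guided mode) ---------------------------------
    if (use_history) {
      idx <- proportional_selection(pop$fitness, n)
      # keep the best individual in the surviving set
      if (!any(idx == which.min(pop$fitness))) {
        idx[1L] <- which.min(pop$fitness)
      }
      pop <- list(genomes = pop$genomes[idx, , drop = FALSE],
                  fitness = pop$fitness[idx],
                  parents = pop$parents[idx])
    }
  }
  finalize(gen)
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", x$algorithm, " seed ", x$seed, ": best energy ",
      format(x$best_energy), " after ", x$generations, " generations / ",
      format(x$evaluations), " evaluations\n", sep = "")
  invisible(x)
}

#' Run a batch of independent optimizations
#'
#' @param config a `run_config` (its `seed` field is overridden per run).
#' @param objective a `dock_objective` factory is not needed: the counter
#'   is snapshotted per run, so one objective may be shared.
#' @param seeds integer vector of distinct per-run seeds.
#' @param topo optional topology forwarded to [dock_run()].
#' @return list of `run_result`, one per seed, in seed order.
#' @export
dock_run_batch <- function(config, objective, seeds, topo = NULL) {
  if (anyDuplicated(seeds)) stop("batch seeds must be distinct")
  lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    dock_run(cfg, objective, topo = topo)
  })
}

# ---------------------------------------------------------------------------
# Result serialization

#' Serialize a run result to JSON
#'
#' Timing is excluded so that identical configuration and seed give
#' bit-identical JSON.
#'
#' @param result a `run_result`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
result_to_json <- function(result, path = NULL) {
  payload <- list(
    algorithm = result$algorithm,
    seed = result$seed,
    best_energy = result$best_energy,
    best_genome = result$best_genome,
    generations = result$generations,
    evaluations = result$evaluations,
    revisits = result$revisits,
    trace = result$trace
  )
  if (!is.null(result$pose)) payload$pose <- result$pose
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write the convergence trace as a tab-separated table
#'
#' One row per generation: generation index, best-so-far energy, population
#' mean energy, cumulative evaluations, cumulative archive redirects.
#'
#' @param result a `run_result`.
#' @param path output file path.
#' @export
write_trace <- function(result, path) {
  utils::write.table(result$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
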