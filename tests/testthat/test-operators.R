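# Genetic operators: CE crossover, ED mutation, two-point crossover,
# Solis-Wets local search and rank-proportional selection.

make_archive <- function(best, best_f, sub, sub_f) {
  a <- history_archive()
  archive_update(a, sub, sub_f)
  archive_update(a, best, best_f)
  a
}

test_that("ED mutation branch 2 reproduces the directed-move arithmetic", {
  b <- gene_bounds(0, 10)
  a <- make_archive(1, -5, 3, -4)
  # m = 2, M_optimum = 1, M_sub = 3, theta = 0.5, delta = 0.25
  out <- ed_mutation(2, a, b, beta = 0, theta = 0.5, delta = 0.25)
  expect_equal(out, 2 + 0.5 * (1 - 3) + 0.25 * (1 - 2))  # = 0.75
})

test_that("ED mutation at beta = 0 is the identity once fully converged", {
  b <- gene_bounds(rep(-5, 4), rep(5, 4))
  m <- c(1, -2, 0.5, 3)
  a <- make_archive(m, -10, m + 1e-9, -9.5)
  a$sub_genome <- m  # converged: M_optimum = M_sub = m
  out <- ed_mutation(m, a, b, beta = 0)
  expect_equal(out, m, tolerance = 1e-12)
})

test_that("ED mutation with an empty archive falls back to exploration", {
  b <- gene_bounds(rep(0, 3), rep(1, 3))
  a <- history_archive()
  set.seed(1)
  out <- ed_mutation(c(0.5, 0.5, 0.5), a, b, beta = 0)
  expect_true(all(out >= 0 & out <= 1))
  # theta = 0.3 must land at lower + 0.3 * span even though beta = 0
  out2 <- ed_mutation(c(0.5, 0.5, 0.5), a, b, beta = 0, theta = 0.3,
                      delta = 0.1)
  expect_equal(out2, rep(0.3, 3))
})

test_that("ED mutation outputs always satisfy bounds and genome invariants", {
  b <- pose_gene_bounds(3)
  set.seed(77)
  for (i in 1:200) {
    g <- repair_genome(runif(10, b$lower, b$upper), b)
    a <- make_archive(repair_genome(runif(10, b$lower, b$upper), b), -2,
                      repair_genome(runif(10, b$lower, b$upper), b), -1)
    out <- ed_mutation(g, a, b, beta = runif(1))
    expect_true(all(out >= b$lower - 1e-9 & out <= b$upper + 1e-9))
    expect_equal(sqrt(sum(out[4:7]^2)), 1, tolerance = 1e-9)
    expect_true(all(out[8:10] >= -180 & out[8:10] < 180))
  }
})

test_that("two-point crossover conserves loci and matches hand enumeration", {
  pa <- c(1, 2, 3, 4, 5, 6)
  pb <- c(10, 20, 30, 40, 50, 60)
  # full swap
  k <- two_point_crossover(pa, pb, cuts = c(0, 6))
  expect_equal(k$child_a, pb)
  expect_equal(k$child_b, pa)
  # identical parents are fixed points for every cut pair
  for (c1 in 0:6) for (c2 in c1:6) {
    k2 <- two_point_crossover(pa, pa, cuts = c(c1, c2))
    expect_equal(k2$child_a, pa)
  }
  # exhaustive locus-provenance audit over all cut pairs
  for (c1 in 0:6) for (c2 in c1:6) {
    k3 <- two_point_crossover(pa, pb, cuts = c(c1, c2))
    inside <- seq_len(6) > c1 & seq_len(6) <= c2
    expect_equal(k3$child_a, ifelse(inside, pb, pa))
    expect_equal(k3$child_b, ifelse(inside, pa, pb))
    # per-locus multiset conservation
    expect_equal(k3$child_a + k3$child_b, pa + pb)
  }
  expect_error(two_point_crossover(pa, pb[1:3]), "equal genome lengths")
})

test_that("Solis-Wets honors max_steps = 0 and never worsens fitness", {
  obj <- benchmark_landscape("sphere", 3)
  g <- c(2, -1, 0.5)
  out <- solis_wets_search(g, obj, max_steps = 0, fitness = sum(g^2))
  expect_identical(out$genome, g)
  expect_equal(out$evals, 0)

  set.seed(5)
  for (i in 1:10) {
    g <- runif(3, -4, 4)
    f0 <- obj_eval(obj, g)
    out <- solis_wets_search(g, obj, max_steps = 60, fitness = f0)
    expect_lte(out$fitness, f0)
    expect_equal(out$fitness, sum(out$genome^2), tolerance = 1e-12)
  }
})

test_that("Solis-Wets converges on a quadratic across seeds", {
  # 1-D quadratic with optimum at 1.7
  b <- gene_bounds(-5, 5)
  for (s in 1:20) {
    obj <- objective_new(function(x) (x - 1.7)^2, b)
    set.seed(s)
    out <- solis_wets_search(2 * ((s %% 5) - 2), obj, max_steps = 200,
                             rho_init = 1.0)
    expect_lt(abs(out$genome - 1.7), 0.1)
    expect_lte(out$evals, 200)
    expect_equal(out$evals, obj_count(obj))
  }
})

test_that("rank-proportional selection matches its stationary frequencies", {
  set.seed(123)
  # two individuals at pressure 1.5: weights 1.5 : 0.5 = 3 : 1
  picks <- proportional_selection(c(-10, -2), size = 10000)
  p_best <- mean(picks == 1)
  expect_gt(p_best, 0.75 - 3 * sqrt(0.75 * 0.25 / 10000))
  expect_lt(p_best, 0.75 + 3 * sqrt(0.75 * 0.25 / 10000))
  # single individual is always selected
  expect_identical(proportional_selection(-3, size = 5), rep(1L, 5))
  # all-equal fitness degenerates to uniform
  u <- proportional_selection(rep(1, 4), size = 20000)
  expect_true(all(abs(tabulate(u, 4) / 20000 - 0.25) < 0.02))
  expect_error(proportional_selection(c(1, Inf)), "finite")
})

test_that("CE crossover preserves each elite with its recorded parents", {
  set.seed(9)
  d <- 5
  g <- matrix(runif(10 * d), 10, d)
  pop <- higadock:::new_population(g, fitness = runif(10))
  arch <- history_archive()
  out <- ce_crossover(pop, arch, elite_fraction = 0.1, generation = 1L)
  expect_equal(nrow(out$genomes), 10)
  expect_length(out$elite_records, 1)  # ceiling(0.1 * 10)
  rec <- out$elite_records[[1]]
  best <- g[which.min(pop$fitness), ]
  expect_equal(rec$genome, best)
  # the elite and both parents are rows of the output population
  contains_row <- function(m, v) any(apply(m, 1, function(r)
    isTRUE(all.equal(r, v, tolerance = 1e-12))))
  expect_true(contains_row(out$genomes, rec$genome))
  expect_true(contains_row(out$genomes, rec$father))
  expect_true(contains_row(out$genomes, rec$mother))
  # never-crossed elites record themselves as both parents
  expect_equal(rec$father, best)
  expect_equal(rec$mother, best)
  # the archive accumulated the generation's records
  expect_length(arch$elites, 1)
})

test_that("CE crossover of a clone population returns clones", {
  g <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  pop <- higadock:::new_population(g, fitness = rep(-1, 8))
  set.seed(2)
  out <- ce_crossover(pop, history_archive(), 0.125)
  expect_true(all(apply(out$genomes, 1, function(r)
    isTRUE(all.equal(r, c(1, 2, 3))))))
})

test_that("CE crossover validates its preconditions", {
  g <- matrix(runif(4), 2, 2)
  pop <- higadock:::new_population(g, fitness = c(1, 2))
  expect_error(ce_crossover(pop, history_archive(), 0.6), "elite_fraction")
  pop_na <- higadock:::new_population(g)
  expect_error(ce_crossover(pop_na, history_archive(), 0.1), "fitness")
  one <- higadock:::new_population(matrix(1, 1, 1), fitness = 0)
  expect_error(ce_crossover(one, history_archive(), 0.1), "at least 2")
})

test_that("history archive tracks best and distinct second-best online", {
  a <- history_archive()
  expect_false(archive_ready(a))
  archive_update(a, c(1, 1), -3)
  expect_false(archive_ready(a))          # no distinct second yet
  archive_update(a, c(1, 1), -3)          # same genome again: still not
  expect_false(archive_ready(a))
  archive_update(a, c(2, 2), -5)          # new best; old best demoted
  expect_true(archive_ready(a))
  expect_equal(a$best_genome, c(2, 2))
  expect_equal(a$sub_genome, c(1, 1))
  expect_equal(a$sub_fit, -3)
  archive_update(a, c(3, 3), -4)          # between best and sub
  expect_equal(a$sub_genome, c(3, 3))
  expect_lte(a$best_fit, a$sub_fit)
})
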