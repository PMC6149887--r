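# Post-run analytics: clustering, success summaries, distribution
# summaries and the pairwise comparison utility.

shifted_pose <- function(base, dx) sweep(base, 2, c(dx, 0, 0), `+`)

test_that("identical poses form a single rank-1 cluster", {
  base <- matrix(rnorm(9), 3, 3)
  rep20 <- replicate(20, base, simplify = FALSE)
  cr <- cluster_conformations(rep20, rnorm(20), rmsd_tol = 2)
  expect_length(cr$clusters, 1)
  expect_equal(cr$clusters[[1]]$size, 20)
})

test_that("distant poses split and clusters are ranked by lowest energy", {
  base <- matrix(0, 2, 3)
  poses <- list(shifted_pose(base, 0), shifted_pose(base, 5))
  cr <- cluster_conformations(poses, c(-3, -8), rmsd_tol = 2)
  expect_length(cr$clusters, 2)
  # pose 2 has the lower energy, so it seeds rank 1
  expect_equal(cr$clusters[[1]]$members, 2)
  expect_equal(cr$clusters[[1]]$lowest_energy, -8)
  expect_true(cr$clusters[[1]]$lowest_energy <=
                cr$clusters[[2]]$lowest_energy)
})

test_that("clustering matches the brute-force leader rule on random poses", {
  set.seed(17)
  base <- matrix(rnorm(12), 4, 3)
  for (rep in 1:10) {
    poses <- lapply(1:8, function(i) shifted_pose(base, runif(1, 0, 10)))
    en <- rnorm(8)
    cr <- cluster_conformations(poses, en, rmsd_tol = 2)
    want <- oracle_cluster(poses, en, 2)
    got <- integer(8)
    for (ci in seq_along(cr$clusters)) {
      got[cr$clusters[[ci]]$members] <- ci
    }
    expect_equal(got, want)
    # conservation: every pose in exactly one cluster
    expect_equal(sort(unlist(lapply(cr$clusters, `[[`, "members"))), 1:8)
    # rank-1 holds the global minimum energy
    expect_equal(cr$clusters[[1]]$lowest_energy, min(en))
  }
})

test_that("clustering is invariant to input permutation", {
  set.seed(19)
  base <- matrix(rnorm(9), 3, 3)
  poses <- lapply(1:10, function(i) shifted_pose(base, runif(1, 0, 12)))
  en <- rnorm(10)
  cr1 <- cluster_conformations(poses, en, 2)
  perm <- sample(10)
  cr2 <- cluster_conformations(poses[perm], en[perm], 2)
  sizes1 <- vapply(cr1$clusters, `[[`, integer(1), "size")
  sizes2 <- vapply(cr2$clusters, `[[`, integer(1), "size")
  expect_equal(sizes1, sizes2)
  expect_equal(vapply(cr1$clusters, `[[`, numeric(1), "lowest_energy"),
               vapply(cr2$clusters, `[[`, numeric(1), "lowest_energy"))
  tab <- cluster_table(cr1)
  expect_equal(tab$rank, seq_along(cr1$clusters))
  expect_equal(sum(tab$size), 10)
})

test_that("empty input clusters to an empty report", {
  cr <- cluster_conformations(list(), numeric(0))
  expect_length(cr$clusters, 0)
  expect_equal(cr$n_poses, 0)
})

test_that("success summary counts strict sub-threshold RMSDs", {
  s <- success_summary(c(1.0, 3.0), rmsd_tol = 2.0)
  expect_equal(s$success, 1)
  expect_equal(s$mean_rmsd_all, 2.0)
  expect_equal(s$mean_rmsd_success, 1.0)
  # strict inequality at the boundary
  s2 <- success_summary(c(2.0), rmsd_tol = 2.0)
  expect_equal(s2$success, 0)
  expect_true(is.na(s2$mean_rmsd_success))  # undefined marker, never 0
  # tol = 0 succeeds only on exact matches (never, strictly)
  s3 <- success_summary(c(0, 0.1), rmsd_tol = 0)
  expect_equal(s3$success, 0)
})

test_that("success summary computes RMSD from run poses", {
  ref <- matrix(rnorm(9), 3, 3)
  mk <- function(dx) list(pose = shifted_pose(ref, dx))
  s <- success_summary(list(mk(0), mk(0)), reference_pose = ref)
  expect_equal(s$success, 2)
  expect_equal(s$mean_rmsd_all, 0)
  expect_equal(s$mean_rmsd_success, 0)
  s2 <- success_summary(list(mk(1), mk(3)), reference_pose = ref,
                        rmsd_tol = 2)
  expect_equal(s2$success, 1)
  expect_equal(s2$rmsd, c(1, 3))
  expect_error(success_summary(list(list(pose = NULL)), ref), "no pose")
})

test_that("distribution summary follows the interpolated quartile rule", {
  d <- distribution_summary(rep(4.2, 6))
  expect_true(all(d$summary == 4.2))
  expect_length(d$outliers, 0)

  d2 <- distribution_summary(1:20)
  expect_equal(unname(d2$summary["median"]), 10.5)
  # linear interpolation between order statistics: Q1 = 1 + 0.25 * 19
  expect_equal(unname(d2$summary["q1"]), 5.75)
  expect_equal(unname(d2$summary["q3"]), 15.25)
  expect_length(d2$outliers, 0)

  d3 <- distribution_summary(c(1, 2, 3, 4, 100))
  expect_equal(d3$outliers, 100)
  expect_equal(unname(d3$summary[c("q1", "q3")]), c(2, 4))
  expect_equal(unname(d3$whiskers["upper"]), 4 + 1.5 * 2)
  expect_error(distribution_summary(numeric(0)), "empty")
})

test_that("one-sided rank-sum comparison detects a shifted sample", {
  set.seed(7)
  a <- rnorm(20, -5)
  b <- rnorm(20, 0)
  expect_lt(compare_energies(a, b)$p.value, 0.01)
  expect_gt(compare_energies(b, a)$p.value, 0.5)
})

test_that("convergence tables stack batch traces", {
  cfg <- run_config("GA", pop_size = 10L, max_generations = 5L,
                    max_evaluations = 1e4, seed = 1L)
  batch <- dock_run_batch(cfg, benchmark_landscape("sphere", 2),
                          seeds = c(1, 2))
  tab <- convergence_table(batch)
  expect_equal(nrow(tab), 10)
  expect_setequal(unique(tab$run), c("1", "2"))
})
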