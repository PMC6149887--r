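# Grid interpolation, grid scoring, the pairwise toy energy and the
# benchmark landscapes.

make_test_maps <- function(seed = 1, npts = 5, spacing = 0.5,
                           types = "A") {
  set.seed(seed)
  maps <- lapply(types, function(t)
    array(rnorm(npts^3), dim = rep(npts, 3)))
  names(maps) <- types
  grid_map_set(c(0, 0, 0), spacing, rep(npts, 3), maps,
               emap = array(rnorm(npts^3), dim = rep(npts, 3)))
}

test_that("trilinear interpolation: nodes, edge midpoints, random oracle", {
  g <- make_test_maps(3)
  lat <- g$maps$A
  # exact node: index (2,3,4) -> coordinates
  origin <- c(0, 0, 0) - (g$npts - 1) / 2 * g$spacing
  p_node <- origin + (c(2, 3, 4) - 1) * g$spacing
  expect_equal(trilinear_interpolate(lat, g, p_node), lat[2, 3, 4],
               tolerance = 1e-12)
  # midpoint of an x-edge blends the two corner values equally
  lat2 <- array(0, dim = g$npts); lat2[3, 3, 3] <- 1
  p_mid <- origin + (c(2.5, 2, 2)) * g$spacing
  expect_equal(trilinear_interpolate(lat2, g, p_mid), 0.5,
               tolerance = 1e-12)
  # random interior points match the direct eight-term formula
  set.seed(9)
  for (i in 1:25) {
    p <- runif(3, origin + 1e-6, origin + (g$npts - 1) * g$spacing - 1e-6)
    expect_equal(trilinear_interpolate(lat, g, p),
                 oracle_trilinear(lat, g$center, g$spacing, p),
                 tolerance = 1e-10)
  }
  expect_error(trilinear_interpolate(lat, g, c(100, 0, 0)), "outside")
})

test_that("grid_score sums per-atom interpolations plus torsion penalty", {
  topo <- make_test_chain4()
  npts <- 21
  zero_maps <- lapply(c(A = "A", B = "B", C = "C", D = "D"),
                      function(t) array(0, dim = rep(npts, 3)))
  gz <- grid_map_set(c(2, 0.5, 0), 0.5, rep(npts, 3), zero_maps)
  expect_equal(grid_score(identity_genome(1), topo, gz, w_tors = 0), 0)
  expect_equal(grid_score(identity_genome(1), topo, gz, w_tors = 0.2983),
               0.2983)

  # single-atom ligand parked on a node reduces to a node lookup
  a1 <- data.frame(id = 1L, name = "C1", element = "C", type = "A",
                   charge = 0, x = 0, y = 0, z = 0)
  t1 <- ligand_topology(a1, root = 1L)
  m <- array(0, dim = rep(5, 3)); m[3, 3, 3] <- -1.3
  g1 <- grid_map_set(c(0, 0, 0), 0.5, rep(5, 3), list(A = m))
  expect_equal(grid_score(identity_genome(0), t1, g1, w_tors = 0), -1.3)

  # multi-atom random poses agree with the trilinear oracle, including the
  # charge * electrostatics term
  gm <- make_test_maps(5, npts = 9, spacing = 1.5,
                       types = c("A", "B", "C", "D"))
  set.seed(4)
  for (i in 1:5) {
    g <- random_pose_genome(1, i)
    g[1:3] <- g[1:3] * 0.3
    co <- decode_pose(g, topo)
    want <- 0.2983 * 1 +
      sum(vapply(1:4, function(k) {
        oracle_trilinear(gm$maps[[topo$atoms$type[k]]], gm$center,
                         gm$spacing, co[k, ]) +
          topo$atoms$charge[k] *
            oracle_trilinear(gm$emap, gm$center, gm$spacing, co[k, ])
      }, numeric(1)))
    expect_equal(grid_score(g, topo, gm), want, tolerance = 1e-9)
  }

  # unmapped atom type errors by name
  gm2 <- make_test_maps(5, npts = 9, spacing = 1.5, types = c("A", "B", "C"))
  expect_error(grid_score(identity_genome(1), topo, gm2), "'D'")
})

test_that("out-of-box poses get the finite distance-graded penalty", {
  topo <- make_test_chain4()
  gm <- make_test_maps(5, npts = 5, spacing = 0.25,
                       types = c("A", "B", "C", "D"))
  g <- identity_genome(1)
  g[1:3] <- c(50, 0, 0)
  e1 <- grid_score(g, topo, gm)
  expect_gte(e1, 1e5)
  g[1:3] <- c(60, 0, 0)
  expect_gt(grid_score(g, topo, gm), e1)  # farther out costs more
})

test_that("grid_objective fast path reproduces grid_score exactly", {
  topo <- make_test_chain4()
  topo$atoms$charge <- c(0.1, -0.2, 0.3, 0)
  tc_maps <- make_test_maps(8, npts = 17, spacing = 1.0,
                            types = c("A", "B", "C", "D"))
  obj <- grid_objective(topo, tc_maps, w_tors = 0.2983)
  set.seed(31)
  for (i in 1:20) {
    g <- repair_genome(random_pose_genome(1, i), obj$bounds)
    expect_equal(obj_eval(obj, g), grid_score(g, topo, tc_maps),
                 tolerance = 1e-10)
  }
  expect_equal(obj_count(obj), 20)
})

test_that("toy pairwise energy: LJ minimum, decay, and pair-loop oracle", {
  a1 <- data.frame(id = 1L, name = "C1", element = "C", type = "A",
                   charge = 0, x = 0, y = 0, z = 0)
  t1 <- ligand_topology(a1, root = 1L)
  rec1 <- data.frame(x = 3.8, y = 0, z = 0, r_eq = 3.8, eps = 0.2,
                     charge = 0)
  expect_equal(toy_pairwise_energy(identity_genome(0), t1, rec1), -0.2,
               tolerance = 1e-12)
  rec_far <- data.frame(x = 38, y = 0, z = 0, r_eq = 3.8, eps = 0.2,
                        charge = 0)
  expect_lt(abs(toy_pairwise_energy(identity_genome(0), t1, rec_far)),
            1e-5 * 0.2)

  topo <- make_test_chain4()
  topo$atoms$charge <- c(0.2, -0.1, 0.05, -0.3)
  rec <- data.frame(x = c(5, -2), y = c(1, 4), z = c(0, -1),
                    r_eq = c(3.5, 4.0), eps = c(0.15, 0.3),
                    charge = c(0.4, -0.25))
  g <- random_pose_genome(1, 2)
  co <- decode_pose(g, topo)
  expect_equal(toy_pairwise_energy(g, topo, rec),
               oracle_pairwise(co, topo$atoms$charge, rec),
               tolerance = 1e-10)
})

test_that("neutral pairwise energy decays monotonically beyond 3 r_eq", {
  a1 <- data.frame(id = 1L, name = "C1", element = "C", type = "A",
                   charge = 0, x = 0, y = 0, z = 0)
  t1 <- ligand_topology(a1, root = 1L)
  es <- vapply(seq(3 * 3.8, 10 * 3.8, length.out = 30), function(r) {
    rec <- data.frame(x = r, y = 0, z = 0, r_eq = 3.8, eps = 0.2,
                      charge = 0)
    abs(toy_pairwise_energy(identity_genome(0), t1, rec))
  }, numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("benchmark landscapes have their recorded optima and bounds", {
  for (nm in c("sphere", "rastrigin-like")) {
    obj <- benchmark_landscape(nm, 4)
    expect_equal(obj_eval(obj, obj$optimum), obj$optimum_value)
    expect_length(obj$bounds$lower, 4)
  }
  df <- benchmark_landscape("double-funnel", 2)
  fl <- df$funnel
  # closed-form values at both funnel centers, including the cross terms
  val_c1 <- -fl$d1 - fl$d2 * exp(-sum((fl$c1 - fl$c2)^2) / (2 * fl$w2^2))
  val_c2 <- -fl$d2 - fl$d1 * exp(-sum((fl$c2 - fl$c1)^2) / (2 * fl$w1^2))
  expect_equal(obj_eval(df, fl$c1), val_c1, tolerance = 1e-12)
  expect_equal(obj_eval(df, fl$c2), val_c2, tolerance = 1e-12)
  expect_lt(val_c1, val_c2)  # the global funnel really is deeper
  expect_error(benchmark_landscape("no-such", 2), "unknown")
})

test_that("objective counters count exactly one increment per evaluation", {
  obj <- benchmark_landscape("sphere", 3)
  expect_equal(obj_count(obj), 0)
  for (i in 1:7) obj_eval(obj, rep(0.1 * i, 3))
  expect_equal(obj_count(obj), 7)
  obj_reset(obj)
  expect_equal(obj_count(obj), 0)
})

test_that("grid energy is covariant with whole-cell map shifts", {
  # shifting the pose by one grid cell and rolling the lattice content by
  # one index must leave the interpolated energy unchanged
  npts <- 9
  set.seed(12)
  lat <- array(rnorm(npts^3), dim = rep(npts, 3))
  g <- grid_map_set(c(0, 0, 0), 0.5, rep(npts, 3), list(A = lat))
  lat_shift <- lat[c(2:npts, 1), , ]   # content moved one cell along -x
  g2 <- grid_map_set(c(0, 0, 0), 0.5, rep(npts, 3), list(A = lat_shift))
  for (i in 1:10) {
    p <- runif(3, -1.2, 0.9)
    e1 <- trilinear_interpolate(lat, g, p + c(0.5, 0, 0))
    e2 <- trilinear_interpolate(lat_shift, g2, p)
    expect_equal(e1, e2, tolerance = 1e-10)
  }
})
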