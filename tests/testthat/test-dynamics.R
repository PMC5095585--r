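test_that("RMSD is zero for self and for rigid-body copies", {
  bb <- build_backbone(10)
  cfg <- trajectory_sim_config(bb$topology, bb$coords, fluctuation_sd = 0.5,
                               n_frames = 20, frame_interval = 1, seed = 3)
  traj <- generate_trajectory_ensemble(cfg)$replicates[[1]]
  expect_equal(max(abs(rmsd_series(traj, traj[5, , ])[5])), 0,
               tolerance = 1e-9)
  moved <- random_rigid(traj, seed = 4)
  per_frame <- vapply(seq_len(dim(traj)[1]), function(f)
    rmsd_series(traj[f, , , drop = FALSE], moved[f, , ]), 0)
  expect_lt(max(per_frame), 1e-9)
  expect_error(rmsd_series(traj, traj[1, , ], integer(0)), "empty")
})

test_that("RMSD after fitting matches the bio3d oracle", {
  set.seed(11)
  for (i in 1:20) {
    P <- matrix(rnorm(15, sd = 3), 5, 3)
    Q <- matrix(rnorm(15, sd = 3), 5, 3)
    traj <- array(P, dim = c(1, 5, 3))
    mine <- rmsd_series(traj, Q)
    theirs <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
    expect_equal(unname(mine), unname(theirs), tolerance = 1e-3)  # bio3d rounds
  }
})

test_that("torsions match an independent oracle on random geometries", {
  set.seed(12)
  worst <- 0
  for (i in 1:1000) {
    p <- matrix(rnorm(12), 4, 3)
    a <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    b <- torsion_oracle(p[1, ], p[2, ], p[3, ], p[4, ])
    worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-9)
  # trans and cis constructions
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
})

test_that("planted backbone dihedrals are recovered from the ensemble", {
  bb <- build_backbone(6, phi = -63, psi = -42)
  cfg <- trajectory_sim_config(bb$topology, bb$coords, fluctuation_sd = 0,
                               seed = 5)
  ens <- generate_trajectory_ensemble(cfg)
  ds <- dihedral_series(ens, 3, window = c(20, 50))
  expect_equal(unique(round(as.vector(ds$phi), 6)), -63)
  expect_equal(unique(round(as.vector(ds$psi), 6)), -42)
  expect_equal(sum(ds$histogram), length(ds$phi) )
  # terminal residues lack phi or psi
  expect_warning(first <- dihedral_series(ens, 1, window = c(20, 50)),
                 "lacks the atoms")
  expect_null(first$phi)
})

test_that("hbond occupancy tracks the geometric criterion and its truth", {
  bb <- build_backbone(8)
  always <- data.frame(donor = 1L, acceptor = 12L, occupancy = 1)
  cfg <- trajectory_sim_config(bb$topology, bb$coords, fluctuation_sd = 0.1,
                               hbond_switch_schedule = always, seed = 6)
  ens <- generate_trajectory_ensemble(cfg)
  occ <- hbond_occupancy(ens, always, window = c(20, 50))
  expect_equal(unname(occ$mean), 1)

  # per-frame decisions equal a brute-force distance check
  crit <- hbond_criteria()
  bond <- data.frame(donor = 3L, acceptor = 17L)
  got <- hbond_occupancy(ens, bond, crit, window = c(0, 50))
  brute <- vapply(seq_along(ens$replicates), function(r) {
    traj <- ens$replicates[[r]]
    mean(vapply(seq_len(dim(traj)[1]), function(f)
      sqrt(sum((traj[f, 3, ] - traj[f, 17, ])^2)) <= 3.5, TRUE))
  }, 0)
  expect_equal(unname(got$per_replicate[1, ]), brute)

  # narrowing the cutoff never increases occupancy
  tight <- hbond_occupancy(ens, bond, hbond_criteria(heavy_distance_max = 2.0),
                           window = c(0, 50))
  expect_true(all(tight$per_replicate <= got$per_replicate))

  # hydrogen-explicit mode requires hydrogens
  expect_error(hbond_occupancy(ens, bond,
                               hbond_criteria(mode = "hydrogen"),
                               window = c(20, 50)),
               "heavy-atom mode")
})

test_that("hydrogen-explicit criteria test distance and angle", {
  topo <- data.frame(atom = c("N", "H", "O"), element = c("N", "H", "O"),
                     resid = c(1L, 1L, 2L), resname = "ALA")
  good <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))   # linear, close
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1.8, 0))   # ~90 deg at H
  mk <- function(co) trajectory_ensemble(
    topo, list(array(rep(co, each = 2), c(2, 3, 3))), c(0, 1))
  bonds <- data.frame(donor = 1L, acceptor = 3L, hydrogen = 2L)
  crit <- hbond_criteria(mode = "hydrogen")
  expect_equal(unname(hbond_occupancy(mk(good), bonds, crit,
                                      window = c(0, 1))$mean), 1)
  expect_equal(unname(hbond_occupancy(mk(bent), bonds, crit,
                                      window = c(0, 1))$mean), 0)
})

test_that("backbone/side-chain distances follow the centre of mass", {
  # residue with a single side-chain atom: distance = |CA - CB|
  topo <- data.frame(atom = c("N", "CA", "C", "CB"),
                     element = c("N", "C", "C", "C"),
                     resid = 1L, resname = "ALA")
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 3, 0))
  ens <- trajectory_ensemble(topo, list(array(rep(co, each = 2),
                                              c(2, 4, 3)),
                                        array(rep(co, each = 2),
                                              c(2, 4, 3))), c(0, 1))
  d <- backbone_sidechain_distance(ens, data.frame(ca_resid = 1,
                                                   sc_resid = 1),
                                   window = c(0, 1))
  expect_equal(d$mean_distance, 3)

  # two equal-mass side-chain atoms: COM is the midpoint
  topo2 <- data.frame(atom = c("N", "CA", "C", "CB", "CG"),
                      element = c("N", "C", "C", "C", "C"),
                      resid = 1L, resname = "XXX")
  co2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 4, 0))
  ens2 <- trajectory_ensemble(topo2, list(array(rep(co2, each = 2),
                                                c(2, 5, 3)),
                                          array(rep(co2, each = 2),
                                                c(2, 5, 3))), c(0, 1))
  d2 <- backbone_sidechain_distance(ens2, data.frame(ca_resid = 1,
                                                     sc_resid = 1),
                                    window = c(0, 1))
  expect_equal(d2$mean_distance, 3)  # CA at origin, COM at (0,3,0)

  # glycine has no side chain
  topo3 <- data.frame(atom = c("N", "CA", "C"), element = c("N", "C", "C"),
                      resid = 1L, resname = "GLY")
  ens3 <- trajectory_ensemble(topo3, list(array(rep(co[1:3, ], each = 2),
                                                c(2, 3, 3)),
                                          array(rep(co[1:3, ], each = 2),
                                                c(2, 3, 3))), c(0, 1))
  expect_error(backbone_sidechain_distance(ens3,
                                           data.frame(ca_resid = 1,
                                                      sc_resid = 1),
                                           window = c(0, 1)),
               "no side chain")
})

test_that("structural features are invariant under global rigid motion", {
  bb <- build_backbone(8)
  # append CB side-chain atoms to residues 2 and 3
  topo <- rbind(bb$topology,
                data.frame(atom = "CB", element = "C", resid = c(2L, 3L),
                           resname = "ALA"))
  coords <- rbind(bb$coords,
                  bb$coords[5, , drop = FALSE] + 1,
                  bb$coords[8, , drop = FALSE] + 1)
  cfg <- trajectory_sim_config(topo, coords, fluctuation_sd = 0.2,
                               n_frames = 21, seed = 7)
  ens <- generate_trajectory_ensemble(cfg)
  moved <- ens
  moved$replicates <- lapply(seq_along(ens$replicates), function(i)
    random_rigid(ens$replicates[[i]], seed = 100 + i))

  bond <- data.frame(donor = 2L, acceptor = 14L)
  o1 <- hbond_occupancy(ens, bond, window = c(0, 20))
  o2 <- hbond_occupancy(moved, bond, window = c(0, 20))
  expect_equal(o1$per_replicate, o2$per_replicate, tolerance = 1e-9)

  pair <- data.frame(ca_resid = 4, sc_resid = 2)
  d1 <- backbone_sidechain_distance(ens, pair, window = c(0, 20))
  d2 <- backbone_sidechain_distance(moved, pair, window = c(0, 20))
  expect_equal(d1$mean_distance, d2$mean_distance, tolerance = 1e-9)

  a1 <- dihedral_series(ens, 4, window = c(0, 20))
  a2 <- dihedral_series(moved, 4, window = c(0, 20))
  expect_equal(a1$phi, a2$phi, tolerance = 1e-7)
  expect_equal(a1$psi, a2$psi, tolerance = 1e-7)
})

test_that("ensemble comparison flags planted shifts and only those", {
  set.seed(8)
  a <- matrix(rnorm(200 * 4, sd = 0.02), 200, 4,
              dimnames = list(sprintf("f%03d", 1:200), NULL))
  b <- a + matrix(rnorm(200 * 4, sd = 0.02), 200, 4)
  b["f007", ] <- b["f007", ] + 0.5   # 5x the replicate noise and more
  res <- compare_ensembles(a, b, delta_min = 0.1)
  expect_equal(res$feature, "f007")
  expect_equal(res$effect, 0.5, tolerance = 0.1)

  # identical ensembles are never reproducibly different
  expect_equal(nrow(compare_ensembles(a, a)), 0)
  # symmetry up to sign
  rev <- compare_ensembles(b, a, delta_min = 0.1)
  expect_equal(rev$effect, -res$effect)
  expect_error(compare_ensembles(a[, 1, drop = FALSE], b), "2 replicates")
})

test_that("null false-flag rate respects the combinatorial bound", {
  set.seed(9)
  n <- 1000
  a <- matrix(rnorm(n * 4), n, 4)
  b <- matrix(rnorm(n * 4), n, 4)
  res <- compare_ensembles(a, b, delta_min = 0)
  p0 <- 2 / choose(8, 4)
  rate <- nrow(res) / n
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / n))
})
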