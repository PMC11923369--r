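test_that("superposition undoes rigid motions and matches analytic cases", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% R, 2, c(5, -2, 1), "+")
  sp <- superpose(Q, P)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  # analytic two-point case: {(0,0,0),(1,0,0)} vs {(0,0,0),(2,0,0)}
  sp2 <- superpose(rbind(c(0, 0, 0), c(1, 0, 0)),
                   rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(sp2$rmsd, 0.5, tolerance = 1e-9)

  # mirror-image difference cannot be removed by proper rotations
  set.seed(2)
  P3 <- matrix(rnorm(15), 5, 3)
  M <- P3; M[, 1] <- -M[, 1]
  sp3 <- superpose(M, P3)
  expect_gt(sp3$rmsd, 0.1)
  # and the Kabsch optimum is no worse than a brute-force rotation grid
  expect_lte(sp3$rmsd,
             rmsd_rotation_grid_oracle(M, P3, steps = 24) + 1e-9)
})

test_that("superposition RMSD is invariant to rigid pre-transforms", {
  set.seed(3)
  P <- matrix(rnorm(24), 8, 3)
  Q <- P + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- superpose(Q, P)$rmsd
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  expect_equal(superpose(sweep(Q %*% R, 2, c(9, 9, 9), "+"), P)$rmsd,
               base, tolerance = 1e-9)
  expect_error(superpose(P[1, , drop = FALSE], Q[1, , drop = FALSE]), "2")
})

test_that("rmsd_series: zeros for static input, periodic for the pincer", {
  spec <- pincer_spec(n_frames = 15, amplitude = 0, fluctuation_sigma = 0,
                      period = 5, seed = 1, n_domains = 2,
                      residues_per_domain = 5)
  static <- generate_pincer_trajectory(spec)
  rs <- rmsd_series(static)
  expect_true(all(rs$values < 1e-9))

  spec2 <- pincer_spec(n_frames = 80, amplitude = 8, period = 40,
                       fluctuation_sigma = 0, seed = 1)
  tr <- generate_pincer_trajectory(spec2)
  rs2 <- rmsd_series(tr)
  expect_equal(rs2$values[1], 0, tolerance = 1e-9)
  expect_equal(rs2$values[1:40], rs2$values[41:80], tolerance = 1e-8)

  # a rigid noiseless domain measured (and fit) on itself stays at zero
  map <- pincer_domain_map(spec2)
  dom <- domain_residues(map, "N")
  rsd <- rmsd_series(tr, sel = dom, fit_sel = dom)
  expect_true(all(rsd$values < 1e-9))
  expect_error(rmsd_series(tr, sel = 9999), "selection")
})

test_that("rmsf: zero for static input, preserves per-domain ordering", {
  spec <- pincer_spec(n_frames = 10, amplitude = 0, fluctuation_sigma = 0,
                      period = 5, seed = 1, n_domains = 2,
                      residues_per_domain = 6)
  expect_true(all(rmsf(generate_pincer_trajectory(spec))$values < 1e-9))

  spec2 <- pincer_spec(n_domains = 2, residues_per_domain = 20,
                       domain_names = c("soft", "stiff"),
                       jaw_pair = c("soft", "stiff"),
                       amplitude = 0, period = 100, n_frames = 800,
                       fluctuation_sigma = c(soft = 1.0, stiff = 0.2),
                       seed = 5)
  tr <- generate_pincer_trajectory(spec2)
  rf <- rmsf(tr)
  expect_gt(mean(rf$values[1:20]), mean(rf$values[21:40]))
  expect_error(rmsf(as_trajectory(tr$topology, tr$coords[, , 1])), "frames")
})

test_that("rmsf is invariant to frame-order permutation", {
  spec <- small_pincer(n_frames = 60)
  tr <- generate_pincer_trajectory(spec)
  shuf <- tr
  set.seed(8)
  shuf$coords <- tr$coords[, , sample(60)]
  expect_equal(rmsf(shuf)$values, rmsf(tr)$values, tolerance = 1e-9)
})

test_that("radius of gyration matches closed forms and is translation-invariant", {
  topo <- toy_topology(c("CA", "CA"), "ALA", 1:2, mass = 1)
  tr <- as_trajectory(topo, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(tr)$values, 1.0)

  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  topo10 <- toy_topology(rep("CA", 10), "ALA", 1:10, mass = runif(10, 1, 3))
  tr10 <- as_trajectory(topo10, x)
  # independent direct computation
  m <- topo10$mass
  com <- colSums(x * m) / sum(m)
  rg_direct <- sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(tr10)$values, rg_direct,
               tolerance = 1e-12)

  tr_shift <- as_trajectory(topo10, sweep(x, 2, c(100, 0, 0), "+"))
  expect_equal(radius_of_gyration(tr_shift)$values,
               radius_of_gyration(tr10)$values, tolerance = 1e-9)

  topo0 <- toy_topology("CA", "ALA", 1, mass = 0)
  expect_error(radius_of_gyration(as_trajectory(topo0, matrix(0, 1, 3))),
               "mass")
})

test_that("interdomain distances: analytic pairs, symmetry, triangle inequality", {
  topo <- toy_topology(c("CA", "CA"), "ALA", 1:2, mass = 1)
  tr <- as_trajectory(topo, rbind(c(0, 0, 0), c(3, 4, 0)))
  map <- domain_map("toy", data.frame(domain = c("a", "b"),
                                      start = 1:2, end = 1:2))
  ds <- interdomain_distances(tr, map)
  expect_equal(as.numeric(ds$series), 5.0)
  expect_equal(pair_distance(ds, "b", "a"), pair_distance(ds, "a", "b"))

  spec <- small_pincer(n_frames = 50, sigma = 0)
  trp <- generate_pincer_trajectory(spec)
  dsp <- interdomain_distances(trp, pincer_domain_map(spec))
  jaw <- pair_distance(dsp, "PAZ", "MID")
  expect_equal(max(jaw) - min(jaw), 2 * spec$amplitude, tolerance = 1e-9)
  nonjaw <- pair_distance(dsp, "N", "L1")
  expect_lt(max(nonjaw) - min(nonjaw), 1e-9)

  # triangle inequality across all domain triples, every frame
  doms <- c("N", "PAZ", "MID")
  for (f in c(1, 25, 50)) {
    ab <- pair_distance(dsp, doms[1], doms[2])[f]
    bc <- pair_distance(dsp, doms[2], doms[3])[f]
    ac <- pair_distance(dsp, doms[1], doms[3])[f]
    expect_lte(ac, ab + bc + 1e-9)
  }

  bad <- domain_map("toy", data.frame(domain = "ghost", start = 99, end = 99))
  expect_error(interdomain_distances(tr, bad), "ghost")
})

test_that("SASA matches closed forms and the two-sphere oracle", {
  topo1 <- toy_topology("CA", "ALA", 1)
  s1 <- sasa(matrix(0, 1, 3), topo1)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 0.01)

  topo2 <- toy_topology(c("CA", "CA"), "ALA", 1:2)
  far <- sasa(rbind(c(0, 0, 0), c(50, 0, 0)), topo2)
  expect_equal(far$total, 2 * 4 * pi * 3.1^2, tolerance = 0.01)

  for (d in c(2.0, 4.0, 5.5)) {
    ov <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), topo2)
    expect_equal(ov$total, two_sphere_sasa_oracle(3.1, 3.1, d),
                 tolerance = 0.02)
  }

  # occlusion monotonicity: adding an atom never increases others' area
  topo3 <- toy_topology(rep("CA", 3), "ALA", 1:3)
  three <- sasa(rbind(c(0, 0, 0), c(4, 0, 0), c(2, 2, 0)), topo3)
  two <- sasa(rbind(c(0, 0, 0), c(4, 0, 0)), topo2)
  expect_lte(three$per_atom[1], two$per_atom[1] + 1e-9)
  expect_lte(three$per_atom[2], two$per_atom[2] + 1e-9)

  topoX <- toy_topology("XX", "ALA", 1)
  expect_error(sasa(matrix(0, 1, 3), topoX), "radius")
})
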