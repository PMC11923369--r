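test_that("salt bridges obey the 4.0 A rule", {
  topo <- toy_topology(c("NZ", "OE1"), c("LYS", "GLU"), c(5L, 100L))
  ev <- detect_contacts(rbind(c(0, 0, 0), c(3.2, 0, 0)), topo, types = "sb")
  expect_equal(nrow(ev), 1)
  expect_identical(ev$type, "sb")
  expect_equal(c(ev$res_i, ev$res_j), c(5, 100))
  expect_equal(ev$distance, 3.2)

  none <- detect_contacts(rbind(c(0, 0, 0), c(4.5, 0, 0)), topo,
                          types = "sb")
  expect_equal(nrow(none), 0)
})

test_that("ring geometries split pi- from t-stacking and find pi-cation", {
  topo <- phe_pair_topology()
  parallel <- rbind(phe_ring_coords(0), phe_ring_coords(4))
  ev <- detect_contacts(parallel, topo, types = c("ps", "ts"))
  expect_identical(ev$type, "ps")
  expect_equal(ev$distance, 4, tolerance = 1e-9)

  tilted <- rbind(phe_ring_coords(0), phe_ring_coords(4, tilt = 75 * pi / 180))
  ev2 <- detect_contacts(tilted, topo, types = c("ps", "ts"))
  expect_identical(ev2$type, "ts")
  expect_equal(ev2$angle, 75, tolerance = 1e-6)

  topo_pc <- toy_topology(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "NZ"),
                          c(rep("PHE", 6), "LYS"), c(rep(1L, 6), 10L))
  ev3 <- detect_contacts(rbind(phe_ring_coords(0), c(0, 0, 4)), topo_pc,
                         types = "pc")
  expect_identical(ev3$type, "pc")

  # cation far off the ring normal is rejected
  ev4 <- detect_contacts(rbind(phe_ring_coords(0), c(5.5, 0, 0.5)), topo_pc,
                         types = "pc")
  expect_equal(nrow(ev4), 0)

  # incomplete ring: skipped with a warning, no event
  topo_bad <- toy_topology(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ",
                             "CG", "CD1"),
                           "PHE", c(rep(1L, 6), 10L, 10L))
  expect_warning(
    ev5 <- detect_contacts(rbind(phe_ring_coords(0), phe_ring_coords(4)[1:2, ]),
                           topo_bad, types = c("ps", "ts")),
    "missing ring")
  expect_equal(nrow(ev5), 0)
})

test_that("hydrogen bonds: distance rule, angle veto, subtype assignment", {
  # backbone N to backbone O, no explicit H: distance-only
  topo <- toy_topology(c("N", "O"), c("GLY", "ALA"), c(1L, 10L),
                       mass = c(14, 16))
  ev <- detect_contacts(rbind(c(0, 0, 0), c(2.9, 0, 0)), topo, types = "hb")
  expect_identical(ev$type, "hbbb")

  # explicit hydrogen: near-linear passes, bent fails
  topoH <- toy_topology(c("N", "H", "O"), c("GLY", "GLY", "ALA"),
                        c(1L, 1L, 10L), mass = c(14, 1, 16))
  lin <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.9, 0.3, 0))
  ev1 <- detect_contacts(lin, topoH, types = "hb")
  expect_equal(nrow(ev1), 1)
  expect_gte(ev1$angle, 110)
  bent <- rbind(c(0, 0, 0), c(-1.0, 0, 0), c(2.9, 0.3, 0))
  expect_equal(nrow(detect_contacts(bent, topoH, types = "hb")), 0)

  # side-chain donor to backbone acceptor -> hbsb; to side-chain -> hbss
  topo_sb <- toy_topology(c("OG", "O"), c("SER", "ALA"), c(1L, 10L))
  expect_identical(detect_contacts(rbind(c(0, 0, 0), c(3.0, 0, 0)),
                                   topo_sb, types = "hb")$type, "hbsb")
  topo_ss <- toy_topology(c("OG", "OE1"), c("SER", "GLN"), c(1L, 10L))
  expect_identical(detect_contacts(rbind(c(0, 0, 0), c(3.0, 0, 0)),
                                   topo_ss, types = "hb")$type, "hbss")
})

test_that("apolar topologies yield no hydrogen bonds; counts are stable", {
  topo_c <- toy_topology(c("CA", "CB"), "ALA", c(1L, 10L))
  expect_equal(nrow(detect_contacts(rbind(c(0, 0, 0), c(3, 0, 0)), topo_c,
                                    types = "hb")), 0)

  # persistent constructed bond across a 100-frame static trajectory
  topo <- toy_topology(c("N", "O"), c("GLY", "ALA"), c(1L, 10L),
                       mass = c(14, 16))
  coords <- array(rep(rbind(c(0, 0, 0), c(2.9, 0, 0)), 100), c(2, 3, 100))
  tr <- as_trajectory(topo, coords)
  hb <- hbond_count_series(tr)
  expect_equal(hb$values, rep(1, 100))
})

test_that("detection is invariant to atom order and events self-validate", {
  topo <- toy_topology(c("NZ", "OE1", "N", "O"),
                       c("LYS", "GLU", "GLY", "ALA"),
                       c(5L, 100L, 20L, 40L), mass = 14)
  co <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(10, 0, 0), c(12.9, 0, 0))
  ev <- detect_contacts(co, topo)
  perm <- c(4, 2, 3, 1)
  ev_perm <- detect_contacts(co[perm, ], topo[perm, ])
  key <- function(e) sort(paste(e$type, e$res_i, e$res_j))
  expect_identical(key(ev), key(ev_perm))
  expect_true(all(ev$res_i < ev$res_j))
  # self-check: every event within its own threshold
  lim <- c(hbbb = 3.5, hbsb = 3.5, hbss = 3.5, sb = 4.0, pc = 6.0,
           ps = 7.0, ts = 7.0)
  expect_true(all(ev$distance <= lim[ev$type]))
})

test_that("medoid catalogues deduplicate on (type, residue pair)", {
  topo <- toy_topology(c("NZ", "OE1"), c("LYS", "GLU"), c(5L, 100L))
  f1 <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(3.9, 0, 0))
  one <- unique_contact_catalog(list(f1), topo, types = "sb")
  expect_equal(nrow(one), 1)
  expect_identical(one$n_medoids_observed, 1L)

  two_same <- unique_contact_catalog(list(f1, f1), topo, types = "sb")
  expect_equal(nrow(two_same), 1)  # idempotent union
  expect_identical(two_same$n_medoids_observed, 2L)

  both <- unique_contact_catalog(list(f1, f2), topo, types = "sb")
  expect_equal(nrow(both), 1)  # same pair, one entry

  # catalogue size is monotone in medoid count
  topo4 <- toy_topology(c("NZ", "OE1", "N", "O"),
                        c("LYS", "GLU", "GLY", "ALA"),
                        c(5L, 100L, 20L, 40L), mass = 14)
  g1 <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(10, 0, 0), c(30, 0, 0))
  g2 <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(10, 0, 0), c(12.9, 0, 0))
  n1 <- nrow(unique_contact_catalog(list(g1), topo4))
  n2 <- nrow(unique_contact_catalog(list(g1, g2), topo4))
  expect_gte(n2, n1)

  # domain labels via map
  map <- domain_map("toy", data.frame(domain = c("D1", "D2"),
                                      start = c(1, 90), end = c(50, 120)))
  lab <- unique_contact_catalog(list(f1), topo, map = map, types = "sb")
  expect_identical(lab$domain_i, "D1")
  expect_identical(lab$domain_j, "D2")
  expect_identical(lab$span, "interdomain")
})
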