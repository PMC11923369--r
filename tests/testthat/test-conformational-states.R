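test_that("smooth_normalize: contract, constant error, step preserved", {
  x <- sin(2 * pi * (0:499) / 100)
  y <- smooth_normalize(x)
  expect_equal(mean(y), 0, tolerance = 1e-9)
  expect_equal(stats::sd(y), 1, tolerance = 1e-9)
  expect_error(smooth_normalize(rep(3, 100)), "variance")
  expect_error(smooth_normalize(1:5), "short")

  step <- c(rep(0, 200), rep(1, 200))
  ys <- smooth_normalize(step, span = 40)
  infl <- which.max(diff(ys))
  expect_lt(abs(infl - 200), 4)  # within span/10 of the step
})

test_that("time_lag: self-lag zero, planted shifts, antisymmetry", {
  t0 <- 0:599
  a <- sin(2 * pi * t0 / 200)
  self <- time_lag(a, a, 100)
  expect_identical(self$lag, 0L)
  expect_equal(self$correlation, 1, tolerance = 1e-6)

  b <- sin(2 * pi * (t0 - 50) / 200)
  expect_identical(time_lag(a, b, 90)$lag, 50L)
  expect_identical(time_lag(b, a, 90)$lag, -50L)

  # lag recovery within 1 frame for a range of periods (noiseless)
  for (period in c(10, 40, 150)) {
    shift <- min(period %/% 3, 30)
    aa <- sin(2 * pi * t0 / period)
    bb <- sin(2 * pi * (t0 - shift) / period)
    got <- time_lag(aa, bb, max_lag = max(4, period %/% 2 - 1))$lag
    expect_lte(abs(got - shift), 1)
  }
  expect_error(time_lag(a, b, 600), "max_lag")
})

test_that("time_lag tolerates noise after smoothing", {
  spec1 <- pincer_spec(n_frames = 600, period = 200, amplitude = 10,
                       fluctuation_sigma = 0, seed = 1)
  spec2 <- spec1; spec2$phase <- 50
  m <- pincer_domain_map(spec1)
  j1 <- pair_distance(interdomain_distances(
    generate_pincer_trajectory(spec1), m), "PAZ", "MID")
  j2 <- pair_distance(interdomain_distances(
    generate_pincer_trajectory(spec2), m), "PAZ", "MID")
  sp <- default_span(length(j1))
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    n1 <- j1 + rnorm(600, sd = stats::sd(j1) / 5)
    n2 <- j2 + rnorm(600, sd = stats::sd(j2) / 5)
    time_lag(smooth_normalize(n1, sp), smooth_normalize(n2, sp), 100)$lag - 50
  }, numeric(1))
  expect_lte(max(abs(errs)), 3)
})

test_that("clustering recovers planted conformers deterministically", {
  tr <- two_state_trajectory()
  cfg <- cluster_config(k_range = 2:6, seed = 2)
  cl <- cluster_frames(tr, cfg)
  expect_identical(cl$k, 2L)
  expect_length(unique(cl$labels[1:40]), 1)
  expect_length(unique(cl$labels[41:80]), 1)
  expect_false(cl$labels[1] == cl$labels[80])
  # medoids are members of their own clusters
  expect_identical(cl$labels[cl$medoids], seq_len(cl$k))
  # determinism
  cl2 <- cluster_frames(tr, cfg)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$medoids, cl2$medoids)
})

test_that("clustering degenerates gracefully on a static trajectory", {
  base <- matrix(seq_len(36 * 3), 36, 3)
  coords <- array(rep(base, 10), c(36, 3, 10))
  topo <- toy_topology(rep("CA", 36), "ALA", 1:36, mass = 1)
  tr <- as_trajectory(topo, coords)
  expect_warning(cl <- cluster_frames(tr), "identical")
  expect_identical(cl$k, 1L)
})

test_that("medoid extraction: singleton, collinear midpoint, membership", {
  # 3 frames: A, midpoint, B -> the midpoint minimizes summed MSD
  topo <- toy_topology(rep("CA", 4), "ALA", 1:4, mass = 1)
  A <- matrix(c(0, 0, 0, 3.8, 0, 0, 0, 3.8, 0, 0, 0, 3.8), 4, 3,
              byrow = TRUE)
  B <- A; B[1, 1] <- B[1, 1] + 6
  mid <- A; mid[1, 1] <- mid[1, 1] + 3
  coords <- array(c(A, mid, B), c(4, 3, 3))
  tr <- as_trajectory(topo, coords)
  feats <- rbind(as.numeric(A), as.numeric(mid), as.numeric(B))
  d2 <- as.matrix(dist(feats))^2
  expect_identical(unname(which.min(rowSums(d2))), 2L)  # direct MSD sums
  cl <- structure(list(labels = rep(1L, 3), medoids = 2L, k = 1L),
                  class = "cluster_result")
  med <- extract_medoids(cl, tr)
  expect_identical(attr(med[[1]], "frame"), 2L)

  trs <- two_state_trajectory()
  cls <- cluster_frames(trs, cluster_config(k_range = 2:4, seed = 1))
  meds <- extract_medoids(cls, trs)
  for (i in seq_along(meds)) {
    f <- attr(meds[[i]], "frame")
    expect_identical(cls$labels[f], i)  # inside its own cloud
  }
})

test_that("state representatives: max/min selection, ties, bracketing", {
  r <- select_state_representatives(c(30, 55, 41), c("m1", "m2", "m3"))
  expect_identical(r$open, "m2")
  expect_identical(r$closed, "m1")
  tie <- select_state_representatives(c(7, 7, 7))
  expect_identical(tie$open, 1L)  # documented first-index tie-break
  expect_identical(tie$closed, 1L)
  expect_warning(select_state_representatives(5), "single")

  # representatives bracket every candidate
  set.seed(10)
  jd <- runif(9, 20, 60)
  rr <- select_state_representatives(jd)
  expect_true(all(jd >= rr$closed_distance & jd <= rr$open_distance))
})

test_that("residue mapping: identity, insertion shift, transpose symmetry", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  mp <- map_residues(s, s)
  expect_equal(mp$pos_a, mp$pos_b)
  expect_equal(nrow(mp), nchar(s))

  ins <- paste0(substr(s, 1, 9), "W", substr(s, 10, nchar(s)))
  mp2 <- map_residues(s, ins)
  expect_true(all(diff(mp2$pos_a) > 0))
  expect_true(all(diff(mp2$pos_b) > 0))
  expect_true(all(mp2$pos_b[mp2$pos_a >= 10] ==
                    mp2$pos_a[mp2$pos_a >= 10] + 1))

  mp_ab <- map_residues(s, ins)
  mp_ba <- map_residues(ins, s)
  expect_equal(mp_ab$pos_a, mp_ba$pos_b)
  expect_equal(mp_ab$pos_b, mp_ba$pos_a)
})

test_that("projection: shape contract, planar recovery, duplicates coincide", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  mapn <- map_residues(s, s)
  set.seed(4)
  pts <- cbind(rnorm(33), rnorm(33), 0)  # exactly planar
  msets <- list(A = list(pts, pts), B = list(pts))
  proj <- stack_and_project(msets, list(B = mapn))
  expect_equal(nrow(proj), 3 * 33)
  expect_true(all(c("dim1", "dim2") %in% names(proj)))
  expect_identical(attr(proj, "embed_config")$n_neighbours, 1000)

  # PCA on planar points reproduces the plane up to rotation: pairwise
  # distances within one medoid are preserved
  one <- proj[proj$protein == "B", c("dim1", "dim2")]
  expect_equal(as.numeric(dist(one)), as.numeric(dist(pts[, 1:2])),
               tolerance = 1e-6)

  # duplicated rows embed to coincident points
  first_a <- proj[proj$protein == "A" & proj$medoid == 1, c("dim1", "dim2")]
  second_a <- proj[proj$protein == "A" & proj$medoid == 2, c("dim1", "dim2")]
  expect_equal(first_a, second_a, tolerance = 1e-9, ignore_attr = TRUE)

  short <- map_residues("MKT", "MKT")
  expect_error(stack_and_project(list(A = list(pts), B = list(pts)),
                                 list(B = short[1:2, ])),
               "3")
})
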