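# Independent oracles used to validate the implementation paths.

# Discrete Frechet distance by exhaustive coupling recursion: explore every
# monotone coupling from (1,1) to (n,m), minimizing the maximum pointwise
# distance. Exponential; only for tiny curves.
frechet_oracle <- function(a, b) {
  A <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  B <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == n && j == m) return(here)
    nexts <- c()
    if (i < n) nexts <- c(nexts, rec(i + 1, j))
    if (j < m) nexts <- c(nexts, rec(i, j + 1))
    if (i < n && j < m) nexts <- c(nexts, rec(i + 1, j + 1))
    max(here, min(nexts))
  }
  rec(1, 1)
}

# Longest common substring(s) by exhaustive enumeration: build the full
# substring set of every sequence and intersect, scanning lengths from the
# longest down.
lcs_oracle <- function(seqs) {
  subs_of_len <- function(s, L) {
    st <- seq_len(nchar(s) - L + 1)
    unique(substring(s, st, st + L - 1))
  }
  for (L in seq(min(nchar(seqs)), 1)) {
    common <- Reduce(intersect, lapply(seqs, subs_of_len, L = L))
    if (length(common)) return(sort(common))
  }
  character(0)
}

# minimal RMSD over proper rotations by brute-force Euler-angle grid
# (after centering); coarse lower-resolution check of the Kabsch path
rmsd_rotation_grid_oracle <- function(P, Q, steps = 40) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  ang <- seq(0, 2 * pi, length.out = steps + 1)[1:steps]
  best <- Inf
  for (a in ang) for (b in seq(0, pi, length.out = steps %/% 2)) {
    for (g in ang) {
      Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3)
      Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3)
      R <- Rz1 %*% Ry %*% Rz2
      r <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
      if (r < best) best <- r
    }
  }
  best
}

# analytic accessible area of two intersecting probe-expanded spheres
two_sphere_sasa_oracle <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  cap_h <- function(R, Rother) R - (d^2 + R^2 - Rother^2) / (2 * d)
  a1 <- 4 * pi * r1^2 - 2 * pi * r1 * max(0, cap_h(r1, r2))
  a2 <- 4 * pi * r2^2 - 2 * pi * r2 * max(0, cap_h(r2, r1))
  a1 + a2
}

random_sequences <- function(k, lengths, alphabet) {
  vapply(lengths, function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}
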