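# Shared fixture builders (all synthetic, generated in code).

toy_topology <- function(elety, resid, resno, mass = 12) {
  data.frame(eleno = seq_along(elety), elety = elety, resid = resid,
             resno = resno, chain = "A",
             mass = rep_len(mass, length(elety)),
             stringsAsFactors = FALSE)
}

# regular hexagonal ring (PHE-like geometry), optionally tilted about x
# and lifted along z
phe_ring_coords <- function(z = 0, tilt = 0) {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  xy <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  if (tilt != 0) {
    R <- matrix(c(1, 0, 0,
                  0, cos(tilt), -sin(tilt),
                  0, sin(tilt), cos(tilt)), 3, 3)
    xy <- xy %*% t(R)
  }
  sweep(xy, 2, c(0, 0, z), "+")
}

phe_pair_topology <- function() {
  toy_topology(rep(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), 2),
               "PHE", rep(c(1L, 10L), each = 6))
}

# trajectory with two planted conformers: atoms 1..18 shifted +20 A in x
# for the second half of the frames (an internal rearrangement that
# superposition cannot remove)
two_state_trajectory <- function(n_frames = 80, sd = 0.5, seed = 9) {
  set.seed(seed)
  base <- matrix(rnorm(36 * 3), 36, 3) * 5
  coords <- array(NA_real_, c(36, 3, n_frames))
  half <- n_frames %/% 2
  for (i in seq_len(n_frames)) {
    b <- base
    if (i > half) b[1:18, 1] <- b[1:18, 1] + 20
    coords[, , i] <- b + matrix(rnorm(36 * 3, sd = sd), 36, 3)
  }
  as_trajectory(toy_topology(rep("CA", 36), "ALA", 1:36, mass = 1), coords)
}

small_pincer <- function(n_frames = 120, period = 60, amplitude = 10,
                         sigma = 0.3, seed = 7, ...) {
  pincer_spec(n_frames = n_frames, period = period, amplitude = amplitude,
              fluctuation_sigma = sigma, seed = seed, ...)
}
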