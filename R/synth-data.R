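#' Specification for a synthetic multi-domain "pincer" trajectory
#'
#' Describes a toy protein made of `n_domains` internally rigid domains, one
#' pseudo-atom (CA, mass 1) per residue. Two designated "jaw" domains
#' oscillate between a closed and an open separation following a raised
#' cosine, emulating the open/close pincer motion of the nucleic-acid
#' binding channel in Argonaute-like proteins; every residue additionally
#' receives i.i.d. isotropic Gaussian noise with a per-domain amplitude.
#'
#' The jaw center-of-mass separation at 0-based frame `t` is, before noise,
#' `closed_distance + amplitude * (1 - cos(2*pi*(t - phase)/period))`,
#' so the peak-to-trough span of the jaw distance is `2 * amplitude`.
#'
#' Defaults emulate the sampling of microsecond-scale simulations of human
#' Argonaute paralogs: 100,000 frames at 1 frame / 10 ps, six domains
#' (N, L1, PAZ, L2, MID, PIWI) with the PAZ/MID pair as jaws, and an open
#' separation exceeding 50 Angstrom.
#'
#' @param n_domains number of rigid domains.
#' @param residues_per_domain residues (= pseudo-atoms) per domain.
#' @param domain_names optional character vector of domain names.
#' @param jaw_pair length-2 character vector naming the two jaw domains.
#' @param closed_distance jaw separation in the closed state (Angstrom).
#' @param amplitude half peak-to-trough jaw separation (Angstrom).
#' @param period oscillation period in frames.
#' @param phase frame offset of the oscillation.
#' @param fluctuation_sigma per-axis Gaussian sigma in Angstrom; a single
#'   number or a named vector with one entry per domain.
#' @param n_frames number of frames to generate.
#' @param stride_ps time per frame in picoseconds.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an object of class `pincer_spec`.
#' @export
pincer_spec <- function(n_domains = 6,
                        residues_per_domain = 30,
                        domain_names = NULL,
                        jaw_pair = NULL,
                        closed_distance = 30,
                        amplitude = 12,
                        period = 200,
                        phase = 0,
                        fluctuation_sigma = 0.5,
                        n_frames = 1000,
                        stride_ps = 10,
                        seed = 1L) {
  n_domains <- check_count(n_domains, "n_domains", min = 2)
  residues_per_domain <- check_count(residues_per_domain, "residues_per_domain")
  if (is.null(domain_names)) {
    domain_names <- if (n_domains == 6) {
      c("N", "L1", "PAZ", "L2", "MID", "PIWI")
    } else {
      paste0("D", seq_len(n_domains))
    }
  }
  if (length(domain_names) != n_domains || anyDuplicated(domain_names)) {
    stop_field("domain_names", "must be n_domains distinct names")
  }
  if (is.null(jaw_pair)) {
    jaw_pair <- if (all(c("PAZ", "MID") %in% domain_names)) {
      c("PAZ", "MID")
    } else {
      domain_names[c(1, n_domains)]
    }
  }
  if (length(jaw_pair) != 2 || !all(jaw_pair %in% domain_names) ||
      jaw_pair[1] == jaw_pair[2]) {
    stop_field("jaw_pair", "must name two distinct existing domains")
  }
  closed_distance <- check_number(closed_distance, "closed_distance", min = 0)
  amplitude <- check_number(amplitude, "amplitude", min = 0)
  period <- check_count(period, "period", min = 2)
  phase <- check_number(phase, "phase")
  if (length(fluctuation_sigma) == 1 && is.null(names(fluctuation_sigma))) {
    fluctuation_sigma <- stats::setNames(rep(as.numeric(fluctuation_sigma),
                                             n_domains), domain_names)
  }
  if (!all(domain_names %in% names(fluctuation_sigma))) {
    stop_field("fluctuation_sigma", "must cover every domain name")
  }
  fluctuation_sigma <- fluctuation_sigma[domain_names]
  if (any(!is.finite(fluctuation_sigma)) || any(fluctuation_sigma < 0)) {
    stop_field("fluctuation_sigma", "must be finite and >= 0 per domain")
  }
  n_frames <- check_count(n_frames, "n_frames")
  stride_ps <- check_number(stride_ps, "stride_ps", min = 1e-12)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(n_domains = n_domains,
         residues_per_domain = residues_per_domain,
         domain_names = domain_names,
         jaw_pair = jaw_pair,
         closed_distance = closed_distance,
         amplitude = amplitude,
         period = period,
         phase = phase,
         fluctuation_sigma = fluctuation_sigma,
         n_frames = n_frames,
         stride_ps = stride_ps,
         seed = seed),
    class = "pincer_spec"
  )
}

# Rigid local lattice for one domain: residues on a cubic grid (3.8 A
# spacing, roughly the CA-CA distance), centered so the domain COM is 0.
domain_lattice <- function(n_res, spacing = 3.8) {
  side <- ceiling(n_res^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                             z = seq_len(side)))[seq_len(n_res), , drop = FALSE]
  g <- g * spacing
  sweep(g, 2, colMeans(g))
}

# Fixed domain-center layout at the closed state: jaws on the x axis at
# -closed/2 and +closed/2; the remaining domains on a parallel line at
# y = 40 A, spread 30 A apart, so non-jaw pair distances are constant.
domain_centers_closed <- function(spec) {
  centers <- matrix(0, spec$n_domains, 3,
                    dimnames = list(spec$domain_names, c("x", "y", "z")))
  centers[spec$jaw_pair[1], ] <- c(-spec$closed_distance / 2, 0, 0)
  centers[spec$jaw_pair[2], ] <- c(+spec$closed_distance / 2, 0, 0)
  others <- setdiff(spec$domain_names, spec$jaw_pair)
  if (length(others)) {
    xs <- (seq_along(others) - (length(others) + 1) / 2) * 30
    centers[others, ] <- cbind(xs, 40, 0)
  }
  centers
}

#' Jaw separation of a pincer spec before noise
#'
#' @param spec a [pincer_spec()].
#' @param frames 0-based frame indices (default all frames of the spec).
#' @return numeric vector of jaw COM separations in Angstrom.
#' @export
jaw_distance_profile <- function(spec, frames = seq_len(spec$n_frames) - 1) {
  spec$closed_distance +
    spec$amplitude * (1 - cos(2 * pi * (frames - spec$phase) / spec$period))
}

#' Generate a synthetic pincer trajectory
#'
#' Builds the domain-labelled pseudo-atom topology and `n_frames` coordinate
#' frames. Domains are internally rigid; only the two jaw domains translate
#' (symmetrically along x) so that their center-of-mass separation follows
#' the raised-cosine profile of the spec exactly before noise; i.i.d.
#' Gaussian noise with the per-domain sigma is then added to every
#' atom/axis/frame.
#'
#' @param spec a [pincer_spec()].
#' @return an object of class `md_trajectory`: a list with `topology`
#'   (data.frame: eleno, elety, resid, resno, chain, mass), `coords`
#'   (array n_atoms x 3 x n_frames, Angstrom) and `stride_ps`.
#' @export
generate_pincer_trajectory <- function(spec) {
  if (!inherits(spec, "pincer_spec")) spec <- do.call(pincer_spec, spec)
  n_res <- spec$residues_per_domain
  n_atoms <- spec$n_domains * n_res
  domain_of_atom <- rep(spec$domain_names, each = n_res)

  topology <- data.frame(
    eleno = seq_len(n_atoms),
    elety = "CA",
    resid = "ALA",
    resno = seq_len(n_atoms),
    chain = "A",
    mass = 1,
    domain = domain_of_atom,
    stringsAsFactors = FALSE
  )

  lattice <- domain_lattice(n_res)
  centers <- domain_centers_closed(spec)
  base <- matrix(0, n_atoms, 3)
  for (d in spec$domain_names) {
    idx <- which(domain_of_atom == d)
    base[idx, ] <- sweep(lattice, 2, centers[d, ], "+")
  }

  t0 <- seq_len(spec$n_frames) - 1
  half_extra <- (jaw_distance_profile(spec, t0) - spec$closed_distance) / 2

  coords <- array(base, dim = c(n_atoms, 3, spec$n_frames))
  jaw1 <- which(domain_of_atom == spec$jaw_pair[1])
  jaw2 <- which(domain_of_atom == spec$jaw_pair[2])
  # jaws separate symmetrically along x
  coords[jaw1, 1, ] <- coords[jaw1, 1, ] +
    rep(-half_extra, each = length(jaw1))
  coords[jaw2, 1, ] <- coords[jaw2, 1, ] +
    rep(+half_extra, each = length(jaw2))

  sigma_atom <- spec$fluctuation_sigma[domain_of_atom]
  if (any(sigma_atom > 0)) {
    noise <- with_seed(spec$seed, {
      array(stats::rnorm(n_atoms * 3 * spec$n_frames),
            dim = c(n_atoms, 3, spec$n_frames))
    })
    coords <- coords + noise * as.numeric(sigma_atom)
  }

  structure(
    list(topology = topology, coords = coords, stride_ps = spec$stride_ps,
         spec = spec),
    class = "md_trajectory"
  )
}

#' Domain map implied by a pincer spec
#'
#' @param spec a [pincer_spec()].
#' @param protein protein name recorded in the map.
#' @return a [domain_map()] covering every residue of the synthetic topology.
#' @export
pincer_domain_map <- function(spec, protein = "synthetic") {
  n <- spec$residues_per_domain
  starts <- (seq_len(spec$n_domains) - 1) * n + 1
  domain_map(protein,
             data.frame(domain = spec$domain_names,
                        start = starts,
                        end = starts + n - 1,
                        stringsAsFactors = FALSE))
}

#' Generate independent replicate trajectories
#'
#' Replicates share the spec (hence the deterministic pincer motion) and
#' differ only in the noise realization, mirroring independent simulation
#' replicas of the same system.
#'
#' @param spec a [pincer_spec()].
#' @param n number of replicates.
#' @param seeds integer vector of `n` distinct seeds.
#' @return list of `md_trajectory` objects.
#' @export
generate_replicates <- function(spec, n, seeds) {
  n <- check_count(n, "n")
  if (length(seeds) != n) stop_field("seeds", "must have length n")
  if (anyDuplicated(seeds)) stop_field("seeds", "must be distinct")
  lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- check_count(s, "seeds", min = -.Machine$integer.max)
    generate_pincer_trajectory(sp)
  })
}

#' Specification for planted-segment random sequences
#'
#' @param alphabet character vector of single symbols.
#' @param k number of sequences.
#' @param lengths per-sequence lengths (recycled to length `k`).
#' @param segment symbol string planted verbatim in every sequence.
#' @param positions per-sequence 1-based insert positions (recycled).
#' @param seed integer RNG seed.
#' @return an object of class `planted_segment_spec`.
#' @export
planted_segment_spec <- function(alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]],
                                 k = 4, lengths = 400, segment,
                                 positions = 1, seed = 1L) {
  k <- check_count(k, "k", min = 1)
  lengths <- rep_len(vapply(lengths, check_count, 1L, field = "lengths"), k)
  positions <- rep_len(vapply(positions, check_count, 1L,
                              field = "positions"), k)
  if (!is.character(segment) || length(segment) != 1 || nchar(segment) == 0) {
    stop_field("segment", "must be a non-empty string")
  }
  seg_chars <- strsplit(segment, "")[[1]]
  if (!all(seg_chars %in% alphabet)) {
    stop_field("segment", "contains symbols outside the alphabet")
  }
  if (any(positions + nchar(segment) - 1 > lengths)) {
    stop_field("positions", "segment would overrun a sequence")
  }
  structure(
    list(alphabet = alphabet, k = k, lengths = lengths, segment = segment,
         positions = positions, seed = check_count(seed, "seed",
                                                   min = -.Machine$integer.max)),
    class = "planted_segment_spec"
  )
}

#' Generate random sequences with a planted common segment
#'
#' Background symbols are i.i.d. uniform over the alphabet; the segment is
#' written verbatim at each stated position.
#'
#' @param spec a [planted_segment_spec()].
#' @return character vector of `k` sequences, named `seq1..seqk`.
#' @export
plant_lcs_sequences <- function(spec) {
  if (!inherits(spec, "planted_segment_spec")) {
    spec <- do.call(planted_segment_spec, spec)
  }
  with_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$k), function(i) {
      s <- sample(spec$alphabet, spec$lengths[i], replace = TRUE)
      seg <- strsplit(spec$segment, "")[[1]]
      s[spec$positions[i] + seq_along(seg) - 1] <- seg
      paste(s, collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("seq", seq_len(spec$k)))
  })
}
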