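#' Time- or residue-indexed metric curve
#'
#' @param index frame numbers (1-based) or residue numbers.
#' @param values numeric values; must be finite and match `index` length.
#' @param kind `"frame"` or `"residue"`.
#' @param units unit string (e.g. `"A"`, `"A^2"`, `"count"`).
#' @param label metric label.
#' @param provenance free-form list (protein, replicate, selection, ...).
#' @return an object of class `metric_series`.
#' @export
metric_series <- function(index, values, kind = c("frame", "residue"),
                          units = "A", label = "", provenance = list()) {
  kind <- match.arg(kind)
  if (length(index) != length(values)) {
    stop_field("values", "length must match index")
  }
  if (any(!is.finite(values))) stop_field("values", "must be finite")
  structure(list(index = index, values = as.numeric(values), kind = kind,
                 units = units, label = label, provenance = provenance),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("metric_series '%s' (%s-indexed, %s): n=%d, mean=%.4g\n",
              x$label, x$kind, x$units, length(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...) {
  df <- data.frame(index = x$index, value = x$values)
  names(df) <- c(x$kind, paste0(x$label, "_", x$units))
  df
}

# resolve a selection (NULL = all atoms, residue_selection, or residue
# numbers) to atom row indices of a topology
resolve_selection <- function(topology, sel) {
  if (is.null(sel)) return(seq_len(nrow(topology)))
  if (inherits(sel, "residue_selection")) sel <- sel$residues
  idx <- which(topology$resno %in% as.integer(sel))
  if (length(idx) == 0) stop("selection resolves to no atoms", call. = FALSE)
  idx
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' the selected atoms of a mobile and a reference frame.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix.
#' At least two selected atoms are required; for degenerate (collinear or
#' two-point) selections the minimal RMSD is still well defined, though the
#' optimal rotation is not unique.
#'
#' @param sel atom indices used for the fit (default all).
#' @return list with `rotation` (3 x 3, det = +1), `translation`
#'   (length 3; transform is `coords %*% rotation + translation`),
#'   `rmsd` (Angstrom, over `sel`) and `coords` (the transformed mobile).
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 2) stop("need >= 2 atoms to superpose", call. = FALSE)
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  # rank-deficient (e.g. collinear) selections still have a well-defined
  # minimal RMSD; the optimal proper rotation is then just not unique
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- cq - as.numeric(cp %*% R)
  fitted_sel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Qc)^2)))
  coords <- sweep(mobile, 2, cp) %*% R
  coords <- sweep(coords, 2, cq, "+")
  list(rotation = R, translation = translation, rmsd = rmsd, coords = coords)
}

#' RMSD of each frame to a reference frame
#'
#' Each frame is superposed on the reference over `fit_sel` (default: the
#' whole structure) before measuring RMSD over `sel` (default: the fit
#' selection) -- the "fit on whole, measure on domain" convention.
#'
#' @param traj an `md_trajectory`.
#' @param reference reference frame index (default 1).
#' @param sel residue numbers (or [selection()]) to measure over.
#' @param fit_sel residue numbers to superpose on; `NULL` = whole structure.
#' @param provenance optional provenance list.
#' @return a frame-indexed [metric_series()] in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1, sel = NULL, fit_sel = NULL,
                        provenance = list()) {
  fit_idx <- resolve_selection(traj$topology, fit_sel)
  meas_idx <- if (is.null(sel)) fit_idx else resolve_selection(traj$topology,
                                                               sel)
  ref <- frame_coords(traj, reference)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    sp <- superpose(frame_coords(traj, i), ref, sel = fit_idx)
    sqrt(mean(rowSums((sp$coords[meas_idx, , drop = FALSE] -
                         ref[meas_idx, , drop = FALSE])^2)))
  }, numeric(1))
  metric_series(seq_len(nf), vals, kind = "frame", units = "A",
                label = "rmsd", provenance = provenance)
}

# superpose every frame onto a reference over fit_idx; returns the array
superpose_frames <- function(traj, ref, fit_idx) {
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    out[, , i] <- superpose(out[, , i, drop = TRUE], ref, sel = fit_idx)$coords
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Fluctuation of each residue around its time-averaged position after
#' superposing every frame on the time-averaged structure (two iterative
#' passes) over `superpose_sel`.
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param sel residues to report (default all).
#' @param superpose_sel residues used for the fit (default all).
#' @param passes number of average-and-refit passes.
#' @param provenance optional provenance list.
#' @return a residue-indexed [metric_series()] in Angstrom.
#' @export
rmsf <- function(traj, sel = NULL, superpose_sel = NULL, passes = 2,
                 provenance = list()) {
  if (n_frames(traj) < 2) stop("RMSF needs >= 2 frames", call. = FALSE)
  fit_idx <- resolve_selection(traj$topology, superpose_sel)
  meas_idx <- resolve_selection(traj$topology, sel)
  coords <- traj$coords
  # initial reference: raw time-average (frame-order invariant)
  ref <- apply(coords, c(1, 2), mean)
  for (p in seq_len(passes)) {
    tr <- traj; tr$coords <- coords
    coords <- superpose_frames(tr, ref, fit_idx)
    ref <- apply(coords, c(1, 2), mean)
  }
  dev2 <- (coords - array(ref, dim(coords)))^2
  per_atom <- sqrt(apply(dev2, 1, mean) * 3)  # mean over axes*frames -> x3
  # one pseudo-atom per residue in synthetic systems; average per residue
  # in general
  resno <- traj$topology$resno[meas_idx]
  vals <- tapply(per_atom[meas_idx], resno, mean)
  metric_series(as.integer(names(vals)), as.numeric(vals), kind = "residue",
                units = "A", label = "rmsf", provenance = provenance)
}

#' Mass-weighted radius of gyration per frame
#'
#' @param traj an `md_trajectory` with positive atomic masses.
#' @param provenance optional provenance list.
#' @return a frame-indexed [metric_series()] in Angstrom.
#' @export
radius_of_gyration <- function(traj, provenance = list()) {
  m <- traj$topology$mass
  if (sum(m) <= 0) stop("total mass must be positive", call. = FALSE)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, numeric(1))
  metric_series(seq_len(n_frames(traj)), vals, kind = "frame", units = "A",
                label = "rg", provenance = provenance)
}

#' Center-of-mass distance series between all domain pairs
#'
#' @param traj an `md_trajectory`.
#' @param map a [domain_map()]; every domain must own at least one atom.
#' @return an object of class `distance_series`: list with `pairs`
#'   (data.frame `domain_i`, `domain_j`) and `series` (n_frames x n_pairs
#'   matrix, Angstrom, columns named `"A|B"`).
#' @export
interdomain_distances <- function(traj, map) {
  doms <- map$entries$domain
  m <- traj$topology$mass
  nf <- n_frames(traj)
  coms <- array(NA_real_, c(length(doms), 3, nf),
                dimnames = list(doms, NULL, NULL))
  for (d in doms) {
    idx <- which(traj$topology$resno %in% domain_residues(map, d))
    if (length(idx) == 0) {
      stop(sprintf("domain '%s' has no atoms in the topology", d),
           call. = FALSE)
    }
    w <- m[idx] / sum(m[idx])
    for (k in 1:3) {
      slab <- matrix(traj$coords[idx, k, ], nrow = length(idx))
      coms[d, k, ] <- colSums(slab * w)
    }
  }
  prs <- utils::combn(doms, 2)
  series <- matrix(NA_real_, nf, ncol(prs))
  colnames(series) <- paste(prs[1, ], prs[2, ], sep = "|")
  for (p in seq_len(ncol(prs))) {
    d <- coms[prs[1, p], , ] - coms[prs[2, p], , ]
    if (nf == 1) d <- matrix(d, ncol = 1)
    series[, p] <- sqrt(colSums(d^2))
  }
  structure(list(pairs = data.frame(domain_i = prs[1, ], domain_j = prs[2, ],
                                    stringsAsFactors = FALSE),
                 series = series, stride_ps = traj$stride_ps),
            class = "distance_series")
}

#' Extract one pair's distance curve from a `distance_series`
#'
#' Pair order is irrelevant.
#'
#' @param ds a `distance_series`.
#' @param a,b domain names.
#' @return numeric vector of COM distances (Angstrom) per frame.
#' @export
pair_distance <- function(ds, a, b) {
  key <- c(paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  hit <- key[key %in% colnames(ds$series)]
  if (length(hit) == 0) stop("pair not found: ", a, "|", b, call. = FALSE)
  ds$series[, hit[1]]
}

#' @export
summary.distance_series <- function(object, ...) {
  data.frame(object$pairs,
             mean = colMeans(object$series),
             median = apply(object$series, 2, stats::median),
             variance = apply(object$series, 2, stats::var),
             row.names = NULL)
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Bondi van der Waals radii (Angstrom)
.vdw_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)

#' Shrake-Rupley solvent accessible surface area
#'
#' Deterministic quadrature on a golden-spiral point set: for each atom,
#' `n_points` points are placed on the sphere of radius `r_vdw + probe`
#' and counted as accessible when outside every neighbouring atom's
#' expanded sphere.
#'
#' @param coords n x 3 coordinate matrix (one frame), Angstrom.
#' @param topology matching topology (elements derived from atom names).
#' @param probe probe radius, default 1.4 Angstrom (water).
#' @param n_points quadrature points per atom.
#' @return list with `total` (Angstrom^2), `per_atom` and `per_residue`
#'   (named by residue number).
#' @export
sasa <- function(coords, topology, probe = 1.4, n_points = 960) {
  stopifnot(nrow(coords) == nrow(topology))
  elem <- element_of(topology$elety)
  r <- unname(.vdw_radii[elem])
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(elem[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  pts <- sphere_points(n_points)
  n <- nrow(coords)
  per_atom <- numeric(n)
  re <- r + probe
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    p <- sweep(pts * re[i], 2, coords[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        buried <- buried |
          (rowSums(sweep(p, 2, coords[j, ])^2) < re[j]^2)
        if (all(buried)) break
      }
      acc <- sum(!buried)
    } else {
      acc <- n_points
    }
    per_atom[i] <- 4 * pi * re[i]^2 * acc / n_points
  }
  per_residue <- tapply(per_atom, topology$resno, sum)
  list(total = sum(per_atom), per_atom = per_atom,
       per_residue = per_residue)
}

#' SASA per frame of a trajectory
#'
#' @param traj an `md_trajectory`.
#' @param sel residues to total over (default all).
#' @param ... passed to [sasa()].
#' @return a frame-indexed [metric_series()] in Angstrom^2.
#' @export
sasa_series <- function(traj, sel = NULL, ...) {
  idx <- resolve_selection(traj$topology, sel)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    s <- sasa(frame_coords(traj, i), traj$topology, ...)
    sum(s$per_atom[idx])
  }, numeric(1))
  metric_series(seq_len(n_frames(traj)), vals, kind = "frame", units = "A^2",
                label = "sasa")
}
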