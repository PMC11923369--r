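# Geometric detection of weak interactions on single frames, plus
# trajectory hydrogen-bond counting and medoid contact catalogues.
#
# Fixed threshold rules (boundaries inclusive):
#   hydrogen bond: donor-acceptor heavy distance <= 3.5 A, and when
#     explicit hydrogens are present, angle D-H...A >= 110 deg for some H
#     bonded to the donor; subtypes hbbb / hbsb / hbss from backbone vs
#     side-chain membership of the donor and acceptor atoms
#   salt bridge (sb): anionic O (Asp OD*, Glu OE*, OXT) to cationic N
#     (Lys NZ, Arg NH*/NE, His ND1/NE2) <= 4.0 A
#   pi-cation (pc): cationic N within 6.0 A of an aromatic ring centroid
#     and <= 60 deg off the ring normal
#   pi-stacking (ps): ring centroids <= 7.0 A, normals angle <= 30 deg
#   t-stacking (ts): ring centroids <= 7.0 A, normals angle 60-90 deg
# Contacts between residues closer than two positions apart in sequence
# are suppressed.

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

.sidechain_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ", TRP = "NE1",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2")
)

.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

.anionic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.cationic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                        HIS = c("ND1", "NE2"))

.ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"))
)

is_backbone <- function(elety) {
  elety %in% .backbone_atoms | grepl("^H", elety)
}

atom_rows <- function(topology, table) {
  hit <- logical(nrow(topology))
  for (res in names(table)) {
    hit <- hit | (topology$resid == res & topology$elety %in% table[[res]])
  }
  which(hit)
}

ring_geometry <- function(coords, topology) {
  out <- list()
  for (res in unique(topology$resno[topology$resid %in% names(.ring_atoms)])) {
    rn <- topology$resid[topology$resno == res][1]
    for (ri in seq_along(.ring_atoms[[rn]])) {
      names_needed <- .ring_atoms[[rn]][[ri]]
      idx <- which(topology$resno == res & topology$elety %in% names_needed)
      if (length(idx) < length(names_needed)) {
        warning(sprintf("residue %s %d: missing ring atoms; skipped", rn, res))
        next
      }
      xyz <- coords[idx, , drop = FALSE]
      centroid <- colMeans(xyz)
      sv <- svd(sweep(xyz, 2, centroid))
      out[[length(out) + 1]] <- list(resno = res, resid = rn, ring = ri,
                                     centroid = centroid,
                                     normal = sv$v[, 3])
    }
  }
  out
}

angle_deg <- function(u, v) {
  c_ <- abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  acos(pmin(pmax(c_, -1), 1)) * 180 / pi
}

contact_row <- function(type, topology, i, j, distance, angle = NA_real_,
                        atom_i = NA, atom_j = NA) {
  ri <- topology$resno[i]; rj <- topology$resno[j]
  if (rj < ri) {  # residue pair ordered lower number first
    tmp <- i; i <- j; j <- tmp
    ri <- topology$resno[i]; rj <- topology$resno[j]
  }
  data.frame(type = type, res_i = ri, res_j = rj,
             resname_i = topology$resid[i], resname_j = topology$resid[j],
             atom_i = if (is.na(atom_i)) topology$elety[i] else atom_i,
             atom_j = if (is.na(atom_j)) topology$elety[j] else atom_j,
             distance = distance, angle = angle,
             stringsAsFactors = FALSE)
}

detect_hbonds <- function(coords, topology) {
  don <- unique(c(which(topology$elety == "N"),
                  atom_rows(topology, .sidechain_donors)))
  acc <- unique(c(which(topology$elety %in% c("O", "OXT")),
                  atom_rows(topology, .sidechain_acceptors)))
  hyd <- which(grepl("^H", topology$elety))
  rows <- list()
  for (d in don) {
    if (length(acc) == 0) break
    dd <- sqrt(rowSums(sweep(coords[acc, , drop = FALSE], 2,
                             coords[d, ])^2))
    ok <- acc[dd <= 3.5 & abs(topology$resno[acc] - topology$resno[d]) >= 2]
    for (a in ok) {
      dist_da <- sqrt(sum((coords[a, ] - coords[d, ])^2))
      ang <- NA_real_
      if (length(hyd)) {
        dh <- sqrt(rowSums(sweep(coords[hyd, , drop = FALSE], 2,
                                 coords[d, ])^2))
        mine <- hyd[dh <= 1.2 & topology$resno[hyd] == topology$resno[d]]
        if (length(mine)) {
          angs <- vapply(mine, function(h) {
            u <- coords[d, ] - coords[h, ]
            v <- coords[a, ] - coords[h, ]
            acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1),
                      1)) * 180 / pi
          }, numeric(1))
          ang <- max(angs)
          if (ang < 110) next
        }
      }
      bb_d <- is_backbone(topology$elety[d])
      bb_a <- is_backbone(topology$elety[a])
      sub <- if (bb_d && bb_a) "hbbb" else if (!bb_d && !bb_a) "hbss" else "hbsb"
      rows[[length(rows) + 1]] <- contact_row(sub, topology, d, a,
                                              dist_da, ang)
    }
  }
  rows
}

detect_saltbridges <- function(coords, topology) {
  an <- atom_rows(topology, .anionic_atoms)
  an <- unique(c(an, which(topology$elety == "OXT")))
  cat_ <- atom_rows(topology, .cationic_atoms)
  rows <- list()
  for (i in an) {
    for (j in cat_) {
      if (abs(topology$resno[i] - topology$resno[j]) < 2) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= 4.0) {
        rows[[length(rows) + 1]] <- contact_row("sb", topology, i, j, d)
      }
    }
  }
  rows
}

detect_aromatic <- function(coords, topology, types) {
  rings <- ring_geometry(coords, topology)
  rows <- list()
  if ("pc" %in% types && length(rings)) {
    cat_ <- atom_rows(topology, .cationic_atoms)
    for (r in rings) {
      for (j in cat_) {
        if (abs(r$resno - topology$resno[j]) < 2) next
        v <- coords[j, ] - r$centroid
        d <- sqrt(sum(v^2))
        if (d <= 6.0 && angle_deg(v, r$normal) <= 60) {
          i <- which(topology$resno == r$resno)[1]
          rows[[length(rows) + 1]] <- contact_row(
            "pc", topology, i, j, d, angle_deg(v, r$normal),
            atom_i = paste0("ring", r$ring)
          )
        }
      }
    }
  }
  if (any(c("ps", "ts") %in% types) && length(rings) > 1) {
    for (a in seq_len(length(rings) - 1)) {
      for (b in (a + 1):length(rings)) {
        ra <- rings[[a]]; rb <- rings[[b]]
        if (abs(ra$resno - rb$resno) < 2) next
        d <- sqrt(sum((ra$centroid - rb$centroid)^2))
        if (d > 7.0) next
        ang <- angle_deg(ra$normal, rb$normal)
        type <- if (ang <= 30) "ps" else if (ang >= 60) "ts" else NA
        if (is.na(type) || !(type %in% types)) next
        i <- which(topology$resno == ra$resno)[1]
        j <- which(topology$resno == rb$resno)[1]
        rows[[length(rows) + 1]] <- contact_row(
          type, topology, i, j, d, ang,
          atom_i = paste0("ring", ra$ring), atom_j = paste0("ring", rb$ring)
        )
      }
    }
  }
  rows
}

#' Detect weak interactions in one frame
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param topology matching topology with PDB-convention residue and atom
#'   names.
#' @param types contact families to detect; any of `"hb"` (expands to the
#'   hbbb/hbsb/hbss subtypes), `"sb"`, `"pc"`, `"ps"`, `"ts"`.
#' @return data.frame of contact events (possibly 0 rows): `type`,
#'   `res_i` < `res_j`, residue/atom identifiers, `distance` (Angstrom),
#'   `angle` (degrees, where applicable).
#' @export
detect_contacts <- function(coords, topology,
                            types = c("hb", "sb", "pc", "ps", "ts")) {
  stopifnot(nrow(coords) == nrow(topology))
  rows <- list()
  if ("hb" %in% types) rows <- c(rows, detect_hbonds(coords, topology))
  if ("sb" %in% types) rows <- c(rows, detect_saltbridges(coords, topology))
  rows <- c(rows, detect_aromatic(coords, topology, types))
  if (length(rows) == 0) {
    return(data.frame(type = character(0), res_i = integer(0),
                      res_j = integer(0), resname_i = character(0),
                      resname_j = character(0), atom_i = character(0),
                      atom_j = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond count per frame
#'
#' @param traj an `md_trajectory`.
#' @return a frame-indexed [metric_series()] of integer counts.
#' @export
hbond_count_series <- function(traj) {
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    nrow(detect_contacts(frame_coords(traj, i), traj$topology,
                         types = "hb"))
  }, numeric(1))
  metric_series(seq_len(n_frames(traj)), vals, kind = "frame",
                units = "count", label = "hbonds")
}

#' Catalogue of unique contacts over cluster medoids
#'
#' Union of the contact events of every medoid frame, deduplicated on
#' (type, residue pair) -- pair order never matters because events store
#' the lower residue number first. Optionally cross-referenced with a
#' domain map into intra-/interdomain labels.
#'
#' @param medoids list of coordinate matrices (e.g. [extract_medoids()]).
#' @param topology matching topology.
#' @param map optional [domain_map()] for domain labels.
#' @param types contact families, as in [detect_contacts()].
#' @return data.frame: `type`, `res_i`, `res_j`, optional `domain_i`,
#'   `domain_j`, and `n_medoids_observed`.
#' @export
unique_contact_catalog <- function(medoids, topology, map = NULL,
                                   types = c("hb", "sb", "pc", "ps", "ts")) {
  stopifnot(length(medoids) >= 1)
  per <- lapply(medoids, function(f) {
    ev <- detect_contacts(f, topology, types)
    unique(ev[, c("type", "res_i", "res_j")])
  })
  all_ev <- do.call(rbind, per)
  if (nrow(all_ev) == 0) {
    out <- data.frame(type = character(0), res_i = integer(0),
                      res_j = integer(0), n_medoids_observed = integer(0))
  } else {
    key <- paste(all_ev$type, all_ev$res_i, all_ev$res_j)
    counts <- table(key)
    uniq <- all_ev[!duplicated(key), , drop = FALSE]
    uniq$n_medoids_observed <- as.integer(counts[paste(uniq$type, uniq$res_i,
                                                       uniq$res_j)])
    out <- uniq[order(uniq$type, uniq$res_i, uniq$res_j), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(map) && nrow(out)) {
    out$domain_i <- assign_domains(map, out$res_i)
    out$domain_j <- assign_domains(map, out$res_j)
    out$span <- ifelse(out$domain_i == out$domain_j, "intradomain",
                       "interdomain")
  }
  out
}
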