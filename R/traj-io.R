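#' Domain map: named residue ranges of a protein
#'
#' Ranges are 1-based and inclusive on both ends, the convention used to
#' annotate Argonaute domains (e.g. the N domain of human AGO2 spanning
#' residues 36-166). Residues not covered by any range are labelled `UNK`.
#'
#' @param protein protein name.
#' @param entries data.frame with columns `domain`, `start`, `end`.
#' @param selections optional named list of residue-number vectors (e.g.
#'   catalytic tetrad or interaction-site selections).
#' @return an object of class `domain_map`.
#' @export
domain_map <- function(protein, entries, selections = list()) {
  stopifnot(is.data.frame(entries),
            all(c("domain", "start", "end") %in% names(entries)))
  entries <- entries[, c("domain", "start", "end")]
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (any(entries$end < entries$start)) {
    stop_field("entries", "range end precedes start")
  }
  if (anyDuplicated(entries$domain)) {
    stop_field("entries", "duplicate domain names")
  }
  o <- order(entries$start)
  so <- entries[o, ]
  if (nrow(so) > 1 && any(so$start[-1] <= so$end[-nrow(so)])) {
    stop_field("entries", "overlapping residue ranges")
  }
  for (nm in names(selections)) {
    selections[[nm]] <- selection(nm, selections[[nm]])
  }
  structure(list(protein = protein, entries = entries,
                 selections = selections),
            class = "domain_map")
}

#' Named residue selection
#'
#' @param name selection label.
#' @param residues non-empty vector of 1-based residue numbers.
#' @return an object of class `residue_selection`.
#' @export
selection <- function(name, residues) {
  residues <- as.integer(residues)
  if (length(residues) == 0 || anyNA(residues)) {
    stop_field("residues", "must be a non-empty integer vector")
  }
  structure(list(name = name, residues = residues),
            class = "residue_selection")
}

#' Label residues with their domain
#'
#' @param map a [domain_map()].
#' @param resno vector of residue numbers.
#' @return character vector of domain labels, `UNK` where unassigned.
#' @export
assign_domains <- function(map, resno) {
  lab <- rep("UNK", length(resno))
  for (i in seq_len(nrow(map$entries))) {
    e <- map$entries[i, ]
    lab[resno >= e$start & resno <= e$end] <- e$domain
  }
  lab
}

#' Residue numbers belonging to a domain
#'
#' @param map a [domain_map()].
#' @param domain domain name present in the map.
#' @return integer vector of residue numbers (1-based, inclusive range).
#' @export
domain_residues <- function(map, domain) {
  e <- map$entries[map$entries$domain == domain, ]
  if (nrow(e) == 0) stop_field("domain", sprintf("'%s' not in map", domain))
  seq.int(e$start, e$end)
}

element_of <- function(elety) {
  # first alphabetic character of the PDB atom name
  substr(gsub("[^A-Za-z].*|^[0-9]*", "", toupper(elety)), 1, 1)
}

# atomic masses for the elements appearing in protein heavy-atom models
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

#' Read a single-model PDB topology
#'
#' Single-chain PDB files only; insertion codes and duplicate atom serial
#' numbers are rejected. Residue numbering is returned 1-based as written.
#'
#' @param path PDB file path.
#' @return topology data.frame (eleno, elety, resid, resno, chain, mass)
#'   with the frame-0 coordinates attached as attribute `xyz`
#'   (n_atoms x 3 matrix, Angstrom).
#' @export
read_topology <- function(path) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) {
                    stop(sprintf("not a parseable PDB file: %s (%s)",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported: ", path, call. = FALSE)
  }
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1) {
    stop("multi-chain PDB; pre-split chains before reading: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(at$eleno)) {
    stop("duplicate atom serial numbers in ", path, call. = FALSE)
  }
  elem <- element_of(at$elety)
  mass <- unname(.element_masses[elem])
  if (anyNA(mass)) mass[is.na(mass)] <- 12.011
  topo <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                     resno = at$resno,
                     chain = if (length(chains)) chains else "A",
                     mass = mass, stringsAsFactors = FALSE)
  attr(topo, "xyz") <- cbind(at$x, at$y, at$z)
  topo
}

#' Assemble a trajectory object
#'
#' @param topology topology data.frame (see [read_topology()]).
#' @param coords n_atoms x 3 x n_frames array, Angstrom.
#' @param stride_ps frame spacing in picoseconds.
#' @return an `md_trajectory`.
#' @export
as_trajectory <- function(topology, coords, stride_ps = 10) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology)) {
    stop("coordinate/topology atom count mismatch", call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("non-finite coordinates in trajectory", call. = FALSE)
  }
  stride_ps <- check_number(stride_ps, "stride_ps", min = 1e-12)
  structure(list(topology = topology, coords = coords,
                 stride_ps = stride_ps),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, stride %g ps\n",
              dim(x$coords)[1], dim(x$coords)[3], x$stride_ps))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_atoms <- function(traj) dim(traj$coords)[1]
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a trajectory from multi-model PDB or the columnar CSV dialect
#'
#' The CSV dialect has a header row and columns `frame`, `atom_index`,
#' `x`, `y`, `z` (Angstrom). Frames with a different atom count than the
#' topology are rejected, naming the offending frame.
#'
#' @param path file path (`.pdb` or `.csv`).
#' @param topology topology the frames must match.
#' @param stride_ps frame spacing in picoseconds.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(path, topology, stride_ps = 10) {
  na <- nrow(topology)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    dt <- data.table::fread(path)
    need <- c("frame", "atom_index", "x", "y", "z")
    if (!all(need %in% names(dt))) {
      stop("trajectory CSV must have columns frame, atom_index, x, y, z",
           call. = FALSE)
    }
    frames <- sort(unique(dt$frame))
    counts <- table(dt$frame)
    bad <- names(counts)[counts != na]
    if (length(bad)) {
      stop(sprintf("frame %s has %s atoms, topology has %d",
                   bad[1], counts[bad[1]], na), call. = FALSE)
    }
    data.table::setorderv(dt, c("frame", "atom_index"))
    coords <- array(NA_real_, c(na, 3, length(frames)))
    m <- as.matrix(dt[, c("x", "y", "z")])
    for (i in seq_along(frames)) {
      coords[, , i] <- m[((i - 1) * na + 1):(i * na), ]
    }
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE))
    xyz <- pdb$xyz
    if (ncol(xyz) != 3 * na) {
      stop(sprintf("frame 1 has %d atoms, topology has %d",
                   ncol(xyz) / 3, na), call. = FALSE)
    }
    coords <- array(NA_real_, c(na, 3, nrow(xyz)))
    for (i in seq_len(nrow(xyz))) {
      coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    }
  }
  if (any(!is.finite(coords))) {
    stop("non-finite coordinate in trajectory ", path, call. = FALSE)
  }
  as_trajectory(topology, coords, stride_ps)
}

#' Write topology (+ frame) as a single-model PDB
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @param frame frame index to write (default 1).
#' @export
write_topology_pdb <- function(traj, path, frame = 1) {
  xyz <- frame_coords(traj, frame)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = traj$topology$resno,
                   resid = traj$topology$resid,
                   eleno = traj$topology$eleno,
                   elety = traj$topology$elety,
                   chain = traj$topology$chain)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  nf <- n_frames(traj)
  xyz <- t(apply(traj$coords, 3, function(f) as.numeric(t(f))))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$topology$resno,
                   resid = traj$topology$resid,
                   eleno = traj$topology$eleno,
                   elety = traj$topology$elety,
                   chain = traj$topology$chain)
  invisible(path)
}

#' Write a trajectory in the columnar CSV dialect
#'
#' Columns `frame` (0-based), `atom_index`, `x`, `y`, `z` in Angstrom;
#' coordinates are written at full (round-trip) precision.
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  fmt <- function(v) sprintf("%.17g", v)  # round-trip precision
  dt <- data.table::data.table(
    frame = rep(seq_len(nf) - 1L, each = na),
    atom_index = rep(seq_len(na), nf),
    x = fmt(as.numeric(traj$coords[, 1, ])),
    y = fmt(as.numeric(traj$coords[, 2, ])),
    z = fmt(as.numeric(traj$coords[, 3, ]))
  )
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a domain-map JSON config
#'
#' Expected shape:
#' `{"protein": ..., "domains": [{"name","start","end"}, ...],
#'   "selections": [{"name","residues"}, ...]}`.
#'
#' @param path JSON file path.
#' @return a [domain_map()].
#' @export
read_domain_map <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$protein) || is.null(cfg$domains)) {
    stop("domain-map config needs 'protein' and 'domains'", call. = FALSE)
  }
  entries <- data.frame(domain = cfg$domains$name,
                        start = cfg$domains$start,
                        end = cfg$domains$end,
                        stringsAsFactors = FALSE)
  sels <- list()
  if (!is.null(cfg$selections)) {
    if (is.data.frame(cfg$selections)) {
      for (i in seq_len(nrow(cfg$selections))) {
        sels[[cfg$selections$name[i]]] <- cfg$selections$residues[[i]]
      }
    } else {
      for (s in cfg$selections) sels[[s$name]] <- s$residues
    }
  }
  domain_map(cfg$protein, entries, sels)
}

#' Read a FASTA file
#'
#' Multi-record, wrapped lines supported. Non-amino-acid symbols trigger a
#' warning but are kept verbatim.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(set), names(set))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO*\\-]", toupper(seqs))
  if (any(bad)) {
    warning("non-amino-acid symbols in: ",
            paste(names(seqs)[bad], collapse = ", "), " (kept verbatim)")
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a result table as CSV (header row, RFC-4180)
#'
#' @param rows data.frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
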