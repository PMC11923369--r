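# Longest common contiguous segments across paralog sequences, segment
# coordinate mapping, and percent identity.

all_substrings_of_length <- function(s, L) {
  n <- nchar(s)
  if (L > n) return(character(0))
  starts <- seq_len(n - L + 1)
  substring(s, starts, starts + L - 1)
}

common_substrings_of_length <- function(seqs, L) {
  sets <- lapply(seqs, function(s) unique(all_substrings_of_length(s, L)))
  Reduce(intersect, sets)
}

#' Longest common contiguous segment(s) across sequences
#'
#' Finds the longest substring (exact, contiguous, case-sensitive) present
#' in every input sequence, via binary search over the segment length with
#' hashed substring-set intersection at each probe. All tied longest
#' segments are returned, each verified against every sequence before
#' return. This is the operation behind conserved-segment calls such as
#' LCS1 (common to all four human Argonautes) and LCS2 (AGO2/AGO3).
#'
#' @param seqs character vector of >= 2 non-empty sequences.
#' @param min_len minimum segment length to report.
#' @param top_n retained for interface symmetry; all ties at the maximum
#'   length are always returned.
#' @return list of segment hits, each a list with `segment`, `length` and
#'   `positions` (per-sequence data.frame of 1-based `start`, `end` of the
#'   first occurrence); empty list when no common segment reaches
#'   `min_len`.
#' @export
longest_common_segments <- function(seqs, min_len = 1, top_n = 1) {
  if (length(seqs) < 2) stop("need >= 2 sequences", call. = FALSE)
  if (any(nchar(seqs) == 0)) stop("empty sequence", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lo <- as.integer(min_len)
  hi <- min(nchar(seqs))
  if (length(common_substrings_of_length(seqs, lo)) == 0) return(list())
  # invariant: a common substring of length `lo` exists, none of `hi + 1`
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (length(common_substrings_of_length(seqs, mid)) > 0) {
      lo <- mid
    } else {
      hi <- mid - 1L
    }
  }
  segs <- sort(common_substrings_of_length(seqs, lo))
  lapply(segs, function(seg) {
    positions <- do.call(rbind, lapply(names(seqs), function(nm) {
      occ <- map_segment(seg, seqs[[nm]])
      stopifnot(nrow(occ) > 0)  # verification against every sequence
      data.frame(sequence = nm, start = occ$start[1], end = occ$end[1],
                 stringsAsFactors = FALSE)
    }))
    list(segment = seg, length = nchar(seg), positions = positions)
  })
}

#' All occurrences of a segment in a sequence
#'
#' Overlapping occurrences are reported.
#'
#' @param segment non-empty search string.
#' @param sequence sequence searched.
#' @return data.frame of 1-based inclusive `start`, `end` (0 rows when
#'   absent).
#' @export
map_segment <- function(segment, sequence) {
  if (nchar(segment) == 0) stop("empty segment", call. = FALSE)
  L <- nchar(segment)
  n <- nchar(sequence)
  if (L > n) return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq_len(n - L + 1)
  hit <- substring(sequence, starts, starts + L - 1) == segment
  data.frame(start = starts[hit], end = starts[hit] + L - 1L)
}

#' Percent identity between two sequences
#'
#' `"ungapped"` compares position by position (equal lengths required);
#' `"global"` performs a Needleman-Wunsch alignment (BLOSUM62, gap
#' opening 10, gap extension 0.5) and counts gap columns as mismatches.
#'
#' @param seq_a,seq_b sequences.
#' @param alignment_mode `"ungapped"` or `"global"`.
#' @return identity in percent (0-100).
#' @export
percent_identity <- function(seq_a, seq_b,
                             alignment_mode = c("ungapped", "global")) {
  alignment_mode <- match.arg(alignment_mode)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  if (alignment_mode == "ungapped") {
    if (nchar(seq_a) != nchar(seq_b)) {
      stop("ungapped mode requires equal lengths", call. = FALSE)
    }
    a <- strsplit(seq_a, "")[[1]]
    b <- strsplit(seq_b, "")[[1]]
    return(100 * mean(a == b))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * mean(pa == pb)  # gap columns never match
}

#' Export segment hits as a table
#'
#' @param hits result of [longest_common_segments()].
#' @return data.frame: `segment`, `length`, `sequence`, `start`, `end`.
#' @export
segment_hits_table <- function(hits) {
  if (length(hits) == 0) {
    return(data.frame(segment = character(0), length = integer(0),
                      sequence = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, lapply(hits, function(h) {
    data.frame(segment = h$segment, length = h$length, h$positions,
               stringsAsFactors = FALSE)
  }))
}

#' Turn a segment hit into residue selections
#'
#' @param hit one element of [longest_common_segments()] output.
#' @param name selection label prefix.
#' @return named list of [selection()]s, one per sequence.
#' @export
segment_selection <- function(hit, name = "LCS") {
  out <- list()
  for (i in seq_len(nrow(hit$positions))) {
    p <- hit$positions[i, ]
    out[[p$sequence]] <- selection(paste0(name, "_", p$sequence),
                                   seq.int(p$start, p$end))
  }
  out
}
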