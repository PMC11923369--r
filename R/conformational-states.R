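#' Smooth and z-normalize a series
#'
#' EWMA smoothing (span defaulting to 10% of the length) followed by
#' z-score normalization, the preprocessing applied to interdomain
#' distance series before synchronization analysis so that inflection
#' points of the largest motions line up across proteins.
#'
#' @param x numeric series, length >= 10.
#' @param span EWMA span.
#' @return smoothed series with mean 0 and sd 1.
#' @export
smooth_normalize <- function(x, span = default_span(length(x))) {
  if (length(x) < 10) stop("series too short (need >= 10)", call. = FALSE)
  y <- ewma(x, span)
  s <- stats::sd(y)
  if (s < 1e-12 * (abs(mean(y)) + 1)) {
    stop("zero variance after smoothing", call. = FALSE)
  }
  (y - mean(y)) / s
}

#' Time lag maximizing the cross-correlation of two series
#'
#' Cross-correlation on z-scored inputs over integer lags in
#' `[-max_lag, max_lag]`, scored on a fixed central window with a
#' constant denominator. A positive lag means `b` trails `a`
#' (i.e. `b[t] ~ a[t - lag]`). Ties are broken toward the smallest
#' absolute lag, so `time_lag(a, b)$lag == -time_lag(b, a)$lag`.
#'
#' @param a,b equal-length series (typically [smooth_normalize()]d).
#' @param max_lag maximum |lag| searched, in frames (< length).
#' @return list with `lag` (frames) and `correlation` at that lag.
#' @export
time_lag <- function(a, b, max_lag = floor(length(a) / 4)) {
  n <- length(a)
  if (length(b) != n) stop("series lengths differ", call. = FALSE)
  if (max_lag >= n) stop("max_lag must be < series length", call. = FALSE)
  z <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("zero-variance series", call. = FALSE)
    (x - mean(x)) / s
  }
  a <- z(a); b <- z(b)
  lags <- -max_lag:max_lag
  # fixed central window: every lag is scored on the same number of
  # terms (constant denominator), so the peak is not biased toward 0
  w <- seq.int(max_lag + 1, n - max_lag)
  if (length(w) < 2) stop("max_lag too large for series length", call. = FALSE)
  cc <- vapply(lags, function(l) sum(a[w] * b[w + l]) / length(w),
               numeric(1))
  # ties toward the smallest |lag|
  o <- order(abs(lags), lags)
  best <- o[which.max(cc[o])]
  list(lag = lags[best], correlation = cc[best])
}

#' Clustering configuration
#'
#' @param k_range candidate cluster counts (default 2-20).
#' @param msd_preference target average within-cluster RMSD (Angstrom)
#'   used as a tie-break among near-optimal Davies-Bouldin scores.
#' @param db_tolerance relative DB-score band treated as a tie.
#' @param nstart k-means restarts per k.
#' @param seed RNG seed making the clustering deterministic.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(k_range = 2:20, msd_preference = 4,
                           db_tolerance = 0.05, nstart = 10, seed = 1L) {
  structure(list(k_range = k_range, msd_preference = msd_preference,
                 db_tolerance = db_tolerance, nstart = nstart,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

# frame featurization: superpose every frame onto the trajectory's average
# structure once, then flatten the alpha-carbon coordinates
frame_features <- function(traj, sel = NULL) {
  fit_idx <- resolve_selection(traj$topology, sel)
  ref <- apply(traj$coords, c(1, 2), mean)
  coords <- superpose_frames(traj, ref, fit_idx)
  nf <- n_frames(traj)
  t(vapply(seq_len(nf), function(i) as.numeric(coords[fit_idx, , i]),
           numeric(length(fit_idx) * 3)))
}

davies_bouldin <- function(features, labels, centers) {
  k <- nrow(centers)
  S <- vapply(seq_len(k), function(i) {
    idx <- which(labels == i)
    mean(sqrt(rowSums(sweep(features[idx, , drop = FALSE], 2,
                            centers[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centers))
  R <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) R[i, j] <- (S[i] + S[j]) / M[i, j]
  }
  mean(apply(R, 1, max))
}

#' Cluster trajectory frames by conformational similarity
#'
#' Frames are featurized as alpha-carbon coordinates after one
#' superposition onto the trajectory's average structure (Euclidean
#' distance on these features is the square root of atom-count-scaled
#' mean-square deviation), then clustered with k-means (k-means++-style
#' restarts via `nstart`). The number of clusters is chosen by the
#' Davies-Bouldin score; among k whose score is within `db_tolerance` of
#' the best, the k whose average within-cluster RMSD is nearest
#' `msd_preference` (4 Angstrom by default) wins.
#'
#' @param traj an `md_trajectory`.
#' @param config a [cluster_config()].
#' @param sel residues to featurize on (default all, i.e. all CA in the
#'   synthetic systems).
#' @return an object of class `cluster_result`: `labels` per frame,
#'   `medoids` (frame indices, one per cluster), `k`, `db_score`,
#'   `avg_within_rmsd` (Angstrom), `by_k` diagnostics and the config.
#' @export
cluster_frames <- function(traj, config = cluster_config(), sel = NULL) {
  features <- frame_features(traj, sel)
  nf <- nrow(features)
  n_at <- ncol(features) / 3
  if (max(stats::dist(features[seq_len(min(nf, 50)), , drop = FALSE])) < 1e-9 &&
        nf > 1 && sum(apply(features, 2, stats::var)) < 1e-12) {
    warning("all frames identical; returning a single cluster")
    return(structure(list(labels = rep(1L, nf), medoids = 1L, k = 1L,
                          db_score = NA_real_, avg_within_rmsd = 0,
                          by_k = NULL, config = config),
                     class = "cluster_result"))
  }
  ks <- config$k_range[config$k_range >= 2 & config$k_range <= nf - 1]
  if (length(ks) == 0) stop("k_range outside [2, n_frames-1]", call. = FALSE)
  rows <- list()
  fits <- list()
  for (k in ks) {
    fit <- with_seed(config$seed, {
      tryCatch(stats::kmeans(features, centers = k, nstart = config$nstart,
                             iter.max = 100),
               error = function(e) NULL)
    })
    if (is.null(fit)) next
    db <- davies_bouldin(features, fit$cluster, fit$centers)
    within_rmsd <- sqrt(fit$tot.withinss / nf / n_at)
    rows[[as.character(k)]] <- data.frame(k = k, db = db,
                                          avg_within_rmsd = within_rmsd)
    fits[[as.character(k)]] <- fit
  }
  by_k <- do.call(rbind, rows)
  best_db <- min(by_k$db)
  cand <- by_k[by_k$db <= best_db * (1 + config$db_tolerance), ]
  pick <- cand$k[which.min(abs(cand$avg_within_rmsd -
                                 config$msd_preference))]
  fit <- fits[[as.character(pick)]]
  medoids <- vapply(seq_len(pick), function(ci) {
    idx <- which(fit$cluster == ci)
    if (length(idx) == 1) return(idx)
    sub <- features[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(sub))^2
    idx[which.min(rowSums(d2))]
  }, integer(1))
  structure(list(labels = fit$cluster, medoids = medoids, k = as.integer(pick),
                 db_score = by_k$db[by_k$k == pick],
                 avg_within_rmsd = by_k$avg_within_rmsd[by_k$k == pick],
                 by_k = by_k, config = config),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k=%d, DB=%.3f, avg within-cluster RMSD=%.2f A\n",
              x$k, x$db_score, x$avg_within_rmsd))
  invisible(x)
}

#' Extract medoid frames of a clustering
#'
#' The medoid of a cluster is the member frame minimizing the summed
#' within-cluster squared feature distance (ties go to the lowest frame
#' index, resolved inside [cluster_frames()]).
#'
#' @param result a `cluster_result`.
#' @param traj the clustered `md_trajectory`.
#' @return list of coordinate matrices (one per cluster), with the frame
#'   index attached as attribute `frame`.
#' @export
extract_medoids <- function(result, traj) {
  lapply(result$medoids, function(i) {
    f <- frame_coords(traj, i)
    attr(f, "frame") <- i
    f
  })
}

#' Pick open/closed state representatives among medoids
#'
#' @param jaw_distances jaw (e.g. PAZ-MID) COM distance of each medoid,
#'   Angstrom.
#' @param medoid_ids identifiers parallel to `jaw_distances`.
#' @return list with `open`, `closed` (ids), `open_distance`,
#'   `closed_distance`. With a single medoid both states coincide (with a
#'   warning); exact ties resolve to the first index.
#' @export
select_state_representatives <- function(jaw_distances,
                                         medoid_ids = seq_along(jaw_distances)) {
  if (length(jaw_distances) == 0) stop("no medoids", call. = FALSE)
  if (length(jaw_distances) == 1) {
    warning("single medoid; open and closed representatives coincide")
  }
  i_open <- which.max(jaw_distances)
  i_closed <- which.min(jaw_distances)
  list(open = medoid_ids[i_open], closed = medoid_ids[i_closed],
       open_distance = jaw_distances[i_open],
       closed_distance = jaw_distances[i_closed])
}

#' Residue mapping from a global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5 -- the EMBOSS Needle defaults) whose aligned non-gap
#' columns define the residue correspondence.
#'
#' @param seq_a,seq_b protein sequences (single strings).
#' @return data.frame with columns `pos_a`, `pos_b` (1-based, strictly
#'   increasing in both), with the scoring parameters attached as
#'   attribute `params`.
#' @export
map_residues <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  pos_a <- integer(0); pos_b <- integer(0)
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      pos_a <- c(pos_a, ia)
      pos_b <- c(pos_b, ib)
    }
  }
  out <- data.frame(pos_a = pos_a, pos_b = pos_b)
  attr(out, "params") <- list(substitutionMatrix = "BLOSUM62",
                              gapOpening = 10, gapExtension = 0.5,
                              type = "global")
  out
}

#' Embedding configuration for medoid projection
#'
#' Records the projection method and its parameters; the recorded
#' defaults follow the UMAP parameterization used for conformational-
#' space maps (`min_dist = 1`, `n_neighbours = 1000`). The default
#' `method = "pca"` is a deterministic fallback suitable for testing;
#' any function `(matrix, config) -> n x 2 matrix` may be supplied.
#'
#' @param method `"pca"` or an embedding function.
#' @param min_dist,n_neighbours recorded manifold parameters.
#' @param seed RNG seed passed to stochastic embedders.
#' @return an object of class `embed_config`.
#' @export
embed_config <- function(method = "pca", min_dist = 1, n_neighbours = 1000,
                         seed = 1L) {
  structure(list(method = method, min_dist = min_dist,
                 n_neighbours = n_neighbours, seed = as.integer(seed)),
            class = "embed_config")
}

#' Stack aligned medoids and project residue points to 2D
#'
#' Restricts every protein's medoids to the residue positions commonly
#' mapped to the reference protein, superposes each medoid rigidly onto
#' the first reference medoid over those positions, stacks one row per
#' (medoid, residue) alpha-carbon and embeds the 3D points in 2D.
#'
#' @param medoid_sets named list; one entry per protein, each a list of
#'   per-residue coordinate matrices (row r = residue r's alpha carbon).
#'   The first entry is the reference protein.
#' @param mappings named list of [map_residues()] mappings from the
#'   reference to each non-reference protein (names must match
#'   `medoid_sets`).
#' @param config an [embed_config()].
#' @return data.frame with `protein`, `medoid`, `position` (reference
#'   numbering), `dim1`, `dim2`; the config is attached as attribute
#'   `embed_config`.
#' @export
stack_and_project <- function(medoid_sets, mappings,
                              config = embed_config()) {
  proteins <- names(medoid_sets)
  ref <- proteins[1]
  common_ref <- sort(Reduce(intersect,
                            lapply(mappings, function(m) m$pos_a)))
  if (length(common_ref) < 3) {
    stop("fewer than 3 commonly mapped residues", call. = FALSE)
  }
  pos_of <- function(protein) {
    if (protein == ref) return(common_ref)
    m <- mappings[[protein]]
    m$pos_b[match(common_ref, m$pos_a)]
  }
  ref_frame <- medoid_sets[[ref]][[1]][common_ref, , drop = FALSE]
  rows <- list()
  for (p in proteins) {
    pos <- pos_of(p)
    for (mi in seq_along(medoid_sets[[p]])) {
      sub <- medoid_sets[[p]][[mi]][pos, , drop = FALSE]
      sub <- superpose(sub, ref_frame)$coords
      rows[[length(rows) + 1]] <- data.frame(
        protein = p, medoid = mi, position = common_ref, sub
      )
    }
  }
  stacked <- do.call(rbind, rows)
  X <- as.matrix(stacked[, c("X1", "X2", "X3")])
  emb <- if (is.function(config$method)) {
    with_seed(config$seed, config$method(X, config))
  } else if (identical(config$method, "pca")) {
    stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  } else {
    stop("unknown embedding method", call. = FALSE)
  }
  out <- data.frame(protein = stacked$protein, medoid = stacked$medoid,
                    position = stacked$position,
                    dim1 = emb[, 1], dim2 = emb[, 2])
  attr(out, "embed_config") <- unclass(config)
  out
}
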