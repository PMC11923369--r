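#' Exponentially weighted moving average
#'
#' Recursive form `y[1] = x[1]`, `y[t] = alpha*x[t] + (1-alpha)*y[t-1]`
#' with `alpha = 2/(span+1)`. The working span for metric series is 10%
#' of the series length; interdomain-distance series use span = 1000 at
#' 100,000 points.
#'
#' @param x numeric series.
#' @param span window-equivalent span (>= 1); `span = 1` is the identity.
#' @return smoothed series, same length as `x`.
#' @export
ewma <- function(x, span) {
  span <- check_number(span, "span", min = 1)
  n <- length(x)
  if (n == 0) stop("empty series", call. = FALSE)
  a <- 2 / (span + 1)
  if (n == 1 || a == 1) return(as.numeric(x))
  y <- stats::filter(a * x[-1], 1 - a, method = "recursive", init = x[1])
  c(x[1], as.numeric(y))
}

#' Default EWMA span: 10% of the series length
#'
#' @param n series length.
#' @return integer span, at least 1.
#' @export
default_span <- function(n) max(1L, as.integer(round(0.1 * n)))

#' Signal-to-noise ratio of a series
#'
#' Mean over population standard deviation; the sign follows the mean.
#' Zero variance yields a signed infinite sentinel with a warning.
#'
#' @param x numeric series of length >= 2.
#' @return a single number (possibly `Inf`/`-Inf`).
#' @export
snr <- function(x) {
  if (length(x) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    warning("zero variance; SNR is infinite")
    return(sign(m) * Inf)
  }
  m / s
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper over the two-sample KS test returning the D statistic and
#' the asymptotic p-value. Optionally also reports a p-value recomputed
#' with autocorrelation-corrected effective sample sizes (off by default;
#' heavily smoothed series violate the test's independence assumption and
#' inflate nominal significance).
#'
#' @param a,b numeric samples (typically EWMA-smoothed metric series).
#' @param effective_p also compute the effective-sample-size corrected p.
#' @return list with `D`, `p` and (optionally) `p_eff`, `n_eff`.
#' @export
ks_compare <- function(a, b, effective_p = FALSE) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  out <- list(D = unname(kt$statistic), p = kt$p.value)
  if (effective_p) {
    ess <- function(x) {
      n <- length(x)
      if (n < 3 || stats::sd(x) == 0) return(n)
      r <- stats::cor(x[-1], x[-n])
      r <- min(max(r, 0), 0.999999)
      max(2, n * (1 - r) / (1 + r))
    }
    na <- ess(a); nb <- ess(b)
    n_eff <- na * nb / (na + nb)
    lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * out$D
    k <- 1:100
    out$p_eff <- min(1, max(0, 2 * sum((-1)^(k - 1) *
                                         exp(-2 * lambda^2 * k^2))))
    out$n_eff <- n_eff
  }
  out
}

#' Cross-replicate significance rule
#'
#' A comparison is significant only when every replicate clears the D
#' threshold with a small enough p; insignificant only when every
#' replicate falls below the insignificance threshold; anything else is
#' inconclusive.
#'
#' @param d_significant D above which a replicate supports significance.
#' @param d_insignificant D below which a replicate supports insignificance.
#' @param p_max maximum p-value for a significant replicate.
#' @return an object of class `verdict_rule`.
#' @export
verdict_rule <- function(d_significant = 0.55, d_insignificant = 0.45,
                         p_max = 0.001) {
  if (!(0 <= d_insignificant && d_insignificant < d_significant &&
          d_significant <= 1)) {
    stop_field("d_insignificant", "need 0 <= d_insig < d_sig <= 1")
  }
  structure(list(d_significant = d_significant,
                 d_insignificant = d_insignificant,
                 p_max = p_max, require_all_replicates = TRUE),
            class = "verdict_rule")
}

#' Aggregate per-replicate (D, p) pairs into a verdict
#'
#' @param pairs list of per-replicate records `list(D=, p=)` (or a
#'   2-column data.frame/matrix with columns D, p).
#' @param rule a [verdict_rule()].
#' @param comparison optional label stored in the verdict.
#' @return an object of class `verdict` with fields `outcome`
#'   (`"significant"`, `"insignificant"` or `"inconclusive"`),
#'   `replicates` and `rule`.
#' @export
replicate_verdict <- function(pairs, rule = verdict_rule(),
                              comparison = "") {
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(i) list(D = pairs[i, "D"], p = pairs[i, "p"]))
  }
  if (length(pairs) == 0) stop("no replicate records", call. = FALSE)
  D <- vapply(pairs, function(x) as.numeric(x$D), numeric(1))
  p <- vapply(pairs, function(x) as.numeric(x$p), numeric(1))
  outcome <- if (all(D > rule$d_significant & p < rule$p_max)) {
    "significant"
  } else if (all(D < rule$d_insignificant)) {
    "insignificant"
  } else {
    "inconclusive"
  }
  structure(list(comparison = comparison,
                 replicates = data.frame(D = D, p = p),
                 outcome = outcome, rule = unclass(rule)),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("verdict [%s]: %s (%d replicates)\n", x$comparison,
              x$outcome, nrow(x$replicates)))
  invisible(x)
}

#' Serialize / read a verdict as JSON
#'
#' @param v a `verdict`.
#' @param path file path.
#' @return the path (write) or the `verdict` (read).
#' @export
write_verdict_json <- function(v, path) {
  jsonlite::write_json(unclass(v), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_verdict_json
#' @export
read_verdict_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(comparison = x$comparison,
                 replicates = as.data.frame(x$replicates),
                 outcome = x$outcome, rule = x$rule),
            class = "verdict")
}

#' Paired Wilcoxon signed-rank comparison of two mapped curves
#'
#' Residue-level curves (typically RMSF) are compared on the positions
#' paired by `mapping`. All-zero differences are insignificant by
#' convention; otherwise the comparison is significant when the two-sided
#' p-value is below `p_max` with a nonzero statistic.
#'
#' @param curve_a,curve_b numeric vectors indexed by residue position.
#' @param mapping two-column matrix/data.frame of paired 1-based positions
#'   (a, b); `NULL` pairs positions 1:1 (requires equal lengths).
#' @param p_max significance threshold.
#' @return list with `W`, `p` and `verdict`.
#' @export
wilcoxon_compare <- function(curve_a, curve_b, mapping = NULL,
                             p_max = 0.001) {
  if (is.null(mapping)) {
    if (length(curve_a) != length(curve_b)) {
      stop("equal lengths required without a mapping", call. = FALSE)
    }
    mapping <- cbind(seq_along(curve_a), seq_along(curve_b))
  }
  mapping <- as.matrix(mapping)
  if (nrow(mapping) < 10) stop("mapping must pair >= 10 positions",
                               call. = FALSE)
  a <- curve_a[mapping[, 1]]
  b <- curve_b[mapping[, 2]]
  d <- a - b
  if (all(d == 0)) {
    return(list(W = 0, p = 1, verdict = "insignificant"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE))
  verdict <- if (wt$p.value < p_max && unname(wt$statistic) != 0) {
    "significant"
  } else {
    "insignificant"
  }
  list(W = unname(wt$statistic), p = wt$p.value, verdict = verdict)
}

#' Discrete Frechet distance between two sampled curves
#'
#' Dynamic-programming evaluation of the classic "dog-leash" distance:
#' the minimum over monotone couplings of the maximum pointwise distance.
#' Value-only inputs are treated as 1D curves (unit index spacing is
#' irrelevant in that mode: only value differences enter).
#'
#' @param a,b numeric vectors (value-only mode) or n x d coordinate
#'   matrices.
#' @return the discrete Frechet distance (same units as the values).
#' @export
frechet_distance <- function(a, b) {
  A <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  B <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty curve", call. = FALSE)
  n <- nrow(A); m <- nrow(B)
  # pairwise distance matrix
  d2 <- outer(rowSums(A^2), rep(1, m)) + outer(rep(1, n), rowSums(B^2)) -
    2 * A %*% t(B)
  cost <- sqrt(pmax(d2, 0))
  ca <- matrix(NA_real_, n, m)
  ca[1, 1] <- cost[1, 1]
  for (i in 2:max(n, 2)) if (n > 1) ca[i, 1] <- max(ca[i - 1, 1], cost[i, 1])
  for (j in 2:max(m, 2)) if (m > 1) ca[1, j] <- max(ca[1, j - 1], cost[1, j])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(min(ca[i - 1, j], ca[i, j - 1], ca[i - 1, j - 1]),
                        cost[i, j])
      }
    }
  }
  ca[n, m]
}

#' Suggest an equilibration cut from an RMSD series
#'
#' Smooths the series with an EWMA and returns the first frame at which
#' the least-squares slope of the smoothed curve over the trailing
#' `window` frames drops to `slope_tol` or below -- the point where the
#' initial drift gives way to bounded periodic motion. If no such frame
#' exists the series is flagged as not converged.
#'
#' @param series numeric RMSD series (Angstrom per frame).
#' @param span EWMA span (default 10% of length).
#' @param slope_tol slope tolerance in Angstrom/frame.
#' @param window trailing window length in frames (default 10% of length).
#' @return list with `cut` (0-based frame index or `NA`), `converged`.
#' @export
suggest_equilibration_cut <- function(series, span = default_span(length(series)),
                                      slope_tol = 1e-4,
                                      window = default_span(length(series))) {
  n <- length(series)
  window <- max(3L, as.integer(window))
  if (n <= window) stop("series shorter than window", call. = FALSE)
  y <- ewma(series, span)
  t_rel <- seq_len(window) - mean(seq_len(window))
  denom <- sum(t_rel^2)
  for (end in window:n) {
    w <- y[(end - window + 1):end]
    slope <- sum(t_rel * (w - mean(w))) / denom
    if (slope <= slope_tol) {
      return(list(cut = end - window, converged = TRUE))
    }
  }
  list(cut = NA_integer_, converged = FALSE)
}
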