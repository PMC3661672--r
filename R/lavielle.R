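#' Optimal K-segment partition of a series
#'
#' Exact minimization of the mean-shift Gaussian contrast (sum over segments
#' of squared deviations from the segment mean) by dynamic programming, under
#' a minimum segment length.  Deterministic; ties resolve to the earliest
#' breakpoints.
#'
#' @param series numeric vector (no `NA`).
#' @param K number of segments (>= 1).
#' @param Lmin minimum segment length in points.
#' @return Integer vector of breakpoints: 1-based indices of the last point
#'   of segments `1..K-1` (empty for `K = 1`), with the achieved contrast in
#'   attribute `"contrast"`.
#' @export
optimal_partition <- function(series, K, Lmin = 10) {
  stopifnot(is.numeric(series), !anyNA(series), K >= 1, Lmin >= 1)
  n <- length(series)
  if (n < K * Lmin)
    stop(sprintf("infeasible partition: n = %d < K*Lmin = %d", n, K * Lmin))
  dp <- .lavielle_dp_cpp(series, as.integer(K), as.integer(Lmin))
  structure(as.integer(dp$breaks[[K]]), contrast = dp$J[K])
}

#' Choose the number of segments by Lavielle's adaptive rule
#'
#' The contrast `J(K)` is rescaled to decrease from `Kmax - 1` to 0; the
#' chosen `K` is the largest one whose second difference
#' `D(K) = Jt(K-1) - 2 Jt(K) + Jt(K+1)` exceeds `threshold`, i.e. the last
#' K at which adding a segment still buys a marked drop in contrast.  Falls
#' back to 1 (no change-points) for short or structureless series.
#'
#' @param series numeric vector (no `NA`).
#' @param Kmax largest candidate segment count.
#' @param Lmin minimum segment length in points.
#' @param threshold second-difference threshold (default 0.75).
#' @param min_drop minimum relative contrast drop `1 - J(Kfeas)/J(1)` that
#'   the best segmentation must achieve before any `K > 1` is considered
#'   (default 0.5).  Optimal segmentation of pure noise removes only a small
#'   share of the contrast (a selection effect of order `ln(n)` variance
#'   units per breakpoint), whereas genuine level shifts remove most of it,
#'   so requiring half the contrast keeps structureless series at `K = 1`.
#' @return Integer `K >= 1`.
#' @export
choose_k <- function(series, Kmax = 20, Lmin = 10, threshold = 0.75,
                     min_drop = 0.5) {
  n <- length(series)
  if (n < 2 * Lmin) return(1L)
  # candidate K are capped at n/(2 Lmin): nearer n/Lmin the minimum-length
  # constraint binds, J(K) can rise again and the rescaling degenerates
  Kfeas <- min(Kmax, n %/% (2L * Lmin))
  if (Kfeas < 3L) return(1L)
  dp <- .lavielle_dp_cpp(series, as.integer(Kfeas), as.integer(Lmin))
  choose_k_from_contrast(dp$J, threshold, min_drop)
}

# Adaptive rule applied to a precomputed contrast curve J(1..Kfeas).
choose_k_from_contrast <- function(J, threshold = 0.75, min_drop = 0.5) {
  Kfeas <- length(J)
  if (Kfeas < 3L) return(1L)
  if (!is.finite(J[1]) || J[1] - J[Kfeas] <= 0) return(1L)  # constant series
  if (J[Kfeas] > (1 - min_drop) * J[1]) return(1L)          # no real structure
  Jt <- (J - J[Kfeas]) / (J[1] - J[Kfeas]) * (Kfeas - 1)
  Ks <- 2:(Kfeas - 1)
  D <- Jt[Ks - 1] - 2 * Jt[Ks] + Jt[Ks + 1]
  hit <- Ks[D > threshold]
  if (length(hit) == 0) 1L else max(hit)
}

#' Label segments as ARS or movement
#'
#' Segments of higher mean belong to area-restricted search, segments of
#' lower mean to movement.  With more than two mean levels the dichotomy is
#' made by one-dimensional 2-means on the segment means (deterministic
#' initialization at the extreme means); a single segment, or a spread of
#' segment means below `min_sep`, yields all-movement — no ARS detected.
#'
#' @param series numeric vector the partition refers to (typically `ln(FPT)`
#'   at the ARS scale).
#' @param breakpoints integer breakpoints as returned by
#'   [optimal_partition()].
#' @param min_sep minimum spread of segment means (in `series` units) below
#'   which no segment is labelled ARS.
#' @return Character vector of per-segment labels, `"ARS"` or `"movement"`.
#' @export
label_segments <- function(series, breakpoints, min_sep = 0.1) {
  K <- length(breakpoints) + 1L
  ends <- c(breakpoints, length(series))
  starts <- c(1L, breakpoints + 1L)
  means <- vapply(seq_len(K), function(k) mean(series[starts[k]:ends[k]]),
                  numeric(1))
  if (K == 1L || diff(range(means)) < min_sep)
    return(rep("movement", K))
  ifelse(two_means_high(means), "ARS", "movement")
}

# 1-D 2-means (Lloyd) with deterministic init at the min and max value.
# Returns a logical vector: TRUE for membership in the high cluster.
two_means_high <- function(v) {
  lo <- min(v); hi <- max(v)
  for (it in 1:100) {
    high <- abs(v - hi) < abs(v - lo)   # ties join the low cluster
    nlo <- mean(v[!high]); nhi <- mean(v[high])
    if (nlo == lo && nhi == hi) break
    lo <- nlo; hi <- nhi
  }
  high
}

#' Segment a first-passage time series into ARS and movement bouts
#'
#' Runs the penalized-contrast segmentation on `ln(FPT)` at the trip's ARS
#' scale: leading and trailing undefined values (path edges, where the circle
#' is never crossed) are trimmed, interior gaps are bridged linearly, the
#' segment count is chosen by [choose_k()], the optimal partition computed,
#' and segments labelled by [label_segments()].
#'
#' @param lnfpt numeric series of `ln(FPT)` values along the interpolated
#'   path (may contain `NA`).
#' @param Lmin,Kmax,threshold,min_drop,min_sep see [choose_k()] and
#'   [label_segments()].
#' @return An `ars_segmentation`: list with the trimmed `series`, `offset`
#'   (index of its first point in the original series), `breakpoints`, `K`,
#'   per-segment `labels` and the contrast curve `contrast_by_K`.
#' @export
segment_fpt <- function(lnfpt, Lmin = 10, Kmax = 20, threshold = 0.75,
                        min_drop = 0.5, min_sep = 0.1) {
  ok <- !is.na(lnfpt)
  if (!any(ok)) stop("all FPT values undefined; nothing to segment")
  first <- which(ok)[1]; last <- tail(which(ok), 1)
  z <- lnfpt[first:last]
  if (anyNA(z)) {  # bridge interior gaps
    idx <- seq_along(z)
    z[is.na(z)] <- stats::approx(idx[!is.na(z)], z[!is.na(z)],
                                 xout = idx[is.na(z)])$y
  }
  n <- length(z)
  Kfeas <- min(Kmax, max(1L, n %/% (2L * Lmin)))
  if (n < 2 * Lmin || Kfeas < 3L) {
    K <- 1L; J <- NA_real_; bp <- integer(0)
  } else {
    dp <- .lavielle_dp_cpp(z, as.integer(Kfeas), as.integer(Lmin))
    J <- dp$J
    K <- choose_k_from_contrast(J, threshold, min_drop)
    bp <- as.integer(dp$breaks[[K]])
  }
  labels <- label_segments(z, bp, min_sep)
  structure(list(series = z, offset = first, breakpoints = bp, K = K,
                 labels = labels, contrast_by_K = J,
                 Lmin = Lmin, Kmax = Kmax, threshold = threshold),
            class = "ars_segmentation")
}

#' @export
print.ars_segmentation <- function(x, ...) {
  cat(sprintf("<ars_segmentation: %d points, K = %d (%d ARS, %d movement)>\n",
              length(x$series), x$K, sum(x$labels == "ARS"),
              sum(x$labels == "movement")))
  invisible(x)
}

#' Export a segmentation as CSV
#'
#' One row per segment: `segment_id,start_index,end_index,start_t,end_t,`
#' `mean_lnfpt,label`, with indices referring to the interpolated path.
#'
#' @param segmentation an `ars_segmentation`.
#' @param path the interpolated `planar_path` it was computed on.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
export_segmentation_csv <- function(segmentation, path, file) {
  s <- segmentation
  ends <- c(s$breakpoints, length(s$series))
  starts <- c(1L, s$breakpoints + 1L)
  pi0 <- s$offset - 1L
  d <- data.frame(segment_id = seq_len(s$K),
                  start_index = starts + pi0, end_index = ends + pi0,
                  start_t = path$points$t[starts + pi0],
                  end_t = path$points$t[ends + pi0],
                  mean_lnfpt = vapply(seq_len(s$K), function(k)
                    mean(s$series[starts[k]:ends[k]]), numeric(1)),
                  label = s$labels)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
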