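#' Marker-free breathing trace from a projection stack (Amsterdam shroud)
#'
#' Each projection is derivative-filtered along the detector SI axis,
#' clipped at robust percentiles to suppress edge artifacts, and summed over
#' the lateral axis, producing one column per frame (the "shroud"). The
#' breathing trace is the per-frame SI shift that maximises the normalised
#' cross-correlation between consecutive shroud columns (with parabolic
#' sub-sample refinement), cumulatively summed and linearly detrended.
#' The sign is aligned so that inhale excursions are positive, using the
#' skewness of the trace (free breathing dwells near exhale, so inhale forms
#' the short positive excursions); for a near-symmetric trace the sign is
#' left as computed.
#'
#' @param stack a [projection_stack()] with at least 2 frames.
#' @param clip quantile pair for derivative clipping.
#' @param max_shift_px largest SI shift searched between consecutive frames
#'   (detector pixels); default is a quarter of the detector height.
#' @return a [respiratory_signal()] whose values are SI shroud shifts in
#'   detector pixels (arbitrary sign-aligned units).
#' @export
amsterdam_shroud <- function(stack, clip = c(0.01, 0.99),
                             max_shift_px = NULL) {
  nf <- n_frames(stack)
  if (nf < 2) stop("need at least 2 frames to extract a breathing trace")
  nr <- dim(stack$pixels)[1]
  if (is.null(max_shift_px)) max_shift_px <- max(2L, nr %/% 4L)
  # shroud: one SI profile of summed clipped SI derivatives per frame
  shroud <- matrix(0, nr - 1, nf)
  for (i in seq_len(nf)) {
    d <- diff(stack$pixels[, , i])       # derivative along SI (rows)
    q <- stats::quantile(d, clip, names = FALSE)
    shroud[, i] <- rowSums(pmin(pmax(d, q[1]), q[2]))
  }
  if (max(apply(shroud, 2, stats::sd)) < 1e-12)
    stop("no respiration detected: projections carry no SI structure")
  shifts <- numeric(nf - 1)
  for (i in seq_len(nf - 1))
    shifts[i] <- ncc_shift(shroud[, i], shroud[, i + 1], max_shift_px)
  trace <- c(0, cumsum(shifts))
  if (stats::sd(trace) < 1e-9)
    stop("no respiration detected: breathing trace is static")
  # remove gantry-induced linear trend
  t <- stack$times_s
  fit <- stats::lm.fit(cbind(1, t), trace)
  trace <- fit$residuals
  sk <- skewness(trace)
  if (is.finite(sk) && abs(sk) > 0.1 && sk < 0) trace <- -trace
  respiratory_signal(trace, t, params = list(source = "amsterdam_shroud",
                                             units = "detector px"))
}

# integer-shift NCC maximisation with parabolic refinement; positive shift
# means b is displaced toward larger row index (superior) relative to a
ncc_shift <- function(a, b, kmax) {
  n <- length(a)
  kmax <- min(kmax, n - 3)
  sc <- vapply(-kmax:kmax, function(k) {
    if (k >= 0) { x <- a[1:(n - k)]; y <- b[(1 + k):n] }
    else { x <- a[(1 - k):n]; y <- b[1:(n + k)] }
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(-Inf)
    stats::cor(x, y)
  }, numeric(1))
  i <- which.max(sc)
  k <- (-kmax:kmax)[i]
  # parabolic sub-pixel refinement on the correlation peak
  if (i > 1 && i < length(sc) && all(is.finite(sc[(i - 1):(i + 1)]))) {
    denom <- sc[i - 1] - 2 * sc[i] + sc[i + 1]
    if (abs(denom) > 1e-12) {
      dk <- 0.5 * (sc[i - 1] - sc[i + 1]) / denom
      k <- k + max(-0.5, min(0.5, dk))
    }
  }
  -k  # anatomy moving superior shifts the shroud pattern up; report anatomy sign
}

skewness <- function(x) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < 1e-12) return(0)
  mean(x^3) / s^3
}

#' Respiratory phase from a breathing trace
#'
#' Detects end-inhale peaks (local maxima separated by at least 0.6 times
#' the median breathing period, the period being first estimated from the
#' trace autocorrelation) and assigns each frame a continuous phase in
#' `[0, 1)` that is linear in time between consecutive peaks (phase 0 at
#' each peak). Frames before the first and after the last peak are
#' extrapolated with the adjacent cycle length.
#'
#' @param trace a [respiratory_signal()].
#' @param n_bins number of phase bins (default 6).
#' @return object of class `phase_assignment`: data.frame `frames` with
#'   columns frame, phase, bin (0-based bin index), plus `peaks`,
#'   `period_frames` and `n_bins`.
#' @export
extract_phase <- function(trace, n_bins = 6) {
  v <- trace$values
  n <- length(v)
  period <- estimate_period(v)
  peaks <- find_peaks(v, min_sep = max(2, floor(0.6 * period)))
  if (length(peaks) < 2)
    stop("insufficient cycles: fewer than 2 breathing peaks detected")
  phase <- numeric(n)
  for (j in seq_len(length(peaks) - 1)) {
    a <- peaks[j]; b <- peaks[j + 1]
    idx <- a:(b - 1)
    phase[idx] <- (idx - a) / (b - a)
  }
  T1 <- peaks[2] - peaks[1]
  Tl <- peaks[length(peaks)] - peaks[length(peaks) - 1]
  pre <- seq_len(n) < peaks[1]
  phase[pre] <- (((seq_len(n)[pre] - peaks[1]) / T1) %% 1)
  post <- seq_len(n) >= peaks[length(peaks)]
  phase[post] <- (((seq_len(n)[post] - peaks[length(peaks)]) / Tl) %% 1)
  bin <- pmin(floor(phase * n_bins), n_bins - 1)
  structure(list(frames = data.frame(frame = seq_len(n), phase = phase,
                                     bin = as.integer(bin)),
                 peaks = peaks,
                 period_frames = stats::median(diff(peaks)),
                 n_bins = as.integer(n_bins)),
            class = "phase_assignment")
}

# breathing period (in frames) from the autocorrelation of the trace
estimate_period <- function(v) {
  n <- length(v)
  ac <- stats::acf(v, lag.max = min(n - 2, max(10, n %/% 2)),
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # first local max beyond the central lobe
  lag <- seq_along(ac) - 1
  neg <- which(ac < 0)
  from <- if (length(neg)) neg[1] else 2L
  if (from >= length(ac)) return(max(4, n %/% 4))
  cand <- from:(length(ac) - 1)
  peak <- cand[which.max(ac[cand + 1])]
  max(4, peak)
}

find_peaks <- function(v, min_sep) {
  n <- length(v)
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  cand <- cand[v[cand] > mean(v)]         # peaks must rise above the mean
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (i in cand[order(v[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Sort projections into respiratory phase bins
#'
#' Partitions the frames of a stack by the bin index of a
#' [extract_phase()] assignment. Every frame lands in exactly one bin.
#'
#' @param stack a [projection_stack()].
#' @param assignment a `phase_assignment` covering all frames.
#' @param n_bins number of bins; defaults to the assignment's.
#' @return list of length `n_bins`; element `b + 1` is the sub-stack of bin
#'   `b` (a [projection_stack()]), or `NULL` with a warning for an empty
#'   bin. Attribute `frames` on each element gives the original frame ids.
#' @export
bin_projections <- function(stack, assignment, n_bins = assignment$n_bins) {
  af <- assignment$frames
  if (nrow(af) != n_frames(stack))
    stop("assignment does not cover all frames")
  out <- vector("list", n_bins)
  for (b in 0:(n_bins - 1)) {
    idx <- af$frame[af$bin == b]
    if (!length(idx)) {
      warning(sprintf("phase bin %d is empty", b))
      out[b + 1] <- list(NULL)
      next
    }
    sub <- projection_stack(stack$pixels[, , idx, drop = FALSE],
                            stack$geometry, stack$angles_deg[idx],
                            stack$times_s[idx])
    attr(sub, "frames") <- idx
    attr(sub, "bin") <- b
    out[[b + 1]] <- sub
  }
  out
}
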