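#' FDK reconstruction parameters
#'
#' @param grid_dim,grid_spacing_mm,grid_origin_mm output grid; origin `NULL`
#'   centres the grid on the isocenter.
#' @param apodization `"ramlak"` for the plain ramp filter or `"hann"` to
#'   apodise it (trades resolution for noise).
#' @param short_scan `TRUE` applies Parker weighting, required for arcs
#'   shorter than 360 degrees (a 200 degree sweep double-counts rays
#'   without it).
#' @return an object of class `fdk_params`.
#' @export
fdk_params <- function(grid_dim = c(64, 64, 64), grid_spacing_mm = 4,
                       grid_origin_mm = NULL,
                       apodization = c("ramlak", "hann"),
                       short_scan = TRUE) {
  grid_spacing_mm <- rep_len(as.numeric(grid_spacing_mm), 3)
  if (any(grid_spacing_mm <= 0)) stop("output spacing must be > 0")
  grid_dim <- as.integer(rep_len(grid_dim, 3))
  if (is.null(grid_origin_mm))
    grid_origin_mm <- -(grid_dim - 1) / 2 * grid_spacing_mm
  structure(list(grid_dim = grid_dim, grid_spacing = grid_spacing_mm,
                 grid_origin = rep_len(as.numeric(grid_origin_mm), 3),
                 apodization = match.arg(apodization),
                 short_scan = isTRUE(short_scan)),
            class = "fdk_params")
}

# Parker short-scan weights for scan angles beta in [0, pi + 2*delta]
# (radians) and per-column fan angles gamma; returns a weight per column.
parker_weights <- function(beta, gamma, delta) {
  g <- pmin(pmax(gamma, -delta + 1e-6), delta - 1e-6)
  w <- rep(1, length(g))
  early <- beta < 2 * delta + 2 * g
  w[early] <- sin(pi / 4 * pmax(beta, 0) / (delta + g[early]))^2
  late <- beta > pi + 2 * g
  w[late] <- sin(pi / 4 * pmax(pi + 2 * delta - beta, 0) /
                   (delta - g[late]))^2
  w
}

# band-limited ramp filter kernel (spatial samples), classic sampled form
ramp_kernel <- function(n, du) {
  h <- numeric(2 * n)
  idx <- c(0:(n - 1), -n, -(n - 1):-1)   # wrap-around ordering
  h[idx == 0] <- 1 / (4 * du^2)
  odd <- idx %% 2 != 0
  h[odd] <- -1 / (pi^2 * idx[odd]^2 * du^2)
  h
}

#' Short-scan FDK reconstruction
#'
#' Feldkamp-Davis-Kress filtered backprojection for a circular (partial)
#' cone-beam arc: cosine pre-weighting, Parker short-scan weighting, ramp
#' filtering of each detector row along the lateral axis (zero-padded FFT
#' convolution with the sampled ramp kernel, optional Hann apodization) and
#' voxel-driven backprojection with the 1/U^2 distance weight. Linear in
#' the projection data. Non-uniform angular subsets (phase bins) are
#' handled by per-view angular weights equal to each view's share of the
#' arc.
#'
#' @param stack a [projection_stack()] (>= 1 projection with known angles).
#' @param params an [fdk_params()].
#' @return reconstructed [volume3d()] (relative attenuation, mm^-1).
#' @export
fdk_reconstruct <- function(stack, params = fdk_params()) {
  if (is.null(stack) || n_frames(stack) < 1)
    stop("empty bin: no projections to reconstruct")
  geom <- stack$geometry
  np <- n_frames(stack)
  nr <- geom$detector_rows; nc <- geom$detector_cols
  mag <- geom$sdd_mm / geom$sad_mm
  # detector coordinates rescaled to the isocenter plane
  du <- geom$pixel_mm / mag
  u_iso <- ((seq_len(nc) - 1) - (nc - 1) / 2) * du
  v_iso <- ((seq_len(nr) - 1) - (nr - 1) / 2) * du
  cosw <- outer(v_iso, u_iso,
                function(v, u) geom$sad_mm / sqrt(geom$sad_mm^2 + u^2 + v^2))
  span <- geom$arc_span_deg * pi / 180
  delta <- (span - pi) / 2
  gamma <- atan(u_iso / geom$sad_mm)

  # frequency response of the ramp (+ optional Hann apodization)
  npad <- 2^ceiling(log2(2 * nc))
  hk <- ramp_kernel(nc, du)
  H <- Re(stats::fft(c(hk[1:nc], rep(0, npad - 2 * nc), hk[(nc + 1):(2 * nc)])))
  if (params$apodization == "hann") {
    f <- seq(0, npad - 1) / npad
    f <- pmin(f, 1 - f) * 2              # 0..1..0 across the band
    H <- H * (0.5 + 0.5 * cos(pi * f))
  }

  ord <- order(stack$angles_deg)
  angles <- stack$angles_deg[ord]
  beta <- (angles - geom$arc_start_deg) * pi / 180
  filtered <- array(0, c(nr, nc, np))
  for (i in seq_len(np)) {
    p <- stack$pixels[, , ord[i]] * cosw
    if (params$short_scan && span > pi && span < 2 * pi)
      p <- sweep(p, 2, parker_weights(beta[i], gamma, delta), `*`)
    # ramp filter along the lateral (fan) axis for each detector row
    pu <- rbind(t(p), matrix(0, npad - nc, nr))
    q <- Re(stats::mvfft(stats::mvfft(pu) * H, inverse = TRUE)) / npad
    filtered[, , i] <- t(q[1:nc, , drop = FALSE]) * du
  }
  dbeta <- view_weights(beta, span)
  vox <- fdk_backproject_cpp(filtered, c(nr, nc, np), angles, dbeta,
                             geom$sad_mm, geom$sdd_mm, geom$pixel_mm,
                             params$grid_dim, params$grid_spacing,
                             params$grid_origin)
  volume3d(vox, params$grid_spacing, params$grid_origin)
}

# per-view angular weight (radians): half-gap to each neighbour, so sparse
# phase-binned subsets integrate over their local share of the arc
view_weights <- function(beta, span) {
  np <- length(beta)
  if (np == 1) return(span)
  mid <- diff(beta) / 2
  lo <- c(mid[1], mid)
  hi <- c(mid, mid[np - 1])
  lo + hi
}

#' Reconstruct a 4D-CBCT set from phase-binned projections
#'
#' Runs [fdk_reconstruct()] on every phase bin, yielding one volume per
#' respiratory phase. Streak artifacts from angular under-sampling within
#' each bin are expected and tolerated.
#'
#' @param stack a [projection_stack()].
#' @param assignment a `phase_assignment` from [extract_phase()].
#' @param params an [fdk_params()].
#' @return list of `n_bins` [volume3d()] objects; each carries attributes
#'   `bin` and `n_projections`.
#' @export
reconstruct_4dcbct <- function(stack, assignment, params = fdk_params()) {
  bins <- bin_projections(stack, assignment)
  lapply(seq_along(bins), function(i) {
    v <- fdk_reconstruct(bins[[i]], params)
    attr(v, "bin") <- i - 1L
    attr(v, "n_projections") <- if (is.null(bins[[i]])) 0L else
      n_frames(bins[[i]])
    v
  })
}
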