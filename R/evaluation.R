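#' Tumor centroid position implied by a displacement field
#'
#' Maps the reference tumor centroid through a displacement field given
#' either directly or via motion-model coefficients. Fields are stored in
#' the pull-back convention of [warp_volume()] (`out(p) = vol(p + D(p))`),
#' so the anatomy that sits at the reference centroid `c` appears in the
#' deformed image at the point `p` solving `p + D(p) = c`; that fixed point
#' is found by iterating `p <- c - D(p)` (first iterate `c - D(c)`). For a
#' uniform field the result is exactly `c - D`.
#'
#' @param model,u a `pca_motion_model` and coefficient vector (used when
#'   `dvf` is `NULL`).
#' @param dvf a [dvf()] (alternative to `model`/`u`).
#' @param ref_centroid_mm reference tumor centroid (world mm); must lie
#'   inside the field's grid.
#' @return 3-vector, tumor centroid in the deformed image (mm).
#' @export
tumor_position <- function(model = NULL, u = NULL, dvf = NULL,
                           ref_centroid_mm) {
  if (is.null(dvf)) {
    if (is.null(model) || is.null(u))
      stop("give either a dvf or a model plus coefficients")
    dvf <- reconstruct_dvf(model, u)
  }
  cen <- as.numeric(ref_centroid_mm)
  d <- dim(dvf$field)[1:3]
  hull_lo <- dvf$origin
  hull_hi <- dvf$origin + (d - 1) * dvf$spacing
  if (any(cen < hull_lo) || any(cen > hull_hi))
    stop("reference centroid lies outside the field grid")
  p <- cen
  for (it in 1:25) {
    disp <- sample_dvf(dvf, p)[1, ]
    p_new <- cen - disp
    if (max(abs(p_new - p)) < 1e-9) { p <- p_new; break }
    p <- p_new
  }
  p
}

#' SI localisation error at isocenter scale
#'
#' Projects an estimated 3D tumor position onto the detector and compares
#' its SI (v) coordinate with a ground-truth detector coordinate; the
#' difference is scaled down by SAD/SDD to an approximate error inside the
#' patient (at isocenter). The lateral component is ignored: the error is
#' measured along the superior-inferior direction only.
#'
#' @param p_est_3d_mm estimated tumor position (world mm).
#' @param p_truth_2d_mm ground-truth detector coordinates `c(u, v)` in mm.
#' @param geom a [cone_beam_geometry()].
#' @return signed SI error in mm at isocenter.
#' @export
detector_error_at_isocenter <- function(p_est_3d_mm, p_truth_2d_mm, geom) {
  uv <- project_point(p_est_3d_mm, geom)
  unname(uv[2] - as.numeric(p_truth_2d_mm)[2]) * geom$sad_mm / geom$sdd_mm
}

#' MAE and 95th percentile of per-frame errors
#'
#' `MAE = mean(|errors|)`; the 95th percentile is computed on `|errors|`
#' with linear interpolation between order statistics (the inclusive
#' definition of `stats::quantile(type = 7)`).
#'
#' @param errors_mm per-frame errors (mm); signs are discarded.
#' @return object of class `error_report`: list with `mae`, `p95`,
#'   `errors` and `n`.
#' @export
mae_and_p95 <- function(errors_mm) {
  if (!length(errors_mm)) stop("no errors supplied")
  a <- abs(as.numeric(errors_mm))
  structure(list(mae = mean(a),
                 p95 = unname(stats::quantile(a, 0.95, type = 7)),
                 errors = as.numeric(errors_mm), n = length(a)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("tumor SI error over %d frames: MAE %.2f mm, 95th percentile %.2f mm\n",
              x$n, x$mae, x$p95))
  invisible(x)
}

#' Diaphragm-to-tumor linear regression (ground-truth builder)
#'
#' Ordinary least squares mapping diaphragm apex detector coordinates to
#' tumor detector coordinates, fitted per output coordinate on training
#' frames; used to construct ground-truth tumor positions on data where
#' only the diaphragm is reliably visible in every projection. By default
#' the SI coordinate is the sole predictor.
#'
#' @param diaphragm_2d numeric vector (SI only) or n x 2 matrix of detector
#'   coordinates per training frame.
#' @param tumor_2d numeric vector or n x k matrix of tumor detector
#'   coordinates on the same frames.
#' @return object of class `diaphragm_regression` (a list of `lm` fits).
#' @export
fit_diaphragm_regression <- function(diaphragm_2d, tumor_2d) {
  Xm <- as.matrix(diaphragm_2d)
  Ym <- as.matrix(tumor_2d)
  if (nrow(Xm) != nrow(Ym)) stop("predictor/response frame counts differ")
  if (nrow(Xm) < 2) stop("need at least 2 training frames")
  if (any(apply(Xm, 2, stats::sd) < 1e-12))
    stop("degenerate fit: diaphragm coordinate has zero variance")
  fits <- lapply(seq_len(ncol(Ym)), function(j) {
    stats::lm.fit(cbind(1, Xm), Ym[, j])
  })
  structure(list(fits = fits, p = ncol(Xm)), class = "diaphragm_regression")
}

#' @rdname fit_diaphragm_regression
#' @param model a `diaphragm_regression`.
#' @param diaphragm_2d coordinates to predict from.
#' @return predicted tumor coordinates (n x k matrix).
#' @export
apply_regression <- function(model, diaphragm_2d) {
  Xm <- as.matrix(diaphragm_2d)
  if (ncol(Xm) != model$p) stop("predictor dimension mismatch")
  sapply(model$fits, function(f) cbind(1, Xm) %*% f$coefficients)
}

#' Automatic diaphragm apex detection in a projection
#'
#' Finds, within a lateral detector band, the superior-most strong
#' tissue-to-lung edge: for each column the row minimising the smoothed SI
#' derivative (attenuation drops when rays leave the diaphragm dome and
#' enter lung), keeping columns whose edge strength reaches a fraction of
#' the strongest edge; the apex is the detected edge with the largest SI
#' coordinate. Deterministic; intended as the phantom-data surrogate for
#' manual annotation.
#'
#' @param proj a [projection2d()].
#' @param band fraction pair of the detector width searched (default the
#'   central half).
#' @param row_band fraction pair of the detector height searched; the
#'   default trims the outer 12 % of rows, where the edges of the imaged
#'   volume produce artificial intensity drops.
#' @param strength_frac minimum edge strength relative to the strongest
#'   edge in the band.
#' @return 2-vector `c(u, v)` detector mm of the apex.
#' @export
detect_diaphragm_apex <- function(proj, band = c(0.25, 0.75),
                                  row_band = c(0.12, 0.88),
                                  strength_frac = 0.5) {
  px <- proj$pixels
  geom <- proj$geometry
  nr <- nrow(px); nc <- ncol(px)
  cols <- max(1, floor(band[1] * nc)):min(nc, ceiling(band[2] * nc))
  rows <- max(1, floor(row_band[1] * nr)):min(nr, ceiling(row_band[2] * nr))
  px <- px[rows, , drop = FALSE]
  d <- diff(px[, cols, drop = FALSE])           # SI derivative per column
  # light SI smoothing to stabilise the edge row
  if (nr > 8) d <- (d + rbind(d[-1, , drop = FALSE], d[nrow(d), ]) +
                      rbind(d[1, ], d[-nrow(d), , drop = FALSE])) / 3
  strength <- -apply(d, 2, min)                 # drop magnitude per column
  if (max(strength) < 1e-8 * max(abs(px), 1e-300))
    stop("no diaphragm edge found in the search band")
  edge_row <- apply(d, 2, which.min) + 0.5      # between the two rows
  ok <- strength >= strength_frac * max(strength)
  # the dome boundary is shallow and contiguous: discard strong columns
  # whose edge row strays far from the consensus (spurious edges at
  # oblique angles), then take the superior-most point of what remains
  med <- stats::median(edge_row[ok])
  ok <- ok & abs(edge_row - med) <= 3
  j <- which(ok)[which.max(edge_row[ok])]
  r <- edge_row[j] + rows[1] - 1; cc <- cols[j]
  c(u = ((cc - 1) - (nc - 1) / 2) * geom$pixel_mm,
    v = ((r - 1) - (nr - 1) / 2) * geom$pixel_mm)
}

# intensity-weighted centroid of a (possibly warped) scalar mask volume
mask_centroid <- function(vol) {
  w <- vol$voxels
  tot <- sum(w)
  if (tot <= 0) stop("empty mask")
  d <- dim(w)
  g <- list(vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
            vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
            vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
  c(sum(apply(w, 1, sum) * g[[1]]), sum(apply(w, 2, sum) * g[[2]]),
    sum(apply(w, 3, sum) * g[[3]])) / tot
}
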