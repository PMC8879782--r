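#' Detector region of interest around moving landmarks
#'
#' Builds a rectangular detector-pixel mask covering the perspective
#' projections of a set of 3D landmarks (typically the reference tumor
#' centroid and the diaphragm apex) with a margin given at isocenter scale,
#' recomputed for the geometry's gantry angle. Restricting the data term to
#' this region suppresses the influence of reconstruction streaks and other
#' non-anatomical differences elsewhere in the projection.
#'
#' @param geom a [cone_beam_geometry()] (its `angle_deg` is used).
#' @param landmarks_mm k x 3 matrix of world points.
#' @param margin_mm margin around the projected landmarks, in mm at
#'   isocenter (scaled by the magnification on the detector).
#' @return logical detector matrix of class `roi_mask`.
#' @export
make_roi <- function(geom, landmarks_mm, margin_mm = 30) {
  landmarks_mm <- matrix(as.numeric(landmarks_mm), ncol = 3)
  uv <- t(apply(landmarks_mm, 1, project_point, geom = geom))
  mag <- geom$sdd_mm / geom$sad_mm
  m <- margin_mm * mag
  u_rng <- range(uv[, 1]) + c(-m, m)
  v_rng <- range(uv[, 2]) + c(-m, m)
  u <- ((seq_len(geom$detector_cols) - 1) - (geom$detector_cols - 1) / 2) *
    geom$pixel_mm
  v <- ((seq_len(geom$detector_rows) - 1) - (geom$detector_rows - 1) / 2) *
    geom$pixel_mm
  mask <- outer(v >= v_rng[1] & v <= v_rng[2], u >= u_rng[1] & u <= u_rng[2],
                `&`)
  if (!any(mask))
    stop("ROI is empty on the detector; landmarks project outside the panel")
  structure(mask, class = c("roi_mask", class(mask)))
}

full_roi <- function(geom) {
  structure(matrix(TRUE, geom$detector_rows, geom$detector_cols),
            class = c("roi_mask", "matrix", "array"))
}

#' Render the model-predicted projection for coefficients u
#'
#' The composition `P(warp(f0, D(u)))`: the motion model's displacement
#' field at `u` deforms the reference volume, which is then forward
#' projected at the given geometry.
#'
#' @param u coefficient vector (length `model$n_modes`).
#' @param f0 reference-phase [volume3d()] on the model grid.
#' @param model a `pca_motion_model`.
#' @param geom a [cone_beam_geometry()].
#' @param step_mm projector ray step.
#' @return a [projection2d()].
#' @export
render_projection <- function(u, f0, model, geom, step_mm = NULL) {
  check_model_grid(model, f0)
  forward_project(warp_volume(f0, reconstruct_dvf(model, u)), geom,
                  step_mm = step_mm)
}

check_model_grid <- function(model, f0) {
  if (!identical(model$dim, dim(f0$voxels)) ||
      max(abs(model$spacing - f0$spacing)) > 1e-9 ||
      max(abs(model$origin - f0$origin)) > 1e-6)
    stop("motion model grid does not match the reference volume")
  invisible(TRUE)
}

#' Closed-form intensity scale between rendered and measured projections
#'
#' The relative pixel intensity lambda minimising
#' `||rendered - lambda * x||^2` over the ROI:
#' `lambda = <rendered, x>_ROI / <x, x>_ROI`.
#'
#' @param rendered,x [projection2d()] objects on the same detector.
#' @param roi a logical detector mask ([make_roi()]); `NULL` uses all
#'   pixels.
#' @return scalar lambda.
#' @export
estimate_lambda <- function(rendered, x, roi = NULL) {
  r <- rendered$pixels; m <- x$pixels
  if (!all(dim(r) == dim(m))) stop("projection dimensions differ")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(m), ncol(m))
  xx <- sum(m[roi]^2)
  if (xx <= 0) stop("degenerate ROI: measured projection is zero inside it")
  sum(r[roi] * m[roi]) / xx
}

#' Cost and analytic gradient of the projection-matching objective
#'
#' Evaluates `J(u) = || M * (P f(D(u), f0) - lambda x) ||^2` with `M` the
#' ROI mask, re-estimating lambda in closed form at every evaluation
#' (block-coordinate treatment of the joint problem in `(u, lambda)`; with
#' lambda at its optimum, the envelope theorem makes the total derivative
#' in `u` equal the partial one). The gradient follows the chain rule: the
#' masked residual is back-projected with the exact adjoint of the
#' projector, multiplied voxel-wise by the exact derivative of the warped
#' reference with respect to displacement, and contracted against each
#' eigenvector field.
#'
#' @inheritParams render_projection
#' @param x measured [projection2d()].
#' @param roi logical detector mask; `NULL` for all pixels.
#' @return list with `cost`, `gradient`, `lambda` and `rendered` (the
#'   model projection, computed on ROI pixels only; pixels outside the ROI
#'   are zero).
#' @export
cost_and_gradient <- function(u, f0, model, geom, x, roi = NULL,
                              step_mm = NULL) {
  check_model_grid(model, f0)
  if (is.null(step_mm)) step_mm <- min(f0$spacing) / 2
  if (is.null(roi)) roi <- full_roi(geom)
  wv <- warp_model_cpp(as.vector(f0$voxels), dim(f0$voxels), f0$spacing,
                       f0$origin, model$mean, model$modes, as.numeric(u))
  rp <- forward_project_roi_cpp(wv, dim(f0$voxels), f0$spacing, f0$origin,
                                geom$sad_mm, geom$sdd_mm, geom$pixel_mm,
                                geom$detector_rows, geom$detector_cols,
                                geom$angle_deg, step_mm, roi)
  lam <- sum(rp[roi] * x$pixels[roi]) / sum(x$pixels[roi]^2)
  if (!is.finite(lam)) stop("degenerate ROI: measured projection is zero inside it")
  res <- (rp - lam * x$pixels) * roi
  if (!all(is.finite(res))) stop("non-finite residual in cost evaluation")
  J <- sum(res^2)
  B <- back_project_cpp(res, dim(f0$voxels), f0$spacing, f0$origin,
                        geom$sad_mm, geom$sdd_mm, geom$pixel_mm,
                        geom$angle_deg, step_mm)
  g <- 2 * grad_contract_model_cpp(as.vector(f0$voxels), dim(f0$voxels),
                                   f0$spacing, f0$origin, model$mean,
                                   model$modes, as.numeric(u), B)
  list(cost = J, gradient = g, lambda = lam,
       rendered = projection2d(rp, geom))
}

cost_only <- function(u, f0, model, geom, x, roi, step_mm) {
  wv <- warp_model_cpp(as.vector(f0$voxels), dim(f0$voxels), f0$spacing,
                       f0$origin, model$mean, model$modes, as.numeric(u))
  rp <- forward_project_roi_cpp(wv, dim(f0$voxels), f0$spacing, f0$origin,
                                geom$sad_mm, geom$sdd_mm, geom$pixel_mm,
                                geom$detector_rows, geom$detector_cols,
                                geom$angle_deg, step_mm, roi)
  lam <- sum(rp[roi] * x$pixels[roi]) / sum(x$pixels[roi]^2)
  sum(((rp - lam * x$pixels) * roi)^2)
}

#' Optimizer controls for per-frame estimation
#'
#' Gradient descent with Armijo backtracking line search: sufficient
#' decrease constant `c = 1e-4`, step shrink 0.5, the initial step
#' calibrated from the first gradient norm so the first trial moves the
#' coefficients by `step_scale_frac` of the training score scale.
#'
#' @param max_iter iteration cap per frame.
#' @param tol relative cost-change stopping tolerance.
#' @param armijo_c,shrink line-search constants.
#' @param step_scale_frac first-trial step as a fraction of the score scale
#'   (square root of the leading eigenvalue).
#' @param max_backtracks line-search cap per iteration.
#' @param floor_frac stop when the cost falls below this fraction of the
#'   ROI energy of the scaled measured projection (a numerically perfect
#'   fit).
#' @export
optimizer_control <- function(max_iter = 50, tol = 1e-4, armijo_c = 1e-4,
                              shrink = 0.5, step_scale_frac = 0.3,
                              max_backtracks = 25, floor_frac = 1e-9) {
  list(max_iter = max_iter, tol = tol, armijo_c = armijo_c, shrink = shrink,
       step_scale_frac = step_scale_frac, max_backtracks = max_backtracks,
       floor_frac = floor_frac)
}

#' Estimate the motion state for a single projection
#'
#' Minimises the ROI-restricted squared L2 mismatch between the measured
#' projection and the projection rendered from the motion model, by
#' gradient descent on the PCA coefficients with backtracking line search.
#' Deterministic given its inputs. Accepted steps never increase the cost;
#' the iteration stops when the relative cost change falls below `tol` or
#' at `max_iter` (with a convergence warning, returning the best-so-far
#' state).
#'
#' @inheritParams cost_and_gradient
#' @param u_init starting coefficients (warm start).
#' @param control an [optimizer_control()].
#' @return list: `u` (optimised coefficients), `volume` (the fluoroscopic
#'   3D frame `f(D(u), f0)`), and `state` (cost history, lambda,
#'   iterations, step size, convergence flag).
#' @export
estimate_frame <- function(x, f0, model, geom, roi = NULL, u_init = NULL,
                           control = optimizer_control(), step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- min(f0$spacing) / 2
  if (is.null(roi)) roi <- full_roi(geom)
  n <- model$n_modes
  u <- if (is.null(u_init)) rep(0, n) else as.numeric(u_init)
  if (length(u) != n) stop("u_init has the wrong length")
  score_scale <- sqrt(max(model$eigenvalues[1], 1e-300))
  cg <- cost_and_gradient(u, f0, model, geom, x, roi, step_mm)
  J <- cg$cost
  hist <- J
  floor_J <- control$floor_frac * sum((cg$lambda * x$pixels[roi])^2)
  gnorm <- sqrt(sum(cg$gradient^2))
  step <- if (gnorm > 0) control$step_scale_frac * score_scale / gnorm else 0
  converged <- J <= floor_J
  iter <- 0
  while (!converged && iter < control$max_iter) {
    iter <- iter + 1
    g <- cg$gradient
    gnorm2 <- sum(g^2)
    if (gnorm2 <= 1e-300 * max(1, J)) { converged <- TRUE; break }
    accepted <- FALSE
    t <- step
    for (bt in seq_len(control$max_backtracks)) {
      u_try <- u - t * g
      J_try <- cost_only(u_try, f0, model, geom, x, roi, step_mm)
      if (J_try <= J - control$armijo_c * t * gnorm2) {
        accepted <- TRUE
        break
      }
      t <- t * control$shrink
    }
    if (!accepted) { converged <- TRUE; break }  # step underflow: at a minimum
    u <- u_try
    rel <- (J - J_try) / max(J, 1e-300)
    J <- J_try
    hist <- c(hist, J)
    step <- if (bt == 1) t * 2 else t      # expand after an easy acceptance
    cg <- cost_and_gradient(u, f0, model, geom, x, roi, step_mm)
    J <- cg$cost  # identical to J_try up to lambda re-estimation
    if (J <= floor_J || rel < control$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("estimate_frame: maximum iterations reached without convergence; returning best-so-far coefficients")
  list(u = u,
       volume = warp_volume(f0, reconstruct_dvf(model, u)),
       state = list(cost = J, cost_history = hist, lambda = cg$lambda,
                    iterations = iter, step = step, converged = converged))
}

#' Estimate the fluoroscopic 3D sequence for a projection stack
#'
#' Processes frames in time order, warm-starting each frame's coefficients
#' from the previous frame (the first frame starts from zero). The ROI is
#' recomputed per gantry angle from reference-phase landmarks when a
#' landmark matrix is given.
#'
#' @param stack measured [projection_stack()].
#' @param f0 reference-phase volume on the model grid.
#' @param model a `pca_motion_model`.
#' @param roi_landmarks_mm k x 3 landmark matrix for [make_roi()] (`NULL`
#'   uses the whole detector).
#' @param roi_margin_mm ROI margin at isocenter scale.
#' @param ref_centroid_mm reference tumor centroid; when given, per-frame
#'   tumor positions are computed with [tumor_position()].
#' @param control an [optimizer_control()].
#' @param store_volumes keep every estimated 3D frame (memory-heavy).
#' @param step_mm projector ray step.
#' @return list: `coefficients` (frames x N), `tumor_mm` (frames x 3 or
#'   NULL), `lambda`, `cost`, `iterations`, `converged` (per frame),
#'   `volumes` (list or NULL), `failed` (indices of frames whose
#'   optimisation errored; their coefficients carry the previous state).
#' @export
estimate_sequence <- function(stack, f0, model, roi_landmarks_mm = NULL,
                              roi_margin_mm = 30, ref_centroid_mm = NULL,
                              control = optimizer_control(),
                              store_volumes = FALSE, step_mm = NULL) {
  nf <- n_frames(stack)
  N <- model$n_modes
  U <- matrix(0, nf, N)
  lam <- cost <- iters <- numeric(nf)
  conv <- logical(nf)
  vols <- if (store_volumes) vector("list", nf) else NULL
  tum <- if (!is.null(ref_centroid_mm)) matrix(0, nf, 3) else NULL
  failed <- integer(0)
  u_prev <- rep(0, N)
  for (i in seq_len(nf)) {
    pr <- get_projection(stack, i)
    roi <- if (is.null(roi_landmarks_mm)) NULL else
      make_roi(pr$geometry, roi_landmarks_mm, roi_margin_mm)
    est <- tryCatch(
      estimate_frame(pr, f0, model, pr$geometry, roi = roi, u_init = u_prev,
                     control = control, step_mm = step_mm),
      error = function(e) {
        warning(sprintf("frame %d failed: %s", i, conditionMessage(e)))
        NULL
      })
    if (is.null(est)) {
      failed <- c(failed, i)
      U[i, ] <- u_prev
      conv[i] <- FALSE
    } else {
      U[i, ] <- est$u
      lam[i] <- est$state$lambda
      cost[i] <- est$state$cost
      iters[i] <- est$state$iterations
      conv[i] <- est$state$converged
      if (store_volumes) vols[[i]] <- est$volume
      u_prev <- est$u
    }
    if (!is.null(tum))
      tum[i, ] <- tumor_position(model = model, u = U[i, ],
                                 ref_centroid_mm = ref_centroid_mm)
  }
  list(coefficients = U, tumor_mm = tum, lambda = lam, cost = cost,
       iterations = iters, converged = conv, volumes = vols, failed = failed)
}
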