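#' The four lumbar marker-set models
#'
#' Model 1: lumbar spine as one segment (L1, L5), first-degree polynomial.
#' Model 2: Plug-in-Gait-style markers nearest the lumbar spine (T10, S1),
#' first degree. Model 3: two equidistant segments (L1, L3, L5), second
#' degree. Model 4: every lumbar vertebra (L1..L5), second degree. Two-marker
#' models use degree 1 because only two points are available; three or more
#' markers use degree 2.
#'
#' @return List of `spine_model_spec` lists with `model_id`, `labels`,
#'   `degree`.
#' @export
spine_model_specs <- function() {
  list(
    structure(list(model_id = 1L, labels = c("L1", "L5"), degree = 1L),
              class = "spine_model_spec"),
    structure(list(model_id = 2L, labels = c("T10", "S1"), degree = 1L),
              class = "spine_model_spec"),
    structure(list(model_id = 3L, labels = c("L1", "L3", "L5"), degree = 2L),
              class = "spine_model_spec"),
    structure(list(model_id = 4L, labels = c("L1", "L2", "L3", "L4", "L5"),
                   degree = 2L),
              class = "spine_model_spec")
  )
}

# least-squares polynomial fit of v on u; exact interpolation when
# length(u) == degree + 1
.polyfit <- function(u, v, degree) {
  qr.solve(outer(u, 0:degree, "^"), v)
}

.polyval <- function(coef, u) {
  drop(outer(u, seq_along(coef) - 1L, "^") %*% coef)
}

#' Fit one spine model to a capture
#'
#' Least-squares polynomial of the model's degree with the longitudinal
#' sagittal coordinate `u` as the independent variable, fitted on the model's
#' markers and evaluated at `n_eval` equidistant points of the evaluation
#' range. By default all models share the capture's lumbar span `[u(L5),
#' u(L1)]` so that inter-model comparisons use a common abscissa (Model 2's
#' line, fitted on T10/S1, is evaluated restricted to that span).
#'
#' @param capture A `capture_instant` from [extract_captures()].
#' @param spec A `spine_model_spec`.
#' @param n_eval Number of equidistant evaluation points (default 5).
#' @param shared_range Evaluate over the capture's lumbar span (default) or
#'   over the model's own marker span.
#' @return A `spine_model_fit` list: `model_id`, `coefficients`, `u_range`,
#'   `eval_u`, `eval_v`.
#' @export
fit_model <- function(capture, spec, n_eval = 5L, shared_range = TRUE) {
  pts <- capture$points
  absent <- setdiff(spec$labels, pts$label)
  if (length(absent)) stop("capture lacks markers ",
                           paste(absent, collapse = ", "))
  u <- pts$u[match(spec$labels, pts$label)]
  v <- pts$v[match(spec$labels, pts$label)]
  if (anyDuplicated(u)) stop("duplicate u values in model ", spec$model_id)
  d <- diff(u)
  if (!(all(d > 0) || all(d < 0))) {
    stop("non-monotone u along model ", spec$model_id,
         " marker chain (spine folded past the pelvis axis)")
  }
  coef <- .polyfit(u, v, spec$degree)
  if (shared_range) {
    lumbar <- pts[pts$label %in% c("L1", "L5"), ]
    if (nrow(lumbar) < 2L) stop("capture lacks L1/L5 for the shared range")
    u_range <- sort(range(lumbar$u))
  } else {
    u_range <- sort(range(u))
  }
  eval_u <- seq(u_range[1], u_range[2], length.out = n_eval)
  structure(list(model_id = spec$model_id, coefficients = coef,
                 u_range = u_range, eval_u = eval_u,
                 eval_v = .polyval(coef, eval_u)),
            class = "spine_model_fit")
}

#' Algebraic (Taubin) circle fit
#'
#' Fits a circle to 2D points by Taubin's algebraic method, which minimizes
#' an approximation of the geometric distance; for three points it returns
#' the circumcircle. Points collinear within `collinear_tol` (maximum
#' perpendicular deviation from the best-fit line) yield a distinct
#' straight-spine signal rather than a spurious huge circle.
#'
#' @param u,v Point coordinates (>= 3 points).
#' @param collinear_tol Collinearity tolerance in the coordinate units.
#' @return A `circle_fit` list: `center` (length 2), `radius`, `collinear`.
#' @export
fit_circle <- function(u, v, collinear_tol = 1e-6) {
  n <- length(u)
  if (n < 3L || length(v) != n) stop("circle fit needs >= 3 (u, v) points")
  mx <- mean(u); my <- mean(v)
  x <- u - mx; y <- v - my
  # collinearity: max perpendicular deviation from the principal axis
  sv <- svd(cbind(x, y))
  if (sv$d[2] <= collinear_tol * sqrt(n)) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          collinear = TRUE), class = "circle_fit"))
  }
  z <- x * x + y * y
  Mxx <- mean(x * x); Myy <- mean(y * y); Mxy <- mean(x * y)
  Mxz <- mean(x * z); Myz <- mean(y * z); Mzz <- mean(z * z)
  Mz <- Mxx + Myy
  Cov_xy <- Mxx * Myy - Mxy^2
  Var_z <- Mzz - Mz^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz^2 - Mzz
  A1 <- Var_z * Mz + 4 * Cov_xy * Mz - Mxz^2 - Myz^2
  A0 <- Mxz^2 * Myy + Myz^2 * Mxx - Mzz * Cov_xy - 2 * Mxz * Myz * Mxy +
    Mz^2 * Cov_xy
  # Newton iteration from eta = 0 (Chernov's scheme); exact data has its
  # root at 0
  eta <- 0
  y_val <- A0
  for (iter in 1:50) {
    dy <- A1 + eta * (2 * A2 + 3 * A3 * eta)
    eta_new <- eta - y_val / dy
    if (!is.finite(eta_new) || abs(eta_new - eta) < 1e-14 * (1 + abs(eta))) {
      eta <- if (is.finite(eta_new)) eta_new else eta
      break
    }
    y_new <- A0 + eta_new * (A1 + eta_new * (A2 + eta_new * A3))
    if (abs(y_new) > abs(y_val)) break
    eta <- eta_new; y_val <- y_new
  }
  Det <- eta^2 - eta * Mz + Cov_xy
  cx <- (Mxz * (Myy - eta) - Myz * Mxy) / Det / 2
  cy <- (Myz * (Mxx - eta) - Mxz * Mxy) / Det / 2
  structure(list(center = c(cx + mx, cy + my),
                 radius = sqrt(cx^2 + cy^2 + Mz),
                 collinear = FALSE),
            class = "circle_fit")
}

#' Circle-fit lumbar lordosis of a capture
#'
#' Fits a circle to the five lumbar markers in the sagittal plane and returns
#' the central angle between the radii through L1 and L5. Sign convention:
#' positive when the lumbar curve is posteriorly convex (flexed/kyphotic,
#' circle center anterior of the L1-L5 chord), negative when lordotic. The
#' lordosis is always computed from the lumbar markers, independently of the
#' model being compared. Collinear markers give a straight-spine angle of 0
#' by continuity.
#'
#' @param capture A `capture_instant`.
#' @param sta_reference The participant's neutral-standing lordosis angle in
#'   degrees (mean over their static-trial captures); `NA` leaves
#'   `relative_lordosis` as `NA`.
#' @param collinear_tol Collinearity tolerance in mm.
#' @return A `lordosis_result` list: `center`, `radius`, `lordosis_angle`,
#'   `relative_lordosis`, `collinear`.
#' @export
lordosis_angle <- function(capture, sta_reference = NA_real_,
                           collinear_tol = 1e-6) {
  pts <- capture$points
  absent <- setdiff(LUMBAR_LABELS, pts$label)
  if (length(absent)) stop("capture lacks lumbar markers ",
                           paste(absent, collapse = ", "))
  idx <- match(LUMBAR_LABELS, pts$label)
  u <- pts$u[idx]; v <- pts$v[idx]
  circ <- fit_circle(u, v, collinear_tol = collinear_tol)
  if (circ$collinear) {
    ang <- 0
  } else {
    r1 <- c(u[1] - circ$center[1], v[1] - circ$center[2])   # L1 radius
    r5 <- c(u[5] - circ$center[1], v[5] - circ$center[2])   # L5 radius
    cosang <- sum(r1 * r5) / sqrt(sum(r1^2) * sum(r5^2))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    mid <- c((u[1] + u[5]) / 2, (v[1] + v[5]) / 2)
    if (circ$center[2] < mid[2]) ang <- -ang   # center posterior: lordotic
  }
  structure(list(center = circ$center, radius = circ$radius,
                 lordosis_angle = ang,
                 relative_lordosis = ang - sta_reference,
                 collinear = circ$collinear),
            class = "lordosis_result")
}

#' Pearson correlation between two model fits
#'
#' Sample Pearson correlation of the two fitted curves' ordinates at the
#' shared evaluation points. Zero variance in either ordinate set makes the
#' correlation undefined; such captures are flagged (`NA` with
#' `undefined = TRUE`) for exclusion with logging, never coerced to 0 or 1.
#'
#' @param fit_i,fit_j `spine_model_fit` objects sharing `eval_u`.
#' @return A `pair_correlation` list: `model_i`, `model_j`, `r`, `undefined`.
#' @export
pearson_pair <- function(fit_i, fit_j) {
  if (fit_i$model_id > fit_j$model_id) { tmp <- fit_i; fit_i <- fit_j; fit_j <- tmp }
  if (max(abs(fit_i$eval_u - fit_j$eval_u)) > 1e-9) {
    stop("fits do not share evaluation points")
  }
  vi <- fit_i$eval_v; vj <- fit_j$eval_v
  degenerate <- function(v) stats::sd(v) <= 1e-10 * (1 + abs(mean(v)))
  if (degenerate(vi) || degenerate(vj)) {
    return(structure(list(model_i = fit_i$model_id, model_j = fit_j$model_id,
                          r = NA_real_, undefined = TRUE),
                     class = "pair_correlation"))
  }
  structure(list(model_i = fit_i$model_id, model_j = fit_j$model_id,
                 r = stats::cor(vi, vj), undefined = FALSE),
            class = "pair_correlation")
}
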