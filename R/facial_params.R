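# Extraction of the facial parameters that drive respirator sizing:
# eye-to-chin distance, and the amplitude A and spread sigma of a Gaussian
# fitted to the nasal cross-section profile.

#' Construct a facial parameter record
#'
#' The per-user record driving sizing: eye-to-chin distance (mm), nasal
#' Gaussian amplitude `A` (mm) and spread `sigma` (mm), nasal ridge angle to
#' the facial plane (degrees), and the RMS residual of the profile fit (mm).
#'
#' @param eye_to_chin,A,sigma Positive values in mm.
#' @param ridge_angle Degrees, in `[0, 90)`.
#' @param fit_rmse Non-negative fit residual (mm).
#' @return An object of class `facial_parameters`.
#' @export
facial_parameters <- function(eye_to_chin, A, sigma, ridge_angle, fit_rmse = 0) {
  vals <- c(eye_to_chin = eye_to_chin, A = A, sigma = sigma,
            ridge_angle = ridge_angle, fit_rmse = fit_rmse)
  if (!all(is.finite(vals)))
    stop("facial parameters must be finite")
  if (eye_to_chin <= 0 || A <= 0 || sigma <= 0)
    stop("eye_to_chin, A and sigma must be positive")
  if (ridge_angle < 0 || ridge_angle >= 90)
    stop("ridge_angle must lie in [0, 90) degrees")
  if (fit_rmse < 0)
    stop("fit_rmse must be non-negative")
  structure(list(eye_to_chin = eye_to_chin, A = A, sigma = sigma,
                 ridge_angle = ridge_angle, fit_rmse = fit_rmse),
            class = "facial_parameters")
}

#' @export
print.facial_parameters <- function(x, ...) {
  cat(sprintf(paste0("facial_parameters: eye-to-chin %.2f mm, A %.2f mm, ",
                     "sigma %.2f mm, ridge angle %.1f deg (fit rmse %.3f mm)\n"),
              x$eye_to_chin, x$A, x$sigma, x$ridge_angle, x$fit_rmse))
  invisible(x)
}

#' Eye-to-chin distance of an oriented face
#'
#' Distance from the eye midpoint (the canonical-frame origin) to the chin
#' landmark projected into the midsagittal (x = 0) plane. Projection removes
#' sensitivity to lateral chin asymmetry.
#'
#' @param mesh A [triangle_mesh()] in the canonical frame (see
#'   [orient_face()]); used only for validation.
#' @param landmarks A [landmark_set()] in the canonical frame.
#' @return Distance in mm.
#' @export
eye_to_chin <- function(mesh, landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  chin <- landmarks$chin
  if (chin[2] > 1e-9)
    stop("chin landmark lies above the eyeline (positive y); ",
         "the mesh does not appear to be oriented")
  sqrt(chin[2]^2 + chin[3]^2)
}

#' Construct a nasal profile curve
#'
#' @param x Lateral offsets from the ridge apex (mm), strictly increasing.
#' @param h Surface heights above the profile baseline (mm).
#' @param station Position along the ridge where the section was cut (mm).
#' @return An object of class `profile_curve`.
#' @export
profile_curve <- function(x, h, station = NA_real_) {
  x <- as.numeric(x)
  h <- as.numeric(h)
  if (length(x) != length(h))
    stop("x and h must have equal length")
  if (any(diff(x) <= 0))
    stop("profile x must be strictly increasing")
  if (!all(is.finite(h)))
    stop("profile heights must be finite")
  # endpoints must sit near the baseline; a small allowance covers the tail
  # of a true Gaussian truncated at a finite lateral span
  tol <- 0.02 * max(abs(h)) + 1e-6
  if (abs(h[1]) > tol || abs(h[length(h)]) > tol)
    stop("profile endpoints are far from the baseline; subtract the chord ",
         "or widen the section")
  structure(list(x = x, h = h, station = station), class = "profile_curve")
}

#' Extract the nasal cross-section profile from an oriented mesh
#'
#' The ridge axis is the line from the nose bridge to the nose tip. A section
#' plane perpendicular to that axis is placed at `station_fraction` along it
#' and intersected with the mesh. The intersection curve is reduced to a
#' lateral coordinate `x` (re-centred so the apex is at x = 0) and a height
#' `h` above the chord joining the two curve endpoints (baseline
#' subtraction), and resampled on a uniform grid.
#'
#' @param mesh Oriented [triangle_mesh()].
#' @param landmarks Oriented [landmark_set()].
#' @param station_fraction Position of the cut along the bridge-to-tip ridge
#'   segment, in `[0, 1]`; default 0.5 (mid-ridge).
#' @param half_width Lateral half-extent of the profile about the apex, mm.
#'   The default (40 mm) keeps the Gaussian tail at the endpoints below 0.3%
#'   of the peak for the spreads seen in adult cohorts, so the chord baseline
#'   does not bias the fitted amplitude.
#' @param spacing Resampling interval in mm (must be <= 0.5).
#' @return A [profile_curve()].
#' @export
extract_nose_profile <- function(mesh, landmarks, station_fraction = 0.5,
                                 half_width = 40, spacing = 0.5) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(landmarks, "landmark_set"))
  if (station_fraction < 0 || station_fraction > 1)
    stop("station_fraction must lie in [0, 1]")
  if (spacing > 0.5 || spacing <= 0)
    stop("profile resampling spacing must be in (0, 0.5] mm")
  ridge <- landmarks$nose_tip - landmarks$nose_bridge
  rlen <- sqrt(sum(ridge^2))
  if (rlen < 1e-9)
    stop("nose_bridge and nose_tip coincide; ridge axis undefined")
  dn <- ridge / rlen
  M <- landmarks$nose_bridge + station_fraction * ridge
  # in-plane basis: u lateral (x-like), e2 the in-plane elevation direction
  e2 <- .cross3(dn, c(1, 0, 0))
  if (sqrt(sum(e2^2)) < 1e-6)
    stop("ridge axis is parallel to the lateral axis; mesh not oriented")
  e2 <- .unit(e2)
  u_axis <- .cross3(e2, dn)

  v <- mesh$vertices
  f <- mesh$faces
  s <- as.numeric((v - matrix(M, nrow(v), 3, byrow = TRUE)) %*% dn)
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing))
    stop("section plane at station ", signif(station_fraction, 3),
         " does not intersect the mesh")
  fc <- f[crossing, , drop = FALSE]
  # unique mesh edges whose endpoints straddle the plane
  e_all <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(1, 3)])
  e_all <- cbind(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  e_all <- unique(e_all)
  sa <- s[e_all[, 1]]; sb <- s[e_all[, 2]]
  hit <- sa * sb < 0
  ea <- e_all[hit, 1]; eb <- e_all[hit, 2]
  t <- s[ea] / (s[ea] - s[eb])
  P <- v[ea, , drop = FALSE] + t * (v[eb, , drop = FALSE] - v[ea, , drop = FALSE])
  on_plane <- which(abs(s) < 1e-12)
  if (length(on_plane)) P <- rbind(P, v[on_plane, , drop = FALSE])
  if (nrow(P) < 10L)
    stop("section plane intersects the mesh in only ", nrow(P),
         " points (need >= 10)")
  rel <- P - matrix(M, nrow(P), 3, byrow = TRUE)
  u <- as.numeric(rel %*% u_axis)
  w <- as.numeric(rel %*% e2)
  ord <- order(u)
  u <- u[ord]; w <- w[ord]
  apex_u <- u[which.max(w)]
  lo <- max(min(u), apex_u - half_width)
  hi <- min(max(u), apex_u + half_width)
  xs <- seq(lo, hi, by = spacing)
  if (length(xs) < 10L)
    stop("profile section is too narrow (", length(xs), " samples)")
  ws <- stats::approx(u, w, xout = xs, ties = mean)$y
  # baseline: chord between the two resampled endpoints
  n <- length(xs)
  base <- ws[1] + (ws[n] - ws[1]) * (xs - xs[1]) / (xs[n] - xs[1])
  h <- ws - base
  x0 <- xs[which.max(h)]
  profile_curve(xs - x0, h, station = station_fraction * rlen)
}

#' Construct a Gaussian fit record
#'
#' @param A Peak height (mm). @param sigma Spread (mm).
#' @param center_offset Fitted apex offset (mm).
#' @param rmse Root-mean-square residual (mm).
#' @param converged Logical solver status.
#' @param message Solver diagnostic.
#' @return An object of class `gaussian_fit`.
#' @export
gaussian_fit <- function(A, sigma, center_offset, rmse, converged,
                         message = "") {
  if (isTRUE(converged)) {
    if (!is.finite(A) || A <= 0 || !is.finite(sigma) || sigma <= 0)
      stop("a converged Gaussian fit requires A > 0 and sigma > 0")
    if (!is.finite(rmse) || rmse < 0)
      stop("rmse must be non-negative")
  }
  structure(list(A = A, sigma = abs(sigma), center_offset = center_offset,
                 rmse = rmse, converged = isTRUE(converged),
                 message = message),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("gaussian_fit: A = %.3f mm, sigma = %.3f mm, centre %.3f mm, rmse %.4g mm\n",
                x$A, x$sigma, x$center_offset, x$rmse))
  else
    cat("gaussian_fit: NOT converged (", x$message, ")\n", sep = "")
  invisible(x)
}

#' Fit a centred Gaussian to a nasal profile
#'
#' Nonlinear least squares of `h = A * exp(-(x - c)^2 / (2 sigma^2))` by
#' damped (Levenberg-Marquardt) least squares. Initialisation: `A0 = max h`,
#' `c0 = argmax x`, `sigma0` from the observed half-width at half maximum
#' divided by `sqrt(2 log 2)`. Convergence tolerance 1e-8 on relative
#' parameter change, at most 200 iterations. `sigma` is reported as its
#' absolute value. A non-positive peak or solver failure yields
#' `converged = FALSE` with a diagnostic message, never silent output.
#'
#' @param profile A [profile_curve()].
#' @return A [gaussian_fit()].
#' @export
fit_gaussian <- function(profile) {
  stopifnot(inherits(profile, "profile_curve"))
  x <- profile$x
  h <- profile$h
  if (length(x) < 10L)
    stop("profile must have at least 10 points")
  A0 <- max(h)
  if (A0 <= 0)
    return(gaussian_fit(NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                        "non-positive profile peak"))
  c0 <- x[which.max(h)]
  above <- x[h >= A0 / 2]
  hwhm <- max(diff(range(above)) / 2, 2 * min(diff(x)))
  s0 <- hwhm / sqrt(2 * log(2))
  span <- diff(range(x))
  if (span < 2 * hwhm)
    stop("profile span (", signif(span, 4), " mm) is less than twice the ",
         "apparent half-width; widen the section")
  resid_fn <- function(p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) - h
  jac_fn <- function(p) {
    E <- exp(-(x - p[2])^2 / (2 * p[3]^2))
    cbind(E,
          p[1] * E * (x - p[2]) / p[3]^2,
          p[1] * E * (x - p[2])^2 / p[3]^3)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A0, c0, s0), fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ptol = 1e-8)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(gaussian_fit(NA_real_, NA_real_, NA_real_, NA_real_, FALSE,
                        conditionMessage(fit)))
  cf <- fit$par
  conv <- fit$info %in% 1:3
  rmse <- sqrt(mean(fit$fvec^2))
  if (!is.finite(cf[1]) || cf[1] <= 0)
    return(gaussian_fit(cf[1], cf[3], cf[2], rmse, FALSE,
                        "fitted peak is non-positive"))
  gaussian_fit(cf[1], abs(cf[3]), cf[2], rmse, conv,
               if (conv) "" else paste0("solver did not converge (",
                                        fit$message, ")"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nasal ridge angle to the facial plane
#'
#' Angle in degrees between the nose-bridge-to-tip line and the canonical
#' facial (x-y) plane, in `[0, 90)`.
#'
#' @param landmarks A [landmark_set()] in the canonical frame.
#' @return Angle in degrees.
#' @export
ridge_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  v <- landmarks$nose_tip - landmarks$nose_bridge
  len <- sqrt(sum(v^2))
  if (len < 1e-9)
    stop("zero-length ridge vector: nose_bridge and nose_tip coincide")
  ang <- atan2(abs(v[3]), sqrt(v[1]^2 + v[2]^2)) * 180 / pi
  if (ang >= 90 - 1e-9)
    stop("degenerate ridge: perpendicular to the facial plane (90 degrees)")
  ang
}

#' Extract all facial parameters from a mesh
#'
#' Composition of [orient_face()], [eye_to_chin()], [extract_nose_profile()],
#' [fit_gaussian()] and [ridge_angle()] into one [facial_parameters()]
#' record. Failures are re-signalled with the pipeline stage identified.
#'
#' @param mesh A [triangle_mesh()] in any frame.
#' @param landmarks A [landmark_set()] in the same frame.
#' @param station_fraction,half_width,spacing Passed to
#'   [extract_nose_profile()].
#' @return A [facial_parameters()] record.
#' @export
extract_all <- function(mesh, landmarks, station_fraction = 0.5,
                        half_width = 40, spacing = 0.5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("extract_all [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  o <- stage("orientation", orient_face(mesh, landmarks))
  ec <- stage("eye_to_chin", eye_to_chin(o$mesh, o$landmarks))
  prof <- stage("profile_extraction",
                extract_nose_profile(o$mesh, o$landmarks, station_fraction,
                                     half_width, spacing))
  fit <- stage("gaussian_fit", fit_gaussian(prof))
  if (!fit$converged)
    stop("extract_all [gaussian_fit]: fit did not converge (",
         fit$message, ")", call. = FALSE)
  ang <- stage("ridge_angle", ridge_angle(o$landmarks))
  stage("assembly",
        facial_parameters(ec, fit$A, fit$sigma, ang, fit$rmse))
}

#' Write facial parameters as a one-row CSV
#'
#' Columns: `eye_to_chin_mm`, `A_mm`, `sigma_mm`, `ridge_angle_deg`,
#' `fit_rmse_mm`.
#'
#' @param params A [facial_parameters()] record.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_facial_parameters <- function(params, path) {
  stopifnot(inherits(params, "facial_parameters"))
  df <- data.frame(eye_to_chin_mm = params$eye_to_chin, A_mm = params$A,
                   sigma_mm = params$sigma,
                   ridge_angle_deg = params$ridge_angle,
                   fit_rmse_mm = params$fit_rmse)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read facial parameters written by [write_facial_parameters()]
#'
#' @param path CSV path.
#' @return A [facial_parameters()] record.
#' @export
read_facial_parameters <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("eye_to_chin_mm", "A_mm", "sigma_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parameter file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  facial_parameters(df$eye_to_chin_mm[1], df$A_mm[1], df$sigma_mm[1],
                    df$ridge_angle_deg[1] %||% 25,
                    df$fit_rmse_mm[1] %||% 0)
}
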