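# Synthetic ground-truth generators: parametric faces, parameter cohorts,
# and leak videos. These define the study conditions under which the
# extraction, sizing and flow-visualisation pipelines are validated.

.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic face
#'
#' Parameters of the parametric face surface: a shallow ellipsoidal base cap
#' standing in for the facial plane, plus a Gaussian nasal ridge of amplitude
#' `A` and lateral spread `sigma` extruded along an axis inclined at
#' `ridge_angle` to the base plane. Landmarks are placed exactly; optional
#' i.i.d. normal vertex noise is applied along vertex normals.
#'
#' @param eye_to_chin Eye-midpoint to chin distance, mm.
#' @param A Nasal profile amplitude at the mid-ridge station, mm.
#' @param sigma Nasal profile lateral spread, mm.
#' @param ridge_angle Ridge inclination to the facial plane, degrees in
#'   `[0, 60)`.
#' @param face_width Lateral extent of the generated surface, mm.
#' @param mesh_resolution Grid spacing, mm. Must resolve the ridge: at least
#'   8 vertices per `sigma`.
#' @param noise_sd Standard deviation of vertex noise along normals, mm.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `face_spec`.
#' @export
face_spec <- function(eye_to_chin = 104.9, A = 24.4, sigma = 10.2,
                      ridge_angle = 25, face_width = 160,
                      mesh_resolution = 1.0, noise_sd = 0, seed = 1L) {
  if (any(c(eye_to_chin, A, sigma, face_width, mesh_resolution) <= 0))
    stop("all face lengths must be positive")
  if (ridge_angle < 0 || ridge_angle >= 60)
    stop("ridge_angle must lie in [0, 60) degrees")
  if (noise_sd < 0)
    stop("noise_sd must be non-negative")
  if (sigma / mesh_resolution < 8)
    stop("mesh_resolution ", mesh_resolution, " mm is too coarse to resolve ",
         "sigma = ", sigma, " mm (need at least 8 vertices per sigma)")
  structure(list(eye_to_chin = eye_to_chin, A = A, sigma = sigma,
                 ridge_angle = ridge_angle, face_width = face_width,
                 mesh_resolution = mesh_resolution, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "face_spec")
}

# Vertex normals as the normalised average of adjacent face normals.
.vertex_normals <- function(vertices, faces) {
  fn <- .face_normals(list(vertices = vertices, faces = faces))
  vn <- matrix(0, nrow(vertices), 3L)
  for (k in 1:3) {
    for (ch in 1:3) {
      acc <- vn[, ch]
      add <- rowsum(fn[, ch], faces[, k], reorder = FALSE)
      idx <- as.integer(rownames(add))
      acc[idx] <- acc[idx] + add[, 1]
      vn[, ch] <- acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len < 1e-12] <- 1
  vn / len
}

#' Generate a synthetic face with known parameters
#'
#' The surface is a shallow ellipsoidal cap with a Gaussian nasal ridge
#' displaced along the in-plane direction perpendicular to the ridge axis,
#' so that the cross-section perpendicular to the ridge is an exact Gaussian
#' of amplitude `A` at the mid-ridge station. Eye landmarks sit symmetrically
#' on the eyeline; the chin landmark is placed at the eye-landmark depth so
#' that the build frame coincides exactly with the landmark-defined
#' canonical frame, making the ground-truth eye-to-chin distance and ridge
#' angle exact. Landmarks are exact regardless of vertex noise.
#'
#' @param spec A [face_spec()].
#' @return List with `mesh` ([triangle_mesh()]), `landmarks`
#'   ([landmark_set()]), `truth` ([facial_parameters()] ground truth at the
#'   default mid-ridge station), and `spec`.
#' @export
synth_face <- function(spec) {
  stopifnot(inherits(spec, "face_spec"))
  ec <- spec$eye_to_chin
  A <- spec$A
  sg <- spec$sigma
  th <- spec$ridge_angle * pi / 180
  res <- spec$mesh_resolution
  w2 <- spec$face_width / 2

  # shallow ellipsoidal base cap (nearly flat laterally so that the chord
  # baseline of a profile section tracks the base to < 0.05 mm)
  z0 <- 15; ax <- 600; by <- 250
  zb <- function(x, y) z0 * sqrt(pmax(0, 1 - (x / ax)^2 - (y / by)^2))

  xs <- seq(-w2, w2, by = res)
  y_lo <- -(ec + 12); y_hi <- 34
  ys <- seq(floor(y_lo / res) * res, y_hi, by = res)

  dn <- c(0, -cos(th), sin(th))            # ridge axis, bridge -> tip
  e2 <- c(0, sin(th), cos(th))             # in-plane elevation direction
  y_B <- -10                               # bridge station (on the y grid)
  band <- round(0.38 * ec / res) * res     # ridge band length along y
  y_T <- y_B - band
  taper <- 15                              # cosine taper length, mm

  zb0 <- function(y) zb(0, y)
  # crest elevation above the base, before the amplitude offset h_B
  delta0 <- function(y) (y_B - y) * sin(th) + (zb0(y_B) - zb0(y)) * cos(th)

  # landmarks on the crest line: bridge at y_B, tip just above the taper
  y_tip <- y_T + max(2, 2 * res)
  crest <- function(y, h_B) {
    a <- h_B + delta0(y)
    c(0, y, zb0(y)) + a * e2
  }
  # the station plane (perpendicular to the ridge axis through the point at
  # station_fraction = 0.5) meets the base at y*; independent of h_B since
  # the amplitude offset is perpendicular to the axis
  M0 <- (crest(y_B, 0) + crest(y_tip, 0)) / 2
  f <- function(y) sum((c(0, y, zb0(y)) - M0) * dn)
  y_star <- stats::uniroot(f, c(y_T - 30, y_B + 10), tol = 1e-10)$root
  h_B <- A - delta0(y_star)
  if (h_B <= 0)
    stop("requested amplitude A = ", A, " mm is too small for the ridge ",
         "geometry (needs A > ", signif(delta0(y_star), 4), " mm)")

  grid <- expand.grid(x = xs, y = ys)
  gx <- grid$x; gy <- grid$y
  base_z <- zb(gx, gy)
  alpha <- pmax(h_B + delta0(gy), 0)
  S <- ifelse(gy >= y_T & gy <= y_B, 1,
        ifelse(gy > y_B & gy < y_B + taper,
               0.5 * (1 + cos(pi * (gy - y_B) / taper)),
        ifelse(gy < y_T & gy > y_T - taper,
               0.5 * (1 + cos(pi * (y_T - gy) / taper)), 0)))
  D <- S * alpha * exp(-gx^2 / (2 * sg^2))
  verts <- cbind(gx + D * e2[1], gy + D * e2[2], base_z + D * e2[3])

  nx <- length(xs); ny <- length(ys)
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (j - 1L) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  if (spec$noise_sd > 0) {
    vn <- .vertex_normals(verts, faces)
    verts <- .with_seed(spec$seed,
                        verts + stats::rnorm(nrow(verts), sd = spec$noise_sd) * vn)
  }
  mesh <- triangle_mesh(verts, faces)

  x_e <- 0.28 * spec$face_width
  z_e <- zb(x_e, 0)
  landmarks <- landmark_set(
    left_eye = c(x_e, 0, z_e),
    right_eye = c(-x_e, 0, z_e),
    chin = c(0, -ec, z_e),
    nose_tip = crest(y_tip, h_B),
    nose_bridge = crest(y_B, h_B))

  truth <- facial_parameters(ec, A, sg, spec$ridge_angle, 0)
  list(mesh = mesh, landmarks = landmarks, truth = truth, spec = spec)
}

#' Specification of a synthetic cohort
#'
#' Independent normal draws per parameter (no covariance structure),
#' winsorised at 3 standard deviations to keep all values positive and
#' bounded. Defaults reproduce the moments implied by the bundled reference
#' sizing table.
#'
#' @param n Number of records.
#' @param eye_to_chin_mu,eye_to_chin_sd Eye-to-chin moments, mm.
#' @param sigma_mu,sigma_sd Nasal spread moments, mm.
#' @param A_mu,A_sd Nasal amplitude moments, mm.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 10000L, eye_to_chin_mu = 104.85,
                        eye_to_chin_sd = 6.37, sigma_mu = 10.1,
                        sigma_sd = 0.68, A_mu = 23.3, A_sd = 1.0,
                        seed = 1L) {
  if (n < 1L)
    stop("cohort size must be at least 1")
  if (any(c(eye_to_chin_sd, sigma_sd, A_sd) < 0))
    stop("standard deviations must be non-negative")
  if (any(c(eye_to_chin_mu, sigma_mu, A_mu) <= 0))
    stop("means must be positive")
  structure(list(n = as.integer(n), eye_to_chin_mu = eye_to_chin_mu,
                 eye_to_chin_sd = eye_to_chin_sd, sigma_mu = sigma_mu,
                 sigma_sd = sigma_sd, A_mu = A_mu, A_sd = A_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of facial parameters
#'
#' @param spec A [cohort_spec()].
#' @return Cohort data frame with columns `subject_id`, `eye_to_chin`, `A`,
#'   `sigma`.
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  winsor <- function(x, mu, sd) pmin(pmax(x, mu - 3 * sd), mu + 3 * sd)
  .with_seed(spec$seed, {
    ec <- winsor(stats::rnorm(spec$n, spec$eye_to_chin_mu, spec$eye_to_chin_sd),
                 spec$eye_to_chin_mu, spec$eye_to_chin_sd)
    sg <- winsor(stats::rnorm(spec$n, spec$sigma_mu, spec$sigma_sd),
                 spec$sigma_mu, spec$sigma_sd)
    A <- winsor(stats::rnorm(spec$n, spec$A_mu, spec$A_sd),
                spec$A_mu, spec$A_sd)
    data.frame(subject_id = sprintf("S%06d", seq_len(spec$n)),
               eye_to_chin = ec, A = A, sigma = sg,
               stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic leak video
#'
#' A dark background with a mild horizontal brightness gradient and a bright
#' vapour disc whose area follows a known schedule: zero before
#' `injection_time`, then growing at `plume_area_rate` px/s, optionally
#' saturating at `plateau_area` px (a sealed mask whose count stabilises at
#' the filter-area level).
#'
#' @param width,height Frame size in pixels.
#' @param fps Frames per second.
#' @param duration Recording length, s.
#' @param injection_time Vapour injection time, s (must precede `duration`).
#' @param plume_area_rate Disc area growth rate, px/s.
#' @param plateau_area Optional saturation area, px.
#' @param noise_sd Greyscale noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `leak_video_spec`.
#' @export
leak_video_spec <- function(width = 96L, height = 96L, fps = 250,
                            duration = 6, injection_time = 1,
                            plume_area_rate = 0, plateau_area = NULL,
                            noise_sd = 0.5, seed = 1L) {
  if (injection_time >= duration)
    stop("injection_time must precede the end of the recording")
  if (plume_area_rate < 0 || (!is.null(plateau_area) && plateau_area < 0))
    stop("area rates must be non-negative")
  if (noise_sd < 0)
    stop("noise_sd must be non-negative")
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration = duration,
                 injection_time = injection_time,
                 plume_area_rate = plume_area_rate,
                 plateau_area = plateau_area, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "leak_video_spec")
}

#' Generate a synthetic leak video with known escape area
#'
#' The disc intensity sits 20 greyscale units above the background, well
#' clear of the detection threshold. The returned ground truth gives the
#' exact rasterised disc pixel count at the first frame of each analysis
#' window of `cfg`.
#'
#' @param spec A [leak_video_spec()].
#' @param cfg A [flowviz_config()] defining the analysis windows for the
#'   ground-truth series.
#' @return List with `stack` ([frame_stack()]), `truth` (data frame with
#'   `time` s and `area_px`), and `spec`.
#' @export
synth_leak_video <- function(spec = leak_video_spec(),
                             cfg = flowviz_config()) {
  stopifnot(inherits(spec, "leak_video_spec"), inherits(cfg, "flowviz_config"))
  h <- spec$height; w <- spec$width
  nf <- round(spec$duration * spec$fps)
  if (nf < 30L)
    stop("video too short: ", nf, " frames")
  t <- (seq_len(nf) - 1L) / spec$fps
  area_at <- function(tt) {
    a <- numeric(length(tt))
    on <- tt >= spec$injection_time
    if (!is.null(spec$plateau_area)) {
      rate <- if (spec$plume_area_rate > 0) spec$plume_area_rate
              else spec$plateau_area / 0.5
      a[on] <- pmin(rate * (tt[on] - spec$injection_time), spec$plateau_area)
    } else {
      a[on] <- spec$plume_area_rate * (tt[on] - spec$injection_time)
    }
    a
  }
  areas <- area_at(t)
  cy <- h / 2; cx <- 0.4 * w
  r_max <- sqrt(max(areas) / pi)
  if (r_max > min(cy, h - cy, cx, w - cx) - 2)
    stop("plume would exceed the frame (max radius ", signif(r_max, 4),
         " px); enlarge the frame or reduce the area schedule")
  col_idx <- matrix(rep(seq_len(w), each = h), h, w)
  row_idx <- matrix(rep(seq_len(h), w), h, w)
  d2 <- (row_idx - cy)^2 + (col_idx - cx)^2
  bg <- 20 + 30 * (col_idx - 1) / (w - 1)
  frames <- array(0, c(h, w, nf))
  for (k in seq_len(nf)) {
    fr <- bg
    if (areas[k] > 0)
      fr <- fr + 20 * (d2 <= areas[k] / pi)
    frames[, , k] <- fr
  }
  if (spec$noise_sd > 0) {
    frames <- .with_seed(spec$seed,
                         frames + array(stats::rnorm(length(frames),
                                                     sd = spec$noise_sd),
                                        dim(frames)))
    frames[frames < 0] <- 0
    frames[frames > 255] <- 255
  }
  starts <- seq(1L, nf - cfg$window + 1L, by = cfg$stride)
  # a pixel switching on at in-window frame j is averaged over (window - j)
  # frames; it clears the threshold when its on-fraction exceeds
  # threshold / amplitude, so the exact expected count of a growing disc is
  # its area at the last qualifying onset frame
  k_on <- min(floor(cfg$window * (1 - cfg$threshold / 20)),
              cfg$window - 1L)
  ref <- pmin(starts + k_on, nf)
  truth <- data.frame(time = (starts - 1L) / spec$fps,
                      area_px = vapply(ref, function(s)
                        sum(d2 <= areas[s] / pi), numeric(1)))
  list(stack = frame_stack(frames, spec$fps), truth = truth, spec = spec)
}
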