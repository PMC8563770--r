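# Seal-leak quantification from high-speed greyscale footage: background
# subtraction, thresholding, despeckling, brightness scaling, vapour pixel
# counts over time, and a post-transient least-squares leak slope.

#' Construct a frame stack
#'
#' An ordered stack of greyscale frames with a common size and a frame rate.
#' Pixel values are greyscale units in `[0, 255]`.
#'
#' @param frames Numeric 3D array `height x width x n_frames`.
#' @param fps Frames per second (> 0).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a height x width x n_frames array")
  if (dim(frames)[3] < 30L)
    stop("a frame stack needs at least 30 frames")
  if (!is.finite(fps) || fps <= 0)
    stop("fps must be positive")
  rng <- range(frames)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("frame values must be finite greyscale units in [0, 255]")
  structure(list(frames = frames, fps = fps), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %dx%d px at %g fps (%.2f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Flow-visualisation analysis configuration
#'
#' @param background_frames Number of leading frames averaged into the
#'   background image (default 5).
#' @param window Frames per analysis mean image (default 10).
#' @param stride Frames between successive analysis windows (default 25; at
#'   250 fps this is one window every 0.1 s).
#' @param threshold Absolute greyscale deviation below which a pixel is
#'   treated as showing no change (default 3).
#' @param scale_max Upper bound of the brightness scaling factor applied to
#'   surviving deviations, `s(b) = 1 + (scale_max - 1) b / b_max` with `b`
#'   the background value (default 2). Scaling affects displayed intensity
#'   only, never mask membership.
#' @param despeckle Despeckle rule for the thresholded mask:
#'   `"isolated"` (default) clears nonzero pixels with no nonzero
#'   8-neighbour; `"median"` applies a 3x3 binary median (majority of 9).
#' @param transient_frac Fraction of the maximum count that marks the end of
#'   the initial transient (default 0.9).
#' @param transient_end Optional fixed transient end time in seconds,
#'   overriding the `transient_frac` rule.
#' @param filter_area Optional reference pixel count corresponding to the
#'   filter area, carried into summaries.
#' @return An object of class `flowviz_config`.
#' @export
flowviz_config <- function(background_frames = 5L, window = 10L, stride = 25L,
                           threshold = 3, scale_max = 2,
                           despeckle = c("isolated", "median"),
                           transient_frac = 0.9, transient_end = NULL,
                           filter_area = NULL) {
  despeckle <- match.arg(despeckle)
  if (background_frames < 1L || window < 1L || stride < 1L)
    stop("background_frames, window and stride must be positive integers")
  if (threshold < 0)
    stop("threshold must be non-negative")
  if (scale_max <= 1)
    stop("scale_max must exceed 1")
  if (window > stride)
    warning("window (", window, ") exceeds stride (", stride,
            "); analysis windows overlap")
  structure(list(background_frames = as.integer(background_frames),
                 window = as.integer(window), stride = as.integer(stride),
                 threshold = threshold, scale_max = scale_max,
                 despeckle = despeckle, transient_frac = transient_frac,
                 transient_end = transient_end, filter_area = filter_area),
            class = "flowviz_config")
}

#' Background image of a frame stack
#'
#' Pixelwise arithmetic mean of the first `background_frames` frames,
#' mitigating minor frame-to-frame variation before injection.
#'
#' @param stack A [frame_stack()].
#' @param cfg A [flowviz_config()].
#' @return Numeric matrix, same size as one frame.
#' @export
background_image <- function(stack, cfg = flowviz_config()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(cfg, "flowviz_config"))
  k <- cfg$background_frames
  if (dim(stack$frames)[3] < k)
    stop("stack has fewer frames (", dim(stack$frames)[3],
         ") than background_frames (", k, ")")
  rowMeans(stack$frames[, , seq_len(k), drop = FALSE], dims = 2)
}

#' Windowed mean images of a frame stack
#'
#' For `k = 0, 1, ...` the mean of frames `[k stride + 1, k stride + window]`
#' with time stamp `(k stride) / fps` seconds.
#'
#' @param stack A [frame_stack()].
#' @param cfg A [flowviz_config()].
#' @return List with `images` (array `h x w x n_windows`) and `times`
#'   (seconds).
#' @export
window_means <- function(stack, cfg = flowviz_config()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(cfg, "flowviz_config"))
  nf <- dim(stack$frames)[3]
  starts <- seq(1L, nf - cfg$window + 1L, by = cfg$stride)
  if (length(starts) < 1L)
    stop("stack too short for a single analysis window")
  d <- dim(stack$frames)
  images <- array(0, c(d[1], d[2], length(starts)))
  for (k in seq_along(starts)) {
    images[, , k] <- rowMeans(
      stack$frames[, , starts[k] + seq_len(cfg$window) - 1L, drop = FALSE],
      dims = 2)
  }
  list(images = images, times = (starts - 1L) / stack$fps)
}

# 3x3 neighbourhood sum (zero padding) used by both despeckle rules.
.boxsum3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z_r <- matrix(0, 1L, nc)
  up <- rbind(m[-1L, , drop = FALSE], z_r)
  dn <- rbind(z_r, m[-nr, , drop = FALSE])
  vert <- m + up + dn
  z_c <- matrix(0, nr, 1L)
  cbind(vert[, -1L, drop = FALSE], z_c) + vert +
    cbind(z_c, vert[, -nc, drop = FALSE])
}

.despeckle_mask <- function(mask, method) {
  m <- mask * 1
  s <- .boxsum3(m)
  if (method == "isolated") {
    mask & (s - m >= 1)        # at least one nonzero 8-neighbour
  } else {
    s >= 5                     # binary 3x3 median = majority of 9
  }
}

#' Deviation map and vapour mask for one analysis window
#'
#' The background is subtracted from the window mean; absolute deviations
#' below the threshold are zeroed; the nonzero mask is despeckled; surviving
#' deviation magnitudes are scaled by `s(b) = 1 + (scale_max - 1) b / b_max`
#' with `b` the background value at that pixel, compensating uneven scene
#' brightness in the rendered output. Scaling never changes mask membership,
#' so pixel counts are independent of it.
#'
#' @param window_image Numeric matrix (a window mean).
#' @param background Numeric matrix from [background_image()].
#' @param cfg A [flowviz_config()].
#' @return List with `deviation` (scaled absolute deviation, zero where
#'   masked out) and `mask` (logical matrix of vapour pixels).
#' @export
deviation_map <- function(window_image, background, cfg = flowviz_config()) {
  stopifnot(inherits(cfg, "flowviz_config"))
  if (!all(dim(window_image) == dim(background)))
    stop("window image and background dimensions differ")
  d <- window_image - background
  d[abs(d) < cfg$threshold] <- 0
  mask <- .despeckle_mask(d != 0, cfg$despeckle)
  bmax <- max(background)
  s <- if (bmax > 0) 1 + (cfg$scale_max - 1) * background / bmax else 1
  dev <- abs(d) * s
  dev[!mask] <- 0
  list(deviation = dev, mask = mask)
}

#' Vapour pixel counts over time
#'
#' Applies [background_image()], [window_means()] and [deviation_map()] to a
#' stack and counts the vapour-mask pixels of each analysis window: a
#' semi-quantitative measure of vapour escape against time.
#'
#' @param stack A [frame_stack()].
#' @param cfg A [flowviz_config()].
#' @return An object of class `leak_series`: list with `times` (s) and
#'   `counts` (non-negative integers).
#' @export
vapour_counts <- function(stack, cfg = flowviz_config()) {
  bg <- background_image(stack, cfg)
  wm <- window_means(stack, cfg)
  counts <- integer(length(wm$times))
  for (k in seq_along(wm$times))
    counts[k] <- sum(deviation_map(wm$images[, , k], bg, cfg)$mask)
  structure(list(times = wm$times, counts = counts), class = "leak_series")
}

#' @export
print.leak_series <- function(x, ...) {
  cat(sprintf("leak_series: %d windows over %.2f s, counts %d..%d px\n",
              length(x$times), max(x$times), min(x$counts), max(x$counts)))
  invisible(x)
}

#' Post-transient leak summary
#'
#' The initial transient (the mask volume filling with vapour) ends at the
#' first time the count reaches `transient_frac` of its maximum, unless a
#' fixed `transient_end` is configured. An ordinary least-squares line is
#' fitted to the counts from that time on; its slope grades the severity of
#' the leak (large slope: vapour escaping quickly; near zero: sealed, counts
#' plateau near the filter-area count).
#'
#' @param series A `leak_series` from [vapour_counts()].
#' @param cfg A [flowviz_config()].
#' @return An object of class `leak_summary`: list with `slope` (px/s),
#'   `transient_end` (s), `plateau_count` (mean post-transient count),
#'   `n_points`, and `filter_area_reference`.
#' @export
leak_summary <- function(series, cfg = flowviz_config()) {
  stopifnot(inherits(series, "leak_series"), inherits(cfg, "flowviz_config"))
  t <- series$times
  y <- series$counts
  if (is.null(cfg$transient_end)) {
    te <- t[which(y >= cfg$transient_frac * max(y))[1]]
  } else {
    te <- cfg$transient_end
    if (te < min(t) || te > max(t))
      stop("configured transient_end (", te, " s) is outside the recording span")
  }
  post <- t >= te
  if (sum(post) < 5L)
    stop("only ", sum(post), " post-transient points (need >= 5); ",
         "lower transient_frac or set transient_end")
  fit <- stats::lm(y[post] ~ t[post])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 transient_end = te,
                 plateau_count = mean(y[post]),
                 n_points = sum(post),
                 filter_area_reference = cfg$filter_area),
            class = "leak_summary")
}

#' @export
print.leak_summary <- function(x, ...) {
  cat(sprintf(paste0("leak_summary: slope %.2f px/s over %d points after ",
                     "%.2f s (plateau %.1f px)\n"),
              x$slope, x$n_points, x$transient_end, x$plateau_count))
  if (!is.null(x$filter_area_reference))
    cat(sprintf("  filter-area reference: %d px\n",
                as.integer(x$filter_area_reference)))
  invisible(x)
}

#' Render false-colour vapour overlays
#'
#' Writes one PNG per analysis window: the background image in greyscale
#' with vapour-mask pixels coloured by scaled deviation intensity (black
#' body palette). Purely presentational; the mask is identical to the one
#' counted by [vapour_counts()].
#'
#' @param stack A [frame_stack()].
#' @param cfg A [flowviz_config()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
render_overlay <- function(stack, cfg = flowviz_config(), out_dir) {
  bg <- background_image(stack, cfg)
  wm <- window_means(stack, cfg)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  grey <- bg / 255
  ramp <- grDevices::colorRamp(c("#400000", "red", "orange", "yellow"))
  paths <- character(dim(wm$images)[3])
  for (k in seq_along(paths)) {
    dm <- deviation_map(wm$images[, , k], bg, cfg)
    img <- array(grey, c(dim(bg), 3L))
    if (any(dm$mask)) {
      v <- dm$deviation[dm$mask]
      cols <- ramp(pmin(v / max(v), 1)) / 255
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[dm$mask] <- cols[, ch]
        img[, , ch] <- plane
      }
    }
    paths[k] <- file.path(out_dir, sprintf("overlay_%04d.png", k))
    png::writePNG(img, paths[k])
  }
  invisible(paths)
}

#' Read a numbered greyscale image sequence as a frame stack
#'
#' PNG files are read in lexicographic order; RGB images are converted to
#' greyscale by channel averaging, and values are rescaled to `[0, 255]`.
#'
#' @param dir Directory containing the frames, or a character vector of file
#'   paths.
#' @param fps Frame rate of the recording.
#' @param pattern Filename pattern when `dir` is a directory.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(dir, fps, pattern = "\\.png$") {
  files <- if (length(dir) == 1L && dir.exists(dir))
    sort(list.files(dir, pattern = pattern, full.names = TRUE))
  else as.character(dir)
  if (length(files) == 0L)
    stop("no frames found in ", paste(dir, collapse = ", "))
  read1 <- function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L)
      img <- rowMeans(img[, , 1:3, drop = FALSE], dims = 2)
    img * 255
  }
  first <- read1(files[1])
  frames <- array(0, c(dim(first), length(files)))
  frames[, , 1] <- first
  for (i in seq_along(files)[-1]) {
    fr <- read1(files[i])
    if (!all(dim(fr) == dim(first)))
      stop("frame ", files[i], " has different dimensions")
    frames[, , i] <- fr
  }
  frame_stack(frames, fps)
}

#' Write a frame stack as a numbered PNG sequence
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  n <- dim(stack$frames)[3]
  paths <- file.path(dir, sprintf("frame_%05d.png", seq_len(n)))
  for (i in seq_len(n))
    png::writePNG(stack$frames[, , i] / 255, paths[i])
  invisible(paths)
}
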