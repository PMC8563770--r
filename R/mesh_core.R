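# Triangle meshes, STL I/O, anatomical orientation, and surface deviation.

#' Construct a triangle mesh
#'
#' A `triangle_mesh` is a triangulated surface: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of faces indexing
#' those vertices. All coordinates must be finite, every face index must refer
#' to an existing vertex, and at least one face is required.
#'
#' @param vertices Numeric matrix (or coercible) with 3 columns, one row per
#'   vertex, coordinates in mm.
#' @param faces Integer matrix with 3 columns, one row per triangular face,
#'   1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("`vertices` must have 3 columns (x, y, z in mm)")
  if (ncol(faces) != 3L)
    stop("`faces` must have 3 columns of vertex indices")
  if (nrow(faces) < 1L)
    stop("mesh must have at least one face")
  if (!all(is.finite(vertices)))
    stop("mesh vertices contain non-finite coordinates")
  if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices must reference existing vertices (1..", nrow(vertices), ")")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Construct a facial landmark set
#'
#' Five anatomical landmarks, each a 3D point in mm and in the same frame as
#' the mesh they annotate: the two outer eye corners, the lowest midline chin
#' point, the nose tip, and the top of the nasal ridge (bridge).
#'
#' @param left_eye,right_eye,chin,nose_tip,nose_bridge Numeric length-3 points
#'   (mm).
#' @return An object of class `landmark_set` (a named list of points).
#' @export
landmark_set <- function(left_eye, right_eye, chin, nose_tip, nose_bridge) {
  lm <- list(left_eye = left_eye, right_eye = right_eye, chin = chin,
             nose_tip = nose_tip, nose_bridge = nose_bridge)
  for (nm in names(lm)) {
    p <- as.numeric(lm[[nm]])
    if (length(p) != 3L || !all(is.finite(p)))
      stop("landmark '", nm, "' must be a finite 3D point")
    lm[[nm]] <- p
  }
  if (sqrt(sum((lm$left_eye - lm$right_eye)^2)) < 1e-9)
    stop("degenerate landmarks: left_eye and right_eye coincide")
  ex <- lm$left_eye - lm$right_eye
  cv <- lm$chin - (lm$left_eye + lm$right_eye) / 2
  cr <- .cross3(ex, cv)
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(ex^2)) * max(sqrt(sum(cv^2)), 1e-12))
    stop("degenerate landmarks: chin is collinear with the eye landmarks")
  structure(lm, class = "landmark_set")
}

#' Read a landmark sidecar file
#'
#' JSON with keys `left_eye`, `right_eye`, `chin`, `nose_tip`, `nose_bridge`,
#' each an `[x, y, z]` array in mm.
#'
#' @param path Path to the JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("landmark file not found: ", path)
  lst <- jsonlite::fromJSON(path)
  need <- c("left_eye", "right_eye", "chin", "nose_tip", "nose_bridge")
  miss <- setdiff(need, names(lst))
  if (length(miss))
    stop("landmark file ", path, " is missing keys: ", paste(miss, collapse = ", "))
  do.call(landmark_set, lst[need])
}

#' Write a landmark sidecar file
#'
#' @param landmarks A [landmark_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Construct a rigid transform
#'
#' A proper rigid-body transform `p -> R p + t`. The rotation must be
#' orthonormal with determinant +1 (tolerance 1e-9).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points, a mesh, or landmarks
#'
#' @param x A `triangle_mesh`, `landmark_set`, or numeric point matrix/vector.
#' @param transform A [rigid_transform()].
#' @return An object of the same type as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- transform$rotation
  t <- transform$translation
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices %*% t(R)
    v <- sweep(v, 2, t, "+")
    return(triangle_mesh(v, x$faces))
  }
  if (inherits(x, "landmark_set")) {
    out <- lapply(unclass(x), function(p) as.numeric(R %*% p + t))
    return(do.call(landmark_set, out))
  }
  if (is.matrix(x)) {
    return(sweep(x %*% t(R), 2, t, "+"))
  }
  as.numeric(R %*% as.numeric(x) + t)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` is the transform that applies `a` first,
#' then `b`.
#'
#' @param b,a [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# ---------------------------------------------------------------------------
# STL I/O

# Merge vertices that coincide within `tol` mm so faces share vertices.
# STL stores each triangle independently; merging is required before any
# surface query (sections, nearest-point distances).
.merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- match(key, key)
  keep <- sort(unique(first))
  remap <- match(first, keep)
  v <- vertices[keep, , drop = FALSE]
  f <- matrix(remap[faces], ncol = 3L)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  if (nrow(f) == 0L) stop("mesh is empty after merging degenerate faces")
  list(vertices = v, faces = f)
}

#' Read an STL file (binary or ASCII)
#'
#' Detects the dialect automatically. Duplicate vertices within 1e-6 mm are
#' merged so that faces share vertices, as required for surface queries.
#'
#' @param path Path to an STL file.
#' @param merge_tol Vertex merge tolerance in mm.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path))
    stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15)
    stop("malformed STL (file too small): ", path)
  is_binary <- FALSE
  if (size >= 84) {
    hdr <- readBin(path, "raw", n = 84L)
    ntri <- readBin(hdr[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && ntri > 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    raw <- readBin(path, "raw", n = size)
    ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    # each 50-byte record: 12 little-endian float32 (normal + 3 vertices)
    # followed by a 2-byte attribute count
    idx <- outer(1:48, 84 + (seq_len(ntri) - 1) * 50, "+")
    vals <- readBin(raw[as.vector(idx)], "numeric", size = 4L,
                    n = 12L * ntri, endian = "little")
    m <- matrix(vals, nrow = 12L)
    verts <- matrix(rbind(m[4:6, ], m[7:9, ], m[10:12, ]), ncol = 3L,
                    byrow = TRUE)
    if (!all(is.finite(verts)))
      stop("malformed binary STL (non-finite vertex data): ", path)
  } else {
    txt <- readLines(path, warn = FALSE)
    toks <- scan(text = txt[grepl("vertex", txt, fixed = TRUE)],
                 what = character(), quiet = TRUE)
    vi <- which(toks == "vertex")
    if (length(vi) == 0L)
      stop("malformed ASCII STL (no vertex records): ", path)
    if (length(vi) %% 3L != 0L)
      stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
    coords <- suppressWarnings(
      cbind(as.numeric(toks[vi + 1L]), as.numeric(toks[vi + 2L]),
            as.numeric(toks[vi + 3L])))
    if (anyNA(coords))
      stop("malformed ASCII STL (non-numeric vertex coordinates): ", path)
    verts <- coords
  }
  ntri <- nrow(verts) / 3L
  if (ntri < 1L)
    stop("empty STL mesh: ", path)
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  mg <- .merge_vertices(verts, faces, merge_tol)
  triangle_mesh(mg$vertices, mg$faces)
}

.face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n / len
}

#' Write an STL file
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- .face_normals(mesh)
  ntri <- nrow(f)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "facefit binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(ntri), con, size = 4L, endian = "little")
    data12 <- rbind(t(nrm), t(v[f[, 1], , drop = FALSE]),
                    t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    fr <- matrix(writeBin(as.vector(data12), raw(), size = 4L,
                          endian = "little"), nrow = 48L)
    writeBin(as.vector(rbind(fr, matrix(as.raw(0), 2L, ntri))), con)
  } else {
    fmt_pt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    lines <- c("solid facefit",
               as.vector(rbind(
                 paste0("  facet normal ", fmt_pt(nrm)),
                 "    outer loop",
                 paste0("      vertex ", fmt_pt(v[f[, 1], , drop = FALSE])),
                 paste0("      vertex ", fmt_pt(v[f[, 2], , drop = FALSE])),
                 paste0("      vertex ", fmt_pt(v[f[, 3], , drop = FALSE])),
                 "    endloop",
                 "  endfacet")),
               "endsolid facefit")
    writeLines(lines, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Orientation

#' Orient a facial mesh into the canonical anatomical frame
#'
#' The canonical frame has its origin at the midpoint of the two eye
#' landmarks, the x-axis along the eye-to-eye direction, the y-axis vertical
#' with the chin at negative y, and the z-axis anterior (the nose tip has the
#' largest z among the landmarks). The x-axis sign is chosen so that the
#' frame is right-handed with an anterior z-axis, which makes the
#' construction deterministic and idempotent.
#'
#' @param mesh A [triangle_mesh()].
#' @param landmarks A [landmark_set()] in the same frame as `mesh`; all
#'   landmarks must lie within the mesh bounding box.
#' @return A list with elements `mesh` (the oriented mesh), `transform` (the
#'   [rigid_transform()] mapping input coordinates into the canonical frame),
#'   and `landmarks` (the landmarks in the canonical frame).
#' @export
orient_face <- function(mesh, landmarks) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(landmarks, "landmark_set"))
  bb <- apply(mesh$vertices, 2, range)
  margin <- 1e-6 + 1e-9 * max(abs(bb))
  for (nm in names(landmarks)) {
    p <- landmarks[[nm]]
    if (any(p < bb[1, ] - margin) || any(p > bb[2, ] + margin))
      stop("landmark '", nm, "' lies outside the mesh bounding box")
  }
  origin <- (landmarks$left_eye + landmarks$right_eye) / 2
  xhat <- .unit(landmarks$left_eye - landmarks$right_eye)
  tvec <- landmarks$chin - origin
  yraw <- tvec - sum(tvec * xhat) * xhat
  if (sqrt(sum(yraw^2)) < 1e-9)
    stop("degenerate landmarks: chin is collinear with the eye landmarks")
  yhat <- -.unit(yraw)                       # chin at negative y
  zhat <- .cross3(xhat, yhat)
  if (sum((landmarks$nose_tip - origin) * zhat) < 0) {
    xhat <- -xhat
    zhat <- -zhat
  }
  R <- rbind(xhat, yhat, zhat)
  dimnames(R) <- NULL
  tf <- rigid_transform(R, as.numeric(-R %*% origin))
  lm2 <- apply_transform(landmarks, tf)
  if (lm2$nose_tip[3] <= max(lm2$chin[3], lm2$left_eye[3], lm2$right_eye[3]))
    stop("degenerate landmarks: nose_tip is not anterior to the ",
         "eye/chin landmarks")
  list(mesh = apply_transform(mesh, tf), transform = tf, landmarks = lm2)
}

# ---------------------------------------------------------------------------
# Deviation maps

# Nearest points on a set of triangles from a single point p.
# Triangles given as row-matrices A, B, C. Returns squared distances.
# Case analysis follows the standard closest-point-on-triangle construction.
.point_tri_dist2 <- function(p, A, B, C) {
  ab <- B - A
  ac <- C - A
  ap <- sweep(-A, 2, p, "+")
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2, p, "+")
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2, p, "+")
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  n <- nrow(A)
  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set <- function(idx, pts) {
    res[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  i <- !done & d1 <= 0 & d2 <= 0
  if (any(i)) set(i, A[i, , drop = FALSE])
  i <- !done & d3 >= 0 & d4 <= d3
  if (any(i)) set(i, B[i, , drop = FALSE])
  i <- !done & d6 >= 0 & d5 <= d6
  if (any(i)) set(i, C[i, , drop = FALSE])
  vc <- d1 * d4 - d3 * d2
  i <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(i)) {
    t <- d1[i] / (d1[i] - d3[i])
    set(i, A[i, , drop = FALSE] + t * ab[i, , drop = FALSE])
  }
  vb <- d5 * d2 - d1 * d6
  i <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(i)) {
    t <- d2[i] / (d2[i] - d6[i])
    set(i, A[i, , drop = FALSE] + t * ac[i, , drop = FALSE])
  }
  va <- d3 * d6 - d5 * d4
  i <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(i)) {
    t <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
    set(i, B[i, , drop = FALSE] + t * (C[i, , drop = FALSE] - B[i, , drop = FALSE]))
  }
  i <- !done
  if (any(i)) {
    denom <- 1 / (va[i] + vb[i] + vc[i])
    v <- vb[i] * denom
    w <- vc[i] * denom
    set(i, A[i, , drop = FALSE] + v * ab[i, , drop = FALSE] +
          w * ac[i, , drop = FALSE])
  }
  diff <- sweep(res, 2, p, "-")
  rowSums(diff^2)
}

#' Unsigned deviation of a query mesh from a reference surface
#'
#' For every vertex of `query`, the Euclidean distance to the nearest point
#' anywhere on the `reference` surface (not just its vertices). Meshes are
#' assumed to be pre-aligned; use [orient_face()] first. Faces are pruned per
#' query vertex with a centroid/bounding-radius test before the exact
#' point-to-triangle distance is evaluated, so the computation is exact.
#'
#' @param query,reference [triangle_mesh()] objects.
#' @return An object of class `deviation_map`: list with `per_vertex_distance`
#'   (mm, one per query vertex) and `summary` (`mean`, `max` in mm).
#' @export
mesh_deviation <- function(query, reference) {
  stopifnot(inherits(query, "triangle_mesh"), inherits(reference, "triangle_mesh"))
  v <- reference$vertices
  f <- reference$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  cen <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cen)^2),
                   rowSums((B - cen)^2),
                   rowSums((C - cen)^2)))
  q <- query$vertices
  nq <- nrow(q)
  d <- numeric(nq)
  for (i in seq_len(nq)) {
    p <- q[i, ]
    dc <- sqrt(rowSums(sweep(cen, 2, p, "-")^2))
    ub <- min(dc + rad)
    cand <- which(dc - rad <= ub + 1e-12)
    d2 <- .point_tri_dist2(p, A[cand, , drop = FALSE],
                           B[cand, , drop = FALSE], C[cand, , drop = FALSE])
    d[i] <- sqrt(max(min(d2), 0))
  }
  structure(list(per_vertex_distance = d,
                 summary = list(mean = mean(d), max = max(d))),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat(sprintf("deviation_map: %d vertices, mean %.4f mm, max %.4f mm\n",
              length(x$per_vertex_distance), x$summary$mean, x$summary$max))
  invisible(x)
}
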