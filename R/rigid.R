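#' Rigid (6-DOF) world-space transforms
#'
#' A rigid transform is stored as a homogeneous 4x4 matrix acting on world
#' coordinates in mm, together with its six parameters: rotations about the
#' world x, y, z axes in degrees (applied as Rz Ry Rx about the origin) and a
#' translation in mm. The rotation block must be orthonormal with
#' determinant +1.
#'
#' @param matrix numeric 4x4 homogeneous rigid matrix.
#' @return An object of class `rigid_transform` with elements `matrix` and
#'   `parameters` (named rx, ry, rz in degrees; tx, ty, tz in mm).
#' @examples
#' t1 <- rigid_from_params(c(0, 0, 30), c(10, 0, 0))
#' rigid_params(t1)
#' h <- halfway_decompose(t1)
#' max(abs(rigid_compose(h$forward_half, h$forward_half)$matrix - t1$matrix))
#' @export
rigid_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (!identical(dim(m), c(4L, 4L)) || any(!is.finite(m)))
    stop("rigid transform must be a finite 4x4 matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last row of a rigid transform must be (0, 0, 0, 1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation block is not orthonormal")
  if (det(R) < 0)
    stop("rotation block has determinant -1 (reflection, not a rotation)")
  # re-orthonormalize via polar decomposition to keep composition stable
  s <- svd(R)
  R <- s$u %*% t(s$v)
  m[1:3, 1:3] <- R
  m[4, ] <- c(0, 0, 0, 1)
  structure(list(matrix = m, parameters = euler_from_matrix(m)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param rotations_deg rotations about x, y, z in degrees.
#' @param translations_mm translation in mm.
#' @export
rigid_from_params <- function(rotations_deg = c(0, 0, 0),
                              translations_mm = c(0, 0, 0)) {
  stopifnot(length(rotations_deg) == 3, length(translations_mm) == 3)
  m <- diag(4)
  m[1:3, 1:3] <- rot3(rotations_deg)
  m[1:3, 4] <- translations_mm
  rigid_transform(m)
}

#' @rdname rigid_transform
#' @param t a `rigid_transform`.
#' @export
rigid_params <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  t$parameters
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_from_params()

rot3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Euler angles (deg) for R = Rz Ry Rx, plus translation. Degenerate at
# ry = +/-90 deg, far outside serial-scan motion.
euler_from_matrix <- function(m) {
  R <- m[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx = rx, ry = ry, rz = rz) * 180 / pi -> ang
  c(ang, tx = m[1, 4], ty = m[2, 4], tz = m[3, 4])
}

#' Invert and compose rigid transforms
#'
#' `rigid_compose(a, b)` returns the transform applying `b` first, then `a`
#' (matrix product `a %*% b`).
#'
#' @param t,a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rigid_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- t$matrix[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t$matrix[1:3, 4]
  rigid_transform(m)
}

#' @rdname rigid_invert
#' @export
rigid_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$matrix %*% b$matrix)
}

# axis-angle of a rotation matrix; angle in [0, pi]
axis_angle <- function(R) {
  angle <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (angle < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(angle - pi) < 1e-7) {
    # axis from the dominant column of R + I
    B <- R + diag(3)
    k <- which.max(colSums(B^2))
    ax <- B[, k] / sqrt(sum(B[, k]^2))
    return(list(axis = ax, angle = angle))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  list(axis = ax, angle = angle)
}

rodrigues <- function(axis, angle) {
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Halfway (square-root) decomposition of a rigid transform
#'
#' Splits the full baseline-to-follow-up transform into a forward half
#' (baseline to intermediate) and a backward half (follow-up to
#' intermediate). The forward half is the rigid square root of the full
#' transform: same rotation axis at half the angle, with the translation
#' solved so that applying the half twice reproduces the full transform
#' exactly. The backward half is `forward_half` composed with the inverse
#' of the full transform. Applying half the motion to each scan shares the
#' interpolation burden symmetrically between timepoints.
#'
#' @param full a [rigid_transform()], baseline world to follow-up world.
#' @return An object of class `halfway_pair`: list with `forward_half`,
#'   `backward_half`, and `full`.
#' @export
halfway_decompose <- function(full) {
  stopifnot(inherits(full, "rigid_transform"))
  aa <- axis_angle(full$matrix[1:3, 1:3])
  if (abs(aa$angle - pi) < 1e-6)
    stop("rotation angle is within 1e-6 of 180 degrees; ",
         "the rigid square root direction is ill-defined")
  Rh <- rodrigues(aa$axis, aa$angle / 2)
  # t_half solves (Rh, t_half)^2 = (R, t):  (I + Rh) t_half = t
  th <- solve(diag(3) + Rh, full$matrix[1:3, 4])
  m <- diag(4)
  m[1:3, 1:3] <- Rh
  m[1:3, 4] <- th
  forward <- rigid_transform(m)
  backward <- rigid_compose(forward, rigid_invert(full))
  structure(list(forward_half = forward, backward_half = backward,
                 full = full),
            class = "halfway_pair")
}

#' @export
print.rigid_transform <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<rigid_transform> rot (%.4g, %.4g, %.4g) deg, trans (%.4g, %.4g, %.4g) mm\n",
    p[1], p[2], p[3], p[4], p[5], p[6]))
  invisible(x)
}

#' @export
print.halfway_pair <- function(x, ...) {
  cat("<halfway_pair>\n  full:     ")
  print(x$full)
  cat("  forward:  ")
  print(x$forward_half)
  cat("  backward: ")
  print(x$backward_half)
  invisible(x)
}

#' Plain-text 4x4 transform files
#'
#' Transforms are exchanged as four whitespace-separated rows of the world-mm
#' homogeneous matrix, one row per line.
#'
#' @param t a [rigid_transform()].
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform()]; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(apply(t$matrix, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop(sprintf("transform file not found: %s", path))
  rows <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 4 || any(lengths(rows) != 4))
    stop(sprintf("'%s' is not a 4-line 4-column transform file", path))
  rigid_transform(matrix(as.numeric(unlist(rows)), 4, 4, byrow = TRUE))
}
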