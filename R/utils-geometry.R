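# Small 3D vector helpers shared across the geometry modules. All coordinates
# are in millimetres; angles cross the package boundary in degrees only.

DEG <- 180 / pi

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    osic_stop(sprintf("%s must be 3 finite coordinates (mm)", what),
              "osic_invalid_point")
  }
  p
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) osic_stop("cannot normalize a zero vector", "osic_zero_vector")
  v / n
}

# Numerically stable angle between two vectors, in degrees.
angle_between <- function(u, v) {
  atan2(norm3(cross3(u, v)), sum(u * v)) * DEG
}

osic_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "osic_error")))
}

osic_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "osic_warning")))
}

#' Apply a rigid transform to points
#'
#' Rotates and translates one point (length-3 vector) or a matrix of points
#' (one point per row). Used throughout the test-bench to verify that angles
#' and widths are invariant under joint rigid motion of all inputs.
#'
#' @param points numeric length-3 vector or n x 3 matrix, mm.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric length-3 translation, mm.
#' @return transformed points in the same shape as the input.
#' @export
rigid_transform <- function(points, rotation, translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
  translation <- as_point3(translation, "translation")
  if (is.matrix(points)) {
    t(rotation %*% t(points)) + matrix(translation, nrow(points), 3L, byrow = TRUE)
  } else {
    as.numeric(rotation %*% as_point3(points)) + translation
  }
}

#' Draw a uniformly distributed random rotation matrix
#'
#' Uses the quaternion method: a standard-normal 4-vector, normalized, is
#' uniform on the unit quaternion sphere and maps to a uniform rotation.
#' Consumes the current RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @return a 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation_matrix <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards. Keeps scene generation deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
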