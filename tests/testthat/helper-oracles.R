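# Independent brute-force oracles for the geometric quantities. These follow
# different computational paths from the implementation (normalized dot
# products, dense sampling with numerical refinement, 2D embeddings) so that
# agreement is informative.

# Unsigned projected angle: project v onto the plane spanned by (ref, other)
# and measure the angle to the reference axis via the normalized dot product.
oracle_projected_angle <- function(v, plane = c("sagittal", "dorsal", "transverse")) {
  plane <- match.arg(plane)
  # component indices in anatomical coordinates (x, y, z)
  ix <- switch(plane,
               sagittal = c(ref = 1L, other = 3L),   # x-z plane, ref = craniocaudal
               dorsal = c(ref = 1L, other = 2L),     # x-y plane, ref = craniocaudal
               transverse = c(ref = 3L, other = 2L)) # z-y plane, ref = ventrodorsal
  p <- c(v[ix["ref"]], v[ix["other"]])
  n <- sqrt(sum(p^2))
  if (n == 0) return(NA_real_)
  acos(max(-1, min(1, p[1] / n))) * 180 / pi
}

# Safety angle by construction: sample points on the circle of radius r about
# S in the plane spanned by (E - I) and (S - I). Directions from I to circle
# points sweep the signed in-plane angles [alpha - beta, alpha + beta] (signs
# positive toward the S side), and the tangent line from I is the angular
# extreme, so the minimum signed angle over circle points is the safety angle
# (negative when the corridor is narrower than the implant). Dense grid plus
# numerical refinement.
oracle_safety_angle <- function(I, E, S, r) {
  u <- E - I
  w <- S - I
  alpha <- acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
  if (r == 0) return(alpha)
  # in-plane orthonormal basis: q1 toward S, q2 perpendicular (toward the axis
  # side when possible). The signed angle of (C - I) relative to q1 for circle
  # points C sweeps [-beta, beta] with beta < 90 degrees, so no wrap-around.
  q1 <- w / sqrt(sum(w^2))
  b <- u - sum(u * q1) * q1
  if (sqrt(sum(b * b)) < 1e-12) {
    b <- if (abs(q1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b <- b - sum(b * q1) * q1
  }
  q2 <- b / sqrt(sum(b * b))
  gamma_at <- function(t) {
    C <- S + r * (cos(t) * q1 + sin(t) * q2)
    d <- C - I
    atan2(sum(d * q2), sum(d * q1)) * 180 / pi
  }
  grid <- seq(0, 2 * pi, length.out = 721L)
  vals <- vapply(grid, gamma_at, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  beta <- stats::optimize(gamma_at, c(lo, hi), maximum = TRUE, tol = 1e-13)$maximum
  beta <- gamma_at(beta)
  alpha - beta
}

# Corridor width via an explicit 2D embedding of the measurement plane:
# coordinates (t, s) with t along the axis and s along the in-plane
# perpendicular; width is the perpendicular gap between the two safety points.
oracle_corridor_width <- function(I, E, S1, S2) {
  d <- (E - I) / sqrt(sum((E - I)^2))
  o1 <- (S1 - I) - sum((S1 - I) * d) * d
  u <- o1 / sqrt(sum(o1^2))
  to2d <- function(P) c(sum((P - I) * d), sum((P - I) * u))
  s1 <- to2d(S1)[2]; s2 <- to2d(S2)[2]
  s1 - s2
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rand_pose <- function(max_t = 100) {
  list(R = random_rotation_matrix(), t = stats::runif(3, -max_t, max_t))
}

# A random valid frame plus its construction landmarks.
rand_frame <- function() {
  repeat {
    O <- stats::rnorm(3, sd = 20)
    A <- O + stats::rnorm(3, sd = 10)
    B <- O + stats::rnorm(3, sd = 10)
    ok <- tryCatch({
      f <- build_frame(O, A, B)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(list(frame = build_frame(O, A, B), O = O, A = A, B = B))
  }
}
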