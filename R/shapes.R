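# Simplified corridor shapes and their centered axes. Each bone corridor is
# simplified into a pyramid, prism or hemi-ellipsoid whose well-defined
# centered axis carries the optimal implant.

#' Construct a corridor shape
#'
#' @param kind `"pyramid"`, `"prism"` or `"hemi_ellipsoid"`.
#' @param points n x 3 matrix of defining points (mm).
#' @param labels character vector, one per point: for a pyramid `"apex"`
#'   (exactly one) and `"base"` (>= 3 vertices); for a prism `"end1"` and
#'   `"end2"` (>= 3 vertices each); for a hemi-ellipsoid `"base"` (>= 3 points
#'   on the cut plane) and `"surface"` (dome samples; >= 9 points in total for
#'   the quadric fit).
#' @return a `corridor_shape` list.
#' @export
corridor_shape <- function(kind = c("pyramid", "prism", "hemi_ellipsoid"),
                           points, labels) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (ncol(points) != 3L || !all(is.finite(points))) {
    osic_stop("shape points must be an n x 3 finite matrix", "osic_validation_error")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) {
    osic_stop("one label per shape point required", "osic_validation_error")
  }
  n <- function(lab) sum(labels == lab)
  ok <- switch(kind,
    pyramid = n("apex") == 1L && n("base") >= 3L,
    prism = n("end1") >= 3L && n("end2") >= 3L,
    hemi_ellipsoid = n("base") >= 3L && nrow(points) >= 9L)
  if (!ok) {
    osic_stop(sprintf("point multiplicity does not match shape kind '%s'", kind),
              "osic_validation_error")
  }
  structure(list(kind = kind, points = points, labels = labels),
            class = "corridor_shape")
}

polygon_area <- function(pts) {
  centroid <- colMeans(pts)
  tot <- c(0, 0, 0)
  m <- nrow(pts)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    tot <- tot + cross3(pts[i, ] - centroid, pts[j, ] - centroid)
  }
  0.5 * norm3(tot)
}

# Algebraic least-squares quadric (ellipsoid) fit; returns centre and the
# principal-axis directions (eigenvectors of the quadratic form).
fit_ellipsoid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  # centre/scale for conditioning
  mu <- colMeans(pts); sc <- max(stats::sd(x), stats::sd(y), stats::sd(z), 1e-12)
  xs <- (x - mu[1L]) / sc; ys <- (y - mu[2L]) / sc; zs <- (z - mu[3L]) / sc
  D <- cbind(xs^2, ys^2, zs^2, xs * ys, xs * zs, ys * zs, xs, ys, zs, 1)
  sv <- svd(D)
  v <- sv$v[, 10L]
  if (sv$d[9L] < 1e-9 * sv$d[1L]) {
    osic_stop("rank-deficient ellipsoid fit: defining points are degenerate",
              "osic_degenerate_shape")
  }
  Q <- matrix(c(v[1L], v[4L] / 2, v[5L] / 2,
                v[4L] / 2, v[2L], v[6L] / 2,
                v[5L] / 2, v[6L] / 2, v[3L]), 3L, 3L)
  l <- v[7:9]
  if (abs(det(Q)) < 1e-12) {
    osic_stop("degenerate quadric: no ellipsoid centre", "osic_degenerate_shape")
  }
  centre_s <- as.numeric(solve(-2 * Q, l))
  eig <- eigen(Q, symmetric = TRUE)
  list(centre = centre_s * sc + mu, axes = eig$vectors)
}

#' Centered axis of a simplified corridor shape
#'
#' * pyramid: the line through the apex and the centroid of the base polygon,
#'   oriented apex to base;
#' * prism: the line through the centroids of the two end faces, oriented
#'   end1 to end2;
#' * hemi-ellipsoid: the least-squares ellipsoid fit's principal axis that is
#'   most aligned with the base-plane normal, through the centroid of the base
#'   points, oriented from the base toward the dome samples.
#'
#' The returned direction is a convention; [simulate_optimal_implant()] fixes
#' the surgical orientation (insertion on the ventral surface) regardless.
#'
#' @param shape a [corridor_shape()].
#' @return list with `point` (mm) and unit `direction`.
#' @export
centered_axis <- function(shape) {
  stopifnot(inherits(shape, "corridor_shape"))
  pts <- shape$points; lab <- shape$labels
  if (shape$kind == "pyramid") {
    apex <- pts[lab == "apex", , drop = FALSE][1L, ]
    base <- pts[lab == "base", , drop = FALSE]
    if (polygon_area(base) <= 1e-9) {
      osic_stop("degenerate pyramid: base polygon has zero area", "osic_degenerate_shape")
    }
    ctr <- colMeans(base)
    if (norm3(ctr - apex) < 1e-12) {
      osic_stop("degenerate pyramid: apex coincides with base centroid",
                "osic_degenerate_shape")
    }
    list(point = apex, direction = unit3(ctr - apex))
  } else if (shape$kind == "prism") {
    e1 <- pts[lab == "end1", , drop = FALSE]
    e2 <- pts[lab == "end2", , drop = FALSE]
    if (polygon_area(e1) <= 1e-9 || polygon_area(e2) <= 1e-9) {
      osic_stop("degenerate prism: an end face has zero area", "osic_degenerate_shape")
    }
    c1 <- colMeans(e1); c2 <- colMeans(e2)
    if (norm3(c2 - c1) < 1e-12) {
      osic_stop("degenerate prism: end-face centroids coincide", "osic_degenerate_shape")
    }
    list(point = c1, direction = unit3(c2 - c1))
  } else {
    base <- pts[lab == "base", , drop = FALSE]
    fit <- fit_ellipsoid(pts)
    base_ctr <- colMeans(base)
    # base-plane normal from the base points
    bc <- sweep(base, 2L, base_ctr)
    nrm <- svd(bc)$v[, 3L]
    align <- abs(t(fit$axes) %*% nrm)
    dir <- fit$axes[, which.max(align)]
    dome <- pts[lab != "base", , drop = FALSE]
    if (nrow(dome) > 0L) {
      side <- colMeans(dome) - base_ctr
      if (sum(side * dir) < 0) dir <- -dir
    }
    list(point = base_ctr, direction = unit3(as.numeric(dir)))
  }
}

#' Place the optimal implant on a centered axis
#'
#' The insertion point is the point of the axis closest to the ventral bone
#' surface samples and the exit point is the point of the axis closest to the
#' far corridor boundary samples; the implant is oriented so insertion
#' precedes exit along its own direction.
#'
#' @param axis list with `point` and unit `direction` (from
#'   [centered_axis()]).
#' @param ventral_surface_points,far_boundary_points non-empty point sets
#'   (n x 3 matrices or length-3 vectors, mm).
#' @param site optional catalog entry (row of [implant_site_catalog()]) whose
#'   `site` and `frame` tags are attached to the result.
#' @return list with `insertion`, `exit` (mm), `site_id`, `frame`.
#' @export
simulate_optimal_implant <- function(axis, ventral_surface_points,
                                     far_boundary_points, site = NULL) {
  d <- unit3(as_point3(axis$direction, "axis direction"))
  a0 <- as_point3(axis$point, "axis point")
  as_set <- function(p) if (is.matrix(p)) p else matrix(as_point3(p), 1L, 3L)
  vp <- as_set(ventral_surface_points); fp <- as_set(far_boundary_points)
  if (nrow(vp) == 0L || nrow(fp) == 0L) {
    osic_stop("boundary point sets must be non-empty", "osic_validation_error")
  }
  nearest_t <- function(set) {
    ts <- as.numeric((set - matrix(a0, nrow(set), 3L, byrow = TRUE)) %*% d)
    perp <- sqrt(pmax(0, rowSums(sweep(set, 2L, a0)^2) - ts^2))
    ts[which.min(perp)]
  }
  tI <- nearest_t(vp); tE <- nearest_t(fp)
  if (abs(tE - tI) < 1e-9) {
    osic_stop("boundary sets project to the same axis parameter: zero-length implant",
              "osic_zero_length")
  }
  list(insertion = a0 + tI * d, exit = a0 + tE * d,
       site_id = if (!is.null(site)) site$site else NA_character_,
       frame = if (!is.null(site)) site$frame else NA_character_)
}
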