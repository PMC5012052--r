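# Projected angles, safety angles and corridor widths. All angle arithmetic
# happens on vectors already expressed in anatomical coordinates
# (x = craniocaudal, y = mediolateral, z = ventrodorsal).

#' Projected angles of an implant vector
#'
#' Given an implant vector in anatomical coordinates, computes the three
#' projected angles (ProjA), each the two-argument arctangent of the vector's
#' components in the named projection plane, measured from the plane's
#' reference axis:
#' * sagittal ProjA = `atan2(z, x)` — projection onto the sagittal (x–z)
#'   plane, from the craniocaudal axis;
#' * dorsal ProjA = `atan2(y, x)` — projection onto the dorsal (x–y) plane,
#'   from the craniocaudal axis;
#' * transverse ProjA = `atan2(y, z)` — projection onto the transverse (z–y)
#'   plane, from the ventrodorsal axis.
#'
#' Two ProjA serve as an implant's 3D direction coordinates; strictly sagittal
#' implants are defined by the sagittal angle alone. Angles are signed and in
#' `(-180, 180]` degrees; reporting layers may take absolute values to match
#' tabulated conventions. If a projection has (numerically) zero in-plane
#' magnitude the corresponding angle is indeterminate and returned as `NA`
#' with a warning.
#'
#' @param v implant vector in anatomical coordinates (mm), e.g. from
#'   [to_anatomical()].
#' @param reported which angles define the site (the reported pair), a subset
#'   of `c("sagittal", "dorsal", "transverse")`; one name for sagittal sites.
#' @return a `projected_angles` list: `sagittal`, `dorsal`, `transverse`
#'   (degrees), `reported` (names) and `reported_values`.
#' @export
projected_angles <- function(v, reported = c("sagittal", "dorsal")) {
  v <- as_point3(v, "anatomical vector")
  if (norm3(v) == 0) {
    osic_stop("undefined direction: zero implant vector", "osic_zero_vector")
  }
  reported <- match.arg(reported, c("sagittal", "dorsal", "transverse"),
                        several.ok = TRUE)
  planes <- list(sagittal = c(3L, 1L),   # atan2(z, x)
                 dorsal = c(2L, 1L),     # atan2(y, x)
                 transverse = c(2L, 3L)) # atan2(y, z)
  ang <- lapply(planes, function(ix) {
    num <- v[ix[1L]]; den <- v[ix[2L]]
    if (num == 0 && den == 0) NA_real_ else atan2(num, den) * DEG
  })
  if (anyNA(unlist(ang[reported]))) {
    osic_warn("projection with zero in-plane magnitude: angle indeterminate",
              "osic_indeterminate_angle")
  }
  structure(list(sagittal = ang$sagittal, dorsal = ang$dorsal,
                 transverse = ang$transverse, reported = reported,
                 reported_values = unlist(ang[reported], use.names = TRUE)),
            class = "projected_angles")
}

#' Safety angle of one safety-margin point
#'
#' The safety angle (SafA) is the angular margin between the optimal implant
#' axis and the line from the insertion point tangent to a circle of implant
#' radius `r` centred on the safety-margin point `S`, measured in the plane
#' spanned by `E - I` and `S - I`:
#' `SafA = alpha - beta`, where `alpha` is the angle between `E - I` and
#' `S - I` and `beta = asin(r / |S - I|)` is the half-angle subtended by the
#' implant circle. With `r = 0` this reduces to the plain planar angle.
#'
#' A negative result means the corridor is narrower than the implant at that
#' margin; it is returned unclamped, with attribute `narrow = TRUE` and a
#' warning. If `S` lies on the axis (`alpha = 0` exactly) the value `-beta`
#' is returned with a collinearity warning.
#'
#' @param I insertion point (mm). @param E exit point (mm).
#' @param S safety-margin point (mm). @param r implant radius (mm, >= 0).
#' @return safety angle in degrees.
#' @export
safety_angle <- function(I, E, S, r = 0) {
  I <- as_point3(I, "I"); E <- as_point3(E, "E"); S <- as_point3(S, "S")
  if (!is.finite(r) || r < 0) osic_stop("implant radius must be >= 0", "osic_validation_error")
  u <- E - I
  if (norm3(u) == 0) osic_stop("implant axis has zero length", "osic_zero_vector")
  w <- S - I
  dS <- norm3(w)
  if (dS <= r) {
    osic_stop(sprintf("tangent undefined: |S - I| = %.6g mm <= r = %.6g mm", dS, r),
              "osic_tangent_undefined")
  }
  alpha <- angle_between(u, w)
  beta <- asin(r / dS) * DEG
  if (alpha == 0) {
    osic_warn("safety point lies on the implant axis", "osic_collinear_safety_point")
  }
  res <- alpha - beta
  if (res < 0) {
    osic_warn(sprintf("negative safety angle (%.4f deg): corridor narrower than implant", res),
              "osic_narrow_corridor")
    attr(res, "narrow") <- TRUE
  }
  res
}

#' Corridor width in one measurement plane
#'
#' Width of the bone corridor in the plane spanned by the implant axis and a
#' pair of opposing safety-margin points: the sum of the perpendicular
#' distances of the two points to the line through `I` and `E`, measured along
#' the common in-plane perpendicular direction. The implant radius affects
#' only safety angles, never the width. If the two points lie on the same side
#' of the axis the (possibly non-positive) signed difference is returned with
#' attribute `flanking = FALSE` and a warning.
#'
#' @param I,E implant insertion and exit points (mm).
#' @param S_pair list or 2 x 3 matrix of the two safety points of one plane.
#' @return width in mm.
#' @export
corridor_width <- function(I, E, S_pair) {
  I <- as_point3(I, "I"); E <- as_point3(E, "E")
  if (is.matrix(S_pair)) S_pair <- list(S_pair[1L, ], S_pair[2L, ])
  S1 <- as_point3(S_pair[[1L]], "S1"); S2 <- as_point3(S_pair[[2L]], "S2")
  d <- unit3(E - I)
  off <- function(S) { w <- S - I; w - sum(w * d) * d }
  o1 <- off(S1); o2 <- off(S2)
  d1 <- norm3(o1)
  if (d1 < 1e-12 || norm3(o2) < 1e-12) {
    osic_stop("safety point lies on the implant axis line: width undefined",
              "osic_degenerate_width")
  }
  u <- o1 / d1                # in-plane perpendicular direction
  s2 <- sum(o2 * u)           # signed offset of S2 along u
  width <- d1 - s2            # = d1 + |s2| when the points flank the axis
  if (s2 >= 0) {
    osic_warn("safety points lie on the same side of the axis: width flagged",
              "osic_nonflanking_width")
    attr(width, "flanking") <- FALSE
  }
  width
}

#' Safety angles, corridor widths and implant length for one implant
#'
#' Applies [safety_angle()] to each of the four safety-margin points (two
#' pairs lying in two orthogonal planes through the implant axis) and
#' [corridor_width()] to each pair, and returns the implant length `|E - I|`.
#' If the two measurement planes deviate from orthogonality by more than 5
#' degrees a warning is raised.
#'
#' @param implant list with `insertion` and `exit` points (mm).
#' @param margins list with `S` (list of 4 points or 4 x 3 matrix, ordered
#'   `S1, S2` = plane-1 pair, `S3, S4` = plane-2 pair) and `r` (implant
#'   radius, mm; the validation study used a 1.5 mm implant diameter, r =
#'   0.75).
#' @return a `safety_angles` list: `saf_a1` .. `saf_a4` (degrees),
#'   `width_plane1`, `width_plane2`, `implant_length` (mm).
#' @export
safety_angles <- function(implant, margins) {
  I <- as_point3(implant$insertion, "insertion")
  E <- as_point3(implant$exit, "exit")
  S <- margins$S
  if (is.matrix(S)) S <- lapply(seq_len(nrow(S)), function(i) S[i, ])
  if (length(S) != 4L) osic_stop("exactly 4 safety points required", "osic_validation_error")
  S <- lapply(S, as_point3, what = "safety point")
  r <- margins$r %||% 0
  d <- unit3(E - I)
  perp <- function(P) { w <- P - I; o <- w - sum(w * d) * d; o }
  u1 <- perp(S[[1L]]); u3 <- perp(S[[3L]])
  if (norm3(u1) > 1e-9 && norm3(u3) > 1e-9) {
    plane_angle <- acos(min(1, abs(sum(unit3(u1) * unit3(u3))))) * DEG
    if (abs(plane_angle - 90) > 5) {
      osic_warn(sprintf("safety-margin planes deviate from orthogonality by %.2f deg",
                        abs(plane_angle - 90)), "osic_nonorthogonal_planes")
    }
  }
  saf <- vapply(S, function(Si) as.numeric(safety_angle(I, E, Si, r)), 0)
  structure(list(saf_a1 = saf[1L], saf_a2 = saf[2L],
                 saf_a3 = saf[3L], saf_a4 = saf[4L],
                 width_plane1 = as.numeric(corridor_width(I, E, S[1:2])),
                 width_plane2 = as.numeric(corridor_width(I, E, S[3:4])),
                 implant_length = norm3(E - I)),
            class = "safety_angles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direction realizing prescribed projected angles
#'
#' Inverse of [projected_angles()] for the (sagittal, dorsal) pair: returns
#' the unit vector in anatomical coordinates whose sagittal and dorsal ProjA
#' equal the prescribed values (valid for |angle| < 90 degrees, where the
#' craniocaudal component is positive).
#'
#' @param sagittal,dorsal prescribed angles in degrees, |angle| < 90.
#' @return unit vector `c(x, y, z)`.
#' @export
direction_from_angles <- function(sagittal, dorsal = 0) {
  if (!is.finite(sagittal) || !is.finite(dorsal) ||
      abs(sagittal) >= 90 || abs(dorsal) >= 90) {
    osic_stop("prescribed projected angles must satisfy |angle| < 90 degrees",
              "osic_spec_error")
  }
  unit3(c(1, tan(dorsal / DEG), tan(sagittal / DEG)))
}
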