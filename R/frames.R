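# Anatomical coordinate frames. Each vertebra's frame is built from three ROI
# points placed in its sagittal plane: O (origin) and A, B spanning the
# in-plane reference axis. Implant vectors are re-expressed in this frame
# (change of basis) before any projected angle is computed.

COLLINEARITY_AREA_TOL <- 1e-6  # mm^2; below landmark-placement precision

#' Build an anatomical coordinate frame from the O, A, B landmarks
#'
#' Constructs an orthonormal, right-handed frame with origin `O`:
#' * `X` is the in-plane reference axis, the unit vector from `B` toward `A`
#'   (craniocaudal for C2, whose A/B lie on the ventral border of the
#'   vertebral foramen with A cranial; ventrodorsal for C1, whose A/B lie on
#'   the cranial border of the dorsal and ventral arches);
#' * `Y` is the unit normal of the plane through `O`, `A`, `B` (the sagittal
#'   plane), oriented along `(A - O) x (B - O)` — mediolateral;
#' * `Z = X x Y` completes the right-handed triad in the sagittal plane
#'   (ventrodorsal for C2). With landmarks placed as documented, `Z` points
#'   ventrally.
#'
#' @param O,A,B landmark coordinates (length-3, mm, scanner space).
#' @param vertebra `"C1"` or `"C2"`; recorded on the frame so downstream code
#'   knows which projection convention the X axis carries.
#' @return an `anatomical_frame`: list with `origin`, `X`, `Y`, `Z`,
#'   `vertebra`.
#' @export
build_frame <- function(O, A, B, vertebra = c("C2", "C1")) {
  vertebra <- match.arg(vertebra)
  O <- as_point3(O, "O"); A <- as_point3(A, "A"); B <- as_point3(B, "B")
  ab <- A - B
  if (norm3(ab) == 0) {
    osic_stop("degenerate landmarks: A and B coincide", "osic_degenerate_landmarks")
  }
  n <- cross3(A - O, B - O)
  area <- 0.5 * norm3(n)
  if (area <= COLLINEARITY_AREA_TOL) {
    osic_stop(sprintf("degenerate landmarks: O, A, B are collinear (triangle area %.2e mm^2)",
                      area), "osic_degenerate_landmarks")
  }
  X <- ab / norm3(ab)
  Y <- n / norm3(n)
  Z <- cross3(X, Y)
  structure(list(origin = O, X = X, Y = Y, Z = Z, vertebra = vertebra),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("Anatomical frame (%s)\n", x$vertebra))
  cat(sprintf("  origin: % .3f % .3f % .3f mm\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("X", "Y", "Z")) {
    cat(sprintf("  %s: % .6f % .6f % .6f\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  }
  invisible(x)
}

validate_frame <- function(frame) {
  if (!inherits(frame, "anatomical_frame")) {
    osic_stop("not an anatomical_frame", "osic_validation_error")
  }
  M <- rbind(frame$X, frame$Y, frame$Z)
  if (max(abs(M %*% t(M) - diag(3))) > 1e-9) {
    osic_stop("frame axes are not orthonormal", "osic_validation_error")
  }
  if (max(abs(cross3(frame$X, frame$Y) - frame$Z)) > 1e-9) {
    osic_stop("frame is not right-handed", "osic_validation_error")
  }
  invisible(frame)
}

#' Express a displacement in anatomical coordinates
#'
#' Change of basis: returns the components of `end - start` along the frame's
#' craniocaudal (`x`), mediolateral (`y`) and ventrodorsal (`z`) axes. Length
#' is preserved: `sqrt(x^2 + y^2 + z^2)` equals `|end - start|`. A zero vector
#' (`start == end`) is permitted here and only fails downstream where a
#' direction is required.
#'
#' @param frame an [build_frame()] result.
#' @param start,end points in scanner coordinates (mm).
#' @return named numeric vector `c(x, y, z)` in mm.
#' @export
to_anatomical <- function(frame, start, end) {
  validate_frame(frame)
  v <- as_point3(end, "end") - as_point3(start, "start")
  c(x = sum(v * frame$X), y = sum(v * frame$Y), z = sum(v * frame$Z))
}

#' Build a vertebra's frame from an ROI dataset
#'
#' Extracts the `landmark_O/A/B` rows for one case and vertebra and calls
#' [build_frame()].
#'
#' @param roi an [roi_dataset()].
#' @param case case identifier.
#' @param vertebra `"C1"` or `"C2"`.
#' @return an `anatomical_frame`.
#' @export
frame_from_roi <- function(roi, case, vertebra) {
  sub <- roi[roi$case == case & roi$vertebra == vertebra, ]
  pts <- lapply(c("landmark_O", "landmark_A", "landmark_B"), function(role) {
    row <- sub[sub$role == role, ]
    if (nrow(row) != 1L) {
      osic_stop(sprintf("case %s, %s: expected exactly one %s point, found %d",
                        case, vertebra, role, nrow(row)),
                "osic_completeness_error")
    }
    c(row$x, row$y, row$z)
  })
  build_frame(pts[[1L]], pts[[2L]], pts[[3L]], vertebra = vertebra)
}
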