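# End-to-end pipeline: from an ROI dataset (anatomical landmarks + implant +
# safety points per site) to the per-implant angle report.

#' Compute projected angles, safety angles and widths for every implant site
#'
#' For each `(case, site)` that carries an `insertion` and an `exit` point,
#' builds the anatomical frame of the vertebra the site's projected angles use
#' (per the site catalog; sites absent from the catalog project in their own
#' vertebra's frame), expresses the implant vector in anatomical coordinates,
#' and computes the site's reported projected angles. If the site's four
#' safety points (`safety_1` .. `safety_4`) are present, safety angles,
#' corridor widths and implant length are computed as well; otherwise those
#' columns are `NA`.
#'
#' @param roi an [roi_dataset()].
#' @param radius implant radius in mm (default 0.75, i.e. the 1.5 mm implant
#'   diameter used in the validation study).
#' @param catalog an [implant_site_catalog()].
#' @param signed keep the internal signed angle convention (`TRUE`) or report
#'   non-negative magnitudes as tabulated (`FALSE`, default).
#' @return data frame, one row per implant site, with columns `case`, `site`,
#'   `proj_a1`, `proj_a2` (degrees; `proj_a2` is `NA` for strictly sagittal
#'   sites), `saf_a1` .. `saf_a4` (degrees), `width_plane1`, `width_plane2`,
#'   `implant_length` (mm).
#' @export
compute_implant_angles <- function(roi, radius = 0.75,
                                   catalog = implant_site_catalog(),
                                   signed = FALSE) {
  roi <- roi_dataset(as.data.frame(roi))
  ins <- roi[roi$role == "insertion", ]
  if (nrow(ins) == 0L) {
    osic_stop("no implant sites (insertion points) in dataset", "osic_empty_results")
  }
  ins <- ins[order(ins$case, ins$site), ]
  frames <- new.env(parent = emptyenv())
  get_frame <- function(case, vertebra) {
    key <- paste(case, vertebra)
    if (is.null(frames[[key]])) frames[[key]] <- frame_from_roi(roi, case, vertebra)
    frames[[key]]
  }
  rows <- lapply(seq_len(nrow(ins)), function(i) {
    case <- ins$case[i]; site <- ins$site[i]
    sub <- roi[roi$case == case & roi$site == site, ]
    pt <- function(role) {
      row <- sub[sub$role == role, ]
      if (nrow(row) != 1L) {
        osic_stop(sprintf("case %s, site %s: expected exactly one '%s' point, found %d",
                          case, site, role, nrow(row)), "osic_completeness_error")
      }
      c(row$x, row$y, row$z)
    }
    I <- pt("insertion"); E <- pt("exit")
    in_catalog <- site %in% catalog$site
    if (in_catalog) {
      entry <- catalog_entry(catalog, site)
      frame_vert <- entry$frame
      reported <- entry$reported[[1L]]
    } else {
      frame_vert <- sub$vertebra[sub$role == "insertion"][1L]
      reported <- c("sagittal", "dorsal")
    }
    frame <- get_frame(case, frame_vert)
    v <- to_anatomical(frame, I, E)
    pa <- projected_angles(v, reported = reported)
    rv <- pa$reported_values
    if (!signed) rv <- abs(rv)
    have_safety <- all(paste0("safety_", 1:4) %in% sub$role)
    if (have_safety) {
      sa <- safety_angles(list(insertion = I, exit = E),
                          list(S = lapply(1:4, function(k) pt(paste0("safety_", k))),
                               r = radius))
    } else {
      sa <- list(saf_a1 = NA_real_, saf_a2 = NA_real_, saf_a3 = NA_real_,
                 saf_a4 = NA_real_, width_plane1 = NA_real_,
                 width_plane2 = NA_real_, implant_length = norm3(E - I))
    }
    data.frame(case = case, site = site,
               proj_a1 = rv[1L],
               proj_a2 = if (length(rv) > 1L) rv[2L] else NA_real_,
               saf_a1 = sa$saf_a1, saf_a2 = sa$saf_a2,
               saf_a3 = sa$saf_a3, saf_a4 = sa$saf_a4,
               width_plane1 = sa$width_plane1, width_plane2 = sa$width_plane2,
               implant_length = sa$implant_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
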