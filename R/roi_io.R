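# Reading and writing labelled 3D ROI point sets. These files replace the
# spreadsheet export step of the original manual workflow: every row is one
# ROI point placed in a DICOM viewer, in scanner (patient) coordinates, mm.

ROI_ROLES <- c("landmark_O", "landmark_A", "landmark_B",
               "insertion", "exit",
               paste0("safety_", 1:4),
               "shape_vertex")

ROI_COLUMNS <- c("case", "vertebra", "site", "role", "x", "y", "z")

#' Construct a labelled ROI point dataset
#'
#' An `roi_dataset` is a data frame of labelled 3D points in scanner (patient)
#' coordinates with one row per ROI point and columns `case`, `vertebra`
#' (`"C1"` or `"C2"`), `site` (implant-site or landmark name), `role`, and
#' `x`, `y`, `z` in millimetres. Roles are `landmark_O/A/B` (anatomical frame
#' landmarks), `insertion`/`exit` (implant axis), `safety_1` .. `safety_4`
#' (safety-margin points) and `shape_vertex` (corridor-shape points).
#'
#' The key `(case, vertebra, site, role)` must be unique and all coordinates
#' finite. Units are fixed at millimetres in a right-handed patient coordinate
#' system; the convention is recorded in the `coordinate_convention` attribute
#' and never converted silently.
#'
#' @param points data frame with the columns listed above.
#' @return an `roi_dataset` (data frame subclass).
#' @export
roi_dataset <- function(points) {
  if (is.null(points) || nrow(points) == 0L) {
    points <- data.frame(case = character(), vertebra = character(),
                         site = character(), role = character(),
                         x = numeric(), y = numeric(), z = numeric())
  }
  missing_cols <- setdiff(ROI_COLUMNS, names(points))
  if (length(missing_cols)) {
    osic_stop(paste("missing ROI columns:", paste(missing_cols, collapse = ", ")),
              "osic_parse_error")
  }
  points <- points[, ROI_COLUMNS]
  for (col in c("case", "vertebra", "site", "role")) {
    points[[col]] <- as.character(points[[col]])
  }
  bad_vert <- !points$vertebra %in% c("C1", "C2")
  if (any(bad_vert)) {
    osic_stop(paste0("vertebra must be C1 or C2 (row ",
                     which(bad_vert)[1L], ")"), "osic_validation_error")
  }
  bad_role <- !points$role %in% ROI_ROLES
  if (any(bad_role)) {
    osic_stop(paste0("unknown role '", points$role[which(bad_role)[1L]],
                     "' (row ", which(bad_role)[1L], ")"), "osic_validation_error")
  }
  for (col in c("x", "y", "z")) {
    points[[col]] <- as.numeric(points[[col]])
    if (anyNA(points[[col]]) || any(!is.finite(points[[col]]))) {
      osic_stop(paste0("non-finite coordinate in column '", col, "' (row ",
                       which(!is.finite(points[[col]]))[1L], ")"),
                "osic_validation_error")
    }
  }
  key <- paste(points$case, points$vertebra, points$site, points$role, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- points[which(duplicated(key))[1L], ]
    osic_stop(sprintf("duplicate ROI point key (case=%s, vertebra=%s, site=%s, role=%s)",
                      dup$case, dup$vertebra, dup$site, dup$role),
              "osic_uniqueness_error")
  }
  rownames(points) <- NULL
  structure(points,
            units = "mm",
            coordinate_convention = "right-handed patient coordinates (mm)",
            class = c("roi_dataset", "data.frame"))
}

#' Read labelled ROI points
#'
#' Reads a labelled 3D ROI point set from a delimited-text file (comma
#' separated, UTF-8, header `case,vertebra,site,role,x,y,z`) or from a
#' structured-text (JSON) file carrying the same fields, and validates it.
#' Full floating-point precision is preserved.
#'
#' @param source file path or connection.
#' @param dialect `"delimited"` (CSV, the default) or `"structured"` (JSON).
#' @return an [roi_dataset()].
#' @export
read_roi_points <- function(source, dialect = c("delimited", "structured")) {
  dialect <- match.arg(dialect)
  if (dialect == "delimited") {
    df <- tryCatch(
      utils::read.csv(source, colClasses = "character", strip.white = TRUE),
      error = function(e) osic_stop(paste("malformed ROI file:", conditionMessage(e)),
                                    "osic_parse_error"))
    if (!all(ROI_COLUMNS %in% names(df))) {
      osic_stop(paste("ROI header must contain:", paste(ROI_COLUMNS, collapse = ",")),
                "osic_parse_error")
    }
    for (col in c("x", "y", "z")) {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- is.na(val) & !(df[[col]] %in% c("NA", "NaN", "Inf", "-Inf"))
      if (any(bad)) {
        osic_stop(sprintf("malformed row: non-numeric '%s' at line %d",
                          col, which(bad)[1L] + 1L), "osic_parse_error")
      }
      df[[col]] <- val
    }
  } else {
    obj <- tryCatch(jsonlite::fromJSON(source),
                    error = function(e) osic_stop(paste("malformed structured ROI file:",
                                                        conditionMessage(e)),
                                                  "osic_parse_error"))
    df <- if (is.data.frame(obj$points)) obj$points else as.data.frame(obj$points)
  }
  roi_dataset(df)
}

#' Write labelled ROI points
#'
#' Inverse of [read_roi_points()]; the round trip reproduces coordinate values
#' bit-for-bit (17 significant digits in the delimited dialect, unrounded JSON
#' numbers in the structured dialect).
#'
#' @param x an [roi_dataset()].
#' @param destination file path or connection.
#' @param dialect `"delimited"` or `"structured"`.
#' @export
write_roi_points <- function(x, destination, dialect = c("delimited", "structured")) {
  dialect <- match.arg(dialect)
  x <- roi_dataset(as.data.frame(x))
  if (dialect == "delimited") {
    out <- as.data.frame(x)
    for (col in c("x", "y", "z")) out[[col]] <- sprintf("%.17g", out[[col]])
    utils::write.csv(out, destination, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(units = "mm",
                              coordinate_convention = attr(x, "coordinate_convention"),
                              points = as.data.frame(x)),
                         destination, auto_unbox = TRUE, digits = I(17))
  }
  invisible(destination)
}

# Columns of a computed angle report, in the deterministic output order.
REPORT_COLUMNS <- c("case", "site", "proj_a1", "proj_a2",
                    paste0("saf_a", 1:4), "width_plane1", "width_plane2",
                    "implant_length")

#' Write a computed implant-angle report
#'
#' One row per implant site with case, site, the two reported projected angles
#' (degrees), the four safety angles (degrees), the two corridor widths (mm)
#' and the implant length (mm). Angles are written with 6 decimal places so a
#' re-read report agrees with the in-memory values to well below 1e-4 degrees.
#'
#' @param results data frame as produced by [compute_implant_angles()].
#' @param destination file path or connection.
#' @param format `"delimited"` (CSV) or `"structured"` (JSON).
#' @export
write_angles_report <- function(results, destination,
                                format = c("delimited", "structured")) {
  format <- match.arg(format)
  if (is.null(results) || nrow(results) == 0L) {
    osic_stop("empty results: nothing to report", "osic_empty_results")
  }
  missing_cols <- setdiff(REPORT_COLUMNS, names(results))
  if (length(missing_cols)) {
    osic_stop(paste("report is missing columns:", paste(missing_cols, collapse = ", ")),
              "osic_validation_error")
  }
  out <- results[, REPORT_COLUMNS]
  if (format == "delimited") {
    num <- setdiff(REPORT_COLUMNS, c("case", "site"))
    for (col in num) out[[col]] <- sprintf("%.6f", out[[col]])
    utils::write.csv(out, destination, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, destination, auto_unbox = TRUE, digits = NA)
  }
  invisible(destination)
}

#' Read back a computed implant-angle report
#'
#' @param source file path or connection.
#' @param format `"delimited"` or `"structured"`.
#' @return data frame with the [write_angles_report()] columns.
#' @export
read_angles_report <- function(source, format = c("delimited", "structured")) {
  format <- match.arg(format)
  df <- if (format == "delimited") {
    utils::read.csv(source, colClasses = c(case = "character", site = "character"))
  } else {
    as.data.frame(jsonlite::fromJSON(source))
  }
  df[, REPORT_COLUMNS]
}
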