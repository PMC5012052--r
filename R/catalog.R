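# The implant-site catalog: 13 optimal implant sites derived from 9 safe bone
# corridors of the atlantoaxial vertebrae (lateral masses x2, ventral arch,
# transarticular x2, cranial articular surfaces x2, cranial vertebral body,
# pedicles x2, caudal vertebral body x3 implant positions).

#' The 13-site optimal implant catalog
#'
#' Returns one descriptor per optimal implant site: corridor name, laterality,
#' the vertebra the corridor belongs to, the vertebra whose anatomical frame
#' its projected angles use (`frame`; transarticular implants project in the
#' C1 frame), the simplified corridor shape kind, whether the site is strictly
#' sagittal (defined by a single sagittal ProjA), whether a sagittal site is
#' directed toward the vertebral canal (safety points are then placed at 75%
#' of corridor length), and the default true angles used by the synthetic
#' scene generator. Numbered sites 0-9 are the oblique implants (right side
#' even, left side odd); the three strictly sagittal sites carry tags instead.
#'
#' @param path optional path to an alternative structured-text catalog; by
#'   default the catalog shipped with the package is used.
#' @return data frame with 13 rows (class `implant_site_catalog`); the
#'   `reported` column is a list of angle names per site.
#' @export
implant_site_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "site_catalog.json", package = "osic",
                        mustWork = TRUE)
  }
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cat <- obj$sites
  if (nrow(cat) != 13L) {
    osic_stop("site catalog must contain exactly 13 entries", "osic_validation_error")
  }
  counts <- table(cat$corridor)
  expected <- c("C1 lateral mass (pedicular)" = 2L, "C1 ventral arch" = 1L,
                "C1-C2 transarticular" = 2L, "C2 cranial articular surface" = 2L,
                "C2 cranial vertebral body" = 1L, "C2 pedicle" = 2L,
                "C2 caudal vertebral body" = 3L)
  if (!setequal(names(counts), names(expected)) ||
      !all(counts[names(expected)] == expected)) {
    osic_stop("site catalog corridor multiplicities are wrong", "osic_validation_error")
  }
  if (any(cat$frame[cat$corridor == "C1-C2 transarticular"] != "C1")) {
    osic_stop("transarticular sites must project in the C1 frame", "osic_validation_error")
  }
  structure(cat, class = c("implant_site_catalog", class(cat)))
}

catalog_entry <- function(catalog, site) {
  row <- catalog[catalog$site == site, , drop = FALSE]
  if (nrow(row) != 1L) {
    osic_stop(sprintf("unknown implant site '%s'", site), "osic_validation_error")
  }
  row
}
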