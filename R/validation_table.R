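# The packaged validation table: gold-standard (mathematically calculated)
# and manually measured ProjA/SafA values for 12 randomly sampled implants,
# measured by 2 observers with 2 repeats each (60 records in total).

MEASUREMENT_SOURCES <- c("gold_standard",
                         "observer1_rep1", "observer1_rep2",
                         "observer2_rep1", "observer2_rep2")

ANGLE_COLUMNS <- c("proj_a1", "proj_a2", paste0("saf_a", 1:4))

#' Load the packaged method-validation table
#'
#' Returns the measurement records used to validate the mathematical angle
#' computation against manual on-screen measurement: for each of 12 implants
#' (one randomly selected implant in each of 12 dogs), the mathematically
#' calculated gold-standard values and the manual measurements by 2 observers
#' with 2 repeats, for 2 projected angles and 4 safety angles (degrees).
#'
#' @param source optional path to an alternative delimited-text table with the
#'   same layout; when omitted the transcription shipped with the package is
#'   used.
#' @return a data frame (class `measurement_table`) with columns `case`,
#'   `implant`, `source` (`gold_standard` or `observerX_repY`) and the six
#'   angle columns, exactly 60 rows (12 implants x 5 sources).
#' @export
load_validation_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "table1_measurements.csv", package = "osic",
                          mustWork = TRUE)
  }
  df <- utils::read.csv(source, colClasses = c(case = "character",
                                               implant = "integer",
                                               source = "character"))
  need <- c("case", "implant", "source", ANGLE_COLUMNS)
  if (!all(need %in% names(df))) {
    osic_stop(paste("validation table must have columns:",
                    paste(need, collapse = ", ")), "osic_parse_error")
  }
  bad <- !df$source %in% MEASUREMENT_SOURCES
  if (any(bad)) {
    osic_stop(paste("unknown measurement source:", df$source[which(bad)[1L]]),
              "osic_validation_error")
  }
  for (col in ANGLE_COLUMNS) {
    if (any(!is.finite(df[[col]]))) {
      osic_stop(paste("non-finite angle in column", col), "osic_validation_error")
    }
  }
  if (!all(df$implant %in% 0:9)) {
    osic_stop("implant ids must be integers 0-9", "osic_validation_error")
  }
  tab <- table(df$case)
  if (any(tab != 5L)) {
    osic_stop(sprintf("case %s does not have all 5 sources",
                      names(tab)[which(tab != 5L)[1L]]),
              "osic_completeness_error")
  }
  per_case <- split(df$source, df$case)
  ok <- vapply(per_case, function(s) setequal(s, MEASUREMENT_SOURCES), TRUE)
  if (!all(ok)) {
    osic_stop(sprintf("case %s is missing a measurement source",
                      names(per_case)[which(!ok)[1L]]),
              "osic_completeness_error")
  }
  df <- df[order(df$case, match(df$source, MEASUREMENT_SOURCES)), ]
  rownames(df) <- NULL
  df$gold_standard <- df$source == "gold_standard"
  structure(df, class = c("measurement_table", "data.frame"))
}

# Long form: one row per (case, angle, source) with angle family and
# observer/repeat labels; the gold-standard value is joined per (case, angle).
measurements_long <- function(records) {
  records <- as.data.frame(records)
  long <- do.call(rbind, lapply(ANGLE_COLUMNS, function(col) {
    data.frame(case = records$case, implant = records$implant,
               source = records$source, angle = col,
               family = if (startsWith(col, "proj")) "ProjA" else "SafA",
               value = records[[col]], stringsAsFactors = FALSE)
  }))
  gs <- long[long$source == "gold_standard", ]
  man <- long[long$source != "gold_standard", ]
  man$reference <- gs$value[match(paste(man$case, man$angle),
                                  paste(gs$case, gs$angle))]
  man$observer <- ifelse(grepl("observer1", man$source), 1L, 2L)
  man$repeat_ <- ifelse(grepl("rep1", man$source), 1L, 2L)
  man[order(man$case, man$angle, man$observer, man$repeat_), ]
}
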