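# Structured validation reports: the concordance / tolerance-limit table and
# the absolute-error grid for the method-validation records, and the
# corresponding analysis for landmark-placement replicate quadruples.

ba_row <- function(family, value1, value2, ref, test, variant = "kfactor") {
  ba <- bland_altman(ref, test, variant = variant)
  cbind(data.frame(family = family, value1 = value1, value2 = value2,
                   stringsAsFactors = FALSE),
        as.data.frame(ba))
}

#' Concordance and absolute-error report for the method-validation table
#'
#' Reproduces the published validation analyses from the 60-record
#' measurement table: for each angle family (ProjA, SafA) a Bland-Altman /
#' concordance comparison of (i) the gold standard against every single manual
#' value (n = 96 ProjA, n = 192 SafA pairs; differences oriented manual minus
#' calculated), (ii) repeat 1 against repeat 2 (observer-matched pairs,
#' differences repeat 1 minus repeat 2) and (iii) observer 1 against observer
#' 2 (repeat-matched pairs, differences observer 1 minus observer 2); plus the
#' grid of absolute errors against the gold standard split by observer and
#' repeat.
#'
#' @param records a measurement table from [load_validation_table()].
#' @param variant tolerance-limit variant, see [tolerance_limits()].
#' @return list with `concordance` (data frame, 6 comparisons) and
#'   `absolute_errors` (data frame: family x observer x repeat, with `"both"`
#'   rows pooling the two repeats).
#' @export
validation_report <- function(records, variant = "kfactor") {
  if (!inherits(records, "measurement_table")) {
    osic_stop("records must come from load_validation_table()", "osic_validation_error")
  }
  man <- measurements_long(records)
  conc <- list(); errs <- list()
  for (fam in c("ProjA", "SafA")) {
    mf <- man[man$family == fam, ]
    mf <- mf[order(mf$case, mf$angle, mf$observer, mf$repeat_), ]
    v <- function(o, r) mf$value[mf$observer == o & mf$repeat_ == r]
    conc[[length(conc) + 1L]] <-
      ba_row(fam, "GS", "Single value", mf$reference, mf$value, variant)
    conc[[length(conc) + 1L]] <-
      ba_row(fam, "Rep1", "Rep2",
             ref = c(v(1, 2), v(2, 2)), test = c(v(1, 1), v(2, 1)), variant)
    conc[[length(conc) + 1L]] <-
      ba_row(fam, "Obs1", "Obs2",
             ref = c(v(2, 1), v(2, 2)), test = c(v(1, 1), v(1, 2)), variant)
    for (obs in 1:2) {
      for (rep in 1:2) {
        sub <- mf[mf$observer == obs & mf$repeat_ == rep, ]
        es <- absolute_error_summary(sub$reference, sub$value)
        errs[[length(errs) + 1L]] <-
          data.frame(family = fam, observer = obs, repeat_ = as.character(rep),
                     mean_abs = es$mean_abs, sd_abs = es$sd_abs, n = es$n)
      }
      sub <- mf[mf$observer == obs, ]
      es <- absolute_error_summary(sub$reference, sub$value)
      errs[[length(errs) + 1L]] <-
        data.frame(family = fam, observer = obs, repeat_ = "both",
                   mean_abs = es$mean_abs, sd_abs = es$sd_abs, n = es$n)
    }
  }
  list(concordance = do.call(rbind, conc),
       absolute_errors = do.call(rbind, errs))
}

#' Agreement analysis of ProjA replicate quadruples
#'
#' For projected angles recomputed under 4 replicate sets of anatomical-axis
#' landmarks (2 observers x 2 repeats), the per-item gold standard is the mean
#' of the 4 values (the true axis position cannot be observed). Reports the
#' agreement of single values, of the mean of the 2 observers (repeat-matched
#' means) and of the mean of the 2 repeats (observer-matched means) against
#' that gold standard; observer-1 vs observer-2 and repeat-1 vs repeat-2
#' comparisons with subgroup analyses by projection plane and by vertebra
#' frame; and the absolute-error summaries for single values, same-observer
#' repeat means and two-observer means.
#'
#' @param values data frame with one row per replicate value: columns `item`
#'   (one id per implant-site angle), `observer` (1/2), `rep` (1/2), `value`
#'   (degrees), and optionally `plane` (`"sagittal"`, `"dorsal"`,
#'   `"transverse"`) and `frame` (`"C1"`, `"C2"`) constant within item. Items
#'   without exactly 4 values (one per observer x repeat) are dropped with a
#'   warning.
#' @param variant tolerance-limit variant, see [tolerance_limits()].
#' @return list with `concordance` and `absolute_errors` data frames and the
#'   per-item `gold_standard`.
#' @export
landmark_proja_analysis <- function(values, variant = "kfactor") {
  need <- c("item", "observer", "rep", "value")
  if (!all(need %in% names(values))) {
    osic_stop(paste("values must have columns:", paste(need, collapse = ", ")),
              "osic_validation_error")
  }
  values$key <- paste(values$observer, values$rep, sep = "r")
  complete <- vapply(split(values$key, values$item),
                     function(k) setequal(k, c("1r1", "1r2", "2r1", "2r2")), TRUE)
  if (!all(complete)) {
    osic_warn(sprintf("%d item(s) without exactly 4 replicate values dropped",
                      sum(!complete)), "osic_incomplete_item")
    values <- values[values$item %in% names(complete)[complete], ]
  }
  if (nrow(values) == 0L) {
    osic_stop("no complete replicate quadruples", "osic_validation_error")
  }
  items <- sort(unique(values$item))
  get <- function(o, r) {
    sub <- values[values$observer == o & values$rep == r, ]
    sub$value[match(items, sub$item)]
  }
  M <- cbind(o1r1 = get(1, 1), o1r2 = get(1, 2),
             o2r1 = get(2, 1), o2r2 = get(2, 2))
  gs <- rowMeans(M)
  meta <- values[match(items, values$item), c("plane", "frame")[c("plane", "frame") %in% names(values)], drop = FALSE]

  conc <- list()
  add <- function(v1, v2, ref, test, subgroup = "all") {
    row <- ba_row("ProjA", v1, v2, ref, test, variant)
    row$subgroup <- subgroup
    conc[[length(conc) + 1L]] <<- row
  }
  add("GS", "Single value", rep(gs, 4L), as.numeric(M))
  add("GS", "Mean 2 Obs", rep(gs, 2L),
      c((M[, "o1r1"] + M[, "o2r1"]) / 2, (M[, "o1r2"] + M[, "o2r2"]) / 2))
  add("GS", "Mean 2 Rep", rep(gs, 2L),
      c((M[, "o1r1"] + M[, "o1r2"]) / 2, (M[, "o2r1"] + M[, "o2r2"]) / 2))
  pair_sets <- list(
    list("Obs1", "Obs2",
         ref = function(ix) c(M[ix, "o2r1"], M[ix, "o2r2"]),
         test = function(ix) c(M[ix, "o1r1"], M[ix, "o1r2"])),
    list("Rep1", "Rep2",
         ref = function(ix) c(M[ix, "o1r2"], M[ix, "o2r2"]),
         test = function(ix) c(M[ix, "o1r1"], M[ix, "o2r1"])))
  for (ps in pair_sets) {
    all_ix <- seq_along(items)
    add(ps[[1L]], ps[[2L]], ps$ref(all_ix), ps$test(all_ix))
    for (col in c("plane", "frame")) {
      if (!col %in% names(meta)) next
      for (g in sort(unique(meta[[col]]))) {
        ix <- which(meta[[col]] == g)
        if (length(ix) >= 2L) {
          add(ps[[1L]], ps[[2L]], ps$ref(ix), ps$test(ix), subgroup = g)
        }
      }
    }
  }

  errs <- rbind(
    data.frame(comparison = "single", mean_abs = mean(abs(M - gs)),
               sd_abs = stats::sd(abs(M - gs)), n = length(M)),
    do.call(rbind, lapply(1:2, function(o) do.call(rbind, lapply(1:2, function(r) {
      e <- abs(M[, paste0("o", o, "r", r)] - gs)
      data.frame(comparison = sprintf("single_obs%d_rep%d", o, r),
                 mean_abs = mean(e), sd_abs = stats::sd(e), n = length(e))
    })))),
    {
      e <- abs(cbind((M[, "o1r1"] + M[, "o1r2"]) / 2,
                     (M[, "o2r1"] + M[, "o2r2"]) / 2) - gs)
      data.frame(comparison = "mean_2_rep", mean_abs = mean(e),
                 sd_abs = stats::sd(as.numeric(e)), n = length(e))
    },
    {
      e <- abs(cbind((M[, "o1r1"] + M[, "o2r1"]) / 2,
                     (M[, "o1r2"] + M[, "o2r2"]) / 2) - gs)
      data.frame(comparison = "mean_2_obs", mean_abs = mean(e),
                 sd_abs = stats::sd(as.numeric(e)), n = length(e))
    })
  rownames(errs) <- NULL
  list(concordance = do.call(rbind, conc), absolute_errors = errs,
       gold_standard = data.frame(item = items, gs = gs))
}
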