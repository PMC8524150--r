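## Behavioral statistics: SSRT (mean method), SCD-RT2 slope, summaries.

#' Mean-method stop-signal reaction time
#'
#' Estimates the latency of the covert stopping process as the mean GO RT
#' minus the mean SSD. Because the 1-up/1-down staircase drives the SSD to
#' the 50% inhibition point, this difference estimates the stopping
#' latency under the independent race model. A negative estimate is
#' returned with a warning (a data-quality flag, not an error).
#'
#' @param mean_go_rt Mean correct GO RT in ms.
#' @param mean_ssd Mean SSD over SC trials in ms.
#' @return SSRT in ms.
#' @examples
#' computeSSRT(507, 267)  # 240
#' @export
computeSSRT <- function(mean_go_rt, mean_ssd) {
  if (is.na(mean_go_rt) || is.na(mean_ssd))
    stop("computeSSRT() requires both means")
  ssrt <- mean_go_rt - mean_ssd
  if (ssrt < 0) warning("negative SSRT estimate (", round(ssrt, 1), " ms)")
  ssrt
}

#' SCD-RT2 slope
#'
#' The ratio of RT2 differences between the two STOP-CHANGE delay
#' conditions, `(RT2_SCD0 - RT2_SCD300) / (SCD0 - SCD300)`. Values near 0
#' indicate a serial (efficient) processing strategy; values near -1 a
#' parallel (less efficient) one.
#'
#' @param mean_rt2_scd0,mean_rt2_scd300 Condition mean RT2s in ms (from
#'   CHANGE onset, successful SC trials with a correct CHANGE response).
#' @param scd0,scd300 The two SCD values in ms; `scd300 > scd0`.
#' @return Dimensionless slope (full precision; round for display).
#' @examples
#' round(computeSlope(854, 693), 2)   # -0.54 (human condition means)
#' round(computeSlope(1139, 975), 2)  # -0.55 (pigeon condition means)
#' @export
computeSlope <- function(mean_rt2_scd0, mean_rt2_scd300, scd0 = 0, scd300 = 300) {
  if (scd300 == scd0) stop("scd300 must differ from scd0")
  if (scd300 < scd0) stop("scd300 must exceed scd0")
  (mean_rt2_scd0 - mean_rt2_scd300) / (scd0 - scd300)
}

#' Summarise one subject's trial log
#'
#' Computes the per-subject measures from a tidy trial log: mean GO RT over
#' correct (non-omitted) GO trials, mean SSD over SC trials (after an
#' optional staircase burn-in), the mean-method SSRT, per-condition RT2
#' means over successful SC trials with a correct CHANGE response, and the
#' SCD-RT2 slope. Multi-session logs are pooled before averaging. Cells
#' with no usable trials yield NA, never zero.
#'
#' @param records Trial log as returned by [runSession()]/[runSubject()].
#' @param subject_id Subject identifier.
#' @param group,species Optional labels carried into the summary.
#' @param ssd_burn_in Number of initial SC trials excluded from the mean
#'   SSD (default 20) to reduce start-value bias; RT2 means are unaffected.
#'   If the log has no more SC trials than the burn-in, all are used.
#' @param scd_values The two SCD values in ms.
#' @return One-row data.frame: `subject_id`, `group`, `species`,
#'   `mean_go_rt`, `mean_ssd`, `ssrt`, `mean_rt2_scd0`, `mean_rt2_scd300`,
#'   `slope`, `n_go`, `n_sc`, `n_rt2_scd0`, `n_rt2_scd300`,
#'   `negative_ssrt` (flag).
#' @export
summarizeSubject <- function(records, subject_id = "S01", group = NA_character_,
                             species = NA_character_, ssd_burn_in = 20,
                             scd_values = c(0, 300)) {
  if (!nrow(records)) stop("empty trial log")
  go <- records[records$trial_type == "GO", , drop = FALSE]
  sc <- records[records$trial_type == "SC", , drop = FALSE]
  mean_go_rt <- if (any(!is.na(go$go_rt))) mean(go$go_rt, na.rm = TRUE) else NA_real_

  mean_ssd <- NA_real_
  if (nrow(sc)) {
    ssd_vals <- if (ssd_burn_in > 0 && nrow(sc) > ssd_burn_in)
      sc$ssd[-seq_len(ssd_burn_in)] else sc$ssd
    mean_ssd <- mean(ssd_vals)
  }
  ssrt <- if (!is.na(mean_go_rt) && !is.na(mean_ssd)) mean_go_rt - mean_ssd else NA_real_

  ok <- sc[!is.na(sc$sc_success) & sc$sc_success &
             !is.na(sc$change_correct) & sc$change_correct &
             !is.na(sc$rt2), , drop = FALSE]
  cellMean <- function(v) {
    x <- ok$rt2[ok$scd == v]
    if (length(x)) mean(x) else NA_real_
  }
  m0 <- cellMean(scd_values[1]); m1 <- cellMean(scd_values[2])
  slope <- if (!is.na(m0) && !is.na(m1))
    computeSlope(m0, m1, scd_values[1], scd_values[2]) else NA_real_

  data.frame(subject_id = subject_id, group = group, species = species,
             mean_go_rt = mean_go_rt, mean_ssd = mean_ssd, ssrt = ssrt,
             mean_rt2_scd0 = m0, mean_rt2_scd300 = m1, slope = slope,
             n_go = sum(!is.na(go$go_rt)), n_sc = nrow(sc),
             n_rt2_scd0 = sum(ok$scd == scd_values[1]),
             n_rt2_scd300 = sum(ok$scd == scd_values[2]),
             negative_ssrt = isTRUE(ssrt < 0),
             stringsAsFactors = FALSE)
}

#' Group summary with standard errors
#'
#' Per-measure mean and SEM (sample SD / sqrt(n)) over a table of subject
#' summaries, grouped by the `group` column (or any other column).
#'
#' @param subjects data.frame of [summarizeSubject()] rows.
#' @param measures Character vector of measure columns to summarise.
#' @param by Grouping column name.
#' @return Long data.frame: `group`, `measure`, `mean`, `sem`, `n`. SEM is
#'   NA for single-subject groups.
#' @export
summarizeGroup <- function(subjects,
                           measures = c("mean_go_rt", "mean_ssd", "ssrt",
                                        "mean_rt2_scd0", "mean_rt2_scd300",
                                        "slope"),
                           by = "group") {
  stopifnot(by %in% names(subjects))
  out <- do.call(rbind, lapply(split(subjects, subjects[[by]]), function(g) {
    do.call(rbind, lapply(measures, function(m) {
      x <- g[[m]][!is.na(g[[m]])]
      n <- length(x)
      data.frame(group = g[[by]][1], measure = m,
                 mean = if (n) mean(x) else NA_real_,
                 sem = if (n >= 2) sd(x) / sqrt(n) else NA_real_,
                 n = n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
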