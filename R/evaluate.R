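#' @include AllClasses.R
NULL

#' Recognition correctness as a percentage
#'
#' @param correct number of correctly identified repetitions.
#' @param total number of performed repetitions (> 0).
#' @return `100 * correct / total`.
#' @examples
#' recognitionRate(49, 50)
#' @export
recognitionRate <- function(correct, total) {
  if (length(total) != 1L || total <= 0) stop("'total' must be positive")
  if (correct < 0 || correct > total)
    stop("'correct' must lie in [0, total]")
  100 * correct / total
}

#' Weighted standard deviation around a reference rate
#'
#' The dispersion statistic used throughout the evaluation:
#' \deqn{U = \sqrt{ \frac{\sum_i w_i (x_i - R)^2}{\frac{n-1}{n} \sum_i w_i} }}
#' where the `x_i` are per-group recognition rates, the `w_i` their
#' repetition-count weights, `n` the number of groups and `R` the pooled
#' reference rate. Note the center is the globally pooled rate, not the
#' weighted mean of the group rates. With equal weights and
#' `center = mean(values)` this reduces to the classical sample standard
#' deviation. The result is invariant to rescaling all weights.
#'
#' @param values per-group recognition rates.
#' @param weights strictly positive per-group weights (same length).
#' @param center the pooled reference rate `R`.
#' @param nGroups the number of groups `n` (default `length(values)`).
#' @return The weighted standard deviation.
#' @examples
#' weightedSD(c(0, 100), c(1, 1), center = 50)  # 70.71
#' @export
weightedSD <- function(values, weights, center,
                       nGroups = length(values)) {
  if (length(values) != length(weights))
    stop("'values' and 'weights' must have equal length")
  if (nGroups < 2L) stop("at least 2 groups are required")
  if (any(weights <= 0)) stop("all weights must be strictly positive")
  if (length(center) != 1L || !is.finite(center))
    stop("'center' must be a single finite reference rate")
  n <- nGroups
  sqrt(sum(weights * (values - center)^2) / (((n - 1) / n) * sum(weights)))
}

#' Column-normalized confusion matrix
#'
#' Builds the recognition-error matrix: entry (recognized `r`, performed
#' `p`) is the percentage of performed-`p` repetitions recognized as `r`.
#' Columns are indexed by the performed activity and sum to 100 exactly
#' (before any display rounding); the diagonal carries the per-activity
#' recognition correctness.
#'
#' @param truth performed activity labels.
#' @param pred recognized activity labels (same length).
#' @param labels the class set; defaults to the classes present in `truth`.
#'   Every label must occur at least once as a performed activity.
#' @return A [ConfusionMatrix-class].
#' @examples
#' cm <- buildConfusion(c("A", "A", "A"), c("A", "A", "B"),
#'                      labels = c("A", "B"))
#' confusionPercent(cm)
#' @export
buildConfusion <- function(truth, pred, labels = sort(unique(truth))) {
  if (length(truth) != length(pred))
    stop("'truth' and 'pred' must have equal length")
  if (!all(truth %in% labels) || !all(pred %in% labels))
    stop("labels outside the class set")
  counts <- table(recognized = factor(pred, levels = labels),
                  performed = factor(truth, levels = labels))
  performed <- colSums(counts)
  if (any(performed == 0L))
    stop("performed class with zero repetitions: ",
         paste(labels[performed == 0L], collapse = ", "))
  percent <- sweep(unclass(counts), 2L, performed, "/") * 100
  new("ConfusionMatrix", percent = percent,
      counts = matrix(as.integer(counts), nrow(counts), ncol(counts),
                      dimnames = dimnames(counts)))
}

# Correct/total counts of a prediction subset.
.pw <- function(truth, pred, sel) {
  c(P = sum(pred[sel] == truth[sel]), W = sum(sel))
}

#' Recognition and dispersion report for one sensor
#'
#' Computes the full evaluation statistics from a labeled prediction set:
#' per activity, the pooled recognition correctness `R_a` and the
#' inter-subject weighted-SD dispersion `U_a` (weights: each subject's
#' repetition count of that activity, center `R_a`); overall, the pooled
#' `R_all` with the subject-weighted dispersion `U_all` and the
#' activity-weighted dispersion `U_act_all`; and per subject, `R_V` with
#' the inter-activity dispersion `U_V`. Groups with zero repetitions
#' contribute nothing and are excluded from the group count; statistics
#' undefined with fewer than two groups are `NA`. Requested subjects or
#' activities absent from the predictions appear as `NA` rows rather than
#' being dropped.
#'
#' @param predictions data.frame with columns `subject`, `activity` (the
#'   performed label) and `pred` (the recognized label), typically the test
#'   split.
#' @param sensor sensor name stored in the report.
#' @param subjects,activities the group sets to report on; default the sets
#'   present in `predictions`.
#' @return A [RecognitionReport-class].
#' @export
buildReport <- function(predictions, sensor = "emg", subjects = NULL,
                        activities = NULL) {
  need <- c("subject", "activity", "pred")
  if (!is.data.frame(predictions) || !all(need %in% names(predictions)))
    stop("'predictions' needs columns ", paste(need, collapse = ", "))
  truth <- as.character(predictions$activity)
  pred <- as.character(predictions$pred)
  subj <- as.character(predictions$subject)
  if (is.null(subjects)) subjects <- sort(unique(subj))
  if (is.null(activities))
    activities <- intersect(activityLevels(), unique(truth))

  PW <- .pw(truth, pred, rep(TRUE, length(truth)))
  Rall <- recognitionRate(PW["P"], PW["W"])

  subjRate <- function(sel) {
    pw <- vapply(subjects, function(v) .pw(truth, pred, sel & subj == v),
                 numeric(2L))
    keep <- pw["W", ] > 0
    list(x = 100 * pw["P", keep] / pw["W", keep], w = pw["W", keep],
         n = sum(keep))
  }
  safeU <- function(x, w, n, center)
    if (n >= 2L) weightedSD(x, w, center, nGroups = n) else NA_real_

  perActivity <- do.call(rbind, lapply(activities, function(a) {
    sel <- truth == a
    if (!any(sel))
      return(data.frame(activity = a, R = NA_real_, U = NA_real_,
                        P = 0L, W = 0L, n = 0L))
    pw <- .pw(truth, pred, sel)
    R <- recognitionRate(pw["P"], pw["W"])
    g <- subjRate(sel)
    data.frame(activity = a, R = R, U = safeU(g$x, g$w, g$n, R),
               P = as.integer(pw["P"]), W = as.integer(pw["W"]), n = g$n)
  }))

  gAll <- subjRate(rep(TRUE, length(truth)))
  Uall <- safeU(gAll$x, gAll$w, gAll$n, Rall)

  actAll <- perActivity[perActivity$W > 0, ]
  UactAll <- safeU(actAll$R, actAll$W, nrow(actAll), Rall)

  perSubject <- do.call(rbind, lapply(subjects, function(v) {
    sel <- subj == v
    if (!any(sel))
      return(data.frame(subject = v, R = NA_real_, U = NA_real_,
                        P = 0L, W = 0L, m = 0L))
    pw <- .pw(truth, pred, sel)
    R <- recognitionRate(pw["P"], pw["W"])
    apw <- vapply(activities, function(a) .pw(truth, pred, sel & truth == a),
                  numeric(2L))
    keep <- apw["W", ] > 0
    z <- 100 * apw["P", keep] / apw["W", keep]
    data.frame(subject = v, R = R,
               U = safeU(z, apw["W", keep], sum(keep), R),
               P = as.integer(pw["P"]), W = as.integer(pw["W"]),
               m = sum(keep))
  }))
  rownames(perActivity) <- rownames(perSubject) <- NULL

  new("RecognitionReport", sensor = sensor,
      perActivity = perActivity, perSubject = perSubject,
      overall = c(R_all = unname(Rall), U_all = unname(Uall),
                  U_act_all = unname(UactAll),
                  P_all = unname(as.numeric(PW["P"])),
                  W_all = unname(as.numeric(PW["W"]))))
}

#' Write the report tables to CSV
#'
#' Emits the three report shapes of the analysis: `table1.csv` (per sensor,
#' the per-activity recognition rates `R` with their dispersions `U` and
#' the overall column), `confusion_<code>.csv` (the column-normalized
#' recognition-error matrix per sensor, percentages rounded to one decimal)
#' and `table6.csv` (per sensor, the per-subject rates with dispersions and
#' the overall column). Sensor codes follow the study: B = emg,
#' C = pressure, D = video, E = acc.
#'
#' @param reports named list of [RecognitionReport-class] (names = sensor
#'   names).
#' @param confusions named list of [ConfusionMatrix-class], optional.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReportTables <- function(reports, confusions = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  sensorOrder <- intersect(c("emg", "pressure", "video", "acc"),
                           names(reports))

  wide <- function(rep, what) {
    pa <- activityStats(rep)
    if (what == "activity") {
      key <- pa$activity; Rv <- pa$R; Uv <- pa$U
    } else {
      ps <- subjectStats(rep)
      key <- ps$subject; Rv <- ps$R; Uv <- ps$U
    }
    ov <- overallStats(rep)
    uAll <- if (what == "activity") ov["U_act_all"] else ov["U_all"]
    r1 <- c(list(sensor = .sensorIds[[sensorId(rep)]], statistic = "R"),
            as.list(round(Rv, 1)), All = round(unname(ov["R_all"]), 1))
    r2 <- c(list(sensor = .sensorIds[[sensorId(rep)]], statistic = "U"),
            as.list(round(Uv, 1)), All = round(unname(uAll), 1))
    names(r1)[3:(2 + length(key))] <- names(r2)[3:(2 + length(key))] <- key
    rbind(as.data.frame(r1, check.names = FALSE),
          as.data.frame(r2, check.names = FALSE))
  }

  t1 <- do.call(rbind, lapply(reports[sensorOrder], wide, what = "activity"))
  p <- file.path(dir, "table1.csv")
  utils::write.csv(t1, p, row.names = FALSE)
  paths <- c(paths, p)

  t6 <- do.call(rbind, lapply(reports[sensorOrder], wide, what = "subject"))
  p <- file.path(dir, "table6.csv")
  utils::write.csv(t6, p, row.names = FALSE)
  paths <- c(paths, p)

  for (s in intersect(sensorOrder, names(confusions))) {
    p <- file.path(dir, paste0("confusion_", .sensorIds[[s]], ".csv"))
    utils::write.csv(round(confusionPercent(confusions[[s]]), 1), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
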