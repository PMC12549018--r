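#' Single-feature linear classification accuracy
#'
#' Fits the optimal-threshold linear classifier on one feature (the 1-D
#' analogue of a linear-kernel maximum-margin classifier): every midpoint
#' between adjacent sorted values is scanned in both orientations and the
#' threshold with the highest training accuracy is selected, ties broken
#' deterministically in favour of the widest margin (threshold midway
#' between the closest values on either side). Accuracy is reported either
#' on the training data (`"resubstitution"`) or by leave-one-out
#' cross-validation (`"leave-one-out"`).
#'
#' @param values Numeric feature vector (one value per subject-condition).
#' @param labels Binary labels (logical, or any two-level vector).
#' @param scheme `"resubstitution"` or `"leave-one-out"`.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
linear_accuracy <- function(values, labels,
                            scheme = c("resubstitution", "leave-one-out")) {
  scheme <- match.arg(scheme)
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2) stop("need both classes present")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  if (scheme == "resubstitution") {
    fit <- fit_threshold(values, y)
    mean(predict_threshold(fit, values) == y)
  } else {
    preds <- vapply(seq_along(values), function(i) {
      fit <- fit_threshold(values[-i], y[-i])
      predict_threshold(fit, values[i])
    }, integer(1))
    mean(preds == y)
  }
}

# best-threshold fit: returns threshold and orientation
fit_threshold <- function(values, y) {
  vs <- sort(unique(values))
  cuts <- if (length(vs) > 1) (vs[-1] + vs[-length(vs)]) / 2 else vs
  cand <- c(vs[1] - 1, cuts, vs[length(vs)] + 1)
  best <- NULL
  for (th in cand) {
    for (orient in c(1L, 2L)) {
      pred <- if (orient == 1L) ifelse(values <= th, 1L, 2L)
              else ifelse(values <= th, 2L, 1L)
      acc <- mean(pred == y)
      lo <- suppressWarnings(max(values[values <= th]))
      hi <- suppressWarnings(min(values[values > th]))
      margin <- if (is.finite(lo) && is.finite(hi)) hi - lo else 0
      if (is.null(best) || acc > best$acc ||
          (acc == best$acc && margin > best$margin)) {
        # max-margin tie-break: re-centre the threshold between neighbours
        th2 <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else th
        if (is.null(best) || acc > best$acc ||
            (acc == best$acc && margin > best$margin))
          best <- list(threshold = th2, orient = orient, acc = acc,
                       margin = margin)
      }
    }
  }
  best
}

predict_threshold <- function(fit, values) {
  if (fit$orient == 1L) ifelse(values <= fit$threshold, 1L, 2L)
  else ifelse(values <= fit$threshold, 2L, 1L)
}

#' Build a labelled feature from a metric table
#'
#' Extracts the full-recording (per-minute normalized where applicable)
#' rows of a [metric_table()] result and labels them according to one of the
#' two study groupings: `"anesthesia-vs-wakefulness"` (condition label), or
#' `"report-vs-no-report"` (wakefulness and ketamine anesthesia count as
#' conscious report; propofol and xenon anesthesia as no report).
#'
#' @param tab A [metric_table()] data frame.
#' @param feature Column name (`"fluidity"`, `"lz_complexity"`,
#'   `"repertoire"`, `"gap"`).
#' @param grouping `"anesthesia-vs-wakefulness"` or `"report-vs-no-report"`.
#' @return List with `values` and `labels` suitable for
#'   [linear_accuracy()].
#' @export
labeled_feature <- function(tab, feature,
                            grouping = c("anesthesia-vs-wakefulness",
                                         "report-vs-no-report")) {
  grouping <- match.arg(grouping)
  full <- tab[tab$segment_id == "full", ]
  values <- full[[feature]]
  labels <- if (grouping == "anesthesia-vs-wakefulness") {
    full$condition == "anesthesia"
  } else {
    !(full$condition == "wakefulness" |
        (full$condition == "anesthesia" & full$drug == "ketamine"))
  }
  list(values = values, labels = labels, grouping = grouping)
}
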