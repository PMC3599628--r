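## CASP-style assessment of per-residue disorder predictions. Positive =
## disordered; residues labelled 'X' (unclassified by assessors) are never
## counted as disordered and enter the confusion table as negatives.

#' Confusion counts at a decision threshold
#'
#' A residue is predicted disordered when its score is at or above the
#' threshold. Labels are \code{O/D/X}; \code{X} residues count as ordered.
#'
#' @param scores Per-residue scores in \[0,1\].
#' @param labels Per-residue labels over \code{O/D/X} (character vector or
#'   single string).
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector \code{(tp, fp, tn, fn)}.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  labels <- as_label_vector(labels)
  if (length(scores) != length(labels))
    stop("scores (", length(scores), ") and labels (", length(labels),
         ") differ in length")
  pos <- labels == "D"
  pred <- scores >= threshold
  c(tp = sum(pred & pos), fp = sum(pred & !pos),
    tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

as_label_vector <- function(labels) {
  if (length(labels) == 1L && nchar(labels[1]) > 1L)
    labels <- strsplit(labels, "")[[1]]
  bad <- setdiff(unique(labels), c("O", "D", "X"))
  if (length(bad))
    stop("labels must be over {O, D, X}; found: ",
         paste(bad, collapse = ", "))
  labels
}

#' Performance rates from confusion counts
#'
#' Sensitivity \code{TP/(TP+FN)}, specificity \code{TN/(TN+FP)}, balanced
#' accuracy \code{(SENS+SPEC)/2}, \code{Sw = SENS + SPEC - 1}, and the
#' F-measure \code{2*precision*SENS/(precision+SENS)} with precision
#' \code{TP/(TP+FP)}. When no residue is predicted disordered the precision
#' is undefined and the F-measure is reported as 0.
#'
#' @param counts Result of \code{\link{confusion}} (or any named vector with
#'   \code{tp, fp, tn, fn}).
#' @return Named numeric vector
#'   \code{(sens, spec, acc_balanced, sw, f_measure)}.
#' @export
rates <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (tp + fn == 0 && tn + fp == 0)
    stop("no residues to evaluate")
  if (tp + fn == 0) stop("no positive (disordered) residues: sensitivity undefined")
  if (tn + fp == 0) stop("no negative (ordered) residues: specificity undefined")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (is.na(prec) || prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  c(sens = sens, spec = spec, acc_balanced = (sens + spec) / 2,
    sw = sens + spec - 1, f_measure = f)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over all distinct scores, records
#' (false positive rate, sensitivity) points, and integrates by the
#' trapezoidal rule. Ties are handled by grouping equal scores, so the
#' result equals the tie-corrected Mann-Whitney statistic.
#'
#' @param scores Per-residue scores.
#' @param labels Labels over \code{O/D/X} (\code{X} counts as ordered).
#' @return List with \code{curve} (data frame \code{fpr, tpr}) and
#'   \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_label_vector(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  pos <- labels == "D"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one disordered and one ordered residue")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold (predict D when score >= s)
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(p)[last] / n_pos)
  fpr <- c(0, cumsum(!p)[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Bootstrap standard error of a performance measure
#'
#' Resamples a fraction of the predicted residues (without replacement by
#' default, i.e. a subsample) \code{reps} times and reports
#' \code{SE = sqrt(sum((theta_i - theta)^2) / reps)} where \code{theta} is
#' the full-data value of the measure. A resample on which the measure is
#' undefined (e.g. no positives) is redrawn; each redraw is reported via a
#' message.
#'
#' @param scores,labels Predictions and labels as in \code{\link{confusion}}.
#' @param metric Function \code{(scores, labels) -> numeric} (e.g. one of
#'   the rate helpers or an AUC wrapper).
#' @param frac Fraction of residues per resample (default 0.8).
#' @param reps Number of resamples (default 1000).
#' @param replace Resample with replacement instead of subsampling.
#' @return The standard error (attribute \code{"theta"} carries the
#'   full-data value).
#' @export
bootstrap_se <- function(scores, labels, metric, frac = 0.8, reps = 1000L,
                         replace = FALSE) {
  labels <- as_label_vector(labels)
  n <- length(scores)
  m <- max(1L, round(frac * n))
  theta <- metric(scores, labels)
  thetas <- numeric(reps)
  redraws <- 0L
  for (r in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, m, replace = replace)
      val <- tryCatch(metric(scores[idx], labels[idx]),
                      error = function(e) NA_real_)
      if (!is.na(val)) break
      redraws <- redraws + 1L
      if (redraws > 100L * reps) stop("metric undefined on nearly all resamples")
    }
    thetas[r] <- val
  }
  if (redraws > 0L)
    message("bootstrap_se: ", redraws, " undefined resample(s) redrawn")
  se <- sqrt(sum((thetas - theta)^2) / reps)
  attr(se, "theta") <- theta
  se
}

#' Dataset order/disorder composition
#'
#' Counts ordered and disordered residues (labels \code{X} count as
#' ordered) and the percentage disordered, either from labelled records or
#' directly from printed counts.
#'
#' @param records List of labelled \code{\link{protein_record}}s (or NULL).
#' @param n_disordered,n_ordered Direct counts (used when \code{records} is
#'   NULL).
#' @return Named vector \code{(n_ordered, n_disordered, pct_disordered)};
#'   the percentage is \code{NA} for an empty dataset.
#' @export
dataset_composition <- function(records = NULL, n_disordered = NULL,
                                n_ordered = NULL) {
  if (!is.null(records)) {
    lab <- unlist(lapply(records, function(r) {
      if (is.null(r$labels)) character(0) else strsplit(r$labels, "")[[1]]
    }))
    n_disordered <- sum(lab == "D")
    n_ordered <- sum(lab != "D")
  }
  total <- n_disordered + n_ordered
  c(n_ordered = n_ordered, n_disordered = n_disordered,
    pct_disordered = if (total > 0) 100 * n_disordered / total else NA_real_)
}

#' Full evaluation report for a set of predictions
#'
#' Computes balanced accuracy, sensitivity, specificity, F-measure, Sw
#' (all as percentages) and AUC, each with a bootstrap standard error,
#' pooling residues across proteins.
#'
#' @param tracks List of \code{\link{score_track}}s.
#' @param labels Named list/vector of label strings (names = protein ids).
#' @param threshold Decision threshold.
#' @param reps Bootstrap resamples (reduce for quick reports).
#' @param predictor Name to print in the report row.
#' @return A one-row data frame in table layout: ACC, ACC_se, SENS,
#'   SENS_se, SPEC, SPEC_se, F, F_se, Sw, Sw_se, AUC, AUC_se.
#' @export
evaluation_report <- function(tracks, labels, threshold = 0.5, reps = 200L,
                              predictor = "idrboost") {
  scores <- numeric(0); labs <- character(0)
  for (tr in tracks) {
    lab <- labels[[tr$id]]
    if (is.null(lab)) stop("no labels for protein '", tr$id, "'")
    lab <- as_label_vector(lab)
    if (length(lab) != length(tr$scores))
      stop("protein '", tr$id, "': ", length(lab), " labels for ",
           length(tr$scores), " scores")
    scores <- c(scores, tr$scores)
    labs <- c(labs, lab)
  }
  rate_metric <- function(name) function(s, l)
    rates(confusion(s, l, threshold))[[name]]
  auc_metric <- function(s, l) roc_auc(s, l)$auc
  metrics <- list(ACC = rate_metric("acc_balanced"),
                  SENS = rate_metric("sens"),
                  SPEC = rate_metric("spec"),
                  F = rate_metric("f_measure"),
                  Sw = rate_metric("sw"),
                  AUC = auc_metric)
  out <- list(Predictor = predictor)
  for (nm in names(metrics)) {
    v <- metrics[[nm]](scores, labs)
    se <- bootstrap_se(scores, labs, metrics[[nm]], reps = reps)
    scale <- if (nm == "AUC") 1 else 100
    out[[nm]] <- scale * v
    out[[paste0(nm, "_se")]] <- scale * as.numeric(se)
  }
  as.data.frame(out, check.names = FALSE)
}

#' Write an evaluation report as tab-separated text
#'
#' @param report Data frame from \code{\link{evaluation_report}}.
#' @param path Output file.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(format(report, digits = 4), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
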