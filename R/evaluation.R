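# Evaluation calculus: confusion matrix, per-class and macro
# precision/recall/F1, accuracy, one-vs-rest ROC and macro-AUC.

check_labels <- function(x, n_classes = 4, what = "labels") {
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 0L | x >= n_classes)) {
    stop(what, " must be integer codes in 0..", n_classes - 1L)
  }
  x
}

#' Confusion matrix
#'
#' Cross-tabulates true against predicted phase codes: rows are the
#' actual class, columns the predicted class, in phase order
#' (HS, FF, HO, SW).
#'
#' @param true,predicted Equal-length integer vectors of phase codes
#'   (0-3).
#' @param n_classes Number of classes (default 4).
#' @return Integer matrix `n_classes x n_classes` with phase dimnames.
#' @export
confusion_matrix <- function(true, predicted, n_classes = 4) {
  true <- check_labels(true, n_classes, "true labels")
  predicted <- check_labels(predicted, n_classes, "predicted labels")
  if (length(true) != length(predicted)) {
    stop("`true` and `predicted` must have equal length")
  }
  lv <- if (n_classes == 4) phase_levels() else as.character(0:(n_classes - 1))
  cm <- table(factor(true, levels = 0:(n_classes - 1)),
              factor(predicted, levels = 0:(n_classes - 1)))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = lv, predicted = lv))
  cm
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest counts for each class: `P_i = TP / (TP + FP)`,
#' `R_i = TP / (TP + FN)`, `F1_i = 2 P_i R_i / (P_i + R_i)`, reported as
#' percentages. Any 0/0 is defined as 0, so a class the model never
#' predicts correctly scores 0 on all three (as the plain LSTM does on
#' heel strike).
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with one row per class: `phase`, the `tp`, `fp`,
#'   `fn`, `tn` counts, and `precision`, `recall`, `f1` in percent.
#' @export
per_class_prf <- function(cm) {
  n <- nrow(cm)
  total <- sum(cm)
  out <- data.frame(
    phase = rownames(cm),
    tp = integer(n), fp = integer(n), fn = integer(n), tn = integer(n),
    precision = numeric(n), recall = numeric(n), f1 = numeric(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- total - tp - fp - fn
    p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    out[i, 2:8] <- list(tp, fp, fn, tn, p, r, f1)
  }
  out
}

#' Overall accuracy
#'
#' Percentage of correctly classified examples: for the multiclass
#' confusion matrix this is the diagonal sum over the total count.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / sum(cm)
}

#' Macro-averaged precision, recall and F1
#'
#' Macro precision and recall are the unweighted class means; macro-F1
#' is their harmonic mean,
#' `macro-F1 = 2 * macro-P * macro-R / (macro-P + macro-R)` -- note this
#' follows the published definition rather than averaging the per-class
#' F1 values.
#'
#' @param class_metrics Output of [per_class_prf()].
#' @return Named numeric vector `macro_p`, `macro_r`, `macro_f1` in
#'   percent.
#' @export
macro_metrics <- function(class_metrics) {
  mp <- mean(class_metrics$precision)
  mr <- mean(class_metrics$recall)
  mf1 <- if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr)
  c(macro_p = mp, macro_r = mr, macro_f1 = mf1)
}

#' One-vs-rest ROC curves and macro-AUC
#'
#' For each class, treats that class as positive, scores every example
#' by the class's predicted probability and sweeps the decision
#' threshold over all distinct scores; the area under the resulting
#' TPR/FPR curve is computed by the trapezoid rule. Macro-AUC is the
#' unweighted mean of the per-class areas; a class absent from the true
#' labels has no defined AUC and is excluded with a warning.
#'
#' @param true Integer phase codes (0-3).
#' @param scores Numeric matrix with one probability row per example and
#'   one column per class.
#' @param n_classes Number of classes.
#' @return List with `per_class` (per class: `fpr`, `tpr`, `auc`) and
#'   `macro_auc`.
#' @export
roc_ovr <- function(true, scores, n_classes = 4) {
  true <- check_labels(true, n_classes, "true labels")
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(true), ncol(scores) == n_classes)
  lv <- if (n_classes == 4) phase_levels() else as.character(0:(n_classes - 1))
  per_class <- vector("list", n_classes)
  names(per_class) <- lv
  aucs <- numeric(0)
  for (k in seq_len(n_classes)) {
    pos <- true == (k - 1L)
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0) {
      warning("class ", lv[k], " absent from the true labels; ",
              "its AUC is undefined and excluded from the macro mean")
      per_class[[k]] <- list(fpr = NA_real_, tpr = NA_real_,
                             auc = NA_real_)
      next
    }
    s <- scores[, k]
    ord <- order(s, decreasing = TRUE)
    tps <- cumsum(pos[ord])
    fps <- cumsum(!pos[ord])
    # collapse threshold ties: keep the last index of each score value
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tps[keep] / n_pos)
    fpr <- if (n_neg == 0) rep(0, sum(keep) + 1) else c(0, fps[keep] / n_neg)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    per_class[[k]] <- list(fpr = fpr, tpr = tpr, auc = auc)
    aucs <- c(aucs, auc)
  }
  list(per_class = per_class,
       macro_auc = if (length(aucs) > 0) mean(aucs) else NA_real_)
}

#' Full metrics report
#'
#' Bundles the complete evaluation of one set of predictions: confusion
#' matrix, per-class precision/recall/F1, overall accuracy, macro
#' precision/recall/F1 and (when probability scores are supplied) the
#' one-vs-rest ROC curves and macro-AUC.
#'
#' @param true Integer phase codes.
#' @param predicted Integer phase codes; defaults to the argmax of
#'   `scores`.
#' @param scores Optional probability matrix (one row per example).
#' @param model,speed Optional labels stored with the report.
#' @return Object of class `"gait_metrics"`.
#' @export
metrics_report <- function(true, predicted = NULL, scores = NULL,
                           model = NA_character_, speed = NA_real_) {
  if (is.null(predicted)) {
    if (is.null(scores)) stop("supply `predicted` or `scores`")
    predicted <- predict_class(as.matrix(scores))
  }
  cm <- confusion_matrix(true, predicted)
  pc <- per_class_prf(cm)
  mm <- macro_metrics(pc)
  roc <- if (is.null(scores)) NULL else roc_ovr(true, scores)
  structure(
    list(model = model, speed = speed, confusion = cm, per_class = pc,
         accuracy = accuracy(cm),
         macro_p = unname(mm["macro_p"]), macro_r = unname(mm["macro_r"]),
         macro_f1 = unname(mm["macro_f1"]),
         macro_auc = if (is.null(roc)) NA_real_ else roc$macro_auc,
         roc = roc),
    class = "gait_metrics"
  )
}

#' Evaluate a fitted model on labeled examples
#'
#' @param model A fitted `"gaitnet"`.
#' @param examples A `"gait_examples"` test set.
#' @return A `"gait_metrics"` report.
#' @export
evaluate_model <- function(model, examples) {
  stopifnot(inherits(model, "gaitnet"), inherits(examples, "gait_examples"))
  probs <- predict(model, examples, type = "prob")
  metrics_report(examples$y, predict_class(probs), scores = probs,
                 model = model$variant, speed = examples$speed)
}

#' @export
print.gait_metrics <- function(x, digits = 1, ...) {
  hdr <- "Gait-phase classification metrics"
  if (!is.na(x$model)) hdr <- paste0(hdr, " - ", x$model)
  if (!is.na(x$speed)) hdr <- paste0(hdr, " @ ", x$speed, " m/s")
  cat(hdr, "\n\nConfusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion)
  cat("\nPer-class metrics (%):\n")
  tab <- x$per_class[, c("phase", "precision", "recall", "f1")]
  tab[, 2:4] <- round(tab[, 2:4], digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "\nAccuracy %.1f%%  macro-P %.1f%%  macro-R %.1f%%  macro-F1 %.1f%%",
    x$accuracy, x$macro_p, x$macro_r, x$macro_f1))
  if (!is.na(x$macro_auc)) cat(sprintf("  macro-AUC %.3f", x$macro_auc))
  cat("\n")
  invisible(x)
}

# JSON-ready plain list view of a report (ROC point lists included
# per class so curves can be re-plotted from the file).
metrics_as_list <- function(x, include_roc = FALSE) {
  stopifnot(inherits(x, "gait_metrics"))
  out <- list(
    model = x$model, speed = x$speed,
    accuracy = x$accuracy, macro_p = x$macro_p, macro_r = x$macro_r,
    macro_f1 = x$macro_f1, macro_auc = x$macro_auc,
    per_class = x$per_class[, c("phase", "tp", "fp", "fn", "tn",
                                "precision", "recall", "f1")],
    confusion = unname(apply(x$confusion, 1, as.integer, simplify = FALSE))
  )
  if (include_roc && !is.null(x$roc)) {
    out$roc <- lapply(x$roc$per_class, function(pc) {
      list(fpr = pc$fpr, tpr = pc$tpr, auc = pc$auc)
    })
  }
  out
}

#' Write a metrics report to JSON
#'
#' Serializes a `"gait_metrics"` report (accuracy, macro metrics,
#' per-class table and confusion counts; optionally the ROC points) to a
#' JSON file.
#'
#' @param x A `"gait_metrics"` report.
#' @param path Output file.
#' @param include_roc Include the per-class ROC point lists.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path, include_roc = FALSE) {
  jsonlite::write_json(metrics_as_list(x, include_roc), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
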