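# Per-class evaluation: confusion matrices, one-vs-rest metrics and AUROC,
# and the cross-stage aggregation rules used for reporting.

#' One-vs-rest per-class metrics and confusion matrix
#'
#' For each intensity level the one-vs-rest sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)` and NPV `TN/(TN+FN)` as
#' fractions in `[0, 1]`; undefined ratios (0/0) are reported as `NA`, not 0.
#'
#' @param y_true,y_pred Integer level vectors (0-4) of equal length.
#' @param levels Label set for the confusion matrix (default: all levels
#'   observed in either vector).
#' @return List `confusion` (true x predicted table) and `metrics` (data
#'   frame: level, sensitivity, specificity, ppv, npv, support).
#' @export
per_class_metrics <- function(y_true, y_pred,
                              levels = sort(union(y_true, y_pred))) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  cm <- table(true = factor(y_true, levels = levels),
              predicted = factor(y_pred, levels = levels))
  rat <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  metrics <- do.call(rbind, lapply(seq_along(levels), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- sum(cm) - tp - fn - fp
    data.frame(level = levels[i],
               sensitivity = rat(tp, fn), specificity = rat(tn, fp),
               ppv = rat(tp, fp), npv = rat(tn, fn),
               support = tp + fn)
  }))
  list(confusion = cm, metrics = metrics)
}

#' One-vs-rest AUROC per level
#'
#' The rank statistic (Mann-Whitney form): for each level, the probability
#' that a positive case outranks a negative one by that level's score, with
#' ties given half credit. Invariant under strictly increasing score
#' transforms. Levels absent from `y_true` get `NA`.
#'
#' @param y_true Integer level vector.
#' @param scores Per-class score matrix, one row per case, columns named by
#'   level.
#' @return Named numeric vector of AUROCs over the score columns.
#' @export
ovr_auroc <- function(y_true, scores) {
  if (nrow(scores) != length(y_true)) {
    stop("scores must have one row per element of y_true")
  }
  vapply(colnames(scores), function(cl) {
    pos <- y_true == as.integer(cl)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, cl])                # ties -> average rank = 0.5 credit
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Aggregate per-stage predictions into a stage report
#'
#' Per stage: the confusion matrix, per-class metrics and AUROC. The
#' `average` block is, per level, the unweighted mean of each metric across
#' the stages whose test set contains that level. The `total` block pools
#' all predictions, computes per-level metrics on the pooled data, and
#' reports their support-weighted means as one overall row.
#'
#' @param stage_results Named list (stage -> list with `y_true`, `y_pred`
#'   and optionally `scores`).
#' @return A list of class `stage_report` with elements `stages`, `average`,
#'   `total`.
#' @export
aggregate_report <- function(stage_results) {
  if (!length(stage_results)) stop("need at least one stage")
  all_levels <- sort(unique(unlist(lapply(stage_results, function(s) {
    union(s$y_true, s$y_pred)
  }))))
  stages <- lapply(stage_results, function(s) {
    pm <- per_class_metrics(s$y_true, s$y_pred)
    if (!is.null(s$scores)) {
      auc <- ovr_auroc(s$y_true, s$scores)
      pm$metrics$auroc <- auc[as.character(pm$metrics$level)]
    } else {
      pm$metrics$auroc <- NA_real_
    }
    pm
  })

  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "auroc")
  average <- do.call(rbind, lapply(all_levels, function(lv) {
    rows <- do.call(rbind, lapply(stages, function(st) {
      m <- st$metrics[st$metrics$level == lv & st$metrics$support > 0, ,
                      drop = FALSE]
      if (nrow(m)) m else NULL
    }))
    if (is.null(rows)) return(NULL)
    out <- data.frame(level = lv)
    for (cc in metric_cols) out[[cc]] <- mean(rows[[cc]], na.rm = TRUE)
    out$n_stages <- nrow(rows)
    out$support <- sum(rows$support)
    out
  }))

  y_true <- unlist(lapply(stage_results, `[[`, "y_true"))
  y_pred <- unlist(lapply(stage_results, `[[`, "y_pred"))
  pooled <- per_class_metrics(y_true, y_pred, levels = all_levels)
  have_scores <- all(vapply(stage_results, function(s) !is.null(s$scores),
                            logical(1)))
  if (have_scores) {
    cols <- as.character(all_levels)
    sc <- do.call(rbind, lapply(stage_results, function(s) {
      m <- matrix(0, nrow(s$scores), length(cols), dimnames = list(NULL, cols))
      shared <- intersect(colnames(s$scores), cols)
      m[, shared] <- s$scores[, shared, drop = FALSE]
      m
    }))
    auc <- ovr_auroc(y_true, sc)
    pooled$metrics$auroc <- auc[as.character(pooled$metrics$level)]
  } else {
    pooled$metrics$auroc <- NA_real_
  }
  pm <- pooled$metrics[pooled$metrics$support > 0, , drop = FALSE]
  w <- pm$support / sum(pm$support)
  total <- data.frame(t(vapply(metric_cols, function(cc) {
    ok <- !is.na(pm[[cc]])
    sum(pm[[cc]][ok] * pm$support[ok]) / sum(pm$support[ok])
  }, numeric(1))))
  total$support <- sum(pm$support)

  structure(list(stages = stages, average = average,
                 per_level_total = pooled$metrics, total = total),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, digits = 2, ...) {
  pct <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !names(df) %in% c("level", "support", "n_stages")
    df[num] <- lapply(df[num], function(v) round(100 * v, digits))
    df
  }
  cat("Per-level average across stages (%):\n")
  print(pct(x$average), row.names = FALSE)
  cat("\nPooled total (%):\n")
  print(pct(x$total), row.names = FALSE)
  invisible(x)
}

# JSON-serializable form of a stage report
report_as_list <- function(report) {
  list(stages = lapply(report$stages, function(st) {
    list(confusion = as.data.frame.matrix(st$confusion),
         metrics = st$metrics)
  }),
  average = report$average,
  per_level_total = report$per_level_total,
  total = report$total)
}
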