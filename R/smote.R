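# Synthetic minority over-sampling (SMOTE) on the feature matrix.

#' Oversample minority intensity levels with SMOTE
#'
#' Brings every class up to the majority-class count by interpolating
#' synthetic rows: each synthetic point is a convex combination
#' `x + u * (neighbour - x)`, `u ~ U(0, 1)`, of a minority point and one of
#' its `k_neighbors` nearest same-class neighbours (Euclidean distance over
#' the feature columns). Classes smaller than `k_neighbors + 1` fall back to
#' the largest feasible `k` with a warning; singleton classes are duplicated.
#' Applied to training data only — never to held-out rows.
#'
#' @param train Feature data frame with a `level` column and the
#'   [feature_names()] columns.
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @param seed Integer seed.
#' @return The balanced data frame; synthetic rows get `event_id`s prefixed
#'   `syn_`.
#' @export
oversample_minority <- function(train, k_neighbors = 5L, seed = 1L) {
  set.seed(seed)
  feats <- intersect(feature_names(), names(train))
  counts <- table(train$level)
  n_maj <- max(counts)
  if (all(counts == n_maj)) return(train)
  out <- list(train)
  for (cls in names(counts)) {
    n_new <- n_maj - counts[[cls]]
    if (n_new == 0L) next
    rows <- which(train$level == as.integer(cls))
    X <- as.matrix(train[rows, feats, drop = FALSE])
    k <- min(k_neighbors, nrow(X) - 1L)
    if (k < k_neighbors) {
      warning(sprintf("level %s has only %d members; k reduced to %d",
                      cls, nrow(X), k))
    }
    if (k < 1L) {                      # singleton class: duplicate
      syn <- X[rep(1L, n_new), , drop = FALSE]
      base <- rep(rows[1L], n_new)
    } else {
      D <- as.matrix(stats::dist(X))
      diag(D) <- Inf
      nn <- apply(D, 1L, function(d) order(d)[seq_len(k)])
      nn <- matrix(nn, nrow = k)       # k x n neighbour indices
      base_i <- rep_len(seq_len(nrow(X)), n_new)[sample.int(n_new)]
      nb_i <- vapply(base_i, function(i) nn[sample.int(k, 1L), i], integer(1))
      u <- stats::runif(n_new)
      syn <- X[base_i, , drop = FALSE] +
        u * (X[nb_i, , drop = FALSE] - X[base_i, , drop = FALSE])
      base <- rows[base_i]
    }
    df <- train[base, , drop = FALSE]
    df[, feats] <- syn
    df$event_id <- sprintf("syn_%s_%04d", cls, seq_len(n_new))
    out[[length(out) + 1L]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
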