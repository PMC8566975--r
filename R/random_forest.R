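# Minimal bagged-CART random forest (Gini splits, random feature
# subsets). No random-forest package is available in the target
# environment; this only serves the no-PCA model comparison table, at
# cohort scale (tens of subjects, tens of features).

rf_grow_tree <- function(x, y, mtry, max_depth, min_node, depth = 0) {
  n <- length(y)
  p_hat <- mean(y)
  if (depth >= max_depth || n < min_node || p_hat == 0 || p_hat == 1) {
    return(list(leaf = TRUE, value = p_hat))
  }
  feats <- sample(ncol(x), mtry)
  best <- list(gain = 0)
  imp0 <- p_hat * (1 - p_hat)
  for (j in feats) {
    xs <- x[, j]
    cuts <- sort(unique(xs))
    if (length(cuts) < 2) next
    thr_cand <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (thr in thr_cand) {
      left <- xs <= thr
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      pl <- mean(y[left]); pr <- mean(y[!left])
      imp <- (nl * pl * (1 - pl) + (n - nl) * pr * (1 - pr)) / n
      gain <- imp0 - imp
      if (gain > best$gain + 1e-12) best <- list(gain = gain, j = j, thr = thr)
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, value = p_hat))
  left <- x[, best$j] <= best$thr
  list(leaf = FALSE, j = best$j, thr = best$thr,
       left = rf_grow_tree(x[left, , drop = FALSE], y[left],
                           mtry, max_depth, min_node, depth + 1),
       right = rf_grow_tree(x[!left, , drop = FALSE], y[!left],
                            mtry, max_depth, min_node, depth + 1))
}

rf_fit <- function(x, y, n_trees = 100, mtry = NULL, max_depth = 5,
                   min_node = 2, seed = 1L) {
  stopifnot(all(y %in% c(0, 1)))
  mtry <- mtry %||% max(1, floor(sqrt(ncol(x))))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample(nrow(x), replace = TRUE)
    rf_grow_tree(x[idx, , drop = FALSE], y[idx], mtry, max_depth, min_node)
  })
  structure(list(trees = trees), class = "ndp_rf")
}

rf_predict_one <- function(tree, xi) {
  while (!tree$leaf) {
    tree <- if (xi[tree$j] <= tree$thr) tree$left else tree$right
  }
  tree$value
}

rf_predict <- function(fit, x) {
  apply(x, 1, function(xi)
    mean(vapply(fit$trees, rf_predict_one, numeric(1), xi = xi)))
}
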