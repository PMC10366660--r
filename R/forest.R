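# Internal random forest: balanced-bootstrap bagged CART with Gini splits.
# Written in-package because no random-forest package ships with the
# analysis environment. Binary classification only, numeric features.

# Best split of y (0/1) on numeric x. Returns c(threshold, impurity, gain)
# or NULL when no valid split exists.
best_split_num <- function(x, y) {
  n <- length(y)
  ord <- order(x, method = "radix")
  xs <- x[ord]
  ys <- y[ord]
  valid <- xs[-n] < xs[-1]
  if (!any(valid)) return(NULL)
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  i <- seq_len(n - 1)
  nL <- i
  nR <- n - i
  p1L <- cum1[i] / nL
  p1R <- (n1 - cum1[i]) / nR
  # total weighted Gini after the split (parent impurity is constant)
  imp <- nL * 2 * p1L * (1 - p1L) + nR * 2 * p1R * (1 - p1R)
  imp[!valid] <- Inf
  j <- which.min(imp)
  p1 <- n1 / n
  parent <- n * 2 * p1 * (1 - p1)
  c(thr = (xs[j] + xs[j + 1]) / 2, imp = imp[j], gain = parent - imp[j])
}

# Grow one CART tree to purity (no depth limit). Node arrays:
# var = 0 marks a leaf; prob is the class-1 fraction in the leaf.
build_tree <- function(X, y, idx, mtry, min_node = 1L) {
  p <- ncol(X)
  cap <- 64L
  var <- integer(cap); thr <- numeric(cap)
  left <- integer(cap); right <- integer(cap); prob <- numeric(cap)
  gain_acc <- numeric(p)
  n_nodes <- 1L
  stack <- list(list(node = 1L, idx = idx))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ii <- top$idx
    yy <- y[ii]
    p1 <- mean(yy)
    make_leaf <- p1 == 0 || p1 == 1 || length(ii) < 2L * min_node
    best <- NULL
    if (!make_leaf) {
      feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
      for (f in feats) {
        s <- best_split_num(X[ii, f], yy)
        if (!is.null(s) && (is.null(best) || s["imp"] < best$imp)) {
          best <- list(f = f, thr = s[["thr"]], imp = s[["imp"]],
                       gain = s[["gain"]])
        }
      }
      if (is.null(best)) make_leaf <- TRUE
    }
    if (make_leaf) {
      var[top$node] <- 0L
      prob[top$node] <- p1
      next
    }
    gain_acc[best$f] <- gain_acc[best$f] + best$gain
    if (n_nodes + 2L > cap) {
      cap <- cap * 2L
      length(var) <- cap; length(thr) <- cap; length(left) <- cap
      length(right) <- cap; length(prob) <- cap
    }
    l <- n_nodes + 1L
    r <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    var[top$node] <- best$f
    thr[top$node] <- best$thr
    left[top$node] <- l
    right[top$node] <- r
    go_left <- X[ii, best$f] <= best$thr
    stack[[length(stack) + 1]] <- list(node = l, idx = ii[go_left])
    stack[[length(stack) + 1]] <- list(node = r, idx = ii[!go_left])
  }
  k <- seq_len(n_nodes)
  list(var = var[k], thr = thr[k], left = left[k], right = right[k],
       prob = prob[k], gain = gain_acc)
}

predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    v <- tree$var[node]
    active <- v > 0L
    if (!any(active)) break
    ai <- which(active)
    xi <- X[cbind(ai, v[ai])]
    go_left <- xi <= tree$thr[node[ai]]
    node[ai] <- ifelse(go_left, tree$left[node[ai]], tree$right[node[ai]])
  }
  tree$prob[node]
}

# Fit the forest. Balanced bootstrap: each tree draws min(n0, n1) samples
# with replacement from each class. Returns trees, OOB accuracy, and
# Gini-gain feature importance.
rf_fit <- function(X, y, n_trees = 200, mtry = NULL, min_node = 1L,
                   seed = NULL) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  p <- ncol(X)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  i0 <- which(y == 0)
  i1 <- which(y == 1)
  nb <- min(length(i0), length(i1))
  n <- nrow(X)
  with_seed_or_current(seed, {
    trees <- vector("list", n_trees)
    oob_sum <- numeric(n)
    oob_cnt <- integer(n)
    importance <- numeric(p)
    for (t in seq_len(n_trees)) {
      boot <- c(sample(i0, nb, replace = TRUE),
                sample(i1, nb, replace = TRUE))
      tree <- build_tree(X, y, boot, mtry, min_node)
      trees[[t]] <- tree
      importance <- importance + tree$gain
      oob <- setdiff(seq_len(n), unique(boot))
      if (length(oob) > 0) {
        oob_sum[oob] <- oob_sum[oob] +
          predict_tree(tree, X[oob, , drop = FALSE])
        oob_cnt[oob] <- oob_cnt[oob] + 1L
      }
    }
    seen <- oob_cnt > 0
    oob_acc <- mean((oob_sum[seen] / oob_cnt[seen] >= 0.5) == (y[seen] == 1))
    list(trees = trees, oob_accuracy = oob_acc,
         importance = importance / n_trees, mtry = mtry,
         n_trees = n_trees, min_node = min_node)
  })
}

rf_predict <- function(fit, X) {
  probs <- matrix(0, nrow(X), length(fit$trees))
  for (t in seq_along(fit$trees)) {
    probs[, t] <- predict_tree(fit$trees[[t]], X)
  }
  rowMeans(probs)
}
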