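#' Gini impurity of a node
#'
#' `1 - sum(p_i^2)` over the class proportions of the instances at a node:
#' 0 for a pure node, approaching `1 - 1/k` for a uniform mix of k classes.
#'
#' @param counts Non-negative integer class counts with positive total.
#' @return Gini impurity in `[0, 1 - 1/k]`.
#' @export
#' @examples
#' gini_impurity(c(5, 5, 5, 5))  # 0.75
gini_impurity <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("Gini impurity undefined for an empty node")
  1 - sum((counts / n)^2)
}

# impurity decrease of a split, Gini-weighted by sample proportion:
# n_ij = w_parent * G_parent - w_left * G_left - w_right * G_right,
# where w = node count / n_total
impurity_decrease <- function(counts_left, counts_right, n_total = NULL) {
  nl <- sum(counts_left); nr <- sum(counts_right)
  if (nl == 0 || nr == 0) stop("both children must be nonempty")
  if (is.null(n_total)) n_total <- nl + nr
  (nl + nr) / n_total * gini_impurity(counts_left + counts_right) -
    nl / n_total * gini_impurity(counts_left) -
    nr / n_total * gini_impurity(counts_right)
}

# Best axis-aligned split of a node over the candidate features.
# Thresholds are midpoints of consecutive distinct sorted values; returns
# NULL when no candidate yields a positive impurity decrease. Ties go to the
# lowest feature index, then the lowest threshold. `dec_rel` is the decrease
# with the node weighted as 1 (multiply by n_node / n_total for the absolute
# importance contribution).
best_split <- function(X, y, idx, feats, k) {
  n <- length(idx)
  if (n < 2L) return(NULL)
  yn <- y[idx]
  counts <- tabulate(yn, k)
  g_parent <- 1 - sum((counts / n)^2)
  if (g_parent <= 0) return(NULL)
  best <- NULL
  best_dec <- 1e-12
  for (f in feats) {
    x <- X[idx, f]
    ord <- order(x, method = "radix")
    xs <- x[ord]
    ys <- yn[ord]
    cut <- which(xs[-n] < xs[-1])
    if (length(cut) == 0L) next
    cum <- vapply(seq_len(k), function(cl) cumsum(ys == cl), numeric(n))
    cl_counts <- cum[cut, , drop = FALSE]
    nl <- cut
    nr <- n - nl
    cr_counts <- rep(counts, each = length(cut)) - cl_counts
    g_l <- 1 - rowSums((cl_counts / nl)^2)
    g_r <- 1 - rowSums((cr_counts / nr)^2)
    dec <- g_parent - (nl * g_l + nr * g_r) / n
    j <- which.max(dec)
    if (dec[j] > best_dec) {
      best_dec <- dec[j]
      thr <- (xs[cut[j]] + xs[cut[j] + 1L]) / 2
      best <- list(feature = f, threshold = thr, dec_rel = dec[j])
    }
  }
  best
}

# Grow a single CART tree on X[idx_rows, ] (class labels y as integers
# 1..k). Returns a flat node list; node 1 is the root. Leaves predict the
# majority class (ties to the lowest class index, i.e. alphabetical order).
# `n_total` is the reference count for sample-proportion weights (the full
# training-set size, not the bootstrap subset size).
grow_tree <- function(X, y, idx = seq_len(nrow(X)), k = max(y),
                      max_depth = 14L, min_samples_split = 2L,
                      mtry = ncol(X), n_total = nrow(X)) {
  if (length(idx) == 0L) stop("cannot grow a tree on empty data")
  stopifnot(max_depth >= 0L, min_samples_split >= 2L,
            mtry >= 1L, mtry <= ncol(X))
  p <- ncol(X)
  nodes <- vector("list", 64L)
  n_nodes <- 0L

  build <- function(idx, depth) {
    id <- n_nodes + 1L
    n_nodes <<- id
    n <- length(idx)
    counts <- tabulate(y[idx], k)
    g <- 1 - sum((counts / n)^2)
    nodes[[id]] <<- list(
      id = id, n = n, counts = counts, gini = g, weight = n / n_total,
      feature = NA_integer_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_,
      decrease = NA_real_, pred = which.max(counts)
    )
    if (depth >= max_depth || n < min_samples_split || g <= 0) return(id)
    feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    sp <- best_split(X, y, idx, feats, k)
    if (is.null(sp)) return(id)
    go_left <- X[idx, sp$feature] <= sp$threshold
    left_id <- build(idx[go_left], depth + 1L)
    right_id <- build(idx[!go_left], depth + 1L)
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    nodes[[id]]$decrease <<- (n / n_total) * sp$dec_rel
    id
  }
  build(idx, 0L)
  nodes[seq_len(n_nodes)]
}

# route every row of X through a tree; returns integer class predictions
predict_tree <- function(nodes, X) {
  pred <- integer(nrow(X))
  route <- function(id, rows) {
    nd <- nodes[[id]]
    if (is.na(nd$feature)) {
      pred[rows] <<- nd$pred
      return(invisible())
    }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) route(nd$left, rows[go_left])
    if (any(!go_left)) route(nd$right, rows[!go_left])
  }
  if (nrow(X) > 0L) route(1L, seq_len(nrow(X)))
  pred
}

# depth of a tree (root split = depth 1; a lone leaf has depth 0)
tree_depth <- function(nodes) {
  walk <- function(id) {
    nd <- nodes[[id]]
    if (is.na(nd$feature)) return(0L)
    1L + max(walk(nd$left), walk(nd$right))
  }
  walk(1L)
}

# per-tree importance: f_i = sum of impurity decreases at nodes splitting on
# feature i, divided by the total decrease over all internal nodes; a tree
# with no internal node contributes zeros
tree_importance <- function(nodes, p) {
  num <- numeric(p)
  den <- 0
  for (nd in nodes) {
    if (!is.na(nd$feature)) {
      num[nd$feature] <- num[nd$feature] + nd$decrease
      den <- den + nd$decrease
    }
  }
  if (den <= 0) numeric(p) else num / den
}
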