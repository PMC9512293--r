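# Recursive feature elimination over protein relative values, with two
# rankers: a linear squared-hinge margin classifier (SVM-style weight
# ranking) and a random forest with out-of-bag permutation importance.
# Both are authored here: at 3-vs-3 scale the models are tiny and the
# elimination loop, not the fitted model, is the deliverable.

#' Build a samples-by-features matrix from a protein table
#'
#' Transposes a protein relative-value table into the matrix the feature
#' selection stage consumes: one row per sample, one column per protein,
#' optionally log2-transformed. Features with any missing cell are dropped
#' (complete-case policy) with a warning.
#'
#' @param proteins protein table from [rollup_proteins()].
#' @param groups data.frame `sample_id`, `group`.
#' @param features optional character vector restricting the columns (e.g.
#'   the up-regulated set from [screen_proteins()]).
#' @param log2 transform values to log2 (default TRUE).
#' @return list with `x` (samples x features numeric matrix) and `y`
#'   (factor of group labels aligned with rows).
#' @export
build_feature_matrix <- function(proteins, groups, features = NULL, log2 = TRUE) {
  key_cols <- intersect(c("protein_id", "n_peptides"), names(proteins))
  samples <- setdiff(names(proteins), key_cols)
  groups <- check_groups(groups, sample_ids = samples, min_per_group = 2L)
  ids <- proteins$protein_id
  if (!is.null(features)) {
    missing <- setdiff(features, ids)
    if (length(missing))
      stop_input(paste0("features absent from protein table: ",
                        paste(missing, collapse = ", ")))
    keep <- ids %in% features
    proteins <- proteins[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  x <- t(as.matrix(proteins[samples]))
  colnames(x) <- ids
  if (log2) x <- base::log2(x)
  complete <- colSums(!is.finite(x)) == 0L
  if (!all(complete)) {
    warning(sprintf("dropped %d feature(s) with missing/non-finite values",
                    sum(!complete)))
    x <- x[, complete, drop = FALSE]
  }
  list(x = x, y = factor(groups$group))
}

check_feature_matrix <- function(x, y) {
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x))
    stop_input("feature matrix must be numeric with no missing cells")
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop_input("exactly two classes required")
  if (any(table(y) < 2L))
    stop_input("need >= 2 samples per class")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = droplevels(y))
}

#' Linear-margin feature importance (SVM-style)
#'
#' Fits an L2-regularized linear classifier with squared hinge loss on
#' internally standardized features and scores each feature by the squared
#' weight of the separating hyperplane — the classical SVM-RFE ranking
#' criterion. The smooth squared hinge makes the fit deterministic via
#' quasi-Newton optimization from a zero start. Constant features get
#' score 0 by convention.
#'
#' @param x samples x features numeric matrix (no missing cells).
#' @param y two-level class factor aligned with rows of `x`.
#' @param cost regularization weight C of the hinge term (fixed default 1,
#'   recorded for reproducibility).
#' @return Named non-negative numeric vector of importance scores.
#' @export
rank_features_linear_margin <- function(x, y, cost = 1) {
  fm <- check_feature_matrix(x, y)
  x <- fm$x
  yy <- ifelse(as.integer(fm$y) == 1L, -1, 1)
  sds <- apply(x, 2L, sd)
  keep <- sds > 0
  scores <- setNames(rep(0, ncol(x)), colnames(x))
  if (!any(keep)) return(scores)
  xs <- scale(x[, keep, drop = FALSE])
  p <- ncol(xs)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - yy * (drop(xs %*% w) + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - yy * (drop(xs %*% w) + b))
    gw <- w - 2 * cost * drop(crossprod(xs, yy * m))
    gb <- -2 * cost * sum(yy * m)
    c(gw, gb)
  }
  fit <- optim(rep(0, p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  scores[keep] <- fit$par[seq_len(p)]^2
  scores
}

# ---- random forest (tiny-n classification) ---------------------------------

# Grow one CART-style classification tree on rows `idx`; gini splits over
# `mtry` randomly sampled features, grown to purity. Returns a nested list;
# leaves carry the majority class (0/1).
grow_tree <- function(x, y01, idx, mtry) {
  ybar <- mean(y01[idx])
  if (length(idx) < 2L || ybar == 0 || ybar == 1)
    return(list(leaf = TRUE, pred = as.integer(ybar >= 0.5)))
  feats <- sample.int(ncol(x), mtry)
  best <- NULL; best_dec <- 0
  n <- length(idx)
  gini_parent <- 2 * ybar * (1 - ybar)
  for (f in feats) {
    v <- x[idx, f]
    o <- order(v)
    vs <- v[o]; ys <- y01[idx][o]
    distinct <- which(diff(vs) > 0)
    if (!length(distinct)) next
    cum1 <- cumsum(ys)
    for (s in distinct) {
      nl <- s; nr <- n - s
      pl <- cum1[s] / nl; pr <- (cum1[n] - cum1[s]) / nr
      dec <- gini_parent - (nl / n) * 2 * pl * (1 - pl) - (nr / n) * 2 * pr * (1 - pr)
      if (dec > best_dec + 1e-12) {
        best_dec <- dec
        best <- list(feat = f, thr = (vs[s] + vs[s + 1L]) / 2)
      }
    }
  }
  if (is.null(best))
    return(list(leaf = TRUE, pred = as.integer(ybar >= 0.5)))
  left <- idx[x[idx, best$feat] <= best$thr]
  right <- idx[x[idx, best$feat] > best$thr]
  list(leaf = FALSE, feat = best$feat, thr = best$thr,
       left = grow_tree(x, y01, left, mtry),
       right = grow_tree(x, y01, right, mtry))
}

predict_tree <- function(tree, xrow) {
  while (!tree$leaf)
    tree <- if (xrow[tree$feat] <= tree$thr) tree$left else tree$right
  tree$pred
}

tree_features <- function(tree) {
  if (tree$leaf) return(integer(0))
  unique(c(tree$feat, tree_features(tree$left), tree_features(tree$right)))
}

#' Random forest feature importance (out-of-bag permutation)
#'
#' Grows a bagged ensemble of gini-split classification trees and scores
#' each feature by the mean decrease in out-of-bag accuracy when that
#' feature's OOB values are permuted — the classical permutation
#' importance. Seeded and deterministic; scores can be slightly negative
#' for uninformative features (a standard property of the estimator).
#'
#' @inheritParams rank_features_linear_margin
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed.
#' @return Named numeric vector of importance scores.
#' @export
rank_features_forest <- function(x, y, n_trees = 500L, mtry = NULL, seed = 1L) {
  fm <- check_feature_matrix(x, y)
  x <- fm$x
  y01 <- as.integer(fm$y) - 1L
  n <- nrow(x); p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(check_count(mtry, "mtry"), p)
  n_trees <- check_count(n_trees, "n_trees")
  set.seed(seed)
  imp <- numeric(p)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), boot)
    tree <- grow_tree(x, y01, boot, mtry)
    if (!length(oob)) next
    base_correct <- sum(vapply(oob, function(i) predict_tree(tree, x[i, ]), integer(1)) == y01[oob])
    for (f in tree_features(tree)) {
      xp <- x[oob, , drop = FALSE]
      xp[, f] <- xp[sample.int(length(oob)), f]
      perm_correct <- sum(vapply(seq_along(oob), function(r) predict_tree(tree, xp[r, ]), integer(1)) == y01[oob])
      imp[f] <- imp[f] + (base_correct - perm_correct) / length(oob)
    }
  }
  setNames(imp / n_trees, colnames(x))
}

# ---- RFE loop and consensus -------------------------------------------------

#' Recursive feature elimination
#'
#' Repeatedly ranks the surviving features with the chosen ranker, removes
#' the `step` lowest-scoring ones (ties broken by feature index: the
#' later-indexed feature is removed first), and re-ranks the survivors,
#' until exactly `target_size` features remain. With a 3-vs-3 design
#' cross-validated size selection is unstable, so the subset size is an
#' explicit required parameter.
#'
#' @inheritParams rank_features_linear_margin
#' @param ranker `"linear_margin"`, `"forest"`, or a function
#'   `(x, y) -> named scores` for custom rankers.
#' @param target_size number of features to retain (1..ncol(x)).
#' @param step features removed per round (default 1).
#' @param seed seed for stochastic rankers; each refit uses a derived
#'   sub-seed so the whole trace is reproducible.
#' @param ... passed through to the built-in rankers (e.g. `n_trees`).
#' @return list of class `rfe_result`: `selected` (character vector, best
#'   combined order first), `ranking` (named integer vector over all
#'   features, 1 = most important / last eliminated), `trace` (list of
#'   surviving feature sets after each elimination round), `method`.
#' @export
recursive_eliminate <- function(x, y, ranker = c("linear_margin", "forest"),
                                target_size, step = 1L, seed = 1L, ...) {
  fm <- check_feature_matrix(x, y)
  x <- fm$x; y <- fm$y
  p <- ncol(x)
  target_size <- check_count(target_size, "target_size")
  if (target_size > p)
    stop_config("target_size", sprintf("exceeds number of features (%d)", p))
  step <- check_count(step, "step")

  if (is.function(ranker)) {
    rank_fun <- function(xs, round) ranker(xs, y)
    method <- "custom"
  } else {
    method <- match.arg(ranker)
    rank_fun <- switch(method,
      linear_margin = function(xs, round) rank_features_linear_margin(xs, y, ...),
      forest = function(xs, round) rank_features_forest(xs, y, seed = seed + round, ...))
  }

  surviving <- colnames(x)
  eliminated <- character(0)   # first eliminated first
  trace <- list()
  round <- 0L
  scores <- rank_fun(x, round)
  while (length(surviving) > target_size) {
    round <- round + 1L
    k <- min(step, length(surviving) - target_size)
    # ascending score, ties resolved by dropping the higher column index first
    ord <- order(scores[surviving], -match(surviving, colnames(x)))
    drop <- surviving[ord[seq_len(k)]]
    drop <- drop[order(-match(drop, colnames(x)))]
    eliminated <- c(eliminated, drop)
    surviving <- setdiff(surviving, drop)
    trace[[round]] <- surviving
    if (length(surviving) > target_size)
      scores <- rank_fun(x[, surviving, drop = FALSE], round)
  }
  final_scores <- if (length(surviving) > 1L && length(eliminated))
    rank_fun(x[, surviving, drop = FALSE], round + 1L) else scores[surviving]
  sel_order <- surviving[order(-final_scores[surviving], match(surviving, colnames(x)))]
  ranking <- setNames(integer(p), colnames(x))
  ranking[sel_order] <- seq_along(sel_order)
  ranking[rev(eliminated)] <- target_size + seq_along(eliminated)
  structure(list(selected = sel_order, ranking = ranking, trace = trace,
                 method = method, target_size = target_size),
            class = "rfe_result")
}

#' Combine two RFE shortlists into a consensus set
#'
#' @param set_a,set_b `rfe_result` objects or plain character vectors of
#'   selected features.
#' @param mode `"intersection"` (default, the stricter combination) or
#'   `"union"`.
#' @return Character vector, ordered by best combined rank (rank sum when
#'   both inputs are `rfe_result`s, otherwise input order); empty with a
#'   warning when disjoint under intersection.
#' @export
consensus_select <- function(set_a, set_b, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  sel_a <- if (inherits(set_a, "rfe_result")) set_a$selected else as.character(set_a)
  sel_b <- if (inherits(set_b, "rfe_result")) set_b$selected else as.character(set_b)
  out <- if (mode == "intersection") intersect(sel_a, sel_b) else union(sel_a, sel_b)
  if (mode == "intersection" && !length(out))
    warning("consensus is empty: method shortlists are disjoint")
  if (inherits(set_a, "rfe_result") && inherits(set_b, "rfe_result")) {
    rk <- function(res, f) ifelse(is.na(res$ranking[f]), length(res$ranking) + 1L, res$ranking[f])
    out <- out[order(rk(set_a, out) + rk(set_b, out), match(out, out))]
  }
  out
}

#' Run both RFE rankers and form the consensus shortlist
#'
#' End-to-end feature selection: recursive elimination with the linear
#' margin ranker and with the random forest ranker at the same target size,
#' then the consensus rule over the two shortlists.
#'
#' @inheritParams recursive_eliminate
#' @param mode consensus mode, see [consensus_select()].
#' @param n_trees trees per forest refit.
#' @return list of class `selection_result`: `margin` and `forest`
#'   (`rfe_result`s), `consensus`, `mode`, `target_size`.
#' @export
select_features <- function(x, y, target_size, step = 1L,
                            mode = c("intersection", "union"),
                            seed = 1L, n_trees = 500L) {
  mode <- match.arg(mode)
  margin <- recursive_eliminate(x, y, "linear_margin", target_size, step, seed)
  forest <- recursive_eliminate(x, y, "forest", target_size, step, seed,
                                n_trees = n_trees)
  structure(list(margin = margin, forest = forest,
                 consensus = consensus_select(margin, forest, mode),
                 mode = mode, target_size = target_size),
            class = "selection_result")
}
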