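## Data distillation: PCA overview, iterative random-forest Gini
## elimination, CART cut-off modelling.

auc_binary <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

#' PCA overview of the multi-parametric feature-set
#'
#' Z-scores the features, projects patients onto the top two principal
#' components, partitions the scores into two clusters and maps the
#' clusters onto outcome by majority vote.  Specificity and sensitivity are
#' reported for the cluster assignment; the AUC is computed from the
#' continuous projection of each patient onto the axis joining the two
#' cluster centroids (oriented towards the poor-outcome cluster).
#'
#' @param X numeric matrix or data frame, patients in rows, features in
#'   columns, no missing values.
#' @param y binary outcome per patient (0 survived / 1 disease-specific
#'   death).
#' @param cfg list; `seed` controls the clustering initialisation.
#' @return list of class `PCAResult`: `scores` (n x 2), `explained`
#'   (variance fractions, non-increasing), `cluster`, `specificity`,
#'   `sensitivity`, `auc`.
#' @export
pca_overview <- function(X, y, cfg = list(seed = 1L)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; clustering metrics undefined")
  if (nrow(X) < 3L) stop("need at least 3 patients")
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant feature column(s) dropped")
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1:2, drop = FALSE]
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  km <- with_seed(cfg$seed %||% 1L,
                  stats::kmeans(scores, centers = 2L, nstart = 10L))
  cl <- km$cluster
  # cluster with the higher event rate = predicted poor outcome
  rate <- tapply(y, cl, mean)
  poor <- as.integer(names(rate)[which.max(rate)])
  pred <- as.integer(cl == poor)
  axis <- km$centers[poor, ] - km$centers[setdiff(c(1, 2), poor), ]
  score <- drop(scores %*% axis)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(scores = scores, explained = explained, cluster = cl,
                 predicted = pred,
                 specificity = tn / (tn + fp), sensitivity = tp / (tp + fn),
                 auc = auc_binary(factor(y, levels = c(0, 1)), score)),
            class = "PCAResult")
}

#' Iterative random-forest Gini elimination
#'
#' Fits a random forest to the full feature table, ranks features by Gini
#' (impurity-decrease) importance, removes the least important feature, and
#' repeats -- refitting the forest each iteration -- until the out-of-bag
#' predictive value (OOB AUC) falls more than `tolerance` below the best
#' value observed.  Returns the smallest surviving feature set whose OOB
#' AUC is within `tolerance` of the best, plus the full per-iteration
#' trace.
#'
#' @param X feature matrix or data frame (patients x features), >= 2
#'   features.
#' @param y binary outcome (0/1).
#' @param cfg list: `n_trees` (default 5000), `tolerance` (default 0.005,
#'   the allowed OOB AUC drop), `seed`.
#' @return list of class `FeatureRanking`: `selected` (character vector of
#'   retained features), `trace` (data frame: iteration, n_features,
#'   oob_auc, dropped), `importance` (Gini importances at the selected
#'   iteration), `best_auc`.
#' @export
rf_iterative_reduce <- function(X, y, cfg = list()) {
  n_trees <- cfg$n_trees %||% 5000L
  tolerance <- cfg$tolerance %||% 0.005
  seed <- cfg$seed %||% 1L
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("need at least 2 features")
  yf <- factor(as.integer(y), levels = c(0, 1))
  if (length(unique(yf)) < 2L) stop("outcome has a single class")

  surviving <- colnames(X)
  trace <- list(); imps <- list(); sets <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- ranger::ranger(x = X[, surviving, drop = FALSE], y = yf,
                          num.trees = n_trees, probability = TRUE,
                          importance = "impurity", seed = seed + iter,
                          num.threads = 1L)
    oob <- fit$predictions[, "1"]
    auc <- auc_binary(yf, oob)
    imp <- fit$variable.importance
    trace[[iter]] <- data.frame(iteration = iter,
                                n_features = length(surviving),
                                oob_auc = auc,
                                dropped = NA_character_)
    imps[[iter]] <- imp
    sets[[iter]] <- surviving
    best <- max(vapply(trace, function(t) t$oob_auc, 0))
    if (auc < best - tolerance || length(surviving) == 1L) break
    drop <- names(imp)[which.min(imp)]
    trace[[iter]]$dropped <- drop
    surviving <- setdiff(surviving, drop)
  }
  tr <- do.call(rbind, trace)
  best <- max(tr$oob_auc)
  ok <- which(tr$oob_auc >= best - tolerance)
  pick <- max(ok)    # smallest set still within tolerance of the best
  structure(list(selected = sets[[pick]], trace = tr,
                 importance = imps[[pick]], best_auc = best,
                 n_trees = n_trees, tolerance = tolerance, seed = seed),
            class = "FeatureRanking")
}

#' Fit a CART model and export the headline cut-off
#'
#' Gini-impurity binary recursive partitioning on continuous features with
#' cost-complexity pruning; the pruning level is chosen by k-fold
#' cross-validated risk under the 1-SE rule.  Split thresholds follow the
#' standard convention of midpoints between adjacent sorted feature values.
#' The root split is exported as the headline optimal parameter/cut-off,
#' and k-fold self-test specificity, sensitivity and AUC are reported from
#' held-out fold predictions.
#'
#' @param X feature matrix or data frame.
#' @param y binary outcome (0/1), >= 2 patients per class.
#' @param cfg list: `folds` (default 10), `min_leaf` (default 5), `seed`.
#' @return list of class `CARTModel`: `tree` (pruned `rpart`),
#'   `root_feature`, `root_threshold`, `metrics`
#'   (`specificity`/`sensitivity`/`auc`, percentages for the first two),
#'   `cptable`, `folds`, `seed`.
#' @export
cart_fit <- function(X, y, cfg = list()) {
  folds <- cfg$folds %||% 10L
  min_leaf <- cfg$min_leaf %||% 5L
  seed <- cfg$seed %||% 1L
  X <- as.data.frame(X)
  yf <- factor(as.integer(y), levels = c(0, 1))
  if (min(table(yf)) < 2L) stop("need >= 2 patients per outcome class")
  dat <- cbind(.outcome = yf, X)
  ctl <- rpart::rpart.control(cp = 0, minbucket = min_leaf,
                              minsplit = 2L * min_leaf, xval = folds)
  fit <- with_seed(seed, rpart::rpart(.outcome ~ ., data = dat,
                                      method = "class", control = ctl))
  cpt <- fit$cptable
  best_i <- which.min(cpt[, "xerror"])
  thr <- cpt[best_i, "xerror"] + cpt[best_i, "xstd"]
  chosen_cp <- if (thr >= 1) {
    # no pruning level beats the trivial majority-class tree within 1 SE:
    # fall back to the single-leaf tree (its relative CV risk is 1 by
    # definition, even though the resampled root row can drift above it)
    cpt[1L, "CP"] * 1.0000001
  } else {
    cpt[min(which(cpt[, "xerror"] <= thr)), "CP"] * 1.0000001
  }
  pruned <- rpart::prune(fit, cp = chosen_cp)
  single_leaf <- nrow(pruned$frame) == 1L
  if (single_leaf) warning("data unsplittable under pruning; single-leaf tree")
  root_feature <- NA_character_; root_threshold <- NA_real_
  if (!single_leaf) {
    root_feature <- as.character(pruned$frame$var[1])
    root_threshold <- unname(pruned$splits[1, "index"])
  }
  ## k-fold self-test on the training data at the chosen complexity
  cvp <- with_seed(seed + 1L, {
    fold_of <- sample(rep_len(seq_len(folds), nrow(dat)))
    p <- numeric(nrow(dat))
    for (k in seq_len(folds)) {
      te <- fold_of == k
      if (length(unique(dat$.outcome[!te])) < 2L) { p[te] <- 0.5; next }
      fk <- rpart::rpart(.outcome ~ ., data = dat[!te, , drop = FALSE],
                         method = "class",
                         control = rpart::rpart.control(
                           cp = chosen_cp, minbucket = min_leaf,
                           minsplit = 2L * min_leaf, xval = 0))
      p[te] <- stats::predict(fk, dat[te, , drop = FALSE])[, "1"]
    }
    p
  })
  pred <- as.integer(cvp > 0.5)
  yi <- as.integer(as.character(yf))
  tn <- sum(pred == 0 & yi == 0); fp <- sum(pred == 1 & yi == 0)
  tp <- sum(pred == 1 & yi == 1); fn <- sum(pred == 0 & yi == 1)
  metrics <- list(specificity = 100 * tn / (tn + fp),
                  sensitivity = 100 * tp / (tp + fn),
                  auc = if (length(unique(cvp)) > 1) auc_binary(yf, cvp) else 0.5)
  structure(list(tree = pruned, cptable = cpt, root_feature = root_feature,
                 root_threshold = root_threshold, metrics = metrics,
                 single_leaf = single_leaf, folds = folds, seed = seed),
            class = "CARTModel")
}

#' @export
print.CARTModel <- function(x, ...) {
  cat("CART model (", x$folds, "-fold self-test)\n", sep = "")
  if (x$single_leaf) cat("  single leaf (no informative split)\n")
  else cat(sprintf("  root split: %s > %.6g\n", x$root_feature,
                   x$root_threshold))
  cat(sprintf("  self-test specificity %.1f%%, sensitivity %.1f%%, AUC %.3f\n",
              x$metrics$specificity, x$metrics$sensitivity, x$metrics$auc))
  invisible(x)
}
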