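#' Labeled training set
#'
#' @param positive character vector of functional lncRNA ids.
#' @param negative character vector of nonfunctional lncRNA ids.
#' @return object of class `labeled_set`.
#' @export
labeled_set <- function(positive, negative) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  both <- intersect(positive, negative)
  if (length(both))
    stop("ids in both classes: ", paste(head(both, 5), collapse = ", "))
  structure(list(positive = positive, negative = negative),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("labeled_set: %d positive, %d negative\n",
              length(x$positive), length(x$negative)))
  invisible(x)
}

labeled_ids <- function(labeled) c(labeled$positive, labeled$negative)

labeled_y <- function(labeled, ids) {
  as.integer(ids %in% labeled$positive)
}

#' Stratified random train/test split
#'
#' `round(train_frac * n)` ids per class go to training; the split is
#' disjoint and exhaustive and reproducible under `seed`.
#'
#' @param labeled a `labeled_set`.
#' @param train_frac training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with `labeled_set` elements `train` and `test`.
#' @export
split_random <- function(labeled, train_frac = 0.8, seed = 1) {
  if (train_frac <= 0 || train_frac > 1) stop("train_frac must be in (0, 1]")
  pick <- function(ids, seed_offset) {
    k <- round(train_frac * length(ids))
    tr <- with_seed(seed + seed_offset, sample(ids, k))
    list(train = tr, test = setdiff(ids, tr))
  }
  p <- pick(labeled$positive, 0)
  n <- pick(labeled$negative, 1)
  if (length(p$test) + length(n$test) == 0)
    warning("train_frac leaves an empty test set")
  list(train = labeled_set(p$train, n$train),
       test = labeled_set(p$test, n$test))
}

kmer_set <- function(seq, k) {
  seq <- toupper(seq)
  if (nchar(seq) < k) return(character())
  unique(substring(seq, 1:(nchar(seq) - k + 1), k:nchar(seq)))
}

#' Cluster lncRNAs by sequence similarity
#'
#' Single-linkage clusters over pairwise k-mer Jaccard similarity: two
#' sequences are linked when `|A intersect B| / |A union B| >= threshold`,
#' and clusters are the connected components of the link graph.
#'
#' @param sequences named character vector of sequences.
#' @param k k-mer size (default 8).
#' @param threshold Jaccard similarity threshold (default 0.3).
#' @param ids optional ids that must all have sequences; missing ones raise
#'   an error listing them.
#' @return named integer vector mapping each id to a cluster index.
#' @export
cluster_by_similarity <- function(sequences, k = 8, threshold = 0.3,
                                  ids = NULL) {
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(sequences))
    if (length(miss))
      stop("missing sequences for: ", paste(miss, collapse = ", "))
    sequences <- sequences[ids]
  }
  n <- length(sequences)
  if (n == 0) return(setNames(integer(), character()))
  sets <- lapply(sequences, kmer_set, k = k)
  from <- integer(); to <- integer()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(sets[[i]]) + length(sets[[j]]) - inter
      jac <- if (uni == 0) 0 else inter / uni
      if (jac >= threshold) { from <- c(from, i); to <- c(to, j) }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp[as.character(seq_len(n))]), names(sequences))
}

#' Group-aware train/test split with zero cluster leakage
#'
#' Whole clusters are assigned greedily (largest first, random tie-break) to
#' whichever side is furthest below its target size, so no cluster ever
#' spans both sets. Warns when the achieved training fraction deviates more
#' than 5 points from `train_frac`.
#'
#' @param labeled a `labeled_set`.
#' @param clusters named vector id -> cluster (from
#'   [cluster_by_similarity()]); must cover all labeled ids.
#' @param train_frac target training fraction.
#' @param seed RNG seed (tie-breaking and cluster order).
#' @return list with `labeled_set` elements `train` and `test`.
#' @export
split_grouped <- function(labeled, clusters, train_frac = 0.8, seed = 1) {
  ids <- labeled_ids(labeled)
  miss <- setdiff(ids, names(clusters))
  if (length(miss))
    stop("no cluster assignment for: ", paste(miss, collapse = ", "))
  cl <- clusters[ids]
  sizes <- table(cl)
  ord <- with_seed(seed, {
    shuffled <- sample(names(sizes))
    shuffled[order(-as.integer(sizes[shuffled]))]
  })
  n <- length(ids)
  target_train <- train_frac * n
  in_train <- character()
  n_train <- 0; n_test <- 0
  for (cname in ord) {
    sz <- as.integer(sizes[[cname]])
    deficit_train <- target_train - n_train
    deficit_test <- (n - target_train) - n_test
    if (deficit_train >= deficit_test) {
      in_train <- c(in_train, cname); n_train <- n_train + sz
    } else n_test <- n_test + sz
  }
  train_ids <- ids[cl %in% in_train]
  test_ids <- setdiff(ids, train_ids)
  achieved <- length(train_ids) / n
  if (abs(achieved - train_frac) > 0.05)
    warning(sprintf("achieved train fraction %.2f differs from target %.2f",
                    achieved, train_frac))
  list(train = labeled_set(intersect(labeled$positive, train_ids),
                           intersect(labeled$negative, train_ids)),
       test = labeled_set(intersect(labeled$positive, test_ids),
                          intersect(labeled$negative, test_ids)))
}

#' Standardize features and screen predictors on the training set
#'
#' Centers and scales every column by its training mean/SD, drops
#' zero-variance columns, and from any pair with |Pearson r| > `cor_cutoff`
#' on the training rows drops the member with the larger mean absolute
#' correlation. Test data must be transformed with the training statistics
#' only ([apply_preprocess()]).
#'
#' @param M raw feature matrix (rows named by lncRNA id).
#' @param train_ids ids of the training rows.
#' @param cor_cutoff correlation screening threshold (default 0.95).
#' @return list of class `funlnc_prep` with `center`, `scale`, `selected`
#'   and the transformed training matrix `x`.
#' @export
preprocess <- function(M, train_ids, cor_cutoff = 0.95) {
  miss <- setdiff(train_ids, rownames(M))
  if (length(miss)) stop("train ids missing from matrix: ",
                         paste(head(miss, 5), collapse = ", "))
  tr <- M[train_ids, , drop = FALSE]
  sds <- apply(tr, 2, sd)
  keep <- colnames(tr)[sds > 0]
  # iterative pairwise correlation screen (caret::findCorrelation-style)
  repeat {
    if (length(keep) < 2) break
    cm <- abs(cor(tr[, keep, drop = FALSE]))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= cor_cutoff) break
    w <- which(cm == mx, arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(cm)
    drop_j <- if (mean_abs[w[1]] >= mean_abs[w[2]]) w[1] else w[2]
    keep <- keep[-drop_j]
  }
  center <- colMeans(tr[, keep, drop = FALSE])
  scale_ <- apply(tr[, keep, drop = FALSE], 2, sd)
  prep <- structure(list(center = center, scale = scale_, selected = keep),
                    class = "funlnc_prep")
  prep$x <- apply_preprocess(prep, M[train_ids, , drop = FALSE])
  prep
}

#' Apply stored preprocessing to new data
#'
#' @param prep a `funlnc_prep`.
#' @param M raw feature matrix containing at least the selected columns.
#' @return transformed numeric matrix restricted to the selected predictors.
#' @export
apply_preprocess <- function(prep, M) {
  miss <- setdiff(prep$selected, colnames(M))
  if (length(miss)) stop("matrix lacks selected predictors: ",
                         paste(head(miss, 5), collapse = ", "))
  x <- M[, prep$selected, drop = FALSE]
  sweep(sweep(x, 2, prep$center), 2, prep$scale, "/")
}

default_mtry <- function(p) max(1L, floor(sqrt(p)))

#' Train the random-forest classifier
#'
#' Grows `ntree` CART trees on bootstrap samples with `mtry` candidate
#' predictors per split (Gini criterion). When `tune = TRUE`, `mtry` is
#' selected by stratified `cv_folds`-fold cross-validation maximizing
#' AUROC over a small grid around sqrt(p). Class probabilities are the
#' across-tree mean of leaf class fractions; refitting with the same seed
#' reproduces them exactly.
#'
#' @param x preprocessed numeric training matrix.
#' @param y labels: 0/1, logical, or factor/character with levels Fun/Non.
#' @param cv_folds folds for tuning (default 10).
#' @param seed RNG seed.
#' @param ntree number of trees (default 500).
#' @param mtry candidate predictors per split; `NULL` tunes (or uses
#'   sqrt(p) when `tune = FALSE`).
#' @param tune whether to tune `mtry` by cross-validation.
#' @param min_node minimum node size (default 1, i.e. grow to purity).
#' @return object of class `funlnc_rf` with elements `forest`, `importance`,
#'   `mtry`, `ntree`, `seed`, `cv` (tuning table or NULL), `features`.
#' @export
train_rf <- function(x, y, cv_folds = 10, seed = 1, ntree = 500,
                     mtry = NULL, tune = is.null(mtry), min_node = 1) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  p <- ncol(x)
  cv <- NULL
  if (is.null(mtry)) mtry <- default_mtry(p)
  if (tune) {
    grid <- sort(unique(pmin(p, pmax(1L, c(
      floor(default_mtry(p) / 2), default_mtry(p), 2L * default_mtry(p))))))
    folds <- stratified_folds(y, cv_folds, seed)
    cv_auc <- vapply(grid, function(m) {
      aucs <- vapply(seq_along(folds), function(f) {
        hold <- folds[[f]]
        fit <- rf_grow_cpp(x[-hold, , drop = FALSE], y[-hold], ntree, m,
                           min_node, seed + f)
        auroc(rf_predict_cpp(fit$trees, x[hold, , drop = FALSE]), y[hold])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    cv <- data.table(mtry = grid, cv_auroc = cv_auc)
    mtry <- grid[which.max(cv_auc)]
  }
  fit <- rf_grow_cpp(x, y, ntree, mtry, min_node, seed)
  structure(list(
    forest = fit$trees,
    importance = setNames(as.numeric(fit$importance), colnames(x)),
    mtry = mtry, ntree = ntree, min_node = min_node, seed = seed,
    cv = cv, features = colnames(x)
  ), class = "funlnc_rf")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("Fun", "Non"))) stop("character labels must be Fun/Non")
    y <- as.integer(y == "Fun")
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  y
}

stratified_folds <- function(y, k, seed) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  k <- max(2, min(k, length(idx1), length(idx0)))
  assign_folds <- function(idx, seed_offset) {
    idx <- with_seed(seed + seed_offset, sample(idx))
    split(idx, rep_len(seq_len(k), length(idx)))
  }
  f1 <- assign_folds(idx1, 100); f0 <- assign_folds(idx0, 200)
  lapply(seq_len(k), function(i) c(f1[[i]], f0[[i]]))
}

#' @export
print.funlnc_rf <- function(x, ...) {
  cat(sprintf("funlnc_rf: %d trees, mtry %d, %d predictors\n",
              x$ntree, x$mtry, length(x$features)))
  invisible(x)
}

#' Fit the full classification model (preprocessing + forest)
#'
#' Convenience wrapper: preprocesses on the training ids, then trains the
#' forest on the transformed training rows.
#'
#' @param M raw feature matrix.
#' @param train_labeled a `labeled_set` of training ids.
#' @param cv_folds,seed,ntree,mtry,tune passed to [train_rf()].
#' @param cor_cutoff passed to [preprocess()].
#' @return object of class `funlnc_model` with `prep`, `rf`, `seed`.
#' @export
fit_classifier <- function(M, train_labeled, cv_folds = 10, seed = 1,
                           ntree = 500, mtry = NULL, tune = is.null(mtry),
                           cor_cutoff = 0.95) {
  ids <- labeled_ids(train_labeled)
  prep <- preprocess(M, ids, cor_cutoff)
  rf <- train_rf(prep$x, labeled_y(train_labeled, ids), cv_folds = cv_folds,
                 seed = seed, ntree = ntree, mtry = mtry, tune = tune)
  structure(list(prep = prep, rf = rf, seed = seed),
            class = "funlnc_model")
}

#' @export
print.funlnc_model <- function(x, ...) {
  cat("funlnc_model\n  ")
  print(x$rf)
  cat(sprintf("  %d/%d predictors selected\n",
              length(x$prep$selected), length(x$prep$center)))
  invisible(x)
}

#' Predict probabilities and Fun/Non labels
#'
#' The label is `Fun` iff probability >= `threshold` (a tie at the
#' threshold counts as Fun).
#'
#' @param model a `funlnc_model` (raw matrix expected) or `funlnc_rf`
#'   (already-preprocessed matrix expected).
#' @param M feature matrix with lncRNA rownames.
#' @param threshold probability threshold (default 0.5).
#' @return `data.table` with columns `lncrna_id`, `probability`, `label`.
#' @export
predict_and_label <- function(model, M, threshold = 0.5) {
  probs <- predict_probability(model, M)
  data.table(lncrna_id = rownames(M), probability = probs,
             label = ifelse(probs >= threshold, "Fun", "Non"))
}

predict_probability <- function(model, M) {
  if (inherits(model, "funlnc_model")) {
    x <- apply_preprocess(model$prep, M)
    rf_predict_cpp(model$rf$forest, as.matrix(x))
  } else if (inherits(model, "funlnc_rf")) {
    rf_predict_cpp(model$forest, as.matrix(M[, model$features, drop = FALSE]))
  } else stop("model must be funlnc_model or funlnc_rf")
}

#' Area under the ROC curve (midrank statistic)
#'
#' @param probs predicted probabilities.
#' @param y true binary labels.
#' @return AUROC in `[0, 1]`; `NA` when one class is absent.
#' @export
auroc <- function(probs, y) {
  y <- as_binary_labels(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Average precision over distinct probability thresholds, descending:
#' `sum (R_t - R_{t-1}) * P_t` with tied probabilities handled as one block.
#'
#' @param probs predicted probabilities.
#' @param y true binary labels.
#' @return AUPRC in `[0, 1]`; `NA` when no positives.
#' @export
auprc <- function(probs, y) {
  y <- as_binary_labels(y)
  P <- sum(y == 1)
  if (P == 0) return(NA_real_)
  o <- order(-probs)
  probs <- probs[o]; y <- y[o]
  blocks <- cumsum(!duplicated(probs))
  tp <- tapply(y, blocks, sum)
  n <- tapply(y, blocks, length)
  ctp <- cumsum(tp); cn <- cumsum(n)
  prec <- ctp / cn
  rec <- ctp / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate prediction records against known labels
#'
#' @param records `data.table` from [predict_and_label()].
#' @param truth a `labeled_set` (ids not in it are ignored).
#' @param threshold probability threshold for precision/recall.
#' @return list of class `funlnc_eval`: `auroc`, `auprc`, `precision`,
#'   `recall`, `threshold`, `n`.
#' @export
evaluate_predictions <- function(records, truth, threshold = 0.5) {
  ids <- intersect(records$lncrna_id, labeled_ids(truth))
  rec <- records[match(ids, records$lncrna_id)]
  y <- labeled_y(truth, ids)
  pred_fun <- rec$probability >= threshold
  tp <- sum(pred_fun & y == 1)
  fp <- sum(pred_fun & y == 0)
  fn <- sum(!pred_fun & y == 1)
  structure(list(
    auroc = auroc(rec$probability, y),
    auprc = auprc(rec$probability, y),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    threshold = threshold, n = length(ids)
  ), class = "funlnc_eval")
}

#' @export
print.funlnc_eval <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f  AUPRC %.3f  precision %.3f  recall %.3f  (n = %d)\n",
    x$auroc, x$auprc, x$precision, x$recall, x$n))
  invisible(x)
}

#' Feature-category ablation
#'
#' Retrains the model dropping each schema subcategory in turn (same split
#' and seed throughout) and reports metric changes relative to the full
#' model; the `none` row drops nothing and has zero deltas by construction.
#'
#' @param M raw feature matrix with a schema attribute.
#' @param labeled a `labeled_set`.
#' @param train_frac,seed split configuration.
#' @param ntree trees per retrain (tuning is off: one fixed sqrt(p) mtry).
#' @param threshold probability threshold for precision/recall.
#' @return `data.table` with per-subcategory AUROC/precision/recall and
#'   deltas vs the full model.
#' @export
ablate_categories <- function(M, labeled, train_frac = 0.8, seed = 1,
                              ntree = 300, threshold = 0.5) {
  schema <- attr(M, "schema")
  if (is.null(schema)) stop("M needs a schema attribute")
  sp <- split_random(labeled, train_frac, seed)
  run <- function(cols_drop) {
    keep <- setdiff(colnames(M), cols_drop)
    Msub <- M[, keep, drop = FALSE]
    model <- fit_classifier(Msub, sp$train, seed = seed, ntree = ntree,
                            tune = FALSE)
    rec <- predict_and_label(model, Msub, threshold)
    evaluate_predictions(rec, sp$test, threshold)
  }
  full <- run(character())
  cats <- unique(schema$subcategory)
  rows <- lapply(c("none", cats), function(cat) {
    ev <- if (cat == "none") full else
      run(schema$name[schema$subcategory == cat])
    data.table(subcategory = cat, auroc = ev$auroc, auprc = ev$auprc,
               precision = ev$precision, recall = ev$recall,
               d_auroc = ev$auroc - full$auroc,
               d_precision = ev$precision - full$precision,
               d_recall = ev$recall - full$recall)
  })
  rbindlist(rows)
}

#' Flip a fixed fraction of labels
#'
#' Exactly `floor(rate * n)` ids (over both classes pooled) have their class
#' flipped, sampled without replacement; the flipped ids are recorded in the
#' `"flipped"` attribute for audit.
#'
#' @param labeled a `labeled_set`.
#' @param rate flip rate in `[0, 1)`.
#' @param seed RNG seed.
#' @return a new `labeled_set` with attribute `"flipped"`.
#' @export
add_label_noise <- function(labeled, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  ids <- labeled_ids(labeled)
  nflip <- floor(rate * length(ids))
  flip <- if (nflip > 0) with_seed(seed, sample(ids, nflip)) else character()
  pos <- union(setdiff(labeled$positive, flip),
               intersect(labeled$negative, flip))
  neg <- union(setdiff(labeled$negative, flip),
               intersect(labeled$positive, flip))
  out <- labeled_set(pos, neg)
  attr(out, "flipped") <- flip
  out
}

#' Label-noise robustness analysis
#'
#' For every noise rate, repeats `iters` cycles of: flip labels, split
#' 80/20, preprocess, train (fixed mtry, no tuning) and evaluate on the
#' held-out (noisy) labels. Reports per-rate mean and SD of AUROC/AUPRC.
#'
#' @param M raw feature matrix.
#' @param labeled a `labeled_set`.
#' @param rates noise rates (default 0, 5, 10, 15 percent).
#' @param iters iterations per rate (default 20).
#' @param seed master seed.
#' @param ntree trees per retrain.
#' @param train_frac training fraction.
#' @return `data.table` with columns `rate`, `mean_auroc`, `sd_auroc`,
#'   `mean_auprc`, `sd_auprc`.
#' @export
noise_robustness <- function(M, labeled, rates = c(0, 0.05, 0.10, 0.15),
                             iters = 20, seed = 1, ntree = 300,
                             train_frac = 0.8) {
  seeds <- sub_seeds(seed, length(rates) * iters)
  k <- 0
  rows <- lapply(rates, function(rate) {
    met <- vapply(seq_len(iters), function(i) {
      k <<- k + 1
      s <- seeds[k]
      noisy <- add_label_noise(labeled, rate, s)
      sp <- split_random(noisy, train_frac, s)
      model <- fit_classifier(M, sp$train, seed = s, ntree = ntree,
                              tune = FALSE)
      rec <- predict_and_label(model, M)
      ev <- evaluate_predictions(rec, sp$test)
      c(ev$auroc, ev$auprc)
    }, numeric(2))
    data.table(rate = rate,
               mean_auroc = mean(met[1, ]), sd_auroc = sd(met[1, ]),
               mean_auprc = mean(met[2, ]), sd_auprc = sd(met[2, ]))
  })
  rbindlist(rows)
}

#' Mean-decrease-Gini importance scores
#'
#' @param model a `funlnc_model` or `funlnc_rf`.
#' @return named non-negative numeric vector over the selected predictors.
#' @export
importance_scores <- function(model) {
  rf <- if (inherits(model, "funlnc_model")) model$rf else model
  rf$importance
}

#' Per-feature odds ratio and relative risk for the predicted label
#'
#' Each feature is dichotomized at its median (high: value > median) and
#' cross-tabulated against the predicted Fun/Non label into a 2x2 table
#' with cells a (high, Fun), b (high, Non), c (low, Fun), d (low, Non);
#' OR = ad/bc and RR = (a/(a+b)) / (c/(c+d)), with the Haldane correction
#' (+0.5 per cell) whenever any cell is zero.
#'
#' @param M raw feature matrix.
#' @param records prediction records from [predict_and_label()].
#' @return `data.table` with columns `feature`, `odds_ratio`,
#'   `relative_risk`.
#' @export
feature_contribution <- function(M, records) {
  ids <- intersect(rownames(M), records$lncrna_id)
  fun <- records$label[match(ids, records$lncrna_id)] == "Fun"
  rows <- lapply(colnames(M), function(f) {
    v <- M[ids, f]
    high <- v > median(v)
    tab <- or_rr(sum(high & fun), sum(high & !fun),
                 sum(!high & fun), sum(!high & !fun))
    data.table(feature = f, odds_ratio = tab[1], relative_risk = tab[2])
  })
  rbindlist(rows)
}

or_rr <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                              c <- c + 0.5; d <- d + 0.5 }
  c(or = (a * d) / (b * c),
    rr = (a / (a + b)) / (c / (c + d)))
}

#' Persist a fitted model as a text directory
#'
#' Writes the forest as a node TSV, preprocessing state as JSON and
#' hyperparameters as JSON; [read_model()] restores it exactly.
#'
#' @param model a `funlnc_model`.
#' @param dir output directory (created if needed).
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- rbindlist(lapply(seq_along(model$rf$forest), function(t) {
    tm <- model$rf$forest[[t]]
    # %.17g round-trips doubles exactly; split thresholds must not move
    data.table(tree = t, var = tm[, 1],
               split = sprintf("%.17g", tm[, 2]),
               left = tm[, 3], right = tm[, 4],
               prob = sprintf("%.17g", tm[, 5]))
  }))
  fwrite(nodes, file.path(dir, "forest.tsv"), sep = "\t")
  # doubles stored as %.17g strings: JSON numeric serialization rounds
  jsonlite::write_json(list(
    center = as.list(setNames(sprintf("%.17g", model$prep$center),
                              names(model$prep$center))),
    scale = as.list(setNames(sprintf("%.17g", model$prep$scale),
                             names(model$prep$scale))),
    selected = model$prep$selected
  ), file.path(dir, "preprocess.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    mtry = model$rf$mtry, ntree = model$rf$ntree,
    min_node = model$rf$min_node, seed = model$seed,
    features = model$rf$features,
    importance = as.list(model$rf$importance)
  ), file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Restore a model written by [write_model()]
#'
#' @param dir model directory.
#' @return a `funlnc_model`.
#' @export
read_model <- function(dir) {
  nodes <- fread(file.path(dir, "forest.tsv"), sep = "\t")
  forest <- lapply(split(nodes, by = "tree"), function(dt)
    as.matrix(dt[, .(var, split, left, right, prob)]))
  names(forest) <- NULL
  pp <- jsonlite::read_json(file.path(dir, "preprocess.json"),
                            simplifyVector = TRUE)
  pars <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  num <- function(x) {
    v <- unlist(x)
    setNames(as.numeric(v), names(v))
  }
  prep <- structure(list(center = num(pp$center),
                         scale = num(pp$scale),
                         selected = pp$selected), class = "funlnc_prep")
  rf <- structure(list(forest = forest,
                       importance = unlist(pars$importance),
                       mtry = pars$mtry, ntree = pars$ntree,
                       min_node = pars$min_node, seed = pars$seed,
                       cv = NULL, features = pars$features),
                  class = "funlnc_rf")
  structure(list(prep = prep, rf = rf, seed = pars$seed),
            class = "funlnc_model")
}
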