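test_that("split_random stratifies, reproduces under seed and warns at frac 1", {
  lab <- labeled_set(sprintf("p%d", 1:10), sprintf("n%d", 1:10))
  sp <- split_random(lab, 0.8, seed = 3)
  expect_length(sp$train$positive, 8)
  expect_length(sp$train$negative, 8)
  expect_length(sp$test$positive, 2)
  expect_length(sp$test$negative, 2)
  expect_length(intersect(funlnc:::labeled_ids(sp$train),
                          funlnc:::labeled_ids(sp$test)), 0)
  sp2 <- split_random(lab, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_warning(split_random(lab, 1.0, seed = 3), "empty test")
  expect_error(labeled_set(c("a", "b"), c("b", "c")), "both classes")
})

test_that("k-mer clustering matches Jaccard edge cases and the oracle", {
  seqs <- c(a = "ACGTACGTACGTACGT", b = "ACGTACGTACGTACGT",
            c = paste(rep("TTTTGGGG", 4), collapse = ""))
  cl <- cluster_by_similarity(seqs, k = 8, threshold = 0.3)
  expect_equal(cl[["a"]], cl[["b"]])   # identical -> Jaccard 1
  expect_false(cl[["a"]] == cl[["c"]]) # no shared 8-mers
  expect_error(cluster_by_similarity(seqs, ids = c("a", "zzz")), "zzz")

  # oracle: all-pairs single-linkage components at n = 30
  set.seed(99)
  fa <- read_fasta_seqs(default_bundle()$fasta)
  sub <- fa[sample(length(fa), 30)]
  got <- cluster_by_similarity(sub, k = 8, threshold = 0.3)
  sim <- bf_kmer_jaccard(sub, 8)
  exp <- bf_components(sim, 0.3)
  # same partition up to relabeling
  expect_equal(length(unique(got)), length(unique(exp)))
  expect_true(all(tapply(exp, got[names(sub)], function(x)
    length(unique(x))) == 1))
})

test_that("split_grouped never leaks clusters and handles a giant cluster", {
  lab <- labeled_set(sprintf("p%d", 1:50), sprintf("n%d", 1:50))
  ids <- funlnc:::labeled_ids(lab)
  # giant cluster holding 90% of ids goes whole into training
  cl_giant <- setNames(c(rep(1L, 90), 2:11), ids)
  expect_warning(sp <- split_grouped(lab, cl_giant, 0.8, seed = 2),
                 "train fraction")
  train_cl <- unique(cl_giant[funlnc:::labeled_ids(sp$train)])
  test_cl <- unique(cl_giant[funlnc:::labeled_ids(sp$test)])
  expect_length(intersect(train_cl, test_cl), 0)
  expect_true(1L %in% train_cl)
  # all singletons behaves like a plain split at the target fraction
  cl_single <- setNames(seq_along(ids), ids)
  sp2 <- split_grouped(lab, cl_single, 0.8, seed = 2)
  expect_equal(length(funlnc:::labeled_ids(sp2$train)), 80)
  expect_error(split_grouped(lab, cl_single[-1], 0.8, 1), "no cluster")
})

test_that("grouped split leakage is zero over 100 random configurations", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(20:60, 1)
    ids <- sprintf("x%03d", seq_len(n))
    npos <- sample(5:(n - 5), 1)
    lab <- labeled_set(ids[1:npos], ids[(npos + 1):n])
    cl <- setNames(sample.int(max(2, n %/% 3), n, replace = TRUE), ids)
    sp <- suppressWarnings(split_grouped(lab, cl, 0.8, seed = i))
    leak <- intersect(unique(cl[funlnc:::labeled_ids(sp$train)]),
                      unique(cl[funlnc:::labeled_ids(sp$test)]))
    expect_length(leak, 0)
  }
})

test_that("preprocess standardizes on train stats and screens predictors", {
  set.seed(4)
  M <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(sprintf("l%03d", 1:200), paste0("f", 1:6)))
  M[, 4] <- 3                    # constant -> dropped
  M[, 5] <- M[, 1] * 2 + 1e-9    # duplicate of f1 -> one of them dropped
  prep <- preprocess(M, rownames(M)[1:150])
  expect_false("f4" %in% prep$selected)
  expect_equal(sum(c("f1", "f5") %in% prep$selected), 1)
  expect_equal(unname(colMeans(prep$x)), rep(0, ncol(prep$x)),
               tolerance = 1e-12)
  expect_equal(unname(apply(prep$x, 2, sd)), rep(1, ncol(prep$x)))
  # test rows are transformed with train statistics only
  tr <- apply_preprocess(prep, M)
  expect_equal(tr[1:150, ], prep$x)
})

test_that("forest separates toy data, is seed-stable, and collapses under permuted labels", {
  set.seed(8)
  n <- 120
  x <- cbind(sig = c(rnorm(n / 2, 2), rnorm(n / 2, -2)),
             noise = rnorm(n))
  rownames(x) <- sprintf("s%03d", 1:n)
  y <- rep(c(1L, 0L), each = n / 2)
  fit <- train_rf(x, y, cv_folds = 5, seed = 5, ntree = 100, tune = TRUE)
  expect_true(all(fit$cv$cv_auroc > 0.95))
  p <- funlnc:::predict_probability(fit, x)
  expect_true(auroc(p, y) > 0.99)
  # exact reproducibility under the same seed
  fit2 <- train_rf(x, y, cv_folds = 5, seed = 5, ntree = 100, tune = TRUE)
  expect_identical(funlnc:::predict_probability(fit2, x), p)
  # label permutation -> chance-level CV AUROC
  yperm <- sample(y)
  fitp <- train_rf(x, yperm, cv_folds = 5, seed = 5, ntree = 150,
                   tune = TRUE)
  expect_true(all(abs(fitp$cv$cv_auroc - 0.5) < 0.15))
})

test_that("predict_and_label applies the >= threshold convention", {
  rec <- data.table::data.table(lncrna_id = c("a", "b"),
                                probability = c(0.50, 0.49))
  # go through the labeling rule directly
  lab <- ifelse(rec$probability >= 0.5, "Fun", "Non")
  expect_equal(lab, c("Fun", "Non"))
  ms <- default_model_split()
  M <- default_features()
  r1 <- predict_and_label(ms$model, M, threshold = 0.3)
  r2 <- predict_and_label(ms$model, M, threshold = 0.7)
  expect_true(sum(r2$label == "Fun") <= sum(r1$label == "Fun"))
  expect_true(all(r1$probability >= 0 & r1$probability <= 1))
})

test_that("AUROC/AUPRC match oracles and handle ties", {
  set.seed(12)
  for (i in 1:5) {
    n <- 20
    y <- sample(c(0, 1), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(auroc(p, y), bf_auroc(p, y))
  }
  expect_equal(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # AUPRC of a random scorer approximates prevalence
  set.seed(13)
  y <- rep(c(1, 0), c(300, 700))
  expect_equal(auprc(runif(1000), y), 0.3, tolerance = 0.08)
})

test_that("evaluate_predictions computes threshold metrics", {
  rec <- data.table::data.table(
    lncrna_id = c("a", "b", "c", "d"),
    probability = c(0.9, 0.6, 0.4, 0.1),
    label = c("Fun", "Fun", "Non", "Non"))
  ev <- evaluate_predictions(rec, labeled_set(c("a", "c"), c("b", "d")))
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$auroc, 0.75)  # 3 of 4 pos-neg pairs correctly ordered
})

test_that("label noise flips exactly floor(rate * n) with audit trail", {
  lab <- labeled_set(sprintf("p%d", 1:60), sprintf("n%d", 1:40))
  noisy <- add_label_noise(lab, 0.1, seed = 6)
  flipped <- attr(noisy, "flipped")
  expect_length(flipped, 10)
  # flipped positives became negatives and vice versa
  fp <- intersect(flipped, lab$positive)
  expect_true(all(fp %in% noisy$negative))
  fn <- intersect(flipped, lab$negative)
  expect_true(all(fn %in% noisy$positive))
  # rate 0 is the identity
  clean <- add_label_noise(lab, 0, seed = 6)
  expect_setequal(clean$positive, lab$positive)
  expect_error(add_label_noise(lab, 1.0), "rate")
})

test_that("importance scores are non-negative over selected predictors and rank planted signal first", {
  set.seed(21)
  n <- 150
  x <- cbind(planted = c(rnorm(n / 2, 1.5), rnorm(n / 2, -1.5)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c(1L, 0L), each = n / 2)
  fit <- train_rf(x, y, seed = 2, ntree = 200, tune = FALSE)
  imp <- importance_scores(fit)
  expect_length(imp, 3)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "planted")
  expect_true(imp["planted"] > imp["noise1"] && imp["planted"] > imp["noise2"])
})

test_that("feature_contribution reproduces the 2x2 arithmetic", {
  # a=30, b=10, c=10, d=30 -> OR 9, RR 3
  expect_equal(unname(funlnc:::or_rr(30, 10, 10, 30)), c(9, 3))
  # Haldane correction keeps zero-cell tables finite
  res <- funlnc:::or_rr(20, 0, 10, 30)
  expect_true(all(is.finite(res)))
  # independence -> OR near 1
  set.seed(33)
  n <- 2000
  M <- matrix(rnorm(n), ncol = 1,
              dimnames = list(sprintf("l%04d", 1:n), "indep"))
  rec <- data.table::data.table(
    lncrna_id = rownames(M),
    probability = runif(n),
    label = sample(c("Fun", "Non"), n, replace = TRUE))
  fc <- feature_contribution(M, rec)
  expect_equal(fc$odds_ratio, 1, tolerance = 0.35)
})

test_that("model round trip through text persistence is exact", {
  ms <- default_model_split()
  M <- default_features()
  dir <- withr::local_tempdir()
  write_model(ms$model, dir)
  back <- read_model(dir)
  expect_equal(predict_and_label(back, M), predict_and_label(ms$model, M))
  expect_equal(importance_scores(back), importance_scores(ms$model))
})
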