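#' Random permutation scoring of predicted functional lncRNAs
#'
#' The random permutation score of a lncRNA measures how far its predicted
#' probability stands above what the model produces on feature matrices
#' whose columns were shuffled across lncRNAs: score =
#' -log10(c / B) where c counts the permuted-matrix probabilities that
#' strictly exceed the observed one over B permutations. Predicted
#' functional lncRNAs with score > 2 are called high-confidence
#' (HCFun_lncs).
#'
#' @name permscore
NULL

#' Permute a feature matrix column-wise
#'
#' Every feature column is shuffled independently across rows: entries keep
#' their column but change row, so each column's marginal distribution is
#' preserved exactly.
#'
#' @param F numeric feature matrix (rows = lncRNAs).
#' @param seed RNG seed.
#' @return permuted matrix of the same shape (row names dropped: rows no
#'   longer correspond to single lncRNAs).
#' @export
permute_matrix <- function(F, seed = NULL) {
  F <- as.matrix(F)
  if (nrow(F) == 0 || ncol(F) == 0) stop("empty feature matrix")
  out <- with_seed(seed, apply(F, 2, function(col)
    col[sample.int(length(col))]))
  out <- matrix(out, nrow = nrow(F), dimnames = list(NULL, colnames(F)))
  out
}

#' Model probabilities on B column-permuted matrices
#'
#' Column k holds the model's probabilities for every lncRNA computed on the
#' k-th permuted matrix.
#'
#' @param model a `funlnc_model` or `funlnc_rf`.
#' @param F raw feature matrix (n lncRNAs x m features).
#' @param B number of permutations (default 1000).
#' @param seed master seed; permutation k uses a derived sub-seed.
#' @return n x B numeric matrix of probabilities.
#' @export
random_probabilities <- function(model, F, B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  F <- as.matrix(F)
  seeds <- sub_seeds(seed, B)
  r <- matrix(NA_real_, nrow = nrow(F), ncol = B)
  for (k in seq_len(B)) {
    Fk <- permute_matrix(F, seeds[k])
    rownames(Fk) <- rownames(F)  # labels only; rows are scrambled
    r[, k] <- predict_probability(model, Fk)
  }
  rownames(r) <- rownames(F)
  r
}

#' Random permutation score from an exceedance vector
#'
#' Counts strict exceedances c = #\{k : p < r_k\} (ties do not count) and
#' returns `-log10(c / B)` in `raw` mode (+Inf when c = 0) or the
#' always-finite `-log10((c + 1) / (B + 1))` in `safe` mode (default).
#'
#' @param p observed probability in `[0, 1]`.
#' @param r vector of B permuted-matrix probabilities.
#' @param mode `"safe"` or `"raw"`.
#' @return non-negative score (possibly `Inf` in raw mode).
#' @export
perm_score <- function(p, r, mode = c("safe", "raw")) {
  mode <- match.arg(mode)
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]")
  B <- length(r)
  if (B < 1) stop("r must have length >= 1")
  cnt <- sum(p < r)
  if (mode == "raw") -log10(cnt / B) else -log10((cnt + 1) / (B + 1))
}

#' Score all lncRNAs and flag high-confidence functional ones
#'
#' @param records prediction records from [predict_and_label()].
#' @param r n x B matrix from [random_probabilities()] (rows aligned with
#'   `records`).
#' @param mode score estimator (see [perm_score()]).
#' @param threshold HC score cutoff; strict inequality (default 2).
#' @return `records` with columns `score` and `hc_flag` appended;
#'   `hc_flag` is TRUE iff `score > threshold` and `label == "Fun"`.
#' @export
call_hc <- function(records, r, mode = c("safe", "raw"), threshold = 2) {
  mode <- match.arg(mode)
  if (nrow(r) != nrow(records)) stop("r rows must match records")
  out <- copy(as.data.table(records))
  out[, score := vapply(seq_len(.N), function(i)
    perm_score(probability[i], r[i, ], mode), numeric(1))]
  out[, hc_flag := score > threshold & label == "Fun"]
  out
}

#' End-to-end random permutation scoring
#'
#' Predicts, permutes, scores and flags in one call.
#'
#' @param model a `funlnc_model`.
#' @param F raw feature matrix of the lncRNAs to score.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @param mode score estimator (see [perm_score()]).
#' @param threshold probability threshold for the Fun label.
#' @param hc_threshold HC score cutoff (default 2).
#' @return prediction records with `score` and `hc_flag`.
#' @export
random_permutation_score <- function(model, F, B = 1000, seed = 1,
                                     mode = c("safe", "raw"),
                                     threshold = 0.5, hc_threshold = 2) {
  records <- predict_and_label(model, F, threshold)
  r <- random_probabilities(model, F, B, seed)
  call_hc(records, r, mode = match.arg(mode), threshold = hc_threshold)
}
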