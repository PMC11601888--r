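# Shared fixtures, built once per test run. The default bundle is the
# package's stated simulated world (sim_config() defaults, seed 1).
.shared <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.shared$bundle)) {
    dir <- file.path(tempdir(), "funlnc_default_bundle")
    .shared$bundle <- simulate_dataset(sim_config(seed = 1), dir)
  }
  .shared$bundle
}

default_network <- function() {
  if (is.null(.shared$network))
    .shared$network <- build_network_bundle(default_bundle())
  .shared$network
}

default_features <- function() {
  if (is.null(.shared$features))
    .shared$features <- build_feature_matrix(default_network())
  .shared$features
}

default_labeled <- function() read_labels(default_bundle())

# a small fitted model on the default world, shared across tests
default_model_split <- function() {
  if (is.null(.shared$model)) {
    sp <- split_random(default_labeled(), 0.8, seed = 11)
    .shared$model <- fit_classifier(default_features(), sp$train,
                                    seed = 11, ntree = 300, tune = FALSE)
    .shared$split <- sp
  }
  list(model = .shared$model, split = .shared$split)
}

# random interval set in BED coordinates for property tests
random_intervals <- function(n, chroms = c("chrA", "chrB"),
                             max_pos = 10000, max_len = 500) {
  st <- sample.int(max_pos, n, replace = TRUE)
  intervals(chrom = sample(chroms, n, replace = TRUE),
            start = st, end = st + sample.int(max_len, n, replace = TRUE),
            name = sprintf("e%03d", seq_len(n)),
            signal = round(runif(n, 0.1, 10), 3))
}

random_promoters <- function(n, chroms = c("chrA", "chrB"),
                             max_pos = 10000, window = 300) {
  tss <- sample.int(max_pos, n, replace = TRUE) + window
  derive_promoters(data.table::data.table(
    id = sprintf("lnc%02d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tss = tss), window)
}
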