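#' Pipeline run configuration
#'
#' @param bundle_dir directory with a fixture/manifest bundle
#'   ([load_bundle()]); ignored when `simulate` is given.
#' @param simulate optional list of [sim_config()] arguments; when present
#'   the pipeline first simulates its own inputs.
#' @param window promoter half-width (bp).
#' @param max_dist distal assignment radius (bp).
#' @param split `"random"` or `"grouped"` (sequence-similarity clusters).
#' @param train_frac training fraction.
#' @param cv_folds cross-validation folds for mtry tuning.
#' @param ntree forest size.
#' @param B permutations for the random permutation score.
#' @param score_mode `"safe"` or `"raw"`.
#' @param threshold probability threshold for the Fun label.
#' @param hc_threshold HC score cutoff.
#' @param seed master seed, recorded in every output.
#' @return list of class `run_config`.
#' @export
run_config <- function(bundle_dir = NULL, simulate = NULL, window = 2000,
                       max_dist = 50000, split = c("random", "grouped"),
                       train_frac = 0.8, cv_folds = 10, ntree = 500,
                       B = 1000, score_mode = c("safe", "raw"),
                       threshold = 0.5, hc_threshold = 2, seed = 1) {
  split <- match.arg(split)
  score_mode <- match.arg(score_mode)
  if (is.null(bundle_dir) && is.null(simulate))
    stop("run_config needs bundle_dir or simulate")
  if (!is.null(bundle_dir) && is.null(simulate) &&
      !file.exists(file.path(bundle_dir, "manifest.json")))
    stop("no manifest.json under bundle_dir: ", bundle_dir)
  structure(list(bundle_dir = bundle_dir, simulate = simulate,
                 window = window, max_dist = max_dist, split = split,
                 train_frac = train_frac, cv_folds = cv_folds,
                 ntree = ntree, B = B, score_mode = score_mode,
                 threshold = threshold, hc_threshold = hc_threshold,
                 seed = seed),
            class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[funlnc] %-14s %6.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline
#'
#' Simulate or load inputs, build the multi-omic network, featurize, train
#' and evaluate the classifier, then score every lncRNA with the random
#' permutation score. Writes `edges.tsv`, `network_summary.json`,
#' `features.tsv`, `model/`, `eval.json`, `predictions.tsv` and
#' `manifest.json` under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisible list with the in-memory artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sc <- do.call(sim_config, config$simulate)
      simulate_dataset(sc, file.path(out_dir, "simulated"))
    } else load_bundle(config$bundle_dir)
  })
  network <- stage("build-network",
                   build_network_bundle(bundle, config$window,
                                        config$max_dist))
  write_network(network, file.path(out_dir, "edges.tsv"),
                file.path(out_dir, "network_summary.json"))
  M <- stage("featurize",
             build_feature_matrix(network, max_dist = config$max_dist))
  write_features(M, file.path(out_dir, "features.tsv"),
                 file.path(out_dir, "schema.json"))
  labeled <- read_labels(bundle)
  sp <- stage("split", {
    if (config$split == "grouped") {
      seqs <- read_fasta_seqs(bundle$fasta)
      clusters <- cluster_by_similarity(seqs, ids = labeled_ids(labeled))
      split_grouped(labeled, clusters, config$train_frac, config$seed)
    } else split_random(labeled, config$train_frac, config$seed)
  })
  model <- stage("train",
                 fit_classifier(M, sp$train, cv_folds = config$cv_folds,
                                seed = config$seed, ntree = config$ntree))
  write_model(model, file.path(out_dir, "model"))
  records <- stage("predict", predict_and_label(model, M, config$threshold))
  eval_ <- evaluate_predictions(records, sp$test, config$threshold)
  jsonlite::write_json(unclass(eval_), file.path(out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA)
  scored <- stage("permscore",
                  call_hc(records,
                          random_probabilities(model, M, config$B,
                                               config$seed),
                          mode = config$score_mode,
                          threshold = config$hc_threshold))
  fwrite(scored, file.path(out_dir, "predictions.tsv"), sep = "\t")
  jsonlite::write_json(list(
    config = unclass(config),
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("funlnc")),
    timestamp = format(Sys.time(), tz = "UTC")
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(bundle = bundle, network = network, features = M,
                 split = sp, model = model, eval = eval_,
                 predictions = scored))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run`, `build-network`, `featurize`, `train`,
#' `predict`, `permscore`, `ablate`, `noise`. All accept `--out DIR`,
#' `--seed N` and where relevant `--bundle DIR`, `--model DIR`, `--B N`,
#' `--mode safe|raw`. The `exec/funlnc` script forwards to this function.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the main artifact of the subcommand.
#' @export
funlnc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) stop(
    "usage: funlnc <simulate|run|build-network|featurize|train|predict|",
    "permscore|ablate|noise> [--bundle DIR] [--out DIR] [--seed N] ...")
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i)) args[i[1] + 1] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "funlnc_out")
  bundle_dir <- opt("bundle")
  invisible(switch(cmd,
    simulate = simulate_dataset(sim_config(
      n_lncrnas = as.integer(opt("n", "200")), seed = seed), out),
    run = run_pipeline(run_config(
      bundle_dir = bundle_dir,
      simulate = if (is.null(bundle_dir)) list(seed = seed),
      split = opt("split", "random"),
      B = as.integer(opt("B", "1000")),
      score_mode = opt("mode", "safe"), seed = seed), out),
    `build-network` = {
      net <- build_network_bundle(load_bundle(bundle_dir))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_network(net, file.path(out, "edges.tsv"),
                    file.path(out, "network_summary.json"))
      net
    },
    featurize = {
      net <- build_network_bundle(load_bundle(bundle_dir))
      M <- build_feature_matrix(net)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_features(M, file.path(out, "features.tsv"),
                     file.path(out, "schema.json"))
      M
    },
    train = run_pipeline(run_config(bundle_dir = bundle_dir, seed = seed,
                                    B = as.integer(opt("B", "1000")),
                                    score_mode = opt("mode", "safe")), out),
    predict = {
      model <- read_model(opt("model"))
      M <- read_features(opt("features"))
      rec <- predict_and_label(model, M)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      fwrite(rec, file.path(out, "predictions.tsv"), sep = "\t")
      rec
    },
    permscore = {
      model <- read_model(opt("model"))
      M <- read_features(opt("features"))
      scored <- random_permutation_score(
        model, M, B = as.integer(opt("B", "1000")), seed = seed,
        mode = opt("mode", "safe"))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      fwrite(scored, file.path(out, "predictions.tsv"), sep = "\t")
      scored
    },
    ablate = {
      bundle <- load_bundle(bundle_dir)
      net <- build_network_bundle(bundle)
      M <- build_feature_matrix(net)
      res <- ablate_categories(M, read_labels(bundle), seed = seed)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      fwrite(res, file.path(out, "ablation.tsv"), sep = "\t")
      res
    },
    noise = {
      bundle <- load_bundle(bundle_dir)
      net <- build_network_bundle(bundle)
      M <- build_feature_matrix(net)
      res <- noise_robustness(M, read_labels(bundle), seed = seed)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      fwrite(res, file.path(out, "noise.tsv"), sep = "\t")
      res
    },
    stop("unknown subcommand: ", cmd)
  ))
}
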