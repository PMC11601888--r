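#' Simulation configuration
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' class-dependent Poisson counts of regulatory elements per promoter,
#' log-normal peak signals with higher location for functional lncRNAs on
#' informative kinds, 3D interaction anchors placing a configured fraction
#' of distal elements in contact with promoters, downstream pair tables
#' with class-dependent degree, and sequences with configurable duplicate
#' clusters for split testing.
#'
#' Defaults state the simulated world used throughout the package tests:
#' 200 lncRNAs, 60% functional (mirroring the 238:152 ratio of the curated
#' hESC positive/negative sets), TF ChIP / histone / typical-enhancer
#' element rates 8 per functional vs 2 per nonfunctional promoter, all
#' other kinds class-balanced.
#'
#' @param n_lncrnas number of lncRNAs (default 200).
#' @param positive_fraction fraction labeled functional (default 0.6).
#' @param genome_size bp per chromosome (default 5e7).
#' @param chroms chromosome names (default chr1, chr2).
#' @param promoter_window promoter half-width used downstream (bp).
#' @param max_dist distal assignment radius (bp).
#' @param rates per-kind rate table; `NULL` for defaults (see Details).
#' @param interaction_fraction fraction of distal elements wired to their
#'   promoter by an anchor pair (default 0.7).
#' @param n_decoy_pairs anchor pairs placed away from promoters.
#' @param downstream named list of `c(pos, neg)` Poisson degree rates for
#'   mRNA / miRNA / protein partners.
#' @param seq_len_range lncRNA sequence length range (nt).
#' @param n_seq_clusters,seq_cluster_size,seq_mutation_rate near-duplicate
#'   sequence clusters for grouped-split tests.
#' @param flat if TRUE, every positive rate is forced equal to its negative
#'   rate (a no-signal world).
#' @param seed master RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lncrnas = 200, positive_fraction = 0.6,
                       genome_size = 5e7, chroms = c("chr1", "chr2"),
                       promoter_window = 2000, max_dist = 50000,
                       rates = NULL, interaction_fraction = 0.7,
                       n_decoy_pairs = 50,
                       downstream = list(mRNA = c(5, 1), miRNA = c(3, 1),
                                         protein = c(2, 1)),
                       seq_len_range = c(500, 1500),
                       n_seq_clusters = 10, seq_cluster_size = 4,
                       seq_mutation_rate = 0.01,
                       flat = FALSE, seed = 1) {
  if (is.null(rates)) rates <- data.table(
    kind = c("tf_chip", "tf_motif", "histone", "methylation",
             "snp_risk", "snp_common", "enhancer_te", "enhancer_se", "atac"),
    lambda_pos = c(8, 3, 8, 3, 1, 2, 8, 1, 3),
    lambda_neg = c(2, 3, 2, 3, 1, 2, 2, 1, 3),
    meanlog_pos = c(1.5, 1.0, 1.5, 1.0, 0, 0, 1.5, 1.0, 1.0),
    meanlog_neg = c(1.0, 1.0, 1.0, 1.0, 0, 0, 1.0, 1.0, 1.0),
    sdlog = c(0.5, 0.5, 0.5, 0.5, 0, 0, 0.5, 0.5, 0.5),
    samples = c(2, 1, 2, 1, 1, 1, 2, 1, 1),
    width = c(300, 200, 500, 2, 1, 1, 2000, 20000, 800),
    placement = c("proximal", "proximal", "proximal", "proximal",
                  "proximal", "proximal", "distal", "distal", "distal"))
  rates <- as.data.table(rates)
  if (flat) {
    rates[, lambda_pos := lambda_neg]
    rates[, meanlog_pos := meanlog_neg]
    downstream <- lapply(downstream, function(x) c(x[2], x[2]))
  }
  cfg <- list(n_lncrnas = n_lncrnas, positive_fraction = positive_fraction,
              genome_size = genome_size, chroms = chroms,
              promoter_window = promoter_window, max_dist = max_dist,
              rates = rates, interaction_fraction = interaction_fraction,
              n_decoy_pairs = n_decoy_pairs, downstream = downstream,
              seq_len_range = seq_len_range,
              n_seq_clusters = n_seq_clusters,
              seq_cluster_size = seq_cluster_size,
              seq_mutation_rate = seq_mutation_rate, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  r <- cfg$rates
  if (any(r$lambda_pos < 0 | r$lambda_neg < 0))
    stop("element rates must be >= 0")
  if (any(r$lambda_pos < r$lambda_neg))
    stop("lambda_pos must be >= lambda_neg for every kind")
  if (cfg$positive_fraction <= 0 || cfg$positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)")
  if (cfg$n_lncrnas < 4) stop("need at least 4 lncRNAs")
  if (cfg$interaction_fraction < 0 || cfg$interaction_fraction > 1)
    stop("interaction_fraction must be in [0, 1]")
  invisible(cfg)
}

SIM_TF_POOL <- c("SOX2", "MYC", "NANOG", "OCT4",
                 paste0("TF", sprintf("%02d", 5:30)))
SIM_MARKS <- c("H3K27ac", "H3K4me3", "H3K4me1", "H3K9ac", "H3K27me3")

#' Simulate a self-contained on-disk fixture bundle
#'
#' Writes lncRNA BED12, per-kind-and-sample element BEDs, BEDPE anchors,
#' a downstream pair table, truth labels, FASTA sequences, a file manifest
#' and the configuration; byte-identical under the same seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisible bundle list (see [load_bundle()]).
#' @export
simulate_dataset <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- sub_seeds(config$seed, 8)
  n <- config$n_lncrnas

  # gene models and labels
  genes <- with_seed(seeds[1], {
    per_chrom <- ceiling(n / length(config$chroms))
    spacing <- config$genome_size / per_chrom
    dt <- data.table(
      id = sprintf("lnc%04d", seq_len(n)),
      chrom = rep(config$chroms, each = per_chrom)[seq_len(n)],
      slot = rep(seq_len(per_chrom), length(config$chroms))[seq_len(n)])
    dt[, tss := round((slot - 0.5) * spacing +
                        runif(.N, -spacing / 8, spacing / 8))]
    dt[, tss := pmax(tss, 10000)]
    dt[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    dt[, positive := id %in% sample(id, round(n * config$positive_fraction))]
    dt
  })
  glen <- 1000
  bed12 <- genes[, {
    st <- ifelse(strand == "+", tss, tss - glen + 1)
    en <- st + glen
    data.table(chrom, st, en, id, 0, strand, st, en, "0", 1, glen, 0)
  }]
  lnc_path <- file.path(out_dir, "lncrnas.bed")
  fwrite(bed12, lnc_path, sep = "\t", col.names = FALSE)
  labels_path <- file.path(out_dir, "labels.tsv")
  fwrite(genes[, .(lncrna_id = id, label = ifelse(positive, "Fun", "Non"))],
         labels_path, sep = "\t")

  # element files, one per kind and biosample
  manifest <- list()
  element_seeds <- sub_seeds(seeds[2], nrow(config$rates) * 10)
  es <- 0
  pair_rows <- list()  # interaction anchors wired from distal elements
  for (ri in seq_len(nrow(config$rates))) {
    r <- config$rates[ri]
    for (s in seq_len(r$samples)) {
      es <- es + 1
      dt <- with_seed(element_seeds[es], {
        counts <- rpois(n, ifelse(genes$positive, r$lambda_pos,
                                  r$lambda_neg))
        gi <- rep(seq_len(n), counts)
        m <- length(gi)
        if (m == 0) NULL else {
        w <- r$width
        offset <- if (r$placement == "proximal")
          round(runif(m, -config$promoter_window + w,
                      config$promoter_window - w)) else
          sample(c(-1, 1), m, TRUE) *
            round(runif(m, config$promoter_window + 1000, 40000))
        center <- genes$tss[gi] + offset
        st <- pmax(0, center - floor(w / 2))
        en <- st + w
        sig <- if (r$sdlog > 0)
          rlnorm(m, ifelse(genes$positive[gi], r$meanlog_pos, r$meanlog_neg),
                 r$sdlog) else rep(1, m)
        nm <- if (r$kind == "tf_chip" || r$kind == "tf_motif")
          sample(SIM_TF_POOL, m, TRUE)
        else if (r$kind == "histone") sample(SIM_MARKS, m, TRUE)
        else sprintf("%s_s%d_%05d", r$kind, s, seq_len(m))
        el <- data.table(chrom = genes$chrom[gi], start = st, end = en,
                         name = nm, signal = round(sig, 4), strand = ".",
                         gi = gi, center = center)
        if (r$placement == "distal") {
          wired_v <- runif(m) < config$interaction_fraction
          el[, wired := wired_v]
        }
        el
        }
      })
      if (is.null(dt)) next
      path <- file.path(out_dir, sprintf("%s_s%d.bed", r$kind, s))
      fwrite(dt[, .(chrom, start, end, name, signal, strand)], path,
             sep = "\t", col.names = FALSE)
      manifest[[length(manifest) + 1]] <-
        data.table(path = basename(path), kind = r$kind,
                   sample_id = sprintf("s%d", s))
      if (r$placement == "distal" && "wired" %in% names(dt))
        pair_rows[[length(pair_rows) + 1]] <- dt[wired == TRUE,
          .(chrom, e_start = start, e_end = end, gi)]
    }
  }

  # BEDPE: anchor A on the element, anchor B inside the promoter
  bedpe_path <- file.path(out_dir, "interactions.bedpe")
  wired <- rbindlist(pair_rows)
  pe <- with_seed(seeds[3], {
    rows <- if (nrow(wired)) wired[, {
      pa <- genes$tss[gi] + round(runif(.N, -1000, 1000))
      data.table(chrom, e_start, e_end, chrom2 = chrom,
                 b_start = pmax(0, pa - 1000), b_end = pa + 1000,
                 freq = 1 + rpois(.N, 2))
    }] else data.table()
    if (config$n_decoy_pairs > 0) {
      dc <- data.table(
        chrom = sample(config$chroms, config$n_decoy_pairs, TRUE),
        a = round(runif(config$n_decoy_pairs, 1e5, config$genome_size)))
      # decoys sit midway between promoter grids, far from any TSS
      dc[, a := a - (a %% 100000) + 60000]
      rows <- rbind(rows, dc[, .(chrom, e_start = a, e_end = a + 2000,
                                 chrom2 = chrom, b_start = a + 5000,
                                 b_end = a + 7000, freq = 1)],
                    use.names = FALSE)
    }
    rows
  })
  if (nrow(pe) == 0) {
    file.create(bedpe_path)
  } else {
    pe[, name := sprintf("pair_%05d", seq_len(.N))]
    fwrite(pe[, .(chrom, e_start, e_end, chrom2, b_start, b_end, name,
                  freq)],
           bedpe_path, sep = "\t", col.names = FALSE)
  }

  # downstream pair table with class-dependent degree
  pairs_path <- file.path(out_dir, "pairs.tsv")
  pools <- list(mRNA = sprintf("gene%03d", 1:500),
                miRNA = sprintf("miR-%03d", 1:200),
                protein = sprintf("prot%03d", 1:150))
  ds <- with_seed(seeds[4], rbindlist(lapply(names(config$downstream),
    function(kd) {
      rate <- config$downstream[[kd]]
      deg <- rpois(n, ifelse(genes$positive, rate[1], rate[2]))
      gi <- rep(seq_len(n), deg)
      if (!length(gi)) return(NULL)
      data.table(lncrna_id = genes$id[gi],
                 partner_id = sample(pools[[kd]], length(gi), TRUE),
                 partner_kind = kd)
    })))
  fwrite(unique(ds), pairs_path, sep = "\t")

  # sequences with near-duplicate clusters
  fasta_path <- file.path(out_dir, "sequences.fa")
  seqs <- with_seed(seeds[5], {
    rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                    collapse = "")
    lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]),
                   n, TRUE)
    out <- vapply(lens, rand_seq, character(1))
    names(out) <- genes$id
    n_cl <- min(config$n_seq_clusters,
                floor(n / config$seq_cluster_size / 2))
    if (n_cl > 0) {
      members <- sample(genes$id, n_cl * config$seq_cluster_size)
      grp <- split(members, rep(seq_len(n_cl), each = config$seq_cluster_size))
      for (g in grp) {
        base <- strsplit(out[[g[1]]], "")[[1]]
        for (m in g[-1]) {
          mut <- runif(length(base)) < config$seq_mutation_rate
          s <- base
          s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), TRUE)
          out[[m]] <- paste(s, collapse = "")
        }
      }
    }
    out
  })
  writeLines(paste0(">", names(seqs), "\n", seqs), fasta_path)

  manifest <- rbindlist(manifest)
  jsonlite::write_json(list(
    lncrnas = basename(lnc_path), labels = basename(labels_path),
    bedpe = basename(bedpe_path), pairs = basename(pairs_path),
    fasta = basename(fasta_path),
    elements = manifest,
    promoter_window = config$promoter_window, max_dist = config$max_dist,
    seed = config$seed
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(load_bundle(out_dir))
}

#' Load a simulated (or equivalently structured) fixture bundle
#'
#' @param dir directory containing `manifest.json` as written by
#'   [simulate_dataset()].
#' @return list with paths, the parsed manifest, and the promoter window /
#'   assignment radius.
#' @export
load_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  list(dir = dir,
       lncrnas = file.path(dir, mf$lncrnas),
       labels = file.path(dir, mf$labels),
       bedpe = file.path(dir, mf$bedpe),
       pairs = file.path(dir, mf$pairs),
       fasta = file.path(dir, mf$fasta),
       elements = as.data.table(mf$elements),
       promoter_window = mf$promoter_window,
       max_dist = mf$max_dist, seed = mf$seed)
}

#' Build the multi-omic network from a fixture bundle
#'
#' Proximal kinds are assigned by promoter overlap; distal kinds by both
#' distance and chromatin interaction; anchor pairs also contribute the
#' interaction-frequency edges; the pair table contributes downstream
#' edges. Global per-kind signal pools are registered for rank features.
#'
#' @param bundle list from [load_bundle()].
#' @param window promoter half-width; defaults to the bundle's.
#' @param max_dist distal radius; defaults to the bundle's.
#' @return a `funlnc_network`.
#' @export
build_network_bundle <- function(bundle, window = NULL, max_dist = NULL) {
  if (is.null(window)) window <- bundle$promoter_window
  if (is.null(max_dist)) max_dist <- bundle$max_dist
  genes <- read_lncrna_bed(bundle$lncrnas)
  promoters <- derive_promoters(genes, window)
  pairs <- read_bedpe(bundle$bedpe)
  edges <- list()
  pools <- list()
  for (i in seq_len(nrow(bundle$elements))) {
    row <- bundle$elements[i]
    el <- read_bed(file.path(bundle$dir, row$path), kind = row$kind)
    pools[[row$kind]] <- c(pools[[row$kind]], mcols(el)$signal)
    if (row$kind %in% UPSTREAM_PROXIMAL_KINDS) {
      edges[[length(edges) + 1]] <-
        assign_proximal(promoters, el, row$kind, row$sample_id)
    } else {
      edges[[length(edges) + 1]] <-
        assign_distance(promoters, el, row$kind, row$sample_id, max_dist)
      edges[[length(edges) + 1]] <-
        assign_by_interaction(promoters, el, pairs, row$kind, row$sample_id)
    }
  }
  edges[[length(edges) + 1]] <- interaction_edges(promoters, pairs)
  edges[[length(edges) + 1]] <-
    build_downstream(read_pair_table(bundle$pairs))
  integrate_network(edges, lncrna_ids = genes$id, pools = pools)
}

#' Read truth labels from a bundle
#'
#' @param bundle list from [load_bundle()] (or a labels TSV path).
#' @return a `labeled_set`.
#' @export
read_labels <- function(bundle) {
  path <- if (is.list(bundle)) bundle$labels else bundle
  dt <- fread(path, sep = "\t")
  labeled_set(dt$lncrna_id[dt$label == "Fun"],
              dt$lncrna_id[dt$label == "Non"])
}

#' Tiny worked example with hand-checkable feature values
#'
#' Three lncRNAs on one chromosome: lncA has SOX2 and NANOG ChIP peaks
#' (tf_chip_count 2, both core), two activating histone marks, one
#' methylation site and a distance-linked super-enhancer 40 kb away that is
#' also wired by one anchor pair of frequency 3; lncB has one H3K4me3 peak
#' (from two biosamples) and two target mRNAs; lncC has nothing and gets an
#' all-zero feature row.
#'
#' @return list with `genes`, `promoters`, `network`, `labeled`.
#' @export
worked_micro_example <- function() {
  genes <- data.table(id = c("lncA", "lncB", "lncC"),
                      chrom = "chr1", strand = c("+", "+", "-"),
                      tss = c(10000, 500000, 900000))
  promoters <- derive_promoters(genes, 2000)
  tf <- intervals("chr1", c(9500, 10500), c(9700, 10800),
                  name = c("SOX2", "NANOG"), signal = c(5, 3))
  hist1 <- intervals("chr1", c(9000, 11000, 499500), c(9400, 11400, 499900),
                     name = c("H3K27ac", "H3K4me3", "H3K4me3"),
                     signal = c(4, 6, 2))
  hist2 <- intervals("chr1", 499600, 499900, name = "H3K4me3", signal = 3)
  meth <- intervals("chr1", 10100, 10102, name = "cpg_1", signal = 2)
  se <- intervals("chr1", 45000, 65000, name = "SE_1", signal = 50)
  pairs <- anchor_pairs_new(
    intervals("chr1", 50000, 52000, name = "p1_a"),
    intervals("chr1", 9000, 11000, name = "p1_b"),
    "p1", 3)
  ds <- data.table(lncrna_id = c("lncB", "lncB"),
                   partner_id = c("gene001", "gene002"),
                   partner_kind = "mRNA")
  network <- integrate_network(list(
    assign_proximal(promoters, tf, "tf_chip", "s1"),
    assign_proximal(promoters, hist1, "histone", "s1"),
    assign_proximal(promoters, hist2, "histone", "s2"),
    assign_proximal(promoters, meth, "methylation", "s1"),
    assign_distance(promoters, se, "enhancer_se", "s1", 50000),
    assign_by_interaction(promoters, se, pairs, "enhancer_se", "s1"),
    interaction_edges(promoters, pairs),
    build_downstream(ds)
  ), lncrna_ids = genes$id,
  pools = list(enhancer_se = mcols(se)$signal))
  list(genes = genes, promoters = promoters, network = network,
       labeled = labeled_set(c("lncA", "lncB"), "lncC"))
}
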