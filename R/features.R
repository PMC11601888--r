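#' The 57-feature multi-omic schema
#'
#' Features fall into three categories: C1 upstream proximal (8 features:
#' TFs, histone marks, methylation, SNPs at the promoter), C2 upstream
#' distal (46 features: super-enhancers, typical enhancers, chromatin
#' accessibility, linked by distance or 3D chromatin interaction, plus the
#' 3D contact frequency), and C3 downstream (3 features: target mRNAs,
#' miRNAs, bound proteins). Sub-category cardinalities are SE 12, TE 23,
#' accessibility 10, 3D 1.
#'
#' The exact per-column statistics within C2 are a documented stand-in that
#' reproduces those cardinalities: SE = 2 manners x \{count, signal_sum,
#' signal_max, rank_mean, rank_best, constituent_count\}; accessibility = 2
#' manners x \{count, signal_sum, signal_max, rank_mean, rank_best\}; TE = 2
#' manners x \{count, signal_sum, signal_max, signal_mean, rank_mean,
#' rank_best, constituent_count, prom_overlap_count, nearest_dist_norm,
#' freq_weighted_count, sample_count\} + 1 combined TE-or-SE count.
#'
#' @return `data.table` with columns `name`, `category`, `subcategory`,
#'   `kind`, `manner`, `statistic`; exactly 57 rows.
#' @export
feature_schema <- function() {
  manners <- c(d = "distance_assigned", i = "chromatin_interaction")
  per_manner <- function(prefix, kind, subcat, stats) {
    rbindlist(lapply(names(manners), function(m) data.table(
      name = sprintf("%s_%s_%s", prefix, m, stats),
      category = "C2", subcategory = subcat, kind = kind,
      manner = manners[[m]], statistic = stats)))
  }
  c1 <- data.table(
    name = c("snp_risk_count", "snp_common_count", "tf_chip_count",
             "tf_chip_core_count", "tf_motif_count", "meth_count",
             "meth_signal_norm", "histone_act_type_count"),
    category = "C1",
    subcategory = c("SNP", "SNP", "TF", "TF", "TF", "Methylation",
                    "Methylation", "Histone"),
    kind = c("snp_risk", "snp_common", "tf_chip", "tf_chip", "tf_motif",
             "methylation", "methylation", "histone"),
    manner = "proximal",
    statistic = c("count", "count", "distinct_count", "core_count",
                  "distinct_count", "count", "signal_sum_norm", "type_count"))
  se <- per_manner("se", "enhancer_se", "SE",
                   c("count", "signal_sum", "signal_max", "rank_mean",
                     "rank_best", "constituent_count"))
  te <- per_manner("te", "enhancer_te", "TE",
                   c("count", "signal_sum", "signal_max", "signal_mean",
                     "rank_mean", "rank_best", "constituent_count",
                     "prom_overlap_count", "nearest_dist_norm",
                     "freq_weighted_count", "sample_count"))
  te_extra <- data.table(name = "te_se_combined_count", category = "C2",
                         subcategory = "TE", kind = "enhancer_te",
                         manner = "any", statistic = "combined_count")
  atac <- per_manner("atac", "atac", "Accessibility",
                     c("count", "signal_sum", "signal_max", "rank_mean",
                       "rank_best"))
  c2_3d <- data.table(name = "interaction_frequency", category = "C2",
                      subcategory = "3D", kind = "interaction",
                      manner = "chromatin_interaction",
                      statistic = "frequency")
  c3 <- data.table(
    name = c("mrna_count", "mirna_count", "protein_count"),
    category = "C3",
    subcategory = c("mRNA_miRNA", "mRNA_miRNA", "Protein"),
    kind = c("mRNA", "miRNA", "protein"),
    manner = c("targeted", "targeted", "annotated"),
    statistic = "distinct_count")
  schema <- rbindlist(list(c1, se, te, te_extra, atac, c2_3d, c3))
  validate_schema(schema)
  schema
}

#' Validate a feature schema against the category cardinalities
#'
#' @param schema a schema `data.table` (see [feature_schema()]).
#' @return the schema, invisibly; errors if any cardinality is violated.
#' @export
validate_schema <- function(schema) {
  schema <- as.data.table(schema)
  if (nrow(schema) != 57) stop("schema must have exactly 57 features, got ",
                               nrow(schema))
  if (anyDuplicated(schema$name)) stop("duplicate feature names in schema")
  cc <- table(schema$category)
  want_cat <- c(C1 = 8L, C2 = 46L, C3 = 3L)
  if (!identical(as.integer(cc[names(want_cat)]), unname(want_cat)))
    stop("category counts must be C1=8, C2=46, C3=3")
  sub <- table(schema$subcategory)
  want <- c(SNP = 2, TF = 3, Methylation = 2, Histone = 1, SE = 12, TE = 23,
            Accessibility = 10, `3D` = 1, mRNA_miRNA = 2, Protein = 1)
  for (s in names(want))
    if (is.na(sub[s]) || sub[s] != want[s])
      stop(sprintf("subcategory %s must have %d features", s, want[s]))
  invisible(schema)
}

#' Default core pluripotency transcription factors
#' @export
CORE_TFS <- c("SOX2", "MYC", "NANOG", "OCT4")

#' Default transcription-activating histone marks
#' @export
ACTIVATING_MARKS <- c("H3K27ac", "H3K4me3", "H3K4me1", "H3K9ac")

edges_of <- function(network, kinds, manners = NULL) {
  e <- network$edges[partner_kind %in% kinds]
  if (!is.null(manners)) e <- e[manner %in% manners]
  e
}

check_lnc <- function(network, lncrna_id) {
  if (!lncrna_id %in% network$lncrnas)
    stop("unknown lncRNA id: ", lncrna_id)
  lncrna_id
}

# normalized descending-signal rank: fraction of the pool with signal <= s,
# i.e. (M - r + 1)/M for rank r (ties share the better rank); in (0, 1]
norm_rank <- function(s, pool) {
  if (length(pool) == 0) return(rep(0, length(s)))
  vapply(s, function(x) mean(pool <= x), numeric(1))
}

kind_pool <- function(network, kind) {
  p <- network$pools[[kind]]
  if (is.null(p)) p <- edges_of(network, kind)$signal
  p
}

#' Count distinct TFs regulating a lncRNA promoter
#'
#' Multiple peaks or biosamples of one TF count once (the TF indicator is
#' 0/1 per TF identity).
#'
#' @param network a `funlnc_network`.
#' @param lncrna_id lncRNA id.
#' @param source `"chip_all"` (all ChIP-seq TFs), `"chip_core"` (ChIP-seq
#'   TFs restricted to `core_tfs`), or `"motif"` (motif-hit TFs).
#' @param core_tfs core TF name set used by `"chip_core"`.
#' @return non-negative integer.
#' @export
tf_count <- function(network, lncrna_id, source = "chip_all",
                     core_tfs = CORE_TFS) {
  check_lnc(network, lncrna_id)
  kind <- switch(source, chip_all = , chip_core = "tf_chip",
                 motif = "tf_motif",
                 stop("unknown source: ", source))
  id_ <- lncrna_id
  tfs <- unique(edges_of(network, kind)[lncrna_id == id_]$partner_id)
  if (source == "chip_core") tfs <- intersect(tfs, core_tfs)
  length(tfs)
}

#' Count distinct activating histone-mark types at a promoter
#'
#' @param network a `funlnc_network`.
#' @param lncrna_id lncRNA id.
#' @param activating_marks mark names counted as transcription-activating.
#' @return non-negative integer.
#' @export
histone_type_count <- function(network, lncrna_id,
                               activating_marks = ACTIVATING_MARKS) {
  check_lnc(network, lncrna_id)
  id_ <- lncrna_id
  marks <- unique(edges_of(network, "histone")[lncrna_id == id_]$partner_id)
  length(intersect(marks, activating_marks))
}

#' Promoter site features: methylation and SNP counts
#'
#' For methylation, returns the site count and the cohort-normalized signal:
#' the per-lncRNA sum of site signals divided by the maximum such sum over
#' all lncRNAs in the network (0 when that maximum is 0). SNP kinds return
#' the count only.
#'
#' @param network a `funlnc_network`.
#' @param lncrna_id lncRNA id.
#' @param kind one of `"methylation"`, `"snp_risk"`, `"snp_common"`.
#' @return named numeric vector `count` (and `normalized_signal` for
#'   methylation).
#' @export
site_features <- function(network, lncrna_id, kind = "methylation") {
  check_lnc(network, lncrna_id)
  check_kind(kind, c("methylation", "snp_risk", "snp_common"))
  id_ <- lncrna_id
  e <- edges_of(network, kind)
  mine <- e[lncrna_id == id_]
  out <- c(count = uniqueN(mine$partner_id))
  if (kind == "methylation") {
    sums <- e[, .(s = sum(signal)), by = lncrna_id]
    gmax <- if (nrow(sums)) max(sums$s) else 0
    out <- c(out, normalized_signal =
               if (gmax > 0) sum(mine$signal) / gmax else 0)
  }
  out
}

# all statistics for one (kind, manner) slice of edges, per lncRNA
element_stats_dt <- function(network, kind, manner_, max_dist = 50000) {
  e <- edges_of(network, kind, manner_)
  pool <- kind_pool(network, kind)
  if (nrow(e) == 0) return(data.table(lncrna_id = character()))
  e[, .(
    count = uniqueN(partner_id),
    signal_sum = sum(signal),
    signal_max = max(signal),
    signal_mean = mean(signal),
    rank_mean = mean(norm_rank(signal, pool)),
    rank_best = max(norm_rank(signal, pool)),
    constituent_count = .N,
    prom_overlap_count = sum(prom_overlap, na.rm = TRUE),
    nearest_dist_norm = {
      d <- suppressWarnings(min(dist_tss, na.rm = TRUE))
      if (!is.finite(d)) 0 else max(0, min(1, 1 - d / max_dist))
    },
    freq_weighted_count = sum(frequency),
    sample_count = uniqueN(sample_id)
  ), by = lncrna_id]
}

#' Distal element statistics for one lncRNA
#'
#' @param network a `funlnc_network`.
#' @param lncrna_id lncRNA id.
#' @param kind one of `"enhancer_se"`, `"enhancer_te"`, `"atac"`.
#' @param manner `"distance_assigned"` or `"chromatin_interaction"`.
#' @param max_dist normalization constant for `nearest_dist_norm` (bp).
#' @return named numeric vector of the 11 element statistics (all 0 when
#'   the lncRNA has no linked element of this kind/manner).
#' @export
element_features <- function(network, lncrna_id, kind,
                             manner = "distance_assigned",
                             max_dist = 50000) {
  check_lnc(network, lncrna_id)
  check_kind(kind, UPSTREAM_DISTAL_KINDS)
  dt <- element_stats_dt(network, kind, manner, max_dist)
  stats <- c("count", "signal_sum", "signal_max", "signal_mean", "rank_mean",
             "rank_best", "constituent_count", "prom_overlap_count",
             "nearest_dist_norm", "freq_weighted_count", "sample_count")
  id_ <- lncrna_id
  row <- dt[lncrna_id == id_]
  if (nrow(row) == 0) return(setNames(numeric(length(stats)), stats))
  setNames(as.numeric(row[, stats, with = FALSE]), stats)
}

#' Total 3D chromatin interaction frequency at a promoter
#'
#' Sum of anchor-pair frequencies over pairs with at least one anchor
#' overlapping the lncRNA promoter.
#'
#' @param network a `funlnc_network` whose `interaction` edges were built
#'   with [interaction_edges()].
#' @param lncrna_id lncRNA id.
#' @return non-negative real.
#' @export
interaction_frequency <- function(network, lncrna_id) {
  check_lnc(network, lncrna_id)
  id_ <- lncrna_id
  sum(edges_of(network, "interaction")[lncrna_id == id_]$frequency)
}

#' Downstream partner counts for one lncRNA
#'
#' @param network a `funlnc_network`.
#' @param lncrna_id lncRNA id.
#' @return named integer vector `(n_mRNA, n_miRNA, n_protein)` of distinct
#'   partners per kind.
#' @export
downstream_counts <- function(network, lncrna_id) {
  check_lnc(network, lncrna_id)
  id_ <- lncrna_id
  e <- edges_of(network, DOWNSTREAM_KINDS)[lncrna_id == id_]
  c(n_mRNA = uniqueN(e[partner_kind == "mRNA"]$partner_id),
    n_miRNA = uniqueN(e[partner_kind == "miRNA"]$partner_id),
    n_protein = uniqueN(e[partner_kind == "protein"]$partner_id))
}

#' Build the 57-column feature matrix
#'
#' Deterministic given the network: every lncRNA gets one row; absence of
#' regulators yields zeros, never missing values.
#'
#' @param network a `funlnc_network`.
#' @param lncrna_ids rows to compute; defaults to `network$lncrnas`.
#' @param schema feature schema (validated before any computation).
#' @param core_tfs,activating_marks C1 configuration.
#' @param max_dist distance-normalization constant (bp), matching the
#'   assignment `max_dist`.
#' @return numeric matrix (lncRNAs x 57) with the schema attached as
#'   attribute `"schema"`.
#' @export
build_feature_matrix <- function(network, lncrna_ids = NULL,
                                 schema = feature_schema(),
                                 core_tfs = CORE_TFS,
                                 activating_marks = ACTIVATING_MARKS,
                                 max_dist = 50000) {
  schema <- validate_schema(schema)
  if (is.null(lncrna_ids)) lncrna_ids <- network$lncrnas
  n <- length(lncrna_ids)
  M <- matrix(0, nrow = n, ncol = nrow(schema),
              dimnames = list(lncrna_ids, schema$name))

  fill <- function(col, dt, value_col) {
    keep <- dt$lncrna_id %in% lncrna_ids
    M[dt$lncrna_id[keep], col] <<- dt[[value_col]][keep]
  }

  # C1: distinct-identity counts
  tf <- edges_of(network, "tf_chip")
  fill("tf_chip_count", tf[, .(v = uniqueN(partner_id)), by = lncrna_id], "v")
  fill("tf_chip_core_count",
       tf[partner_id %in% core_tfs, .(v = uniqueN(partner_id)),
          by = lncrna_id], "v")
  fill("tf_motif_count",
       edges_of(network, "tf_motif")[, .(v = uniqueN(partner_id)),
                                     by = lncrna_id], "v")
  fill("histone_act_type_count",
       edges_of(network, "histone")[partner_id %in% activating_marks,
                                    .(v = uniqueN(partner_id)),
                                    by = lncrna_id], "v")
  me <- edges_of(network, "methylation")
  fill("meth_count", me[, .(v = uniqueN(partner_id)), by = lncrna_id], "v")
  msum <- me[, .(v = sum(signal)), by = lncrna_id]
  gmax <- if (nrow(msum)) max(msum$v) else 0
  if (gmax > 0) {
    msum[, v := v / gmax]
    fill("meth_signal_norm", msum, "v")
  }
  for (k in c("snp_risk", "snp_common"))
    fill(paste0(k, "_count"),
         edges_of(network, k)[, .(v = uniqueN(partner_id)),
                              by = lncrna_id], "v")

  # C2: per (kind, manner) element statistics
  el_rows <- schema[category == "C2" & kind %in% UPSTREAM_DISTAL_KINDS &
                      manner != "any"]
  for (grp in split(el_rows, by = c("kind", "manner"))) {
    if (nrow(grp) == 0) next
    dt <- element_stats_dt(network, grp$kind[1], grp$manner[1], max_dist)
    if (nrow(dt) == 0) next
    for (j in seq_len(nrow(grp))) fill(grp$name[j], dt, grp$statistic[j])
  }
  comb <- edges_of(network, c("enhancer_te", "enhancer_se"))[
    , .(v = uniqueN(partner_id)), by = lncrna_id]
  fill("te_se_combined_count", comb, "v")
  fill("interaction_frequency",
       edges_of(network, "interaction")[, .(v = sum(frequency)),
                                        by = lncrna_id], "v")

  # C3
  ds <- edges_of(network, DOWNSTREAM_KINDS)
  for (p in list(c("mRNA", "mrna_count"), c("miRNA", "mirna_count"),
                 c("protein", "protein_count")))
    fill(p[2], ds[partner_kind == p[1], .(v = uniqueN(partner_id)),
                  by = lncrna_id], "v")

  attr(M, "schema") <- schema
  M
}

#' Write a feature matrix as TSV (plus optional schema JSON)
#'
#' @param M feature matrix from [build_feature_matrix()].
#' @param path output TSV path (first column `lncrna_id`).
#' @param schema_path optional path for the schema JSON.
#' @export
write_features <- function(M, path, schema_path = NULL) {
  dt <- data.table(lncrna_id = rownames(M))
  # %.17g keeps values exactly reproducible through a TSV round trip
  vals <- as.data.table(lapply(as.data.frame(M), function(x)
    sprintf("%.17g", x)))
  dt <- cbind(dt, vals)
  fwrite(dt, path, sep = "\t", quote = FALSE)
  sch <- attr(M, "schema")
  if (!is.null(schema_path) && !is.null(sch))
    jsonlite::write_json(sch, schema_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix TSV written by [write_features()]
#'
#' @param path TSV path.
#' @param schema schema to attach (and validate column order against).
#' @return numeric matrix with lncRNA rownames.
#' @export
read_features <- function(path, schema = feature_schema()) {
  dt <- fread(path, sep = "\t")
  M <- as.matrix(dt[, -1])
  rownames(M) <- dt[[1]]
  if (!identical(colnames(M), schema$name))
    stop("feature columns do not match schema")
  attr(M, "schema") <- schema
  M
}
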