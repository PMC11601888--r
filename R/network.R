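#' Multi-omic regulatory network assembly
#'
#' Edges connect lncRNAs to upstream regulators (TF ChIP peaks, TF motif
#' hits, histone-mark peaks, methylation sites, SNPs, typical enhancers,
#' super-enhancers, chromatin-accessibility regions, 3D interaction anchors)
#' and downstream partners (target mRNAs, miRNAs, bound proteins). Every
#' edge carries its assignment manner and the biosample it came from, so
#' features can distinguish distinct regulators from distinct peaks.
#'
#' @name network
NULL

UPSTREAM_PROXIMAL_KINDS <- c("tf_chip", "tf_motif", "histone", "methylation",
                             "snp_risk", "snp_common")
UPSTREAM_DISTAL_KINDS <- c("enhancer_te", "enhancer_se", "atac")
DOWNSTREAM_KINDS <- c("mRNA", "miRNA", "protein")
ALL_KINDS <- c(UPSTREAM_PROXIMAL_KINDS, UPSTREAM_DISTAL_KINDS,
               "interaction", DOWNSTREAM_KINDS)

# findOverlaps without the noisy disjoint-seqlevels warning
overlaps <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(a, b))
}

empty_edges <- function() {
  data.table(lncrna_id = character(), partner_id = character(),
             partner_kind = character(), manner = character(),
             sample_id = character(), signal = numeric(),
             frequency = numeric(), prom_overlap = logical(),
             dist_tss = numeric())
}

check_kind <- function(kind, allowed = ALL_KINDS) {
  if (length(kind) != 1 || !kind %in% allowed)
    stop("unknown element kind: ", kind,
         " (expected one of: ", paste(allowed, collapse = ", "), ")")
  kind
}

# midpoint of an element in BED coordinates
element_midpoint <- function(elements) {
  floor((start(elements) - 1 + end(elements)) / 2)
}

# distance from element midpoints to each promoter's TSS (Inf across chroms)
tss_distance <- function(promoters, pidx, elements, eidx) {
  d <- abs(element_midpoint(elements)[eidx] - mcols(promoters)$tss[pidx])
  same <- as.character(seqnames(promoters))[pidx] ==
    as.character(seqnames(elements))[eidx]
  d[!same] <- Inf
  d
}

edge_rows <- function(promoters, pidx, elements, eidx, kind, manner,
                      sample_id, frequency = 1) {
  if (length(pidx) == 0) return(empty_edges())
  ov <- overlaps(promoters, elements)
  direct <- paste(queryHits(ov), subjectHits(ov))
  data.table(
    lncrna_id = mcols(promoters)$id[pidx],
    partner_id = mcols(elements)$name[eidx],
    partner_kind = kind,
    manner = manner,
    sample_id = sample_id,
    signal = mcols(elements)$signal[eidx],
    frequency = as.numeric(frequency),
    prom_overlap = paste(pidx, eidx) %in% direct,
    dist_tss = tss_distance(promoters, pidx, elements, eidx)
  )
}

#' Assign elements to promoters by direct overlap
#'
#' One edge per (lncRNA, element) pair whose promoter and element intervals
#' intersect under half-open semantics; edge signal is the element signal.
#'
#' @param promoters `GRanges` from [derive_promoters()].
#' @param elements `GRanges` from [read_bed()].
#' @param kind element kind (one of the upstream kinds).
#' @param sample_id biosample identifier recorded on every edge.
#' @return edge `data.table` with `manner = "proximal"`.
#' @export
assign_proximal <- function(promoters, elements, kind, sample_id = "s1") {
  check_kind(kind, c(UPSTREAM_PROXIMAL_KINDS, UPSTREAM_DISTAL_KINDS))
  ov <- overlaps(promoters, elements)
  edge_rows(promoters, queryHits(ov), elements, subjectHits(ov),
            kind, "proximal", sample_id)
}

#' Assign distal elements to promoters via 3D chromatin interactions
#'
#' An edge (lncRNA, element) is emitted iff some anchor pair has the element
#' overlapping one anchor and the promoter overlapping the other (either
#' orientation). A link supported by several distinct pairs collapses to one
#' edge whose `frequency` is the sum of the pair frequencies (a single pair
#' never contributes more than once, even if both orientations match).
#'
#' @param promoters `GRanges` from [derive_promoters()].
#' @param elements `GRanges` of distal elements.
#' @param pairs `anchor_pairs` from [read_bedpe()].
#' @param kind element kind.
#' @param sample_id biosample identifier.
#' @return edge `data.table` with `manner = "chromatin_interaction"`.
#' @export
assign_by_interaction <- function(promoters, elements, pairs, kind,
                                  sample_id = "s1") {
  check_kind(kind, c(UPSTREAM_PROXIMAL_KINDS, UPSTREAM_DISTAL_KINDS))
  ea <- overlaps(elements, pairs$anchor_a)
  eb <- overlaps(elements, pairs$anchor_b)
  pa <- overlaps(promoters, pairs$anchor_a)
  pb <- overlaps(promoters, pairs$anchor_b)
  link <- function(ehits, phits) {
    e <- data.table(eidx = queryHits(ehits), pair = subjectHits(ehits))
    p <- data.table(pidx = queryHits(phits), pair = subjectHits(phits))
    merge(e, p, by = "pair", allow.cartesian = TRUE)
  }
  li <- rbind(link(ea, pb), link(eb, pa))
  if (nrow(li) == 0) return(empty_edges())
  li <- unique(li, by = c("pair", "eidx", "pidx"))
  li[, frequency := pairs$frequency[pair]]
  agg <- li[, .(frequency = sum(frequency)), by = .(pidx, eidx)]
  out <- edge_rows(promoters, agg$pidx, elements, agg$eidx, kind,
                   "chromatin_interaction", sample_id, agg$frequency)
  setorder(out, lncrna_id, partner_id)
  out
}

#' Assign enhancer calls to promoters by genomic distance
#'
#' An edge is emitted iff the enhancer midpoint lies within `max_dist` of the
#' TSS, or the enhancer overlaps the promoter window directly (the overlap
#' short-circuits the distance test).
#'
#' @param promoters `GRanges` from [derive_promoters()].
#' @param enhancer_calls `GRanges` of TE/SE interval calls (ROSE-style
#'   output or [stitch_enhancers()]).
#' @param kind element kind.
#' @param sample_id biosample identifier.
#' @param max_dist maximum TSS-to-midpoint distance in bp (> 0); default
#'   50 kb.
#' @return edge `data.table` with `manner = "distance_assigned"`.
#' @export
assign_distance <- function(promoters, enhancer_calls, kind,
                            sample_id = "s1", max_dist = 50000) {
  check_kind(kind, c(UPSTREAM_PROXIMAL_KINDS, UPSTREAM_DISTAL_KINDS))
  if (!is.numeric(max_dist) || max_dist <= 0)
    stop("max_dist must be > 0")
  np <- length(promoters); ne <- length(enhancer_calls)
  if (np == 0 || ne == 0) return(empty_edges())
  # candidates: same chromosome only
  cand <- data.table(
    pidx = rep(seq_len(np), each = ne),
    eidx = rep(seq_len(ne), times = np)
  )
  d <- tss_distance(promoters, cand$pidx, enhancer_calls, cand$eidx)
  ov <- overlaps(promoters, enhancer_calls)
  direct <- paste(queryHits(ov), subjectHits(ov))
  keep <- d <= max_dist | paste(cand$pidx, cand$eidx) %in% direct
  cand <- cand[keep]
  edge_rows(promoters, cand$pidx, enhancer_calls, cand$eidx, kind,
            "distance_assigned", sample_id)
}

#' Record 3D interaction pairs touching each promoter
#'
#' One edge of kind `interaction` per anchor pair with at least one anchor
#' overlapping the promoter; a pair with both anchors on the same promoter is
#' counted once. The per-lncRNA sum of `frequency` over these edges is the 3D
#' chromatin interaction frequency feature.
#'
#' @param promoters `GRanges` from [derive_promoters()].
#' @param pairs `anchor_pairs`.
#' @param sample_id biosample identifier.
#' @return edge `data.table` with `manner = "chromatin_interaction"`.
#' @export
interaction_edges <- function(promoters, pairs, sample_id = "s1") {
  oa <- overlaps(promoters, pairs$anchor_a)
  ob <- overlaps(promoters, pairs$anchor_b)
  hit <- unique(rbind(
    data.table(pidx = queryHits(oa), pair = subjectHits(oa)),
    data.table(pidx = queryHits(ob), pair = subjectHits(ob))
  ))
  if (nrow(hit) == 0) return(empty_edges())
  data.table(
    lncrna_id = mcols(promoters)$id[hit$pidx],
    partner_id = pairs$name[hit$pair],
    partner_kind = "interaction",
    manner = "chromatin_interaction",
    sample_id = sample_id,
    signal = pairs$frequency[hit$pair],
    frequency = pairs$frequency[hit$pair],
    prom_overlap = TRUE,
    dist_tss = NA_real_
  )
}

#' Build downstream post-transcriptional edges from curated pair tables
#'
#' mRNA and miRNA partners (knockdown/overexpression targets and
#' miRNA interactions) get manner `targeted`; protein partners
#' (binding annotations) get `annotated`. Duplicate rows collapse.
#'
#' @param pair_tables a pair `data.table` ([read_pair_table()]) or a list of
#'   them.
#' @return edge `data.table`.
#' @export
build_downstream <- function(pair_tables) {
  if (is.data.frame(pair_tables)) pair_tables <- list(pair_tables)
  dt <- unique(rbindlist(lapply(pair_tables, as.data.table)))
  if (nrow(dt) == 0) return(empty_edges())
  bad <- !dt$partner_kind %in% DOWNSTREAM_KINDS
  if (any(bad)) stop("unknown downstream kind: ", dt$partner_kind[which(bad)[1]])
  data.table(
    lncrna_id = dt$lncrna_id,
    partner_id = dt$partner_id,
    partner_kind = dt$partner_kind,
    manner = ifelse(dt$partner_kind == "protein", "annotated", "targeted"),
    sample_id = "curated",
    signal = 1.0,
    frequency = 1.0,
    prom_overlap = NA,
    dist_tss = NA_real_
  )
}

#' Integrate edge lists into a multi-omic network
#'
#' Takes the union of edge lists with global deduplication of exact
#' duplicates, and records per-kind signal pools used later for
#' cohort-relative rank features. Integration is idempotent and
#' order-independent.
#'
#' @param edge_lists a single edge `data.table` or a list of them.
#' @param lncrna_ids optional character vector fixing the lncRNA node set
#'   (ids without edges are kept as isolated nodes).
#' @param pools named list `kind -> numeric vector` of all element signals of
#'   that kind (the global pool a linked element is ranked against). Kinds
#'   absent from `pools` fall back to the signals observed on edges.
#' @return object of class `funlnc_network`.
#' @export
integrate_network <- function(edge_lists, lncrna_ids = NULL, pools = list()) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  edges <- unique(rbindlist(c(list(empty_edges()), edge_lists),
                            use.names = TRUE))
  setorder(edges, partner_kind, manner, lncrna_id, partner_id, sample_id)
  if (is.null(lncrna_ids)) lncrna_ids <- sort(unique(edges$lncrna_id))
  counts <- edges[, .N, by = .(partner_kind, manner)]
  setorder(counts, partner_kind, manner)
  structure(list(
    edges = edges,
    lncrnas = lncrna_ids,
    partners = sort(unique(edges$partner_id)),
    counts = counts,
    pools = pools
  ), class = "funlnc_network")
}

#' @export
print.funlnc_network <- function(x, ...) {
  cat(sprintf("funlnc_network: %d lncRNAs, %d partners, %d edges\n",
              length(x$lncrnas), length(x$partners), nrow(x$edges)))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Network summary as a plain list
#'
#' @param object a `funlnc_network`.
#' @param ... unused.
#' @return list with node/edge counts per kind and manner.
#' @export
summary.funlnc_network <- function(object, ...) {
  list(
    n_lncrnas = length(object$lncrnas),
    n_partners = length(object$partners),
    n_edges = nrow(object$edges),
    per_kind = as.list(setNames(
      object$edges[, .N, by = partner_kind]$N,
      object$edges[, .N, by = partner_kind]$partner_kind)),
    per_manner = as.list(setNames(
      object$edges[, .N, by = manner]$N,
      object$edges[, .N, by = manner]$manner))
  )
}

#' Export a network as a TSV edge list plus JSON summary
#'
#' @param network a `funlnc_network`.
#' @param edges_path path for the edge TSV.
#' @param summary_path optional path for the JSON summary.
#' @export
write_network <- function(network, edges_path, summary_path = NULL) {
  fwrite(network$edges, edges_path, sep = "\t")
  if (!is.null(summary_path))
    jsonlite::write_json(summary.funlnc_network(network), summary_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(edges_path)
}

#' Re-import a network edge TSV written by [write_network()]
#'
#' @param edges_path path to the edge TSV.
#' @param lncrna_ids,pools passed to [integrate_network()].
#' @return a `funlnc_network`.
#' @export
read_network <- function(edges_path, lncrna_ids = NULL, pools = list()) {
  edges <- fread(edges_path, sep = "\t",
                 colClasses = list(character = c(
                   "lncrna_id", "partner_id", "partner_kind", "manner",
                   "sample_id")))
  edges[, prom_overlap := as.logical(prom_overlap)]
  edges[, dist_tss := as.numeric(dist_tss)]
  edges[, signal := as.numeric(signal)]
  edges[, frequency := as.numeric(frequency)]
  integrate_network(edges, lncrna_ids = lncrna_ids, pools = pools)
}

#' Naive ROSE-style enhancer stitcher (optional helper)
#'
#' Merges enhancer peaks within `stitch_dist` of each other into stitched
#' regions whose signal is the sum of constituent signals, and splits them
#' into super-enhancers (top fraction by signal) and typical enhancers. This
#' is a convenience stand-in: real TE/SE calls are normally consumed as
#' inputs.
#'
#' @param peaks `GRanges` of enhancer-mark peaks.
#' @param stitch_dist gap tolerance in bp (default 12500, the ROSE
#'   convention).
#' @param se_fraction fraction of stitched regions, ranked by signal, called
#'   super-enhancers (default 0.1).
#' @return list with `GRanges` elements `te` and `se`.
#' @export
stitch_enhancers <- function(peaks, stitch_dist = 12500, se_fraction = 0.1) {
  if (length(peaks) == 0) return(list(te = peaks, se = peaks))
  merged <- GenomicRanges::reduce(peaks, min.gapwidth = stitch_dist + 1)
  ov <- overlaps(merged, peaks)
  sig <- tapply(mcols(peaks)$signal[subjectHits(ov)], queryHits(ov), sum)
  mcols(merged)$signal <- as.numeric(sig[as.character(seq_along(merged))])
  mcols(merged)$name <- sprintf("stitched_%d", seq_along(merged))
  n_se <- max(1, floor(length(merged) * se_fraction))
  o <- order(-mcols(merged)$signal)
  list(se = merged[o[seq_len(n_se)]],
       te = merged[o[-seq_len(n_se)]])
}
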