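# Brute-force reference implementations, kept deliberately independent of
# the package internals: plain loops over BED-coordinate data frames.

# half-open overlap of two BED intervals
bf_overlaps <- function(s1, e1, s2, e2, chr1, chr2) {
  chr1 == chr2 & s1 < e2 & s2 < e1
}

# all (promoter, element) index pairs that overlap, O(n^2)
bf_proximal_pairs <- function(prom_df, el_df) {
  out <- list()
  for (i in seq_len(nrow(prom_df))) {
    for (j in seq_len(nrow(el_df))) {
      if (bf_overlaps(prom_df$start[i], prom_df$end[i],
                      el_df$start[j], el_df$end[j],
                      prom_df$chrom[i], el_df$chrom[j]))
        out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(pidx = integer(), eidx = integer()))
  m <- do.call(rbind, out)
  data.frame(pidx = m[, 1], eidx = m[, 2])
}

# element-promoter links through anchor pairs, with per-link summed
# frequency (each pair counted once per link whatever the orientation)
bf_interaction_links <- function(prom_df, el_df, a_df, b_df, freq) {
  links <- list()
  for (k in seq_along(freq)) {
    for (i in seq_len(nrow(prom_df))) {
      for (j in seq_len(nrow(el_df))) {
        o1 <- bf_overlaps(el_df$start[j], el_df$end[j], a_df$start[k],
                          a_df$end[k], el_df$chrom[j], a_df$chrom[k]) &&
          bf_overlaps(prom_df$start[i], prom_df$end[i], b_df$start[k],
                      b_df$end[k], prom_df$chrom[i], b_df$chrom[k])
        o2 <- bf_overlaps(el_df$start[j], el_df$end[j], b_df$start[k],
                          b_df$end[k], el_df$chrom[j], b_df$chrom[k]) &&
          bf_overlaps(prom_df$start[i], prom_df$end[i], a_df$start[k],
                      a_df$end[k], prom_df$chrom[i], a_df$chrom[k])
        if (o1 || o2) {
          key <- paste(i, j)
          links[[key]] <- c(links[[key]], freq[k])
        }
      }
    }
  }
  if (!length(links))
    return(data.frame(pidx = integer(), eidx = integer(), freq = numeric()))
  keys <- do.call(rbind, strsplit(names(links), " "))
  data.frame(pidx = as.integer(keys[, 1]), eidx = as.integer(keys[, 2]),
             freq = vapply(links, sum, numeric(1)), row.names = NULL)
}

# AUROC by explicit positive-negative pair counting
bf_auroc <- function(probs, y) {
  pos <- probs[y == 1]; neg <- probs[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# single-linkage components over a similarity matrix via label propagation
bf_components <- function(sim, threshold) {
  n <- nrow(sim)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sim[i, j] >= threshold && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# plain k-mer Jaccard similarity matrix
bf_kmer_jaccard <- function(seqs, k) {
  sets <- lapply(seqs, function(s) {
    s <- toupper(s)
    if (nchar(s) < k) return(character())
    unique(vapply(seq_len(nchar(s) - k + 1),
                  function(i) substr(s, i, i + k - 1), character(1)))
  })
  n <- length(sets)
  sim <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    sim[i, j] <- sim[j, i] <- if (uni == 0) 0 else inter / uni
  }
  sim
}

# rebuild every permuted matrix and re-predict, counting exceedances by hand
bf_perm_scores <- function(model, F, B, seed, mode = "safe") {
  seeds <- funlnc:::sub_seeds(seed, B)
  p <- predict_and_label(model, F)$probability
  cnt <- rep(0, nrow(F))
  for (k in seq_len(B)) {
    Fk <- permute_matrix(F, seeds[k])
    rownames(Fk) <- rownames(F)
    rk <- predict_and_label(model, Fk)$probability
    cnt <- cnt + (p < rk)
  }
  if (mode == "raw") -log10(cnt / B) else -log10((cnt + 1) / (B + 1))
}

# brute-force recount of a count-type feature from the raw edge list
bf_distinct_count <- function(edges, id, kinds, manners = NULL,
                              names_in = NULL) {
  sel <- edges$lncrna_id == id & edges$partner_kind %in% kinds
  if (!is.null(manners)) sel <- sel & edges$manner %in% manners
  ids <- unique(edges$partner_id[sel])
  if (!is.null(names_in)) ids <- intersect(ids, names_in)
  length(ids)
}
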