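#' Genomic interval input/output
#'
#' All files are interpreted with BED semantics: coordinates are 0-based,
#' half-open `[start, end)`. Internally intervals are carried as
#' [GenomicRanges::GRanges] (1-based, closed); the loaders perform the
#' conversion, and [write_bed()] converts back, so a write/read round trip is
#' the identity on `(chrom, start, end, strand, name, signal)`.
#'
#' @name genomic_io
NULL

# convert validated BED-coordinate columns to GRanges with name/signal mcols
bed_to_granges <- function(chrom, start, end, strand, name, signal) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  mcols(gr)$name <- name
  mcols(gr)$signal <- signal
  gr
}

#' Turn a GRanges back into a BED-coordinate data.table
#'
#' @param gr a `GRanges` with `name` and `signal` metadata columns.
#' @return `data.table` with columns chrom, start (0-based), end (exclusive),
#'   name, signal, strand.
#' @export
intervals_df <- function(gr) {
  data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = mcols(gr)$name,
    signal = mcols(gr)$signal,
    strand = as.character(strand(gr))
  )
}

#' Construct intervals from BED-style vectors
#'
#' Convenience constructor used throughout the package and its tests; applies
#' the same invariants as [read_bed()].
#'
#' @param chrom chromosome names (non-empty strings).
#' @param start 0-based inclusive starts.
#' @param end exclusive ends; must satisfy `start < end`.
#' @param strand one of `+`, `-`, `.` (default `.`, mapped to `*` internally).
#' @param name interval names; auto-generated when `NULL`.
#' @param signal non-negative signal values; defaults to 1.
#' @return a `GRanges` with `name` and `signal` metadata columns.
#' @export
intervals <- function(chrom, start, end, strand = ".", name = NULL,
                      signal = 1) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n); end <- rep_len(end, n)
  strand <- rep_len(ifelse(strand == ".", "*", strand), n)
  if (is.null(name)) name <- sprintf("iv_%d", seq_len(n))
  signal <- rep_len(as.numeric(signal), n)
  bad <- which(!nzchar(chrom) | start < 0 | start >= end | signal < 0)
  if (length(bad))
    stop("invalid interval(s) at position(s): ", paste(bad, collapse = ", "))
  bed_to_granges(chrom, start, end, strand, rep_len(name, n), signal)
}

bed_stop <- function(path, i, msg) {
  stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
}

#' Read a BED3/5/6 file of genomic elements
#'
#' Columns: chrom, start, end, then optionally name (4), signal (5) and
#' strand (6). A missing signal column defaults to 1.0 for every record;
#' missing names are auto-generated from the file name and line number.
#' Records are returned sorted by (chrom, start).
#'
#' @param path path to a tab-separated BED file.
#' @param kind optional element kind tag stored as the `kind` metadata column
#'   (e.g. `"tf_chip"`, `"histone"`).
#' @return `GRanges` with metadata columns `name`, `signal` (and `kind` if
#'   given).
#' @export
read_bed <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(intervals(character(), integer(), integer())[0])
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = "character", blank.lines.skip = FALSE)
  if (nrow(dt) == 0)
    return(intervals(character(), integer(), integer())[0])
  if (ncol(dt) < 3) stop(path, ": BED needs >= 3 tab-separated columns")
  for (i in seq_len(nrow(dt))) {
    if (!nzchar(dt[[1]][i])) bed_stop(path, i, "empty chrom")
    if (is.na(suppressWarnings(as.numeric(dt[[2]][i]))) ||
        is.na(suppressWarnings(as.numeric(dt[[3]][i]))))
      bed_stop(path, i, "non-numeric coordinates")
  }
  start <- as.numeric(dt[[2]]); end <- as.numeric(dt[[3]])
  bad <- which(start >= end)
  if (length(bad)) bed_stop(path, bad[1], sprintf(
    "start >= end (%s >= %s)", start[bad[1]], end[bad[1]]))
  if (any(start < 0)) bed_stop(path, which(start < 0)[1], "negative start")
  nm <- if (ncol(dt) >= 4) dt[[4]] else
    sprintf("%s_%d", tools::file_path_sans_ext(basename(path)), seq_len(nrow(dt)))
  sig <- if (ncol(dt) >= 5) suppressWarnings(as.numeric(dt[[5]])) else
    rep(1.0, nrow(dt))
  if (anyNA(sig)) bed_stop(path, which(is.na(sig))[1], "non-numeric signal")
  if (any(sig < 0)) bed_stop(path, which(sig < 0)[1], "negative signal")
  str <- if (ncol(dt) >= 6) dt[[6]] else rep(".", nrow(dt))
  if (!all(str %in% c("+", "-", ".", "*")))
    bed_stop(path, which(!str %in% c("+", "-", ".", "*"))[1], "bad strand")
  gr <- bed_to_granges(dt[[1]], start, end, ifelse(str == ".", "*", str),
                       nm, sig)
  if (!is.null(kind)) mcols(gr)$kind <- kind
  sort_intervals(gr)
}

# sort by (chrom, start) with stable chromosome order by first appearance
sort_intervals <- function(gr) {
  o <- order(as.character(seqnames(gr)), start(gr), end(gr), method = "radix")
  gr[o]
}

#' Write intervals to a BED6 file
#'
#' @param gr `GRanges` with `name` and `signal` metadata columns.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- intervals_df(gr)
  df[, strand := ifelse(strand == "*", ".", strand)]
  fwrite(df[, .(chrom, start, end, name, signal, strand)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of 3D chromatin interaction anchor pairs
#'
#' Columns 1-6 are the two anchors (chromA, startA, endA, chromB, startB,
#' endB); optional column 7 is a pair name and column 8 the contact
#' frequency (contact count or normalized frequency, strictly positive;
#' defaults to 1.0).
#'
#' @param path path to a tab-separated BEDPE file.
#' @return an object of class `anchor_pairs`: list with `GRanges` slots
#'   `anchor_a`, `anchor_b` and parallel vectors `name`, `frequency`.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- file.size(path) == 0
  dt <- if (empty) data.table() else
    fread(path, header = FALSE, sep = "\t", fill = TRUE,
          colClasses = "character")
  if (nrow(dt) == 0) return(anchor_pairs_new(
    intervals(character(), integer(), integer()),
    intervals(character(), integer(), integer()),
    character(), numeric()))
  if (ncol(dt) < 6) stop(path, ": BEDPE needs >= 6 columns")
  num <- function(col) suppressWarnings(as.numeric(dt[[col]]))
  sa <- num(2); ea <- num(3); sb <- num(5); eb <- num(6)
  for (i in seq_len(nrow(dt))) {
    if (anyNA(c(sa[i], ea[i], sb[i], eb[i])))
      bed_stop(path, i, "non-numeric coordinates")
    if (sa[i] >= ea[i] || sb[i] >= eb[i]) bed_stop(path, i, "start >= end")
    if (sa[i] < 0 || sb[i] < 0) bed_stop(path, i, "negative start")
  }
  nm <- if (ncol(dt) >= 7) dt[[7]] else sprintf("pair_%d", seq_len(nrow(dt)))
  freq <- if (ncol(dt) >= 8) suppressWarnings(as.numeric(dt[[8]])) else
    rep(1.0, nrow(dt))
  if (anyNA(freq)) bed_stop(path, which(is.na(freq))[1], "non-numeric frequency")
  if (any(freq <= 0)) bed_stop(path, which(freq <= 0)[1],
                               "frequency must be > 0")
  anchor_pairs_new(
    bed_to_granges(dt[[1]], sa, ea, "*", paste0(nm, "_a"), 1),
    bed_to_granges(dt[[4]], sb, eb, "*", paste0(nm, "_b"), 1),
    nm, freq)
}

anchor_pairs_new <- function(anchor_a, anchor_b, name, frequency) {
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 name = name, frequency = frequency),
            class = "anchor_pairs")
}

#' @export
length.anchor_pairs <- function(x) length(x$frequency)

#' @export
print.anchor_pairs <- function(x, ...) {
  cat(sprintf("anchor_pairs with %d interaction(s), total frequency %.3g\n",
              length(x), sum(x$frequency)))
  invisible(x)
}

#' Write anchor pairs to BEDPE
#'
#' @param pairs an `anchor_pairs` object.
#' @param path output path.
#' @export
write_bedpe <- function(pairs, path) {
  a <- intervals_df(pairs$anchor_a); b <- intervals_df(pairs$anchor_b)
  fwrite(data.table(a$chrom, a$start, a$end, b$chrom, b$start, b$end,
                    pairs$name, pairs$frequency),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a downstream pair table
#'
#' Tab-separated with header `lncrna_id  partner_id  partner_kind`; kinds are
#' restricted to mRNA / miRNA / protein. Duplicate triples are dropped.
#'
#' @param path path to the TSV file.
#' @return `data.table` with the three columns, deduplicated.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("lncrna_id", "partner_id", "partner_kind")
  if (!all(need %in% names(dt)))
    stop(path, ": pair table needs header columns ",
         paste(need, collapse = ", "))
  bad <- !dt$partner_kind %in% c("mRNA", "miRNA", "protein")
  if (any(bad))
    stop(path, ": unknown partner_kind '", dt$partner_kind[which(bad)[1]], "'")
  unique(dt[, need, with = FALSE])
}

#' Read lncRNA gene models from a BED12 (or BED6) annotation
#'
#' Only chrom, strand, name and the transcription start site are consumed:
#' the TSS is `start` on the + strand and `end - 1` on the - strand.
#'
#' @param path path to the annotation BED.
#' @return `data.table` with columns `id`, `chrom`, `strand`, `tss`
#'   (0-based position of the TSS base).
#' @export
read_lncrna_bed <- function(path) {
  gr <- read_bed(path)
  df <- intervals_df(gr)
  if (any(!df$strand %in% c("+", "-")))
    stop(path, ": lncRNA annotation requires explicit +/- strand")
  if (anyDuplicated(df$name))
    stop(path, ": duplicate lncRNA ids: ",
         paste(head(unique(df$name[duplicated(df$name)]), 3), collapse = ", "))
  data.table(id = df$name, chrom = df$chrom, strand = df$strand,
             tss = ifelse(df$strand == "+", df$start, df$end - 1L))
}

#' Read a GTF-lite lncRNA annotation
#'
#' Consumes `gene` feature rows of a 9-column GTF; 1-based closed
#' coordinates are converted to the package's 0-based convention on load.
#' The gene id is taken from the `gene_id "..."` attribute.
#'
#' @param path path to the GTF file.
#' @return same layout as [read_lncrna_bed()].
#' @export
read_lncrna_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(dt) < 9) stop(path, ": GTF needs 9 columns")
  dt <- dt[dt[[3]] == "gene"]
  if (nrow(dt) == 0) stop(path, ": no gene rows")
  ids <- sub('.*gene_id "([^"]+)".*', "\\1", dt[[9]])
  s1 <- as.numeric(dt[[4]]); e1 <- as.numeric(dt[[5]])
  if (any(is.na(s1) | is.na(e1) | s1 > e1)) stop(path, ": bad coordinates")
  strand <- dt[[7]]
  if (any(!strand %in% c("+", "-"))) stop(path, ": gene rows need +/- strand")
  # GTF 1-based closed -> BED 0-based: start-1, end stays
  data.table(id = ids, chrom = dt[[1]], strand = strand,
             tss = ifelse(strand == "+", s1 - 1, e1 - 1))
}

#' Derive promoter windows around lncRNA transcription start sites
#'
#' The promoter is the symmetric window `[tss - window, tss + window)` in BED
#' coordinates, clipped at zero; the width is strand-independent (the window
#' is centered on the TSS whichever strand the gene is on).
#'
#' @param genes `data.table` as returned by [read_lncrna_bed()].
#' @param window half-width in bp (> 0); default 2000 (TSS +/- 2 kb).
#' @return `GRanges` of promoters with metadata columns `id`, `tss`,
#'   `strand_gene`; names are the lncRNA ids.
#' @export
derive_promoters <- function(genes, window = 2000) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0)
    stop("window must be a single positive number")
  genes <- as.data.table(genes)
  if (!all(c("id", "chrom", "strand", "tss") %in% names(genes)))
    stop("genes needs columns id, chrom, strand, tss")
  if (anyNA(genes$tss)) stop("missing TSS for: ",
                             paste(genes$id[is.na(genes$tss)], collapse = ", "))
  st <- pmax(0, genes$tss - window)
  en <- genes$tss + window
  gr <- bed_to_granges(genes$chrom, st, en, "*", genes$id, 1)
  mcols(gr)$id <- genes$id
  mcols(gr)$tss <- genes$tss
  mcols(gr)$strand_gene <- genes$strand
  names(gr) <- genes$id
  gr
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences (ids from the header up to the
#'   first whitespace).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
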