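#' Detect miRNA gene clusters from genomic coordinates
#'
#' Two or more miRNA genes on the same contig, transcribed in the same
#' direction and less than `max_gap` nucleotides apart form a gene cluster
#' (the 10 kb default is the miRBase convention). Chaining is transitive:
#' within a (contig, strand) group the genes are sorted by start and linked
#' whenever consecutive genes are close enough, so a cluster may span more
#' than `max_gap` end to end. Singletons are not clusters.
#'
#' The gap between consecutive genes is `max(0, next_start - prev_end - 1)`
#' (edge-to-edge, coordinates 1-based inclusive) by default;
#' `gap_mode = "start"` instead measures start-to-start distance, for the
#' alternative reading of the 10-kb rule.
#'
#' @param loci data.frame with `gene_id`, `contig`, `start`, `end`, `strand`;
#'   gene ids must be unique, `start <= end`.
#' @param max_gap integer; genes are chained when their gap is strictly less
#'   than this (default 10000).
#' @param gap_mode `"edge"` (default) or `"start"`.
#' @return data.frame with one row per clustered gene: `cluster_id`
#'   (`contig:strand:first-member-start`), `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `cluster_size`, `span_start`, `span_end`; members are
#'   ordered by cluster then start. Zero rows when no clusters exist.
#' @export
detect_clusters <- function(loci, max_gap = 10000L,
                            gap_mode = c("edge", "start")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(is.data.frame(loci), max_gap >= 1)
  empty <- data.frame(cluster_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      cluster_size = integer(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE)
  if (nrow(loci) == 0L) return(empty)
  if (anyDuplicated(loci$gene_id)) stop("duplicate gene_id in loci")
  if (any(loci$start > loci$end)) stop("locus with start > end")

  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(loci$start, loci$end),
    strand = loci$strand, gene_id = loci$gene_id)
  if (gap_mode == "start") {
    # start-to-start distance: chain on point ranges at each start; two
    # width-1 ranges at s1 < s2 have inter-range gap s2 - s1 - 1, so the
    # strict rule s2 - s1 < max_gap needs min.gapwidth = max_gap - 1
    chain_gr <- GenomicRanges::GRanges(
      seqnames = loci$contig,
      ranges = IRanges::IRanges(loci$start, width = 1L),
      strand = loci$strand)
    min_gapwidth <- max_gap - 1L
  } else {
    # reduce() merges ranges whose gap is < min.gapwidth, i.e. <= max_gap - 1,
    # which is exactly the strict "less than max_gap" rule on edge gaps
    chain_gr <- gr
    min_gapwidth <- max_gap
  }
  merged <- GenomicRanges::reduce(chain_gr, min.gapwidth = min_gapwidth,
                                  ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(chain_gr, merged)
  comp <- integer(nrow(loci))
  comp[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)

  out <- loci
  out$.comp <- comp
  pieces <- lapply(split(seq_len(nrow(out)), out$.comp), function(idx) {
    m <- out[idx, , drop = FALSE]
    if (nrow(m) < 2L) return(NULL)
    m <- m[order(m$start, m$end, m$gene_id), , drop = FALSE]
    data.frame(
      cluster_id = paste(m$contig[1L], m$strand[1L], min(m$start), sep = ":"),
      gene_id = m$gene_id, contig = m$contig, strand = m$strand,
      start = m$start, end = m$end,
      cluster_size = nrow(m),
      span_start = min(m$start), span_end = max(m$end),
      stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(empty)
  res <- do.call(rbind, pieces)
  res <- res[order(res$contig, res$strand, res$span_start, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarise clusters from a member table
#'
#' @param members output of [detect_clusters()].
#' @return one row per cluster: `cluster_id`, `contig`, `strand`, `n_genes`,
#'   `span_start`, `span_end`, `members` (comma-joined gene ids in start
#'   order).
#' @export
summarise_clusters <- function(members) {
  if (nrow(members) == 0L)
    return(data.frame(cluster_id = character(), contig = character(),
                      strand = character(), n_genes = integer(),
                      span_start = integer(), span_end = integer(),
                      members = character(), stringsAsFactors = FALSE))
  pieces <- lapply(split(members, members$cluster_id), function(m) {
    m <- m[order(m$start), , drop = FALSE]
    data.frame(cluster_id = m$cluster_id[1L], contig = m$contig[1L],
               strand = m$strand[1L], n_genes = nrow(m),
               span_start = m$span_start[1L], span_end = m$span_end[1L],
               members = paste(m$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, pieces)
  res <- res[order(res$contig, res$strand, res$span_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
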