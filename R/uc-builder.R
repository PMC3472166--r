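# Unigene clusters (UCs): maximal groups of same-contig, same-strand
# transcript models, pooled across samples, connected (transitively) by
# >= 1 bp of exonic overlap. A UC is treated as one expressed locus.

#' Cluster transcript models from all samples into unigene clusters
#'
#' Clusters are the connected components of the graph whose edges join
#' same-contig, same-strand transcripts sharing at least one base of exonic
#' overlap. The overlap unit is exonic bases, not genomic span, so nested
#' but intron-contained genes are not fused; strands never merge. The result
#' is independent of input order: cluster ids are assigned canonically by
#' (contig, footprint start, strand).
#'
#' @param exons Exon tibble with columns `sample_id`, `gene_id`,
#'   `transcript_id`, `contig`, `strand`, `start`, `end` (1-based
#'   inclusive), one row per exon. Transcripts from different samples may
#'   reuse ids; a transcript is keyed by (`sample_id`, `transcript_id`).
#' @return An object of class `uc_set`: a list with
#'   * `clusters`: one row per UC (`uc_id`, `contig`, `strand`, `start`,
#'     `end`, `footprint_length`, `n_members`, `n_samples`, `gene_ids`),
#'   * `members`: transcript-to-UC assignment,
#'   * `footprint`: merged exonic intervals per UC,
#'   * `rejected`: malformed transcript records dropped with a warning.
#' @export
cluster_transcripts <- function(exons) {
  check_strand(exons$strand)
  exons <- as_tibble(exons) %>%
    mutate(.tx = paste(.data$sample_id, .data$transcript_id, sep = "\r"))

  # per-record validation: one contig/strand per transcript, exons
  # non-overlapping, positive width
  bad_interval <- exons %>%
    filter(.data$end < .data$start) %>%
    pull(".tx")
  chk <- exons %>%
    group_by(.data$.tx) %>%
    summarise(
      n_ctg = n_distinct(.data$contig), n_str = n_distinct(.data$strand),
      self_overlap = {
        o <- order(.data$start)
        any(head(.data$end[o], -1) >= .data$start[o][-1]) && n() > 1
      },
      .groups = "drop"
    )
  bad <- union(
    bad_interval,
    chk$.tx[chk$n_ctg > 1 | chk$n_str > 1 | chk$self_overlap]
  )
  if (length(bad) > 0) {
    warn(sprintf(
      "dropping %d malformed transcript record(s): %s",
      length(bad),
      paste(head(sub("\r", ":", bad), 5), collapse = ", ")
    ))
    exons <- exons %>% filter(!.data$.tx %in% bad)
  }
  rejected <- tibble(key = sub("\r", ":", bad))
  if (nrow(exons) == 0) abort("no valid transcripts to cluster")

  gr <- GenomicRanges::GRanges(
    exons$contig, IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand
  )
  blocks <- GenomicRanges::reduce(gr) # strand-aware merged exonic intervals
  hits <- GenomicRanges::findOverlaps(gr, blocks)
  tx_ids <- unique(exons$.tx)
  # connected components of the transcript-block bipartite graph: two
  # transcripts overlap exonically iff their exons share a reduced block
  edges <- rbind(
    match(exons$.tx, tx_ids)[S4Vectors::queryHits(hits)],
    length(tx_ids) + S4Vectors::subjectHits(hits)
  )
  g <- igraph::make_graph(edges, n = length(tx_ids) + length(blocks), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(tx_ids)]

  members <- exons %>%
    distinct(.data$.tx, .data$sample_id, .data$gene_id, .data$transcript_id) %>%
    mutate(.comp = comp[match(.data$.tx, tx_ids)])

  fp <- exons %>%
    mutate(.comp = comp[match(.data$.tx, tx_ids)]) %>%
    group_by(.data$.comp, .data$contig, .data$strand) %>%
    summarise(
      iv = list(IRanges::reduce(IRanges::IRanges(.data$start, .data$end))),
      .groups = "drop"
    )
  # canonical ids: contig, footprint start, strand
  fp <- fp %>%
    mutate(.start = map_int(.data$iv, function(r) min(IRanges::start(r)))) %>%
    arrange(.data$contig, .data$.start, .data$strand) %>%
    mutate(uc_id = sprintf("UC%05d", row_number()))

  footprint <- fp %>%
    mutate(tbl = map(.data$iv, function(r) {
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    })) %>%
    select("uc_id", "contig", "strand", "tbl") %>%
    unnest("tbl")

  members <- members %>%
    left_join(fp %>% select(".comp", "uc_id"), by = ".comp") %>%
    select("uc_id", "sample_id", "gene_id", "transcript_id") %>%
    arrange(.data$uc_id, .data$sample_id, .data$transcript_id)

  clusters <- fp %>%
    mutate(
      start = .data$.start,
      end = map_int(.data$iv, function(r) max(IRanges::end(r))),
      footprint_length = map_int(.data$iv, function(r) sum(IRanges::width(r)))
    ) %>%
    select("uc_id", "contig", "strand", "start", "end", "footprint_length") %>%
    left_join(
      members %>%
        group_by(.data$uc_id) %>%
        summarise(
          n_members = n(), n_samples = n_distinct(.data$sample_id),
          gene_ids = id_set(.data$gene_id), .groups = "drop"
        ),
      by = "uc_id"
    ) %>%
    arrange(.data$uc_id)

  structure(
    list(
      clusters = clusters, members = members,
      footprint = footprint, rejected = rejected
    ),
    class = "uc_set"
  )
}

#' @export
print.uc_set <- function(x, ...) {
  cat(
    "<uc_set>", nrow(x$clusters), "unigene clusters from",
    nrow(x$members), "transcripts\n"
  )
  if (!is.null(x$clusters$status)) {
    print(count(x$clusters, .data$status))
  }
  invisible(x)
}

#' @export
tidy.uc_set <- function(x, ...) x$clusters

#' @export
glance.uc_set <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_transcripts = nrow(x$members),
    n_annotated = if (is.null(x$clusters$status)) NA_integer_ else sum(x$clusters$status == "annotated"),
    n_novel = if (is.null(x$clusters$status)) NA_integer_ else sum(x$clusters$status == "novel"),
    total_footprint_bp = sum(x$clusters$footprint_length)
  )
}

# footprint tibble -> GRanges keyed by uc_id
.footprint_gr <- function(footprint) {
  GenomicRanges::GRanges(
    footprint$contig, IRanges::IRanges(footprint$start, footprint$end),
    strand = footprint$strand, uc_id = footprint$uc_id
  )
}

#' Classify unigene clusters against a reference annotation
#'
#' A cluster is `annotated` iff its exonic footprint shares at least one
#' base, on the same strand, with an exon of any annotated gene; otherwise
#' `novel`. Matched gene ids are recorded.
#'
#' @param ucs A `uc_set` from [cluster_transcripts()].
#' @param annotation Reference annotation tibble (see
#'   [read_annotation_gtf()]); only `exon` features are used.
#' @return The `uc_set` with `status` and `matched_gene_ids` columns added
#'   to `clusters`.
#' @export
classify_clusters <- function(ucs, annotation) {
  ann_ex <- annotation %>% filter(.data$feature == "exon")
  if (nrow(ann_ex) == 0) {
    warn("empty annotation: all clusters classified novel")
    ucs$clusters$status <- "novel"
    ucs$clusters$matched_gene_ids <- ""
    return(ucs)
  }
  fp_gr <- .footprint_gr(ucs$footprint)
  ann_gr <- GenomicRanges::GRanges(
    ann_ex$contig, IRanges::IRanges(ann_ex$start, ann_ex$end),
    strand = ann_ex$strand
  )
  hits <- GenomicRanges::findOverlaps(fp_gr, ann_gr) # strand-aware
  matched <- tibble(
    uc_id = fp_gr$uc_id[S4Vectors::queryHits(hits)],
    gene_id = ann_ex$gene_id[S4Vectors::subjectHits(hits)]
  ) %>%
    group_by(.data$uc_id) %>%
    summarise(matched_gene_ids = id_set(.data$gene_id), .groups = "drop")
  ucs$clusters <- ucs$clusters %>%
    select(-dplyr::any_of(c("status", "matched_gene_ids"))) %>%
    left_join(matched, by = "uc_id") %>%
    mutate(
      status = if_else(is.na(.data$matched_gene_ids), "novel", "annotated"),
      matched_gene_ids = dplyr::coalesce(.data$matched_gene_ids, "")
    )
  ucs
}

#' Extract footprint sequences of clusters from the genome
#'
#' Concatenates the merged exonic intervals of each cluster (plus-strand
#' orientation; the six-frame ORF scan is orientation-free).
#'
#' @param ucs A `uc_set`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param uc_ids Optional subset of cluster ids.
#' @return A named character vector of sequences.
#' @export
uc_footprint_seqs <- function(ucs, genome, uc_ids = NULL) {
  fp <- ucs$footprint
  if (!is.null(uc_ids)) fp <- fp %>% filter(.data$uc_id %in% uc_ids)
  if (any(!fp$contig %in% names(genome))) {
    abort("cluster footprint on a contig absent from the genome")
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(fp$start < 1 | fp$end > lens[fp$contig])) {
    abort("cluster footprint outside genome bounds")
  }
  fp %>%
    mutate(seq = vapply(seq_len(n()), function(i) {
      as.character(Biostrings::subseq(genome[[fp$contig[i]]], fp$start[i], fp$end[i]))
    }, character(1))) %>%
    group_by(.data$uc_id) %>%
    summarise(seq = paste(.data$seq, collapse = ""), .groups = "drop") %>%
    (function(d) setNames(d$seq, d$uc_id))
}

# longest ATG..stop ORF (in nt, stop codon included) in one reading frame
.frame_max_orf <- function(codons) {
  atg <- which(codons == "ATG")
  stop <- which(codons %in% .STOPS)
  if (length(atg) == 0 || length(stop) == 0) {
    return(0L)
  }
  nxt <- stop[findInterval(atg, stop) + 1L]
  ok <- !is.na(nxt)
  if (!any(ok)) {
    return(0L)
  }
  as.integer(max((nxt[ok] - atg[ok] + 1L) * 3L))
}

#' Six-frame ORF length filter
#'
#' A sequence is kept iff any of the six reading frames (three on each
#' strand) contains a complete open reading frame -- ATG through an in-frame
#' stop, stop included -- of at least `min_orf_nt` nucleotides. Applied to
#' novel cluster footprints to separate protein-coding candidates from
#' spurious fragments.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param min_orf_nt Minimum ORF length in nucleotides (>= 3; default 300,
#'   i.e. 100 codons).
#' @return A tibble with `id`, `max_orf_nt` and `kept`.
#' @export
orf_filter <- function(seqs, min_orf_nt = 300) {
  if (min_orf_nt < 3) abort("min_orf_nt must be >= 3")
  seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  max_orf <- vapply(seqs, function(s) {
    s <- toupper(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    best <- 0L
    for (src in c(s, rc)) {
      n <- nchar(src)
      for (off in 0:2) {
        k <- floor((n - off) / 3)
        if (k < 2) next
        codons <- substring(
          src, off + 1L + 3L * (seq_len(k) - 1L),
          off + 3L * seq_len(k)
        )
        best <- max(best, .frame_max_orf(codons))
      }
    }
    best
  }, integer(1))
  tibble(
    id = names(seqs), max_orf_nt = unname(max_orf),
    kept = unname(max_orf) >= min_orf_nt
  )
}

#' Per-tissue expressed cluster flags
#'
#' A feature counts as expressed in a tissue iff its FPKM exceeds
#' `min_fpkm` in at least one sample of that tissue.
#'
#' @param fpkm Long FPKM tibble (`feature_id`, `sample_id`, `fpkm`).
#' @param samples Sample sheet.
#' @param min_fpkm Expression threshold (default 0: any positive evidence).
#' @return A tibble with `feature_id`, `blood`, `muscle` (logical flags).
#' @export
tissue_expressed <- function(fpkm, samples, min_fpkm = 0) {
  samples <- validate_samples(samples)
  missing <- setdiff(unique(fpkm$sample_id), samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples absent from sample sheet: ", paste(missing, collapse = ", ")))
  }
  fpkm %>%
    left_join(samples %>% select("sample_id", "tissue"), by = "sample_id") %>%
    group_by(.data$feature_id, .data$tissue) %>%
    summarise(expressed = any(.data$fpkm > min_fpkm), .groups = "drop") %>%
    pivot_wider(
      names_from = "tissue", values_from = "expressed", values_fill = FALSE
    ) %>%
    mutate(across(dplyr::any_of(c("blood", "muscle")), ~ dplyr::coalesce(.x, FALSE))) %>%
    arrange(.data$feature_id)
}

#' Three-way expressed/annotated Venn region counts
#'
#' Partitions clusters into the eight regions of the
#' blood-expressed / muscle-expressed / annotated Venn diagram (the region
#' counts sum to the total cluster count).
#'
#' @param clusters `clusters` tibble of a classified `uc_set` (needs
#'   `uc_id`, `status`).
#' @param expressed Output of [tissue_expressed()] keyed by `uc_id`.
#' @return A tibble with `region` and `n`.
#' @export
uc_venn <- function(clusters, expressed) {
  d <- clusters %>%
    select("uc_id", "status") %>%
    left_join(expressed, by = c(uc_id = "feature_id")) %>%
    mutate(
      blood = dplyr::coalesce(.data$blood, FALSE),
      muscle = dplyr::coalesce(.data$muscle, FALSE),
      annotated = .data$status == "annotated"
    )
  all_regions <- crossing(blood = c(TRUE, FALSE), muscle = c(TRUE, FALSE), annotated = c(TRUE, FALSE)) %>%
    mutate(region = .venn_label(.data$blood, .data$muscle, .data$annotated))
  d %>%
    count(.data$blood, .data$muscle, .data$annotated) %>%
    dplyr::right_join(all_regions, by = c("blood", "muscle", "annotated")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    select("region", "n") %>%
    arrange(.data$region)
}

.venn_label <- function(blood, muscle, annotated) {
  lab <- purrr::pmap_chr(
    list(blood, muscle, annotated),
    function(b, m, a) {
      parts <- c("blood"[b], "muscle"[m], "annotation"[a])
      if (length(parts) == 0) "none" else paste(parts, collapse = "&")
    }
  )
  lab
}

#' Write unigene cluster models as GTF
#'
#' One gene per cluster, with a single merged-exon transcript spanning the
#' footprint intervals.
#'
#' @param ucs A `uc_set`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_uc_gtf <- function(ucs, file) {
  ucs$footprint %>%
    mutate(
      gene_id = .data$uc_id,
      transcript_id = paste0(.data$uc_id, ".m")
    ) %>%
    write_transcript_gtf(file)
}
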