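# Independent brute-force oracles. Each deliberately takes a different
# computational route from the package implementation it checks.

# O(n^2) pairwise exonic-overlap union-find over transcripts; returns a
# canonical partition: sorted list of sorted member keys
oracle_cluster <- function(exons) {
  key <- paste(exons$sample_id, exons$transcript_id, sep = ":")
  tx <- unique(key)
  ex_of <- split(seq_len(nrow(exons)), key)
  parent <- seq_along(tx)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  overlaps <- function(i, j) {
    a <- exons[ex_of[[tx[i]]], ]
    b <- exons[ex_of[[tx[j]]], ]
    if (a$contig[1] != b$contig[1] || a$strand[1] != b$strand[1]) {
      return(FALSE)
    }
    for (p in seq_len(nrow(a))) {
      for (q in seq_len(nrow(b))) {
        if (a$start[p] <= b$end[q] && b$start[q] <= a$end[p]) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- length(tx)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (overlaps(i, j)) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(tx), find, integer(1))
  parts <- unname(split(tx, roots))
  sorted <- lapply(parts, sort)
  sorted[order(vapply(sorted, `[`, character(1), 1))]
}

# canonical partition of a uc_set for comparison with the oracle
uc_partition <- function(ucs) {
  key <- paste(ucs$members$sample_id, ucs$members$transcript_id, sep = ":")
  parts <- split(key, ucs$members$uc_id)
  sorted <- lapply(unname(parts), sort)
  sorted[order(vapply(sorted, `[`, character(1), 1))]
}

# six-frame ORF decision via translation + regex (vs the codon-scan in the
# package): longest "M...*" run in amino acids, stop included
oracle_orf_kept <- function(seq, min_orf_nt) {
  seq <- Biostrings::DNAString(seq)
  best <- 0L
  for (src in list(seq, Biostrings::reverseComplement(seq))) {
    for (off in 0:2) {
      n <- length(src) - off
      n <- n - n %% 3
      if (n < 6) next
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::subseq(src, off + 1, off + n))
      ))
      m <- regmatches(aa, gregexpr("M[^*]*\\*", aa))[[1]]
      if (length(m) > 0) best <- max(best, max(nchar(m)) * 3L)
    }
  }
  best >= min_orf_nt
}

# full-CDS translate-and-diff effect oracle: mutate the genome, re-extract
# the whole spliced CDS, translate both, compare protein sequences
oracle_effect <- function(contig_seq, cds_tbl, pos, alt) {
  extract <- function(s) {
    ord <- order(cds_tbl$start)
    parts <- vapply(ord, function(i) {
      substr(s, cds_tbl$start[i], cds_tbl$end[i])
    }, character(1))
    dna <- Biostrings::DNAString(paste(parts, collapse = ""))
    if (cds_tbl$strand[1] == "-") dna <- Biostrings::reverseComplement(dna)
    # plain genetic code: do not remap alternative initiator codons to M
    as.character(Biostrings::translate(dna, no.init.codon = TRUE))
  }
  mutated <- contig_seq
  substr(mutated, pos, pos) <- alt
  if (extract(contig_seq) == extract(mutated)) "synonymous" else "non_synonymous"
}

# exhaustive per-feature evaluation of the fold-change voting rule from a
# wide FPKM matrix, plain base R
oracle_degs <- function(fpkm, samples, fold_threshold = 2, min_horses = 4,
                        pseudocount = 0.1) {
  wide <- tidyr::pivot_wider(fpkm,
    id_cols = "feature_id",
    names_from = "sample_id", values_from = "fpkm"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$feature_id
  out <- list()
  for (tis in unique(samples$tissue)) {
    horses <- unique(samples$horse[samples$tissue == tis])
    for (f in wide$feature_id) {
      n_up <- 0L
      n_dn <- 0L
      for (h in horses) {
        sid <- function(tp) {
          samples$sample_id[samples$horse == h &
            samples$tissue == tis & samples$timepoint == tp]
        }
        fold <- (m[f, sid("after")] + pseudocount) /
          (m[f, sid("before")] + pseudocount)
        if (fold > fold_threshold) n_up <- n_up + 1L
        if (fold < 1 / fold_threshold) n_dn <- n_dn + 1L
      }
      if (n_up >= min_horses) {
        out[[length(out) + 1]] <- data.frame(
          feature_id = f, tissue = tis, direction = "up"
        )
      }
      if (n_dn >= min_horses) {
        out[[length(out) + 1]] <- data.frame(
          feature_id = f, tissue = tis, direction = "down"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      feature_id = character(), tissue = character(), direction = character()
    ))
  }
  d <- do.call(rbind, out)
  d[order(d$tissue, d$direction, d$feature_id), ]
}

# linear-interpolation quantile from first principles (sort + index)
oracle_quantile <- function(x, p) {
  x <- unname(sort(x))
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# random multi-exon transcripts for clustering tests
random_transcripts <- function(n, contigs = c("c1", "c2", "c3"), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n)) {
    contig <- sample(contigs, 1)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    start <- sample(1:5000, 1)
    exs <- list()
    for (e in seq_len(n_ex)) {
      len <- sample(20:200, 1)
      exs[[e]] <- c(start, start + len - 1)
      start <- start + len + sample(10:300, 1)
    }
    rows[[i]] <- data.frame(
      sample_id = sample(c("s1", "s2", "s3"), 1),
      gene_id = sprintf("g%d", i),
      transcript_id = sprintf("t%d", i),
      contig = contig, strand = strand,
      start = vapply(exs, `[`, numeric(1), 1),
      end = vapply(exs, `[`, numeric(1), 2)
    )
  }
  dplyr::as_tibble(do.call(rbind, rows))
}
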