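# The generator is the foundation every other suite leans on: it must be
# deterministic, its gene models structurally valid, and its planted truths
# complete and exactly recoverable in the noiseless limit.

test_that("study design enumerates the 24 paired samples", {
  d <- sim_design(seed = 3)
  expect_equal(nrow(d$samples), 24)
  expect_equal(
    nrow(dplyr::distinct(d$samples, horse, tissue, timepoint)), 24
  )
  expect_error(validate_samples(d$samples[-1, ], complete = TRUE), "timepoint|exactly one")
})

test_that("same seed reproduces a byte-identical corpus on disk", {
  s1 <- sim_study(seed = 11, n_contigs = 2, n_genes = 24, n_sites = 60, n_artifacts = 20)
  s2 <- sim_study(seed = 11, n_contigs = 2, n_genes = 24, n_sites = 60, n_artifacts = 20)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  write_study(s1, d1)
  write_study(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = paste("file", f)
    )
  }
  s3 <- sim_study(seed = 12, n_contigs = 2, n_genes = 24, n_sites = 60, n_artifacts = 20)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("generated annotation is structurally valid after a GTF round-trip", {
  g <- sim_genome(2, 200000L, 40, seed = 1)
  gtf <- file.path(tempdir(), "ann.gtf")
  write_annotation_gtf(g$annotation, gtf)
  ann <- read_annotation_gtf(gtf) # independent parser (rtracklayer)
  lens <- stats::setNames(Biostrings::width(g$genome), names(g$genome))
  expect_true(all(ann$start >= 1 & ann$end <= lens[ann$contig]))
  expect_true(all(ann$start <= ann$end))
  # per-gene transcripts share one strand
  per_gene <- dplyr::summarise(dplyr::group_by(ann, gene_id),
    n_strand = dplyr::n_distinct(strand), .groups = "drop"
  )
  expect_true(all(per_gene$n_strand == 1))
  # every CDS translates M...* without internal stops
  cds <- ann[ann$feature == "CDS", ]
  expect_gt(nrow(cds), 0)
  for (i in seq_len(nrow(cds))) {
    seq <- Biostrings::subseq(g$genome[[cds$contig[i]]], cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") seq <- Biostrings::reverseComplement(seq)
    aa <- as.character(Biostrings::translate(seq))
    expect_match(aa, "^M[^*]+\\*$")
  }
})

test_that("infeasible packing and bad preconditions error out", {
  expect_error(sim_genome(1, 50000L, 60, seed = 1), "fit")
  expect_error(sim_genome(1, 10000L, 5, seed = 1), "50 kb")
  expect_error(sim_genome(3, 60000L, 4, seed = 1), "2 genes")
  expect_error(sim_counts(mini_samples(), effect = 0), "> 0")
  expect_error(sim_study(seed = 1, effect = -2), "> 0")
})

test_that("noiseless planted effects give exact fold changes in every horse", {
  sc <- sim_counts(mini_samples(),
    n_features = 50,
    n_deg = c(blood_up = 3, blood_down = 0, muscle_up = 0, muscle_down = 2),
    effect = 4, cv = 0, seed = 7
  )
  wide <- tidyr::pivot_wider(sc$counts,
    names_from = "sample_id", values_from = "count"
  )
  up <- unique(sc$deg_truth$feature_id[sc$deg_truth$direction == "up"])
  for (f in up) {
    row <- wide[wide$feature_id == f, ]
    for (h in sprintf("H%d", 1:6)) {
      expect_identical(
        row[[paste0(h, "_blood_after")]] / row[[paste0(h, "_blood_before")]],
        4
      )
      # effect is tissue-specific
      expect_identical(
        row[[paste0(h, "_muscle_after")]] / row[[paste0(h, "_muscle_before")]],
        1
      )
    }
  }
})

test_that("planted heterozygous sites show near-0.5 allele fractions at high depth", {
  exons <- tibble::tibble(contig = "c1", start = c(1000, 3000), end = c(2000, 4000))
  ss <- sim_sites(mini_samples(), exons,
    n_sites = 40, n_artifacts = 5,
    depth_mean = 1000, error_rate = 0, seed = 5
  )
  het <- dplyr::filter(ss$genotype_truth, genotype == "het", type == "SNP")
  obs <- dplyr::inner_join(
    ss$observations,
    dplyr::inner_join(het, mini_samples()[c("sample_id", "horse")],
      by = "horse", relationship = "many-to-many"
    ),
    by = c("contig", "pos", "sample_id")
  )
  frac <- mapply(
    function(i) {
      alt <- obs[[obs$alt[i]]][i]
      alt / (obs$A[i] + obs$C[i] + obs$G[i] + obs$T[i])
    },
    seq_len(nrow(obs))
  )
  expect_gt(nrow(obs), 100)
  expect_gt(mean(frac >= 0.45 & frac <= 0.55), 0.98)
})

test_that("artifact alleles appear only in carrier samples", {
  exons <- tibble::tibble(contig = "c1", start = c(1000, 3000), end = c(2000, 4000))
  samples <- mini_samples()
  carriers <- tidyr::crossing(
    contig = "c1", start = 1000, end = 4000,
    sample_id = samples$sample_id[samples$tissue == "muscle"]
  )
  ss <- sim_sites(samples, exons,
    n_sites = 10, n_artifacts = 15,
    depth_mean = 50, error_rate = 0, carrier_map = carriers, seed = 9
  )
  art_obs <- dplyr::inner_join(
    ss$observations, ss$artifact_sites[c("contig", "pos", "alt")],
    by = c("contig", "pos")
  )
  alt_count <- vapply(
    seq_len(nrow(art_obs)),
    function(i) art_obs[[art_obs$alt[i]]][i], numeric(1)
  )
  tissue <- samples$tissue[match(art_obs$sample_id, samples$sample_id)]
  expect_true(all(alt_count[tissue == "blood"] == 0))
  expect_gt(sum(alt_count[tissue == "muscle"]), 0)
})

test_that("database overlap fractions behave as planted", {
  exons <- tibble::tibble(contig = "c1", start = 1000, end = 9000)
  ss <- sim_sites(mini_samples(), exons,
    n_sites = 200, n_artifacts = 5,
    indel_fraction = 0, seed = 13
  )
  clen <- c(c1 = 10000L)
  # full overlap: every truth site in both; none: every site novel
  full <- sim_snp_databases(ss$site_truth, c(1, 1), n_extra = 0, contig_lengths = clen, seed = 1)
  st <- compare_to_databases(ss$site_truth, full$db1, full$db2)
  expect_true(all(st$db_status == "both"))
  none <- sim_snp_databases(ss$site_truth, c(0, 0), n_extra = 10, contig_lengths = clen, seed = 1)
  st0 <- compare_to_databases(ss$site_truth, none$db1, none$db2)
  expect_true(all(st0$db_status == "novel"))
  # independent draws: both-count near 200 * 0.5 * 0.3 (binomial, +-5 sd)
  half <- sim_snp_databases(ss$site_truth, c(0.5, 0.3), n_extra = 0, contig_lengths = clen, seed = 2)
  n_both <- sum(half$membership$in_db1 & half$membership$in_db2)
  expect_lt(abs(n_both - 200 * 0.5 * 0.3), 5 * sqrt(200 * 0.15 * 0.85))
  expect_error(
    sim_snp_databases(ss$site_truth, c(1.2, 0), 0, contig_lengths = clen),
    "\\[0, 1\\]"
  )
})

test_that("truth tables are complete and artifact sites disjoint from genotypes", {
  s <- test_study()
  # every planted DEG slot appears once per horse
  slot_counts <- dplyr::count(s$truth$deg, feature_id, tissue, direction)
  expect_true(all(slot_counts$n == length(unique(s$samples$horse))))
  expect_false(any(duplicated(
    dplyr::distinct(s$truth$deg, feature_id, tissue)[c("feature_id", "tissue")]
  )))
  # artifacts never coincide with genotype-truth positions
  overlap <- dplyr::inner_join(
    s$truth$artifacts[c("contig", "pos")],
    s$truth$genotype[c("contig", "pos")],
    by = c("contig", "pos")
  )
  expect_equal(nrow(overlap), 0)
  # switch truth references real isoforms of the gene
  sw <- dplyr::left_join(s$truth$switch, s$gene_map,
    by = c(gene_id = "gene_id", isoform_a = "transcript_id"),
    keep = FALSE
  )
  expect_true(all(s$truth$switch$isoform_a %in% s$gene_map$transcript_id))
  expect_true(all(s$truth$switch$isoform_b %in% s$gene_map$transcript_id))
  # novel transcripts lie outside every annotated gene footprint
  novel_tx <- s$truth$novelty$transcript_id[s$truth$novelty$status == "novel"]
  ann_ex <- s$annotation[s$annotation$feature == "exon", ]
  ann_gr <- GenomicRanges::GRanges(
    ann_ex$contig, IRanges::IRanges(ann_ex$start, ann_ex$end)
  )
  ntx <- s$sample_exons[s$sample_exons$transcript_id %in% novel_tx, ]
  ntx_gr <- GenomicRanges::GRanges(
    ntx$contig, IRanges::IRanges(ntx$start, ntx$end)
  )
  expect_false(any(IRanges::overlapsAny(ntx_gr, ann_gr)))
})
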