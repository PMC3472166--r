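# Gates, the junction misalignment filter, merging/set algebra, database
# comparison and coding-effect annotation.

obs_row <- function(sample = "H1_blood_before", contig = "c1", pos = 100,
                    ref = "A", A = 0, C = 0, G = 0, T = 0,
                    indel = 0, indel_allele = NA_character_) {
  tibble::tibble(
    sample_id = sample, contig = contig, pos = pos, ref = ref,
    A = A, C = C, G = G, T = T, indel = indel, indel_allele = indel_allele
  )
}

test_that("depth, alt-read and fraction gates govern calling and genotyping", {
  # depth 30, alt 15 -> het under defaults
  calls <- call_variants(obs_row(ref = "A", A = 15, G = 15))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt, "G")
  expect_equal(calls$genotype, "het")
  # depth 3 below min_depth 4 -> nothing
  expect_equal(nrow(call_variants(obs_row(A = 1, G = 2), min_depth = 4)), 0)
  # hom boundary is inclusive at hom_fraction
  hom <- call_variants(obs_row(ref = "A", A = 6, G = 24))
  expect_equal(hom$genotype, "hom")
  # multi-allelic site decomposes into one record per alt
  multi <- call_variants(obs_row(ref = "A", A = 10, C = 10, G = 10))
  expect_setequal(multi$alt, c("C", "G"))
  # indel allele called as INDEL type
  ind <- call_variants(obs_row(ref = "A", A = 20, indel = 10, indel_allele = "+AC"))
  expect_equal(ind$type, "INDEL")
  expect_equal(ind$alt, "+AC")
  # unknown reference base skipped with a message
  expect_message(
    none <- call_variants(obs_row(ref = "N", A = 30)),
    "unknown"
  )
  expect_equal(nrow(none), 0)
})

test_that("thresholds are monotone: raising any gate never adds calls", {
  set.seed(23)
  obs <- dplyr::bind_rows(lapply(1:200, function(i) {
    counts <- as.integer(rmultinom(1, sample(2:60, 1), runif(4)))
    obs_row(
      pos = i, ref = sample(c("A", "C", "G", "T"), 1),
      A = counts[1], C = counts[2], G = counts[3], T = counts[4]
    )
  }))
  key <- function(d) paste(d$pos, d$alt)
  base <- call_variants(obs)
  for (arg in list(
    list(min_depth = 10), list(min_alt_reads = 5), list(min_alt_fraction = 0.4)
  )) {
    stricter <- do.call(call_variants, c(list(obs), arg))
    expect_true(all(key(stricter) %in% key(base)), label = names(arg))
  }
})

test_that("junction filter removes boundary-adjacent candidates, monotonically", {
  boundaries <- tibble::tibble(contig = "c1", pos = c(500, 1000))
  cands <- tibble::tibble(
    contig = "c1",
    pos = c(497, 510, 550, 990, 1000, 700)
  )
  kept <- junction_filter(cands, boundaries, window_bp = 10)
  expect_setequal(kept$pos, c(550, 700)) # 497/510/990/1000 within 10 of a boundary
  # 50 bp interior point survives any reasonable window
  expect_true(700 %in% junction_filter(cands, boundaries, 40)$pos)
  # monotone: larger window keeps a subset
  prev <- cands
  for (w in c(0, 5, 10, 20, 60)) {
    cur <- junction_filter(cands, boundaries, w)
    expect_true(all(cur$pos %in% prev$pos), label = paste("window", w))
    prev <- cur
  }
  expect_error(junction_filter(cands, boundaries, -1), ">= 0")
})

test_that("junction filter commutes with the calling gates", {
  s <- test_study()
  boundaries <- exon_boundaries(
    s$annotation_all[s$annotation_all$feature == "exon", ]
  )
  obs <- s$observations[s$observations$sample_id == s$samples$sample_id[1], ]
  a <- junction_filter(call_variants(obs), boundaries, 10)
  b <- call_variants(junction_filter(obs, boundaries, 10))
  expect_identical(
    dplyr::arrange(a, contig, pos, alt),
    dplyr::arrange(b, contig, pos, alt)
  )
})

test_that("merging is keyed by allele, tracks carriers and individual-specificity", {
  samples <- mini_samples()
  calls <- tibble::tibble(
    sample_id = c(
      "H1_blood_before", "H1_muscle_before", "H2_blood_after", # v1: 2 horses
      "H3_blood_before", "H3_muscle_after" # v2: 1 horse
    ),
    contig = "c1",
    pos = c(10, 10, 10, 20, 20),
    ref = "A", alt = c("G", "G", "G", "C", "C"),
    type = "SNP"
  )
  m <- merge_variants(calls, samples)
  expect_equal(nrow(m), 2)
  v1 <- m[m$pos == 10, ]
  expect_equal(v1$n_horses, 2L)
  expect_false(v1$individual_specific)
  v2 <- m[m$pos == 20, ]
  expect_equal(v2$horses, "H3")
  expect_true(v2$individual_specific)
  expect_equal(sum(m$individual_specific) + sum(!m$individual_specific), nrow(m))
  # conflicting reference alleles across samples are inconsistent inputs
  bad <- dplyr::bind_rows(calls, tibble::tibble(
    sample_id = "H4_blood_before", contig = "c1", pos = 10,
    ref = "T", alt = "G", type = "SNP"
  ))
  expect_error(merge_variants(bad, samples), "conflicting")
})

test_that("merged counts equal a brute-force set-algebra oracle on random call sets", {
  set.seed(41)
  samples <- mini_samples()
  calls <- dplyr::bind_rows(lapply(samples$sample_id, function(sid) {
    n <- sample(5:30, 1)
    pos <- sample(1:60, n)
    tibble::tibble(
      sample_id = sid, contig = "c1", pos = pos,
      ref = "A", alt = "G", type = "SNP"
    )
  }))
  m <- merge_variants(calls, samples)
  presence <- variant_presence(m, horses = unique(samples$horse))
  # oracle: plain tapply over positions
  horse_of <- samples$horse[match(calls$sample_id, samples$sample_id)]
  by_pos <- split(horse_of, calls$pos)
  expect_equal(nrow(m), length(by_pos))
  for (p in names(by_pos)) {
    hs <- sort(unique(by_pos[[p]]))
    row <- m[m$pos == as.integer(p), ]
    expect_equal(row$n_horses, length(hs))
    expect_equal(row$horses, paste(hs, collapse = ","))
    expect_equal(row$individual_specific, length(hs) == 1)
    prow <- presence[presence$pos == as.integer(p), ]
    expect_equal(
      sort(names(prow)[vapply(prow, isTRUE, logical(1))]), hs
    )
  }
  expect_equal(
    sum(m$individual_specific) + sum(m$n_horses > 1), nrow(m)
  )
})

test_that("database comparison requires allele identity and summarises percentages", {
  v <- tibble::tibble(
    contig = "c1", pos = c(1, 2, 3, 4),
    ref = c("A", "A", "A", "A"), alt = c("G", "G", "G", "G")
  )
  db1 <- tibble::tibble(contig = "c1", pos = c(1, 2, 3), ref = "A", alt = c("G", "G", "C"))
  db2 <- tibble::tibble(contig = "c1", pos = c(1, 3), ref = "A", alt = c("G", "G"))
  st <- compare_to_databases(v, db1, db2)
  expect_equal(st$db_status, c("both", "db1_only", "db2_only", "novel"))
  sm <- db_summary(st)
  expect_equal(sum(sm$n), 4)
  expect_equal(sm$pct[sm$db_status == "both"], 25)
})

test_that("codon-level effects match hand-built cases on both strands", {
  # gene on +: CDS ATG GGA TAA at 11..19; gene on -: CDS at 31..39
  plus_cds <- "ATGGGATAA"
  minus_cds_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_cds)))
  contig <- paste0(
    strrep("T", 10), plus_cds, strrep("T", 11), minus_cds_rc, strrep("T", 10)
  )
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  ann <- tibble::tibble(
    feature = "CDS",
    gene_id = c("gp", "gm"), transcript_id = c("tp", "tm"),
    contig = "c1", strand = c("+", "-"),
    start = c(11, 31), end = c(19, 39), frame = 0L
  )
  v <- tibble::tibble(
    contig = "c1",
    # + strand: GGA->GGG codon pos 3 (silent); GGA->AGA codon pos 1 (Gly->Arg)
    # - strand: same two edits through reverse complement coordinates
    pos = c(19, 14, 31, 36),
    ref = c("A", "G", "T", "C"),
    alt = c("G", "A", "C", "T"),
    type = "SNP"
  )
  out <- annotate_effects(v, ann, genome)
  expect_equal(out$effect, c(
    "synonymous", "non_synonymous", "synonymous", "non_synonymous"
  ))
  expect_equal(out$aa_ref[2], "G")
  expect_equal(out$aa_alt[2], "R")
  expect_equal(out$cds_transcript, c("tp", "tp", "tm", "tm"))
})

test_that("spliced CDS, indels, non-coding and frame defects are handled", {
  # CDS split across two exons: ATGG | GATAA (plus strand)
  contig <- paste0(strrep("A", 10), "ATGG", strrep("C", 6), "GATAA", strrep("A", 10))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  ann <- tibble::tibble(
    feature = "CDS", gene_id = "g", transcript_id = "t",
    contig = "c1", strand = "+",
    start = c(11, 21), end = c(14, 25), frame = c(0L, NA_integer_)
  )
  # position 21 is CDS base 5 (codon 2 pos 2: GGA -> GTA, Gly->Val)
  v <- tibble::tibble(
    contig = "c1", pos = c(21, 12, 5, 3),
    ref = c("G", "T", "A", "A"), alt = c("T", "+CC", "G", "C"),
    type = c("SNP", "INDEL", "SNP", "SNP")
  )
  out <- annotate_effects(
    v, ann, genome,
    exonic = tibble::tibble(contig = "c1", start = 1, end = 7)
  )
  expect_equal(out$effect, c("non_synonymous", "non_synonymous", "non_coding", "non_coding"))
  expect_equal(out$location, c("exonic_UC", "exonic_UC", "exonic_UC", "exonic_UC"))
  # outside CDS and outside exonic footprint
  far <- annotate_effects(
    tibble::tibble(contig = "c1", pos = 30, ref = "A", alt = "G", type = "SNP"),
    ann, genome
  )
  expect_equal(far$location, "other")
  expect_true(is.na(far$effect))
  # CDS length not divisible by 3: warn and mark NA
  bad_ann <- dplyr::mutate(ann[1, ], end = 14) # 4 nt
  expect_warning(
    na_out <- annotate_effects(v[1, ] |> dplyr::mutate(pos = 12, ref = "T", alt = "C"), bad_ann, genome),
    "divisible"
  )
  expect_true(is.na(na_out$effect))
  expect_equal(na_out$location, "exonic_UC")
})

test_that("density report is boundary-inclusive and tallies per-animal profiles", {
  v <- tibble::tibble(
    contig = "c1", pos = 1:5, ref = "A", alt = "G", type = "SNP",
    horses = c("H1", "H1,H2", "H1", "H2", "H3"),
    cds_transcript = c("t1", "t1", "t1", "t2", NA),
    cds_pos = c(3L, 6L, 9L, 3L, NA),
    effect = c("non_synonymous", "non_synonymous", "synonymous", "non_synonymous", NA)
  )
  d2 <- variant_density(v, min_nonsyn = 2)
  expect_equal(d2$ranking$transcript_id, "t1")
  expect_equal(d2$ranking$n_nonsyn, 2L)
  expect_equal(d2$ranking$n_syn, 1L)
  # boundary inclusive: transcripts with exactly min_nonsyn are reported
  d1 <- variant_density(v, min_nonsyn = 1)
  expect_setequal(d1$ranking$transcript_id, c("t1", "t2"))
  # profile expands carriers; H1,H2 variant contributes two rows
  expect_equal(sum(d1$profiles$transcript_id == "t1"), 4)
  d9 <- variant_density(v, min_nonsyn = 9)
  expect_equal(nrow(d9$ranking), 0)
})
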