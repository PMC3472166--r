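# SNV/indel discovery from per-sample site observations: depth and allele
# fraction gates, the exon-intron boundary misalignment filter, merging to a
# non-redundant set, database comparison and coding-effect annotation.
# Indels are represented by alt tokens "+SEQ" (insertion after the site) and
# "-SEQ" (deletion of SEQ following the site).

#' Call candidate variants for each sample from site observations
#'
#' A site is called iff total depth >= `min_depth`, alternate reads >=
#' `min_alt_reads` and alternate fraction >= `min_alt_fraction`; every
#' non-reference allele passing the gates yields its own record
#' (multi-allelic sites decompose). The genotype is heterozygous below
#' `hom_fraction`, homozygous at or above it.
#'
#' @param observations Tibble with `sample_id`, `contig`, `pos`, `ref`,
#'   base-count columns `A`, `C`, `G`, `T`, and `indel`/`indel_allele`.
#' @param min_depth Minimum total read depth (default 4).
#' @param min_alt_reads Minimum alternate-supporting reads (default 2).
#' @param min_alt_fraction Minimum alternate allele fraction (default 0.2).
#' @param hom_fraction Fraction at or above which a call is homozygous
#'   (default 0.8).
#' @return Tibble of calls: `sample_id`, `contig`, `pos`, `ref`, `alt`,
#'   `type`, `depth`, `alt_count`, `alt_fraction`, `genotype`.
#' @export
call_variants <- function(observations, min_depth = 4, min_alt_reads = 2,
                          min_alt_fraction = 0.2, hom_fraction = 0.8) {
  obs <- as_tibble(observations)
  unknown <- !obs$ref %in% .BASES
  if (any(unknown)) {
    inform(sprintf("skipping %d site(s) with unknown reference base", sum(unknown)))
    obs <- obs[!unknown, ]
  }
  if (!"indel" %in% names(obs)) obs$indel <- 0L
  if (!"indel_allele" %in% names(obs)) obs$indel_allele <- NA_character_
  obs <- obs %>%
    mutate(depth = .data$A + .data$C + .data$G + .data$T + .data$indel)

  subs <- obs %>%
    pivot_longer(dplyr::all_of(.BASES), names_to = "alt", values_to = "alt_count") %>%
    filter(.data$alt != .data$ref, .data$alt_count > 0) %>%
    mutate(type = "SNP")
  indels <- obs %>%
    filter(.data$indel > 0, !is.na(.data$indel_allele)) %>%
    mutate(alt = .data$indel_allele, alt_count = .data$indel, type = "INDEL")
  bind_rows(subs, indels) %>%
    mutate(alt_fraction = .data$alt_count / .data$depth) %>%
    filter(
      .data$depth >= min_depth,
      .data$alt_count >= min_alt_reads,
      .data$alt_fraction >= min_alt_fraction
    ) %>%
    mutate(genotype = if_else(.data$alt_fraction < hom_fraction, "het", "hom")) %>%
    select(
      "sample_id", "contig", "pos", "ref", "alt", "type",
      "depth", "alt_count", "alt_fraction", "genotype"
    ) %>%
    arrange(.data$sample_id, .data$contig, .data$pos, .data$alt)
}

#' Exon boundary positions from an exon table
#'
#' @param exons Tibble with `contig`, `start`, `end` (exon intervals from
#'   the reference annotation and/or cluster models).
#' @return Tibble of unique boundary positions (`contig`, `pos`).
#' @export
exon_boundaries <- function(exons) {
  bind_rows(
    exons %>% select("contig", pos = "start"),
    exons %>% select("contig", pos = "end")
  ) %>%
    distinct() %>%
    arrange(.data$contig, .data$pos)
}

#' Exon-intron boundary misalignment filter
#'
#' Removes every candidate whose position lies within `window_bp` bases of
#' an exon start or end. Spliced reads misaligned across exon-intron
#' boundaries pile up spurious alternate alleles there; this positional
#' filter discards them. Monotone: a larger window never retains more.
#'
#' @param candidates Variant call tibble (needs `contig`, `pos`).
#' @param boundaries Boundary positions from [exon_boundaries()].
#' @param window_bp Window half-width in bp (>= 0, default 10).
#' @return The retained candidates.
#' @export
junction_filter <- function(candidates, boundaries, window_bp = 10) {
  if (window_bp < 0) abort("window_bp must be >= 0")
  if (nrow(candidates) == 0 || nrow(boundaries) == 0) {
    return(candidates)
  }
  cand_gr <- GenomicRanges::GRanges(
    candidates$contig, IRanges::IRanges(candidates$pos, candidates$pos)
  )
  bnd_gr <- GenomicRanges::GRanges(
    boundaries$contig,
    IRanges::IRanges(boundaries$pos - window_bp, boundaries$pos + window_bp)
  )
  hit <- IRanges::overlapsAny(cand_gr, bnd_gr)
  candidates[!hit, , drop = FALSE]
}

#' Merge per-sample calls into a non-redundant variant set
#'
#' Variants are keyed by (contig, pos, ref, alt). A variant is
#' individual-specific iff all carrying samples belong to one animal.
#' Presence is judged on called presence only: an absent call counts as
#' absence, regardless of coverage.
#'
#' @param calls Per-sample call tibble (from [call_variants()], possibly
#'   filtered).
#' @param samples Sample sheet mapping `sample_id` to `horse`.
#' @return Tibble with one row per variant: `contig`, `pos`, `ref`, `alt`,
#'   `type`, `n_samples`, `n_horses`, `horses`, `sample_ids`,
#'   `individual_specific`.
#' @export
merge_variants <- function(calls, samples) {
  samples <- validate_samples(samples)
  calls <- calls %>%
    left_join(samples %>% select("sample_id", "horse"), by = "sample_id")
  if (any(is.na(calls$horse))) abort("calls reference samples absent from the sample sheet")
  conflict <- calls %>%
    distinct(.data$contig, .data$pos, .data$ref) %>%
    count(.data$contig, .data$pos) %>%
    filter(n > 1)
  if (nrow(conflict) > 0) {
    abort(sprintf(
      "conflicting reference allele at %d position(s); inputs inconsistent (first: %s:%d)",
      nrow(conflict), conflict$contig[1], conflict$pos[1]
    ))
  }
  calls %>%
    group_by(.data$contig, .data$pos, .data$ref, .data$alt, .data$type) %>%
    summarise(
      n_samples = n_distinct(.data$sample_id),
      n_horses = n_distinct(.data$horse),
      horses = id_set(.data$horse),
      sample_ids = id_set(.data$sample_id),
      .groups = "drop"
    ) %>%
    mutate(individual_specific = .data$n_horses == 1L) %>%
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
}

#' Per-animal variant presence matrix
#'
#' @param merged Merged variant tibble from [merge_variants()].
#' @param horses Character vector of all animals (columns; defaults to the
#'   carriers observed).
#' @return Wide tibble: one row per variant, one logical column per animal.
#' @export
variant_presence <- function(merged, horses = NULL) {
  long <- merged %>%
    select("contig", "pos", "ref", "alt", "horses") %>%
    mutate(horse = strsplit(.data$horses, ",", fixed = TRUE)) %>%
    select(-"horses") %>%
    unnest("horse") %>%
    mutate(present = TRUE)
  if (is.null(horses)) horses <- sort(unique(long$horse))
  long %>%
    pivot_wider(names_from = "horse", values_from = "present", values_fill = FALSE) %>%
    (function(d) {
      for (h in setdiff(horses, names(d))) d[[h]] <- FALSE
      d
    }) %>%
    select("contig", "pos", "ref", "alt", dplyr::all_of(horses))
}

#' Compare a variant set with two SNP databases
#'
#' A database match requires identical contig, position, reference and
#' alternate allele (positional matching alone would inflate the overlap).
#'
#' @param variants Merged variant tibble.
#' @param db1,db2 Database site tables (`contig`, `pos`, `ref`, `alt`) or
#'   paths to VCF files.
#' @return `variants` with a `db_status` column: `"novel"`, `"db1_only"`,
#'   `"db2_only"` or `"both"`.
#' @export
compare_to_databases <- function(variants, db1, db2) {
  if (is.character(db1)) db1 <- read_snp_vcf(db1)
  if (is.character(db2)) db2 <- read_snp_vcf(db2)
  key <- c("contig", "pos", "ref", "alt")
  in1 <- !is.na(vctrs_match(variants[key], db1[key]))
  in2 <- !is.na(vctrs_match(variants[key], db2[key]))
  variants %>%
    mutate(db_status = dplyr::case_when(
      in1 & in2 ~ "both",
      in1 ~ "db1_only",
      in2 ~ "db2_only",
      TRUE ~ "novel"
    ))
}

# row-wise match of two keyed data frames
vctrs_match <- function(x, table) {
  match(
    do.call(paste, c(x, sep = "\r")),
    do.call(paste, c(table, sep = "\r"))
  )
}

#' Database-status summary with percentages
#'
#' @param variants Variant tibble carrying `db_status`.
#' @return Tibble with `db_status`, `n`, `pct` (percentages of the total,
#'   via [percentage()]).
#' @export
db_summary <- function(variants) {
  variants %>%
    count(.data$db_status) %>%
    mutate(pct = percentage(.data$n, sum(.data$n)))
}

# CDS models from an annotation: one entry per transcript with ordered
# features, total length, spliced sequence and a genomic-position index
.cds_models <- function(annotation, genome) {
  cds <- annotation %>%
    filter(.data$feature == "CDS") %>%
    arrange(.data$transcript_id, .data$start)
  if (nrow(cds) == 0) {
    return(list())
  }
  split(cds, cds$transcript_id) %>%
    purrr::imap(function(d, tx) {
      len <- sum(d$end - d$start + 1L)
      frame_ok <- len %% 3L == 0L
      if (!frame_ok) {
        warn(sprintf("CDS length of %s not divisible by 3; effects marked NA", tx))
      }
      plus_pos <- unlist(map2(d$start, d$end, seq)) # ascending genomic
      seq_plus <- paste(
        vapply(seq_len(nrow(d)), function(i) {
          as.character(Biostrings::subseq(genome[[d$contig[i]]], d$start[i], d$end[i]))
        }, character(1)),
        collapse = ""
      )
      strand <- d$strand[1]
      cds_seq <- if (strand == "+") {
        seq_plus
      } else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_plus)))
      }
      list(
        transcript_id = tx, contig = d$contig[1], strand = strand,
        len = len, frame_ok = frame_ok,
        plus_pos = plus_pos, cds_seq = cds_seq,
        gr = GenomicRanges::GRanges(d$contig, IRanges::IRanges(d$start, d$end))
      )
    })
}

.GENETIC_CODE <- Biostrings::GENETIC_CODE

#' Annotate coding effects of variants
#'
#' For a substitution inside an annotated coding sequence the affected codon
#' is rebuilt strand-aware, the alternate base substituted and both codons
#' translated: the effect is `synonymous` iff the amino acid is unchanged.
#' Indels inside a CDS are `non_synonymous`. Variants outside every CDS but
#' within an exonic cluster footprint are `non_coding` with location
#' `exonic_UC`; all remaining variants have location `other` and effect
#' `NA`. When a variant falls in several transcripts' CDS, the
#' lexicographically first transcript is used (recorded in
#' `cds_transcript`).
#'
#' @param variants Merged variant tibble.
#' @param annotation Reference annotation tibble with CDS features.
#' @param genome A [Biostrings::DNAStringSet].
#' @param exonic Optional exonic interval tibble (`contig`, `start`, `end`),
#'   e.g. a cluster footprint, defining the `exonic_UC` location class.
#' @return `variants` with `location`, `effect`, `cds_transcript`,
#'   `cds_pos`, `aa_ref`, `aa_alt` columns.
#' @export
annotate_effects <- function(variants, annotation, genome, exonic = NULL) {
  models <- .cds_models(annotation, genome)
  v_gr <- GenomicRanges::GRanges(
    variants$contig, IRanges::IRanges(variants$pos, variants$pos)
  )
  n <- nrow(variants)
  location <- rep("other", n)
  effect <- rep(NA_character_, n)
  cds_tx <- rep(NA_character_, n)
  cds_pos <- rep(NA_integer_, n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)

  if (length(models) > 0) {
    all_cds <- suppressWarnings(do.call(
      c, unname(map(models, `[[`, "gr"))
    ))
    model_of <- rep(names(models), vapply(models, function(m) length(m$gr), integer(1)))
    hits <- GenomicRanges::findOverlaps(v_gr, all_cds, ignore.strand = TRUE)
    hit_tbl <- tibble(
      vi = S4Vectors::queryHits(hits),
      tx = model_of[S4Vectors::subjectHits(hits)]
    ) %>%
      arrange(.data$vi, .data$tx) %>%
      distinct(.data$vi, .keep_all = TRUE)
    for (r in seq_len(nrow(hit_tbl))) {
      i <- hit_tbl$vi[r]
      m <- models[[hit_tbl$tx[r]]]
      location[i] <- "exonic_UC"
      cds_tx[i] <- m$transcript_id
      if (!m$frame_ok) next
      if (variants$type[i] == "INDEL") {
        effect[i] <- "non_synonymous"
        next
      }
      pi <- match(variants$pos[i], m$plus_pos)
      ci <- if (m$strand == "+") pi else m$len - pi + 1L
      cds_pos[i] <- ci
      codon_i <- (ci - 1L) %/% 3L
      codon <- substr(m$cds_seq, 3L * codon_i + 1L, 3L * codon_i + 3L)
      within <- ci - 3L * codon_i
      alt_base <- variants$alt[i]
      if (m$strand == "-") alt_base <- chartr("ACGT", "TGCA", alt_base)
      codon_alt <- codon
      substr(codon_alt, within, within) <- alt_base
      aa_ref[i] <- .GENETIC_CODE[[codon]]
      aa_alt[i] <- .GENETIC_CODE[[codon_alt]]
      effect[i] <- if (aa_ref[i] == aa_alt[i]) "synonymous" else "non_synonymous"
    }
  }

  # outside any CDS but inside an exonic footprint -> non-coding exonic
  if (!is.null(exonic) && nrow(exonic) > 0) {
    ex_gr <- GenomicRanges::GRanges(
      exonic$contig, IRanges::IRanges(exonic$start, exonic$end)
    )
    in_ex <- IRanges::overlapsAny(v_gr, ex_gr, ignore.strand = TRUE)
    sel <- in_ex & location == "other"
    location[sel] <- "exonic_UC"
    effect[sel] <- "non_coding"
  }

  variants %>%
    mutate(
      location = location, effect = effect, cds_transcript = cds_tx,
      cds_pos = cds_pos, aa_ref = aa_ref, aa_alt = aa_alt
    )
}

#' Rank transcripts by non-synonymous variant load
#'
#' Counts non-synonymous variants per coding transcript and reports those
#' with at least `min_nonsyn` (boundary inclusive), together with a
#' per-animal site profile (each variant's CDS-relative position and effect
#' class per carrying animal) for the reported transcripts.
#'
#' @param variants Effect-annotated merged variant tibble (needs
#'   `cds_transcript`, `effect`, `horses`).
#' @param min_nonsyn Minimum non-synonymous count (default 10).
#' @return A list with `ranking` (transcript, `n_nonsyn`, `n_syn`,
#'   descending) and `profiles` (long per-animal site table).
#' @export
variant_density <- function(variants, min_nonsyn = 10) {
  coding <- variants %>% filter(!is.na(.data$cds_transcript))
  ranking <- coding %>%
    group_by(transcript_id = .data$cds_transcript) %>%
    summarise(
      n_nonsyn = sum(.data$effect == "non_synonymous", na.rm = TRUE),
      n_syn = sum(.data$effect == "synonymous", na.rm = TRUE),
      .groups = "drop"
    ) %>%
    filter(.data$n_nonsyn >= min_nonsyn) %>%
    arrange(dplyr::desc(.data$n_nonsyn), .data$transcript_id)
  profiles <- coding %>%
    semi_join(ranking, by = c(cds_transcript = "transcript_id")) %>%
    select(
      transcript_id = "cds_transcript", "contig", "pos", "cds_pos",
      "effect", "horses"
    ) %>%
    mutate(horse = strsplit(.data$horses, ",", fixed = TRUE)) %>%
    select(-"horses") %>%
    unnest("horse") %>%
    arrange(.data$transcript_id, .data$cds_pos, .data$horse)
  list(ranking = ranking, profiles = profiles)
}
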