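# Readers and writers for the standard formats the pipeline touches.
# GTF goes through rtracklayer, FASTA through Biostrings, VCF reading through
# vcfR; coordinates are 1-based inclusive throughout (GTF/VCF native).

#' Read per-sample transcript models from a GTF file
#'
#' @param file Path to a GTF file with `exon` features carrying `gene_id` and
#'   `transcript_id` attributes (Cufflinks-style transcript models).
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble of exons: `sample_id`, `gene_id`, `transcript_id`,
#'   `contig`, `strand`, `start`, `end` (one row per exon).
#' @export
read_transcript_gtf <- function(file, sample_id) {
  gr <- rtracklayer::import(file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tibble(
    sample_id = sample_id,
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Write transcript models to GTF
#'
#' @param exons Exon tibble (`gene_id`, `transcript_id`, `contig`, `strand`,
#'   `start`, `end`; a `sample_id` column is ignored).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_transcript_gtf <- function(exons, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$contig,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand,
    type = "exon",
    source = "exertome",
    gene_id = exons$gene_id,
    transcript_id = exons$transcript_id
  )
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read a reference annotation (exon + CDS features) from GTF
#'
#' @param file Path to a GTF file.
#' @return A tibble with `feature` (`"exon"` or `"CDS"`), `gene_id`,
#'   `transcript_id`, `contig`, `strand`, `start`, `end`, `frame` (CDS phase,
#'   `NA` for exons).
#' @export
read_annotation_gtf <- function(file) {
  gr <- rtracklayer::import(file, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  phase <- if ("phase" %in% names(S4Vectors::mcols(gr))) {
    as.integer(gr$phase)
  } else {
    rep(NA_integer_, length(gr))
  }
  tibble(
    feature = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    frame = ifelse(as.character(gr$type) == "CDS", phase, NA_integer_)
  )
}

#' Write a reference annotation (exon + CDS features) to GTF
#'
#' @param annotation Annotation tibble as returned by [read_annotation_gtf()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$feature,
    source = "exertome",
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    phase = annotation$frame
  )
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read a genome FASTA into a DNAStringSet
#'
#' @param file Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_genome_fasta <- function(file) {
  Biostrings::readDNAStringSet(file)
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_genome_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome, file)
  invisible(file)
}

#' Read a SNP database VCF into a site table
#'
#' Multi-allelic records are decomposed into one row per alternate allele.
#'
#' @param file Path to a VCF file.
#' @return A tibble with `contig`, `pos`, `ref`, `alt`.
#' @export
read_snp_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      contig = character(), pos = integer(),
      ref = character(), alt = character()
    ))
  }
  tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  ) %>%
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) %>%
    unnest("alt") %>%
    distinct()
}

#' Write variants to a VCF 4.2 file
#'
#' Emits a minimal site-only VCF. If the variant table carries `db_status`,
#' `effect`, `location` or `horses` columns they are written as INFO keys
#' (`DB`, `EFF`, `LOC`, `CARRIERS`).
#'
#' @param variants Tibble with `contig`, `pos`, `ref`, `alt` and optional
#'   annotation columns.
#' @param file Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `file`, invisibly.
#' @export
write_variants_vcf <- function(variants, file, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=exertome",
    if (!is.null(contig_lengths)) {
      sprintf(
        "##contig=<ID=%s,length=%d>",
        names(contig_lengths), as.integer(contig_lengths)
      )
    },
    "##INFO=<ID=DB,Number=1,Type=String,Description=\"Database status: novel, db1_only, db2_only or both\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect: synonymous, non_synonymous, non_coding or NA\">",
    "##INFO=<ID=LOC,Number=1,Type=String,Description=\"Location class: exonic_UC or other\">",
    "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Comma-separated carrier animals\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info_field <- function(key, col) {
    if (is.null(variants[[col]])) NULL else paste0(key, "=", variants[[col]])
  }
  parts <- list(
    info_field("DB", "db_status"),
    info_field("EFF", "effect"),
    info_field("LOC", "location"),
    info_field("CARRIERS", "horses")
  )
  parts <- parts[!vapply(parts, is.null, logical(1))]
  info <- if (length(parts) == 0) {
    rep(".", nrow(variants))
  } else {
    do.call(paste, c(parts, sep = ";"))
  }
  # indel tokens: "+SEQ" inserts SEQ after the anchor base, "-SEQ" deletes
  # SEQ following it; converted to anchored REF/ALT alleles
  ref <- variants$ref
  alt <- variants$alt
  ins <- startsWith(alt, "+")
  del <- startsWith(alt, "-")
  alt[ins] <- paste0(ref[ins], substring(alt[ins], 2))
  ref[del] <- paste0(variants$ref[del], substring(variants$alt[del], 2))
  alt[del] <- variants$ref[del]
  ord <- order(variants$contig, variants$pos, ref, alt)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
    variants$contig[ord], variants$pos[ord], ref[ord], alt[ord], info[ord]
  )
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read per-sample site observations from TSV
#'
#' @param file Path to a tab-separated table with columns `sample_id`,
#'   `contig`, `pos`, `ref`, `A`, `C`, `G`, `T`, `indel`, `indel_allele`.
#' @return The observation tibble.
#' @export
read_sites_tsv <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    sample_id = readr::col_character(),
    contig = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    A = readr::col_integer(),
    C = readr::col_integer(),
    G = readr::col_integer(),
    T = readr::col_integer(),
    indel = readr::col_integer(),
    indel_allele = readr::col_character()
  ))
}

#' Read a counts matrix TSV into long format
#'
#' @param file Tab-separated table: first column `feature_id`, one column per
#'   sample.
#' @return A long tibble with `feature_id`, `sample_id`, `count`.
#' @export
read_counts_tsv <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()
  )) %>%
    pivot_longer(-"feature_id", names_to = "sample_id", values_to = "count")
}

#' Write a long counts/FPKM table as a wide TSV
#'
#' @param x Long tibble with `feature_id`, `sample_id` and one value column.
#' @param file Output path.
#' @param value Name of the value column (default `"count"`).
#' @return `file`, invisibly.
#' @export
write_matrix_tsv <- function(x, file, value = "count") {
  x %>%
    pivot_wider(
      id_cols = "feature_id", names_from = "sample_id",
      values_from = dplyr::all_of(value)
    ) %>%
    arrange(.data$feature_id) %>%
    readr::write_tsv(file)
  invisible(file)
}
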