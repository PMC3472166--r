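# End-to-end orchestration: one configuration drives clustering, variant
# discovery, expression/DEG calling and switch detection on a corpus laid
# out as written by write_study(), and a consistency report reproduces
# arithmetic relations between printed counts.

#' Build a pipeline configuration
#'
#' Flat named list of every stage parameter with its documented default;
#' round-trips through YAML via [read_config()]/[write_config()].
#'
#' @param input_dir Directory with the corpus (layout of [write_study()]).
#' @param output_dir Output directory.
#' @param ... Overrides of the defaults (unknown names error).
#' @return A named list of class `exertome_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, ...) {
  cfg <- list(
    input_dir = input_dir,
    output_dir = output_dir,
    min_orf_nt = 300, # ORF length filter on novel clusters (nt)
    min_fpkm_expressed = 0, # expression evidence threshold
    min_depth = 4, # variant depth gate
    min_alt_reads = 2, # variant alternate-read gate
    min_alt_fraction = 0.2, # variant allele-fraction gate
    hom_fraction = 0.8, # het/hom genotype boundary
    window_bp = 10, # junction misalignment window
    min_nonsyn = 10, # density report threshold
    fold_threshold = 2, # DEG fold threshold (strict)
    min_horses = 4, # DEG / switch voting quorum
    pseudocount = 0.1, # FPKM pseudocount for folds
    switch_min_fpkm = 1, # dominant-isoform FPKM floor
    switch_min_ratio = 1 # dominance ratio
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("exertome_config", "list"))
}

#' @rdname pipeline_config
#' @param file YAML file path.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(pipeline_config, y)
}

#' @rdname pipeline_config
#' @param config An `exertome_config`.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

.validate_config <- function(config, samples) {
  n_horses <- n_distinct(samples$horse)
  if (config$min_horses > n_horses) {
    abort(sprintf(
      "min_horses (%d) exceeds the %d animals in the sample sheet",
      config$min_horses, n_horses
    ))
  }
  if (config$min_orf_nt < 3) abort("min_orf_nt must be >= 3")
  if (config$window_bp < 0) abort("window_bp must be >= 0")
  if (config$fold_threshold <= 1) abort("fold_threshold must be > 1")
  invisible(config)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Reads the corpus from `config$input_dir`, runs unigene clustering,
#' variant discovery, expression/DEG calling and isoform switch detection,
#' writes all tabular outputs plus a `summary.json` into
#' `config$output_dir`, and returns the result objects. Deterministic: the
#' same inputs and configuration give byte-identical summaries.
#'
#' @param config An `exertome_config` (or path to a YAML config file).
#' @return Invisibly, a list with `ucs`, `expressed`, `venn`, `orf`,
#'   `variants`, `density`, `degs`, `switches`, `fpkm`, `summary` and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  ind <- config$input_dir
  samples <- validate_samples(
    readr::read_csv(file.path(ind, "sample_sheet.csv"),
      col_types = readr::cols(.default = readr::col_character())
    ),
    complete = TRUE
  )
  .validate_config(config, samples)
  outd <- config$output_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)

  inputs <- .stage("load", {
    list(
      genome = read_genome_fasta(file.path(ind, "genome.fa")),
      annotation = read_annotation_gtf(file.path(ind, "reference.gtf")),
      sample_exons = bind_rows(lapply(samples$sample_id, function(sid) {
        read_transcript_gtf(file.path(ind, "samples", paste0(sid, ".gtf")), sid)
      })),
      gene_counts = read_counts_tsv(file.path(ind, "counts_gene.tsv")),
      tx_counts = read_counts_tsv(file.path(ind, "counts_transcript.tsv")),
      gene_lengths = readr::read_tsv(file.path(ind, "lengths_gene.tsv"),
        col_types = "ci"
      ),
      tx_lengths = readr::read_tsv(file.path(ind, "lengths_transcript.tsv"),
        col_types = "ci"
      ),
      gene_map = readr::read_tsv(file.path(ind, "gene_map.tsv"),
        col_types = "cc"
      ),
      observations = read_sites_tsv(file.path(ind, "sites.tsv")),
      db1 = read_snp_vcf(file.path(ind, "db1.vcf")),
      db2 = read_snp_vcf(file.path(ind, "db2.vcf"))
    )
  })

  ## -- unigene clusters ----------------------------------------------------
  uc_res <- .stage("uc_builder", {
    ucs <- cluster_transcripts(inputs$sample_exons) %>%
      classify_clusters(inputs$annotation)
    novel_ids <- ucs$clusters$uc_id[ucs$clusters$status == "novel"]
    orf <- if (length(novel_ids) > 0) {
      orf_filter(
        uc_footprint_seqs(ucs, inputs$genome, novel_ids),
        min_orf_nt = config$min_orf_nt
      )
    } else {
      tibble(id = character(), max_orf_nt = integer(), kept = logical())
    }
    list(ucs = ucs, orf = orf)
  })
  ucs <- uc_res$ucs

  ## -- expression ----------------------------------------------------------
  expr_res <- .stage("expression_deg", {
    gene_fpkm <- compute_fpkm(inputs$gene_counts, inputs$gene_lengths)
    # gene -> cluster status (a gene inherits its cluster's novelty)
    gene_status <- ucs$members %>%
      distinct(.data$uc_id, .data$gene_id) %>%
      left_join(
        ucs$clusters %>% select("uc_id", "status"),
        by = "uc_id"
      ) %>%
      distinct(feature_id = .data$gene_id, .data$status)
    # cluster-level counts: sum of member gene counts
    uc_genes <- ucs$members %>% distinct(.data$uc_id, .data$gene_id)
    uc_counts <- uc_genes %>%
      inner_join(inputs$gene_counts, by = c(gene_id = "feature_id")) %>%
      group_by(feature_id = .data$uc_id, .data$sample_id) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    uc_fpkm <- compute_fpkm(
      uc_counts,
      ucs$clusters %>% select(feature_id = "uc_id", length = "footprint_length"),
      totals = inputs$gene_counts %>%
        group_by(.data$sample_id) %>%
        summarise(total = sum(.data$count), .groups = "drop")
    )
    expressed <- tissue_expressed(uc_fpkm, samples, config$min_fpkm_expressed)
    venn <- uc_venn(ucs$clusters, expressed)
    degs <- call_degs(
      gene_fpkm, samples,
      fold_threshold = config$fold_threshold,
      min_horses = config$min_horses,
      pseudocount = config$pseudocount,
      uc_status = gene_status
    )
    list(
      gene_fpkm = gene_fpkm, uc_fpkm = uc_fpkm, expressed = expressed,
      venn = venn, degs = degs,
      corr = sample_correlation(gene_fpkm),
      quartiles = expression_quantiles(uc_fpkm)
    )
  })

  ## -- variants ------------------------------------------------------------
  var_res <- .stage("variant_caller", {
    boundaries <- exon_boundaries(bind_rows(
      inputs$annotation %>%
        filter(.data$feature == "exon") %>%
        select("contig", "start", "end"),
      ucs$footprint %>% select("contig", "start", "end")
    ))
    calls <- call_variants(
      inputs$observations,
      min_depth = config$min_depth,
      min_alt_reads = config$min_alt_reads,
      min_alt_fraction = config$min_alt_fraction,
      hom_fraction = config$hom_fraction
    ) %>%
      junction_filter(boundaries, config$window_bp)
    merged <- merge_variants(calls, samples) %>%
      compare_to_databases(inputs$db1, inputs$db2) %>%
      annotate_effects(
        inputs$annotation, inputs$genome,
        exonic = ucs$footprint %>% select("contig", "start", "end")
      )
    list(
      calls = calls, merged = merged,
      density = variant_density(merged, config$min_nonsyn)
    )
  })

  ## -- isoform switches ----------------------------------------------------
  switch_res <- .stage("isoform_switch", {
    tx_fpkm <- compute_fpkm(
      inputs$tx_counts, inputs$tx_lengths,
      totals = inputs$tx_counts %>%
        group_by(.data$sample_id) %>%
        summarise(total = sum(.data$count), .groups = "drop")
    )
    detect_switches(
      tx_fpkm, inputs$gene_map, samples,
      min_horses = config$min_horses,
      min_fpkm = config$switch_min_fpkm,
      min_ratio = config$switch_min_ratio
    )
  })

  summary <- .pipeline_summary(ucs, uc_res$orf, expr_res, var_res, switch_res)

  ## -- outputs -------------------------------------------------------------
  paths <- .stage("write", {
    clen <- setNames(
      Biostrings::width(inputs$genome), names(inputs$genome)
    )
    uc_table <- ucs$clusters %>%
      left_join(expr_res$expressed, by = c(uc_id = "feature_id")) %>%
      rename(expressed_blood = "blood", expressed_muscle = "muscle") %>%
      left_join(uc_res$orf %>% select(uc_id = "id", orf_kept = "kept"),
        by = "uc_id"
      )
    p <- list(
      uc_gtf = file.path(outd, "uc_models.gtf"),
      uc_table = file.path(outd, "uc_table.tsv"),
      fpkm = file.path(outd, "fpkm_gene.tsv"),
      correlation = file.path(outd, "sample_correlation.tsv"),
      degs = file.path(outd, "degs.tsv"),
      variants = file.path(outd, "variants.vcf"),
      density = file.path(outd, "nonsyn_density.tsv"),
      switches = file.path(outd, "switch_events.tsv"),
      switch_profiles = file.path(outd, "switch_profiles.tsv"),
      summary = file.path(outd, "summary.json")
    )
    write_uc_gtf(ucs, p$uc_gtf)
    readr::write_tsv(uc_table, p$uc_table)
    write_matrix_tsv(expr_res$gene_fpkm, p$fpkm, value = "fpkm")
    readr::write_tsv(expr_res$corr, p$correlation)
    readr::write_tsv(tidy(expr_res$degs), p$degs)
    write_variants_vcf(var_res$merged, p$variants, contig_lengths = clen)
    readr::write_tsv(var_res$density$ranking, p$density)
    readr::write_tsv(tidy(switch_res), p$switches)
    readr::write_tsv(switch_res$profiles, p$switch_profiles)
    jsonlite::write_json(summary, p$summary,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    p
  })

  invisible(list(
    ucs = ucs, orf = uc_res$orf,
    fpkm = expr_res$gene_fpkm, uc_fpkm = expr_res$uc_fpkm,
    expressed = expr_res$expressed, venn = expr_res$venn,
    correlation = expr_res$corr, quartiles = expr_res$quartiles,
    degs = expr_res$degs,
    calls = var_res$calls, variants = var_res$merged,
    density = var_res$density,
    switches = switch_res,
    summary = summary, paths = paths
  ))
}

# every count and percentage the pipeline reports; percentages are always
# percentage() of the printed numerator and denominator
.pipeline_summary <- function(ucs, orf, expr_res, var_res, switch_res) {
  cl <- ucs$clusters
  n_uc <- nrow(cl)
  n_ann <- sum(cl$status == "annotated")
  n_nov <- sum(cl$status == "novel")
  merged <- var_res$merged
  n_var <- nrow(merged)
  n_snp <- sum(merged$type == "SNP")
  n_indel <- sum(merged$type == "INDEL")
  n_exonic <- sum(merged$location == "exonic_UC")
  n_nonsyn <- sum(merged$effect == "non_synonymous", na.rm = TRUE)
  dg <- glance(expr_res$degs)
  db <- merged %>% count(.data$db_status)
  db_n <- function(s) sum(db$n[db$db_status == s])
  ex <- expr_res$expressed
  venn <- setNames(expr_res$venn$n, expr_res$venn$region)
  list(
    uc = list(
      n_clusters = n_uc,
      n_annotated = n_ann,
      pct_annotated = percentage(n_ann, n_uc),
      n_novel = n_nov,
      pct_novel = percentage(n_nov, n_uc),
      total_footprint_bp = sum(cl$footprint_length),
      n_novel_orf_kept = sum(orf$kept),
      expressed_blood = sum(ex$blood),
      expressed_muscle = sum(ex$muscle),
      venn = as.list(venn)
    ),
    variants = list(
      n_total = n_var,
      n_snp = n_snp,
      n_indel = n_indel,
      n_individual_specific = sum(merged$individual_specific),
      n_in_both_databases = db_n("both"),
      pct_in_both_databases = if (n_var > 0) percentage(db_n("both"), n_var) else NA,
      n_novel = db_n("novel"),
      pct_novel = if (n_var > 0) percentage(db_n("novel"), n_var) else NA,
      n_exonic = n_exonic,
      pct_exonic = if (n_var > 0) percentage(n_exonic, n_var) else NA,
      n_non_synonymous = n_nonsyn,
      pct_non_synonymous = if (n_exonic > 0) percentage(n_nonsyn, n_exonic) else NA,
      n_high_density_transcripts = nrow(var_res$density$ranking)
    ),
    expression = list(
      fpkm_q25 = expr_res$quartiles$q25,
      fpkm_median = expr_res$quartiles$median,
      fpkm_q75 = expr_res$quartiles$q75,
      deg = as.list(dg)
    ),
    switches = list(
      n_events = nrow(switch_res$events),
      blood = sum(switch_res$events$tissue == "blood"),
      muscle = sum(switch_res$events$tissue == "muscle")
    )
  )
}

#' Arithmetic consistency report over a table of printed counts
#'
#' A pure function: given named counts, emits the requested sums and
#' percentages (via [percentage()]), so that a set of published counts can
#' be checked for internal consistency.
#'
#' @param counts Named numeric vector or list of counts.
#' @param sums Named list; each element is a character vector of count
#'   names to add.
#' @param percentages Named list; each element is `c(part, total)` count
#'   names.
#' @return A tibble with `name` and `value` (sums first, then percentages).
#' @examples
#' consistency_report(
#'   c(snp = 182722, indel = 7251, in_both = 7316),
#'   sums = list(total_snv = c("snp", "indel")),
#'   percentages = list(pct_in_both = c("in_both", "snp"))
#' )
#' @export
consistency_report <- function(counts, sums = list(), percentages = list()) {
  counts <- unlist(counts)
  need <- unique(c(unlist(sums), unlist(percentages)))
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("missing named count(s): ", paste(miss, collapse = ", ")))
  }
  s <- purrr::imap(sums, function(parts, nm) {
    tibble(name = nm, value = sum(counts[parts]))
  })
  p <- purrr::imap(percentages, function(pt, nm) {
    tibble(name = nm, value = percentage(counts[[pt[1]]], counts[[pt[2]]]))
  })
  bind_rows(bind_rows(s), bind_rows(p))
}
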