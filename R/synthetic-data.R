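# Synthetic study generator: a self-contained toy corpus (genome, annotation,
# 24 samples, SNP databases) with complete ground-truth tables, emulating a
# six-animal x {blood, muscle} x {before, after} paired exercise design.
# Every downstream stage of the pipeline is testable against these truths.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.CODONS <- {
  g <- expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}
.CODONS_NONSTOP <- setdiff(.CODONS, .STOPS)

.random_dna <- function(n) sample(.BASES, n, replace = TRUE)

.sub_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483587)

#' Define the paired two-tissue study design
#'
#' @param horses Character vector of animal identifiers (default six).
#' @param seed Integer seed recorded with the design; all generator output is
#'   a deterministic function of it.
#' @return An object of class `study_design`: a list with `samples` (the
#'   24-row sample sheet), `horses`, `tissues`, `timepoints` and `seed`.
#' @export
sim_design <- function(horses = sprintf("H%d", 1:6), seed = 1) {
  tissues <- c("blood", "muscle")
  timepoints <- c("before", "after")
  samples <- crossing(
    horse = horses, tissue = tissues, timepoint = timepoints
  ) %>%
    mutate(
      sample_id = paste(.data$horse, .data$tissue, .data$timepoint, sep = "_")
    ) %>%
    select("sample_id", "horse", "tissue", "timepoint") %>%
    arrange(.data$sample_id)
  structure(
    list(
      samples = samples, horses = horses, tissues = tissues,
      timepoints = timepoints, seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# one gene structure: exon layout, transcripts, contiguous CDS in the
# largest exon of the primary transcript
.sim_gene_structure <- function() {
  n_ex <- sample(2:8, 1)
  ex_len <- sample(80:400, n_ex, replace = TRUE)
  introns <- if (n_ex > 1) sample(50:500, n_ex - 1, replace = TRUE) else integer()
  rel_start <- cumsum(c(1L, head(ex_len, -1) + introns))
  rel_end <- rel_start + ex_len - 1L
  span <- rel_end[n_ex]
  strand <- sample(.strand_levels, 1)

  # transcripts: primary keeps all exons, alternates drop one internal exon
  n_tx <- sample(1:3, 1)
  internal <- if (n_ex >= 3) seq(2L, n_ex - 1L) else integer()
  n_alt <- min(n_tx - 1L, length(internal))
  dropped <- if (n_alt > 0) sample(internal, n_alt) else integer()
  tx_exons <- c(
    list(seq_len(n_ex)),
    lapply(dropped, function(d) setdiff(seq_len(n_ex), d))
  )

  # CDS inside the largest exon: ATG + non-stop codons + stop
  big <- which.max(ex_len)
  max_codons <- floor((ex_len[big] - 6) / 3)
  n_codons <- sample(10:min(100, max_codons), 1)
  cds_nt <- 3L * n_codons
  cds_rel <- rel_start[big] + sample(0:(ex_len[big] - cds_nt), 1)
  cds_seq <- paste0(
    "ATG",
    paste(sample(.CODONS_NONSTOP, n_codons - 2L, replace = TRUE), collapse = ""),
    sample(.STOPS, 1)
  )
  list(
    n_ex = n_ex, rel_start = rel_start, rel_end = rel_end, span = span,
    strand = strand, tx_exons = tx_exons,
    cds_rel_start = cds_rel, cds_nt = cds_nt, cds_seq = cds_seq
  )
}

#' Generate a toy genome with a multi-transcript gene annotation
#'
#' Lays out non-overlapping gene loci on random-sequence contigs. Each gene
#' has 2-8 exons and 1-3 transcripts sharing one strand; the primary
#' transcript carries a contiguous coding sequence (starts ATG, ends with a
#' stop, length divisible by 3, no internal stops) planted into the genome
#' sequence strand-aware.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (>= 50 kb).
#' @param n_genes Total number of genes (>= 2 per contig).
#' @param seed Integer seed.
#' @return A list with `genome` (a [Biostrings::DNAStringSet]), `annotation`
#'   (tibble of `exon`/`CDS` features, 1-based inclusive) and `genes`
#'   (tibble of gene-level metadata).
#' @export
sim_genome <- function(n_contigs = 2, contig_length = 200000L, n_genes = 40,
                       seed = 1) {
  if (contig_length < 50000) abort("contig_length must be >= 50 kb")
  if (n_genes < 2 * n_contigs) abort("need at least 2 genes per contig")
  set.seed(seed)
  contigs <- sprintf("ctg%d", seq_len(n_contigs))
  per_contig <- diff(floor(seq(0, n_genes, length.out = n_contigs + 1)))

  seqs <- list()
  ann <- list()
  genes <- list()
  gi <- 0L
  min_gap <- 200L
  for (ci in seq_len(n_contigs)) {
    k <- per_contig[ci]
    structs <- replicate(k, .sim_gene_structure(), simplify = FALSE)
    spans <- vapply(structs, `[[`, integer(1), "span")
    slack <- contig_length - sum(spans) - (k + 1L) * min_gap
    if (slack < 0) {
      abort(sprintf(
        "gene loci (%d bp + gaps) do not fit contig of %d bp",
        sum(spans), contig_length
      ))
    }
    gaps <- min_gap + as.integer(rmultinom(1, slack, rep(1, k + 1L)))
    # locus start offsets (0-based): leading gaps plus preceding spans
    offsets <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, spans[-k]))
    contig_seq <- .random_dna(contig_length)

    for (j in seq_len(k)) {
      gi <- gi + 1L
      st <- structs[[j]]
      gene_id <- sprintf("G%04d", gi)
      gstart <- offsets[j] # 0-based offset; rel coords are 1-based
      abs_start <- gstart + st$rel_start
      abs_end <- gstart + st$rel_end
      cds_start <- gstart + st$cds_rel_start
      cds_end <- cds_start + st$cds_nt - 1L
      planted <- strsplit(st$cds_seq, "")[[1]]
      if (st$strand == "-") {
        planted <- rev(chartr("ACGT", "TGCA", planted))
      }
      contig_seq[cds_start:cds_end] <- planted

      tx_ids <- sprintf("%s.t%d", gene_id, seq_along(st$tx_exons))
      ex_rows <- purrr::imap(st$tx_exons, function(idx, ti) {
        tibble(
          feature = "exon", gene_id = gene_id, transcript_id = tx_ids[ti],
          contig = contigs[ci], strand = st$strand,
          start = abs_start[idx], end = abs_end[idx], frame = NA_integer_
        )
      })
      cds_row <- tibble(
        feature = "CDS", gene_id = gene_id, transcript_id = tx_ids[1],
        contig = contigs[ci], strand = st$strand,
        start = cds_start, end = cds_end, frame = 0L
      )
      ann[[gi]] <- bind_rows(ex_rows, cds_row)
      genes[[gi]] <- tibble(
        gene_id = gene_id, contig = contigs[ci], strand = st$strand,
        start = abs_start[1], end = abs_end[st$n_ex],
        n_exons = st$n_ex, n_transcripts = length(st$tx_exons),
        primary_transcript = tx_ids[1],
        cds_start = cds_start, cds_end = cds_end
      )
    }
    seqs[[ci]] <- paste(contig_seq, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(setNames(unlist(seqs), contigs))
  list(
    genome = genome,
    annotation = bind_rows(ann) %>%
      arrange(.data$contig, .data$start, .data$transcript_id, .data$feature),
    genes = bind_rows(genes)
  )
}

# mean-preserving multiplicative log-normal noise at coefficient of
# variation `cv`; cv = 0 returns the means unchanged (noiseless oracle limit)
.noisy_counts <- function(means, cv) {
  if (cv == 0) {
    return(round(means))
  }
  sdlog <- sqrt(log(1 + cv^2))
  round(means * rlnorm(length(means), meanlog = -sdlog^2 / 2, sdlog = sdlog))
}

#' Simulate a feature-by-sample count matrix with planted fold changes
#'
#' The count model is deliberately simple so tests have closed-form
#' expectations: each feature has a log-normal baseline mean; "after" samples
#' of affected animals in the affected tissue have that mean multiplied by
#' the planted effect; observed counts are the mean times mean-preserving
#' log-normal noise with coefficient of variation `cv`, rounded. `cv = 0`
#' gives exactly the means (noiseless oracle limit).
#'
#' @param samples Sample sheet (see [sim_design()]).
#' @param n_features Number of features.
#' @param n_deg Named integer vector of planted differentially expressed
#'   features per tissue and direction: `blood_up`, `blood_down`,
#'   `muscle_up`, `muscle_down`.
#' @param effect Fold-change multiplier for planted effects (> 0; upregulated
#'   features use `effect`, downregulated `1/effect`).
#' @param cv Log-normal coefficient of variation of count noise.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of feature
#'   baseline means (floored at 5 counts).
#' @param length_range Range of feature effective lengths (bp).
#' @param seed Integer seed.
#' @return A list with `counts` (long tibble: `feature_id`, `sample_id`,
#'   `count`), `lengths` (tibble: `feature_id`, `length`) and `deg_truth`
#'   (long tibble: `feature_id`, `tissue`, `direction`, `horse`,
#'   `multiplier`).
#' @export
sim_counts <- function(samples, n_features = 2000,
                       n_deg = c(
                         blood_up = 20, blood_down = 20,
                         muscle_up = 20, muscle_down = 20
                       ),
                       effect = 4, cv = 0.1,
                       baseline_meanlog = log(150), baseline_sdlog = 0.8,
                       length_range = c(500L, 3000L), seed = 1) {
  if (effect <= 0) abort("effect multiplier must be > 0")
  samples <- validate_samples(samples, complete = TRUE)
  set.seed(seed)
  features <- sprintf("F%05d", seq_len(n_features))
  baseline <- pmax(5, round(rlnorm(n_features, baseline_meanlog, baseline_sdlog)))
  lengths <- tibble(
    feature_id = features,
    length = sample(length_range[1]:length_range[2], n_features, replace = TRUE)
  )

  # planted effects: disjoint feature sets across the four tissue/direction slots
  slots <- crossing(tissue = c("blood", "muscle"), direction = c("up", "down")) %>%
    mutate(n = n_deg[paste(.data$tissue, .data$direction, sep = "_")])
  if (sum(slots$n) > n_features) abort("more planted effects than features")
  picked <- sample(features, sum(slots$n))
  slots$feature_ids <- split(
    picked,
    factor(rep(seq_len(nrow(slots)), slots$n), levels = seq_len(nrow(slots)))
  )
  deg_truth <- slots %>%
    select("tissue", "direction", "feature_ids") %>%
    unnest_longer_chr("feature_ids", "feature_id") %>%
    crossing(horse = unique(samples$horse)) %>%
    mutate(multiplier = if_else(.data$direction == "up", effect, 1 / effect)) %>%
    select("feature_id", "tissue", "direction", "horse", "multiplier") %>%
    arrange(.data$feature_id, .data$tissue, .data$horse)

  grid <- crossing(feature_id = features, samples) %>%
    mutate(mean = baseline[match(.data$feature_id, features)]) %>%
    left_join(
      deg_truth %>% select("feature_id", "tissue", "horse", "multiplier"),
      by = c("feature_id", "tissue", "horse")
    ) %>%
    mutate(
      mean = if_else(
        .data$timepoint == "after" & !is.na(.data$multiplier),
        .data$mean * .data$multiplier, .data$mean
      ),
      count = .noisy_counts(.data$mean, cv)
    )
  counts <- grid %>%
    select("feature_id", "sample_id", "count") %>%
    arrange(.data$feature_id, .data$sample_id)
  list(counts = counts, lengths = lengths, deg_truth = deg_truth)
}

# tidyr::unnest_longer with a fixed output name, kept dependency-light
unnest_longer_chr <- function(df, col, out) {
  df %>%
    mutate("{out}" := .data[[col]]) %>%
    select(-dplyr::all_of(col)) %>%
    unnest(dplyr::all_of(out))
}

#' Simulate per-sample site observations with planted genotypes and
#' junction-adjacent artifacts
#'
#' True variant sites are placed in exon interiors (more than
#' `window_bp + 2` bp from any exon boundary); artifact sites sit within
#' `window_bp` of an exon start or end and carry a spurious alternate allele
#' at a 20-40% fraction, mimicking spliced-read misalignment at exon-intron
#' boundaries. Depth is Poisson, base errors uniform across the other three
#' bases.
#'
#' @param samples Sample sheet.
#' @param exons Tibble of exon intervals (`contig`, `start`, `end`, optional
#'   `gene_id`) in which to place sites.
#' @param n_sites Number of true variant sites.
#' @param n_artifacts Number of junction-adjacent artifact sites.
#' @param depth_mean Poisson mean sequencing depth per site and sample.
#' @param error_rate Per-read base error probability.
#' @param window_bp Junction window defining artifact placement.
#' @param artifact_fraction Range of artifact allele fractions.
#' @param indel_fraction Fraction of true sites that are short indels.
#' @param carrier_map Optional tibble restricting which samples show each
#'   artifact allele, with columns `contig`, `sample_id` and either `pos` or
#'   an interval (`start`, `end`); default all samples.
#' @param genome Optional [Biostrings::DNAStringSet] supplying reference
#'   bases; random bases otherwise.
#' @param seed Integer seed.
#' @return A list with `observations` (per sample x site base counts),
#'   `genotype_truth` (per-animal genotypes at true sites), `site_truth`
#'   (site-level alleles) and `artifact_sites`.
#' @export
sim_sites <- function(samples, exons, n_sites = 300, n_artifacts = 60,
                      depth_mean = 30, error_rate = 0.01, window_bp = 10,
                      artifact_fraction = c(0.2, 0.4), indel_fraction = 0.1,
                      carrier_map = NULL, genome = NULL, seed = 1) {
  samples <- validate_samples(samples)
  set.seed(seed)
  horses <- unique(samples$horse)
  margin <- window_bp + 2L

  wide <- exons %>% filter(.data$end - .data$start + 1L > 2L * margin + 2L)
  if (nrow(wide) == 0) abort("no exon wide enough to place interior sites")
  interior <- wide %>%
    mutate(pos = map2(.data$start + margin + 1L, .data$end - margin - 1L, seq)) %>%
    select("contig", "pos") %>%
    unnest("pos") %>%
    distinct()
  if (nrow(interior) < n_sites) abort("too few interior positions for n_sites")
  truth_pos <- interior %>% slice(sample(n(), n_sites))

  near <- crossing(
    exons %>% select("contig", "start", "end") %>% distinct(),
    off = 0:window_bp, side = c("start", "end")
  ) %>%
    mutate(pos = if_else(.data$side == "start", .data$start + .data$off, .data$end - .data$off)) %>%
    select("contig", "pos") %>%
    distinct() %>%
    anti_join(truth_pos, by = c("contig", "pos"))
  if (nrow(near) < n_artifacts) abort("too few boundary positions for n_artifacts")
  art_pos <- near %>% slice(sample(n(), n_artifacts))

  ref_at <- function(df) {
    if (is.null(genome)) {
      sample(.BASES, nrow(df), replace = TRUE)
    } else {
      vapply(seq_len(nrow(df)), function(i) {
        as.character(Biostrings::subseq(
          genome[[df$contig[i]]], df$pos[i], df$pos[i]
        ))
      }, character(1))
    }
  }
  alt_for <- function(ref) {
    vapply(ref, function(r) sample(setdiff(.BASES, r), 1), character(1))
  }

  site_truth <- truth_pos %>%
    mutate(
      ref = ref_at(truth_pos),
      is_indel = runif(n()) < indel_fraction,
      alt = if_else(
        .data$is_indel,
        paste0(
          sample(c("+", "-"), n(), replace = TRUE),
          map_chr(sample(1:3, n(), replace = TRUE), function(k) {
            paste(sample(.BASES, k, replace = TRUE), collapse = "")
          })
        ),
        alt_for(.data$ref)
      ),
      type = if_else(.data$is_indel, "INDEL", "SNP")
    ) %>%
    select("contig", "pos", "ref", "alt", "type") %>%
    arrange(.data$contig, .data$pos)

  # carriers: skewed towards few animals so individual-specific variants exist
  n_carriers <- sample(seq_along(horses), n_sites,
    replace = TRUE,
    prob = c(0.35, 0.2, 0.15, 0.12, 0.1, 0.08)[seq_along(horses)]
  )
  genotype_truth <- site_truth %>%
    mutate(carrier_set = map(n_carriers, function(k) sample(horses, k))) %>%
    unnest_longer_chr("carrier_set", "horse") %>%
    mutate(genotype = sample(c("het", "hom"), n(), replace = TRUE, prob = c(0.7, 0.3))) %>%
    select("contig", "pos", "ref", "alt", "type", "horse", "genotype") %>%
    arrange(.data$contig, .data$pos, .data$horse)

  artifact_sites <- art_pos %>%
    mutate(
      ref = ref_at(art_pos),
      alt = alt_for(.data$ref),
      fraction = runif(n(), artifact_fraction[1], artifact_fraction[2])
    ) %>%
    arrange(.data$contig, .data$pos)

  # per sample x site expected alt fraction
  truth_grid <- crossing(site_truth, samples["sample_id"]) %>%
    left_join(samples[c("sample_id", "horse")], by = "sample_id") %>%
    left_join(
      genotype_truth %>% select("contig", "pos", "horse", "genotype"),
      by = c("contig", "pos", "horse")
    ) %>%
    mutate(p_alt = dplyr::case_when(
      is.na(.data$genotype) ~ 0,
      .data$genotype == "het" ~ 0.5,
      TRUE ~ 1
    ))
  art_grid <- crossing(
    artifact_sites %>% mutate(type = "ARTIFACT"),
    samples["sample_id"]
  ) %>%
    mutate(p_alt = .data$fraction) %>%
    select(-"fraction")
  if (!is.null(carrier_map)) {
    pos_map <- if ("pos" %in% names(carrier_map)) {
      carrier_map %>% select("contig", "pos", "sample_id")
    } else {
      art_grid %>%
        distinct(.data$contig, .data$pos) %>%
        inner_join(
          carrier_map,
          by = dplyr::join_by("contig", dplyr::between(x$pos, y$start, y$end))
        ) %>%
        select("contig", "pos", "sample_id") %>%
        distinct()
    }
    art_grid <- art_grid %>%
      left_join(
        pos_map %>% mutate(.carried = TRUE),
        by = c("contig", "pos", "sample_id")
      ) %>%
      mutate(p_alt = if_else(is.na(.data$.carried), 0, .data$p_alt)) %>%
      select(-".carried")
  }
  grid <- bind_rows(
    truth_grid %>% select("contig", "pos", "ref", "alt", "type", "sample_id", "p_alt"),
    art_grid %>% select("contig", "pos", "ref", "alt", "type", "sample_id", "p_alt")
  ) %>%
    arrange(.data$contig, .data$pos, .data$sample_id)

  n <- nrow(grid)
  depth <- rpois(n, depth_mean)
  alt_reads <- rbinom(n, depth, grid$p_alt)
  ref_reads <- depth - alt_reads

  # misreads: ref- and (substitution) alt-derived reads each err uniformly
  # into the three other bases
  counts <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, .BASES))
  is_indel <- grid$type == "INDEL"
  indel_count <- integer(n)
  indel_count[is_indel] <- alt_reads[is_indel]

  add_reads <- function(counts, source_base, n_reads) {
    err <- rbinom(length(n_reads), n_reads, error_rate)
    keep <- n_reads - err
    counts[cbind(seq_along(n_reads), match(source_base, .BASES))] <-
      counts[cbind(seq_along(n_reads), match(source_base, .BASES))] + keep
    idx <- which(err > 0)
    for (i in idx) {
      others <- setdiff(.BASES, source_base[i])
      spread <- as.integer(rmultinom(1, err[i], rep(1, 3)))
      counts[i, others] <- counts[i, others] + spread
    }
    counts
  }
  counts <- add_reads(counts, grid$ref, ref_reads)
  sub_alt <- !is_indel
  if (any(sub_alt)) {
    tmp <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, .BASES))
    tmp[sub_alt, ] <- add_reads(
      tmp[sub_alt, , drop = FALSE], grid$alt[sub_alt], alt_reads[sub_alt]
    )
    counts <- counts + tmp
  }

  observations <- grid %>%
    select("sample_id", "contig", "pos", "ref") %>%
    bind_cols(as_tibble(counts)) %>%
    mutate(
      indel = indel_count,
      indel_allele = if_else(is_indel, grid$alt, NA_character_)
    ) %>%
    arrange(.data$sample_id, .data$contig, .data$pos)

  list(
    observations = observations,
    genotype_truth = genotype_truth,
    site_truth = site_truth,
    artifact_sites = artifact_sites %>% select("contig", "pos", "ref", "alt", "fraction")
  )
}

#' Simulate two SNP database VCF tables from the planted genotypes
#'
#' Each database independently contains each true substitution site with the
#' stated probability, plus decoy sites absent from the truth.
#'
#' @param site_truth Site-level truth (from [sim_sites()]); only SNP rows are
#'   used (the emulated databases hold substitutions).
#' @param overlap_fractions Length-2 numeric in `[0, 1]`: per-database
#'   inclusion probability for each truth site.
#' @param n_extra Number of decoy sites per database.
#' @param contig_lengths Named vector of contig lengths (decoy placement).
#' @param genome Optional genome for decoy reference bases.
#' @param seed Integer seed.
#' @return A list with `db1` and `db2` (tibbles: `contig`, `pos`, `ref`,
#'   `alt`) and `membership` (truth sites with `in_db1`, `in_db2` flags).
#' @export
sim_snp_databases <- function(site_truth, overlap_fractions = c(0.2, 0.15),
                              n_extra = 300, contig_lengths, genome = NULL,
                              seed = 1) {
  if (any(overlap_fractions < 0 | overlap_fractions > 1)) {
    abort("overlap_fractions must lie in [0, 1]")
  }
  set.seed(seed)
  snps <- site_truth %>%
    filter(.data$type == "SNP") %>%
    distinct(.data$contig, .data$pos, .data$ref, .data$alt)
  membership <- snps %>%
    mutate(
      in_db1 = runif(n()) < overlap_fractions[1],
      in_db2 = runif(n()) < overlap_fractions[2]
    )
  decoys <- function() {
    d <- tibble(
      contig = sample(names(contig_lengths), n_extra, replace = TRUE)
    ) %>%
      mutate(pos = map_int(
        .data$contig,
        function(ct) sample.int(contig_lengths[[ct]], 1)
      )) %>%
      anti_join(snps, by = c("contig", "pos")) %>%
      distinct(.data$contig, .data$pos)
    d$ref <- if (is.null(genome)) {
      sample(.BASES, nrow(d), replace = TRUE)
    } else {
      vapply(seq_len(nrow(d)), function(i) {
        as.character(Biostrings::subseq(genome[[d$contig[i]]], d$pos[i], d$pos[i]))
      }, character(1))
    }
    d$alt <- vapply(d$ref, function(r) sample(setdiff(.BASES, r), 1), character(1))
    d
  }
  db1 <- bind_rows(
    membership %>% filter(.data$in_db1) %>% select("contig", "pos", "ref", "alt"),
    decoys()
  ) %>% arrange(.data$contig, .data$pos)
  db2 <- bind_rows(
    membership %>% filter(.data$in_db2) %>% select("contig", "pos", "ref", "alt"),
    decoys()
  ) %>% arrange(.data$contig, .data$pos)
  list(db1 = db1, db2 = db2, membership = membership)
}

#' Generate the full synthetic study corpus
#'
#' Composes [sim_genome()], per-sample transcript models, transcript- and
#' gene-level counts with planted fold changes and isoform switches,
#' [sim_sites()] and [sim_snp_databases()] into one deterministic corpus with
#' complete ground-truth tables. A fraction of gene loci is withheld from the
#' reference annotation, so their transcripts are genuinely novel (outside
#' every annotated footprint); each gene is expressed in blood, muscle or
#' both, and per-sample transcript GTF tables contain only the transcripts
#' expressed in that sample's tissue.
#'
#' @param seed Integer seed determining the entire corpus.
#' @param design A [sim_design()] object.
#' @param n_contigs,contig_length,n_genes Passed to [sim_genome()].
#' @param fraction_novel Fraction of gene loci excluded from the reference
#'   annotation.
#' @param tissue_profile_probs Probabilities that a gene is expressed in
#'   both tissues, blood only, muscle only.
#' @param n_deg Planted differentially expressed genes per tissue/direction
#'   (named: `blood_up`, `blood_down`, `muscle_up`, `muscle_down`).
#' @param effect Planted fold-change multiplier (> 0).
#' @param cv Count-noise coefficient of variation.
#' @param n_switch Named integer vector: planted isoform switches per tissue.
#' @param switch_ratio Dominance ratio between the two switching isoforms.
#' @param n_sites,n_artifacts,depth_mean,error_rate,window_bp,artifact_fraction,indel_fraction
#'   Passed to [sim_sites()].
#' @param db_overlap,db_extra Passed to [sim_snp_databases()].
#' @param baseline_meanlog,baseline_sdlog Gene baseline log-normal
#'   parameters.
#' @return An object of class `exertome_study`: a list with the genome,
#'   reference annotation, per-sample transcript exons, counts, site
#'   observations, SNP databases, sample sheet and a `truth` list
#'   (`deg`, `genotype`, `sites`, `artifacts`, `switch`, `novelty`).
#' @export
sim_study <- function(seed = 1, design = sim_design(seed = seed),
                      n_contigs = 3, contig_length = 200000L, n_genes = 120,
                      fraction_novel = 0.25,
                      tissue_profile_probs = c(both = 0.5, blood = 0.25, muscle = 0.25),
                      n_deg = c(
                        blood_up = 2, blood_down = 3,
                        muscle_up = 5, muscle_down = 3
                      ),
                      effect = 4, cv = 0.1,
                      n_switch = c(muscle = 3, blood = 1), switch_ratio = 5,
                      n_sites = 300, n_artifacts = 60, depth_mean = 30,
                      error_rate = 0.01, window_bp = 10,
                      artifact_fraction = c(0.2, 0.4), indel_fraction = 0.1,
                      db_overlap = c(0.2, 0.15), db_extra = 300,
                      baseline_meanlog = log(150), baseline_sdlog = 0.8) {
  if (effect <= 0) abort("effect multiplier must be > 0")
  samples <- design$samples
  g <- sim_genome(n_contigs, contig_length, n_genes, seed = .sub_seed(seed, 0))
  annotation_all <- g$annotation
  genes <- g$genes
  gene_map <- annotation_all %>%
    filter(.data$feature == "exon") %>%
    distinct(.data$gene_id, .data$transcript_id)

  set.seed(.sub_seed(seed, 1))
  # novelty: withheld loci are novel; the rest form the reference annotation
  novel_genes <- sample(genes$gene_id, round(fraction_novel * nrow(genes)))
  annotation <- annotation_all %>% filter(!.data$gene_id %in% novel_genes)
  novelty_truth <- gene_map %>%
    mutate(status = if_else(.data$gene_id %in% novel_genes, "novel", "annotated")) %>%
    arrange(.data$transcript_id)

  profile <- sample(names(tissue_profile_probs), nrow(genes),
    replace = TRUE, prob = tissue_profile_probs
  )
  genes$profile <- profile
  expressed_in <- function(tissue) {
    genes$gene_id[genes$profile %in% c("both", tissue)]
  }

  # per-sample transcript models: all transcripts of genes expressed in the
  # sample's tissue
  tx_exons <- annotation_all %>%
    filter(.data$feature == "exon") %>%
    select("gene_id", "transcript_id", "contig", "strand", "start", "end")
  sample_exons <- samples %>%
    mutate(gene_set = map(.data$tissue, expressed_in)) %>%
    select("sample_id", "gene_set") %>%
    mutate(ex = map(.data$gene_set, function(gs) filter(tx_exons, .data$gene_id %in% gs))) %>%
    select("sample_id", "ex") %>%
    unnest("ex") %>%
    arrange(.data$sample_id, .data$contig, .data$start, .data$transcript_id)

  # baselines and isoform weights (dominance-separated so only planted
  # switches can reverse isoform order under noise)
  set.seed(.sub_seed(seed, 2))
  genes$baseline <- pmax(5, round(rlnorm(nrow(genes), baseline_meanlog, baseline_sdlog)))
  iso <- gene_map %>%
    group_by(.data$gene_id) %>%
    mutate(weight = sample(2.5^(seq_len(n()) - 1))) %>%
    ungroup() %>%
    left_join(genes %>% select("gene_id", "baseline", "profile"), by = "gene_id") %>%
    mutate(tx_mean = pmax(2, round(.data$baseline * .data$weight / 4)))

  # planted DEGs: per tissue/direction, disjoint from switch genes
  multi_iso <- genes %>% filter(.data$n_transcripts >= 2)
  switch_truth <- purrr::imap(n_switch, function(k, tis) {
    pool <- multi_iso %>% filter(.data$profile %in% c("both", tis))
    picked <- sample(pool$gene_id, k)
    tibble(gene_id = picked, tissue = tis)
  }) %>% bind_rows()
  used <- character()
  deg_truth <- purrr::imap(n_deg, function(k, slot) {
    parts <- strsplit(slot, "_")[[1]]
    tis <- parts[1]
    dir <- parts[2]
    pool <- setdiff(expressed_in(tis), c(switch_truth$gene_id, used))
    picked <- sample(pool, k)
    used <<- c(used, picked)
    crossing(feature_id = picked, horse = design$horses) %>%
      mutate(
        tissue = tis, direction = dir,
        multiplier = if (dir == "up") effect else 1 / effect
      )
  }) %>%
    bind_rows() %>%
    select("feature_id", "tissue", "direction", "horse", "multiplier") %>%
    arrange(.data$feature_id, .data$tissue, .data$horse)
  # (a gene may be planted as a DEG in both tissues; that is intentional)

  # switch pairs: the two heaviest isoforms swap dominance after exercise
  switch_truth <- switch_truth %>%
    mutate(pair = map(.data$gene_id, function(gid) {
      two <- iso %>%
        filter(.data$gene_id == gid) %>%
        arrange(dplyr::desc(.data$weight), .data$transcript_id) %>%
        head(2)
      u <- max(4, round(mean(two$tx_mean) / (switch_ratio + 1) * 2))
      tibble(
        isoform_a = two$transcript_id[1], isoform_b = two$transcript_id[2],
        mean_low = u, mean_high = switch_ratio * u
      )
    })) %>%
    unnest("pair") %>%
    select(
      "gene_id", "tissue", "isoform_a", "isoform_b", "mean_low", "mean_high"
    ) %>%
    arrange(.data$gene_id)

  # transcript-level count means per sample
  set.seed(.sub_seed(seed, 3))
  grid <- crossing(
    iso %>% select("gene_id", "transcript_id", "profile", "tx_mean"),
    samples
  ) %>%
    mutate(expressed = .data$profile == "both" | .data$profile == .data$tissue) %>%
    mutate(mean = if_else(.data$expressed, as.numeric(.data$tx_mean), 0)) %>%
    left_join(
      deg_truth %>% select("feature_id", "tissue", "horse", "multiplier"),
      by = c(gene_id = "feature_id", "tissue", "horse")
    ) %>%
    mutate(mean = if_else(
      .data$timepoint == "after" & !is.na(.data$multiplier),
      .data$mean * .data$multiplier, .data$mean
    )) %>%
    select(-"multiplier")
  # overwrite means for switching isoform pairs in their tissue
  sw_long <- switch_truth %>%
    pivot_longer(c("isoform_a", "isoform_b"),
      names_to = "role", values_to = "transcript_id"
    ) %>%
    crossing(timepoint = design$timepoints) %>%
    mutate(sw_mean = dplyr::case_when(
      .data$role == "isoform_a" & .data$timepoint == "before" ~ .data$mean_high,
      .data$role == "isoform_a" & .data$timepoint == "after" ~ as.numeric(.data$mean_low),
      .data$role == "isoform_b" & .data$timepoint == "before" ~ as.numeric(.data$mean_low),
      TRUE ~ .data$mean_high
    )) %>%
    select("transcript_id", "tissue", "timepoint", "sw_mean")
  grid <- grid %>%
    left_join(sw_long, by = c("transcript_id", "tissue", "timepoint")) %>%
    mutate(mean = if_else(
      !is.na(.data$sw_mean) & .data$expressed, .data$sw_mean, .data$mean
    )) %>%
    mutate(count = .noisy_counts(.data$mean, cv))

  tx_counts <- grid %>%
    select(feature_id = "transcript_id", "sample_id", "count") %>%
    arrange(.data$feature_id, .data$sample_id)
  gene_counts <- grid %>%
    group_by(feature_id = .data$gene_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$feature_id, .data$sample_id)

  exonic_len <- function(df) {
    gr <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
    sum(IRanges::width(GenomicRanges::reduce(gr)))
  }
  tx_lengths <- tx_exons %>%
    group_by(feature_id = .data$transcript_id) %>%
    summarise(length = sum(.data$end - .data$start + 1L), .groups = "drop")
  gene_lengths <- tx_exons %>%
    nest(ex = c("contig", "start", "end")) %>%
    group_by(feature_id = .data$gene_id) %>%
    summarise(
      length = exonic_len(bind_rows(.data$ex)), .groups = "drop"
    )

  # sites: truth in exon interiors, artifacts at junctions, carried only by
  # samples expressing the owning gene
  primary_exons <- annotation_all %>%
    filter(
      .data$feature == "exon",
      .data$transcript_id %in% genes$primary_transcript
    ) %>%
    select("gene_id", "contig", "start", "end")
  carrier_map <- primary_exons %>%
    left_join(genes %>% select("gene_id", "profile"), by = "gene_id") %>%
    mutate(sample_id = map(.data$profile, function(p) {
      samples$sample_id[samples$tissue == p | p == "both"]
    })) %>%
    select("contig", "start", "end", "sample_id") %>%
    unnest("sample_id")
  sites <- sim_sites(
    samples, primary_exons,
    n_sites = n_sites, n_artifacts = n_artifacts,
    depth_mean = depth_mean, error_rate = error_rate, window_bp = window_bp,
    artifact_fraction = artifact_fraction, indel_fraction = indel_fraction,
    carrier_map = carrier_map,
    genome = g$genome, seed = .sub_seed(seed, 4)
  )
  art_carriers <- sites$artifact_sites %>%
    select("contig", "pos") %>%
    inner_join(
      carrier_map,
      by = dplyr::join_by("contig", dplyr::between(x$pos, y$start, y$end))
    ) %>%
    select("contig", "pos", "sample_id") %>%
    distinct()

  dbs <- sim_snp_databases(
    sites$site_truth,
    overlap_fractions = db_overlap, n_extra = db_extra,
    contig_lengths = setNames(
      Biostrings::width(g$genome), names(g$genome)
    ),
    genome = g$genome, seed = .sub_seed(seed, 5)
  )

  structure(
    list(
      seed = as.integer(seed),
      samples = samples,
      genome = g$genome,
      annotation = annotation,
      annotation_all = annotation_all,
      genes = genes,
      gene_map = gene_map,
      sample_exons = sample_exons,
      tx_counts = tx_counts,
      gene_counts = gene_counts,
      tx_lengths = tx_lengths,
      gene_lengths = gene_lengths,
      observations = sites$observations,
      db1 = dbs$db1,
      db2 = dbs$db2,
      params = list(
        effect = effect, cv = cv, window_bp = window_bp,
        depth_mean = depth_mean, error_rate = error_rate,
        fraction_novel = fraction_novel, db_overlap = db_overlap
      ),
      truth = list(
        deg = deg_truth,
        genotype = sites$genotype_truth,
        sites = sites$site_truth,
        artifacts = sites$artifact_sites %>%
          semi_join(art_carriers, by = c("contig", "pos")),
        artifact_carriers = art_carriers,
        switch = switch_truth,
        novelty = novelty_truth,
        db_membership = dbs$membership
      )
    ),
    class = "exertome_study"
  )
}

#' @export
print.exertome_study <- function(x, ...) {
  cat("<exertome_study> seed", x$seed, "\n")
  cat(
    " ", length(x$genome), "contigs;",
    n_distinct(x$gene_map$gene_id), "genes;",
    nrow(x$gene_map), "transcripts;",
    nrow(x$samples), "samples\n"
  )
  cat(
    "  truth:", nrow(distinct(x$truth$deg, .data$feature_id, .data$tissue)),
    "DEG slots,", nrow(x$truth$sites), "variant sites,",
    nrow(x$truth$artifacts), "artifacts,",
    nrow(x$truth$switch), "isoform switches\n"
  )
  invisible(x)
}

#' Write a synthetic study corpus to disk
#'
#' Materialises the corpus as the plain-text files the pipeline reads:
#' genome FASTA, reference GTF (with CDS), 24 per-sample transcript GTFs,
#' site-observation TSV, gene- and transcript-level count TSVs, two database
#' VCFs, the sample sheet CSV and all truth tables as TSV.
#'
#' @param study An `exertome_study` object.
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "reference.gtf"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    sites = file.path(dir, "sites.tsv"),
    gene_counts = file.path(dir, "counts_gene.tsv"),
    tx_counts = file.path(dir, "counts_transcript.tsv"),
    gene_lengths = file.path(dir, "lengths_gene.tsv"),
    tx_lengths = file.path(dir, "lengths_transcript.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    db1 = file.path(dir, "db1.vcf"),
    db2 = file.path(dir, "db2.vcf")
  )
  write_genome_fasta(study$genome, paths$genome)
  write_annotation_gtf(study$annotation, paths$annotation)
  readr::write_csv(study$samples, paths$sample_sheet)
  readr::write_tsv(study$observations, paths$sites)
  write_matrix_tsv(study$gene_counts, paths$gene_counts)
  write_matrix_tsv(study$tx_counts, paths$tx_counts)
  readr::write_tsv(study$gene_lengths, paths$gene_lengths)
  readr::write_tsv(study$tx_lengths, paths$tx_lengths)
  readr::write_tsv(study$gene_map, paths$gene_map)
  clen <- setNames(Biostrings::width(study$genome), names(study$genome))
  write_variants_vcf(study$db1, paths$db1, contig_lengths = clen)
  write_variants_vcf(study$db2, paths$db2, contig_lengths = clen)
  paths$sample_gtfs <- vapply(
    unique(study$samples$sample_id),
    function(sid) {
      p <- file.path(dir, "samples", paste0(sid, ".gtf"))
      write_transcript_gtf(
        study$sample_exons %>% filter(.data$sample_id == sid), p
      )
      p
    },
    character(1)
  )
  for (nm in names(study$truth)) {
    p <- file.path(dir, "truth", paste0(nm, ".tsv"))
    readr::write_tsv(study$truth[[nm]], p)
    paths[[paste0("truth_", nm)]] <- p
  }
  invisible(paths)
}
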