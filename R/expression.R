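# Expression quantification (FPKM), sample-level summaries, and the
# per-animal fold-change voting rule for differential expression: a feature
# is differentially expressed in a tissue iff it shows more than
# `fold_threshold`-fold change in the same direction in at least
# `min_horses` of the animals.

#' Compute FPKM from fragment counts
#'
#' FPKM (fragments per kilobase of exon model per million mapped fragments):
#' `fpkm = count * 1e9 / (length * total)`. The transformation is exactly
#' invertible given lengths and totals.
#'
#' @param counts Long count tibble (`feature_id`, `sample_id`, `count`).
#' @param lengths Tibble of feature effective lengths (`feature_id`,
#'   `length` in bp, > 0).
#' @param totals Optional tibble of per-sample total mapped fragments
#'   (`sample_id`, `total`, > 0); defaults to the per-sample sum of
#'   `counts`.
#' @return The input with an `fpkm` column (and `length`/`total` joined in).
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  if (is.null(totals)) {
    totals <- counts %>%
      group_by(.data$sample_id) %>%
      summarise(total = sum(.data$count), .groups = "drop")
  }
  if (any(totals$total <= 0)) abort("per-sample totals must be > 0")
  out <- counts %>%
    left_join(lengths, by = "feature_id") %>%
    left_join(totals, by = "sample_id")
  if (any(is.na(out$length))) abort("missing feature length(s)")
  if (any(out$length <= 0)) abort("feature lengths must be > 0")
  out %>%
    mutate(fpkm = .data$count * 1e9 / (.data$length * .data$total))
}

#' Sample-sample Pearson correlation of log-transformed FPKM
#'
#' Correlations are computed on `log(fpkm + 1)`; a pair involving a
#' constant-expression sample is undefined and reported as `NA`.
#'
#' @param fpkm Long FPKM tibble.
#' @return A symmetric tibble: `sample_id` column plus one column per
#'   sample.
#' @export
sample_correlation <- function(fpkm) {
  wide <- fpkm %>%
    select("feature_id", "sample_id", "fpkm") %>%
    pivot_wider(names_from = "sample_id", values_from = "fpkm")
  if (nrow(wide) < 2) abort("need at least 2 features for correlations")
  m <- as.matrix(wide[-1])
  r <- suppressWarnings(cor(log1p(m), method = "pearson"))
  as_tibble(r, rownames = "sample_id")
}

#' Quartiles of per-feature mean FPKM
#'
#' @param fpkm Long FPKM tibble.
#' @return A one-row tibble with `q25`, `median`, `q75` of the per-feature
#'   mean FPKM across samples (linear-interpolation quantiles).
#' @export
expression_quantiles <- function(fpkm) {
  means <- fpkm %>%
    group_by(.data$feature_id) %>%
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop")
  q <- quantile(means$mean_fpkm, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(q25 = q[1], median = q[2], q75 = q[3])
}

#' Per-animal before/after fold changes on FPKM
#'
#' @param fpkm Long FPKM tibble.
#' @param samples Sample sheet.
#' @param pseudocount Added to both timepoints before dividing (bounds the
#'   fold when expression is zero).
#' @param allow_missing Exclude animals lacking a timepoint with a warning
#'   instead of erroring.
#' @return Tibble with `feature_id`, `tissue`, `horse`, `fpkm_before`,
#'   `fpkm_after`, `fold`.
#' @export
horse_folds <- function(fpkm, samples, pseudocount = 0.1, allow_missing = FALSE) {
  samples <- validate_samples(samples)
  have <- samples %>%
    count(.data$horse, .data$tissue) %>%
    filter(n == 2L)
  incomplete <- samples %>%
    distinct(.data$horse, .data$tissue) %>%
    anti_join(have, by = c("horse", "tissue"))
  if (nrow(incomplete) > 0) {
    msg <- sprintf(
      "%d (horse, tissue) pair(s) lack a timepoint", nrow(incomplete)
    )
    if (!allow_missing) abort(paste0(msg, "; set allow_missing = TRUE to drop them"))
    warn(paste0(msg, "; excluded"))
  }
  fpkm %>%
    inner_join(
      samples %>%
        semi_join(have, by = c("horse", "tissue")) %>%
        select("sample_id", "horse", "tissue", "timepoint"),
      by = "sample_id"
    ) %>%
    select("feature_id", "tissue", "horse", "timepoint", "fpkm") %>%
    pivot_wider(
      names_from = "timepoint", values_from = "fpkm", names_prefix = "fpkm_"
    ) %>%
    mutate(fold = (.data$fpkm_after + pseudocount) / (.data$fpkm_before + pseudocount))
}

#' Call differentially expressed features by the per-animal voting rule
#'
#' For each animal the before/after fold change is computed on FPKM (with a
#' pseudocount); a feature is an up-regulated DEG in a tissue iff its fold
#' exceeds `fold_threshold` in at least `min_horses` animals, and a
#' down-regulated DEG iff the fold is below `1/fold_threshold` in at least
#' `min_horses`. "More than `fold_threshold`-fold" is strict (`>`, `<`).
#' With `min_horses` above half the animals the up and down sets are
#' disjoint by construction.
#'
#' @inheritParams horse_folds
#' @param fold_threshold Fold-change threshold (strict; default 2).
#' @param min_horses Minimum supporting animals (default 4 of 6).
#' @param uc_status Optional tibble (`feature_id`, `status`) to break DEG
#'   counts down by annotated/novel status.
#' @return An object of class `deg_result` with `degs` (one row per DEG and
#'   tissue), `folds` (all per-animal folds), and the parameters;
#'   [tidy()]/[glance()]/[autoplot()] methods apply.
#' @export
call_degs <- function(fpkm, samples, fold_threshold = 2, min_horses = 4,
                      pseudocount = 0.1, uc_status = NULL,
                      allow_missing = FALSE) {
  samples <- validate_samples(samples)
  n_horses_avail <- n_distinct(samples$horse)
  if (min_horses > n_horses_avail) {
    abort(sprintf(
      "min_horses (%d) exceeds the number of animals (%d)",
      min_horses, n_horses_avail
    ))
  }
  folds <- horse_folds(fpkm, samples, pseudocount, allow_missing)
  votes <- folds %>%
    group_by(.data$feature_id, .data$tissue) %>%
    summarise(
      n_up = sum(.data$fold > fold_threshold),
      n_down = sum(.data$fold < 1 / fold_threshold),
      up_horses = id_set(.data$horse[.data$fold > fold_threshold]),
      down_horses = id_set(.data$horse[.data$fold < 1 / fold_threshold]),
      .groups = "drop"
    )
  degs <- bind_rows(
    votes %>%
      filter(.data$n_up >= min_horses) %>%
      mutate(
        direction = "up", n_support = .data$n_up,
        supporting_horses = .data$up_horses
      ),
    votes %>%
      filter(.data$n_down >= min_horses) %>%
      mutate(
        direction = "down", n_support = .data$n_down,
        supporting_horses = .data$down_horses
      )
  ) %>%
    select(
      "feature_id", "tissue", "direction", "n_support", "supporting_horses"
    ) %>%
    arrange(.data$tissue, .data$direction, .data$feature_id)
  if (!is.null(uc_status)) {
    degs <- degs %>%
      left_join(uc_status %>% select("feature_id", "status"), by = "feature_id")
  }
  structure(
    list(
      degs = degs, folds = folds,
      params = list(
        fold_threshold = fold_threshold, min_horses = min_horses,
        pseudocount = pseudocount
      )
    ),
    class = "deg_result"
  )
}

#' @export
print.deg_result <- function(x, ...) {
  cat(
    "<deg_result>", nrow(x$degs), "DEG calls (fold >",
    x$params$fold_threshold, "in >=", x$params$min_horses, "animals)\n"
  )
  print(count(x$degs, .data$tissue, .data$direction))
  invisible(x)
}

#' @export
tidy.deg_result <- function(x, ...) x$degs

# glance(): per-tissue up/down counts, the raw total over tissues, and the
# total after deduplicating features called in both tissues (the two differ
# whenever a feature responds in both)
#' @export
glance.deg_result <- function(x, ...) {
  d <- x$degs
  cnt <- function(tis, dir) sum(d$tissue == tis & d$direction == dir)
  tibble(
    blood_up = cnt("blood", "up"), blood_down = cnt("blood", "down"),
    muscle_up = cnt("muscle", "up"), muscle_down = cnt("muscle", "down"),
    total_raw = nrow(d),
    total_dedup = n_distinct(d$feature_id),
    novel = if (is.null(d$status)) NA_integer_ else sum(d$status == "novel", na.rm = TRUE)
  )
}

#' Cross-reference DEG calls with a known-gene list
#'
#' @param degs A `deg_result`.
#' @param known Tibble of genes of interest: `gene_id` plus optional
#'   `expected_direction` (`"up"`/`"down"`).
#' @param feature_map Optional tibble (`gene_id`, `feature_id`) mapping gene
#'   ids to expression features; defaults to identity.
#' @param expressed Optional output of [tissue_expressed()] to flag
#'   expression per tissue.
#' @return One row per known gene: mapping flag, per-tissue expression
#'   flags, DEG call (tissue/direction) and `direction_agreement`
#'   (`"agree"`, `"disagree"`, or `NA` when not a DEG or no expectation).
#'   Unmappable ids are retained with `mapped = FALSE`, never dropped.
#' @export
crossref_gene_lists <- function(degs, known, feature_map = NULL,
                                expressed = NULL) {
  stopifnot(inherits(degs, "deg_result"))
  known <- as_tibble(known)
  if (nrow(known) == 0) {
    return(tibble(
      gene_id = character(), mapped = logical(), feature_id = character(),
      deg_tissue = character(), deg_direction = character(),
      direction_agreement = character()
    ))
  }
  if (is.null(feature_map)) {
    feature_map <- tibble(
      gene_id = known$gene_id, feature_id = known$gene_id
    )
  }
  out <- known %>%
    left_join(feature_map, by = "gene_id") %>%
    mutate(mapped = !is.na(.data$feature_id) &
      .data$feature_id %in% unique(c(degs$folds$feature_id))) %>%
    left_join(
      degs$degs %>%
        select("feature_id",
          deg_tissue = "tissue", deg_direction = "direction"
        ),
      by = "feature_id"
    )
  if (!is.null(expressed)) {
    out <- out %>%
      left_join(
        expressed %>%
          rename(expressed_blood = "blood", expressed_muscle = "muscle"),
        by = "feature_id"
      )
  }
  if ("expected_direction" %in% names(out)) {
    out <- out %>%
      mutate(direction_agreement = dplyr::case_when(
        is.na(.data$deg_direction) | is.na(.data$expected_direction) ~ NA_character_,
        .data$deg_direction == .data$expected_direction ~ "agree",
        TRUE ~ "disagree"
      ))
  } else {
    out$direction_agreement <- NA_character_
  }
  out
}
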