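# Isoform expression switches: genes whose two splice forms reverse their
# dominance order between the before and after timepoints, consistently
# across animals (the voting spirit of the DEG rule applied to isoform
# dominance).

#' Detect isoform dominance switches between timepoints
#'
#' For an isoform pair (a, b) of one gene and one animal, a switch in the
#' "a then b" orientation holds iff `fpkm_a > min_ratio * fpkm_b` before
#' exercise and `fpkm_b > min_ratio * fpkm_a` after, with the dominant
#' isoform at least `min_fpkm` at both timepoints. An event is reported for
#' a gene and tissue iff at least `min_horses` animals agree on the same
#' orientation; when several pairs of a gene qualify, the pair with most
#' support wins (ties broken by lexicographic isoform ids). Genes with a
#' single isoform are skipped.
#'
#' @param tx_fpkm Long transcript-level FPKM tibble (`feature_id`,
#'   `sample_id`, `fpkm`).
#' @param gene_map Tibble mapping `transcript_id` to `gene_id`.
#' @param samples Sample sheet.
#' @param min_horses Minimum agreeing animals (default 4 of 6).
#' @param min_fpkm Minimum FPKM of the dominant isoform (default 1).
#' @param min_ratio Dominance ratio (default 1: strict dominance).
#' @param allow_missing Drop animals lacking a timepoint with a warning.
#' @return An object of class `switch_result`: `events` (one row per gene
#'   and tissue: `gene_id`, `tissue`, `isoform_a` dominant before,
#'   `isoform_b` dominant after, `n_support`, `supporting_horses`) and
#'   `profiles` (per-animal FPKM pairs of the event isoforms, plot-ready).
#' @export
detect_switches <- function(tx_fpkm, gene_map, samples, min_horses = 4,
                            min_fpkm = 1, min_ratio = 1,
                            allow_missing = FALSE) {
  samples <- validate_samples(samples)
  if (min_horses > n_distinct(samples$horse)) {
    abort("min_horses exceeds the number of animals")
  }
  wide <- horse_folds(tx_fpkm, samples,
    pseudocount = 0, allow_missing = allow_missing
  ) %>%
    select("feature_id", "tissue", "horse", "fpkm_before", "fpkm_after") %>%
    inner_join(gene_map, by = c(feature_id = "transcript_id"))

  pairs <- gene_map %>%
    group_by(.data$gene_id) %>%
    filter(n() >= 2) %>%
    summarise(tx = list(sort(.data$transcript_id)), .groups = "drop") %>%
    mutate(pair = map(.data$tx, function(t) {
      idx <- utils::combn(length(t), 2)
      tibble(tx_p = t[idx[1, ]], tx_q = t[idx[2, ]])
    })) %>%
    select("gene_id", "pair") %>%
    unnest("pair")
  if (nrow(pairs) == 0) {
    return(.switch_result(
      tibble(
        gene_id = character(), tissue = character(),
        isoform_a = character(), isoform_b = character(),
        n_support = integer(), supporting_horses = character()
      ),
      tibble(), min_horses, min_fpkm, min_ratio
    ))
  }

  p_vals <- wide %>%
    rename(
      tx_p = "feature_id",
      p_before = "fpkm_before", p_after = "fpkm_after"
    )
  q_vals <- wide %>%
    select(-"gene_id") %>%
    rename(
      tx_q = "feature_id",
      q_before = "fpkm_before", q_after = "fpkm_after"
    )
  per_horse <- pairs %>%
    inner_join(p_vals,
      by = c("gene_id", "tx_p"), relationship = "many-to-many"
    ) %>%
    inner_join(q_vals, by = c("tx_q", "tissue", "horse")) %>%
    mutate(
      pq = .data$p_before > min_ratio * .data$q_before &
        .data$q_after > min_ratio * .data$p_after &
        .data$p_before >= min_fpkm & .data$q_after >= min_fpkm,
      qp = .data$q_before > min_ratio * .data$p_before &
        .data$p_after > min_ratio * .data$q_after &
        .data$q_before >= min_fpkm & .data$p_after >= min_fpkm
    )
  support <- per_horse %>%
    group_by(.data$gene_id, .data$tissue, .data$tx_p, .data$tx_q) %>%
    summarise(
      n_pq = sum(.data$pq), n_qp = sum(.data$qp),
      pq_horses = id_set(.data$horse[.data$pq]),
      qp_horses = id_set(.data$horse[.data$qp]),
      .groups = "drop"
    ) %>%
    mutate(
      n_support = pmax(.data$n_pq, .data$n_qp),
      isoform_a = if_else(.data$n_pq >= .data$n_qp, .data$tx_p, .data$tx_q),
      isoform_b = if_else(.data$n_pq >= .data$n_qp, .data$tx_q, .data$tx_p),
      supporting_horses = if_else(
        .data$n_pq >= .data$n_qp, .data$pq_horses, .data$qp_horses
      )
    )
  events <- support %>%
    filter(.data$n_support >= min_horses) %>%
    group_by(.data$gene_id, .data$tissue) %>%
    arrange(
      dplyr::desc(.data$n_support), .data$isoform_a, .data$isoform_b,
      .by_group = TRUE
    ) %>%
    slice(1) %>%
    ungroup() %>%
    select(
      "gene_id", "tissue", "isoform_a", "isoform_b",
      "n_support", "supporting_horses"
    ) %>%
    arrange(.data$gene_id, .data$tissue)

  profiles <- events %>%
    pivot_longer(c("isoform_a", "isoform_b"),
      names_to = "role", values_to = "transcript_id"
    ) %>%
    inner_join(
      wide %>% rename(transcript_id = "feature_id") %>% select(-"gene_id"),
      by = c("transcript_id", "tissue")
    ) %>%
    pivot_longer(c("fpkm_before", "fpkm_after"),
      names_to = "timepoint", values_to = "fpkm", names_prefix = "fpkm_"
    ) %>%
    mutate(timepoint = factor(.data$timepoint, levels = c("before", "after"))) %>%
    select(
      "gene_id", "tissue", "horse", "transcript_id", "role",
      "timepoint", "fpkm"
    ) %>%
    arrange(.data$gene_id, .data$tissue, .data$horse, .data$transcript_id)

  .switch_result(events, profiles, min_horses, min_fpkm, min_ratio)
}

.switch_result <- function(events, profiles, min_horses, min_fpkm, min_ratio) {
  structure(
    list(
      events = events, profiles = profiles,
      params = list(
        min_horses = min_horses, min_fpkm = min_fpkm, min_ratio = min_ratio
      )
    ),
    class = "switch_result"
  )
}

#' @export
print.switch_result <- function(x, ...) {
  cat(
    "<switch_result>", nrow(x$events),
    "isoform dominance switch(es) (>=", x$params$min_horses, "animals)\n"
  )
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}

#' @export
tidy.switch_result <- function(x, ...) x$events

#' @export
glance.switch_result <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_genes = n_distinct(x$events$gene_id),
    blood = sum(x$events$tissue == "blood"),
    muscle = sum(x$events$tissue == "muscle")
  )
}
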