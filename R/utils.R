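#' Percentage of a part in a total, rounded half-up to two decimals
#'
#' Computes `100 * part / total` and rounds half-up (so 0.005 rounds to 0.01,
#' unlike [round()], which rounds half to even). Used for every percentage the
#' pipeline reports, so that printed counts and their percentages are always
#' mutually consistent.
#'
#' @param part Non-negative count (vectorised).
#' @param total Positive count (vectorised, recycled).
#' @return Numeric vector of percentages with two decimal places.
#' @examples
#' percentage(11933, 32361) # 36.87
#' percentage(20428, 32361) # 63.13
#' @export
percentage <- function(part, total) {
  if (any(total <= 0)) abort("`total` must be > 0")
  if (any(part < 0) || any(part > total)) {
    abort("`part` must satisfy 0 <= part <= total")
  }
  round_half_up(100 * part / total, 2)
}

# round half away from zero at `digits` decimals; round() is half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Validate a sample sheet for the paired two-tissue design
#'
#' Checks the `sample_id`, `horse`, `tissue`, `timepoint` columns, that tissue
#' and timepoint use the expected levels, and that sample ids are unique.
#'
#' @param samples Data frame with columns `sample_id`, `horse`, `tissue`,
#'   `timepoint`.
#' @param complete If `TRUE`, additionally require every (horse, tissue)
#'   combination to have both timepoints.
#' @return The sample sheet as a tibble, invisibly usable in a pipe.
#' @export
validate_samples <- function(samples, complete = FALSE) {
  req <- c("sample_id", "horse", "tissue", "timepoint")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")))
  }
  samples <- as_tibble(samples)
  if (anyDuplicated(samples$sample_id) > 0) abort("duplicated sample_id")
  if (!all(samples$tissue %in% c("blood", "muscle"))) {
    abort("tissue must be 'blood' or 'muscle'")
  }
  if (!all(samples$timepoint %in% c("before", "after"))) {
    abort("timepoint must be 'before' or 'after'")
  }
  if (complete) {
    chk <- samples %>%
      count(.data$horse, .data$tissue) %>%
      filter(n != 2L)
    if (nrow(chk) > 0) {
      abort("each (horse, tissue) must have exactly one before and one after sample")
    }
  }
  samples
}

# stable canonical strand factor
.strand_levels <- c("+", "-")

check_strand <- function(strand) {
  if (!all(strand %in% .strand_levels)) abort("strand must be '+' or '-'")
  strand
}

# comma-joined sorted unique ids (canonical set representation in tables)
id_set <- function(x) paste(sort(unique(x)), collapse = ",")
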