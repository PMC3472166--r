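# Shared synthetic corpus, built once per test run (the default study
# conditions; several suites read from it).

.corpus_env <- new.env(parent = emptyenv())

test_study <- function() {
  if (is.null(.corpus_env$study)) {
    .corpus_env$study <- sim_study(seed = 42)
  }
  .corpus_env$study
}

# the same corpus written to disk, plus a completed pipeline run
test_pipeline_run <- function() {
  if (is.null(.corpus_env$run)) {
    dir <- file.path(tempdir(), "exertome-corpus")
    out <- file.path(tempdir(), "exertome-out")
    write_study(test_study(), dir)
    cfg <- pipeline_config(dir, out)
    .corpus_env$run <- list(
      dir = dir, out = out, cfg = cfg,
      res = run_pipeline(cfg)
    )
  }
  .corpus_env$run
}

# minimal sample sheet for unit tests that do not need the full corpus
mini_samples <- function(n_horses = 6, tissues = c("blood", "muscle")) {
  s <- validate_samples(sim_design(sprintf("H%d", seq_len(n_horses)))$samples)
  s[s$tissue %in% tissues, ]
}

# long FPKM tibble from a named fold pattern: one feature, one tissue,
# before fixed at `base`, after = base * fold per horse
fpkm_from_folds <- function(folds, tissue = "muscle", base = 10,
                            feature_id = "F1") {
  horses <- sprintf("H%d", seq_along(folds))
  samples <- mini_samples(length(folds), tissue)
  before <- tibble::tibble(
    feature_id = feature_id,
    sample_id = paste(horses, tissue, "before", sep = "_"),
    fpkm = base
  )
  after <- tibble::tibble(
    feature_id = feature_id,
    sample_id = paste(horses, tissue, "after", sep = "_"),
    fpkm = base * folds
  )
  list(fpkm = dplyr::bind_rows(before, after), samples = samples)
}
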