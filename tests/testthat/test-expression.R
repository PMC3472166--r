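# FPKM algebra, correlations, quantiles and the voting DEG rule.

test_that("FPKM follows its definition and inverts exactly", {
  counts <- tibble::tibble(
    feature_id = c("f1", "f2"), sample_id = "s1", count = c(100, 0)
  )
  lengths <- tibble::tibble(feature_id = c("f1", "f2"), length = c(1000, 500))
  totals <- tibble::tibble(sample_id = "s1", total = 1e6)
  f <- compute_fpkm(counts, lengths, totals)
  expect_equal(f$fpkm, c(100, 0))
  expect_error(
    compute_fpkm(counts, dplyr::mutate(lengths, length = c(0, 500)), totals),
    "> 0"
  )
  # algebraic inversion on a random matrix
  set.seed(3)
  grid <- tidyr::crossing(
    feature_id = sprintf("f%02d", 1:40), sample_id = sprintf("s%02d", 1:10)
  )
  grid$count <- rpois(nrow(grid), 50)
  lens <- tibble::tibble(
    feature_id = sprintf("f%02d", 1:40), length = sample(200:3000, 40)
  )
  f2 <- compute_fpkm(grid, lens)
  back <- f2$fpkm * f2$length * f2$total / 1e9
  err <- abs(back - f2$count) / pmax(f2$count, 1)
  expect_lt(max(err), 1e-12)
})

test_that("sample correlations match the textbook formula; degenerate columns give NA", {
  set.seed(5)
  grid <- tidyr::crossing(
    feature_id = sprintf("f%03d", 1:100), sample_id = sprintf("s%02d", 1:24)
  )
  grid$fpkm <- rlnorm(nrow(grid), 2, 1)
  corr <- sample_correlation(grid)
  m <- log1p(matrix(grid$fpkm[order(grid$sample_id, grid$feature_id)], nrow = 100))
  # direct formula: sum of products over centred columns
  manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  got <- as.matrix(corr[-1])
  rownames(got) <- corr$sample_id
  expect_equal(unname(diag(got)), rep(1, 24))
  expect_equal(unname(got), unname(t(got)))
  for (j in c(2, 17)) {
    expect_lt(abs(got[1, j] - manual(m[, 1], m[, j])), 1e-10)
  }
  # duplicated column correlates at exactly 1
  dup <- dplyr::mutate(grid, fpkm = ifelse(sample_id == "s02",
    grid$fpkm[grid$sample_id == "s01"][match(feature_id, sprintf("f%03d", 1:100))],
    fpkm
  ))
  cd <- sample_correlation(dup)
  m_cd <- as.matrix(cd[-1])
  rownames(m_cd) <- cd$sample_id
  expect_equal(unname(m_cd["s01", "s02"]), 1)
  # constant column: undefined correlation reported NA
  const <- dplyr::mutate(grid, fpkm = ifelse(sample_id == "s03", 7, fpkm))
  ccor <- sample_correlation(const)
  cc <- as.matrix(ccor[-1])
  rownames(cc) <- ccor$sample_id
  expect_true(all(is.na(cc["s03", setdiff(colnames(cc), "s03")])))
})

test_that("expression quantiles use linear interpolation over per-feature means", {
  flat <- tidyr::crossing(
    feature_id = sprintf("f%d", 1:10), sample_id = sprintf("s%d", 1:4)
  )
  flat$fpkm <- 5
  expect_equal(
    as.numeric(expression_quantiles(flat)), c(5, 5, 5)
  )
  seqd <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:100), sample_id = "s1", fpkm = 1:100
  )
  expect_equal(expression_quantiles(seqd)$median, 50.5)
  set.seed(9)
  rnd <- tidyr::crossing(
    feature_id = sprintf("f%03d", 1:73), sample_id = sprintf("s%d", 1:24)
  )
  rnd$fpkm <- rlnorm(nrow(rnd), 0, 2)
  q <- expression_quantiles(rnd)
  means <- tapply(rnd$fpkm, rnd$feature_id, mean)
  expect_equal(q$q25, oracle_quantile(means, 0.25))
  expect_equal(q$median, oracle_quantile(means, 0.5))
  expect_equal(q$q75, oracle_quantile(means, 0.75))
})

test_that("the voting rule calls DEGs exactly as specified on crafted folds", {
  up4 <- fpkm_from_folds(c(2.5, 2.1, 3.0, 2.2, 0.9, 1.1))
  res <- call_degs(up4$fpkm, up4$samples, pseudocount = 0)
  expect_equal(nrow(tidy(res)), 1)
  expect_equal(tidy(res)$direction, "up")
  expect_equal(tidy(res)$n_support, 4L)
  expect_equal(tidy(res)$supporting_horses, "H1,H2,H3,H4")
  # 3 up + 3 down: no DEG under a quorum of 4
  split33 <- fpkm_from_folds(c(2.5, 2.1, 3.0, 0.4, 0.4, 0.3))
  expect_equal(nrow(tidy(call_degs(split33$fpkm, split33$samples, pseudocount = 0))), 0)
  # the threshold is strict: fold exactly 2 does not vote
  exact2 <- fpkm_from_folds(c(2, 2, 2, 2, 2, 2))
  expect_equal(nrow(tidy(call_degs(exact2$fpkm, exact2$samples, pseudocount = 0))), 0)
  just_over <- fpkm_from_folds(c(2.01, 2.01, 2.01, 2.01, 0.9, 1))
  expect_equal(nrow(tidy(call_degs(just_over$fpkm, just_over$samples, pseudocount = 0))), 1)
})

test_that("swapping before/after maps up-DEGs onto down-DEGs exactly", {
  run <- test_pipeline_run()
  s <- test_study()
  fpkm <- run$res$fpkm
  swapped <- dplyr::mutate(s$samples,
    timepoint = ifelse(timepoint == "before", "after", "before")
  )
  fwd <- tidy(call_degs(fpkm, s$samples))
  rev <- tidy(call_degs(fpkm, swapped))
  flip <- function(d) ifelse(d == "up", "down", "up")
  expect_identical(
    dplyr::arrange(dplyr::mutate(fwd[1:4], direction = flip(direction)), tissue, direction, feature_id),
    dplyr::arrange(rev[1:4], tissue, direction, feature_id)
  )
})

test_that("DEG calls are monotone in threshold and quorum, and directions disjoint", {
  run <- test_pipeline_run()
  s <- test_study()
  fpkm <- run$res$fpkm
  key <- function(r) paste(tidy(r)$feature_id, tidy(r)$tissue, tidy(r)$direction)
  prev <- NULL
  for (thr in c(1.5, 2, 3, 4)) {
    cur <- key(call_degs(fpkm, s$samples, fold_threshold = thr))
    if (!is.null(prev)) expect_true(all(cur %in% prev), label = paste("fold", thr))
    prev <- cur
  }
  prev <- NULL
  for (mh in 4:6) {
    cur <- key(call_degs(fpkm, s$samples, min_horses = mh))
    if (!is.null(prev)) expect_true(all(cur %in% prev), label = paste("quorum", mh))
    prev <- cur
  }
  d <- tidy(call_degs(fpkm, s$samples, min_horses = 4))
  both_dir <- dplyr::count(d, feature_id, tissue)
  expect_true(all(both_dir$n == 1))
  expect_error(call_degs(fpkm, s$samples, min_horses = 7), "exceeds")
})

test_that("library-size rescaling of one sample leaves DEG calls unchanged", {
  s <- test_study()
  counts <- s$gene_counts
  scaled <- dplyr::mutate(counts,
    count = ifelse(sample_id == "H1_muscle_after", count * 7, count)
  )
  f1 <- compute_fpkm(counts, s$gene_lengths)
  f2 <- compute_fpkm(scaled, s$gene_lengths)
  # folds computed with pseudocount 0 are exactly invariant
  expect_identical(
    tidy(call_degs(f1, s$samples, pseudocount = 0)),
    tidy(call_degs(f2, s$samples, pseudocount = 0))
  )
})

test_that("missing timepoints error unless explicitly allowed", {
  s <- test_study()
  run <- test_pipeline_run()
  fpkm <- run$res$fpkm
  dropped <- s$samples[s$samples$sample_id != "H1_muscle_after", ]
  fpkm_d <- fpkm[fpkm$sample_id %in% dropped$sample_id, ]
  expect_error(call_degs(fpkm_d, dropped), "allow_missing")
  expect_warning(
    res <- call_degs(fpkm_d, dropped, allow_missing = TRUE),
    "excluded"
  )
  # H1 is excluded from muscle votes only
  expect_false("H1" %in% unlist(strsplit(
    tidy(res)$supporting_horses[tidy(res)$tissue == "muscle"], ","
  )))
})

test_that("known-gene cross-referencing reports matches, directions and unmappable ids", {
  run <- test_pipeline_run()
  degs <- run$res$degs
  expect_equal(nrow(crossref_gene_lists(degs, tibble::tibble(gene_id = character()))), 0)
  d1 <- tidy(degs)[1, ]
  known <- tibble::tibble(
    gene_id = c(d1$feature_id, "NOT_A_GENE"),
    expected_direction = c(d1$direction, "up")
  )
  rep <- crossref_gene_lists(degs, known)
  expect_equal(nrow(rep), 2)
  expect_true(rep$mapped[1])
  expect_equal(rep$direction_agreement[1], "agree")
  expect_false(rep$mapped[2])
  # overlap count equals plain set intersection
  s <- test_study()
  set.seed(11)
  rand <- tibble::tibble(gene_id = sample(unique(s$gene_map$gene_id), 30))
  rep2 <- crossref_gene_lists(degs, rand)
  expect_equal(
    sum(!is.na(rep2$deg_direction)),
    nrow(dplyr::inner_join(rand, tidy(degs), by = c(gene_id = "feature_id")))
  )
})
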