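test_that("merging a set against a copy of itself yields all-PERFECT output", {
  truth <- simulate_truth(n_genes = 30, mode = "eukaryote", seed = 8)
  for (t in c(0.8, 1.0)) {
    res <- merge_predictions(
      set_strategy(truth, "ab_initio"), set_strategy(truth, "evidence"),
      merge_config(t, "eukaryote")
    )
    expect_equal(nrow(res$merged), nrow(ps_transcripts(truth)))
    expect_true(all(res$merged$support_class == "PERFECT"))
    expect_equal(nrow(res$unsupported_ab_initio), 0)
    expect_equal(nrow(res$unmatched_evidence), 0)
  }
})

test_that("method-unique false positives are filtered out of the consensus", {
  fx <- filtering_fixture(seed = 101L)
  res <- merge_predictions(fx$ab, fx$ev, merge_config(0.8, "prokaryote"))
  merged <- merged_prediction_set(res)
  ev_report <- evaluate_predictions(fx$ev, fx$expressed, level = "exon")
  ab_report <- evaluate_predictions(fx$ab, fx$expressed, level = "exon")
  m_report <- evaluate_predictions(merged, fx$expressed, level = "exon")
  expect_equal(m_report$specificity, 1.0)
  expect_gt(m_report$specificity, ab_report$specificity)
  expect_gt(m_report$specificity, ev_report$specificity)
  # every truth gene predicted by both strategies is retained
  kept_true <- intersect(
    perturb_manifest(fx$ab)$gene_id[perturb_manifest(fx$ab)$origin == "true"],
    perturb_manifest(fx$ev)$gene_id[perturb_manifest(fx$ev)$origin == "true"]
  )
  kept_true <- intersect(kept_true, unique(fx$expressed$gene_id))
  expect_equal(nrow(res$merged), length(kept_true))
  # and no method-unique false positive survives the merge
  fp_ids <- c(
    perturb_manifest(fx$ab)$gene_id[perturb_manifest(fx$ab)$origin == "fp"],
    perturb_manifest(fx$ev)$gene_id[perturb_manifest(fx$ev)$origin == "fp"]
  )
  source_gene_ids <- unlist(purrr::map(res$merged$sources, "gene_id"))
  expect_length(intersect(source_gene_ids, fp_ids), 0)
})

test_that("every merged record traces to both strategies (or 2+ evidence)", {
  fx <- filtering_fixture(seed = 55L)
  res <- merge_predictions(fx$ab, fx$ev, merge_config(0.8, "prokaryote"))
  expect_gt(nrow(res$merged), 0)
  ok <- purrr::map_lgl(seq_len(nrow(res$merged)), function(i) {
    src <- res$merged$sources[[i]]
    cls <- res$merged$support_class[i]
    if (cls == "NOVEL_EVIDENCE") {
      dplyr::n_distinct(src$method) >= 2 && !"abinit" %in% src$method
    } else {
      "abinit" %in% src$method && any(src$method != "abinit")
    }
  })
  expect_true(all(ok))
  expect_equal(res$merged$score,
               unname(res$config$score_map[res$merged$support_class]))
})

test_that("supported set shrinks as the threshold rises", {
  truth <- simulate_truth(n_genes = 40, mode = "eukaryote", seed = 77)
  ev <- perturb_predictions(
    truth,
    error_profile("cuff", "evidence", boundary_jitter_sd = 4,
                  exon_drop_rate = 0.05),
    seed = 78
  )
  ab <- set_strategy(truth, "ab_initio")
  counts <- vapply(seq(0.5, 1.0, by = 0.1), function(t) {
    nrow(merge_predictions(ab, ev, merge_config(t, "eukaryote"))$merged)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("permuting evidence sets does not change the consensus", {
  truth <- simulate_truth(n_genes = 30, mode = "prokaryote", seed = 300)
  expressed <- sample_expressed(truth, 0.7, seed = 301)
  pools <- fp_pools(intergenic_gaps(truth), 3)
  ab <- perturb_predictions(
    truth, error_profile("ab", "ab_initio", drop_rate = 0.1, fp_rate = 0.2),
    seed = 302, fp_pool = pools[[1]]
  )
  ev1 <- perturb_predictions(
    expressed, error_profile("ev1", "evidence", fp_rate = 0.2),
    seed = 303, fp_pool = pools[[2]]
  )
  ev2 <- perturb_predictions(
    expressed, error_profile("ev2", "evidence", drop_rate = 0.2),
    seed = 304, fp_pool = pools[[3]]
  )
  cfg <- merge_config(0.8, "prokaryote", include_novel = TRUE)
  r12 <- merge_predictions(ab, list(ev1, ev2), cfg)
  r21 <- merge_predictions(ab, list(ev2, ev1), cfg)
  key <- function(r) {
    d <- tidy(r)[, c("seqid", "start", "end", "strand", "support_class")]
    dplyr::arrange(d, .data$seqid, .data$start)
  }
  expect_equal(key(r12), key(r21))
})

test_that("novel genes need concordant support from 2+ evidence methods", {
  cfg <- merge_config(0.8, "prokaryote", include_novel = TRUE)
  ab <- ps_single(0, 1000, gene_id = "gA", transcript_id = "gA.t1",
                  method = "ab", strategy = "ab_initio")
  shared <- tibble::tibble(
    seqid = "chr1", start = c(5000L, 0L), end = c(6000L, 900L),
    strand = "+", gene_id = c("n1", "o1"),
    transcript_id = c("n1.t1", "o1.t1")
  )
  # n1: in both evidence sets, away from ab initio -> novel
  # u1: only in ev1 -> not novel
  # o1: in both evidence sets but fully covered by the ab initio gene
  #     (and itself covering 0.9 of it) -> handled in the main pass
  ev1 <- prediction_set(dplyr::bind_rows(
    shared,
    tibble::tibble(seqid = "chr1", start = 20000L, end = 21000L,
                   strand = "+", gene_id = "u1", transcript_id = "u1.t1")
  ), method = "ev1", strategy = "evidence")
  ev2 <- prediction_set(shared, method = "ev2", strategy = "evidence")

  novel <- find_novel(list(ev1, ev2), list(ab), cfg)
  expect_equal(nrow(novel), 1)
  expect_equal(novel$start, 5000L)
  expect_setequal(novel$sources[[1]]$method, c("ev1", "ev2"))
  expect_equal(novel$support_class, "NOVEL_EVIDENCE")

  # o1 covers 900/1000 of the ab initio gene -> main pass, not novel;
  # the full merge reports it once, as a supported leading record
  res <- merge_predictions(ab, list(ev1, ev2), cfg)
  expect_setequal(res$merged$support_class,
                  c("SUPPORTED", "NOVEL_EVIDENCE"))

  expect_error(find_novel(list(ev1), list(ab), cfg), "two evidence")
})

test_that("merge validates strategy tagging and empty input", {
  a <- ps_single(0, 100, method = "m1", strategy = "ab_initio")
  b <- ps_single(0, 100, gene_id = "g2", transcript_id = "g2.t1",
                 method = "m2", strategy = "ab_initio")
  expect_error(merge_predictions(a, b, merge_config()), "not recommended")

  empty <- prediction_set(tibble::tibble(
    seqid = character(0), start = integer(0), end = integer(0),
    strand = character(0), gene_id = character(0),
    transcript_id = character(0)
  ), method = "ab", strategy = "ab_initio")
  ev <- set_strategy(b, "evidence")
  expect_warning(res <- merge_predictions(empty, ev, merge_config()), "empty")
  expect_equal(nrow(res$merged), 0)
  expect_equal(nrow(res$unmatched_evidence) > 0, TRUE)
})

test_that("strand policy controls cross-strand and unstranded support", {
  lead <- ps_single(0, 1000, strand = "+", method = "ab",
                    strategy = "ab_initio")
  ev_minus <- ps_single(0, 1000, strand = "-", gene_id = "e",
                        transcript_id = "e.t1", method = "ev",
                        strategy = "evidence")
  ev_dot <- ps_single(0, 1000, strand = ".", gene_id = "e",
                      transcript_id = "e.t1", method = "ev",
                      strategy = "evidence")
  cls <- function(ev, policy) {
    classify_locus_prok(
      lead, list(ev), merge_config(0.8, "prokaryote", strand_policy = policy)
    )$support_class
  }
  expect_equal(cls(ev_minus, "require_match"), "UNSUPPORTED")
  expect_equal(cls(ev_dot, "require_match"), "UNSUPPORTED")
  expect_equal(cls(ev_dot, "ignore_unstranded"), "PERFECT")
  expect_equal(cls(ev_minus, "ignore_unstranded"), "UNSUPPORTED")
  expect_equal(cls(ev_minus, "ignore_all"), "PERFECT")
})

test_that("merge outputs four files with consistent provenance", {
  fx <- filtering_fixture(seed = 202L)
  res <- merge_predictions(fx$ab, fx$ev, merge_config(0.8, "prokaryote"))
  dir <- withr::local_tempdir()
  paths <- write_merge_outputs(res, dir)
  expect_true(all(file.exists(paths)))
  merged_back <- read_gtf(paths[["merged"]])
  expect_equal(dplyr::n_distinct(merged_back$gene_id), nrow(res$merged))
  side_ab <- read_gtf(paths[["unsupported_ab_initio"]])
  side_ev <- read_gtf(paths[["unmatched_evidence"]])
  # side sets and consensus partition the leading input
  expect_equal(
    dplyr::n_distinct(side_ab$transcript_id) +
      sum(res$merged$origin == "leading"),
    nrow(ps_transcripts(fx$ab))
  )
  expect_gt(nrow(side_ev), 0)
})
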