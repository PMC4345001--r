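test_that("prokaryotic classification distinguishes perfect, supported, unsupported", {
  lead <- ps_single(0, 1000, gene_id = "gL", transcript_id = "gL.t1",
                    method = "ab", strategy = "ab_initio")
  cfg <- merge_config(0.8, "prokaryote")

  identical_ev <- ps_single(0, 1000, gene_id = "gE", transcript_id = "gE.t1",
                            method = "ev", strategy = "evidence")
  res <- classify_locus_prok(lead, list(identical_ev), cfg)
  expect_equal(res$support_class, "PERFECT")
  expect_equal(res$sources$transcript_id, "gE.t1")

  # 810 of 1000 nt covered: 0.81 > 0.8
  partial_ev <- ps_single(0, 810, gene_id = "gE", transcript_id = "gE.t1",
                          method = "ev", strategy = "evidence")
  expect_equal(classify_locus_prok(lead, list(partial_ev), cfg)$support_class,
               "SUPPORTED")

  none <- ps_single(5000, 6000, gene_id = "gF", transcript_id = "gF.t1",
                    method = "ev", strategy = "evidence")
  expect_equal(classify_locus_prok(lead, list(none), cfg)$support_class,
               "UNSUPPORTED")
})

test_that("an overlap of exactly t is not supporting (strict inequality)", {
  lead <- ps_single(0, 1000, method = "ab", strategy = "ab_initio")
  boundary <- ps_single(0, 800, gene_id = "gE", transcript_id = "gE.t1",
                        method = "ev", strategy = "evidence")
  res <- classify_locus_prok(lead, list(boundary),
                             merge_config(0.8, "prokaryote"))
  expect_equal(res$support_class, "UNSUPPORTED")
  # one nucleotide more crosses the threshold
  above <- ps_single(0, 801, gene_id = "gE", transcript_id = "gE.t1",
                     method = "ev", strategy = "evidence")
  expect_equal(
    classify_locus_prok(lead, list(above),
                        merge_config(0.8, "prokaryote"))$support_class,
    "SUPPORTED"
  )
})

test_that("tied supporting evidence transcripts are all reported as sources", {
  lead <- ps_single(0, 1000, method = "ab", strategy = "ab_initio")
  ev1 <- ps_single(0, 900, gene_id = "a", transcript_id = "a.t1",
                   method = "ev1", strategy = "evidence")
  ev2 <- ps_single(100, 1000, gene_id = "b", transcript_id = "b.t1",
                   method = "ev2", strategy = "evidence")
  res <- classify_locus_prok(lead, list(ev1, ev2),
                             merge_config(0.8, "prokaryote"))
  expect_equal(res$support_class, "SUPPORTED")
  expect_setequal(res$sources$method, c("ev1", "ev2"))
})

test_that("eukaryotic classification covers the full class ladder", {
  cfg <- merge_config(0.8, "eukaryote")
  lead <- ps_single(c(0, 500, 1000), c(100, 650, 1200),
                    method = "ab", strategy = "ab_initio")

  exact <- ps_single(c(0, 500, 1000), c(100, 650, 1200), gene_id = "e",
                     transcript_id = "e.t1", method = "ev",
                     strategy = "evidence")
  expect_equal(classify_transcript_euk(lead, list(exact), cfg)$support_class,
               "PERFECT")

  # one boundary off by 3 nt but every exon matched within t
  near <- ps_single(c(0, 500, 1000), c(100, 650, 1197), gene_id = "e",
                    transcript_id = "e.t1", method = "ev",
                    strategy = "evidence")
  res <- classify_transcript_euk(lead, list(near), cfg)
  expect_equal(res$support_class, "SUPPORTED")

  # only 2 of 3 exons matched; candidate has 3 exons with 2 matched:
  # k=2 >= floor(0.8*3)=2 on both sides -> PARTIAL_ACCEPTED
  partial <- ps_single(c(0, 500, 2000), c(100, 650, 2100), gene_id = "e",
                       transcript_id = "e.t1", method = "ev",
                       strategy = "evidence")
  expect_equal(classify_transcript_euk(lead, list(partial), cfg)$support_class,
               "PARTIAL_ACCEPTED")

  none <- ps_single(5000, 5100, gene_id = "e", transcript_id = "e.t1",
                    method = "ev", strategy = "evidence")
  expect_equal(classify_transcript_euk(lead, list(none), cfg)$support_class,
               "UNSUPPORTED")
})

test_that("PARTIAL_ACCEPTED requires the exon-count rule on both sides", {
  cfg <- merge_config(0.8, "eukaryote")
  # leading 2 exons, candidate 5 exons, only 1 shared: the leading side
  # passes (1 >= floor(0.8*2) = 1) but the candidate side fails
  # (1 < floor(0.8*5) = 4) -> rejected
  lead <- ps_single(c(0, 500), c(100, 650), method = "ab",
                    strategy = "ab_initio")
  cand <- ps_single(c(0, 1000, 2000, 3000, 4000),
                    c(100, 1100, 2100, 3100, 4100),
                    gene_id = "e", transcript_id = "e.t1",
                    method = "ev", strategy = "evidence")
  expect_equal(classify_transcript_euk(lead, list(cand), cfg)$support_class,
               "UNSUPPORTED")

  # positive control: 5-exon leading, candidate with 5 exons of which 4
  # match -> k = 4 >= floor(0.8*5) = 4 on both sides -> PARTIAL_ACCEPTED
  lead5 <- ps_single(seq(0, 4000, by = 1000), seq(100, 4100, by = 1000),
                     method = "ab", strategy = "ab_initio")
  cand5 <- ps_single(c(seq(0, 3000, by = 1000), 8000),
                     c(seq(100, 3100, by = 1000), 8100),
                     gene_id = "e", transcript_id = "e.t1",
                     method = "ev", strategy = "evidence")
  expect_equal(classify_transcript_euk(lead5, list(cand5), cfg)$support_class,
               "PARTIAL_ACCEPTED")
})

test_that("concordant evidence replaces a disagreeing leading transcript", {
  fx <- conflict_fixture()
  cfg <- merge_config(0.8, "eukaryote")
  res <- classify_transcript_euk(fx$leading, list(fx$ev_a, fx$ev_b), cfg)
  expect_equal(res$support_class, "SUPPORTED")
  expect_false(is.null(res$replacements))
  expect_setequal(res$sources$method, c("evA", "evB"))
})

test_that("conflict resolution keeps the leading transcript when evidence disagrees", {
  cfg <- merge_config(0.8, "eukaryote")
  lead <- ps_single(c(0, 500, 1000), c(100, 650, 1200),
                    gene_id = "gL", transcript_id = "gL.t1",
                    method = "ab", strategy = "ab_initio")
  # ev_a shares 2 of 3 leading exons (both sides pass k >= floor(t*n));
  # ev_b is a different structure disagreeing with both
  ev_a <- ps_single(c(0, 500, 2000), c(100, 650, 2100), gene_id = "gA",
                    transcript_id = "gA.t1", method = "evA",
                    strategy = "evidence")
  ev_b <- ps_single(c(40, 900), c(400, 1100), gene_id = "gB",
                    transcript_id = "gB.t1", method = "evB",
                    strategy = "evidence")
  res <- resolve_conflict(lead, list(ev_a, ev_b), cfg)
  expect_equal(res$decision, "keep_leading")
  expect_equal(res$chosen$method, "evA")

  # neither candidate meets the exon-count rule with the leading transcript
  ev_c <- ps_single(c(40, 900), c(250, 1150), gene_id = "gC",
                    transcript_id = "gC.t1", method = "evC",
                    strategy = "evidence")
  res2 <- resolve_conflict(lead, list(ev_b, ev_c), cfg)
  expect_equal(res2$decision, "undecided")

  expect_error(resolve_conflict(lead, list(ev_a), cfg), ">= 2")
})
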