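# Shared fixture builders and independent brute-force oracles.

# Quick single-transcript prediction set from an exon matrix / vectors.
ps_single <- function(starts, ends, strand = "+", seqid = "chr1",
                      gene_id = "g1", transcript_id = "g1.t1",
                      method = "m", strategy = NA_character_) {
  prediction_set(
    tibble::tibble(
      seqid = seqid, start = as.integer(starts), end = as.integer(ends),
      strand = strand, gene_id = gene_id, transcript_id = transcript_id
    ),
    method = method, strategy = strategy
  )
}

exon_mat <- function(starts, ends) {
  cbind(start = as.integer(starts), end = as.integer(ends))
}

# Random disjoint sorted exon chain on a small coordinate range.
random_chain <- function(n_exons, max_len = 30L, max_gap = 20L,
                         origin = NULL) {
  origin <- origin %||% sample(0:40, 1)
  lens <- sample(1:max_len, n_exons, replace = TRUE)
  gaps <- sample(1:max_gap, n_exons, replace = TRUE)
  starts <- origin + cumsum(gaps) + c(0L, cumsum(lens[-n_exons]))
  exon_mat(starts, starts + lens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle 1: nucleotide-position-set overlap. Enumerates every covered
# position of both exon sets and counts the intersection directly.
positions_of <- function(ex) {
  unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq(ex[i, "start"], ex[i, "end"] - 1L)
  }))
}

oracle_overlap_fraction <- function(leading, other) {
  lp <- positions_of(leading)
  length(intersect(lp, positions_of(other))) / length(lp)
}

# Oracle 2: maximum order-preserving (non-crossing) matching size, by plain
# recursion over all pairings. A leading/candidate exon pair is matchable
# when boundaries are identical or the shared nucleotides exceed t of the
# leading exon's length.
oracle_max_matching <- function(leading, candidate, t) {
  n <- nrow(leading); m <- nrow(candidate)
  matchable <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ov <- min(leading[i, "end"], candidate[j, "end"]) -
        max(leading[i, "start"], candidate[j, "start"])
      exact <- leading[i, "start"] == candidate[j, "start"] &&
        leading[i, "end"] == candidate[j, "end"]
      matchable[i, j] <- exact ||
        (ov / (leading[i, "end"] - leading[i, "start"])) > t
    }
  }
  rec <- function(i, jmin) {
    if (i > n || jmin > m) return(0L)
    best <- rec(i + 1L, jmin)  # leave leading exon i unmatched
    for (j in jmin:m) {
      if (matchable[i, j]) best <- max(best, 1L + rec(i + 1L, j + 1L))
    }
    best
  }
  rec(1L, 1L)
}

# Model equality up to row order: identical exon tables after sorting
# (container attributes such as method/strategy are not part of the model).
expect_same_model <- function(a, b) {
  cols <- c("seqid", "start", "end", "strand", "gene_id", "transcript_id",
            "exon_rank")
  norm <- function(x) {
    key <- c("seqid", "transcript_id", "start")
    tb <- dplyr::arrange(tibble::as_tibble(x),
                         dplyr::across(dplyr::all_of(key)))
    lapply(as.list(tb)[cols], function(col) `attributes<-`(col, NULL))
  }
  expect_equal(norm(a), norm(b))
}

# Shared hand-built eukaryotic conflict fixture: a leading transcript whose
# terminal exon is extended past the true boundary, and two evidence methods
# that both predict the correct structure.
conflict_fixture <- function() {
  list(
    leading = ps_single(c(100, 500, 900), c(200, 600, 1050),
                        gene_id = "gL", transcript_id = "gL.t1",
                        method = "abinit", strategy = "ab_initio"),
    ev_a = ps_single(c(100, 500, 900), c(200, 600, 1000),
                     gene_id = "gA", transcript_id = "gA.t1",
                     method = "evA", strategy = "evidence"),
    ev_b = ps_single(c(100, 500, 900), c(200, 600, 1000),
                     gene_id = "gB", transcript_id = "gB.t1",
                     method = "evB", strategy = "evidence")
  )
}

# Standard prokaryotic filtering fixture (used by merge tests and the
# acceptance suite): 200 genes, 70% expressed, method-unique false
# positives drawn from disjoint intergenic pools of the full truth.
filtering_fixture <- function(seed = 101L) {
  truth <- simulate_truth(n_genes = 200, mode = "prokaryote", seed = seed)
  expressed <- sample_expressed(truth, 0.7, seed = seed + 1L)
  pools <- fp_pools(intergenic_gaps(truth), 2)
  ab <- perturb_predictions(
    truth,
    error_profile("abinit", "ab_initio", drop_rate = 0.05, fp_rate = 0.3),
    seed = seed + 2L, fp_pool = pools[[1]]
  )
  ev <- perturb_predictions(
    expressed,
    error_profile("rnaseq", "evidence", drop_rate = 0.1, fp_rate = 0.3),
    seed = seed + 3L, fp_pool = pools[[2]]
  )
  list(truth = truth, expressed = expressed, ab = ab, ev = ev)
}

cli_path <- function() system.file("cli", "genemerge.R", package = "genemerge")

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(cli_path(), ...), stdout = TRUE, stderr = TRUE)
  )
  list(status = attr(out, "status") %||% 0L, output = out)
}
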