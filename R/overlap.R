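#' Exonic overlap fraction of an evidence prediction over a leading prediction
#'
#' The fraction of the leading (ab initio) transcript's exonic nucleotides
#' that are also covered by exons of the other transcript. The denominator is
#' always the leading transcript's exonic length, so the fraction measures
#' how much of the ab initio prediction is supported, regardless of how much
#' extra sequence the other prediction contains.
#'
#' @param leading,other Exon tables: either a `prediction_set`/tibble holding
#'   exactly one transcript, or a two-column matrix with columns `start`,
#'   `end` (0-based half-open). Matrices are assumed to share a seqid.
#' @param leading_seqid,other_seqid Seqids, required only for matrix input if
#'   they may differ. Transcripts on different seqids have fraction 0.
#' @return A single number in \[0, 1\].
#' @export
exonic_overlap_fraction <- function(leading, other,
                                    leading_seqid = NULL, other_seqid = NULL) {
  lm <- as_exon_matrix(leading)
  om <- as_exon_matrix(other)
  ls <- leading_seqid %||% attr(lm, "seqid")
  os <- other_seqid %||% attr(om, "seqid")
  if (!is.null(ls) && !is.null(os) && !identical(ls, os)) return(0)
  exon_matrix_overlap(lm, om) / sum(lm[, "end"] - lm[, "start"])
}

as_exon_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(c("start", "end") %in% colnames(x)))
    m <- x[, c("start", "end"), drop = FALSE]
    return(m[order(m[, "start"]), , drop = FALSE])
  }
  tb <- tibble::as_tibble(x)
  if (dplyr::n_distinct(tb$transcript_id) != 1) {
    rlang::abort("expected exactly one transcript")
  }
  tb <- dplyr::arrange(tb, .data$start)
  m <- cbind(start = tb$start, end = tb$end)
  attr(m, "seqid") <- tb$seqid[1]
  m
}

# Shared nucleotides between two sets of disjoint sorted intervals: because
# exons within a transcript are disjoint, the intersection of the two unions
# is the sum of pairwise intersections.
exon_matrix_overlap <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a[i, "end"], b[, "end"]) - pmax(a[i, "start"], b[, "start"])
    tot <- tot + sum(ov[ov > 0])
  }
  tot
}

#' Match the exon chains of two transcripts
#'
#' Pairs exons of a leading transcript with exons of a candidate transcript
#' by genomic overlap, preserving order (no crossing pairs; each exon pairs
#' with at most one exon on the other side). A pair is `EXACT` when both
#' boundaries are identical and `PARTIAL` when the shared nucleotides exceed
#' the threshold fraction of the leading exon's length; otherwise the leading
#' exon is `UNMATCHED`. The pairing is the exact maximum non-crossing
#' matching (dynamic programme maximising matched pairs, then exact pairs,
#' then shared nucleotides), so chain similarity never depends on greedy
#' tie-breaking.
#'
#' @param leading,candidate Exon matrices or single-transcript exon tables
#'   (as in [exonic_overlap_fraction()]).
#' @param config A [merge_config()]; only `threshold` is used here.
#' @return A `chain_match` list: `n` (leading exon count), `k` (matched
#'   pairs), `n_candidate`, `per_exon` (status per leading exon),
#'   `all_exact`, `all_matched`, `pairs` (two-column matrix of paired
#'   indices).
#' @export
match_exon_chain <- function(leading, candidate, config = merge_config()) {
  lm <- as_exon_matrix(leading)
  cm <- as_exon_matrix(candidate)
  t <- config$threshold
  n <- nrow(lm); m <- nrow(cm)

  # Pair status and weight for every (leading, candidate) exon pair.
  ov <- matrix(0, n, m)
  for (i in seq_len(n)) {
    o <- pmin(lm[i, "end"], cm[, "end"]) - pmax(lm[i, "start"], cm[, "start"])
    ov[i, ] <- pmax(o, 0)
  }
  exact <- outer(lm[, "start"], cm[, "start"], "==") &
    outer(lm[, "end"], cm[, "end"], "==")
  llen <- lm[, "end"] - lm[, "start"]
  partial <- !exact & (ov / llen) > t
  matchable <- exact | partial

  # Non-crossing maximum matching, lexicographic objective
  # (matched, exact, overlap); LCS-style DP over (i, j) prefixes.
  M <- matrix(0L, n + 1, m + 1)   # matched pairs
  E <- matrix(0L, n + 1, m + 1)   # exact pairs
  W <- matrix(0, n + 1, m + 1)    # total shared nucleotides
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- c(M[i, j + 1], E[i, j + 1], W[i, j + 1])
      alt <- c(M[i + 1, j], E[i + 1, j], W[i + 1, j])
      if (lex_gt(alt, best)) best <- alt
      if (matchable[i, j]) {
        alt <- c(M[i, j] + 1L, E[i, j] + as.integer(exact[i, j]),
                 W[i, j] + ov[i, j])
        if (lex_gt(alt, best)) best <- alt
      }
      M[i + 1, j + 1] <- as.integer(best[1])
      E[i + 1, j + 1] <- as.integer(best[2])
      W[i + 1, j + 1] <- best[3]
    }
  }
  # Traceback.
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("leading", "candidate")))
  status <- rep("UNMATCHED", n)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    cur <- c(M[i + 1, j + 1], E[i + 1, j + 1], W[i + 1, j + 1])
    took <- matchable[i, j] &&
      isTRUE(all.equal(cur, c(M[i, j] + 1L, E[i, j] + as.integer(exact[i, j]),
                              W[i, j] + ov[i, j])))
    if (took) {
      pairs <- rbind(c(i, j), pairs)
      status[i] <- if (exact[i, j]) "EXACT" else "PARTIAL"
      i <- i - 1; j <- j - 1
    } else if (identical(cur, c(M[i, j + 1], E[i, j + 1], W[i, j + 1]))) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  k <- sum(status != "UNMATCHED")
  structure(
    list(
      n = n, k = k, n_candidate = m, per_exon = status,
      all_exact = k == n && m == n && all(status == "EXACT"),
      all_matched = k == n,
      pairs = pairs
    ),
    class = "chain_match"
  )
}

lex_gt <- function(a, b) {
  if (a[1] != b[1]) return(a[1] > b[1])
  if (a[2] != b[2]) return(a[2] > b[2])
  a[3] > b[3]
}

#' Exon-count acceptance rule
#'
#' A partially matched transcript is acceptable when the number of matched
#' exons `k` reaches `floor(t * n)` of the total exon count `n`. Note the
#' asymmetry with the nucleotide-overlap test: the integer exon-count rule is
#' `>=` (with floor), the nucleotide-fraction rule is strictly `>`.
#'
#' @param match A `chain_match` from [match_exon_chain()], or `NULL` if `k`
#'   and `n` are given directly.
#' @param config A [merge_config()].
#' @param k,n Override the match's counts (used for the candidate side of
#'   the both-sides rule).
#' @return `TRUE` when `k >= floor(t * n)`.
#' @export
accept_by_exon_count <- function(match = NULL, config = merge_config(),
                                 k = NULL, n = NULL) {
  k <- k %||% match$k
  n <- n %||% match$n
  k >= floor(config$threshold * n)
}

# Both sides of a chain match must satisfy the exon-count rule: the leading
# transcript (k of n) and the chosen candidate (k of n_candidate).
accept_both_sides <- function(match, config) {
  accept_by_exon_count(config = config, k = match$k, n = match$n) &&
    accept_by_exon_count(config = config, k = match$k, n = match$n_candidate)
}
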