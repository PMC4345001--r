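#' Classify a prokaryotic leading locus against evidence predictions
#'
#' Locus-level support test for single-exon (prokaryotic) genes: `PERFECT`
#' when some evidence transcript has identical exon boundaries, else
#' `SUPPORTED` when the best exonic overlap fraction strictly exceeds the
#' threshold, else `UNSUPPORTED`. All evidence transcripts above threshold
#' (ties included) are reported as sources.
#'
#' @param leading One row of an engine transcript table (see details), or a
#'   single-transcript `prediction_set`.
#' @param evidence_sets A list of evidence-tagged [prediction_set()]s.
#' @param config A [merge_config()].
#' @return A list with `support_class` and `sources` (tibble of method,
#'   gene_id, transcript_id).
#' @export
classify_locus_prok <- function(leading, evidence_sets, config = merge_config()) {
  lead <- as_lead_tx(leading)
  ev <- bind_evidence_tx(evidence_sets)
  classify_prok_tx(lead, ev, config)
}

#' Classify a eukaryotic leading transcript against evidence predictions
#'
#' Exon-chain support test for one leading transcript: `PERFECT` when some
#' evidence transcript matches every exon with identical boundaries (and has
#' no extra exons); `SUPPORTED` when some evidence transcript matches every
#' leading exon within the threshold; otherwise conflict resolution between
#' the overlapping evidence transcripts decides between `SUPPORTED`
#' replacement records, `PARTIAL_ACCEPTED` (both-sides exon-count rule) and
#' `UNSUPPORTED`.
#'
#' @inheritParams classify_locus_prok
#' @return A list with `support_class`, `sources`, and — when the leading
#'   transcript is rejected in favour of concordant evidence —
#'   `replacements` (an engine transcript tibble).
#' @export
classify_transcript_euk <- function(leading, evidence_sets,
                                    config = merge_config()) {
  lead <- as_lead_tx(leading)
  ev <- bind_evidence_tx(evidence_sets)
  classify_euk_tx(lead, ev, config)
}

as_lead_tx <- function(leading) {
  if (is.data.frame(leading) && "exons" %in% names(leading)) {
    stopifnot(nrow(leading) == 1)
    return(leading)
  }
  tx <- ps_transcripts(leading)
  if (nrow(tx) != 1) rlang::abort("expected exactly one leading transcript")
  tx$method <- attr(leading, "method") %||% "leading"
  tx
}

bind_evidence_tx <- function(evidence_sets) {
  if (is.data.frame(evidence_sets) && "exons" %in% names(evidence_sets)) {
    return(evidence_sets)  # already an engine transcript table
  }
  if (inherits(evidence_sets, "prediction_set")) {
    evidence_sets <- list(evidence_sets)
  }
  purrr::map_dfr(evidence_sets, function(ps) {
    if (is.data.frame(ps) && "exons" %in% names(ps) && "method" %in% names(ps)) {
      return(ps)  # already an engine transcript table
    }
    tx <- ps_transcripts(ps)
    tx$method <- attr(ps, "method") %||% "evidence"
    tx
  })
}

# lead: 1-row engine tx table; ev: engine tx table of candidate evidence
# transcripts (same seqid, strand-compatible rows are selected here).
classify_prok_tx <- function(lead, ev, config) {
  cand <- candidate_rows(lead, ev, config)
  if (nrow(cand) == 0) {
    return(list(support_class = "UNSUPPORTED", sources = empty_sources()))
  }
  frac <- purrr::map_dbl(cand$exons, ~ exon_matrix_overlap(lead$exons[[1]], .x) /
                           lead$exonic_length)
  identical_chain <- purrr::map_lgl(cand$exons, ~ same_chain(lead$exons[[1]], .x))
  supporting <- frac > config$threshold | identical_chain
  if (any(identical_chain)) {
    cls <- "PERFECT"
  } else if (any(frac > config$threshold)) {
    cls <- "SUPPORTED"
  } else {
    return(list(support_class = "UNSUPPORTED", sources = empty_sources()))
  }
  list(support_class = cls, sources = sources_of(cand[supporting, ]))
}

classify_euk_tx <- function(lead, ev, config) {
  cand <- candidate_rows(lead, ev, config)
  if (nrow(cand) == 0) {
    return(list(support_class = "UNSUPPORTED", sources = empty_sources()))
  }
  matches <- purrr::map(cand$exons, ~ match_exon_chain(lead$exons[[1]], .x, config))
  all_exact <- purrr::map_lgl(matches, "all_exact")
  all_matched <- purrr::map_lgl(matches, "all_matched")
  if (any(all_exact)) {
    return(list(support_class = "PERFECT", sources = sources_of(cand[all_exact, ])))
  }
  if (any(all_matched)) {
    return(list(support_class = "SUPPORTED",
                sources = sources_of(cand[all_matched, ])))
  }
  n_methods <- dplyr::n_distinct(cand$method)
  if (nrow(cand) >= 2 && n_methods >= 2) {
    res <- resolve_conflict(lead, cand, config, matches = matches)
    if (res$decision == "replace_with") {
      # Replacement records carry class SUPPORTED: concordant evidence, not a
      # boundary-identical confirmation of the (rejected) leading structure.
      return(list(support_class = "SUPPORTED", sources = sources_of(res$chosen),
                  replacements = res$chosen))
    }
    if (res$decision == "keep_leading") {
      return(list(support_class = "PARTIAL_ACCEPTED",
                  sources = sources_of(res$chosen)))
    }
    return(list(support_class = "UNSUPPORTED", sources = empty_sources()))
  }
  # Single overlapping evidence transcript: apply the both-sides exon-count
  # rule directly (conflict resolution needs two disagreeing candidates).
  ok <- purrr::map_lgl(matches, ~ .x$k > 0 && accept_both_sides(.x, config))
  if (any(ok)) {
    return(list(support_class = "PARTIAL_ACCEPTED",
                sources = sources_of(cand[ok, ])))
  }
  list(support_class = "UNSUPPORTED", sources = empty_sources())
}

#' Resolve a conflict between a leading transcript and overlapping evidence
#'
#' Invoked when no evidence transcript fully supports the leading transcript
#' but at least two evidence transcripts from distinct methods overlap it.
#' If the evidence transcripts agree with each other (mutually matched exon
#' chains at the same threshold) while each disagrees with the leading
#' transcript, the leading prediction is judged incorrect and the concordant
#' evidence structures replace it. If the evidence transcripts also disagree
#' among themselves, the leading transcript is kept only when it satisfies
#' the exon-count rule `k >= floor(t * n)` on both sides against one of them;
#' otherwise the case is undecided and the leading transcript ends up
#' unsupported.
#'
#' @param leading A 1-row engine transcript table or single-transcript
#'   `prediction_set`.
#' @param overlapping Evidence transcripts overlapping the leading span
#'   (engine transcript table or list of single-transcript sets), from at
#'   least 2 distinct methods.
#' @param config A [merge_config()].
#' @param matches Optional precomputed chain matches of leading vs each
#'   overlapping transcript.
#' @return A list with `decision` (`"replace_with"`, `"keep_leading"` or
#'   `"undecided"`) and `chosen` (the relevant evidence transcripts).
#' @export
resolve_conflict <- function(leading, overlapping, config = merge_config(),
                             matches = NULL) {
  lead <- as_lead_tx(leading)
  cand <- bind_evidence_tx(overlapping)
  if (nrow(cand) < 2 || dplyr::n_distinct(cand$method) < 2) {
    rlang::abort("conflict resolution requires >= 2 overlapping evidence transcripts from distinct methods")
  }
  cand <- dplyr::arrange(cand, .data$method, .data$transcript_id)
  if (is.null(matches)) {
    matches <- purrr::map(cand$exons, ~ match_exon_chain(lead$exons[[1]], .x, config))
  }
  # Agreement group: deterministically seed with the first cross-method pair
  # that mutually matches, then extend with candidates consistent with all
  # chosen members.
  mutual <- function(a, b) {
    match_exon_chain(cand$exons[[a]], cand$exons[[b]], config)$all_matched &&
      match_exon_chain(cand$exons[[b]], cand$exons[[a]], config)$all_matched
  }
  group <- integer(0)
  nc <- nrow(cand)
  for (a in seq_len(nc - 1)) {
    for (b in seq((a + 1), nc)) {
      if (cand$method[a] != cand$method[b] && mutual(a, b)) {
        group <- c(a, b)
        break
      }
    }
    if (length(group) > 0) break
  }
  if (length(group) > 0) {
    for (x in setdiff(seq_len(nc), group)) {
      if (all(purrr::map_lgl(group, ~ mutual(.x, x)))) group <- c(group, x)
    }
    return(list(decision = "replace_with", chosen = cand[sort(group), ]))
  }
  ok <- purrr::map_lgl(matches, ~ .x$k > 0 && accept_both_sides(.x, config))
  if (any(ok)) {
    return(list(decision = "keep_leading", chosen = cand[ok, ]))
  }
  list(decision = "undecided", chosen = cand[0, ])
}

candidate_rows <- function(lead, ev, config) {
  if (nrow(ev) == 0) return(ev)
  keep <- ev$seqid == lead$seqid &
    ev$tx_start < lead$tx_end & ev$tx_end > lead$tx_start &
    strands_compatible(ev$strand, lead$strand, config$strand_policy)
  dplyr::arrange(ev[keep, ], .data$method, .data$transcript_id)
}

same_chain <- function(a, b) {
  nrow(a) == nrow(b) && all(a[, "start"] == b[, "start"]) &&
    all(a[, "end"] == b[, "end"])
}

sources_of <- function(cand) {
  tibble::tibble(
    method = cand$method, gene_id = cand$gene_id,
    transcript_id = cand$transcript_id
  ) |> dplyr::arrange(.data$method, .data$transcript_id)
}

empty_sources <- function() {
  tibble::tibble(method = character(0), gene_id = character(0),
                 transcript_id = character(0))
}
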