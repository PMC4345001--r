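#' Merge ab initio and evidence-based gene predictions
#'
#' The combination engine. Iterates over the ab initio ("leading")
#' transcripts and tests each for support by the evidence-based predictions:
#' in prokaryotic mode by exonic-overlap fraction at the locus level, in
#' eukaryotic mode by order-preserving exon-chain matching, including
#' conflict resolution when overlapping evidence transcripts agree with each
#' other but not with the leading prediction. Supported transcripts become
#' consensus records classified `PERFECT`, `SUPPORTED` or `PARTIAL_ACCEPTED`;
#' unsupported ab initio transcripts and evidence transcripts that supported
#' nothing are returned as side sets; optionally, genes absent from the ab
#' initio output but concordantly predicted by at least
#' `config$min_evidence_for_novel` evidence methods are appended as
#' `NOVEL_EVIDENCE` records. The engine is fully deterministic.
#'
#' @param ab_initio One [prediction_set()] or a list of them (strategy
#'   `"ab_initio"`; untagged sets are tagged on entry).
#' @param evidence One prediction set or a list (strategy `"evidence"`).
#' @param config A [merge_config()].
#' @return A `genemerge_result`: list with `merged` (tibble of consensus
#'   records: `merged_id`, coordinates, `support_class`, `score`, `origin`,
#'   list columns `exons` and `sources`), `tracking` (provenance tibble),
#'   `unsupported_ab_initio` and `unmatched_evidence` (side prediction
#'   sets), and `config`.
#' @examples
#' truth <- simulate_truth(n_genes = 20, mode = "prokaryote", seed = 1)
#' ab <- set_strategy(truth, "ab_initio")
#' ev <- set_strategy(truth, "evidence")
#' res <- merge_predictions(ab, ev)
#' glance(res)
#' @export
merge_predictions <- function(ab_initio, evidence, config = merge_config()) {
  ab_sets <- as_set_list(ab_initio, "ab_initio")
  ev_sets <- as_set_list(evidence, "evidence")
  tags <- c(purrr::map_chr(ab_sets, ps_strategy),
            purrr::map_chr(ev_sets, ps_strategy))
  if (length(tags) > 1 && dplyr::n_distinct(tags) == 1) {
    rlang::abort(paste0(
      "all inputs carry the same strategy tag ('", tags[1], "'); ",
      "combining ab initio with ab initio methods is not recommended - ",
      "tag one category as 'evidence'"
    ))
  }
  if (length(ev_sets) == 0) rlang::abort("at least one evidence set is required")

  ev_tx <- bind_evidence_tx(ev_sets)
  lead_tx <- purrr::map_dfr(ab_sets, function(ps) {
    tx <- ps_transcripts(ps)
    tx$method <- ps_method(ps)
    tx
  })
  if (config$mode == "prokaryote" && nrow(lead_tx) > 0) {
    multi <- lead_tx |>
      dplyr::count(.data$method, .data$gene_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(multi) > 0) {
      rlang::warn(paste0(
        nrow(multi), " multi-transcript locus/loci in prokaryotic mode; ",
        "transcripts are tested individually"
      ))
    }
  }
  if (nrow(lead_tx) == 0 && !config$include_novel) {
    rlang::warn("no ab initio transcripts and include_novel = FALSE: empty result")
    return(new_merge_result(empty_records(), ab_sets, ev_sets, ev_tx,
                            used = character(0), unsupported = lead_tx,
                            config = config))
  }

  hit_idx <- span_overlap_hits(lead_tx, ev_tx)
  records <- list()
  unsupported_rows <- integer(0)
  used_evidence <- character(0)   # "method|transcript_id" of consumed supporters
  consumed_repl <- character(0)   # replacement structures already emitted

  for (i in seq_len(nrow(lead_tx))) {
    lead <- lead_tx[i, ]
    cand <- ev_tx[hit_idx[[i]], ]
    cand <- candidate_rows(lead, cand, config)
    res <- if (config$mode == "prokaryote") {
      classify_prok_tx(lead, cand, config)
    } else {
      classify_euk_tx(lead, cand, config)
    }
    if (res$support_class == "UNSUPPORTED") {
      unsupported_rows <- c(unsupported_rows, i)
      next
    }
    used_evidence <- c(used_evidence,
                       paste(res$sources$method, res$sources$transcript_id,
                             sep = "|"))
    if (!is.null(res$replacements)) {
      # The leading prediction is judged incorrect; emit the concordant
      # evidence structures instead (each structure once per merge run).
      repl <- res$replacements
      keys <- paste(repl$method, repl$transcript_id, sep = "|")
      fresh <- !keys %in% consumed_repl
      consumed_repl <- c(consumed_repl, keys[fresh])
      repl <- repl[fresh, ]
      if (nrow(repl) > 0) {
        sig <- purrr::map_chr(seq_len(nrow(repl)), function(j) {
          chain_signature(repl$seqid[j], repl$strand[j], repl$exons[[j]])
        })
        for (s in unique(sig)) {
          r <- repl[sig == s, ][1, ]
          records[[length(records) + 1]] <- record_row(
            r, support_class = "SUPPORTED", origin = "replacement",
            sources = res$sources
          )
        }
      }
      next
    }
    lead_source <- tibble::tibble(
      method = lead$method, gene_id = lead$gene_id,
      transcript_id = lead$transcript_id
    )
    records[[length(records) + 1]] <- record_row(
      lead, support_class = res$support_class, origin = "leading",
      sources = dplyr::bind_rows(lead_source, res$sources)
    )
  }

  if (config$include_novel) {
    novel <- find_novel(ev_sets, ab_sets, config)
    for (j in seq_len(nrow(novel))) {
      records[[length(records) + 1]] <- novel[j, ]
    }
    used_evidence <- c(
      used_evidence,
      unlist(purrr::map(novel$sources,
                        ~ paste(.x$method, .x$transcript_id, sep = "|")))
    )
  }

  rec <- if (length(records) > 0) dplyr::bind_rows(records) else empty_records()
  rec <- collapse_duplicate_records(rec)
  new_merge_result(rec, ab_sets, ev_sets, ev_tx, used = used_evidence,
                   unsupported = lead_tx[unsupported_rows, ], config = config)
}

#' Detect novel genes supported only by evidence-based methods
#'
#' A transcript predicted by one evidence method is reported as novel when
#' (a) no ab initio transcript overlaps it above the threshold fraction and
#' (b) at least `config$min_evidence_for_novel` distinct evidence methods
#' predict it concordantly under the mode-appropriate matching (prokaryote:
#' overlap fraction strictly above threshold or identical boundaries;
#' eukaryote: fully matched exon chain or the both-sides exon-count rule).
#' Mutually supporting transcripts are reported once, with every supporting
#' method listed as a source.
#'
#' @param evidence_sets List of >= 2 evidence prediction sets (distinct
#'   methods).
#' @param ab_initio_sets List of ab initio prediction sets (may be empty).
#' @param config A [merge_config()].
#' @return A tibble of `NOVEL_EVIDENCE` records (same shape as
#'   `genemerge_result$merged`, without `merged_id`/`score`).
#' @export
find_novel <- function(evidence_sets, ab_initio_sets = list(),
                       config = merge_config()) {
  ev_sets <- as_set_list(evidence_sets, "evidence")
  if (length(ev_sets) < 2) {
    rlang::abort("novel-gene detection requires at least two evidence-based prediction outputs")
  }
  ab_sets <- as_set_list(ab_initio_sets, "ab_initio")
  ev_tx <- bind_evidence_tx(ev_sets)
  ab_tx <- bind_evidence_tx(ab_sets)
  ev_tx <- dplyr::arrange(ev_tx, .data$method, .data$gene_id,
                          .data$transcript_id)
  ab_hits <- span_overlap_hits(ev_tx, ab_tx)
  ev_hits <- span_overlap_hits(ev_tx, ev_tx)
  consumed <- character(0)
  out <- list()
  for (i in seq_len(nrow(ev_tx))) {
    e <- ev_tx[i, ]
    key <- paste(e$method, e$transcript_id, sep = "|")
    if (key %in% consumed) next
    ab_cand <- candidate_rows(e, ab_tx[ab_hits[[i]], ], config)
    if (nrow(ab_cand) > 0) {
      frac <- purrr::map_dbl(
        ab_cand$exons, ~ exon_matrix_overlap(e$exons[[1]], .x) / e$exonic_length
      )
      if (any(frac > config$threshold)) next  # handled in the main pass
    }
    cand <- candidate_rows(e, ev_tx[setdiff(ev_hits[[i]], i), ], config)
    cand <- cand[cand$method != e$method, ]
    if (nrow(cand) == 0) next
    supp <- purrr::map_lgl(seq_len(nrow(cand)), function(j) {
      other <- cand$exons[[j]]
      if (config$mode == "prokaryote") {
        same_chain(e$exons[[1]], other) ||
          exon_matrix_overlap(e$exons[[1]], other) / e$exonic_length >
            config$threshold
      } else {
        m <- match_exon_chain(e$exons[[1]], other, config)
        m$all_matched || (m$k > 0 && accept_both_sides(m, config))
      }
    })
    supporters <- cand[supp, ]
    n_methods <- dplyr::n_distinct(c(e$method, supporters$method))
    if (n_methods < config$min_evidence_for_novel) next
    src <- dplyr::bind_rows(sources_of(e), sources_of(supporters)) |>
      dplyr::arrange(.data$method, .data$transcript_id)
    out[[length(out) + 1]] <- record_row(
      e, support_class = "NOVEL_EVIDENCE", origin = "novel", sources = src
    )
    consumed <- c(consumed, key,
                  paste(supporters$method, supporters$transcript_id, sep = "|"))
  }
  if (length(out) == 0) empty_records() else dplyr::bind_rows(out)
}

as_set_list <- function(x, role) {
  if (inherits(x, "prediction_set")) x <- list(x)
  if (is.null(x)) x <- list()
  stopifnot(is.list(x))
  purrr::map(x, function(ps) {
    stopifnot(inherits(ps, "prediction_set"))
    tag <- ps_strategy(ps)
    if (is.na(tag)) ps <- set_strategy(ps, role)
    ps
  })
}

record_row <- function(tx, support_class, origin, sources) {
  tibble::tibble(
    seqid = tx$seqid, strand = tx$strand,
    start = tx$tx_start, end = tx$tx_end, n_exons = tx$n_exons,
    support_class = support_class, origin = origin,
    exons = list(tx$exons[[1]]),
    sources = list(dplyr::distinct(sources))
  )
}

empty_records <- function() {
  tibble::tibble(
    seqid = character(0), strand = character(0),
    start = integer(0), end = integer(0), n_exons = integer(0),
    support_class = character(0), origin = character(0),
    exons = list(), sources = list()
  )
}

chain_signature <- function(seqid, strand, exm) {
  paste(seqid, strand, paste(exm[, "start"], exm[, "end"], sep = "-",
                             collapse = ","), sep = "|")
}

# Identical consensus structures produced from different leading sets are
# collapsed: highest reliability class wins, sources are unioned.
collapse_duplicate_records <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  sig <- purrr::map_chr(seq_len(nrow(rec)), function(i) {
    chain_signature(rec$seqid[i], rec$strand[i], rec$exons[[i]])
  })
  prio <- match(rec$support_class, support_classes())
  keep <- order(sig, prio)
  rec2 <- rec[keep, ]
  sig2 <- sig[keep]
  first <- !duplicated(sig2)
  out <- rec2[first, ]
  src_union <- split(rec2$sources, sig2)
  out$sources <- purrr::map(src_union[unique(sig2)], function(lst) {
    dplyr::bind_rows(lst) |>
      dplyr::distinct() |>
      dplyr::arrange(.data$method, .data$transcript_id)
  })
  out
}

new_merge_result <- function(rec, ab_sets, ev_sets, ev_tx, used, unsupported,
                             config) {
  rec <- dplyr::arrange(
    rec, .data$seqid, .data$start, .data$end, .data$support_class
  )
  rec$merged_id <- sprintf("GM_%05d", seq_len(nrow(rec)))
  rec$score <- unname(config$score_map[rec$support_class])
  rec <- rec[, c("merged_id", "seqid", "strand", "start", "end", "n_exons",
                 "support_class", "score", "origin", "exons", "sources")]
  tracking <- tibble::tibble(
    merged_id = rec$merged_id, support_class = rec$support_class,
    sources = rec$sources
  )
  unmatched <- ev_tx[!paste(ev_tx$method, ev_tx$transcript_id, sep = "|")
                     %in% unique(used), ]
  structure(
    list(
      merged = rec,
      tracking = tracking,
      unsupported_ab_initio = prediction_set(
        tx_to_exons(unsupported), method = "unsupported_ab_initio",
        strategy = "ab_initio"
      ),
      unmatched_evidence = prediction_set(
        tx_to_exons(unmatched), method = "unmatched_evidence",
        strategy = "evidence"
      ),
      config = config
    ),
    class = "genemerge_result"
  )
}

# Per-query list of subject row indices whose spans overlap, via
# GenomicRanges::findOverlaps (strand handled separately by policy).
span_overlap_hits <- function(query_tx, subject_tx) {
  if (nrow(query_tx) == 0) return(list())
  if (nrow(subject_tx) == 0) return(rep(list(integer(0)), nrow(query_tx)))
  q <- GenomicRanges::GRanges(
    query_tx$seqid,
    IRanges::IRanges(query_tx$tx_start + 1L, query_tx$tx_end)
  )
  s <- GenomicRanges::GRanges(
    subject_tx$seqid,
    IRanges::IRanges(subject_tx$tx_start + 1L, subject_tx$tx_end)
  )
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  out <- rep(list(integer(0)), nrow(query_tx))
  split_hits <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (nm in names(split_hits)) out[[as.integer(nm)]] <- split_hits[[nm]]
  out
}

#' @export
print.genemerge_result <- function(x, ...) {
  cat("<genemerge_result>\n")
  cat(sprintf("  mode=%s threshold=%g novel=%s\n", x$config$mode,
              x$config$threshold, x$config$include_novel))
  cat(sprintf("  %d merged records; %d unsupported ab initio transcripts; %d unmatched evidence transcripts\n",
              nrow(x$merged),
              dplyr::n_distinct(x$unsupported_ab_initio$transcript_id),
              dplyr::n_distinct(x$unmatched_evidence$transcript_id)))
  tab <- table(x$merged$support_class)
  for (cls in names(tab)) cat(sprintf("    %s: %d\n", cls, tab[[cls]]))
  invisible(x)
}

#' Write all output files of a merge
#'
#' Writes the consensus GTF, the provenance tracking file, and the two side
#' GTFs (ab initio transcripts without evidence support; evidence transcripts
#' that supported nothing).
#'
#' @param result A `genemerge_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_merge_outputs <- function(result, dir, prefix = "genemerge") {
  stopifnot(inherits(result, "genemerge_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    merged = file.path(dir, paste0(prefix, "_merged.gtf")),
    tracking = file.path(dir, paste0(prefix, "_tracking.tsv")),
    unsupported_ab_initio = file.path(dir, paste0(prefix, "_unsupported_ab_initio.gtf")),
    unmatched_evidence = file.path(dir, paste0(prefix, "_unmatched_evidence.gtf"))
  )
  write_gtf(result, paths[["merged"]])
  write_tracking(result, paths[["tracking"]])
  write_gtf(result$unsupported_ab_initio, paths[["unsupported_ab_initio"]])
  write_gtf(result$unmatched_evidence, paths[["unmatched_evidence"]])
  invisible(paths)
}

#' Convert merged consensus records to a prediction set
#'
#' Each merged record becomes one single-transcript gene locus identified by
#' its `merged_id`, so the consensus can be fed back into evaluation or a
#' further merge.
#'
#' @param result A `genemerge_result`.
#' @return A [prediction_set()] (method `"genemerge"`, strategy unset).
#' @export
merged_prediction_set <- function(result) {
  stopifnot(inherits(result, "genemerge_result"))
  rec <- result$merged
  tx <- tibble::tibble(
    gene_id = rec$merged_id, transcript_id = rec$merged_id,
    seqid = rec$seqid, strand = rec$strand, exons = rec$exons
  )
  prediction_set(tx_to_exons(tx), method = "genemerge")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a merge result
#'
#' @param x A `genemerge_result`.
#' @param ... Unused.
#' @return One row per merged record with provenance summarised
#'   (`n_sources`, `n_methods`) instead of list columns.
#' @export
tidy.genemerge_result <- function(x, ...) {
  rec <- x$merged
  tibble::tibble(
    merged_id = rec$merged_id, seqid = rec$seqid, strand = rec$strand,
    start = rec$start, end = rec$end, n_exons = rec$n_exons,
    support_class = rec$support_class, score = rec$score,
    origin = rec$origin,
    n_sources = purrr::map_int(rec$sources, nrow),
    n_methods = purrr::map_int(rec$sources, ~ dplyr::n_distinct(.x$method))
  )
}

#' Summarise a merge result in one row
#'
#' @param x A `genemerge_result`.
#' @param ... Unused.
#' @return A one-row tibble: record counts per support class, side-set
#'   sizes, threshold and mode.
#' @export
glance.genemerge_result <- function(x, ...) {
  cls <- x$merged$support_class
  tibble::tibble(
    n_merged = nrow(x$merged),
    n_perfect = sum(cls == "PERFECT"),
    n_supported = sum(cls == "SUPPORTED"),
    n_partial = sum(cls == "PARTIAL_ACCEPTED"),
    n_novel = sum(cls == "NOVEL_EVIDENCE"),
    n_unsupported_ab_initio =
      dplyr::n_distinct(x$unsupported_ab_initio$transcript_id),
    n_unmatched_evidence =
      dplyr::n_distinct(x$unmatched_evidence$transcript_id),
    threshold = x$config$threshold,
    mode = x$config$mode
  )
}

#' Plot the reliability-class composition of a merge
#'
#' @param object A `genemerge_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of merged-record counts per support class.
#' @export
autoplot.genemerge_result <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::count(.data$support_class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$support_class, y = .data$n,
                                  fill = .data$support_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "support class", y = "merged records",
                  title = "Consensus composition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
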