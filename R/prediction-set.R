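#' Prediction sets: tidy containers for gene annotations
#'
#' A prediction set is the package's core container: one tibble with one row
#' per exon, carrying the method that produced the predictions and the
#' prediction strategy it belongs to (`"ab_initio"` or `"evidence"`).
#' Coordinates are held 0-based half-open internally; GTF input/output
#' converts to/from the 1-based inclusive convention at the file boundary, so
#' exon length is always `end - start`.
#'
#' Columns: `seqid`, `start`, `end`, `strand` (`+`, `-` or `.`), `gene_id`,
#' `transcript_id`, `exon_rank` (1-based, in genomic coordinate order).
#'
#' Exons of one transcript that touch or overlap in the input are merged on
#' construction with a warning: downstream matching assumes disjoint exons
#' within a transcript.
#'
#' @param exons A data frame with columns `seqid`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`. Coordinates 0-based half-open.
#' @param method Name of the gene finder that produced these predictions.
#' @param strategy `"ab_initio"`, `"evidence"`, or `NA` (assigned later).
#' @return A `prediction_set`: a tibble of exons with `method` and `strategy`
#'   attributes.
#' @examples
#' ps <- prediction_set(
#'   tibble::tibble(
#'     seqid = "chr1", start = c(100L, 300L), end = c(200L, 400L),
#'     strand = "+", gene_id = "g1", transcript_id = "t1"
#'   ),
#'   method = "toy", strategy = "ab_initio"
#' )
#' exonic_length(ps)
#' @export
prediction_set <- function(exons, method = "unknown", strategy = NA_character_) {
  stopifnot(is.data.frame(exons))
  required <- c("seqid", "start", "end", "strand", "gene_id", "transcript_id")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "exon table is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  ex <- tibble::as_tibble(exons)[required]
  ex$start <- as.integer(ex$start)
  ex$end <- as.integer(ex$end)
  ex$seqid <- as.character(ex$seqid)
  ex$strand <- as.character(ex$strand)
  ex$gene_id <- as.character(ex$gene_id)
  ex$transcript_id <- as.character(ex$transcript_id)

  if (nrow(ex) > 0) {
    bad <- which(!(ex$start < ex$end))
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "exon(s) with start >= end (0-based half-open requires start < end): rows ",
        paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    if (any(!nzchar(ex$seqid)) || any(is.na(ex$seqid))) {
      rlang::abort("empty seqid")
    }
    if (!all(ex$strand %in% c("+", "-", "."))) {
      rlang::abort("strand must be one of '+', '-', '.'")
    }
    ex <- dplyr::arrange(ex, .data$seqid, .data$transcript_id, .data$start)
    ex <- merge_touching_exons(ex)
    check_transcript_consistency(ex)
    ex <- ex |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::mutate(exon_rank = seq_len(dplyr::n())) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$seqid, .data$start, .data$transcript_id,
                     .data$exon_rank)
  } else {
    ex$exon_rank <- integer(0)
  }
  new_prediction_set(ex, method = method, strategy = strategy)
}

new_prediction_set <- function(ex, method, strategy) {
  if (!is.na(strategy) && !strategy %in% c("ab_initio", "evidence")) {
    rlang::abort("strategy must be 'ab_initio' or 'evidence' (or NA)")
  }
  structure(
    ex,
    method = method,
    strategy = strategy,
    class = c("prediction_set", class(tibble::tibble()))
  )
}

# Exons of one transcript that touch (end == next start) or overlap are fused;
# the merge and evaluation logic assume disjoint exons within a transcript.
merge_touching_exons <- function(ex) {
  fuse <- function(d) {
    if (nrow(d) <= 1) return(d)
    d <- d[order(d$start), ]
    keep_start <- d$start[1]
    out_start <- integer(0); out_end <- integer(0)
    cur_s <- d$start[1]; cur_e <- d$end[1]
    fused <- FALSE
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur_e) {
        cur_e <- max(cur_e, d$end[i]); fused <- TRUE
      } else {
        out_start <- c(out_start, cur_s); out_end <- c(out_end, cur_e)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out_start <- c(out_start, cur_s); out_end <- c(out_end, cur_e)
    if (fused) {
      attr(out_start, "fused") <- TRUE
    }
    d2 <- d[seq_along(out_start), ]
    d2$start <- as.integer(out_start); d2$end <- as.integer(out_end)
    attr(d2, "fused") <- fused
    d2
  }
  pieces <- split(ex, ex$transcript_id)
  fused_any <- FALSE
  pieces <- lapply(pieces, function(d) {
    d2 <- fuse(d)
    if (isTRUE(attr(d2, "fused"))) fused_any <<- TRUE
    attr(d2, "fused") <- NULL
    d2
  })
  if (fused_any) {
    rlang::warn("overlapping or touching exons within a transcript were merged")
  }
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$seqid, .data$transcript_id, .data$start)
}

check_transcript_consistency <- function(ex) {
  per_tx <- ex |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_seq = dplyr::n_distinct(.data$seqid),
      n_strand = dplyr::n_distinct(.data$strand),
      n_gene = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    )
  bad <- per_tx$transcript_id[per_tx$n_seq > 1 | per_tx$n_strand > 1]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "transcript(s) spanning multiple seqids or strands: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- per_tx$transcript_id[per_tx$n_gene > 1]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "transcript_id mapped to more than one gene_id: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf(
    "<prediction_set> method=%s strategy=%s: %d exons, %d transcripts, %d genes\n",
    attr(x, "method") %||% "?", attr(x, "strategy") %||% NA,
    nrow(x), dplyr::n_distinct(x$transcript_id), dplyr::n_distinct(x$gene_id)
  ))
  NextMethod()
}

#' @export
`[.prediction_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "method") <- attr(x, "method")
    attr(out, "strategy") <- attr(x, "strategy")
  }
  out
}

#' Accessors for prediction-set metadata
#'
#' @param ps A `prediction_set`.
#' @return `ps_method()` and `ps_strategy()` return the stored strings;
#'   `set_strategy()` returns the prediction set with the strategy replaced.
#' @export
ps_method <- function(ps) attr(ps, "method")

#' @rdname ps_method
#' @export
ps_strategy <- function(ps) attr(ps, "strategy")

#' @rdname ps_method
#' @param strategy `"ab_initio"` or `"evidence"`.
#' @export
set_strategy <- function(ps, strategy) {
  new_prediction_set(tibble::as_tibble(ps), attr(ps, "method"), strategy)
}

#' Exonic length of each transcript
#'
#' The exonic length of a transcript is the sum of the lengths of its exons —
#' the number of transcribed nucleotides, not the genomic span. This is the
#' length against which the supporting-overlap threshold is applied.
#'
#' @param ps A `prediction_set`.
#' @return A tibble with `gene_id`, `transcript_id`, `n_exons`,
#'   `exonic_length`.
#' @export
exonic_length <- function(ps) {
  tibble::as_tibble(ps) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      n_exons = dplyr::n(),
      exonic_length = sum(.data$end - .data$start),
      .groups = "drop"
    )
}

#' Genomic hull of each gene locus
#'
#' The locus span is the smallest interval covering every exon of every
#' transcript of the gene.
#'
#' @param ps A `prediction_set`.
#' @return A tibble with `gene_id`, `seqid`, `start`, `end`, `strand`
#'   (`"."` when transcripts of the locus disagree).
#' @export
locus_hull <- function(ps) {
  tb <- tibble::as_tibble(ps)
  n_seq <- tb |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$seqid), .groups = "drop")
  if (any(n_seq$n > 1)) {
    rlang::abort(paste0(
      "gene locus spans multiple seqids: ",
      paste(utils::head(n_seq$gene_id[n_seq$n > 1], 5), collapse = ", ")
    ))
  }
  tb |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      seqid = .data$seqid[1],
      start = min(.data$start),
      end = max(.data$end),
      strand = if (dplyr::n_distinct(.data$strand) == 1) .data$strand[1] else ".",
      .groups = "drop"
    )
}

# One row per transcript with an exon matrix (cols start, end) in a list
# column; the working representation of the merge engine and evaluator.
ps_transcripts <- function(ps) {
  tb <- tibble::as_tibble(ps)
  if (nrow(tb) == 0) {
    return(tibble::tibble(
      gene_id = character(0), transcript_id = character(0),
      seqid = character(0), strand = character(0),
      tx_start = integer(0), tx_end = integer(0), n_exons = integer(0),
      exonic_length = integer(0), exons = list()
    ))
  }
  tb |>
    dplyr::arrange(.data$seqid, .data$transcript_id, .data$start) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      seqid = .data$seqid[1],
      strand = .data$strand[1],
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      n_exons = dplyr::n(),
      exonic_length = sum(.data$end - .data$start),
      exons = list(cbind(start = .data$start, end = .data$end)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$seqid, .data$tx_start, .data$transcript_id)
}

# Inverse of ps_transcripts for engine-internal transcript tables.
tx_to_exons <- function(tx) {
  if (nrow(tx) == 0) {
    return(tibble::tibble(
      seqid = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene_id = character(0),
      transcript_id = character(0)
    ))
  }
  purrr::pmap_dfr(
    list(tx$gene_id, tx$transcript_id, tx$seqid, tx$strand, tx$exons),
    function(g, t, s, str, ex) {
      tibble::tibble(
        seqid = s, start = as.integer(ex[, "start"]),
        end = as.integer(ex[, "end"]), strand = str,
        gene_id = g, transcript_id = t
      )
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
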