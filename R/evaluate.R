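#' Evaluate a prediction set against a reference annotation
#'
#' Cuffcompare-convention accuracy evaluation at the exon and transcript
#' levels. Note that "specificity" here follows Cuffcompare's usage and is
#' what most fields call precision, TP / (TP + FP) — not the
#' epidemiological true-negative rate, which is undefined for open genomic
#' intervals.
#'
#' At the exon level a predicted exon counts as a true positive when a
#' reference exon with identical boundaries and compatible strand exists;
#' identical exon coordinates shared by several isoforms are deduplicated on
#' each side first so multi-isoform genes do not inflate the counts. At the
#' transcript level a predicted transcript is a true positive when its full
#' exon chain matches a reference transcript: all internal boundaries
#' exactly, and the two terminal boundaries (chain start and chain end)
#' within `terminal_tolerance` nucleotides (default 0, i.e. fully strict).
#' `missed` counts reference features with no overlap at all from the
#' prediction; `novel` counts predicted features with no reference overlap.
#'
#' @param pred,ref [prediction_set()]s on the same coordinate system; `ref`
#'   must be non-empty.
#' @param level `"exon"`, `"transcript"`, or both (default).
#' @param terminal_tolerance Allowed slack, in nucleotides, at the two chain
#'   termini for transcript-level matching.
#' @return A tibble with one row per level: `level`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `f_measure`, `missed`, `novel`.
#'   Sensitivity/specificity are `NA` when their denominator is 0.
#' @examples
#' truth <- simulate_truth(n_genes = 10, mode = "prokaryote", seed = 7)
#' evaluate_predictions(truth, truth)
#' @export
evaluate_predictions <- function(pred, ref,
                                 level = c("exon", "transcript"),
                                 terminal_tolerance = 0L) {
  level <- match.arg(level, several.ok = TRUE)
  if (nrow(tibble::as_tibble(ref)) == 0) {
    rlang::abort("reference annotation is empty")
  }
  purrr::map_dfr(level, function(lv) {
    if (lv == "exon") eval_exon_level(pred, ref)
    else eval_transcript_level(pred, ref, terminal_tolerance)
  })
}

eval_exon_level <- function(pred, ref) {
  p <- unique_exons(pred)
  r <- unique_exons(ref)
  tp <- sum(purrr::map_lgl(seq_len(nrow(p)), function(i) {
    any(r$seqid == p$seqid[i] & r$start == p$start[i] & r$end == p$end[i] &
          strands_compatible(r$strand, p$strand[i], "ignore_unstranded"))
  }))
  fp <- nrow(p) - tp
  fn <- nrow(r) - sum(purrr::map_lgl(seq_len(nrow(r)), function(i) {
    any(p$seqid == r$seqid[i] & p$start == r$start[i] & p$end == r$end[i] &
          strands_compatible(p$strand, r$strand[i], "ignore_unstranded"))
  }))
  missed <- count_no_overlap(r, p)
  novel <- count_no_overlap(p, r)
  accuracy_row("exon", tp, fp, fn, missed, novel)
}

eval_transcript_level <- function(pred, ref, tol) {
  p <- ps_transcripts(pred)
  r <- ps_transcripts(ref)
  match_tx <- function(a, b) {
    # a, b: single rows; exact internal structure, termini within tol
    if (a$seqid != b$seqid) return(FALSE)
    if (!strands_compatible(a$strand, b$strand, "ignore_unstranded")) return(FALSE)
    ea <- a$exons[[1]]; eb <- b$exons[[1]]
    if (nrow(ea) != nrow(eb)) return(FALSE)
    n <- nrow(ea)
    internal_a <- c(ea[-1, "start"], ea[-n, "end"])
    internal_b <- c(eb[-1, "start"], eb[-n, "end"])
    if (n > 1 && !all(internal_a == internal_b)) return(FALSE)
    abs(ea[1, "start"] - eb[1, "start"]) <= tol &&
      abs(ea[n, "end"] - eb[n, "end"]) <= tol
  }
  p_hit <- purrr::map_lgl(seq_len(nrow(p)), function(i) {
    any(purrr::map_lgl(seq_len(nrow(r)), function(j) match_tx(p[i, ], r[j, ])))
  })
  r_hit <- purrr::map_lgl(seq_len(nrow(r)), function(j) {
    any(purrr::map_lgl(seq_len(nrow(p)), function(i) match_tx(p[i, ], r[j, ])))
  })
  tp <- sum(p_hit)
  fp <- nrow(p) - tp
  fn <- sum(!r_hit)
  missed <- count_no_overlap_tx(r, p)
  novel <- count_no_overlap_tx(p, r)
  accuracy_row("transcript", tp, fp, fn, missed, novel)
}

unique_exons <- function(ps) {
  tibble::as_tibble(ps) |>
    dplyr::distinct(.data$seqid, .data$start, .data$end, .data$strand)
}

count_no_overlap <- function(a, b) {
  if (nrow(a) == 0) return(0L)
  if (nrow(b) == 0) return(nrow(a))
  sum(purrr::map_lgl(seq_len(nrow(a)), function(i) {
    !any(b$seqid == a$seqid[i] & b$start < a$end[i] & b$end > a$start[i])
  }))
}

count_no_overlap_tx <- function(a, b) {
  if (nrow(a) == 0) return(0L)
  ea <- tx_to_exons(a); eb <- tx_to_exons(b)
  hit_tx <- unique(purrr::map_chr(which(purrr::map_lgl(
    seq_len(nrow(ea)),
    function(i) any(eb$seqid == ea$seqid[i] & eb$start < ea$end[i] &
                      eb$end > ea$start[i])
  )), ~ ea$transcript_id[.x]))
  sum(!unique(ea$transcript_id) %in% hit_tx)
}

accuracy_row <- function(level, tp, fp, fn, missed, novel) {
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  tibble::tibble(
    level = level, tp = tp, fp = fp, fn = fn,
    sensitivity = sn, specificity = sp,
    f_measure = f_measure(sn, sp),
    missed = missed, novel = novel
  )
}

#' F-measure of sensitivity and specificity
#'
#' Harmonic mean `2 * sn * sp / (sn + sp)`, the single-number accuracy
#' summary; defined as 0 when both inputs are 0.
#'
#' @param sn,sp Fractions in \[0, 1\] (Cuffcompare-convention sensitivity and
#'   specificity/precision).
#' @return The harmonic mean, or `NA` if either input is `NA`.
#' @export
f_measure <- function(sn, sp) {
  if (is.na(sn) || is.na(sp)) return(NA_real_)
  if (sn + sp == 0) return(0)
  2 * sn * sp / (sn + sp)
}

#' Write an accuracy report to TSV
#'
#' @param report A tibble from [evaluate_predictions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}

#' Plot accuracy metrics per evaluation level
#'
#' @param report A tibble from [evaluate_predictions()] (optionally row-bound
#'   across several prediction sets with an extra `method` column).
#' @return A ggplot with sensitivity, specificity and F-measure per level.
#' @export
plot_accuracy <- function(report) {
  d <- report |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "f_measure"),
                        names_to = "metric", values_to = "value")
  aes <- if ("method" %in% names(report)) {
    ggplot2::aes(x = .data$metric, y = .data$value, fill = .data$method)
  } else {
    ggplot2::aes(x = .data$metric, y = .data$value, fill = .data$metric)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~level) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Prediction accuracy") +
    ggplot2::theme_minimal()
}
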