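#' Read a Cufflinks-dialect GTF file into a prediction set
#'
#' Exon feature lines are grouped into transcripts by the `transcript_id`
#' attribute and into gene loci by `gene_id`; all other feature types are
#' ignored. Coordinates are converted from GTF's 1-based inclusive convention
#' to the package's 0-based half-open convention on read.
#'
#' @param path Path to a 9-column tab-separated GTF file.
#' @param method Method name to record on the returned set (defaults to the
#'   file name without extension).
#' @param strategy Optional strategy tag (`"ab_initio"` or `"evidence"`).
#' @return A [prediction_set()].
#' @export
read_gtf <- function(path, method = NULL,
                     strategy = NA_character_) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  method <- method %||% tools::file_path_sans_ext(basename(path))
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- stringr::str_split(lines[keep], "\t")
  n_fields <- lengths(fields)
  bad <- keep[n_fields < 9]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "line ", bad[1], ": expected 9 tab-separated columns, got ",
      n_fields[match(bad[1], keep)]
    ))
  }
  feat <- vapply(fields, `[[`, character(1), 3)
  is_exon <- feat == "exon"
  if (!all(is_exon)) {
    rlang::inform(paste0(
      "ignoring ", sum(!is_exon), " non-exon feature line(s) in ", path
    ), class = "genemerge_debug")
  }
  idx <- which(is_exon)
  if (length(idx) == 0) {
    return(prediction_set(empty_exon_table(), method = method,
                          strategy = strategy))
  }
  fx <- fields[idx]
  line_no <- keep[idx]
  start1 <- suppressWarnings(as.integer(vapply(fx, `[[`, character(1), 4)))
  end1 <- suppressWarnings(as.integer(vapply(fx, `[[`, character(1), 5)))
  if (anyNA(start1) || anyNA(end1)) {
    i <- which(is.na(start1) | is.na(end1))[1]
    rlang::abort(paste0("line ", line_no[i], ": non-numeric start/end"))
  }
  if (any(end1 < start1)) {
    i <- which(end1 < start1)[1]
    rlang::abort(paste0("line ", line_no[i], ": end < start"))
  }
  attrs <- vapply(fx, `[[`, character(1), 9)
  gene_id <- gtf_attribute(attrs, "gene_id")
  transcript_id <- gtf_attribute(attrs, "transcript_id")
  if (anyNA(gene_id)) {
    rlang::abort(paste0(
      "line ", line_no[which(is.na(gene_id))[1]], ": missing gene_id attribute"
    ))
  }
  if (anyNA(transcript_id)) {
    rlang::abort(paste0(
      "line ", line_no[which(is.na(transcript_id))[1]],
      ": missing transcript_id attribute"
    ))
  }
  ex <- tibble::tibble(
    seqid = vapply(fx, `[[`, character(1), 1),
    start = start1 - 1L,  # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = vapply(fx, `[[`, character(1), 7),
    gene_id = gene_id,
    transcript_id = transcript_id
  )
  prediction_set(ex, method = method, strategy = strategy)
}

gtf_attribute <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"'))
  m[, 2]
}

empty_exon_table <- function() {
  tibble::tibble(
    seqid = character(0), start = integer(0), end = integer(0),
    strand = character(0), gene_id = character(0), transcript_id = character(0)
  )
}

#' Write a prediction set or merge result to GTF
#'
#' Writes one `exon` line per exon in Cufflinks-dialect GTF (1-based inclusive
#' coordinates, `gene_id "..."; transcript_id "...";` attributes). For merged
#' consensus records the reliability class is written as a `support_class`
#' attribute and the numeric reliability score goes in the GTF score column.
#' Output ordering is deterministic: seqid, start, transcript_id.
#'
#' @param x A [prediction_set()] or a `genemerge_result` (see
#'   [merge_predictions()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  UseMethod("write_gtf")
}

#' @export
write_gtf.prediction_set <- function(x, path) {
  tb <- tibble::as_tibble(x) |>
    dplyr::arrange(.data$seqid, .data$start, .data$transcript_id)
  src <- attr(x, "method") %||% "genemerge"
  lines <- c(
    "# GTF written by genemerge",
    if (nrow(tb) > 0) sprintf(
      '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      tb$seqid, src, tb$start + 1L, tb$end, tb$strand, tb$gene_id,
      tb$transcript_id
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
write_gtf.genemerge_result <- function(x, path) {
  rec <- x$merged
  lines <- "# GTF written by genemerge"
  if (nrow(rec) > 0) {
    ex <- purrr::pmap_dfr(
      list(rec$merged_id, rec$seqid, rec$strand, rec$support_class,
           rec$score, rec$exons),
      function(id, seqid, strand, cls, score, exm) {
        tibble::tibble(
          seqid = seqid,
          start = as.integer(exm[, "start"]), end = as.integer(exm[, "end"]),
          strand = strand, gene_id = id, transcript_id = id,
          support_class = cls, score = score
        )
      }
    ) |>
      dplyr::arrange(.data$seqid, .data$start, .data$transcript_id)
    lines <- c(lines, sprintf(
      '%s\tgenemerge\texon\t%d\t%d\t%s\t%s\t.\tgene_id "%s"; transcript_id "%s"; support_class "%s";',
      ex$seqid, ex$start + 1L, ex$end, format_score(ex$score), ex$strand,
      ex$gene_id, ex$transcript_id, ex$support_class
    ))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

format_score <- function(s) {
  out <- trimws(formatC(s, format = "g", digits = 6))
  out[is.na(s)] <- "."
  out
}

#' Write the provenance tracking file of a merge
#'
#' One tab-separated line per merged record: the merged id, its support
#' class, then one `method|gene_id|transcript_id` token per source
#' prediction.
#'
#' @param result A `genemerge_result` from [merge_predictions()], or its
#'   `tracking` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(result, path) {
  tr <- if (inherits(result, "genemerge_result")) result$tracking else result
  lines <- character(0)
  if (nrow(tr) > 0) {
    lines <- purrr::pmap_chr(
      list(tr$merged_id, tr$support_class, tr$sources),
      function(id, cls, src) {
        tokens <- sprintf("%s|%s|%s", src$method, src$gene_id,
                          src$transcript_id)
        paste(c(id, cls, tokens), collapse = "\t")
      }
    )
  }
  readr::write_lines(lines, path)
  invisible(path)
}
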