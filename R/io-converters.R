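#' Convert a Glimmer3 predict file to a prediction set
#'
#' Glimmer3 `.predict` output lists one ORF per row under a `>seqid` header:
#' `orfID start end frame score`, with 1-based inclusive coordinates on the
#' forward strand reading frame. Each ORF becomes a single-exon,
#' single-transcript gene locus. The strand is derived from the sign of the
#' frame column; for negative frames Glimmer prints start > end, and the
#' coordinates are normalised so that start < end. This frame-sign
#' interpretation is a stated convention of this converter: the format itself
#' does not carry an explicit strand column.
#'
#' @param path Path to a Glimmer3 `.predict` file.
#' @param method Method name for the returned set (default: file name).
#' @return A [prediction_set()] of single-exon loci (strategy unset).
#' @export
read_glimmer3 <- function(path, method = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  method <- method %||% tools::file_path_sans_ext(basename(path))
  lines <- readr::read_lines(path)
  seqid <- NA_character_
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      seqid <- sub("^>\\s*", "", strsplit(ln, "\\s+")[[1]][1])
      seqid <- sub("^>", "", seqid)
      next
    }
    if (is.na(seqid)) {
      rlang::abort(paste0("line ", i, ": ORF row before any '>seqid' header"))
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 4) {
      rlang::abort(paste0("line ", i, ": expected 'orfID start end frame [score]'"))
    }
    s <- suppressWarnings(as.integer(parts[2]))
    e <- suppressWarnings(as.integer(parts[3]))
    if (is.na(s) || is.na(e)) {
      rlang::abort(paste0("line ", i, ": non-numeric coordinates"))
    }
    frame <- parts[4]
    strand <- if (startsWith(frame, "-")) "-" else if (startsWith(frame, "+")) "+" else "."
    lo <- min(s, e); hi <- max(s, e)
    rows[[length(rows) + 1]] <- tibble::tibble(
      seqid = seqid, start = lo - 1L, end = hi, strand = strand,
      gene_id = parts[1], transcript_id = paste0(parts[1], ".t1")
    )
  }
  ex <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty_exon_table()
  prediction_set(ex, method = method, strategy = NA_character_)
}

#' Convert an AUGUSTUS GFF file to a prediction set
#'
#' AUGUSTUS GFF mixes bare-identifier group columns (on `gene` and
#' `transcript` rows) with GTF-style `transcript_id "..."; gene_id "...";`
#' attributes on `exon`/`CDS` rows. Exon rows are grouped per transcript;
#' when a transcript has no `exon` rows at all, its `CDS` rows are used as
#' exons instead (AUGUSTUS omits exon features in some configurations), with
#' a message. Transcripts with neither are skipped with a warning.
#'
#' @param path Path to an AUGUSTUS GFF file.
#' @param method Method name for the returned set (default: file name).
#' @return A [prediction_set()] (strategy unset).
#' @export
read_augustus <- function(path, method = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  method <- method %||% tools::file_path_sans_ext(basename(path))
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- stringr::str_split(lines[keep], "\t")
  ok <- lengths(fields) >= 9
  if (any(!ok)) {
    rlang::abort(paste0("line ", keep[which(!ok)[1]],
                        ": expected 9 tab-separated columns"))
  }
  feat <- vapply(fields, `[[`, character(1), 3)
  idx <- which(feat %in% c("exon", "CDS"))
  if (length(idx) == 0) {
    return(prediction_set(empty_exon_table(), method = method))
  }
  fx <- fields[idx]
  line_no <- keep[idx]
  attrs <- vapply(fx, `[[`, character(1), 9)
  tid <- gtf_attribute(attrs, "transcript_id")
  gid <- gtf_attribute(attrs, "gene_id")
  # Some AUGUSTUS emissions use a bare "g1.t1" group column instead.
  bare <- is.na(tid)
  tid[bare] <- trimws(attrs[bare])
  gid[bare] <- sub("\\.t[0-9]+$", "", tid[bare])
  gid[is.na(gid)] <- sub("\\.t[0-9]+$", "", tid[is.na(gid)])
  if (any(!nzchar(tid))) {
    rlang::abort(paste0("line ", line_no[which(!nzchar(tid))[1]],
                        ": cannot determine transcript grouping"))
  }
  tb <- tibble::tibble(
    seqid = vapply(fx, `[[`, character(1), 1),
    feature = feat[idx],
    start = as.integer(vapply(fx, `[[`, character(1), 4)) - 1L,
    end = as.integer(vapply(fx, `[[`, character(1), 5)),
    strand = vapply(fx, `[[`, character(1), 7),
    gene_id = gid, transcript_id = tid
  )
  has_exon <- unique(tb$transcript_id[tb$feature == "exon"])
  cds_only <- setdiff(unique(tb$transcript_id), has_exon)
  if (length(cds_only) > 0) {
    rlang::inform(paste0(
      "using CDS rows as exons for ", length(cds_only),
      " transcript(s) lacking exon rows"
    ), class = "genemerge_debug")
  }
  ex <- tb |>
    dplyr::filter(
      (.data$feature == "exon" & .data$transcript_id %in% has_exon) |
        (.data$feature == "CDS" & .data$transcript_id %in% cds_only)
    ) |>
    dplyr::select(-"feature")
  prediction_set(ex, method = method, strategy = NA_character_)
}
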