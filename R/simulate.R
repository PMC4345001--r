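#' Simulate a ground-truth gene annotation
#'
#' Deterministic, seeded generator of a non-overlapping gene annotation used
#' as ground truth for end-to-end testing of the merge engine. Prokaryotic
#' mode emits single-exon, single-transcript loci; eukaryotic mode emits
#' multi-exon transcripts and optionally additional isoforms that share exons
#' with the primary isoform (an internal exon is skipped). Gene and gap
#' lengths are drawn uniformly within the configured ranges. Given the same
#' seed and parameters the output is identical down to the byte when written
#' to GTF.
#'
#' @param n_genes Number of gene loci.
#' @param mode `"prokaryote"` or `"eukaryote"`.
#' @param seed Integer seed; the generator touches no global RNG state.
#' @param genome_length Genome size in nucleotides. Default `NULL` sizes the
#'   genome to an upper bound that always fits `n_genes`; a user-supplied
#'   value that cannot fit the simulated genes raises an error.
#' @param gene_length Range (prokaryote) of gene lengths, nt.
#' @param exons_per_gene,exon_length,intron_length Eukaryotic structure
#'   ranges, nt.
#' @param isoforms_per_gene Range of isoform counts per eukaryotic gene;
#'   extra isoforms skip one internal exon of the primary isoform.
#' @param gap_length Range of intergenic gap lengths, nt.
#' @param seqid Sequence name of the simulated chromosome.
#' @return A [prediction_set()] (method `"truth"`, strategy unset).
#' @examples
#' truth <- simulate_truth(n_genes = 5, mode = "eukaryote", seed = 42)
#' exonic_length(truth)
#' @export
simulate_truth <- function(n_genes, mode = c("prokaryote", "eukaryote"),
                           seed = 1L, genome_length = NULL,
                           gene_length = c(300L, 3000L),
                           exons_per_gene = c(2L, 8L),
                           exon_length = c(50L, 400L),
                           intron_length = c(50L, 2000L),
                           isoforms_per_gene = c(1L, 3L),
                           gap_length = c(200L, 2000L),
                           seqid = "chrSim") {
  mode <- match.arg(mode)
  stopifnot(n_genes >= 1)
  max_gene <- if (mode == "prokaryote") {
    gene_length[2]
  } else {
    exons_per_gene[2] * exon_length[2] +
      (exons_per_gene[2] - 1) * intron_length[2]
  }
  bound <- n_genes * (max_gene + gap_length[2]) + gap_length[2]
  genome_length <- genome_length %||% bound

  exons <- withr::with_seed(seed, {
    cursor <- 0L
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gap <- sample(gap_length[1]:gap_length[2], 1)
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("g%04d", g)
      start <- cursor + gap
      if (mode == "prokaryote") {
        len <- sample(gene_length[1]:gene_length[2], 1)
        rows[[g]] <- tibble::tibble(
          seqid = seqid, start = start, end = start + len, strand = strand,
          gene_id = gid, transcript_id = paste0(gid, ".t1")
        )
        cursor <- start + len
      } else {
        n_ex <- sample(exons_per_gene[1]:exons_per_gene[2], 1)
        ex_len <- sample(exon_length[1]:exon_length[2], n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) {
          sample(intron_length[1]:intron_length[2], n_ex - 1, replace = TRUE)
        } else integer(0)
        ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
        ex_end <- ex_start + ex_len
        n_iso <- sample(isoforms_per_gene[1]:isoforms_per_gene[2], 1)
        iso <- list(seq_len(n_ex))
        if (n_iso > 1 && n_ex >= 3) {
          skippable <- 2:(n_ex - 1)
          extra <- sample(skippable, min(n_iso - 1, length(skippable)))
          for (s in extra) iso[[length(iso) + 1]] <- setdiff(seq_len(n_ex), s)
        }
        rows[[g]] <- purrr::imap_dfr(iso, function(keep, k) {
          tibble::tibble(
            seqid = seqid, start = ex_start[keep], end = ex_end[keep],
            strand = strand, gene_id = gid,
            transcript_id = sprintf("%s.t%d", gid, k)
          )
        })
        cursor <- max(ex_end)
      }
    }
    dplyr::bind_rows(rows)
  })
  if (max(exons$end) + gap_length[1] > genome_length) {
    rlang::abort(sprintf(
      "n_genes = %d does not fit in genome_length = %d (needs >= %d)",
      n_genes, genome_length, max(exons$end) + gap_length[1]
    ))
  }
  ps <- prediction_set(exons, method = "truth")
  attr(ps, "genome_length") <- genome_length
  ps
}

#' Subsample the expressed fraction of a truth annotation
#'
#' Real expression evidence never covers every annotated gene; only a
#' fraction of genes is expressed under one condition. This draws a seeded
#' subset of exactly `round(fraction * n_genes)` genes. The retained subset
#' is the ground truth against which evidence-derived predictions (and the
#' merged consensus) should be evaluated.
#'
#' @param truth A [prediction_set()] from [simulate_truth()].
#' @param fraction Fraction of genes to keep, in (0, 1]; default 0.7.
#' @param seed Integer seed.
#' @return A prediction set containing the retained genes.
#' @export
sample_expressed <- function(truth, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  genes <- unique(tibble::as_tibble(truth)$gene_id)
  n_keep <- round(fraction * length(genes))
  keep <- withr::with_seed(seed, sort(sample(genes, n_keep)))
  ex <- tibble::as_tibble(truth) |>
    dplyr::filter(.data$gene_id %in% keep) |>
    dplyr::select(-"exon_rank")
  out <- prediction_set(ex, method = attr(truth, "method"),
                        strategy = ps_strategy(truth))
  attr(out, "genome_length") <- attr(truth, "genome_length")
  out
}

#' Error profile of a simulated gene finder
#'
#' Describes how one method's predictions deviate from the truth it is
#' derived from: genes it misses entirely (`drop_rate`), spurious intergenic
#' predictions (`fp_rate`), Gaussian jitter on exon boundaries
#' (`boundary_jitter_sd`), internal exons missing from multi-exon transcripts
#' (`exon_drop_rate`, emulating partial evidence such as low RNA-seq
#' coverage), and a fixed extension of the 3' terminal exon
#' (`terminal_extension`, emulating gene finders that misjudge the first or
#' last exon).
#'
#' @param method_name Name recorded on the perturbed prediction set.
#' @param strategy `"ab_initio"` or `"evidence"`.
#' @param drop_rate Fraction of genes removed entirely.
#' @param fp_rate Spurious genes injected, as a fraction of the base gene
#'   count.
#' @param boundary_jitter_sd Standard deviation (nt) of boundary jitter.
#' @param exon_drop_rate Per-exon drop probability in multi-exon transcripts.
#' @param terminal_extension Extension (nt) of the chain's 3' end.
#' @return An `error_profile` list.
#' @export
error_profile <- function(method_name, strategy,
                          drop_rate = 0, fp_rate = 0,
                          boundary_jitter_sd = 0, exon_drop_rate = 0,
                          terminal_extension = 0L) {
  rates <- c(drop_rate, fp_rate, exon_drop_rate)
  if (any(rates < 0 | rates > 1)) rlang::abort("rates must be in [0, 1]")
  structure(
    list(method_name = method_name, strategy = strategy,
         drop_rate = drop_rate, fp_rate = fp_rate,
         boundary_jitter_sd = boundary_jitter_sd,
         exon_drop_rate = exon_drop_rate,
         terminal_extension = as.integer(terminal_extension)),
    class = "error_profile"
  )
}

#' Intergenic gaps of an annotation
#'
#' Gaps between consecutive gene hulls (and before the first gene), shrunk by
#' `margin` on both sides so anything placed inside a gap can never touch a
#' real gene.
#'
#' @param ps A [prediction_set()].
#' @param margin Safety margin in nt (default 50).
#' @param genome_length Optional genome length to add the terminal gap.
#' @return A tibble `seqid`, `start`, `end` of usable intergenic intervals.
#' @export
intergenic_gaps <- function(ps, margin = 50L, genome_length = NULL) {
  genome_length <- genome_length %||% attr(ps, "genome_length")
  hull <- locus_hull(ps) |> dplyr::arrange(.data$seqid, .data$start)
  purrr::map_dfr(split(hull, hull$seqid), function(h) {
    bounds_start <- c(0L, h$end)
    bounds_end <- c(h$start, genome_length %||% max(h$end))
    tibble::tibble(
      seqid = h$seqid[1],
      start = bounds_start + margin,
      end = bounds_end - margin
    ) |>
      dplyr::filter(.data$end - .data$start >= 100L)
  })
}

#' Partition intergenic gaps into method-unique pools
#'
#' Spurious predictions injected for different methods must never overlap
#' each other (method-unique false positives are what makes consensus
#' filtering exact). Gaps are dealt round-robin in coordinate order into `n`
#' disjoint pools.
#'
#' @param gaps A gap tibble from [intergenic_gaps()].
#' @param n Number of pools (methods).
#' @return A list of `n` disjoint gap tibbles.
#' @export
fp_pools <- function(gaps, n) {
  gaps <- dplyr::arrange(gaps, .data$seqid, .data$start)
  purrr::map(seq_len(n), function(i) {
    gaps[seq_len(nrow(gaps)) %% n == i %% n, ]
  })
}

#' Perturb a prediction set according to an error profile
#'
#' Produces one simulated gene finder's output from a base annotation:
#' drops a seeded sample of `round(drop_rate * n)` genes, jitters exon
#' boundaries, drops exons from multi-exon transcripts (always keeping at
#' least one), extends the 3' terminal exon, then injects
#' `round(fp_rate * n)` spurious single-exon genes into the supplied
#' intergenic pool. A manifest mapping every output gene to its origin
#' (`true` with the source gene, or `fp`) is attached as the `"manifest"`
#' attribute and retrievable with [perturb_manifest()].
#'
#' @param base A [prediction_set()] (typically the truth or its expressed
#'   subset).
#' @param profile An [error_profile()].
#' @param seed Integer seed.
#' @param fp_pool Intergenic intervals allowed for spurious genes; defaults
#'   to [intergenic_gaps()] of `base`. Pass one pool per method from
#'   [fp_pools()] to guarantee method-unique false positives.
#' @param fp_length Range of spurious gene lengths, nt.
#' @return A prediction set tagged with the profile's method and strategy.
#' @export
perturb_predictions <- function(base, profile, seed = 1L, fp_pool = NULL,
                                fp_length = c(300L, 1500L)) {
  stopifnot(inherits(profile, "error_profile"))
  tx <- ps_transcripts(base)
  genes <- unique(tx$gene_id)
  n <- length(genes)

  withr::with_seed(seed, {
    # 1. gene drops (exact seeded count)
    n_drop <- round(profile$drop_rate * n)
    dropped <- if (n_drop > 0) sample(genes, n_drop) else character(0)
    tx <- tx[!tx$gene_id %in% dropped, ]

    # 2.-4. per-transcript structural errors
    if (nrow(tx) > 0) {
      tx$exons <- purrr::map(tx$exons, function(ex) {
        ex <- jitter_exons(ex, profile$boundary_jitter_sd)
        ex <- drop_exons(ex, profile$exon_drop_rate)
        if (profile$terminal_extension > 0) {
          ex[nrow(ex), "end"] <- ex[nrow(ex), "end"] + profile$terminal_extension
        }
        ex
      })
    }

    # 5. method-unique spurious genes in intergenic space
    n_fp <- round(profile$fp_rate * n)
    fp_rows <- NULL
    if (n_fp > 0) {
      pool <- fp_pool %||% intergenic_gaps(base)
      fp_rows <- place_false_positives(pool, n_fp, fp_length,
                                       profile$method_name)
    }
  })

  ex_true <- tx_to_exons(tx)
  ex <- dplyr::bind_rows(ex_true, fp_rows)
  out <- prediction_set(ex, method = profile$method_name,
                        strategy = profile$strategy)
  manifest <- dplyr::bind_rows(
    tibble::tibble(gene_id = unique(ex_true$gene_id), origin = "true",
                   source_gene_id = unique(ex_true$gene_id)),
    if (!is.null(fp_rows)) {
      tibble::tibble(gene_id = unique(fp_rows$gene_id), origin = "fp",
                     source_gene_id = NA_character_)
    }
  )
  attr(out, "manifest") <- manifest
  attr(out, "genome_length") <- attr(base, "genome_length")
  out
}

#' @rdname perturb_predictions
#' @param ps A perturbed prediction set.
#' @export
perturb_manifest <- function(ps) attr(ps, "manifest")

jitter_exons <- function(ex, sd) {
  if (sd <= 0) return(ex)
  n <- nrow(ex)
  s <- ex[, "start"] + as.integer(round(stats::rnorm(n, 0, sd)))
  e <- ex[, "end"] + as.integer(round(stats::rnorm(n, 0, sd)))
  bad <- e <= s
  s[bad] <- ex[bad, "start"]; e[bad] <- ex[bad, "end"]
  s[s < 0] <- 0L
  # keep exons disjoint after jitter
  for (i in seq_len(n)[-1]) {
    if (s[i] <= e[i - 1]) s[i] <- e[i - 1] + 1L
    if (e[i] <= s[i]) e[i] <- ex[i, "end"]
    if (e[i] <= s[i]) e[i] <- s[i] + 1L
  }
  cbind(start = s, end = e)
}

drop_exons <- function(ex, rate) {
  n <- nrow(ex)
  if (rate <= 0 || n < 2) return(ex)
  keep <- stats::runif(n) >= rate
  if (!any(keep)) keep[1] <- TRUE
  ex[keep, , drop = FALSE]
}

place_false_positives <- function(pool, n_fp, fp_length, method_name) {
  pool <- dplyr::arrange(pool, .data$seqid, .data$start)
  usable <- pool[pool$end - pool$start >= fp_length[1], ]
  if (nrow(usable) == 0) {
    rlang::abort("no intergenic space left for spurious genes; lower fp_rate")
  }
  rows <- vector("list", n_fp)
  for (i in seq_len(n_fp)) {
    gap <- usable[((i - 1) %% nrow(usable)) + 1, ]
    # cycle through gaps; within one gap place successive genes side by side
    round_idx <- (i - 1) %/% nrow(usable)
    max_len <- min(fp_length[2], gap$end - gap$start)
    len <- sample(fp_length[1]:max_len, 1)
    offset_max <- gap$end - gap$start - len
    start <- gap$start + sample(0:offset_max, 1)
    if (round_idx > 0) {
      rlang::abort("no intergenic space left for spurious genes; lower fp_rate")
    }
    rows[[i]] <- tibble::tibble(
      seqid = gap$seqid, start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), 1),
      gene_id = sprintf("%s_fp%03d", method_name, i),
      transcript_id = sprintf("%s_fp%03d.t1", method_name, i)
    )
  }
  dplyr::bind_rows(rows)
}
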