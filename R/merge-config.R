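#' Configuration for the merge engine
#'
#' @param threshold Supporting-overlap threshold `t` in (0, 1]. An evidence
#'   overlap supports a leading (ab initio) prediction only when the shared
#'   exonic nucleotides exceed `t` of the leading prediction's exonic length
#'   (strictly greater). Default 0.8; set 1 to accept only perfect
#'   (boundary-identical) overlaps.
#' @param mode `"prokaryote"` (locus-level, single-exon genes) or
#'   `"eukaryote"` (exon-chain matching per transcript isoform).
#' @param include_novel Report genes absent from the ab initio output but
#'   concordantly predicted by at least `min_evidence_for_novel` distinct
#'   evidence-based methods.
#' @param min_evidence_for_novel Minimum number of distinct evidence methods
#'   that must agree before a gene is reported as novel (>= 2).
#' @param strand_policy `"require_match"`: strands must be identical;
#'   `"ignore_unstranded"`: a `"."` strand (e.g. from Glimmer3 conversions)
#'   is comparable to both strands; `"ignore_all"`: strand never restricts
#'   comparison.
#' @param score_map Named numeric vector mapping support classes to the score
#'   written to the merged GTF. Only the ordering PERFECT > SUPPORTED is
#'   semantically fixed; values are conventions.
#' @return A `merge_config` list.
#' @export
merge_config <- function(threshold = 0.8,
                         mode = c("prokaryote", "eukaryote"),
                         include_novel = FALSE,
                         min_evidence_for_novel = 2L,
                         strand_policy = c("require_match",
                                           "ignore_unstranded",
                                           "ignore_all"),
                         score_map = c(PERFECT = 1.0, SUPPORTED = 0.75,
                                       PARTIAL_ACCEPTED = 0.5,
                                       NOVEL_EVIDENCE = 0.5)) {
  mode <- match.arg(mode)
  strand_policy <- match.arg(strand_policy)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    rlang::abort("threshold must be a single number in (0, 1]")
  }
  if (min_evidence_for_novel < 2) {
    rlang::abort("min_evidence_for_novel must be >= 2")
  }
  needed <- c("PERFECT", "SUPPORTED", "PARTIAL_ACCEPTED", "NOVEL_EVIDENCE")
  if (!all(needed %in% names(score_map))) {
    rlang::abort(paste0("score_map must name: ", paste(needed, collapse = ", ")))
  }
  structure(
    list(
      threshold = threshold, mode = mode, include_novel = include_novel,
      min_evidence_for_novel = as.integer(min_evidence_for_novel),
      strand_policy = strand_policy, score_map = score_map
    ),
    class = "merge_config"
  )
}

support_classes <- function() {
  c("PERFECT", "SUPPORTED", "PARTIAL_ACCEPTED", "NOVEL_EVIDENCE",
    "UNSUPPORTED")
}

strands_compatible <- function(a, b, policy) {
  switch(policy,
    require_match = a == b,
    ignore_unstranded = a == b | a == "." | b == ".",
    ignore_all = rep(TRUE, length(a))
  )
}
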