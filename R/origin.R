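# Viral pore-module consensus and candidate-hit evaluation: derive the
# family consensus, search it against a protein set, and check whether a
# hit carries the canonical selectivity filter (a similar protein without
# the filter is unlikely to be a working K+ channel).

#' Consensus sequence of a viral pore-module family
#'
#' Aligns the pore modules progressively and takes the column-majority
#' consensus; provenance (alignment, threshold, ids) is attached.
#'
#' @param modules record `data.frame` of >= 3 viral pore-module sequences.
#' @param threshold consensus threshold in (0, 1] (default 0.7).
#' @param matrix,gap_open,gap_extend alignment parameters
#'   (see [align_progressive()]).
#' @return list with `sequence`, `threshold`, `alignment`, `ids`.
#' @export
viral_consensus <- function(modules, threshold = 0.7, matrix = "BLOSUM62",
                            gap_open = -10, gap_extend = -1) {
  if (NROW(modules) < 3L) stop("need >= 3 pore modules")
  aln <- align_progressive(modules, matrix, gap_open, gap_extend)
  cons <- consensus_sequence(aln, threshold)
  list(sequence = cons$sequence, threshold = threshold, alignment = aln,
       ids = rownames(aln))
}

#' Evaluate a similarity-search hit as a K+ channel candidate
#'
#' Runs the filter-motif scan and the consensus TM prediction on the hit;
#' `has_canonical_filter` is true iff at least one motif sits in the
#' canonical TxxTxG\[FY\]G context. A hit with conserved membrane topology
#' but no canonical filter (an LPA-like decoy) is reported as a probable
#' non-channel.
#'
#' @param record one-row protein record or sequence string.
#' @param params screen parameters (see [screen_candidates()]).
#' @return list with `has_canonical_filter`, `hits` (motif table),
#'   `tm_count`, `tms`.
#' @export
evaluate_hit <- function(record, params = list()) {
  p <- modifyList(list(window_sizes = c(19L, 21L), threshold = 1.6,
                       min_votes = 2L, min_len = 15L), params)
  r <- as_protein(record)
  hits <- scan_filter_motifs(r$seq)
  tms <- if (nchar(r$seq) >= max(p$window_sizes)) {
    predict_tm_segments(r$seq, p$window_sizes, p$threshold, p$min_votes,
                        p$min_len)
  } else {
    data.frame(start = integer(), end = integer(),
               mean_hydropathy = numeric(), votes = integer())
  }
  list(has_canonical_filter = any(hits$canonical),
       hits = hits, tm_count = nrow(tms), tms = tms)
}

#' Write a hit-evaluation report TSV
#'
#' @param evaluations named list of [evaluate_hit()] results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_report <- function(evaluations, path) {
  tab <- do.call(rbind, lapply(names(evaluations), function(id) {
    e <- evaluations[[id]]
    data.frame(id = id, has_canonical_filter = e$has_canonical_filter,
               n_motifs = nrow(e$hits), n_tms = e$tm_count,
               motif_positions = paste(e$hits$position, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
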