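# K+ channel candidate screen: selectivity-filter motifs, hydropathy-based
# transmembrane prediction, and pore-module delineation.
#
# The selectivity filter of every known K+ channel carries one of the
# tripeptides GYG / GFG / GLG; the canonical signature is the 8-residue
# pattern TxxTxG[F/Y]G ending on the motif's final G. The pore module is the
# minimal channel unit: the transmembrane helix before the filter, the pore
# helix + filter, and the transmembrane helix after it.

FILTER_MOTIFS <- c("GYG", "GFG", "GLG")

as_protein <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) stop("expected a single record")
    if (record$alphabet != "protein") stop("protein record required, got nucleotide")
    list(id = record$id, seq = record$seq)
  } else if (is.character(record) && length(record) == 1L) {
    list(id = "query", seq = toupper(record))
  } else stop("record must be a one-row record data.frame or a string")
}

#' Scan a protein for selectivity-filter motifs
#'
#' Finds all occurrences of the K+ channel filter tripeptides GYG, GFG and
#' GLG. A hit is flagged `canonical` when the surrounding 8 residues match
#' the signature `TxxTxG[FY]G` (anchored so the signature's final G is the
#' motif's last residue); GLG hits are therefore never canonical.
#'
#' @param record one-row protein record `data.frame`, or a plain sequence
#'   string.
#' @return a `data.frame` with columns `motif`, `position` (1-based motif
#'   start) and `canonical`, sorted by position.
#' @export
scan_filter_motifs <- function(record) {
  r <- as_protein(record)
  hits <- data.frame(motif = character(), position = integer(),
                     canonical = logical(), stringsAsFactors = FALSE)
  for (m in FILTER_MOTIFS) {
    p <- gregexpr(m, r$seq, fixed = TRUE)[[1]]
    # gregexpr misses overlapping occurrences of the same motif; GYGYG-style
    # overlaps matter here, so rescan from each match + 1
    pos <- integer()
    start <- 1L
    while (TRUE) {
      hit <- regexpr(m, substring(r$seq, start), fixed = TRUE)
      if (hit == -1L) break
      pos <- c(pos, start + as.integer(hit) - 1L)
      start <- start + as.integer(hit)
    }
    if (length(pos)) {
      hits <- rbind(hits, data.frame(motif = m, position = pos,
                                     canonical = FALSE, stringsAsFactors = FALSE))
    }
  }
  if (nrow(hits)) {
    hits <- hits[order(hits$position), , drop = FALSE]
    rownames(hits) <- NULL
    for (i in seq_len(nrow(hits))) {
      p <- hits$position[[i]]
      if (p >= 6L) {
        ctx <- substring(r$seq, p - 5L, p + 2L)
        hits$canonical[[i]] <- grepl("^T..T.G[FY]G$", ctx)
      }
    }
  }
  hits
}

#' Sliding-window hydropathy profile
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy over a sliding
#' window; the unknown residue X contributes 0. `values[i]` is the mean over
#' residues `[i, i + window_size - 1]`.
#'
#' @param record one-row protein record or sequence string.
#' @param window_size odd window width in residues, >= 7, <= sequence length.
#' @return list with `record_id`, `window_size` and numeric `values` of
#'   length `nchar(seq) - window_size + 1`.
#' @export
hydropathy_profile <- function(record, window_size = 19L) {
  r <- as_protein(record)
  n <- nchar(r$seq)
  w <- as.integer(window_size)
  if (w %% 2L == 0L || w < 7L) stop("window_size must be odd and >= 7")
  if (w > n) stop("window (", w, ") longer than sequence (", n, ")")
  kd <- load_kd_scale()
  vals <- kd[strsplit(r$seq, "")[[1]]]
  vals[is.na(vals)] <- 0 # X
  cs <- c(0, cumsum(vals))
  prof <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  list(record_id = r$id, window_size = w, values = unname(prof))
}

#' Consensus transmembrane-segment prediction
#'
#' Runs the hydropathy profile at several window sizes; for each size,
#' maximal runs of window positions at or above `threshold` become candidate
#' intervals covering the full window extent. Overlapping candidates from
#' different window sizes are merged; a merged segment is kept when it is
#' supported by at least `min_votes` window sizes and spans at least
#' `min_len` residues.
#'
#' @param record one-row protein record or sequence string.
#' @param window_sizes odd window widths (default 19 and 21).
#' @param threshold mean hydropathy cutoff (Kyte-Doolittle units,
#'   default 1.6).
#' @param min_votes minimum number of supporting window sizes (default 2).
#' @param min_len minimum segment length in residues (default 15).
#' @return a `data.frame` of non-overlapping, sorted segments with columns
#'   `start`, `end` (1-based, closed), `mean_hydropathy`, `votes`.
#' @export
predict_tm_segments <- function(record, window_sizes = c(19L, 21L),
                                threshold = 1.6, min_votes = 2L,
                                min_len = 15L) {
  if (!length(window_sizes)) stop("empty window_sizes")
  r <- as_protein(record)
  cand <- list()
  for (w in as.integer(window_sizes)) {
    prof <- hydropathy_profile(r$seq, w)$values
    above <- prof >= threshold
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      cand[[length(cand) + 1L]] <-
        c(start = starts[[k]], end = ends[[k]] + w - 1L, w = w)
    }
  }
  out <- data.frame(start = integer(), end = integer(),
                    mean_hydropathy = numeric(), votes = integer())
  if (!length(cand)) return(out)
  cm <- do.call(rbind, cand)
  cm <- cm[order(cm[, "start"], cm[, "end"]), , drop = FALSE]
  # merge overlapping candidate intervals, counting distinct window sizes
  segs <- list()
  cur <- list(start = cm[1, "start"], end = cm[1, "end"], ws = cm[1, "w"])
  for (i in seq_len(nrow(cm))[-1]) {
    if (cm[i, "start"] <= cur$end) {
      cur$end <- max(cur$end, cm[i, "end"])
      cur$ws <- c(cur$ws, cm[i, "w"])
    } else {
      segs[[length(segs) + 1L]] <- cur
      cur <- list(start = cm[i, "start"], end = cm[i, "end"], ws = cm[i, "w"])
    }
  }
  segs[[length(segs) + 1L]] <- cur
  kd <- load_kd_scale()
  chars <- strsplit(r$seq, "")[[1]]
  vals <- kd[chars]; vals[is.na(vals)] <- 0
  for (s in segs) {
    votes <- length(unique(s$ws))
    len <- s$end - s$start + 1L
    if (votes >= min_votes && len >= min_len) {
      out <- rbind(out, data.frame(
        start = as.integer(s$start), end = as.integer(s$end),
        mean_hydropathy = mean(vals[s$start:s$end]),
        votes = as.integer(votes)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Screen a protein set for K+ channel candidates
#'
#' A record passes when it carries at least one selectivity-filter motif and
#' at least two predicted transmembrane segments. Every record is reported
#' with its evidence; nothing is silently dropped.
#'
#' @param records a protein record `data.frame`.
#' @param params list of screen parameters: `window_sizes`, `threshold`,
#'   `min_votes`, `min_len` (see [predict_tm_segments()]).
#' @return a list with one entry per record: `id`, `hits` (filter motifs),
#'   `tms` (TM segments), `passed`. The summary table is available via
#'   [screen_summary()].
#' @export
screen_candidates <- function(records, params = list()) {
  p <- modifyList(list(window_sizes = c(19L, 21L), threshold = 1.6,
                       min_votes = 2L, min_len = 15L), params)
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    hits <- scan_filter_motifs(rec)
    tms <- if (nchar(rec$seq) >= max(p$window_sizes)) {
      predict_tm_segments(rec, p$window_sizes, p$threshold, p$min_votes,
                          p$min_len)
    } else {
      data.frame(start = integer(), end = integer(),
                 mean_hydropathy = numeric(), votes = integer())
    }
    list(id = rec$id, record = rec, hits = hits, tms = tms,
         passed = nrow(hits) >= 1L && nrow(tms) >= 2L)
  })
  names(out) <- records$id
  class(out) <- "screen_result"
  out
}

#' @rdname screen_candidates
#' @export
screen_summary <- function(screen) {
  do.call(rbind, lapply(screen, function(x) {
    mod <- tryCatch(extract_pore_module(x$record, x$tms, x$hits),
                    error = function(e) NULL)
    data.frame(id = x$id, n_motifs = nrow(x$hits), n_tms = nrow(x$tms),
               passed = x$passed,
               module_start = if (is.null(mod)) NA_integer_ else mod$module_start,
               module_end = if (is.null(mod)) NA_integer_ else mod$module_end,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Delineate the pore module
#'
#' The pore module runs from the start of the transmembrane segment before
#' the selectivity filter to the end of the transmembrane segment after it.
#' Among filter hits flanked by such a TM pair, canonical hits are
#' preferred; remaining ties are broken by tightest flanking-TM spacing,
#' then by smallest position. Aromatic residues (F/W/Y) in the 15 residues
#' upstream of the filter (the pore helix) are recorded.
#'
#' @param record one-row protein record.
#' @param tms TM segment `data.frame` from [predict_tm_segments()].
#' @param hits filter hits from [scan_filter_motifs()].
#' @return a list of class `pore_module`: `record_id`, `module_start`,
#'   `module_end`, `tm1`, `tm2`, `filter` (the chosen hit),
#'   `pore_helix_aromatics` (absolute positions), `seq` (module substring).
#' @export
extract_pore_module <- function(record, tms, hits) {
  r <- as_protein(record)
  if (nrow(tms) < 1L) stop("NoPoreModule: no TM segment")
  if (nrow(hits) < 1L) stop("NoPoreModule: no filter motif")
  best <- NULL
  for (i in seq_len(nrow(hits))) {
    p <- hits$position[[i]]
    # hydropathy windows bleed across the (partly hydrophobic) filter, so a
    # predicted TM often overlaps it; the filter is by definition not
    # transmembrane, so clip segments at the filter boundaries before
    # looking for the flanking pair (clipped parts must still look like a
    # TM, i.e. span >= 15 residues)
    cand <- tms
    for (s in seq_len(nrow(tms))) {
      if (tms$start[[s]] <= p - 1L && tms$end[[s]] >= p - 1L &&
          p - tms$start[[s]] >= 15L) {
        cand <- rbind(cand, transform(tms[s, ], end = p - 1L))
      }
      if (tms$start[[s]] <= p + 3L && tms$end[[s]] >= p + 3L &&
          tms$end[[s]] - (p + 2L) >= 15L) {
        cand <- rbind(cand, transform(tms[s, ], start = p + 3L))
      }
    }
    up <- cand[cand$end <= p - 1L, , drop = FALSE]
    down <- cand[cand$start >= p + 3L, , drop = FALSE]
    if (!nrow(up) || !nrow(down)) next
    tm1 <- up[which.max(up$end), ]
    tm2 <- down[which.min(down$start), ]
    gap <- (p - tm1$end) + (tm2$start - (p + 2L))
    cand <- list(hit = hits[i, ], tm1 = tm1, tm2 = tm2, gap = gap)
    if (is.null(best) ||
        (cand$hit$canonical && !best$hit$canonical) ||
        (cand$hit$canonical == best$hit$canonical &&
         (cand$gap < best$gap ||
          (cand$gap == best$gap && cand$hit$position < best$hit$position)))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("NoPoreModule: no filter hit flanked by a TM pair")
  p <- best$hit$position
  upstream <- max(1L, p - 15L):(p - 1L)
  chars <- strsplit(r$seq, "")[[1]]
  arom <- upstream[chars[upstream] %in% c("F", "W", "Y")]
  structure(list(
    record_id = r$id,
    module_start = as.integer(best$tm1$start),
    module_end = as.integer(best$tm2$end),
    tm1 = best$tm1, tm2 = best$tm2, filter = best$hit,
    pore_helix_aromatics = as.integer(arom),
    seq = substring(r$seq, best$tm1$start, best$tm2$end)
  ), class = "pore_module")
}

#' Extract pore modules for a screened record set
#'
#' Convenience over [screen_candidates()] + [extract_pore_module()]. Records
#' whose module cannot be delineated fall back to their full-length sequence
#' (flagged in the result) so that downstream taxon sets stay complete.
#'
#' @param records protein record `data.frame`.
#' @param params screen parameters (see [screen_candidates()]).
#' @return record `data.frame` of module sequences, with extra columns
#'   `module_start`, `module_end`, `is_module`.
#' @export
prepare_pore_modules <- function(records, params = list()) {
  screen <- screen_candidates(records, params)
  rows <- lapply(screen, function(x) {
    mod <- tryCatch(extract_pore_module(x$record, x$tms, x$hits),
                    error = function(e) NULL)
    r <- x$record
    if (!is.null(mod)) {
      r$seq <- mod$seq
      r$module_start <- mod$module_start
      r$module_end <- mod$module_end
      r$is_module <- TRUE
    } else {
      r$module_start <- NA_integer_
      r$module_end <- NA_integer_
      r$is_module <- FALSE
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the screen report TSV
#'
#' @param screen a `screen_result` from [screen_candidates()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path) {
  write.table(screen_summary(screen), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
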