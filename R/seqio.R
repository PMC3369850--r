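# Sequence and tree I/O: FASTA, label maps (TSV), Newick.
#
# Coordinate convention: all positions and intervals in this package are
# 1-based and closed ([start, end] includes both endpoints), the R/IRanges
# convention.

PROTEIN_ALPHABET <- c(AA20, "X")
NUCLEOTIDE_ALPHABET <- c(NUC4, "N")
ROLES <- c("viral", "host", "outgroup", "unknown")

alphabet_chars <- function(alphabet, gapped = FALSE) {
  chars <- switch(alphabet,
    protein = PROTEIN_ALPHABET,
    nucleotide = NUCLEOTIDE_ALPHABET,
    stop("unknown alphabet: ", alphabet)
  )
  if (gapped) chars <- c(chars, "-")
  chars
}

#' Construct a set of sequence records
#'
#' The core data model is a plain `data.frame` with one row per sequence and
#' columns `id`, `seq`, `alphabet`, `role`, `source`, `desc`. Sequences are
#' stored uppercase; ids must be unique; every character must belong to the
#' declared alphabet (protein: the 20 residues plus X; nucleotide: ACGT plus
#' N), with `-` additionally permitted when `gapped = TRUE`.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of residue strings (case-insensitive input).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param role one of `"viral"`, `"host"`, `"outgroup"`, `"unknown"`
#'   (recycled).
#' @param source free-text provenance tag, e.g. the host species (recycled).
#' @param desc FASTA description (text after the first whitespace).
#' @param gapped allow the gap character `-` (alignment rows).
#' @return a `data.frame` of validated sequence records.
#' @export
seq_records <- function(id, seq, alphabet = "protein", role = "unknown",
                        source = NA_character_, desc = "", gapped = FALSE) {
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (length(id) == 0L) stop("empty record set")
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  if (any(!nzchar(seq))) stop("empty sequence for id: ", id[!nzchar(seq)][1L])
  ok <- alphabet_chars(alphabet, gapped = gapped)
  for (i in seq_along(seq)) {
    chars <- strsplit(seq[[i]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad)) {
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   chars[bad[1L]], id[[i]], bad[1L]))
    }
  }
  role <- rep_len(as.character(role), length(id))
  if (any(!role %in% ROLES)) stop("unknown role: ", setdiff(role, ROLES)[1L])
  data.frame(id = id, seq = seq, alphabet = alphabet, role = role,
             source = rep_len(as.character(source), length(id)),
             desc = rep_len(as.character(desc), length(id)),
             stringsAsFactors = FALSE)
}

#' Read and write FASTA
#'
#' `read_fasta()` parses a (possibly line-wrapped) FASTA file into a record
#' `data.frame` (see [seq_records()]); the header token before the first
#' whitespace becomes the id, the remainder the description; input order is
#' preserved. Duplicate ids, illegal characters and empty files are hard
#' errors. `write_fasta()` emits records with sequence lines wrapped at 80
#' columns; the round trip reproduces ids and sequences exactly.
#'
#' @param path file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param gapped allow gap characters (aligned FASTA).
#' @param records a record `data.frame`.
#' @return `read_fasta()`: a record `data.frame`; `write_fasta()`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path, alphabet = "protein", gapped = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("FASTA must start with a '>' header: ", path)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[grp == i & !hdr], collapse = "")
  }, character(1))
  seq_records(id, seqs, alphabet = alphabet, desc = desc, gapped = gapped)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  if (NROW(records) == 0L) stop("refusing to write an empty FASTA")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$id[[i]],
                  if (nzchar(records$desc[[i]] %||% "")) paste0(" ", records$desc[[i]]) else "")
    writeLines(hdr, con)
    s <- records$seq[[i]]
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Read and write viral/host label maps
#'
#' A label map is a headerless TSV with columns id, role and (optionally) a
#' source tag such as the host species. `assign_roles()` joins a label map
#' onto a record set; every record id must resolve to exactly one role.
#'
#' @param path TSV file path.
#' @param labels a label-map `data.frame` (columns `id`, `role`, optional
#'   `source`).
#' @param records a record `data.frame`.
#' @return `read_label_map()`: a `data.frame` with columns `id`, `role`,
#'   `source`; `assign_roles()`: the records with `role` (and `source`)
#'   filled in.
#' @export
read_label_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("label map needs at least 2 columns (id, role)")
  out <- data.frame(id = as.character(tab[[1]]), role = as.character(tab[[2]]),
                    source = if (ncol(tab) >= 3L) as.character(tab[[3]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop("duplicate id in label map: ", out$id[duplicated(out$id)][1L])
  }
  if (any(!out$role %in% ROLES)) {
    stop("unknown role in label map: ", setdiff(out$role, ROLES)[1L])
  }
  out
}

#' @rdname read_label_map
#' @export
write_label_map <- function(labels, path) {
  cols <- c("id", "role", if (!all(is.na(labels$source))) "source")
  write.table(labels[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_label_map
#' @export
assign_roles <- function(records, labels) {
  idx <- match(records$id, labels$id)
  if (anyNA(idx)) {
    stop("no role for id: ", records$id[is.na(idx)][1L])
  }
  records$role <- labels$role[idx]
  if (!all(is.na(labels$source))) records$source <- labels$source[idx]
  records
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape that enforce this package's conventions: trees are
#' unrooted, branch lengths are substitutions/site, and internal-node labels
#' are bootstrap/posterior support values in \[0, 100\] (non-numeric labels
#' are rejected). `read_newick()` accepts a Newick string or a file path.
#'
#' @param text a Newick string (or a path to a file containing one).
#' @param tree an ape `phylo` object.
#' @param include_support emit internal-node support labels.
#' @return `read_newick()`: an ape `phylo`; `write_newick()`: a Newick
#'   string.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- gsub("\r", "", text)
  no <- sum(strsplit(text, "")[[1]] == "(")
  nc <- sum(strsplit(text, "")[[1]] == ")")
  if (no != nc) {
    stop(sprintf("unbalanced parentheses in Newick (%d open, %d close) near offset %d",
                 no, nc, nchar(text)))
  }
  if (grepl(",\\s*[),]", text) || grepl("\\(\\s*,", text)) {
    stop("dangling comma in Newick at offset ",
         regexpr(",\\s*[),]|\\(\\s*,", text)[1L])
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse failure")
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    nonempty <- nzchar(lab)
    sup <- suppressWarnings(as.numeric(lab[nonempty]))
    if (anyNA(sup)) {
      stop("non-numeric internal node label (labels are support values): ",
           lab[nonempty][is.na(sup)][1L])
    }
    if (length(sup) && (min(sup) < 0 || max(sup) > 100)) {
      stop("support label outside [0, 100]")
    }
  }
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, include_support = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (!include_support) tree$node.label <- NULL
  ape::write.tree(tree, digits = 12)
}
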