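#' Read sequences from a FASTA file
#'
#' Parses a (multi-record, wrapped or single-line) FASTA file of contigs or
#' long reads into a sequence record table. Sequences are uppercased; the
#' record id is the header token before the first whitespace. Only the
#' alphabet \code{A,C,G,T,N} (case-insensitive) is accepted: ambiguity codes
#' other than N are rejected so that downstream k-mer semantics stay
#' well-defined.
#'
#' @param path Path to an existing FASTA file with at least one record.
#' @return A data.frame of class \code{seq_records} with columns
#'   \code{id} (character, unique), \code{seq} (uppercase character),
#'   \code{length} (integer, bp) and \code{gc} (GC fraction computed over
#'   non-N positions only; \code{NA} if the sequence is all N).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a contig", "ACGT", ">s2", "GGGNCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA header with empty id in: ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop("sequence '", ids[i], "' contains disallowed character '", ch,
         "' (allowed: A, C, G, T, N)")
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id '", ids[which(nchar(seqs) == 0L)[1L]], "'")
  }
  new_seq_records(ids, seqs)
}

new_seq_records <- function(ids, seqs) {
  recs <- data.frame(
    id = ids,
    seq = unname(seqs),
    length = nchar(seqs),
    gc = gc_fraction(seqs),
    stringsAsFactors = FALSE
  )
  rownames(recs) <- NULL
  class(recs) <- c("seq_records", "data.frame")
  recs
}

#' GC fraction over non-N positions
#'
#' @param seqs Character vector of uppercase DNA sequences (A/C/G/T/N).
#' @return Numeric vector in \[0, 1\]; \code{NA} where no A/C/G/T position exists.
#' @export
gc_fraction <- function(seqs) {
  gc <- nchar(gsub("[^GC]", "", seqs))
  acgt <- nchar(gsub("[^ACGT]", "", seqs))
  ifelse(acgt > 0L, gc / acgt, NA_real_)
}

#' Filter sequence records by minimum length
#'
#' Keeps records with \code{length >= min_length} (inclusive), preserving
#' input order, and reports the discarded ids with their lengths. Short
#' sequences are not lost downstream: the binning pipeline routes them to
#' classifier-based assignment instead of embedding them.
#'
#' @param records A \code{seq_records} table from [read_fasta()].
#' @param min_length Minimum length in bp (default 500).
#' @return A list of class \code{length_filter_result} with elements
#'   \code{kept} (a \code{seq_records} table), \code{discarded}
#'   (data.frame \code{id}, \code{length}) and \code{min_length}.
#' @export
filter_by_length <- function(records, min_length = 500L) {
  stopifnot(inherits(records, "data.frame"), min_length >= 1)
  keep <- records$length >= min_length
  if (!any(keep)) stop("no sequences pass length filter (min_length = ", min_length, ")")
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("seq_records", "data.frame")
  res <- list(
    kept = kept,
    discarded = data.frame(
      id = records$id[!keep],
      length = records$length[!keep],
      stringsAsFactors = FALSE
    ),
    min_length = as.integer(min_length)
  )
  class(res) <- "length_filter_result"
  res
}

#' Write sequence records to a FASTA file
#'
#' @param records A \code{seq_records} table.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines (default 80).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(nrow(records) > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.seq_records <- function(x, ...) {
  cat("<seq_records> ", nrow(x), " sequence(s), total ",
      sum(x$length), " bp\n", sep = "")
  NextMethod()
}
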