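#' Reverse complement of DNA strings
#'
#' @param x Character vector over A/C/G/T/N (uppercase).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Build the canonical k-mer feature space
#'
#' Enumerates all k-mers over \{A,C,G,T\} and collapses each with its reverse
#' complement; the canonical form is the lexicographic minimum of the pair.
#' Collapsing removes strand ambiguity (a contig's strand is arbitrary) and
#' yields 136 features for k = 4 (16 palindromes + 120 pairs) and 512 for
#' k = 5 (odd k has no reverse-complement palindromes).
#'
#' @param k Word length, 4 or 5.
#' @return A list of class \code{kmer_index}: \code{k}, \code{kmers}
#'   (canonical k-mers in lexicographic order = column order),
#'   \code{n_features}, and \code{collapse_map} (integer vector mapping each
#'   of the 4^k plain k-mers, in lexicographic order, to its canonical
#'   column).
#' @examples
#' build_kmer_index(4)$n_features  # 136
#' @export
build_kmer_index <- function(k) {
  if (length(k) != 1L || !k %in% c(4L, 5L)) {
    stop("k must be 4 or 5 (profiles of other lengths are unsupported)")
  }
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  all_kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                               stringsAsFactors = FALSE)))
  all_kmers <- sort(all_kmers)
  rc <- revcomp(all_kmers)
  canon <- pmin(all_kmers, rc)
  kmers <- sort(unique(canon))
  idx <- list(
    k = k,
    kmers = kmers,
    n_features = length(kmers),
    collapse_map = match(canon, kmers)
  )
  class(idx) <- "kmer_index"
  idx
}

#' Normalized canonical k-mer profile of one sequence
#'
#' Slides a window of length k (step 1) over the sequence; windows containing
#' N are skipped; each valid window increments its canonical k-mer's count.
#' The profile is the count vector divided by the number of valid windows.
#'
#' @param seq A single uppercase DNA string, or a one-row \code{seq_records}
#'   table.
#' @param index A \code{kmer_index} from [build_kmer_index()].
#' @return A list with \code{profile} (named numeric vector over the
#'   canonical feature space, summing to 1) and \code{valid_kmer_count}.
#' @export
kmer_profile <- function(seq, index) {
  id <- "<sequence>"
  if (inherits(seq, "data.frame")) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    seq <- seq$seq
  }
  if (nchar(seq) < index$k) {
    stop("sequence '", id, "' is shorter than k = ", index$k)
  }
  counts <- canonical_counts(seq, index)
  total <- sum(counts)
  if (total == 0L) {
    stop("sequence '", id, "' has no valid k-mer window (all windows contain N)")
  }
  list(profile = counts / total, valid_kmer_count = total)
}

# Canonical k-mer counts for a vector of sequences: n x n_features integer
# matrix. Window counting delegates to oligonucleotideFrequency (windows with
# any non-ACGT letter contribute to no count, i.e. N-windows are skipped);
# reverse-complement collapsing sums plain counts into canonical columns.
canonical_counts <- function(seqs, index) {
  dss <- Biostrings::DNAStringSet(seqs)
  raw <- Biostrings::oligonucleotideFrequency(dss, width = index$k)
  # raw columns are the 4^k plain k-mers in lexicographic order
  n <- nrow(raw)
  out <- matrix(0L, nrow = n, ncol = index$n_features,
                dimnames = list(NULL, index$kmers))
  for (col in seq_along(index$collapse_map)) {
    tgt <- index$collapse_map[col]
    out[, tgt] <- out[, tgt] + raw[, col]
  }
  if (n == 1L) return(out[1L, ])
  out
}

#' Profile matrix for a set of sequences
#'
#' Batch form of [kmer_profile()]: one row per record, rows in input order.
#'
#' @param records A \code{seq_records} table (every sequence must have at
#'   least one N-free window of length k).
#' @param k Word length, 4 or 5 (default 5).
#' @return A list of class \code{profile_matrix}: \code{ids}, \code{k},
#'   \code{values} (n x n_features matrix, rows sum to 1),
#'   \code{valid_kmer_counts}, and the \code{kmer_index} used.
#' @export
profile_matrix <- function(records, k = 5L) {
  if (!inherits(records, "data.frame") || nrow(records) == 0L) {
    stop("no sequence records to profile")
  }
  index <- build_kmer_index(k)
  too_short <- records$length < index$k
  if (any(too_short)) {
    stop("sequence '", records$id[which(too_short)[1L]],
         "' is shorter than k = ", index$k)
  }
  counts <- canonical_counts(records$seq, index)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, index$kmers))
  totals <- rowSums(counts)
  if (any(totals == 0L)) {
    stop("sequence '", records$id[which(totals == 0L)[1L]],
         "' has no valid k-mer window (all windows contain N)")
  }
  pm <- list(
    ids = records$id,
    k = index$k,
    values = counts / totals,
    valid_kmer_counts = as.integer(totals),
    index = index
  )
  class(pm) <- "profile_matrix"
  pm
}

#' Export a profile matrix as TSV
#'
#' First column \code{sequence_id}, then one column per canonical k-mer.
#'
#' @param pm A \code{profile_matrix}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_profile_tsv <- function(pm, path) {
  df <- data.frame(sequence_id = pm$ids, pm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", length(x$ids), " sequence(s) x ",
      ncol(x$values), " canonical ", x$k, "-mers\n", sep = "")
  invisible(x)
}
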