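# Ground-truthed synthetic communities: each genome is an order-m Markov
# chain whose transition rows are drawn from a Dirichlet prior, so genomes
# carry distinct k-mer signatures by construction and every stage of the
# binning pipeline can be benchmarked without external data.

#' Specification of a synthetic community
#'
#' @param n_genomes Number of source genomes (>= 2).
#' @param genome_length Genome length in bp (default 200000).
#' @param markov_order Context length of the per-genome Markov chain
#'   (default 3, <= 4); order 3 makes 4-mer and 5-mer profiles
#'   genome-identifying by construction.
#' @param distinctness_alpha Dirichlet concentration for transition rows
#'   (default 0.1); smaller values give more distinct genomes.
#' @param fragments_per_genome Fragments drawn per genome (default 200).
#' @param fragment_length_median Median fragment length in bp (default 5000).
#' @param fragment_length_sigma Lognormal sd of fragment lengths
#'   (default 0.5) — emulates the skewed length distributions of assemblies
#'   and nanopore runs.
#' @param seed Integer master seed; all draws derive from it.
#' @return A list of class \code{community_spec}.
#' @export
community_spec <- function(n_genomes = 5L, genome_length = 200000L,
                           markov_order = 3L, distinctness_alpha = 0.1,
                           fragments_per_genome = 200L,
                           fragment_length_median = 5000L,
                           fragment_length_sigma = 0.5, seed = 1L) {
  stopifnot(n_genomes >= 2L, genome_length >= 1L, markov_order >= 1L,
            markov_order <= 4L, distinctness_alpha > 0,
            fragments_per_genome >= 1L, fragment_length_median >= 1L,
            fragment_length_sigma > 0)
  spec <- list(n_genomes = as.integer(n_genomes),
               genome_length = as.integer(genome_length),
               markov_order = as.integer(markov_order),
               distinctness_alpha = distinctness_alpha,
               fragments_per_genome = as.integer(fragments_per_genome),
               fragment_length_median = as.integer(fragment_length_median),
               fragment_length_sigma = fragment_length_sigma,
               seed = as.integer(seed))
  class(spec) <- "community_spec"
  spec
}

# Deterministic substream seed for (master seed, genome, purpose), kept
# within 32-bit integer range.
substream_seed <- function(seed, genome_index, stream) {
  (abs(seed) * 97L + genome_index * 7919L + stream * 104729L) %%
    .Machine$integer.max
}

#' Sample one synthetic genome
#'
#' Draws a per-genome transition matrix over the 4^markov_order contexts
#' (each row Dirichlet(distinctness_alpha)) from the genome's own substream
#' of the master seed, then generates the sequence from the chain.
#' Deterministic given (spec$seed, genome_index).
#'
#' @param spec A [community_spec()].
#' @param genome_index Genome number (1-based).
#' @return A single uppercase DNA string of length \code{spec$genome_length}.
#' @export
sample_genome <- function(spec, genome_index) {
  stopifnot(inherits(spec, "community_spec"),
            genome_index >= 1L, genome_index <= spec$n_genomes)
  set.seed(substream_seed(spec$seed, genome_index, 1L))
  m <- spec$markov_order
  n_ctx <- 4L^m
  # Dirichlet rows via normalized gammas
  g <- matrix(stats::rgamma(n_ctx * 4L, shape = spec$distinctness_alpha),
              nrow = n_ctx)
  g[g == 0] <- .Machine$double.xmin  # guard against underflow at tiny alpha
  trans <- g / rowSums(g)
  cum1 <- trans[, 1L]
  cum2 <- cum1 + trans[, 2L]
  cum3 <- cum2 + trans[, 3L]

  L <- spec$genome_length
  bases <- c("A", "C", "G", "T")
  out <- integer(L) # base codes 0..3
  # initial context: uniform bases
  init <- sample.int(4L, min(m, L), replace = TRUE) - 1L
  out[seq_along(init)] <- init
  if (L > m) {
    ctx <- 0L
    for (j in seq_len(m)) ctx <- ctx * 4L + init[j]
    u <- stats::runif(L - m)
    mod <- n_ctx %/% 4L
    for (i in (m + 1L):L) {
      r <- ctx + 1L
      ui <- u[i - m]
      b <- (ui > cum1[r]) + (ui > cum2[r]) + (ui > cum3[r])
      out[i] <- b
      ctx <- (ctx %% mod) * 4L + b
    }
  }
  paste(bases[out + 1L], collapse = "")
}

#' Fragment a genome into sequence records
#'
#' Draws \code{fragments_per_genome} fragments with lognormal lengths
#' (median \code{fragment_length_median}, sd \code{fragment_length_sigma}),
#' clipped to \[500, genome_length\], at uniform start positions.
#' Deterministic given the spec seed and genome index.
#'
#' @param genome A genome string from [sample_genome()].
#' @param spec A [community_spec()].
#' @param genome_index Genome number (used for ids and seeding).
#' @param id_prefix Optional prefix prepended to fragment ids (used to keep
#'   ids unique across classes in differential designs).
#' @param n_fragments Number of fragments (default
#'   \code{spec$fragments_per_genome}).
#' @param stream Substream selector so different designs draw independent
#'   fragment sets.
#' @return A list: \code{records} (a \code{seq_records} table with ids
#'   \code{[prefix]g<genome>_f<j>}) and \code{truth} (data.frame
#'   \code{sequence_id}, \code{genome}).
#' @export
fragment_genome <- function(genome, spec, genome_index, id_prefix = "",
                            n_fragments = spec$fragments_per_genome,
                            stream = 2L) {
  glen <- nchar(genome)
  if (glen < 500L) stop("genome shorter than the minimum fragment length (500 bp)")
  if (n_fragments < 1L) stop("n_fragments must be >= 1")
  set.seed(substream_seed(spec$seed, genome_index, stream))
  lens <- round(stats::rlnorm(n_fragments,
                              meanlog = log(spec$fragment_length_median),
                              sdlog = spec$fragment_length_sigma))
  lens <- pmin(pmax(lens, 500L), glen)
  starts <- floor(stats::runif(n_fragments) * (glen - lens + 1L)) + 1L
  seqs <- substring(genome, starts, starts + lens - 1L)
  ids <- sprintf("%sg%d_f%04d", id_prefix, genome_index, seq_len(n_fragments))
  list(
    records = new_seq_records(ids, seqs),
    truth = data.frame(sequence_id = ids, genome = genome_index,
                       stringsAsFactors = FALSE)
  )
}

#' Generate a single-class synthetic community
#'
#' @param spec A [community_spec()].
#' @return A list: \code{records} (all fragments, genome blocks in order),
#'   \code{truth} (sequence_id, genome), \code{genomes} (character vector).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  genomes <- vapply(seq_len(spec$n_genomes), function(i) sample_genome(spec, i),
                    character(1))
  parts <- lapply(seq_len(spec$n_genomes), function(i) {
    fragment_genome(genomes[i], spec, i)
  })
  recs <- do.call(rbind, lapply(parts, `[[`, "records"))
  class(recs) <- c("seq_records", "data.frame")
  list(records = recs,
       truth = do.call(rbind, lapply(parts, `[[`, "truth")),
       genomes = genomes)
}

#' Generate a two-class differential community
#'
#' Per class, the fragment count for genome g is
#' \code{round(fragments_per_genome * abundance[g])}; a genome with
#' abundance 0 in one class yields class-exclusive fragments — the planted
#' differential signal.
#'
#' @param spec A [community_spec()].
#' @param abundance_A,abundance_B Non-negative vectors of length
#'   \code{n_genomes}, each summing to 1.
#' @return A list: \code{records}, \code{classes} (data.frame
#'   \code{sequence_id}, \code{class} in \{A, B\}), \code{truth}
#'   (\code{sequence_id}, \code{genome}, \code{class}), \code{genomes}.
#' @export
generate_differential_pair <- function(spec, abundance_A, abundance_B) {
  stopifnot(inherits(spec, "community_spec"),
            length(abundance_A) == spec$n_genomes,
            length(abundance_B) == spec$n_genomes,
            all(abundance_A >= 0), all(abundance_B >= 0))
  if (abs(sum(abundance_A) - 1) > 1e-6 || abs(sum(abundance_B) - 1) > 1e-6) {
    stop("each abundance vector must sum to 1")
  }
  counts <- list(A = round(spec$fragments_per_genome * abundance_A),
                 B = round(spec$fragments_per_genome * abundance_B))
  if (sum(unlist(counts)) == 0L) stop("design yields zero fragments")
  genomes <- vapply(seq_len(spec$n_genomes), function(i) sample_genome(spec, i),
                    character(1))
  parts <- list()
  for (cl in c("A", "B")) {
    stream <- if (cl == "A") 3L else 4L
    for (i in seq_len(spec$n_genomes)) {
      n <- counts[[cl]][i]
      if (n < 1L) next
      fr <- fragment_genome(genomes[i], spec, i,
                            id_prefix = paste0(cl, "_"),
                            n_fragments = n, stream = stream)
      fr$truth$class <- cl
      parts[[length(parts) + 1L]] <- fr
    }
  }
  recs <- do.call(rbind, lapply(parts, `[[`, "records"))
  class(recs) <- c("seq_records", "data.frame")
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  list(records = recs,
       classes = data.frame(sequence_id = truth$sequence_id,
                            class = truth$class, stringsAsFactors = FALSE),
       truth = truth,
       genomes = genomes)
}

#' Write a synthetic community to disk
#'
#' FASTA plus truth TSV (\code{sequence_id}, \code{genome}\[, \code{class}\])
#' and, for differential designs, a class-label TSV compatible with
#' [density_difference()].
#'
#' @param community Output of [generate_community()] or
#'   [generate_differential_pair()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "community.fasta")
  write_fasta(community$records, fa)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(community$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(fa, truth)
  if (!is.null(community$classes)) {
    cls <- file.path(dir, "classes.tsv")
    utils::write.table(community$classes, cls, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, cls)
  }
  invisible(paths)
}
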