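# End-to-end orchestration: read -> length filter -> k-mer profiles ->
# embed -> cluster -> classifier assignment -> bin summary (+ optional
# two-class differential density), with a JSON run manifest sufficient to
# reproduce every output.

#' N50 of a set of lengths
#'
#' Largest L such that members with length >= L sum to at least half the
#' total bases.
#'
#' @param lengths Integer vector of sequence lengths.
#' @return Integer N50.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0L)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Summarize bins
#'
#' One row per bin (>= 1) with size, total bp, N50, mean GC, the bin's
#' fraction of all input sequences, and a minor-bin flag
#' (fraction < 0.01) marking bins small enough to be discarded from
#' further analysis.
#'
#' @param assignment A \code{bin_assignment} covering the records.
#' @param records The full \code{seq_records} table (denominator for
#'   fractions = all input sequences).
#' @return data.frame: \code{bin}, \code{n_sequences}, \code{total_bp},
#'   \code{n50}, \code{mean_gc}, \code{fraction_of_sequences},
#'   \code{minor_flag}.
#' @export
summarize_bins <- function(assignment, records) {
  total_n <- nrow(records)
  idx <- match(assignment$id, records$id)
  if (anyNA(idx)) stop("assignment contains id(s) not present in records")
  bins <- sort(unique(assignment$bin[assignment$bin >= 1L]))
  out <- do.call(rbind, lapply(bins, function(b) {
    rows <- idx[assignment$bin == b]
    lens <- records$length[rows]
    data.frame(bin = b,
               n_sequences = length(rows),
               total_bp = sum(as.numeric(lens)),
               n50 = n50(lens),
               mean_gc = mean(records$gc[rows], na.rm = TRUE),
               fraction_of_sequences = length(rows) / total_n,
               minor_flag = length(rows) / total_n < 0.01)
  }))
  out
}

#' Pipeline configuration
#'
#' @param k k-mer length, 4 or 5 (default 5).
#' @param min_length Length-filter floor in bp (default 500).
#' @param embed_method,cluster_method Backend names (defaults
#'   \code{"umap"}, \code{"hdbscan"}).
#' @param cluster_params Named list of clustering parameters.
#' @param compress,compress_dims Profile compression before embedding; see
#'   [embed_config()].
#' @param confidence_threshold Classifier assignment cut-off (default 0.5).
#' @param bandwidth,grid_size Differential-density parameters
#'   (\code{NULL} bandwidth = Scott's rule; grid default 250).
#' @param seed Master seed for every stochastic stage (default 42).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(k = 5L, min_length = 500L, embed_method = "umap",
                            cluster_method = "hdbscan",
                            cluster_params = list(), compress = NULL,
                            compress_dims = 50L, confidence_threshold = 0.5,
                            bandwidth = NULL, grid_size = 250L, seed = 42L) {
  cfg <- list(k = as.integer(k), min_length = as.integer(min_length),
              embed_method = embed_method, cluster_method = cluster_method,
              cluster_params = cluster_params, compress = compress,
              compress_dims = as.integer(compress_dims),
              confidence_threshold = confidence_threshold,
              bandwidth = bandwidth, grid_size = as.integer(grid_size),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

# write.table via a temp file + rename, so readers never see partial files
write_tsv_atomic <- function(df, path, col.names = TRUE) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full binning pipeline
#'
#' Reads a FASTA, filters by length, computes canonical k-mer profiles,
#' embeds the filtered sequences in 2D, clusters the embedding, trains the
#' bin classifier on the clustered subset and assigns every remaining
#' profileable sequence, then writes all result tables plus a JSON run
#' manifest to \code{out_dir}. When \code{class_table} is given (a TSV path
#' or data.frame with \code{sequence_id}, \code{class}), the two-class
#' differential density outputs are written as well.
#'
#' @param fasta Input FASTA path.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param class_table Optional two-class label table (path or data.frame).
#' @return Invisibly, a list with the in-memory results (\code{assignment},
#'   \code{embedding}, \code{clusters}, \code{summary}, \code{manifest},
#'   and \code{diff} when computed).
#' @export
run_pipeline <- function(fasta, out_dir, config = pipeline_config(),
                         class_table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- stage("seq_io", read_fasta(fasta))
  flt <- stage("seq_io", filter_by_length(records, config$min_length))
  message("read ", nrow(records), " sequence(s); ", nrow(flt$kept),
          " pass the ", config$min_length, " bp length filter")

  # profiles for every sequence long enough to count k-mers (short ones are
  # classifier-assignment candidates, not embedded)
  profileable <- records[records$length >= config$k, , drop = FALSE]
  profiles <- stage("kmer", profile_matrix(profileable, config$k))
  kept_rows <- match(flt$kept$id, profiles$ids)
  kept_profiles <- list(ids = profiles$ids[kept_rows], k = profiles$k,
                        values = profiles$values[kept_rows, , drop = FALSE],
                        valid_kmer_counts = profiles$valid_kmer_counts[kept_rows],
                        index = profiles$index)
  class(kept_profiles) <- "profile_matrix"

  ecfg <- embed_config(method = config$embed_method, seed = config$seed,
                       compress = config$compress,
                       compress_dims = config$compress_dims)
  embedding <- stage("embed", embed_2d(kept_profiles, ecfg))
  message("embedded ", length(embedding$ids), " sequence(s) with ",
          config$embed_method)

  clusters <- stage("cluster",
                    cluster_embedding(embedding, config$cluster_method,
                                      config$cluster_params, config$seed))
  message("found ", max(clusters$labels), " cluster(s), ",
          sum(clusters$labels == 0L), " noise point(s)")

  subset <- stage("assign", select_training_subset(clusters))
  classifier <- stage("assign",
                      train_bin_classifier(profiles, subset$train_ids,
                                           subset$train_labels))
  assignment <- stage("assign",
                      assign_bins(classifier, profiles, clusters,
                                  config$confidence_threshold))
  # sequences too short to profile are carried as unassigned
  missing <- setdiff(records$id, assignment$id)
  if (length(missing)) {
    extra <- data.frame(id = missing, bin = 0L, source = "unassigned",
                        confidence = NA_real_, stringsAsFactors = FALSE)
    assignment <- rbind(assignment, extra)
  }
  message("assigned: ", sum(assignment$source == "cluster"), " by cluster, ",
          sum(assignment$source == "classifier"), " by classifier, ",
          sum(assignment$source == "unassigned"), " unassigned")

  summary <- stage("report", summarize_bins(assignment, records))

  ridx <- match(assignment$id, records$id)
  assign_out <- data.frame(sequence_id = assignment$id, bin = assignment$bin,
                           source = assignment$source,
                           confidence = assignment$confidence,
                           length = records$length[ridx],
                           gc = records$gc[ridx], stringsAsFactors = FALSE)
  write_tsv_atomic(assign_out, file.path(out_dir, "assignment.tsv"))
  write_tsv_atomic(data.frame(sequence_id = embedding$ids,
                              x = embedding$coords[, 1],
                              y = embedding$coords[, 2]),
                   file.path(out_dir, "embedding.tsv"))
  write_tsv_atomic(data.frame(sequence_id = clusters$ids,
                              cluster = clusters$labels),
                   file.path(out_dir, "clusters.tsv"))
  write_tsv_atomic(summary, file.path(out_dir, "bin_summary.tsv"))
  if (nrow(flt$discarded)) {
    write_tsv_atomic(data.frame(sequence_id = flt$discarded$id,
                                length = flt$discarded$length,
                                reason = "below_min_length"),
                     file.path(out_dir, "discarded.tsv"))
  }

  result <- list(assignment = assignment, embedding = embedding,
                 clusters = clusters, summary = summary)

  if (!is.null(class_table)) {
    classes <- if (is.character(class_table)) {
      stage("diffdensity", read_class_table(class_table))
    } else class_table
    classes <- classes[classes$sequence_id %in% embedding$ids, , drop = FALSE]
    diff <- stage("diffdensity",
                  density_difference(embedding, classes, clusters,
                                     bandwidth = config$bandwidth,
                                     grid_size = config$grid_size))
    write_diff_outputs(diff, out_dir)
    result$diff <- diff
  }

  manifest <- list(
    tool = "compbin",
    version = as.character(utils::packageVersion("compbin")),
    parameters = config[setdiff(names(config), "seed")],
    seed = config$seed,
    input = list(path = fasta,
                 md5 = unname(tools::md5sum(fasta)),
                 n_sequences = nrow(records)),
    counts = list(read = nrow(records), passed_filter = nrow(flt$kept),
                  embedded = length(embedding$ids),
                  clusters = max(clusters$labels),
                  assigned_cluster = sum(assignment$source == "cluster"),
                  assigned_classifier = sum(assignment$source == "classifier"),
                  unassigned = sum(assignment$source == "unassigned")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- file.path(out_dir, "manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  result$manifest <- manifest
  invisible(result)
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' @param path Path to a \code{manifest.json} written by [run_pipeline()].
#' @return A [pipeline_config()] reproducing the recorded run.
#' @export
config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- m$parameters
  pipeline_config(
    k = p$k, min_length = p$min_length, embed_method = p$embed_method,
    cluster_method = p$cluster_method,
    cluster_params = as.list(p$cluster_params),
    compress = p$compress, compress_dims = p$compress_dims,
    confidence_threshold = p$confidence_threshold,
    bandwidth = p$bandwidth, grid_size = p$grid_size, seed = m$seed
  )
}
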