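#' Select the classifier training subset from cluster labels
#'
#' The training subset is every clustered (non-noise) sequence, excluding
#' clusters with fewer than 5 members (too few examples to learn from);
#' members of the dropped clusters are routed to classifier assignment
#' instead.
#'
#' @param labels A \code{cluster_labels}.
#' @param min_members Minimum cluster size usable as a training class
#'   (default 5).
#' @return A list: \code{train_ids}, \code{train_labels} (integer bin per
#'   training sequence), \code{dropped_ids} (members of under-sized
#'   clusters).
#' @export
select_training_subset <- function(labels, min_members = 5L) {
  stopifnot(inherits(labels, "cluster_labels"))
  nz <- labels$labels != 0L
  sizes <- table(labels$labels[nz])
  good <- as.integer(names(sizes)[sizes >= min_members])
  if (length(good) < 2L) {
    stop("insufficient cluster structure for classification ",
         "(need >= 2 clusters with >= ", min_members, " members)")
  }
  in_train <- labels$labels %in% good
  list(
    train_ids = labels$ids[in_train],
    train_labels = labels$labels[in_train],
    dropped_ids = labels$ids[nz & !in_train]
  )
}

#' Train the bin classifier on k-mer profiles
#'
#' Fits a ridge-regularized multinomial logistic model (via
#' \pkg{glmnet}) on the normalized k-mer profiles of the training subset.
#' Features are the profiles, not the 2D embedding, so new sequences can be
#' assigned without re-embedding. The fit is deterministic.
#'
#' @param profiles A \code{profile_matrix} covering (at least) the training
#'   ids.
#' @param train_ids,train_labels Training subset from
#'   [select_training_subset()].
#' @param lambda Ridge penalty used for prediction. \code{NULL} (default)
#'   fits a regularization path and uses its smallest value — the weakest
#'   penalty the warm-started path solves stably.
#' @return A list of class \code{bin_classifier}: the glmnet \code{fit},
#'   \code{classes} (bin labels), \code{lambda}, \code{train_accuracy}.
#' @export
train_bin_classifier <- function(profiles, train_ids, train_labels,
                                 lambda = NULL) {
  stopifnot(inherits(profiles, "profile_matrix"))
  rows <- match(train_ids, profiles$ids)
  if (anyNA(rows)) stop("training id(s) missing from profile matrix")
  x <- profiles$values[rows, , drop = FALSE]
  y <- factor(train_labels)
  if (nlevels(y) < 2L) stop("need >= 2 classes to train a bin classifier")
  if (nrow(unique(x)) == 1L) {
    stop("degenerate features: identical profiles across different classes")
  }
  # a path fit (warm starts, large to small penalty) is numerically stable
  # where a cold single-lambda multinomial fit is not
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        nlambda = 50L, lambda.min.ratio = 1e-6,
                        standardize = FALSE)
  if (is.null(lambda)) lambda <- min(fit$lambda)
  pred <- predict_bins(list(fit = fit, classes = levels(y), lambda = lambda), x)
  clf <- list(
    fit = fit,
    classes = as.integer(levels(y)),
    lambda = lambda,
    train_accuracy = mean(pred$bin == as.integer(as.character(y)))
  )
  class(clf) <- "bin_classifier"
  clf
}

# Argmax bin + its probability for a matrix of profiles.
predict_bins <- function(clf, x) {
  p <- predict(clf$fit, newx = x, type = "response", s = clf$lambda)[, , 1L]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  j <- max.col(p, ties.method = "first")
  list(bin = as.integer(as.character(clf$classes[j])),
       confidence = p[cbind(seq_len(nrow(p)), j)])
}

#' Assign every sequence to a bin
#'
#' Clustered sequences keep their cluster label (source \code{"cluster"});
#' all other candidates — noise points, members of dropped small clusters,
#' and sequences below the length filter but long enough to profile — get
#' the classifier's argmax bin when its probability reaches
#' \code{confidence_threshold} (source \code{"classifier"}), and bin 0
#' otherwise (source \code{"unassigned"}).
#'
#' @param classifier A \code{bin_classifier}.
#' @param all_profiles A \code{profile_matrix} over every candidate
#'   sequence (clustered or not).
#' @param labels A \code{cluster_labels}; ids absent from it are treated as
#'   unclustered candidates.
#' @param confidence_threshold Probability cut-off in \[0, 1\] (default 0.5).
#' @return A data.frame of class \code{bin_assignment}: \code{id},
#'   \code{bin} (0 = unassigned), \code{source}, \code{confidence}
#'   (\code{NA} for cluster-sourced rows).
#' @export
assign_bins <- function(classifier, all_profiles, labels,
                        confidence_threshold = 0.5) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1)
  ids <- all_profiles$ids
  cl <- labels$labels[match(ids, labels$ids)]
  cl[is.na(cl)] <- 0L
  bin <- cl
  source <- ifelse(cl != 0L, "cluster", "unassigned")
  confidence <- rep(NA_real_, length(ids))
  cand <- which(cl == 0L)
  if (length(cand)) {
    pred <- predict_bins(classifier,
                         all_profiles$values[cand, , drop = FALSE])
    ok <- pred$confidence >= confidence_threshold
    bin[cand[ok]] <- pred$bin[ok]
    source[cand[ok]] <- "classifier"
    confidence[cand] <- pred$confidence
  }
  out <- data.frame(id = ids, bin = as.integer(bin), source = source,
                    confidence = confidence, stringsAsFactors = FALSE)
  class(out) <- c("bin_assignment", "data.frame")
  out
}
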