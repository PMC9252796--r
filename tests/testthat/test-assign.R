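# training-subset selection and classifier-based bin assignment

make_labels <- function(sizes, noise = 0) {
  labels <- c(rep(seq_along(sizes), times = sizes), rep(0L, noise))
  ids <- sprintf("s%04d", seq_along(labels))
  fake_cluster_labels(ids, labels)
}

test_that("training subset is the clustered sequences of sufficiently large clusters", {
  sub <- select_training_subset(make_labels(c(100, 80), noise = 20))
  expect_equal(length(sub$train_ids), 180L)
  expect_equal(sort(unique(sub$train_labels)), c(1L, 2L))
  expect_equal(length(sub$dropped_ids), 0L)

  expect_error(select_training_subset(make_labels(c(100, 3))),
               "insufficient cluster structure")

  sub3 <- select_training_subset(make_labels(c(50, 50, 4)))
  expect_equal(length(sub3$train_ids), 100L)
  expect_equal(sort(unique(sub3$train_labels)), c(1L, 2L))
  expect_equal(length(sub3$dropped_ids), 4L)  # routed to the classifier
})

# separable two-class profile fixture shared by the classifier tests
separable_fixture <- function(n_per = 50, seed = 41) {
  cp <- centroid_profiles(n_per, n_features = 136, n_groups = 2, seed = seed)
  ids <- sprintf("t%03d", seq_len(nrow(cp$values)))
  pm <- structure(list(ids = ids, k = 4L, values = cp$values,
                       valid_kmer_counts = rep(1000L, nrow(cp$values)),
                       index = build_kmer_index(4)),
                  class = "profile_matrix")
  list(pm = pm, ids = ids, groups = cp$groups)
}

test_that("classifier separates clear compositional classes perfectly", {
  fx <- separable_fixture()
  clf <- train_bin_classifier(fx$pm, fx$ids, fx$groups)
  expect_equal(clf$train_accuracy, 1.0)

  expect_error(train_bin_classifier(fx$pm, fx$ids, rep(1L, length(fx$ids))),
               ">= 2 classes")

  # degenerate: identical rows across classes
  pm_bad <- fx$pm
  pm_bad$values <- matrix(rep(fx$pm$values[1, ], nrow(fx$pm$values)),
                          nrow = nrow(fx$pm$values), byrow = TRUE)
  expect_error(train_bin_classifier(pm_bad, fx$ids, fx$groups), "degenerate")
})

test_that("assignment respects threshold boundaries and provenance", {
  fx <- separable_fixture()
  half <- fx$ids[c(1:25, 51:75)]
  labels <- fake_cluster_labels(fx$ids,
                                ifelse(fx$ids %in% half, fx$groups, 0L))
  sub <- select_training_subset(labels)
  clf <- train_bin_classifier(fx$pm, sub$train_ids, sub$train_labels)

  a0 <- assign_bins(clf, fx$pm, labels, confidence_threshold = 0)
  expect_equal(sum(a0$source == "unassigned"), 0L)  # argmax always accepted

  a1 <- assign_bins(clf, fx$pm, labels, confidence_threshold = 1)
  cand <- a1$source != "cluster"
  expect_true(all(a1$bin[cand & a1$confidence < 1] == 0L))

  a <- assign_bins(clf, fx$pm, labels, confidence_threshold = 0.5)
  expect_true(all(a$source[a$id %in% half] == "cluster"))
  expect_true(all(a$bin[a$id %in% half] == fx$groups[fx$ids %in% half]))
  expect_true(all(a$confidence[a$source == "classifier"] >= 0.5))
  # conservation
  expect_equal(sum(a$source == "cluster") + sum(a$source == "classifier") +
                 sum(a$source == "unassigned"), length(fx$ids))
})

test_that("raising the threshold never assigns more sequences", {
  fx <- separable_fixture(seed = 42)
  labels <- fake_cluster_labels(fx$ids,
                                ifelse(seq_along(fx$ids) %% 2 == 0, fx$groups, 0L))
  sub <- select_training_subset(labels)
  clf <- train_bin_classifier(fx$pm, sub$train_ids, sub$train_labels)
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(th) {
    sum(assign_bins(clf, fx$pm, labels, th)$source == "classifier")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("held-out fragments from a training genome recover its bin", {
  com <- small_community()
  pm <- profile_matrix(com$records, 4)
  truth <- com$truth$genome[match(pm$ids, com$truth$sequence_id)]
  labels <- fake_cluster_labels(pm$ids, truth)
  sub <- select_training_subset(labels)
  clf <- train_bin_classifier(pm, sub$train_ids, sub$train_labels)
  spec <- com$spec
  spec$fragment_length_median <- 500L
  spec$fragment_length_sigma <- 1e-6
  held <- fragment_genome(com$genomes[2], spec, 2L, id_prefix = "h_",
                          n_fragments = 50, stream = 8L)
  hp <- profile_matrix(held$records, 4)
  asg <- assign_bins(clf, hp, labels, 0.5)
  expect_gte(mean(asg$bin == 2L & asg$source == "classifier"), 0.8)
})
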