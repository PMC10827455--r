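small_selftrain_setup <- function(seed, n_per_cell = 4L, hw = 32L) {
  sp <- synthetic_spec(n_per_cell = n_per_cell, image_size = c(hw, hw), seed = seed)
  db <- synthetic_batch(sp)
  m <- split_dataset(db$manifest, 0.25, seed = seed)
  m <- sample_initial_labeled(m, 0.25, seed = seed)
  spec <- architecture_spec(stages_included = c("conv1", "conv2"),
                            branch_widths = c(4L, 4L, 4L), head = "gap",
                            input_size = c(hw, hw, 3L), stem_width = 4L,
                            stage_blocks = c(conv2 = 1L))
  list(x = db$x, manifest = m, model = assemble_model(spec, seed = seed))
}

test_that("pseudo-label predictions expose max-probability confidence", {
  su <- small_selftrain_setup(1)
  ids <- su$manifest$id[1:5]
  res <- predict_labels(su$model, su$x[, , , 1:5, drop = FALSE], ids)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$confidence >= 0.5 & res$confidence <= 1))
  expect_identical(res$record_id, ids)
  # empty input -> empty output
  empty <- predict_labels(su$model, su$x[, , , 0, drop = FALSE], character())
  expect_equal(nrow(empty), 0L)
})

test_that("the confidence filter is strict and order-preserving", {
  res <- tibble::tibble(record_id = c("a", "b", "c", "d"),
                        predicted_label = c("benign", "malignant", "benign", "malignant"),
                        confidence = c(0.95, 0.85, 0.91, 0.90),
                        accepted = NA)
  kept <- filter_confident(res, 0.90)
  expect_identical(kept$record_id, c("a", "c"))       # 2 of {0.95,0.85,0.91}
  expect_false("d" %in% kept$record_id)               # exactly 0.90 rejected
  expect_equal(nrow(filter_confident(res, 1.0)), 0L)  # nothing beyond 1
  expect_error(filter_confident(res, 0), "0, 1")
})

test_that("self-training conserves pools and never touches the test set", {
  su <- small_selftrain_setup(2)
  st <- self_train_state(su$x, su$manifest)
  n_tr <- length(st$labeled_ids) + length(st$unlabeled_ids)
  cfg <- train_config(batch_size = 8, seed = 2)
  res <- self_train(su$model, st, rounds = 3, per_round_epochs = 1,
                    initial_epochs = 2, threshold = 0.9, train_cfg = cfg)
  s <- res$state
  expect_equal(length(s$labeled_ids) + length(s$unlabeled_ids), n_tr)
  expect_length(intersect(s$labeled_ids, s$unlabeled_ids), 0)
  expect_length(intersect(s$test_ids, c(s$labeled_ids, s$unlabeled_ids)), 0)
  # labeled pool non-decreasing, unlabeled non-increasing
  expect_true(all(diff(s$history$labeled_size) >= 0))
  # each absorbed record appears exactly once in the pseudo-label map
  expect_false(anyDuplicated(names(s$pseudo_label_map)) > 0)
  expect_true(all(names(s$pseudo_label_map) %in% s$labeled_ids))
  expect_equal(nrow(s$history), s$round)
})

test_that("an unreachable threshold reduces to plain training", {
  su <- small_selftrain_setup(3)
  st <- self_train_state(su$x, su$manifest)
  cfg <- train_config(batch_size = 8, seed = 3)
  res <- self_train(su$model, st, rounds = 2, per_round_epochs = 1,
                    initial_epochs = 1, threshold = 1, train_cfg = cfg)
  expect_equal(res$state$history$accepted, c(0L, 0L))
  expect_equal(unique(res$state$history$labeled_size),
               sum(su$manifest$pool == "labeled"))
  expect_length(res$state$pseudo_label_map, 0)
})

test_that("threshold zero absorbs the whole unlabeled pool in round one", {
  su <- small_selftrain_setup(4)
  st <- self_train_state(su$x, su$manifest)
  cfg <- train_config(batch_size = 8, seed = 4)
  # two-class probabilities are strictly positive, so any confidence
  # exceeds a vanishing threshold
  res <- self_train(su$model, st, rounds = 3, per_round_epochs = 1,
                    initial_epochs = 1, threshold = 1e-9, train_cfg = cfg)
  expect_equal(res$state$history$accepted[1],
               sum(su$manifest$pool == "unlabeled"))
  expect_length(res$state$unlabeled_ids, 0)
  expect_equal(res$state$round, 1L)  # loop stops once the pool empties
})

test_that("state construction rejects leaking or empty pools", {
  su <- small_selftrain_setup(5)
  bad <- su$manifest
  bad$pool[bad$split == "test"][1] <- "labeled"
  expect_error(self_train_state(su$x, bad), "leak")
  ok <- self_train_state(su$x, su$manifest)
  ok$labeled_ids <- character()
  expect_error(self_train(su$model, ok, rounds = 1), "empty")
})
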