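#' Initialize self-training state from a manifest
#'
#' Binds the preprocessed image batch to the manifest's pools: records with
#' `pool == "labeled"` form the initial labeled pool (their true labels are
#' visible to training), `pool == "unlabeled"` the unlabeled pool (labels
#' hidden until pseudo-labeled), and `split == "test"` the held-out test
#' set, which never enters a training pool.
#'
#' @param x `(H, W, 3, N)` array, rows aligned with `manifest`.
#' @param manifest manifest tibble with `split` and `pool` assigned (see
#'   [split_dataset()] and [sample_initial_labeled()]).
#' @return An object of class `self_train_state`.
#' @export
self_train_state <- function(x, manifest) {
  if (dim(x)[4] != nrow(manifest)) abort("`x` and `manifest` sizes must agree")
  truth <- stats::setNames(as.character(manifest$class_label), manifest$id)
  st <- structure(list(
    x = x, ids = manifest$id, truth = truth,
    labeled_ids = manifest$id[manifest$pool == "labeled"],
    unlabeled_ids = manifest$id[manifest$pool == "unlabeled"],
    test_ids = manifest$id[manifest$split == "test"],
    pseudo_label_map = character(),
    history = tibble::tibble(round = integer(), labeled_size = integer(),
                             accepted = integer(), train_acc = double(),
                             test_acc = double()),
    round = 0L), class = "self_train_state")
  check_pools(st)
  st
}

check_pools <- function(st) {
  assert_that(length(intersect(st$labeled_ids, st$unlabeled_ids)) == 0L,
              "labeled and unlabeled pools overlap")
  assert_that(length(intersect(st$test_ids, c(st$labeled_ids, st$unlabeled_ids))) == 0L,
              "test records leaked into a training pool")
  invisible(st)
}

pool_x <- function(st, ids) st$x[, , , match(ids, st$ids), drop = FALSE]

# labels visible to training: ground truth for the initial labeled pool,
# frozen pseudo-labels for absorbed records
pool_labels <- function(st, ids) {
  out <- st$truth[ids]
  ps <- intersect(ids, names(st$pseudo_label_map))
  out[ps] <- st$pseudo_label_map[ps]
  unname(out)
}

#' Predict pseudo-labels for unlabeled records
#'
#' Inference-mode predictions (center-cropped, un-mixed inputs); the
#' confidence is the maximum of the 2-class probability vector, with a
#' deterministic tie-break to the first class at exactly 0.5.
#'
#' @param model trained `model_graph`.
#' @param x `(H, W, 3, N)` unlabeled images (`N = 0` is legal).
#' @param ids record ids aligned with `x`.
#' @return A tibble: `record_id`, `predicted_label`, `confidence`,
#'   `accepted` (`NA` until filtered).
#' @export
predict_labels <- function(model, x, ids) {
  if (length(ids) == 0L)
    return(tibble::tibble(record_id = character(), predicted_label = character(),
                          confidence = double(), accepted = logical()))
  p <- predict_proba(model, x)
  tibble::tibble(record_id = ids, predicted_label = p$predicted_label,
                 confidence = p$confidence, accepted = NA)
}

#' Keep only confidently pseudo-labeled records
#'
#' Strict threshold: a record is accepted iff `confidence > threshold`
#' ("beyond" the threshold), so a confidence exactly at the threshold is
#' rejected. Order is preserved.
#'
#' @param results tibble from [predict_labels()].
#' @param threshold acceptance threshold in (0, 1].
#' @return The accepted subset, with `accepted = TRUE`.
#' @export
filter_confident <- function(results, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  results$accepted <- results$confidence > threshold
  dplyr::filter(results, .data$accepted)
}

#' Confidence-thresholded pseudo-label self-training
#'
#' Each round: (1) train the model on the current labeled pool (with the
#' standard augmentations and mixup when configured), (2) predict on the
#' unlabeled pool, (3) move records whose confidence exceeds the threshold
#' into the labeled pool with their pseudo-labels frozen thereafter, and
#' (4) record pool sizes and train/test accuracy. Terminates after
#' `rounds` rounds or when the unlabeled pool empties. Pool disjointness
#' and test isolation are asserted every round. The defaults mirror the
#' published run: 11 rounds of one epoch each, threshold 0.90, batch 16,
#' Adam at 0.001.
#'
#' @param model `model_graph`.
#' @param state `self_train_state`.
#' @param rounds number of self-training rounds (>= 1).
#' @param per_round_epochs training epochs per round.
#' @param initial_epochs extra supervised epochs on the initial labeled
#'   pool before the first round (the published protocol trains the model
#'   on the labeled data before incremental growth begins; 0 disables). The
#'   default trains a randomly initialized reduced model to approximate
#'   convergence on a desk-scale labeled pool, which balanced pseudo-label
#'   acceptance requires.
#' @param threshold pseudo-label confidence threshold in (0, 1]; values
#'   above 1 are legal and make acceptance unreachable.
#' @param train_cfg `train_config` (its `epochs` field is overridden by
#'   `per_round_epochs`).
#' @return A list: `model`, `state` (with per-round `history` tibble).
#' @export
self_train <- function(model, state, rounds = 11L, per_round_epochs = 1L,
                       initial_epochs = 15L, threshold = 0.9,
                       train_cfg = train_config()) {
  if (length(state$labeled_ids) == 0L) abort("initial labeled pool is empty")
  if (rounds < 1L) abort("`rounds` must be >= 1")
  n_total <- length(state$labeled_ids) + length(state$unlabeled_ids)
  opt <- adam_init()
  if (initial_epochs > 0L) {
    cfg0 <- train_cfg
    cfg0$epochs <- as.integer(initial_epochs)
    cfg0$seed <- derive_seed(train_cfg$seed, 32452843)
    fit0 <- train_model(model, pool_x(state, state$labeled_ids),
                        pool_labels(state, state$labeled_ids), cfg0, opt = opt)
    model <- fit0$model; opt <- fit0$opt
  }
  for (r in seq_len(rounds)) {
    check_pools(state)
    state$round <- r
    cfg <- train_cfg
    cfg$epochs <- as.integer(per_round_epochs)
    cfg$seed <- derive_seed(train_cfg$seed, 15485863, r)
    labeled_size <- length(state$labeled_ids)
    fit <- train_model(model, pool_x(state, state$labeled_ids),
                       pool_labels(state, state$labeled_ids), cfg, opt = opt)
    model <- fit$model; opt <- fit$opt
    train_acc <- model_accuracy(model, pool_x(state, state$labeled_ids),
                                pool_labels(state, state$labeled_ids))
    test_acc <- if (length(state$test_ids) > 0L)
      model_accuracy(model, pool_x(state, state$test_ids),
                     state$truth[state$test_ids]) else NA_real_
    accepted_n <- 0L
    if (length(state$unlabeled_ids) > 0L) {
      preds <- predict_labels(model, pool_x(state, state$unlabeled_ids),
                              state$unlabeled_ids)
      # a threshold above 1 is legal and unreachable (probabilities <= 1)
      acc <- filter_confident(preds, min(threshold, 1))
      accepted_n <- nrow(acc)
      if (accepted_n > 0L) {
        state$pseudo_label_map[acc$record_id] <- acc$predicted_label
        state$labeled_ids <- c(state$labeled_ids, acc$record_id)
        state$unlabeled_ids <- setdiff(state$unlabeled_ids, acc$record_id)
      }
    }
    state$history <- dplyr::bind_rows(state$history, tibble::tibble(
      round = r, labeled_size = labeled_size, accepted = accepted_n,
      train_acc = train_acc, test_acc = test_acc))
    assert_that(length(state$labeled_ids) + length(state$unlabeled_ids) == n_total,
                "pool conservation violated")
    if (length(state$unlabeled_ids) == 0L) break
  }
  check_pools(state)
  list(model = model, state = state)
}
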