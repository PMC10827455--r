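test_that("the learning-rate schedule decays geometrically to its floor", {
  cfg <- scheduler_config(lr_max = 5e-5, lr_min = 1e-5, decay = 0.8)
  expect_equal(lr_schedule(0, cfg), 5e-5)
  lrs <- lr_schedule(0:100, cfg)
  above <- which(lrs[-1] > cfg$lr_min)
  expect_equal(lrs[above + 1] / lrs[above], rep(0.8, length(above)))
  expect_equal(lr_schedule(100, cfg), 1e-5)
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs >= cfg$lr_min & lrs <= cfg$lr_max))
  expect_error(scheduler_config(lr_max = 1e-6, lr_min = 1e-5), "exceed")
  expect_error(scheduler_config(decay = 1.2), "0, 1")
})

test_that("training rejects degenerate requests", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
  m <- assemble_model(mini_spec(), seed = 1L)
  expect_error(train_model(m, array(0, c(16, 16, 3, 0)), matrix(0, 0, 2)),
               "empty")
})

test_that("a fully frozen model is bit-identical after training", {
  m <- assemble_model(mini_spec(), seed = 2L)
  m$nodes <- lapply(m$nodes, function(nd) { nd$trainable <- FALSE; nd })
  db <- separable_batch(6, seed = 3)
  fit <- train_model(m, db$x, db$labels,
                     train_config(batch_size = 4, epochs = 2, seed = 1))
  expect_identical(lapply(fit$model$nodes, `[[`, "params"),
                   lapply(m$nodes, `[[`, "params"))
  expect_equal(nrow(fit$history), 2L)
})

test_that("training is deterministic given the seed, with and without augmentation", {
  db <- separable_batch(6, seed = 4)
  run <- function(augment = NULL, mixup = FALSE) {
    m <- assemble_model(mini_spec(), seed = 7L)
    train_model(m, db$x, db$labels,
                train_config(batch_size = 8, epochs = 3, seed = 5,
                             augment = augment, mixup = mixup))$history
  }
  expect_identical(run(), run())
  aug <- augment_config(seed = 9L)
  h1 <- run(aug, mixup = TRUE)
  expect_identical(h1, run(aug, mixup = TRUE))
  # augmentation and mixup change the optimization path
  expect_false(identical(h1$loss, run()$loss))
})

test_that("a small model fits linearly separable data", {
  # separability guarantees a near-perfect fit within 20 epochs
  accs <- vapply(1:3, function(seed) {
    db <- separable_batch(12, seed = 20 + seed)
    m <- assemble_model(mini_spec(), seed = seed)
    fit <- train_model(m, db$x, db$labels,
                       train_config(batch_size = 8, base_lr = 1e-2,
                                    epochs = 20, seed = seed))
    model_accuracy(fit$model, db$x, db$labels)
  }, 0)
  expect_gte(mean(accs >= 0.95), 2 / 3)
  expect_gte(min(accs), 0.9)
})

test_that("loss decreases over the first epochs on separable data", {
  db <- separable_batch(10, seed = 31)
  m <- assemble_model(mini_spec(), seed = 3L)
  fit <- train_model(m, db$x, db$labels,
                     train_config(batch_size = 8, base_lr = 1e-2,
                                  epochs = 6, seed = 2))
  expect_lt(mean(utils::tail(fit$history$loss, 2)),
            mean(utils::head(fit$history$loss, 2)))
})

test_that("fine-tuning freezes the configured backbone and logs the schedule", {
  spec <- architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                            branch_widths = c(4L, 4L, 4L), head = "gap",
                            input_size = c(16L, 16L, 3L), stem_width = 4L,
                            stage_blocks = c(conv2 = 1L, conv3 = 1L))
  m <- assemble_model(spec, seed = 4L)
  db <- separable_batch(8, seed = 41)
  cfg <- train_config(batch_size = 8, epochs = 4, seed = 6,
                      freeze = freeze_config(1),
                      scheduler = scheduler_config())
  fit <- fine_tune(m, db$x, db$labels, cfg)
  # backbone weights bit-identical under config 1
  for (nm in names(m$nodes)) {
    blk <- m$nodes[[nm]]$block
    if (!is.na(blk) && startsWith(blk, "conv"))
      expect_identical(fit$model$nodes[[nm]]$params, m$nodes[[nm]]$params)
  }
  # recorded learning rates equal the schedule
  expect_equal(fit$history$lr, lr_schedule(0:3, cfg$scheduler))
  expect_error(fine_tune(m, db$x, db$labels, train_config(epochs = 2)),
               "freeze")
})

test_that("full fine-tuning matches or beats head-only tuning on easy data", {
  spec <- architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                            branch_widths = c(4L, 4L, 4L), head = "gap",
                            input_size = c(16L, 16L, 3L), stem_width = 4L,
                            stage_blocks = c(conv2 = 1L, conv3 = 1L))
  wins <- vapply(1:3, function(seed) {
    db <- separable_batch(10, seed = 50 + seed)
    m <- assemble_model(spec, seed = seed)
    acc <- vapply(c(1L, 4L), function(k) {
      cfg <- train_config(batch_size = 8, base_lr = 1e-2, epochs = 8,
                          seed = seed, freeze = freeze_config(k),
                          scheduler = scheduler_config(lr_max = 1e-2,
                                                       lr_min = 1e-3,
                                                       decay = 0.8))
      fit <- fine_tune(m, db$x, db$labels, cfg)
      model_accuracy(fit$model, db$x, db$labels)
    }, 0)
    acc[2] >= acc[1]
  }, TRUE)
  expect_gte(sum(wins), 2L)
})
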