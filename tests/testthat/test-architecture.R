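# independent closed-form oracle for the audit: sums per-layer arithmetic
# written against the layer shapes of an assembled graph (never the spec)
oracle_count <- function(model) {
  sum(vapply(model$nodes, function(nd) {
    if (nd$op == "conv") {
      kd <- dim(nd$params$W)
      prod(kd) + length(nd$params$b)
    } else if (nd$op == "bn") {
      4L * length(nd$params$gamma)
    } else if (nd$op == "dense") {
      prod(dim(nd$params$W)) + length(nd$params$b)
    } else 0L
  }, 0))
}

test_that("assembled models and the closed-form audit agree on random specs", {
  for (seed in 1:10) {
    spec <- random_small_spec(seed)
    model <- assemble_model(spec, seed = seed)
    audit <- count_parameters(model)
    expect_equal(audit$total, oracle_count(model))
    expect_equal(audit$total, count_parameters_spec(spec))
    expect_equal(count_parameters(model, trainable_only = TRUE)$total,
                     count_parameters_spec(spec, trainable_only = TRUE))
  }
})

test_that("hand-computed layer counts match the audit convention", {
  # stem convolution: 7*7*3*64 + 64 biases
  full <- assemble_model(baseline_spec(), seed = 1L)
  stem <- dplyr::filter(count_parameters(full)$layers, layer == "conv1_conv")
  expect_equal(stem$count, 7 * 7 * 3 * 64 + 64)   # 9,472
  # dense head on the flattened 7x7x2048 stage-5 output: (100352+1)*2
  dense <- dplyr::filter(count_parameters(full)$layers, layer == "head_dense")
  expect_equal(dense$count, (7 * 7 * 2048 + 1) * 2)  # 200,706
})

test_that("backbone truncation points have the published shapes and counts", {
  spec3 <- architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                             with_inception = FALSE, head = "gap")
  # conv3 output: 28x28 spatial, 512 channels on a 224x224 input
  bk <- build_backbone(spec3)
  expect_equal(bk$out_channels, 512L)
  # truncated conv1-conv3 backbone: 1,460,096 parameters
  gap_head <- 512 * 2 + 2
  expect_equal(count_parameters_spec(spec3) - gap_head, 1460096)
})

test_that("the naive-inception fragment concatenates and counts as derived", {
  inc <- build_naive_inception("x", 512L, widths = c(64L, 64L, 64L))
  expect_equal(inc$out_channels, 64 + 64 + 64 + 512)
  # closed-form branch costs: 513 F1 + 4609 F3 + 12801 F5 (bias on, no BN)
  for (w in list(c(1L, 1L, 1L), c(3L, 5L, 7L))) {
    f <- build_naive_inception("x", 512L, widths = w)
    got <- sum(vapply(f$nodes, function(nd)
      if (nd$op == "conv") prod(dim(nd$params$W)) + length(nd$params$b) else 0L, 0))
    expect_equal(got, 513 * w[1] + 4609 * w[2] + 12801 * w[3])
  }
  # the maxpool branch is parameter-free
  pool <- Filter(function(nd) nd$op == "maxpool", inc$nodes)
  expect_length(pool[[1]]$params, 0L)
})

test_that("forward pass emits a probability vector and is shape-stable", {
  spec <- mini_spec()
  m <- assemble_model(spec, seed = 5L)
  x <- array(rnorm(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  p <- forward_graph(m, x)$prob
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # assembling twice from one spec gives identical layer shapes
  m2 <- assemble_model(spec, seed = 99L)
  shapes <- function(mm) lapply(mm$nodes, function(nd) lapply(nd$params, dim))
  expect_identical(shapes(m), shapes(m2))
})

test_that("freeze configurations are nested and monotone in trainable size", {
  spec <- architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                            branch_widths = c(4L, 4L, 4L), head = "gap",
                            input_size = c(64L, 64L, 3L), stem_width = 4L,
                            stage_blocks = c(conv2 = 1L, conv3 = 1L))
  model <- assemble_model(spec, seed = 1L)
  totals <- vapply(1:4, function(k) {
    frozen <- apply_freeze_config(model, freeze_config(k))
    count_parameters(frozen, trainable_only = TRUE)$total
  }, 0)
  expect_true(all(diff(totals) > 0))
  # config 1: no backbone layer trainable
  m1 <- apply_freeze_config(model, freeze_config(1))
  backbone_nodes <- Filter(function(nd) !is.na(nd$block) &&
                             startsWith(nd$block, "conv"), m1$nodes)
  expect_true(all(!vapply(backbone_nodes, `[[`, TRUE, "trainable")))
  # config 4: everything trainable
  m4 <- apply_freeze_config(model, freeze_config(4))
  expect_true(all(vapply(m4$nodes, `[[`, TRUE, "trainable")))
  # nesting of the trainable block sets
  for (k in 1:3)
    expect_true(all(freeze_config(k)$trainable_blocks %in%
                      freeze_config(k + 1)$trainable_blocks))
  expect_error(freeze_config(5), "1, 2, 3 or 4")
})

test_that("the width search pins a spec that re-counts to its budget", {
  spec <- find_reference_widths(3649506L)
  expect_equal(count_parameters_spec(spec), 3649506)
  model <- assemble_model(spec, seed = 1L)
  expect_equal(count_parameters(model)$total, 3649506)
  # infeasible budget: barely above the backbone cannot be matched
  expect_error(find_reference_widths(1460200L), "nearest achievable")
  expect_error(find_reference_widths(100L), "does not exceed")
})

test_that("spec YAML serialization round-trips", {
  spec <- reference_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec_yaml(spec, path)
  back <- read_spec_yaml(path)
  expect_equal(back$branch_widths, spec$branch_widths)
  expect_equal(back$head, spec$head)
  expect_equal(count_parameters_spec(back), count_parameters_spec(spec))
})
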