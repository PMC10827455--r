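# Shared desk-scale fixtures, all generated in code.

# a miniature architecture: stem + one conv2 block + inception + GAP head
mini_spec <- function(input = c(16L, 16L, 3L), head = "gap") {
  architecture_spec(stages_included = c("conv1", "conv2"),
                    branch_widths = c(4L, 4L, 4L), head = head,
                    input_size = input, stem_width = 4L,
                    stage_blocks = c(conv2 = 1L))
}

# a linearly separable two-class image set: class signal is a constant
# brightness offset in one half of the frame plus mild noise (not
# standardized, so the offset survives)
separable_batch <- function(n_per_class = 20L, hw = 16L, seed = 1L) {
  n <- 2L * n_per_class
  x <- array(0, dim = c(hw, hw, 3L, n))
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  set.seed(seed)
  for (i in seq_len(n)) {
    img <- array(rnorm(hw * hw * 3L, 0, 0.3), dim = c(hw, hw, 3L))
    if (labels[i] == "malignant") img[seq_len(hw / 2L), , ] <- img[seq_len(hw / 2L), , ] + 1.5
    x[, , , i] <- img
  }
  list(x = x, labels = labels)
}

random_small_spec <- function(seed) {
  set.seed(seed)
  architecture_spec(
    stages_included = c("conv1", "conv2", "conv3")[seq_len(sample(2:3, 1))],
    with_inception = TRUE,
    branch_widths = sample(1:6, 3, replace = TRUE),
    head = sample(c("flatten", "gap"), 1),
    conv_bias = sample(c(TRUE, FALSE), 1),
    head_batchnorm = sample(c(TRUE, FALSE), 1),
    input_size = c(32L, 32L, 3L),
    stem_width = sample(c(2L, 4L), 1),
    stage_blocks = c(conv2 = sample(1:2, 1), conv3 = 1L))
}
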