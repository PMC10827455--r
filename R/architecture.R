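STAGE_ORDER <- c("conv1", "conv2", "conv3", "conv4", "conv5")

#' Describe a model architecture
#'
#' The model family couples (a prefix of) a 50-layer bottleneck residual
#' backbone with an optional naive-inception head: parallel 1x1, 3x3 and
#' 5x5 convolutions plus a passthrough 3x3 maxpool on the same input,
#' channel-concatenated and fed to a 2-unit dense classifier. The
#' `stem_width` and `stage_blocks` arguments default to the standard
#' 50-layer configuration (stem 64, blocks 3-4-6-3, stage widths doubling)
#' and may be shrunk proportionally for desk-scale models.
#'
#' @param stages_included ordered prefix of
#'   `c("conv1","conv2","conv3","conv4","conv5")`.
#' @param with_inception attach the naive-inception module to the backbone
#'   output?
#' @param branch_widths integer `(F1, F3, F5)` filter counts of the 1x1,
#'   3x3 and 5x5 branches.
#' @param head `"flatten"` (flatten + dense) or `"gap"` (global average
#'   pooling + dense).
#' @param conv_bias do the inception branch convolutions carry bias terms?
#'   (Backbone convolutions always do, per the package's counting
#'   convention.)
#' @param head_batchnorm add batch normalization after each inception
#'   branch convolution?
#' @param input_size integer `(H, W, 3)` network input size.
#' @param stem_width filters in the stem convolution.
#' @param stage_blocks named integer vector of bottleneck block counts for
#'   the included stages beyond `conv1`.
#' @param num_classes output classes (2: benign, malignant).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(stages_included = c("conv1", "conv2", "conv3"),
                              with_inception = TRUE,
                              branch_widths = c(64L, 64L, 64L),
                              head = c("flatten", "gap"),
                              conv_bias = TRUE,
                              head_batchnorm = FALSE,
                              input_size = c(224L, 224L, 3L),
                              stem_width = 64L,
                              stage_blocks = c(conv2 = 3L, conv3 = 4L,
                                               conv4 = 6L, conv5 = 3L),
                              num_classes = 2L) {
  head <- match.arg(head)
  n <- length(stages_included)
  if (n < 1L || !identical(as.character(stages_included), STAGE_ORDER[seq_len(n)]))
    abort("`stages_included` must be a non-empty prefix of conv1..conv5")
  if (with_inception && (length(branch_widths) != 3L || any(branch_widths < 1L)))
    abort("`branch_widths` must be three integers >= 1")
  if (num_classes < 2L) abort("`num_classes` must be >= 2")
  structure(list(stages_included = as.character(stages_included),
                 with_inception = isTRUE(with_inception),
                 branch_widths = as.integer(branch_widths),
                 head = head, conv_bias = isTRUE(conv_bias),
                 head_batchnorm = isTRUE(head_batchnorm),
                 input_size = as.integer(input_size),
                 stem_width = as.integer(stem_width),
                 stage_blocks = stage_blocks,
                 num_classes = as.integer(num_classes)),
            class = "architecture_spec")
}

#' The full-depth baseline architecture
#'
#' All five residual stages with a flatten + 2-unit dense head and no
#' inception module; under the package's counting convention this model
#' totals 23,788,418 parameters at 224x224x3 input.
#'
#' @inheritParams architecture_spec
#' @return An `architecture_spec`.
#' @export
baseline_spec <- function(input_size = c(224L, 224L, 3L)) {
  architecture_spec(stages_included = STAGE_ORDER, with_inception = FALSE,
                    head = "flatten", input_size = input_size)
}

#' A proportionally shrunk spec for desk-scale experiments
#'
#' Same structural family (stem + conv2 + conv3 bottleneck stages +
#' naive-inception + dense) at one-eighth width - stem 8, branch widths
#' (8, 8, 8) - with one block per stage, a GAP head and 64x64 input: small
#' enough to train on a CPU in seconds while exercising every layer type
#' of the full model, yet wide enough to fit a separable two-class problem
#' to high accuracy within a few epochs.
#'
#' @param input_size integer `(H, W, 3)`.
#' @return An `architecture_spec`.
#' @export
reduced_spec <- function(input_size = c(64L, 64L, 3L)) {
  architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                    branch_widths = c(8L, 8L, 8L), head = "gap",
                    input_size = input_size, stem_width = 8L,
                    stage_blocks = c(conv2 = 1L, conv3 = 1L))
}

stage_mid_width <- function(spec, stage) {
  spec$stem_width * 2L^(match(stage, STAGE_ORDER) - 2L)
}

# spatial size (H, W) at the backbone output, "same"-padding convention
backbone_out_spatial <- function(spec) {
  hw <- ceiling(spec$input_size[1:2] / 2)  # stem conv, stride 2
  hw <- ceiling(hw / 2)                    # stem maxpool, stride 2
  for (s in setdiff(spec$stages_included, c("conv1", "conv2")))
    hw <- ceiling(hw / 2)                  # stages 3+ downsample
  as.integer(hw)
}

backbone_out_channels <- function(spec) {
  last <- spec$stages_included[length(spec$stages_included)]
  if (last == "conv1") spec$stem_width else 4L * stage_mid_width(spec, last)
}

# ---- graph fragments ---------------------------------------------------

conv_node <- function(name, input, kh, kw, cin, cout, stride, block,
                      bias = TRUE, padding = "same") {
  new_node(name, "conv", input, block, init_conv(kh, kw, cin, cout, bias),
           cfg = list(stride = stride, padding = padding,
                      kh = kh, kw = kw, cin = cin, cout = cout))
}

bn_node <- function(name, input, c, block) {
  new_node(name, "bn", input, block, init_bn(c), cfg = list(c = c))
}

bottleneck_block <- function(nodes, input, prefix, cin, mid, stride, block) {
  cout <- 4L * mid
  nm <- function(s) paste0(prefix, "_", s)
  nodes[[length(nodes) + 1L]] <- conv_node(nm("c1"), input, 1L, 1L, cin, mid, stride, block)
  nodes[[length(nodes) + 1L]] <- bn_node(nm("bn1"), nm("c1"), mid, block)
  nodes[[length(nodes) + 1L]] <- new_node(nm("r1"), "relu", nm("bn1"), block)
  nodes[[length(nodes) + 1L]] <- conv_node(nm("c2"), nm("r1"), 3L, 3L, mid, mid, 1L, block)
  nodes[[length(nodes) + 1L]] <- bn_node(nm("bn2"), nm("c2"), mid, block)
  nodes[[length(nodes) + 1L]] <- new_node(nm("r2"), "relu", nm("bn2"), block)
  nodes[[length(nodes) + 1L]] <- conv_node(nm("c3"), nm("r2"), 1L, 1L, mid, cout, 1L, block)
  nodes[[length(nodes) + 1L]] <- bn_node(nm("bn3"), nm("c3"), cout, block)
  shortcut <- input
  if (cin != cout || stride != 1L) {
    nodes[[length(nodes) + 1L]] <- conv_node(nm("ds"), input, 1L, 1L, cin, cout, stride, block)
    nodes[[length(nodes) + 1L]] <- bn_node(nm("dsbn"), nm("ds"), cout, block)
    shortcut <- nm("dsbn")
  }
  nodes[[length(nodes) + 1L]] <- new_node(nm("add"), "add", c(nm("bn3"), shortcut), block)
  nodes[[length(nodes) + 1L]] <- new_node(nm("out"), "relu", nm("add"), block)
  nodes
}

#' Build the (possibly truncated) residual backbone
#'
#' Standard 50-layer bottleneck layout: a 7x7/2 stem convolution with batch
#' norm and 3x3/2 maxpool, then bottleneck stages with block counts and
#' widths from the spec, truncated after the last included stage. For a
#' 224x224 input truncated after conv3 the output is 28x28x512.
#'
#' @param spec `architecture_spec`.
#' @return A graph fragment: list with `nodes`, `output` (node name),
#'   `out_channels`.
#' @export
build_backbone <- function(spec) {
  sw <- spec$stem_width
  nodes <- list(new_node("input", "input"))
  nodes[[2L]] <- conv_node("conv1_conv", "input", 7L, 7L, spec$input_size[3], sw, 2L, "conv1")
  nodes[[3L]] <- bn_node("conv1_bn", "conv1_conv", sw, "conv1")
  nodes[[4L]] <- new_node("conv1_relu", "relu", "conv1_bn", "conv1")
  nodes[[5L]] <- new_node("conv1_pool", "maxpool", "conv1_relu", "conv1",
                          cfg = list(k = 3L, stride = 2L, padding = "same"))
  out <- "conv1_pool"; cin <- sw
  for (stage in setdiff(spec$stages_included, "conv1")) {
    mid <- stage_mid_width(spec, stage)
    nb <- spec$stage_blocks[[stage]]
    for (b in seq_len(nb)) {
      stride <- if (b == 1L && stage != "conv2") 2L else 1L
      prefix <- paste0(stage, "_b", b)
      nodes <- bottleneck_block(nodes, out, prefix, cin, mid, stride, stage)
      out <- paste0(prefix, "_out"); cin <- 4L * mid
    }
  }
  list(nodes = nodes, output = out, out_channels = cin)
}

#' Build the naive-inception module
#'
#' Four parallel branches on one input: 1x1, 3x3 and 5x5 convolutions with
#' `widths` filters each (stride 1, same padding, ReLU, optional batch
#' norm) and a passthrough 3x3 stride-1 maxpool, concatenated along
#' channels into `F1 + F3 + F5 + in_channels` channels.
#'
#' @param input name of the input node.
#' @param in_channels channels of the input feature map.
#' @param widths integer `(F1, F3, F5)`.
#' @param conv_bias do branch convolutions carry biases?
#' @param batchnorm add batch norm after each branch convolution?
#' @return A graph fragment: list with `nodes`, `output`, `out_channels`.
#' @export
build_naive_inception <- function(input, in_channels, widths = c(64L, 64L, 64L),
                                  conv_bias = TRUE, batchnorm = FALSE) {
  if (any(widths < 1L)) abort("branch widths must be >= 1")
  nodes <- list(); ends <- character()
  ks <- c(1L, 3L, 5L)
  for (i in seq_len(3L)) {
    nm <- paste0("incep_b", ks[i])
    nodes[[length(nodes) + 1L]] <- conv_node(paste0(nm, "_conv"), input, ks[i], ks[i],
                                             in_channels, widths[i], 1L, "inception",
                                             bias = conv_bias)
    prev <- paste0(nm, "_conv")
    if (batchnorm) {
      nodes[[length(nodes) + 1L]] <- bn_node(paste0(nm, "_bn"), prev, widths[i], "inception")
      prev <- paste0(nm, "_bn")
    }
    nodes[[length(nodes) + 1L]] <- new_node(paste0(nm, "_relu"), "relu", prev, "inception")
    ends <- c(ends, paste0(nm, "_relu"))
  }
  nodes[[length(nodes) + 1L]] <- new_node("incep_pool", "maxpool", input, "inception",
                                          cfg = list(k = 3L, stride = 1L, padding = "same"))
  ends <- c(ends, "incep_pool")
  nodes[[length(nodes) + 1L]] <- new_node("incep_concat", "concat", ends, "inception")
  list(nodes = nodes, output = "incep_concat",
       out_channels = sum(widths) + in_channels)
}

#' Assemble a full model graph from a spec
#'
#' Backbone, optional naive-inception module, flatten/GAP + dense head and
#' softmax output, with seeded He-normal weight initialization. The graph
#' is deterministic given `(spec, seed)`.
#'
#' @param spec `architecture_spec`.
#' @param seed integer seed for weight initialization.
#' @return A `model_graph`.
#' @export
assemble_model <- function(spec, seed = 1L) {
  with_seed(seed, {
    bk <- build_backbone(spec)
    nodes <- bk$nodes; out <- bk$output; cc <- bk$out_channels
    if (spec$with_inception) {
      inc <- build_naive_inception(out, cc, spec$branch_widths,
                                   conv_bias = spec$conv_bias,
                                   batchnorm = spec$head_batchnorm)
      nodes <- c(nodes, inc$nodes); out <- inc$output; cc <- inc$out_channels
    }
    if (spec$head == "flatten") {
      hw <- backbone_out_spatial(spec)
      nodes[[length(nodes) + 1L]] <- new_node("head_flatten", "flatten", out, "dense")
      feat <- prod(hw) * cc
      out <- "head_flatten"
    } else {
      nodes[[length(nodes) + 1L]] <- new_node("head_gap", "gap", out, "dense")
      feat <- cc
      out <- "head_gap"
    }
    nodes[[length(nodes) + 1L]] <- new_node("head_dense", "dense", out, "dense",
                                            init_dense(feat, spec$num_classes),
                                            cfg = list(cin = feat, cout = spec$num_classes))
    nodes[[length(nodes) + 1L]] <- new_node("prob", "softmax", "head_dense", "dense")
    new_model_graph(nodes, spec)
  })
}

# ---- parameter auditing ------------------------------------------------

#' Audit the parameters of an assembled model
#'
#' Counts every weight, bias, batch-norm scale/shift and batch-norm moving
#' statistic actually allocated in the graph, layer by layer. With
#' `trainable_only = TRUE`, frozen layers and the (never-trainable) moving
#' statistics are excluded.
#'
#' @param model `model_graph`.
#' @param trainable_only count only trainable parameters?
#' @return An object of class `param_audit`: list with `layers` (a tibble:
#'   layer, block, op, count, trainable), `total` and `trainable_total`.
#' @export
count_parameters <- function(model, trainable_only = FALSE) {
  rows <- purrr::map_dfr(model$nodes, function(nd) {
    if (length(nd$params) == 0L) return(NULL)
    ps <- nd$params
    n_all <- sum(vapply(ps, length, 0L))
    n_tr <- if (nd$op == "bn") length(ps$gamma) + length(ps$beta) else n_all
    if (!nd$trainable) n_tr <- 0L
    tibble::tibble(layer = nd$name, block = nd$block, op = nd$op,
                   count = n_all, trainable_count = n_tr,
                   trainable = nd$trainable)
  })
  if (nrow(rows) == 0L) rows <- tibble::tibble(layer = character(), block = character(),
                                               op = character(), count = integer(),
                                               trainable_count = integer(),
                                               trainable = logical())
  if (trainable_only) {
    rows <- dplyr::filter(rows, .data$trainable)
    rows$count <- rows$trainable_count
  }
  structure(list(layers = rows,
                 total = sum(rows$count),
                 trainable_total = sum(rows$trainable_count)),
            class = "param_audit")
}

#' @export
print.param_audit <- function(x, ...) {
  print(x$layers, n = 20)
  cat(sprintf("total: %s   trainable: %s\n",
              format(x$total, big.mark = ","),
              format(x$trainable_total, big.mark = ",")))
  invisible(x)
}

#' Closed-form parameter count for a spec
#'
#' Pure integer arithmetic over the layer shapes implied by a spec - no
#' model is instantiated. Convention: every convolution carries a bias
#' (inception branches configurably), batch normalization contributes four
#' parameters per channel (scale, shift, and two moving statistics), and
#' the dense head carries a bias. Serves as the independent cross-check of
#' [count_parameters()] and powers [find_reference_widths()].
#'
#' @param spec `architecture_spec`.
#' @param trainable_only count only trainable parameters (moving statistics
#'   excluded; with `freeze`, frozen blocks excluded)?
#' @param freeze optional `freeze_config` applied before counting.
#' @return Integer total.
#' @export
count_parameters_spec <- function(spec, trainable_only = FALSE, freeze = NULL) {
  bn_pp <- if (trainable_only) 2L else 4L
  tr_blocks <- if (is.null(freeze)) c(STAGE_ORDER, "inception", "dense")
               else freeze$trainable_blocks
  on <- function(block) !trainable_only || block %in% tr_blocks
  total <- 0
  sw <- spec$stem_width
  if (on("conv1")) total <- total + (7 * 7 * spec$input_size[3] * sw + sw) + bn_pp * sw
  cin <- sw
  for (stage in setdiff(spec$stages_included, "conv1")) {
    mid <- stage_mid_width(spec, stage)
    for (b in seq_len(spec$stage_blocks[[stage]])) {
      blk <- (1 * 1 * cin * mid + mid) + bn_pp * mid +
        (3 * 3 * mid * mid + mid) + bn_pp * mid +
        (1 * 1 * mid * 4 * mid + 4 * mid) + bn_pp * 4 * mid
      if (cin != 4L * mid)
        blk <- blk + (1 * 1 * cin * 4 * mid + 4 * mid) + bn_pp * 4 * mid
      if (on(stage)) total <- total + blk
      cin <- 4L * mid
    }
  }
  cc <- cin
  if (spec$with_inception) {
    ks <- c(1, 3, 5)
    br <- sum((ks^2 * cc + spec$conv_bias) * spec$branch_widths) +
      if (spec$head_batchnorm) bn_pp * sum(spec$branch_widths) else 0
    if (on("inception")) total <- total + br
    cc <- cc + sum(spec$branch_widths)
  }
  feat <- if (spec$head == "flatten") prod(backbone_out_spatial(spec)) * cc else cc
  if (on("dense")) total <- total + feat * spec$num_classes + spec$num_classes
  total
}

# ---- freeze configurations --------------------------------------------

#' Block-freezing configuration
#'
#' The four transfer-learning configurations: config 1 trains only the
#' inception module and dense head; config 2 additionally conv3; config 3
#' additionally conv2; config 4 trains the whole network. The trainable
#' sets are nested, and the inception module and dense head are always
#' trainable.
#'
#' @param config_id integer in 1..4.
#' @return An object of class `freeze_config` with fields `config_id` and
#'   `trainable_blocks`.
#' @export
freeze_config <- function(config_id) {
  if (!config_id %in% 1:4) abort("`config_id` must be 1, 2, 3 or 4")
  tb <- switch(config_id,
    c("inception", "dense"),
    c("conv3", "inception", "dense"),
    c("conv2", "conv3", "inception", "dense"),
    c(STAGE_ORDER, "inception", "dense"))
  structure(list(config_id = as.integer(config_id), trainable_blocks = tb),
            class = "freeze_config")
}

#' Apply a freeze configuration to a model
#'
#' Sets every node's trainable flag according to its block membership.
#' Frozen batch-norm layers also stop updating their moving statistics and
#' run in inference mode during training.
#'
#' @param model `model_graph`.
#' @param cfg `freeze_config`.
#' @return The model with updated trainable flags.
#' @export
apply_freeze_config <- function(model, cfg) {
  if (!inherits(cfg, "freeze_config")) abort("`cfg` must be a freeze_config")
  model$nodes <- lapply(model$nodes, function(nd) {
    nd$trainable <- is.na(nd$block) || nd$block %in% cfg$trainable_blocks
    nd
  })
  model
}

# ---- reference width search -------------------------------------------

the <- new.env(parent = emptyenv())

#' Pin the inception branch widths against a parameter budget
#'
#' The published audit table gives the proposed model's exact total but not
#' the branch widths (F1, F3, F5) or head variant. This search enumerates,
#' in a fixed order - head (flatten, gap) x branch bias (on, off) x branch
#' batch-norm (off, on), then (F1, F3, F5) lexicographically over
#' `[1, search_max]^3` - and returns the first spec whose closed-form total
#' equals the budget exactly. Pure integer arithmetic; no model is built.
#'
#' @param parameter_budget target total parameter count.
#' @param search_max upper bound for each branch width.
#' @return An `architecture_spec` (conv1-conv3 backbone, 224x224x3 input)
#'   whose closed-form count equals `parameter_budget`, with a `search`
#'   attribute recording the enumeration size. Errors with the nearest
#'   achievable totals if no configuration matches.
#' @export
find_reference_widths <- function(parameter_budget, search_max = 512L) {
  key <- paste0(parameter_budget, ":", search_max)
  if (!is.null(the$width_cache[[key]])) return(the$width_cache[[key]])
  base <- architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                            with_inception = FALSE, head = "gap")
  backbone <- count_parameters_spec(base) -
    (backbone_out_channels(base) * base$num_classes + base$num_classes)
  budget_head <- parameter_budget - backbone
  cin <- backbone_out_channels(base)        # 512
  hw <- prod(backbone_out_spatial(base))    # 28*28
  ncls <- base$num_classes
  if (budget_head <= 0)
    abort(sprintf("budget %d does not exceed the truncated backbone (%d)",
                  parameter_budget, backbone))
  n_checked <- 0; nearest <- c(-Inf, Inf)
  note_nearest <- function(tot) {
    if (tot <= parameter_budget) nearest[1] <<- max(nearest[1], tot)
    else nearest[2] <<- min(nearest[2], tot)
  }
  f3s <- seq_len(search_max)
  for (head in c("flatten", "gap")) for (cb in c(TRUE, FALSE)) for (hbn in c(FALSE, TRUE)) {
    per_w <- if (head == "flatten") hw * ncls else ncls  # dense cost per concat channel
    a <- c(1, 9, 25) * cin + as.integer(cb) + if (hbn) 4 else 0
    a <- a + per_w
    const <- backbone + per_w * cin + ncls
    R <- parameter_budget - const
    for (f1 in seq_len(search_max)) {
      rem <- R - a[1] * f1 - a[2] * f3s
      f5 <- rem / a[3]
      n_checked <- n_checked + length(f3s)
      ok <- which(f5 >= 1 & f5 <= search_max & f5 == floor(f5))
      note_nearest(const + a[1] * f1 + a[2] * 1 + a[3] * 1)
      if (length(ok)) {
        f3 <- f3s[ok[1]]
        spec <- architecture_spec(stages_included = c("conv1", "conv2", "conv3"),
                                  branch_widths = c(f1, f3, as.integer(f5[ok[1]])),
                                  head = head, conv_bias = cb, head_batchnorm = hbn)
        stopifnot(count_parameters_spec(spec) == parameter_budget)
        attr(spec, "search") <- list(n_checked = n_checked, budget = parameter_budget)
        if (is.null(the$width_cache)) the$width_cache <- list()
        the$width_cache[[key]] <- spec
        return(spec)
      }
    }
  }
  abort(sprintf(paste0("no (F1,F3,F5) in [1,%d]^3 matches budget %d exactly; ",
                       "nearest achievable totals bracket it as [%s, %s]"),
                search_max, parameter_budget,
                format(nearest[1]), format(nearest[2])))
}

#' The pinned reference architecture
#'
#' [find_reference_widths()] run against the published total of the
#' proposed truncated-backbone + naive-inception model (3,649,506
#' parameters), cached after the first call.
#'
#' @param parameter_budget published total parameter count of the proposed
#'   architecture.
#' @return An `architecture_spec`.
#' @export
reference_spec <- function(parameter_budget = 3649506L) {
  find_reference_widths(parameter_budget)
}

#' Serialize / deserialize an architecture spec
#'
#' @param spec `architecture_spec`.
#' @param path YAML file path.
#' @return `read_spec_yaml()` returns an `architecture_spec`;
#'   `write_spec_yaml()` returns `path` invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  v <- lapply(unclass(spec), function(x) {
    if (is.numeric(x)) storage.mode(x) <- "integer"
    x
  })
  v$stage_blocks <- as.list(v$stage_blocks)  # keep names in the YAML map
  yaml::write_yaml(v, path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  sb <- unlist(v$stage_blocks)
  architecture_spec(stages_included = v$stages_included,
                    with_inception = v$with_inception,
                    branch_widths = unlist(v$branch_widths),
                    head = v$head, conv_bias = v$conv_bias,
                    head_batchnorm = v$head_batchnorm,
                    input_size = unlist(v$input_size),
                    stem_width = v$stem_width,
                    stage_blocks = sb,
                    num_classes = v$num_classes)
}
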