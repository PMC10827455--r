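# Model graphs: a directed acyclic graph of layer nodes held in forward
# (topological) order. Each node records its op, input node names, the
# architecture block it belongs to (conv1..conv5, inception, dense) for
# freeze bookkeeping, its parameter arrays, and a trainable flag.

new_node <- function(name, op, inputs = character(), block = NA_character_,
                     params = list(), cfg = list(), trainable = TRUE) {
  list(name = name, op = op, inputs = inputs, block = block,
       params = params, cfg = cfg, trainable = trainable)
}

new_model_graph <- function(nodes, spec) {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  structure(list(nodes = nodes, spec = spec, input = "input", output = "prob"),
            class = "model_graph")
}

#' @export
print.model_graph <- function(x, ...) {
  audit <- count_parameters(x)
  cat(sprintf("<model_graph: %d nodes, %s parameters (%s trainable)>\n",
              length(x$nodes),
              format(audit$total, big.mark = ","),
              format(audit$trainable_total, big.mark = ",")))
  invisible(x)
}

init_conv <- function(kh, kw, cin, cout, bias) {
  W <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  p <- list(W = W)
  if (bias) p$b <- numeric(cout)
  p
}

init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                            moving_mean = numeric(c), moving_var = rep(1, c))

init_dense <- function(cin, cout) {
  list(W = matrix(rnorm(cout * cin, sd = sqrt(2 / cin)), nrow = cout), b = numeric(cout))
}

#' Run a model graph forward
#'
#' Evaluates the graph on a batch and returns the class-probability matrix.
#' In training mode batch-normalization uses batch statistics (for trainable
#' nodes) and layer caches are retained for the backward pass.
#'
#' @param model `model_graph`.
#' @param x `(H, W, 3, N)` input array.
#' @param training logical; training-mode forward.
#' @return A list with `prob` (`N x 2` matrix, rows summing to 1), and when
#'   `training = TRUE` the cached `values` and `caches` used by backprop.
#' @export
forward_graph <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  values <- list(); caches <- list()
  for (nd in model$nodes) {
    out <- switch(nd$op,
      input = x,
      conv = {
        cc <- conv_fwd(values[[nd$inputs]], nd$params$W, nd$params$b,
                       nd$cfg$stride, nd$cfg$padding)
        if (training) caches[[nd$name]] <- cc[-1L]
        cc$out
      },
      bn = {
        use_batch <- training && nd$trainable
        cc <- bn_fwd(values[[nd$inputs]], nd$params$gamma, nd$params$beta,
                     nd$params$moving_mean, nd$params$moving_var, use_batch)
        if (training) caches[[nd$name]] <- cc[-1L]
        cc$out
      },
      relu = pmax(values[[nd$inputs]], 0),
      maxpool = {
        cc <- maxpool_fwd(values[[nd$inputs]], nd$cfg$k, nd$cfg$stride, nd$cfg$padding)
        if (training) caches[[nd$name]] <- cc[-1L]
        cc$out
      },
      add = values[[nd$inputs[1]]] + values[[nd$inputs[2]]],
      concat = {
        parts <- lapply(nd$inputs, function(nm) values[[nm]])
        d1 <- dim(parts[[1]])
        cs <- vapply(parts, function(p) dim(p)[3], 0)
        out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
        at <- 0L
        for (p in parts) {
          out[, , at + seq_len(dim(p)[3]), ] <- p
          at <- at + dim(p)[3]
        }
        out
      },
      gap = {
        # (C, N) feature matrix of spatial means
        v <- values[[nd$inputs]]
        d <- dim(v)
        matrix(colSums(matrix(v, nrow = d[1] * d[2])) / (d[1] * d[2]), nrow = d[3])
      },
      flatten = {
        v <- values[[nd$inputs]]
        d <- dim(v)
        matrix(v, nrow = d[1] * d[2] * d[3])
      },
      dense = {
        cc <- dense_fwd(values[[nd$inputs]], nd$params$W, nd$params$b)
        if (training) caches[[nd$name]] <- cc["x"]
        cc$out
      },
      softmax = softmax_cols(values[[nd$inputs]]),
      abort(paste0("unknown op: ", nd$op))
    )
    values[[nd$name]] <- out
  }
  prob <- t(values[[model$output]])
  colnames(prob) <- CLASS_LEVELS
  list(prob = prob, values = if (training) values, caches = if (training) caches)
}

# Backward pass seeded with the cross-entropy gradient at the logits
# (the input of the softmax node). Returns per-node parameter gradients
# for trainable nodes plus the batch BN statistics for moving updates.
backward_graph <- function(model, fwd, dlogits) {
  nodes <- model$nodes
  softmax_in <- nodes[[model$output]]$inputs
  grads <- list(); pgrads <- list()
  grads[[softmax_in]] <- dlogits
  for (k in rev(seq_along(nodes))) {
    nd <- nodes[[k]]
    g <- grads[[nd$name]]
    if (is.null(g) || nd$op %in% c("input", "softmax")) next
    add_grad <- function(nm, dg) {
      grads[[nm]] <<- if (is.null(grads[[nm]])) dg else grads[[nm]] + dg
    }
    switch(nd$op,
      conv = {
        bw <- conv_bwd(g, fwd$caches[[nd$name]], nd$params$W,
                       !is.null(nd$params$b), nd$cfg$stride)
        if (nd$trainable) pgrads[[nd$name]] <- list(W = bw$dW, b = bw$db)
        add_grad(nd$inputs, bw$dx)
      },
      bn = {
        if (nd$trainable) {
          bw <- bn_bwd(g, fwd$caches[[nd$name]], nd$params$gamma)
          pgrads[[nd$name]] <- list(
            gamma = bw$dgamma, beta = bw$dbeta,
            batch_mean = fwd$caches[[nd$name]]$batch_mean,
            batch_var = fwd$caches[[nd$name]]$batch_var)
          add_grad(nd$inputs, bw$dx)
        } else {
          # frozen BN is a fixed affine map per channel
          d <- dim(g)
          sc <- nd$params$gamma / sqrt(nd$params$moving_var + BN_EPS)
          add_grad(nd$inputs, g * bcast_ch(sc, d))
        }
      },
      relu = add_grad(nd$inputs, g * (fwd$values[[nd$name]] > 0)),
      maxpool = add_grad(nd$inputs, maxpool_bwd(g, fwd$caches[[nd$name]],
                                                nd$cfg$k, nd$cfg$stride)),
      add = { add_grad(nd$inputs[1], g); add_grad(nd$inputs[2], g) },
      concat = {
        at <- 0L
        for (nm in nd$inputs) {
          cc <- dim(fwd$values[[nm]])[3]
          add_grad(nm, g[, , at + seq_len(cc), , drop = FALSE])
          at <- at + cc
        }
      },
      gap = {
        v <- fwd$values[[nd$inputs]]
        d <- dim(v)
        dg <- array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
        add_grad(nd$inputs, dg)
      },
      flatten = add_grad(nd$inputs, array(g, dim = dim(fwd$values[[nd$inputs]]))),
      dense = {
        bw <- dense_bwd(g, fwd$caches[[nd$name]], nd$params$W)
        if (nd$trainable) pgrads[[nd$name]] <- list(W = bw$dW, b = bw$db)
        add_grad(nd$inputs, bw$dx)
      }
    )
  }
  pgrads
}

#' Predict class probabilities
#'
#' Inference-mode forward pass (batch normalization uses its moving
#' statistics; no augmentation).
#'
#' @param model `model_graph`.
#' @param x `(H, W, 3, N)` array.
#' @return A tibble with columns `benign`, `malignant`, `predicted_label`,
#'   `confidence` (one row per image).
#' @export
predict_proba <- function(model, x) {
  p <- forward_graph(model, x, training = FALSE)$prob
  # deterministic tie-break: the first class wins at exactly 0.5
  idx <- max.col(p, ties.method = "first")
  tibble::tibble(
    benign = p[, 1L], malignant = p[, 2L],
    predicted_label = CLASS_LEVELS[idx],
    confidence = p[cbind(seq_len(nrow(p)), idx)]
  )
}
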