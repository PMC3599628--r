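## Deep belief networks: hidden layers pretrained greedily as RBMs on the
## previous layer's deterministic activation probabilities, a supervised
## sigmoid output layer, and end-to-end fine-tuning by backpropagation on
## masked Bernoulli cross-entropy.

#' Pretrain a stack of RBMs layer by layer
#'
#' The first RBM is trained on the data; each subsequent RBM is trained on
#' the deterministic hidden activation probabilities of the previous one
#' applied to the full dataset.
#'
#' @param data Matrix of input rows in \[0,1\].
#' @param hidden_sizes Integer vector of hidden layer sizes (bottom up).
#' @param hyper RBM hyperparameters (\code{\link{rbm_hyper}}).
#' @param init_sd Initial weight sd passed to each RBM.
#' @return List of trained \code{rbm} objects, bottom up.
#' @export
pretrain_stack <- function(data, hidden_sizes, hyper = rbm_hyper(),
                           init_sd = 0.01) {
  if (!length(hidden_sizes)) stop("hidden_sizes must be non-empty")
  stack <- vector("list", length(hidden_sizes))
  input <- data
  for (k in seq_along(hidden_sizes)) {
    stack[[k]] <- train_rbm(input, hidden_sizes[k], hyper, init_sd)
    input <- hidden_probs(input, stack[[k]])
    if (is.null(dim(input))) input <- matrix(input, nrow = 1L)
  }
  stack
}

#' Deep network constructor
#'
#' @param layers List of \code{list(W, b)} pairs, bottom up; all layers use
#'   sigmoid activations.
#' @return Object of class \code{deep_net}.
#' @export
deep_net <- function(layers) {
  for (k in seq_along(layers)[-1]) {
    if (ncol(layers[[k - 1]]$W) != nrow(layers[[k]]$W))
      stop("layer ", k, " input dim ", nrow(layers[[k]]$W),
           " != layer ", k - 1, " output dim ", ncol(layers[[k - 1]]$W))
  }
  structure(list(layers = layers,
                 d_in = nrow(layers[[1]]$W),
                 d_out = ncol(layers[[length(layers)]]$W)),
            class = "deep_net")
}

#' @export
print.deep_net <- function(x, ...) {
  dims <- c(x$d_in, vapply(x$layers, function(l) ncol(l$W), integer(1)))
  cat("<deep_net> ", paste(dims, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Attach and train a supervised output layer on a pretrained stack
#'
#' The RBM stack's weights and hidden biases become the hidden layers
#' (units treated as returning real-valued, deterministic probabilities); a
#' single sigmoid output layer is trained by mini-batch gradient descent on
#' masked cross-entropy against the top-level activations.
#'
#' @param stack List of trained \code{rbm}s from \code{\link{pretrain_stack}}.
#' @param data Input matrix.
#' @param targets Binary target matrix (columns = target-window positions).
#' @param masks Mask matrix, same shape as \code{targets}; masked (0)
#'   positions contribute no loss or gradient.
#' @param epochs,batch,lr Output-layer training schedule.
#' @param init_sd Output-weight init sd.
#' @return A \code{\link{deep_net}} ending in the trained output layer.
#' @export
attach_output_layer <- function(stack, data, targets, masks = NULL,
                                epochs = 10L, batch = 1000L, lr = 0.1,
                                init_sd = 0.01) {
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = nrow(data))
  if (nrow(targets) != nrow(data))
    stop("targets have ", nrow(targets), " rows, data has ", nrow(data))
  if (is.null(masks)) masks <- matrix(1, nrow(targets), ncol(targets))
  top <- data
  for (r in stack) {
    top <- hidden_probs(top, r)
    if (is.null(dim(top))) top <- matrix(top, nrow = 1L)
  }
  d_top <- ncol(top); d_out <- ncol(targets)
  out <- list(W = matrix(rnorm(d_top * d_out, 0, init_sd), d_top, d_out),
              b = numeric(d_out))
  n <- nrow(top)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    for (s in seq(1L, n, by = batch)) {
      rows <- idx[s:min(s + batch - 1L, n)]
      a <- sigmoid(add_bias(top[rows, , drop = FALSE] %*% out$W, out$b))
      delta <- (a - targets[rows, , drop = FALSE]) *
        masks[rows, , drop = FALSE]
      out$W <- out$W - lr * crossprod(top[rows, , drop = FALSE], delta) /
        length(rows)
      out$b <- out$b - lr * colMeans(delta)
    }
  }
  hidden <- lapply(stack, function(r) list(W = r$W, b = r$c))
  deep_net(c(hidden, list(out)))
}

#' Forward pass through a deep network
#'
#' @param net A \code{\link{deep_net}}.
#' @param x Input vector or matrix (rows = examples).
#' @return Output activations in (0,1); a vector for a single input.
#' @export
net_forward <- function(net, x) {
  a <- as_row_matrix(x, net$d_in, "network")
  for (l in net$layers) a <- sigmoid(add_bias(a %*% l$W, l$b))
  drop_if_vector(a)
}

# forward pass retaining all layer activations (input first)
net_forward_all <- function(net, x) {
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1]] <- as_row_matrix(x, net$d_in, "network")
  for (k in seq_along(net$layers))
    acts[[k + 1]] <- sigmoid(add_bias(acts[[k]] %*% net$layers[[k]]$W,
                                      net$layers[[k]]$b))
  acts
}

#' Masked cross-entropy loss
#'
#' Mean over examples of the summed Bernoulli cross-entropy over unmasked
#' target-window positions.
#'
#' @param net A \code{deep_net}.
#' @param x Input matrix.
#' @param y Binary target matrix.
#' @param mask Mask matrix (1 = position contributes).
#' @return Scalar loss.
#' @export
cross_entropy <- function(net, x, y, mask = NULL) {
  out <- net_forward(net, x)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(out))
  if (is.null(mask)) mask <- matrix(1, nrow(y), ncol(y))
  -sum(mask * (y * log(out) + (1 - y) * log(1 - out))) / nrow(out)
}

#' Analytic gradient of the masked cross-entropy
#'
#' Standard backpropagation for a sigmoid network with Bernoulli
#' cross-entropy: the output delta is \code{(a - y) * mask}; hidden deltas
#' multiply by the sigmoid derivative. Gradients are means over the batch.
#'
#' @inheritParams cross_entropy
#' @return List with per-layer \code{list(W, b)} gradients and \code{loss}.
#' @export
net_gradient <- function(net, x, y, mask = NULL) {
  x <- as_row_matrix(x, net$d_in, "network")
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(x))
  if (is.null(mask)) mask <- matrix(1, nrow(y), ncol(y))
  n <- nrow(x)
  acts <- net_forward_all(net, x)
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- (acts[[L + 1]] - y) * mask
  for (k in L:1) {
    grads[[k]] <- list(W = crossprod(acts[[k]], delta) / n,
                       b = colMeans(delta))
    if (k > 1L)
      delta <- (delta %*% t(net$layers[[k]]$W)) *
        acts[[k]] * (1 - acts[[k]])
  }
  out <- acts[[L + 1]]
  list(grads = grads,
       loss = -sum(mask * (y * log(out) + (1 - y) * log(1 - out))) / n)
}

#' Fine-tune a deep network end-to-end
#'
#' Mini-batch gradient descent on the masked cross-entropy; all layers are
#' updated.
#'
#' @param net A \code{deep_net}.
#' @param x Input matrix.
#' @param y Binary target matrix.
#' @param mask Mask matrix; masked positions contribute zero loss and zero
#'   gradient.
#' @param epochs,batch,lr Fine-tuning schedule (defaults 25 epochs, batches
#'   of 1000, rate 0.1).
#' @return Fine-tuned \code{deep_net}; attribute \code{"loss"} records the
#'   pre/post training-set loss.
#' @export
finetune <- function(net, x, y, mask = NULL, epochs = 25L, batch = 1000L,
                     lr = 0.1) {
  if (is.null(dim(x)) || nrow(x) == 0L) stop("empty training data")
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(x))
  if (is.null(mask)) mask <- matrix(1, nrow(y), ncol(y))
  loss_before <- cross_entropy(net, x, y, mask)
  n <- nrow(x)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    for (s in seq(1L, n, by = batch)) {
      rows <- idx[s:min(s + batch - 1L, n)]
      g <- net_gradient(net, x[rows, , drop = FALSE],
                        y[rows, , drop = FALSE],
                        mask[rows, , drop = FALSE])
      for (k in seq_along(net$layers)) {
        net$layers[[k]]$W <- net$layers[[k]]$W - lr * g$grads[[k]]$W
        net$layers[[k]]$b <- net$layers[[k]]$b - lr * g$grads[[k]]$b
      }
    }
  }
  attr(net, "loss") <- c(before = loss_before,
                         after = cross_entropy(net, x, y, mask))
  net
}

#' Pretrain, attach an output layer and fine-tune in one call
#'
#' The standard training path for one base classifier: greedy RBM
#' pretraining of the hidden layers, supervised output-layer training, then
#' end-to-end fine-tuning.
#'
#' @param x,y,mask Training examples, binary target windows, masks.
#' @param hidden_sizes Hidden layer sizes.
#' @param hyper RBM hyperparameters for pretraining.
#' @param output_epochs Output-layer epochs before fine-tuning.
#' @param epochs,batch,lr Fine-tuning schedule.
#' @param pretrain If \code{FALSE}, skip RBM pretraining and use random
#'   initial hidden layers (baseline for comparisons).
#' @return Fine-tuned \code{deep_net}.
#' @export
train_deep_net <- function(x, y, mask = NULL, hidden_sizes = c(40L, 20L),
                           hyper = rbm_hyper(),
                           output_epochs = 10L, epochs = 25L, batch = 1000L,
                           lr = 0.1, pretrain = TRUE) {
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(x))
  if (pretrain) {
    stack <- pretrain_stack(x, hidden_sizes, hyper)
  } else {
    stack <- list()
    d <- ncol(x)
    for (hsz in hidden_sizes) {
      r <- rbm_new(d, hsz)
      stack <- c(stack, list(r))
      d <- hsz
    }
  }
  net <- attach_output_layer(stack, x, y, mask, epochs = output_epochs,
                             batch = batch, lr = lr)
  finetune(net, x, y, mask, epochs = epochs, batch = batch, lr = lr)
}
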