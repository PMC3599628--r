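## Modified AdaBoost over deep networks. Each round draws a weighted sample
## from the pool of windowed examples, trains a deep network on it,
## evaluates the full pool, converts the weighted error eps_t into a member
## weight alpha_t = 0.5 * log((1 - eps_t)/eps_t), and reweights the pool:
## correctly classified examples are scaled by exp(-alpha_t), misclassified
## ones by exp(beta_i * alpha_t) where beta_i counts the misclassified
## target residues. Every `reinit_period` completed rounds the pool weights
## are reset to uniform so that a few hard examples cannot dominate
## sampling. The ensemble score is the performance-weighted vote
## H(x) = sum_{t: m_t(x) > 0.5} alpha_t / sum_t alpha_t.

#' Draw a weighted training sample from the pool
#'
#' Indices drawn i.i.d. with replacement according to the pool selection
#' probabilities.
#'
#' @param w Probability vector over pool examples (sums to 1).
#' @param n Sample size (60,000 at full scale).
#' @return Integer vector of pool indices (a multiset).
#' @export
draw_training_sample <- function(w, n = 60000L) {
  if (!length(w)) stop("empty training pool")
  if (abs(sum(w) - 1) > 1e-6)
    stop("selection probabilities must sum to 1 (got ", sum(w), ")")
  sample.int(length(w), size = n, replace = TRUE, prob = w)
}

#' Threshold network outputs into hard target-window calls
#'
#' Componentwise threshold at 0.5; an output of exactly 0.5 is called
#' disordered.
#'
#' @param m_out Numeric vector/matrix of network outputs in \[0,1\].
#' @return Binary object of the same shape.
#' @export
hard_classify <- function(m_out) {
  h <- (m_out >= 0.5) * 1
  h
}

#' Weighted error of a member over the pool
#'
#' An example counts as misclassified when any unmasked target residue in
#' its window is misclassified; \code{eps_t} is the summed selection
#' probability of the misclassified examples. A fractional variant
#' (weighting each example by its misclassified fraction of unmasked
#' positions) is available via \code{rule = "fraction"}.
#'
#' @param w Pool selection probabilities.
#' @param predictions Binary prediction matrix (pool rows x target window).
#' @param targets Binary target matrix.
#' @param masks Mask matrix (0 positions ignored).
#' @param rule \code{"any"} (default) or \code{"fraction"}.
#' @return \code{eps_t} in \[0,1\].
#' @export
weighted_error <- function(w, predictions, targets, masks = NULL,
                           rule = c("any", "fraction")) {
  rule <- match.arg(rule)
  if (is.null(dim(predictions))) predictions <- cbind(predictions)
  if (is.null(dim(targets))) targets <- cbind(targets)
  if (is.null(masks)) masks <- matrix(1, nrow(targets), ncol(targets))
  mis <- rowSums((predictions != targets) * masks)
  if (rule == "any") sum(w[mis > 0])
  else {
    denom <- pmax(rowSums(masks), 1)
    sum(w * mis / denom)
  }
}

#' Member weight from the weighted error
#'
#' \code{alpha_t = 0.5 * log((1 - eps_t) / eps_t)}. A zero error is clamped
#' to 1e-10 (with a warning); an error of 0.5 or worse rejects the member
#' (alpha 0) since it carries no usable signal.
#'
#' @param eps_t Weighted error in \[0,1\].
#' @return \code{alpha_t >= 0}.
#' @export
compute_alpha <- function(eps_t) {
  if (eps_t <= 0) {
    warning("weighted error 0 clamped to 1e-10")
    eps_t <- 1e-10
  }
  if (eps_t >= 0.5) return(0)
  0.5 * log((1 - eps_t) / eps_t)
}

#' Reweight the pool after a round
#'
#' Correct examples are scaled by \code{exp(-alpha_t)}, misclassified ones
#' by \code{exp(beta_i * alpha_t)} with \code{beta_i} the number of
#' misclassified unmasked target residues; the result is renormalised to a
#' probability distribution.
#'
#' @param w Current selection probabilities.
#' @param alpha_t Member weight.
#' @param beta Per-example misclassified-residue counts (0 for correct
#'   examples).
#' @return Updated probability vector.
#' @export
reweight <- function(w, alpha_t, beta) {
  stopifnot(length(w) == length(beta), all(beta >= 0))
  scale <- ifelse(beta > 0, exp(beta * alpha_t), exp(-alpha_t))
  w2 <- w * scale
  w2 / sum(w2)
}

#' Periodic reinitialisation of pool weights
#'
#' At the start of every round following a multiple of
#' \code{period} completed rounds (rounds 8, 15, 22, 29 for the default
#' period 7) the selection probabilities are reset to uniform; otherwise
#' they pass through unchanged.
#'
#' @param w Selection probabilities.
#' @param t Round number about to start (1-based).
#' @param period Reinitialisation period.
#' @return Possibly reset probability vector.
#' @export
maybe_reinitialize <- function(w, t, period = 7L) {
  if (t > 1L && (t - 1L) %% period == 0L)
    rep(1 / length(w), length(w))
  else w
}

# per-example misclassified-residue counts (the beta of the reweight rule)
misclassified_counts <- function(predictions, targets, masks) {
  rowSums((predictions != targets) * masks)
}

#' Train a boosted ensemble of deep networks
#'
#' Runs the full boosting loop over a pool of windowed examples: weight
#' reinitialisation check, weighted sampling, deep-network training
#' (RBM pretraining + output layer + fine-tuning), full-pool evaluation,
#' member weighting and pool reweighting.
#'
#' @param pool A pooled \code{windowed_examples} object (with \code{Y} and
#'   \code{M}).
#' @param rounds Boosting rounds (35 at full scale).
#' @param sample_size Training-sample size per round (60,000 at full scale).
#' @param hidden_sizes Deep-network hidden layer sizes.
#' @param hyper RBM hyperparameters for pretraining.
#' @param output_epochs,finetune_epochs,finetune_batch,lr Network training
#'   schedule.
#' @param pretrain Use RBM pretraining (default TRUE).
#' @param reinit_period Pool-weight reinitialisation period (default 7).
#' @param error_rule Misclassification rule for \code{\link{weighted_error}}.
#' @param track_auc Record the pool AUC of the growing ensemble after each
#'   round (costs one aggregation per round).
#' @return Object of class \code{boosted_ensemble}: \code{members} (list of
#'   \code{list(net, alpha)}), \code{l_in}, \code{l_tgt}, and a per-round
#'   \code{log} data frame (round, eps, alpha, pool_auc).
#' @export
train_boosted_ensemble <- function(pool, rounds = 35L, sample_size = 60000L,
                                   hidden_sizes = c(40L, 20L),
                                   hyper = rbm_hyper(),
                                   output_epochs = 10L,
                                   finetune_epochs = 25L,
                                   finetune_batch = 1000L, lr = 0.1,
                                   pretrain = TRUE, reinit_period = 7L,
                                   error_rule = "any", track_auc = FALSE) {
  if (is.null(pool$X) || nrow(pool$X) == 0L) stop("empty training pool")
  if (is.null(pool$Y)) stop("training pool has no targets")
  n <- nrow(pool$X)
  w <- rep(1 / n, n)
  members <- vector("list", rounds)
  log <- data.frame(round = integer(0), eps = numeric(0),
                    alpha = numeric(0), pool_auc = numeric(0))
  vote_num <- matrix(0, n, pool$l_tgt)  # running sum alpha_t * [m_t > 0.5]
  alpha_sum <- 0
  for (t in seq_len(rounds)) {
    w <- maybe_reinitialize(w, t, reinit_period)
    idx <- draw_training_sample(w, sample_size)
    net <- train_deep_net(pool$X[idx, , drop = FALSE],
                          pool$Y[idx, , drop = FALSE],
                          pool$M[idx, , drop = FALSE],
                          hidden_sizes = hidden_sizes, hyper = hyper,
                          output_epochs = output_epochs,
                          epochs = finetune_epochs, batch = finetune_batch,
                          lr = lr, pretrain = pretrain)
    out <- net_forward(net, pool$X)
    if (is.null(dim(out))) out <- matrix(out, nrow = n)
    pred <- hard_classify(out)
    eps <- weighted_error(w, pred, pool$Y, pool$M, rule = error_rule)
    alpha <- compute_alpha(eps)
    members[[t]] <- list(net = net, alpha = alpha)
    if (alpha > 0) {
      beta <- misclassified_counts(pred, pool$Y, pool$M)
      w <- reweight(w, alpha, beta)
      vote_num <- vote_num + alpha * (out > 0.5)
      alpha_sum <- alpha_sum + alpha
    }
    auc <- NA_real_
    if (track_auc && alpha_sum > 0) {
      H <- vote_num / alpha_sum
      keep <- pool$M == 1
      auc <- roc_auc(H[keep], ifelse(pool$Y[keep] == 1, "D", "O"))$auc
    }
    log <- rbind(log, data.frame(round = t, eps = eps, alpha = alpha,
                                 pool_auc = auc))
  }
  structure(list(members = members, l_in = pool$l_in, l_tgt = pool$l_tgt,
                 log = log),
            class = "boosted_ensemble")
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  alphas <- vapply(x$members, `[[`, numeric(1), "alpha")
  cat("<boosted_ensemble> windows ", x$l_in, "->", x$l_tgt, ", ",
      length(x$members), " members (", sum(alphas > 0), " retained)\n",
      sep = "")
  invisible(x)
}

#' Performance-weighted ensemble output
#'
#' \code{H(x) = sum_{t: m_t(x) > 0.5} alpha_t / sum_t alpha_t},
#' componentwise over the target window. Members with alpha 0 contribute
#' nothing (numerator and denominator alike).
#'
#' @param ensemble A \code{boosted_ensemble} (or its member list).
#' @param x Input vector or matrix of windowed examples.
#' @return Matrix (rows = examples) of scores in \[0,1\]; a vector for a
#'   single input.
#' @export
ensemble_output <- function(ensemble, x) {
  members <- if (inherits(ensemble, "boosted_ensemble")) ensemble$members
             else ensemble
  alphas <- vapply(members, `[[`, numeric(1), "alpha")
  if (all(alphas <= 0)) stop("no ensemble member has positive weight")
  xm <- if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  num <- NULL
  for (m in members) {
    if (m$alpha <= 0) next
    out <- net_forward(m$net, xm)
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(xm))
    contrib <- m$alpha * (out > 0.5)
    num <- if (is.null(num)) contrib else num + contrib
  }
  drop_if_vector(num / sum(alphas[alphas > 0]))
}
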