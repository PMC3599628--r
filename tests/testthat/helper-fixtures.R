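# Shared fixtures and independent oracles used across the suite.

# hand-built residue track: every feature set explicitly, no generator
make_track <- function(sequence = "MKVLA", ss = "CHHEC", sa = "ebbee",
                       info = NULL, lik = NULL, labels = NULL,
                       id = "toy") {
  n <- nchar(sequence)
  if (is.null(info)) info <- rep(0.5, n)
  if (is.null(lik)) lik <- matrix(0.05, n, 20,
                                  dimnames = list(NULL, idrboost:::AA_STANDARD))
  rec <- protein_record(id, sequence, labels)
  pssm <- list(info = info, info_raw = info * 6, likelihood = lik,
               residues = strsplit(sequence, "")[[1]])
  list(record = rec, track = residue_track(rec, pssm, ss, sa))
}

# independent window builder: assembles the input vector slot by slot from
# first principles, with a configurable left/right split of the context
build_window_direct <- function(track, center, l_in, l_tgt,
                                left_heavy = TRUE) {
  n <- track$length
  feats <- cbind(track$sa, track$ss, track$atchley, track$pssm_info,
                 track$pssm_likelihood)
  first_target <- center - (l_tgt - 1L) %/% 2L
  context <- l_in - l_tgt
  left <- if (left_heavy) ceiling(context / 2) else floor(context / 2)
  start <- first_target - left
  x <- c()
  for (slot in seq.int(start, length.out = l_in)) {
    if (slot >= 1 && slot <= n) x <- c(x, feats[slot, ], 1)
    else x <- c(x, rep(0, 31), 0)
  }
  unname(c(x, track$global, center / n))
}

# exhaustive positive-negative pair counting (Mann-Whitney with ties)
auc_by_pair_counting <- function(scores, labels) {
  pos <- scores[labels == "D"]
  neg <- scores[labels != "D"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# textbook binary AdaBoost reweighting (single-label, beta absent):
# w_i <- w_i * exp(-alpha * y~_i * h~_i) with labels/predictions in {-1,+1}
adaboost_reweight_textbook <- function(w, alpha, predictions, targets) {
  yy <- 2 * targets - 1
  hh <- 2 * predictions - 1
  w2 <- w * exp(-alpha * yy * hh)
  w2 / sum(w2)
}

# joint-state enumeration of an RBM's visible marginal, energy recomputed
# from its definition (independent of the package's closed form)
enumerate_pv <- function(rbm) {
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  vs <- expand.grid(rep(list(0:1), nv))
  hs <- expand.grid(rep(list(0:1), nh))
  un <- numeric(nrow(vs))
  for (i in seq_len(nrow(vs))) {
    v <- as.numeric(vs[i, ])
    for (j in seq_len(nrow(hs))) {
      h <- as.numeric(hs[j, ])
      e <- -sum(rbm$a * v) - sum(rbm$c * h) -
        sum(outer(v, h) * rbm$W)
      un[i] <- un[i] + exp(-e)
    }
  }
  list(configs = as.matrix(vs), p = un / sum(un))
}

# small learnable pool of windowed examples for boosting/network tests
make_learnable_pool <- function(n_proteins = 20, seed = 11, l_in = 20,
                                l_tgt = 3, coupling = 1) {
  ds <- generate_dataset(synthetic_config(n_proteins = n_proteins,
                                          coupling = coupling, seed = seed))
  pool <- pool_examples(mapply(encode_protein, ds$records, ds$tracks,
                               MoreArgs = list(l_in = l_in, l_tgt = l_tgt),
                               SIMPLIFY = FALSE))
  list(pool = pool, dataset = ds)
}

# latent-prototype classification task: inputs cluster around binary
# prototypes, labels depend only on the prototype, so unsupervised
# structure learning has something to find
make_prototype_task <- function(seed, n_train = 300, n_test = 500,
                                d = 40, k = 8, flip = 0.08) {
  set.seed(seed)
  protos <- matrix(rbinom(k * d, 1, 0.5), k, d)
  lab_of <- rbinom(k, 1, 0.5)
  gen <- function(n) {
    ki <- sample(seq_len(k), n, replace = TRUE)
    X <- protos[ki, , drop = FALSE]
    X <- abs(X - (matrix(runif(n * d), n, d) < flip))
    list(X = X, y = cbind(lab_of[ki]))
  }
  list(train = gen(n_train), test = gen(n_test))
}

# reduced training schedule used by network/boosting tests
desk_net_args <- function() {
  list(hidden_sizes = c(24L, 12L), hyper = rbm_hyper(epochs = 2L),
       output_epochs = 5L, finetune_epochs = 30L, finetune_batch = 100L,
       lr = 0.5)
}
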