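## Synthetic proteins with disorder labels and label-coupled feature tracks.
## The generator emulates the statistics of the curated disorder training
## sets this kind of predictor is built on: proteins longer than 30
## residues, at least one disordered region of >= 3 residues per protein,
## ~6.5% disordered residues overall, disorder concentrated in terminal and
## short internal regions, and features (coil/exposure propensity, PSSM
## entropy, residue composition) statistically coupled to the labels.

# background amino-acid frequencies (approximate UniProt composition)
AA_BACKGROUND <- c(A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.014,
                   Q = 0.039, E = 0.067, G = 0.071, H = 0.023, I = 0.059,
                   L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
                   S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.069)

# disorder-promoting composition: enriched in P, E, S, Q, K, G, A and
# depleted in the order-promoting hydrophobics/aromatics (W, C, F, I, Y, V, L)
AA_DISORDER <- c(A = 0.090, R = 0.055, N = 0.040, D = 0.060, C = 0.003,
                 Q = 0.060, E = 0.110, G = 0.090, H = 0.020, I = 0.025,
                 L = 0.050, K = 0.090, M = 0.015, F = 0.015, P = 0.110,
                 S = 0.110, T = 0.055, W = 0.002, Y = 0.012, V = 0.033)

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the emulated study conditions: lognormal protein
#' lengths (median ~150 residues, minimum 31), a target disorder fraction
#' of 6.5%, terminal regions more likely than internal ones, region lengths
#' of at least 3 residues with a geometric tail, a 1% rate of unclassified
#' (\code{X}) residues, and full-strength feature-label coupling.
#'
#' @param n_proteins Number of proteins.
#' @param length_meanlog,length_sdlog Lognormal length distribution.
#' @param min_length Minimum protein length (31: every protein longer than
#'   30 residues).
#' @param disorder_fraction Target fraction of disordered residues.
#' @param p_terminal Probability that each terminus carries a disordered
#'   region.
#' @param region_geom_p Geometric parameter of the region-length tail
#'   (region length = \code{min_region} + Geometric(p)).
#' @param min_region Minimum disordered-region length (3).
#' @param coupling Feature-label coupling strength in \[0,1\]; 0 makes all
#'   features independent of the labels.
#' @param noise Probability of flipping a predicted SS/SA state away from
#'   its sampled value (emulates upstream predictor error).
#' @param x_rate Rate of unclassified \code{X} labels.
#' @param seed Optional RNG seed for \code{\link{generate_dataset}}.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_proteins = 200L, length_meanlog = 5.0,
                             length_sdlog = 0.45, min_length = 31L,
                             disorder_fraction = 0.065, p_terminal = 0.3,
                             region_geom_p = 0.15, min_region = 3L,
                             coupling = 1, noise = 0.1, x_rate = 0.01,
                             seed = NULL) {
  if (disorder_fraction <= 0 || disorder_fraction >= 1)
    stop("disorder_fraction must be in (0,1): a disordered region is mandatory")
  if (min_region < 3L) stop("min_region must be >= 3")
  if (min_length < 31L) stop("min_length must be >= 31")
  stopifnot(coupling >= 0, coupling <= 1, noise >= 0, noise <= 1,
            x_rate >= 0, x_rate < 1, p_terminal >= 0, p_terminal <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 disorder_fraction = disorder_fraction,
                 p_terminal = p_terminal, region_geom_p = region_geom_p,
                 min_region = as.integer(min_region), coupling = coupling,
                 noise = noise, x_rate = x_rate, seed = seed),
            class = "synthetic_config")
}

# draw one region length: min_region + geometric tail
draw_region_length <- function(cfg) cfg$min_region + rgeom(1, cfg$region_geom_p)

# disorder label mask for one protein. Terminal regions appear with
# probability p_terminal each; the internal-region count is Poisson with a
# rate derived from the target fraction so the realized dataset fraction
# tracks the target by construction.
draw_disorder_mask <- function(n, cfg) {
  mean_len <- cfg$min_region + (1 - cfg$region_geom_p) / cfg$region_geom_p
  dis <- logical(n)
  if (runif(1) < cfg$p_terminal)
    dis[seq_len(min(n, draw_region_length(cfg)))] <- TRUE
  if (runif(1) < cfg$p_terminal) {
    len <- min(n, draw_region_length(cfg))
    dis[seq.int(n - len + 1L, n)] <- TRUE
  }
  # internal-region rate from the target fraction: solve
  #   (2 p_term + lambda + P(no region)) * mean_len = fraction * n
  # by fixed point, where P(no region) = (1-p_term)^2 exp(-lambda) accounts
  # for the mandatory-region fallback below
  lambda <- max(0, cfg$disorder_fraction * n / mean_len - 2 * cfg$p_terminal)
  for (it in 1:20) {
    p_none <- (1 - cfg$p_terminal)^2 * exp(-lambda)
    lambda <- max(0, cfg$disorder_fraction * n / mean_len -
                    2 * cfg$p_terminal - p_none)
  }
  for (k in seq_len(rpois(1, lambda))) {
    len <- min(n, draw_region_length(cfg))
    start <- sample.int(n - len + 1L, 1L)
    dis[seq.int(start, start + len - 1L)] <- TRUE
  }
  # every protein must contain at least one region of >= min_region residues
  if (!has_min_region(dis, cfg$min_region)) {
    len <- min(n, draw_region_length(cfg))
    start <- sample.int(n - len + 1L, 1L)
    dis[seq.int(start, start + len - 1L)] <- TRUE
  }
  dis
}

has_min_region <- function(dis, min_region) {
  r <- rle(dis)
  any(r$values & r$lengths >= min_region)
}

# per-residue feature simulation given the disorder mask
simulate_tracks <- function(dis, cfg) {
  n <- length(dis)
  cp <- cfg$coupling
  # residue composition
  p_dis <- (1 - cp) * AA_BACKGROUND + cp * AA_DISORDER
  aa <- character(n)
  aa[!dis] <- sample(names(AA_BACKGROUND), sum(!dis), replace = TRUE,
                     prob = AA_BACKGROUND)
  if (any(dis))
    aa[dis] <- sample(names(AA_DISORDER), sum(dis), replace = TRUE,
                      prob = p_dis)
  # secondary structure: disorder shifts mass onto coil
  p_coil <- ifelse(dis, 0.45 + 0.45 * cp, 0.45)
  ss <- vapply(p_coil, function(pc) {
    rest <- 1 - pc
    sample(c("C", "H", "E"), 1L, prob = c(pc, rest * 0.6, rest * 0.4))
  }, character(1))
  # solvent accessibility: disorder shifts mass onto exposed
  p_exp <- ifelse(dis, 0.45 + 0.40 * cp, 0.45)
  sa <- ifelse(runif(n) < p_exp, "e", "b")
  # upstream-predictor noise: flip to a random state
  flip <- runif(n) < cfg$noise
  ss[flip] <- sample(c("C", "H", "E"), sum(flip), replace = TRUE)
  flip <- runif(n) < cfg$noise
  sa[flip] <- sample(c("e", "b"), sum(flip), replace = TRUE)
  # PSSM: ordered positions are conserved (peaked likelihoods, higher
  # information); disordered positions are low-complexity (flat, lower info)
  own_w <- ifelse(dis, 0.55 - 0.35 * cp, 0.55)
  lik_pct <- matrix(0L, n, 20, dimnames = list(NULL, AA_STANDARD))
  for (i in seq_len(n)) {
    w <- rep((1 - own_w[i]) / 19, 20)
    names(w) <- AA_STANDARD
    aak <- if (aa[i] %in% AA_STANDARD) aa[i] else sample(AA_STANDARD, 1L)
    w[aak] <- own_w[i]
    w <- w * rgamma(20, shape = 8, rate = 8)  # profile noise
    lik_pct[i, ] <- round(100 * w / sum(w))
  }
  # information content on a 2-decimal grid so fixture files round-trip
  # bitwise through the ASCII PSSM dialect
  info <- as.numeric(sprintf("%.2f",
                             pmin(pmax(rnorm(n, 2.0 - 1.2 * cp * dis, 0.4),
                                       0), 6)))
  list(aa = aa, ss = paste(ss, collapse = ""),
       sa = paste(sa, collapse = ""), lik_pct = lik_pct, info = info)
}

#' Generate a synthetic labelled dataset
#'
#' Draws proteins, disorder labels and coupled feature tracks according to
#' the configuration. Deterministic for a fixed \code{cfg$seed}.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return Object of class \code{synthetic_dataset}: lists \code{records}
#'   (labelled \code{\link{protein_record}}s) and \code{tracks}
#'   (\code{\link{residue_track}}s), plus the \code{cfg}.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  records <- vector("list", cfg$n_proteins)
  tracks <- vector("list", cfg$n_proteins)
  for (p in seq_len(cfg$n_proteins)) {
    n <- max(cfg$min_length,
             round(rlnorm(1, cfg$length_meanlog, cfg$length_sdlog)))
    dis <- draw_disorder_mask(n, cfg)
    sim <- simulate_tracks(dis, cfg)
    lab <- ifelse(dis, "D", "O")
    # X residues are injected over ordered positions only, so the mandatory
    # disordered region of every protein survives in the labels
    lab[runif(n) < cfg$x_rate & !dis] <- "X"
    id <- sprintf("SYN%04d", p)
    rec <- protein_record(id, paste(sim$aa, collapse = ""),
                          paste(lab, collapse = ""))
    pssm <- list(info = pmin(pmax(sim$info / 6, 0), 1),
                 info_raw = sim$info,
                 likelihood = sim$lik_pct / 100,
                 residues = sim$aa)
    records[[p]] <- rec
    tracks[[p]] <- residue_track(rec, pssm, sim$ss, sim$sa)
  }
  structure(list(records = records, tracks = tracks, cfg = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  comp <- dataset_composition(x$records)
  cat("<synthetic_dataset> ", length(x$records), " proteins, ",
      sprintf("%.2f%%", comp[["pct_disordered"]]), " disordered residues\n",
      sep = "")
  invisible(x)
}

#' Tiny exactly-solvable RBM fixture
#'
#' A small random RBM together with its exact visible-configuration
#' probability table computed by direct enumeration of every joint (v, h)
#' state from the energy definition (independent of the closed-form
#' marginalisation used by \code{\link{exact_visible_probability}}).
#'
#' @param n_visible,n_hidden Layer sizes (at most 4 and 3).
#' @param seed RNG seed for the random parameters.
#' @param zero Use all-zero parameters instead of random ones.
#' @return List with \code{rbm} and \code{table} (data frame of visible
#'   configurations and probabilities summing to 1).
#' @export
tiny_rbm_fixture <- function(n_visible = 3L, n_hidden = 2L, seed = 1L,
                             zero = FALSE) {
  if (n_visible > 4L || n_hidden > 3L)
    stop("fixture limited to n_visible <= 4, n_hidden <= 3")
  set.seed(seed)
  rbm <- rbm_new(n_visible, n_hidden, init_sd = if (zero) 0 else 0.5)
  if (!zero) {
    rbm$a <- rnorm(n_visible, 0, 0.5)
    rbm$c <- rnorm(n_hidden, 0, 0.5)
  }
  vs <- all_binary_vectors(n_visible)
  hs <- all_binary_vectors(n_hidden)
  joint <- matrix(0, nrow(vs), nrow(hs))
  for (i in seq_len(nrow(vs)))
    for (j in seq_len(nrow(hs)))
      joint[i, j] <- exp(-rbm_energy(vs[i, ], hs[j, ], rbm))
  pv <- rowSums(joint) / sum(joint)
  list(rbm = rbm,
       table = data.frame(config = apply(vs, 1, paste, collapse = ""),
                          p = pv))
}

#' Write a synthetic dataset to fixture files
#'
#' Emits the same file dialects the encoders read: one multi-record FASTA,
#' per-protein PSSM, secondary-structure, solvent-accessibility and label
#' files, and a manifest listing the proteins and the generator seed.
#'
#' @param dataset A \code{\link{generate_dataset}} result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_fixture_files <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(dataset$records, `[[`, character(1), "sequence")
  names(seqs) <- vapply(dataset$records, `[[`, character(1), "id")
  write_fasta(seqs, file.path(dir, "dataset.fasta"))
  for (p in seq_along(dataset$records)) {
    rec <- dataset$records[[p]]; tr <- dataset$tracks[[p]]
    write_pssm(file.path(dir, paste0(rec$id, ".pssm")), rec$sequence,
               # stored info is scaled by 6; emit the raw bits
               tr$pssm_info * 6, tr$pssm_likelihood * 100)
    write_track_file(file.path(dir, paste0(rec$id, ".ss")), rec$id,
                     paste(c("H", "E", "C")[max.col(tr$ss)], collapse = ""))
    write_track_file(file.path(dir, paste0(rec$id, ".sa")), rec$id,
                     paste(c("e", "b")[max.col(tr$sa)], collapse = ""))
    write_track_file(file.path(dir, paste0(rec$id, ".labels")), rec$id,
                     rec$labels)
  }
  manifest <- data.frame(
    id = names(seqs),
    length = nchar(seqs),
    n_disordered = vapply(dataset$records, function(r)
      sum(strsplit(r$labels, "")[[1]] == "D"), integer(1)),
    seed = dataset$cfg$seed %||% NA_integer_)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory back into records and tracks
#'
#' Inverse of \code{\link{write_fixture_files}}; label files are optional
#' (prediction-only directories).
#'
#' @param dir Directory written by \code{\link{write_fixture_files}} (or
#'   assembled by hand in the same layout).
#' @return A list with \code{records} and \code{tracks}.
#' @export
read_dataset <- function(dir) {
  fasta <- file.path(dir, "dataset.fasta")
  if (!file.exists(fasta)) stop("missing file: ", fasta)
  seqs <- read_fasta(fasta)
  records <- vector("list", length(seqs))
  tracks <- vector("list", length(seqs))
  for (p in seq_along(seqs)) {
    id <- names(seqs)[p]
    need <- file.path(dir, paste0(id, c(".pssm", ".ss", ".sa")))
    miss <- need[!file.exists(need)]
    if (length(miss)) stop("missing file: ", miss[1])
    labf <- file.path(dir, paste0(id, ".labels"))
    labels <- if (file.exists(labf))
      read_track_file(labf, c("O", "D", "X"))$track
    rec <- protein_record(id, seqs[[p]], labels)
    pssm <- parse_pssm(need[1], sequence = seqs[[p]])
    ss <- read_track_file(need[2], c("H", "E", "C"))$track
    sa <- read_track_file(need[3], c("b", "e"))$track
    records[[p]] <- rec
    tracks[[p]] <- residue_track(rec, pssm, ss, sa)
  }
  list(records = records, tracks = tracks)
}
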