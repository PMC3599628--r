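## Per-residue feature encoding: one-hot secondary structure and solvent
## accessibility, scaled Atchley factors, PSSM likelihoods and information
## content, assembled into sliding input windows with multi-residue targets.

# Atchley et al. (2005) five-factor solution for the 20 amino acids:
# factor 1 polarity/accessibility, 2 secondary-structure propensity,
# 3 molecular volume, 4 codon diversity, 5 electrostatic charge.
ATCHLEY_RAW <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512,  # Y
  -1.337, -0.279, -0.544,  1.242, -1.262   # V
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  paste0("f", 1:5)))

# min-max rescaled per factor over the 20-residue population, so every
# stored value lies in [0,1]
ATCHLEY_SCALED <- apply(ATCHLEY_RAW, 2, function(v) (v - min(v)) / (max(v) - min(v)))

# residue feature block layout within one window slot (31 values + bounds flag)
N_RESIDUE_FEATURES <- 31L
N_SLOT_FEATURES <- 32L
N_GLOBAL_FEATURES <- 4L

#' Scaled Atchley factors for one residue
#'
#' The five published Atchley physicochemical factors, min-max rescaled per
#' factor across the 20 standard residues so all values lie in \[0,1\].
#' Non-standard letters (B, Z, X, U, J, O) receive the neutral per-factor
#' value 0.5.
#'
#' @param residue A single one-letter amino-acid code.
#' @return Numeric vector of length 5.
#' @export
atchley_factors <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  residue <- toupper(residue)
  if (residue %in% rownames(ATCHLEY_SCALED))
    return(unname(ATCHLEY_SCALED[residue, ]))
  rep(0.5, 5)
}

atchley_matrix <- function(sequence) {
  aas <- strsplit(sequence, "")[[1]]
  t(vapply(aas, atchley_factors, numeric(5)))
}

#' One-hot encode predicted secondary structure
#'
#' Per-residue 3-state secondary structure mapped to three binary inputs in
#' the order (alpha, beta, coil): H -> 100, E -> 010, C -> 001.
#'
#' @param ss_string Per-residue string over \code{H/E/C}.
#' @return Integer matrix, rows = residues, columns \code{(alpha, beta, coil)}.
#' @export
encode_ss <- function(ss_string) {
  ch <- strsplit(toupper(ss_string), "")[[1]]
  bad <- which(!(ch %in% c("H", "E", "C")))
  if (length(bad))
    stop("secondary structure: unknown character '", ch[bad[1]],
         "' at position ", bad[1])
  m <- cbind(alpha = as.integer(ch == "H"),
             beta  = as.integer(ch == "E"),
             coil  = as.integer(ch == "C"))
  m
}

#' One-hot encode predicted solvent accessibility
#'
#' Per-residue 2-state relative solvent accessibility mapped to two binary
#' inputs in the order (exposed, buried): e -> 10, b -> 01.
#'
#' @param sa_string Per-residue string over \code{b/e} (buried/exposed).
#' @return Integer matrix, rows = residues, columns \code{(exposed, buried)}.
#' @export
encode_sa <- function(sa_string) {
  ch <- strsplit(tolower(sa_string), "")[[1]]
  bad <- which(!(ch %in% c("b", "e")))
  if (length(bad))
    stop("solvent accessibility: unknown character '", ch[bad[1]],
         "' at position ", bad[1])
  cbind(exposed = as.integer(ch == "e"),
        buried  = as.integer(ch == "b"))
}

#' Assemble a per-residue feature track
#'
#' Combines the sequence, parsed PSSM, predicted secondary structure and
#' predicted solvent accessibility into the per-residue feature rows used by
#' the windowed encoder. All values lie in \[0,1\].
#'
#' @param record A \code{\link{protein_record}}.
#' @param pssm Result of \code{\link{parse_pssm}} (matching the sequence).
#' @param ss Secondary-structure string over \code{H/E/C}.
#' @param sa Solvent-accessibility string over \code{b/e}.
#' @return An object of class \code{residue_track}.
#' @export
residue_track <- function(record, pssm, ss, sa) {
  n <- nchar(record$sequence)
  if (nchar(ss) != n)
    stop("protein '", record$id, "': secondary structure length ",
         nchar(ss), " != sequence length ", n)
  if (nchar(sa) != n)
    stop("protein '", record$id, "': solvent accessibility length ",
         nchar(sa), " != sequence length ", n)
  if (nrow(pssm$likelihood) != n)
    stop("protein '", record$id, "': PSSM has ", nrow(pssm$likelihood),
         " rows for ", n, " residues")
  ssm <- encode_ss(ss)
  sam <- encode_sa(sa)
  structure(list(
    id = record$id,
    length = n,
    sequence = record$sequence,
    ss = ssm,
    sa = sam,
    atchley = atchley_matrix(record$sequence),
    pssm_info = pssm$info,
    pssm_likelihood = pssm$likelihood,
    global = c(frac_exposed = mean(sam[, "exposed"]),
               frac_helix = mean(ssm[, "alpha"]),
               frac_sheet = mean(ssm[, "beta"]))
  ), class = "residue_track")
}

#' Protein-level composition features
#'
#' Fractions of residues predicted exposed, alpha helix and beta sheet,
#' computed over the whole protein.
#'
#' @param track A \code{\link{residue_track}}.
#' @return Named numeric vector \code{(frac_exposed, frac_helix, frac_sheet)}.
#' @export
global_features <- function(track) track$global

# dense residue-feature matrix (n x 31): sa(2) ss(3) atchley(5) info(1) lik(20)
residue_feature_matrix <- function(track) {
  cbind(track$sa, track$ss, track$atchley, info = track$pssm_info,
        track$pssm_likelihood)
}

#' Input feature dimension for a window size
#'
#' Each window slot contributes 31 residue features plus one in-bounds flag;
#' four protein-level features are appended: 32 * L_in + 4 (644 for a
#' 20-residue window, 804 for 25, 964 for 30).
#'
#' @param l_in Input window length.
#' @return Integer dimension.
#' @export
window_input_dim <- function(l_in) N_SLOT_FEATURES * as.integer(l_in) + N_GLOBAL_FEATURES

# slot indices (may run outside 1..n) of the input window for a given center.
# Left context = ceiling((l_in - l_tgt)/2) slots before the first target
# residue; the remainder sits to the right.
window_slots <- function(center, l_in, l_tgt) {
  first_target <- center - (l_tgt - 1L) %/% 2L
  start <- first_target - ceiling((l_in - l_tgt) / 2)
  seq.int(start, length.out = l_in)
}

#' Build one windowed training/prediction example
#'
#' Extracts the input window of \code{l_in} consecutive slots positioned
#' around the target window of \code{l_tgt} residues centred at
#' \code{center}. Slots that fall outside the sequence contribute all-zero
#' residue features and an in-bounds flag of 0; in-sequence slots carry their
#' 31 features and flag 1. The four protein-level features (fraction exposed,
#' fraction helix, fraction sheet, relative position \code{center/length})
#' are appended.
#'
#' @param track A \code{\link{residue_track}}.
#' @param center 1-based index of the target-window centre residue.
#' @param l_in Input window length (20, 25 or 30 at full scale).
#' @param l_tgt Target window length (3, 5 or 7; odd).
#' @param labels Optional per-residue label vector over \code{O/D/X}.
#' @return List with \code{x} (length \code{32*l_in + 4}), \code{y} (length
#'   \code{l_tgt}, 0/1, NULL when no labels), \code{mask} (1 where the target
#'   position is a real residue with a usable label), \code{center}.
#' @export
build_window <- function(track, center, l_in, l_tgt, labels = NULL) {
  n <- track$length
  if (center < 1L || center > n)
    stop("center ", center, " out of range 1..", n)
  if (l_tgt %% 2L == 0L) stop("l_tgt must be odd")
  feats <- residue_feature_matrix(track)
  slots <- window_slots(center, l_in, l_tgt)
  x <- numeric(N_SLOT_FEATURES * l_in)
  inb <- slots >= 1L & slots <= n
  for (k in seq_len(l_in)) {
    off <- (k - 1L) * N_SLOT_FEATURES
    if (inb[k]) {
      x[off + seq_len(N_RESIDUE_FEATURES)] <- feats[slots[k], ]
      x[off + N_SLOT_FEATURES] <- 1
    }
  }
  x <- c(x, unname(track$global), center / n)
  half <- (l_tgt - 1L) %/% 2L
  tpos <- seq.int(center - half, center + half)
  tin <- tpos >= 1L & tpos <= n
  mask <- as.numeric(tin)
  y <- NULL
  if (!is.null(labels)) {
    y <- numeric(l_tgt)
    y[tin] <- as.numeric(labels[tpos[tin]] == "D")
    # 'X' residues: target 0 and excluded from the loss
    mask[tin][labels[tpos[tin]] == "X"] <- 0
  }
  list(x = x, y = y, mask = mask, center = center)
}

#' Encode a whole protein into windowed examples
#'
#' Slides the target window with stride 1 so every residue is the centre of
#' exactly one example per window combination.
#'
#' @inheritParams build_window
#' @param record The \code{\link{protein_record}} the track was built from
#'   (its labels, if any, supply the targets).
#' @return Object of class \code{windowed_examples}: list with matrix
#'   \code{X} (one row per residue), matrix \code{Y} and \code{M} (targets
#'   and masks, NULL/\code{M} in-bounds-only when unlabelled), \code{centers},
#'   \code{id}, \code{length}, \code{l_in}, \code{l_tgt}.
#' @export
encode_protein <- function(record, track, l_in, l_tgt) {
  n <- track$length
  labels <- if (!is.null(record$labels)) strsplit(record$labels, "")[[1]]
  X <- matrix(0, n, window_input_dim(l_in))
  Y <- if (!is.null(labels)) matrix(0, n, l_tgt)
  M <- matrix(0, n, l_tgt)
  for (i in seq_len(n)) {
    w <- build_window(track, i, l_in, l_tgt, labels)
    X[i, ] <- w$x
    if (!is.null(labels)) Y[i, ] <- w$y
    M[i, ] <- w$mask
  }
  structure(list(X = X, Y = Y, M = M, centers = seq_len(n), id = record$id,
                 length = n, l_in = as.integer(l_in),
                 l_tgt = as.integer(l_tgt)),
            class = "windowed_examples")
}

#' Pool windowed examples from several proteins
#'
#' Stacks the per-protein example matrices into one training pool, keeping
#' protein ids and centres so pool rows can be traced back to residues.
#'
#' @param examples List of \code{windowed_examples} (same \code{l_in},
#'   \code{l_tgt}).
#' @return A \code{windowed_examples}-like list with pooled \code{X},
#'   \code{Y}, \code{M} and per-row \code{protein}/\code{centers}.
#' @export
pool_examples <- function(examples) {
  stopifnot(length(examples) > 0L)
  l_in <- unique(vapply(examples, `[[`, integer(1), "l_in"))
  l_tgt <- unique(vapply(examples, `[[`, integer(1), "l_tgt"))
  stopifnot(length(l_in) == 1L, length(l_tgt) == 1L)
  structure(list(
    X = do.call(rbind, lapply(examples, `[[`, "X")),
    Y = do.call(rbind, lapply(examples, `[[`, "Y")),
    M = do.call(rbind, lapply(examples, `[[`, "M")),
    centers = unlist(lapply(examples, `[[`, "centers")),
    protein = rep(vapply(examples, `[[`, character(1), "id"),
                  vapply(examples, `[[`, integer(1), "length")),
    l_in = l_in, l_tgt = l_tgt), class = "windowed_examples")
}
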