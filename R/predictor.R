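## From windowed ensemble outputs to per-residue disorder scores: overlap
## aggregation within one boosted ensemble, unweighted averaging across the
## window-combination ensembles, and optional meta averaging with an
## external predictor's score track.

# the five input/target window combinations used at full scale
DEFAULT_WINDOW_COMBOS <- list(c(20L, 3L), c(25L, 3L), c(25L, 5L),
                              c(30L, 5L), c(30L, 7L))

combo_key <- function(combo) paste(combo[1], combo[2], sep = "_")

#' Aggregate overlapping target-window outputs into per-residue scores
#'
#' With stride-1 target windows, residue i is covered by up to
#' \code{l_tgt} windows (those centred within \code{(l_tgt-1)/2} of i); its
#' score is the arithmetic mean of the unmasked window outputs covering it.
#'
#' @param h Matrix of ensemble outputs, one row per centre residue,
#'   \code{l_tgt} columns.
#' @param masks In-bounds mask matrix of the same shape.
#' @param id Protein identifier for the returned track.
#' @return A \code{\link{score_track}} of length \code{nrow(h)}.
#' @export
aggregate_residue_scores <- function(h, masks, id = "protein") {
  if (is.null(dim(h))) h <- rbind(h)
  n <- nrow(h); l_tgt <- ncol(h)
  half <- (l_tgt - 1L) %/% 2L
  num <- numeric(n); cnt <- numeric(n)
  for (k in seq_len(l_tgt)) {
    # window centred at c covers residue c + (k - 1 - half) at position k
    offs <- k - 1L - half
    centers <- seq_len(n)
    resi <- centers + offs
    ok <- resi >= 1L & resi <= n & masks[, k] == 1
    num[resi[ok]] <- num[resi[ok]] + h[centers[ok], k]
    cnt[resi[ok]] <- cnt[resi[ok]] + 1
  }
  if (any(cnt == 0))
    stop("internal error: residue covered by no window output")
  score_track(id, num / cnt)
}

#' Score one protein with a single boosted ensemble
#'
#' Encodes the protein for the ensemble's window combination, applies the
#' performance-weighted ensemble to every windowed example and aggregates
#' the overlapping target windows.
#'
#' @param ensemble A \code{boosted_ensemble}.
#' @param record A \code{\link{protein_record}}.
#' @param track Its \code{\link{residue_track}}.
#' @return A \code{\link{score_track}}.
#' @export
predict_ensemble <- function(ensemble, record, track) {
  ex <- encode_protein(record, track, ensemble$l_in, ensemble$l_tgt)
  h <- ensemble_output(ensemble, ex$X)
  if (is.null(dim(h))) h <- matrix(h, nrow = nrow(ex$X))
  # aggregation uses the in-bounds mask only (X-label masking concerns the
  # loss, not prediction coverage)
  half <- (ensemble$l_tgt - 1L) %/% 2L
  inb <- outer(seq_len(ex$length), seq_len(ensemble$l_tgt) - 1L - half, "+")
  inbounds <- (inb >= 1L) & (inb <= ex$length)
  aggregate_residue_scores(h, inbounds * 1, id = record$id)
}

#' Ensemble set over window combinations
#'
#' Groups the boosted ensembles trained for the different input/target
#' window combinations (20-3, 25-3, 25-5, 30-5, 30-7 at full scale; any
#' non-empty subset is allowed at desk scale).
#'
#' @param ensembles List of \code{boosted_ensemble} objects.
#' @return Object of class \code{ensemble_set}, keyed
#'   \code{"<l_in>_<l_tgt>"}.
#' @export
ensemble_set <- function(ensembles) {
  if (!length(ensembles)) stop("ensemble set must contain at least one ensemble")
  keys <- vapply(ensembles, function(e) combo_key(c(e$l_in, e$l_tgt)),
                 character(1))
  names(ensembles) <- keys
  structure(list(ensembles = ensembles), class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat("<ensemble_set> combinations: ",
      paste(names(x$ensembles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Combine the window-combination ensembles into the final score
#'
#' The final per-residue prediction is the unweighted mean of the score
#' tracks produced by each boosted ensemble.
#'
#' @param set An \code{\link{ensemble_set}}.
#' @param record A \code{\link{protein_record}}.
#' @param track Its \code{\link{residue_track}}.
#' @return A \code{\link{score_track}}.
#' @export
combine_ensembles <- function(set, record, track) {
  if (!length(set$ensembles)) stop("empty ensemble set")
  tracks <- lapply(set$ensembles, predict_ensemble, record = record,
                   track = track)
  scores <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "scores")))
  score_track(record$id, scores)
}

#' @rdname combine_ensembles
#' @export
predict_disorder <- combine_ensembles

#' Average two score tracks (meta prediction)
#'
#' Componentwise mean of this predictor's track and an external predictor's
#' track for the same protein.
#'
#' @param a,b \code{\link{score_track}}s of equal length.
#' @return A \code{\link{score_track}}.
#' @export
meta_average <- function(a, b) {
  if (length(a$scores) != length(b$scores))
    stop("score tracks differ in length: ", length(a$scores), " vs ",
         length(b$scores))
  score_track(a$id, (a$scores + b$scores) / 2, threshold = a$threshold)
}

#' Two-state calls from a score track
#'
#' Scores at or above the threshold are called disordered (\code{"D"}),
#' the rest ordered (\code{"O"}); the tie goes to disorder, mirroring the
#' hard-vote rule of the base classifiers.
#'
#' @param track A \code{\link{score_track}}.
#' @param threshold Decision threshold in (0,1).
#' @return Character vector over \code{O/D}.
#' @export
classify <- function(track, threshold = track$threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  ifelse(track$scores >= threshold, "D", "O")
}
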