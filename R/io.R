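## Readers and writers for the external formats the pipeline consumes:
## multi-record FASTA, the PSI-BLAST ASCII PSSM dialect, two-line
## secondary-structure / solvent-accessibility / label tracks, plain
## two-column score tracks, and the CASP DR submission format.

#' Read a multi-record FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences as multi-record FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the standard `-Q`-style ASCII matrix: after the header, one row per
#' query residue carrying the residue index and letter, 20 log-odds columns,
#' 20 percentage (weighted observed frequency) columns, the per-position
#' information content and a gap weight. Percentages are scaled to \[0,1\]
#' likelihoods by division by 100; the information content is scaled to
#' \[0,1\] by clamped division by 6 (information per position is bounded
#' near log2(20) ~ 4.3 bits, so 6 gives headroom).
#'
#' @param path File path, or \code{NULL} when \code{text} is given.
#' @param text Character scalar or vector of lines (alternative to
#'   \code{path}).
#' @param sequence Optional query sequence; when given, row letters are
#'   checked against it.
#' @return List with \code{residues} (letters), \code{info_raw},
#'   \code{info} (scaled), \code{likelihood} (n x 20 matrix in \[0,1\],
#'   PSI-BLAST column order ARNDCQEGHILKMFPSTWYV) and \code{logodds}.
#' @export
parse_pssm <- function(path = NULL, text = NULL, sequence = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("either path or text must be given")
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
             else text
  }
  rows <- list(); letters_seen <- character(0); row_lines <- integer(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 2L || is.na(suppressWarnings(as.integer(tok[1]))))
      next
    if (!grepl("^[A-Za-z]$", tok[2])) next
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (length(vals) < 42L || anyNA(vals[1:42]))
      stop("PSSM parse error at line ", i, ": expected 20 log-odds, ",
           "20 percentage columns, information and gap weight; got ",
           length(vals), " numeric fields")
    rows[[length(rows) + 1L]] <- vals
    letters_seen <- c(letters_seen, toupper(tok[2]))
    row_lines <- c(row_lines, i)
  }
  if (!length(rows))
    stop("PSSM parse error: no matrix rows found")
  vals <- do.call(rbind, rows)
  if (!is.null(sequence)) {
    sq <- strsplit(toupper(sequence), "")[[1]]
    if (length(sq) != nrow(vals))
      stop("PSSM has ", nrow(vals), " rows but sequence has ",
           length(sq), " residues")
    mism <- which(letters_seen != sq)
    if (length(mism))
      stop("PSSM residue mismatch at position ", mism[1], " (line ",
           row_lines[mism[1]], "): matrix '", letters_seen[mism[1]],
           "' vs sequence '", sq[mism[1]], "'")
  }
  lik <- vals[, 21:40, drop = FALSE] / 100
  colnames(lik) <- AA_STANDARD
  info_raw <- vals[, 41]
  list(residues = letters_seen,
       info_raw = info_raw,
       info = pmin(pmax(info_raw / 6, 0), 1),
       likelihood = lik,
       logodds = `colnames<-`(vals[, 1:20, drop = FALSE], AA_STANDARD))
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the same layout \code{\link{parse_pssm}} reads (used by the
#' synthetic fixture writer; round-trips exactly at integer percentages and
#' 2-decimal information values).
#'
#' @param path Output file.
#' @param sequence Query sequence.
#' @param info_raw Per-residue information content (bits).
#' @param likelihood_pct n x 20 integer percentage matrix.
#' @param logodds Optional n x 20 log-odds matrix (defaults to zeros).
#' @export
write_pssm <- function(path, sequence, info_raw, likelihood_pct,
                       logodds = NULL) {
  sq <- strsplit(toupper(sequence), "")[[1]]
  n <- length(sq)
  stopifnot(nrow(likelihood_pct) == n, length(info_raw) == n)
  if (is.null(logodds)) logodds <- matrix(0L, n, 20)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA_STANDARD), collapse = " "),
           "  ", paste(sprintf("%3s", AA_STANDARD), collapse = " "))), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("%5d %s  %s  %s %5.2f %8.2f", i, sq[i],
                       paste(sprintf("%3d", round(logodds[i, ])), collapse = " "),
                       paste(sprintf("%3d", round(likelihood_pct[i, ])), collapse = " "),
                       info_raw[i], 0), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read a two-line per-residue track file
#'
#' The SSpro/ACCpro-style dialect: a \code{">id"} header line followed by one
#' line holding the per-residue string. Used for predicted secondary
#' structure (\code{H/E/C}), solvent accessibility (\code{b/e}) and
#' order/disorder labels (\code{O/D/X}).
#'
#' @param path File path.
#' @param alphabet Optional allowed character set; violations are errors.
#' @return List with \code{id} and \code{track} (character scalar).
#' @export
read_track_file <- function(path, alphabet = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !startsWith(lines[1], ">"))
    stop("track file '", path, "': expected '>id' header then one track line")
  id <- sub("^>\\s*", "", trimws(lines[1]))
  track <- trimws(lines[2])
  if (!is.null(alphabet)) {
    ch <- strsplit(track, "")[[1]]
    bad <- which(!(ch %in% alphabet))
    if (length(bad))
      stop("track file '", path, "': character '", ch[bad[1]],
           "' at position ", bad[1], " not in {",
           paste(alphabet, collapse = ","), "}")
  }
  list(id = id, track = track)
}

#' Write a two-line per-residue track file
#'
#' @param path Output file.
#' @param id Protein identifier.
#' @param track Per-residue string.
#' @export
write_track_file <- function(path, id, track) {
  writeLines(c(paste0(">", id), track), path)
  invisible(path)
}

#' Per-residue disorder score track
#'
#' @param id Protein identifier.
#' @param scores Per-residue scores in \[0,1\] (0 = ordered, 1 = disordered).
#' @param threshold Decision threshold used by \code{\link{classify}}.
#' @return Object of class \code{score_track}.
#' @export
score_track <- function(id, scores, threshold = 0.5) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("scores must be finite and in [0,1]")
  structure(list(id = id, scores = scores, threshold = threshold),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("<score_track> ", x$id, ": ", length(x$scores),
      " residues, mean score ", sprintf("%.3f", mean(x$scores)), "\n", sep = "")
  invisible(x)
}

#' Read / write a plain two-column score track
#'
#' Format: one line per residue, \code{<index> <score>}, used to exchange
#' score tracks with external predictors for meta averaging.
#'
#' @param path File path.
#' @param id Identifier to attach on read.
#' @return \code{read_score_track}: a \code{\link{score_track}}.
#' @export
read_score_track <- function(path, id = basename(path)) {
  d <- utils::read.table(path, col.names = c("index", "score"))
  if (any(d$index != seq_len(nrow(d))))
    stop("score track '", path, "': indices must be 1..n in order")
  score_track(id, d$score)
}

#' @rdname read_score_track
#' @param track A \code{\link{score_track}}.
#' @export
write_score_track <- function(track, path) {
  utils::write.table(
    data.frame(index = seq_along(track$scores),
               score = sprintf("%.6f", track$scores)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a CASP DR prediction file
#'
#' Bit-exact CASP disorder-prediction layout: \code{PFRMAT DR},
#' \code{TARGET <id>}, \code{MODEL 1}, then one line per residue
#' \code{<AA> <D|O> <score>} with the score printed to 2 decimals, and a
#' final \code{END}.
#'
#' @param track A \code{\link{score_track}}.
#' @param sequence The protein sequence (same length as the track).
#' @param path Output file.
#' @param threshold Decision threshold for the two-state call.
#' @export
write_casp_dr <- function(track, sequence, path, threshold = track$threshold) {
  aas <- strsplit(sequence, "")[[1]]
  if (length(aas) != length(track$scores))
    stop("sequence length ", length(aas), " != score count ",
         length(track$scores))
  calls <- classify(track, threshold)
  writeLines(c("PFRMAT DR",
               paste("TARGET", track$id),
               "MODEL 1",
               sprintf("%s %s %.2f", aas, calls, track$scores),
               "END"), path)
  invisible(path)
}

#' Parse a CASP DR prediction file
#'
#' @param path File written by \code{\link{write_casp_dr}} (or any
#'   conforming DR file with single-model records).
#' @return List with \code{id}, \code{sequence}, \code{calls},
#'   and a \code{\link{score_track}}.
#' @export
read_casp_dr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "PFRMAT DR")
    stop("DR file '", path, "': missing PFRMAT DR header")
  id <- sub("^TARGET\\s+", "", grep("^TARGET", lines, value = TRUE)[1])
  body <- lines[!grepl("^(PFRMAT|TARGET|MODEL|END)", lines)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("DR file '", path, "': malformed residue line ", bad[1])
  m <- do.call(rbind, parts)
  list(id = id,
       sequence = paste(m[, 1], collapse = ""),
       calls = m[, 2],
       track = score_track(id, as.numeric(m[, 3])))
}
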