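#' Protein record
#'
#' A protein sequence with an identifier and, optionally, per-residue
#' order/disorder labels: \code{"O"} ordered, \code{"D"} disordered,
#' \code{"X"} unclassified (excluded from training loss and never counted as
#' disordered in evaluation).
#'
#' @param id Character identifier.
#' @param sequence Amino-acid sequence (one-letter codes; the 20 standard
#'   letters plus the ambiguity codes B, Z, X, U, J, O are accepted).
#' @param labels Optional per-residue label string over \code{O/D/X}, same
#'   length as \code{sequence}.
#' @return An object of class \code{protein_record}.
#' @export
protein_record <- function(id, sequence, labels = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    stop("protein '", id, "': empty sequence")
  bad <- setdiff(strsplit(sequence, "")[[1]],
                 c(AA_STANDARD, c("B", "Z", "X", "U", "J", "O")))
  if (length(bad))
    stop("protein '", id, "': unexpected sequence characters: ",
         paste(unique(bad), collapse = ", "))
  if (!is.null(labels)) {
    labels <- toupper(labels)
    if (nchar(labels) != nchar(sequence))
      stop("protein '", id, "': labels length ", nchar(labels),
           " != sequence length ", nchar(sequence))
    badl <- setdiff(strsplit(labels, "")[[1]], c("O", "D", "X"))
    if (length(badl))
      stop("protein '", id, "': labels must be over {O, D, X}; found: ",
           paste(unique(badl), collapse = ", "))
  }
  structure(list(id = id, sequence = sequence, labels = labels),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " aa",
      if (!is.null(x$labels))
        sprintf(", %d disordered",
                sum(strsplit(x$labels, "")[[1]] == "D")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Disordered regions of a labelled protein
#'
#' Runs of consecutive \code{"D"} labels as (start, end) pairs (1-based,
#' inclusive).
#'
#' @param record A \code{\link{protein_record}} with labels.
#' @return A two-column integer matrix with one row per region.
#' @export
disordered_regions <- function(record) {
  if (is.null(record$labels)) stop("record has no labels")
  lab <- strsplit(record$labels, "")[[1]] == "D"
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# the 20 standard residues, PSI-BLAST column order
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
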