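# Extended amino-acid alphabet shared by all modules.
#
# Sequences and patterns may contain, besides the 20 standard residues, the
# ambiguity codes B (Asx = D/N), Z (Glx = E/Q), J (I/L) and X (any residue).
# A stop ('*') is tolerated only at the end of a sequence on input and is
# stripped there; gaps ('-') are legal only inside alignments.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AMBIGUITY <- list(
  B = c("D", "N"),
  Z = c("E", "Q"),
  J = c("I", "L"),
  X = AA20
)

# Code order used for integer-encoded sequences and the extended score matrix.
AA_EXTENDED <- c(AA20, names(AMBIGUITY))

#' Expand a residue letter to its set of possible standard residues
#'
#' Standard residues map to themselves; the ambiguity codes B, Z, J and X
#' expand to \{D,N\}, \{E,Q\}, \{I,L\} and all 20 residues respectively.
#'
#' @param ch A single residue letter from the extended alphabet.
#' @return Character vector of standard one-letter residue codes.
#' @examples
#' residue_set("B")
#' residue_set("W")
#' @export
residue_set <- function(ch) {
  if (!is.character(ch) || length(ch) != 1L || is.na(ch)) {
    stop("residue must be a single letter", call. = FALSE)
  }
  if (ch %in% AA20) return(ch)
  if (ch %in% names(AMBIGUITY)) return(AMBIGUITY[[ch]])
  stop(sprintf("unknown residue '%s'", ch), call. = FALSE)
}

# Integer-encode a residue string over the extended alphabet (1..24).
encode_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_EXTENDED)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("illegal residue '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  codes
}

# Validate a residue string; returns the cleaned (uppercased, stop-stripped)
# string or signals an error naming the record and 1-based offset.
validate_residues <- function(residues, id = "sequence") {
  res <- toupper(residues)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) {
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  }
  if (chars[length(chars)] == "*") {
    chars <- chars[-length(chars)]
    if (length(chars) == 0L) {
      stop(sprintf("record '%s': sequence is a bare stop", id), call. = FALSE)
    }
  }
  ok <- chars %in% AA_EXTENDED
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, chars[bad], bad), call. = FALSE)
  }
  paste(chars, collapse = "")
}

# Internal coordinates are 0-based half-open; reports use 1-based inclusive.
to_report_coords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

from_report_coords <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}
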