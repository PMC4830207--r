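# Degenerate motifs are ordered lists of residue sets. In pattern strings,
# 'x'/'X' is a wildcard (any residue), B = {D,N}, Z = {E,Q}, J = {I,L}, and a
# plain letter constrains the position to that residue. Matching between a
# motif position and a sequence residue is by non-empty intersection of the
# two residue sets, so a sequence 'X' satisfies every position and a sequence
# 'B' satisfies any position admitting D or N.

#' Parse a degenerate pattern string into a motif
#'
#' @param text Pattern string over the 20 amino acids plus `x`/`X`
#'   (wildcard), `B`, `Z` and `J`.
#' @param id Identifier attached to the motif (defaults to the pattern text).
#' @return An object of class `degenerate_motif` with elements `id`,
#'   `sets` (list of residue sets) and `source` (`"literal"` or `"derived"`).
#' @examples
#' m <- parse_pattern("RxxxxPxxYW")
#' render_pattern(m)
#' @export
parse_pattern <- function(text, id = text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      nchar(text) == 0L) {
    stop("pattern must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  sets <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "x") ch <- "X"
    if (!(ch %in% AA_EXTENDED)) {
      stop(sprintf("illegal pattern character '%s' at position %d",
                   chars[i], i), call. = FALSE)
    }
    sets[[i]] <- residue_set(ch)
  }
  new_motif(id, sets, source = "literal")
}

new_motif <- function(id, sets, source = c("literal", "derived")) {
  source <- match.arg(source)
  if (length(sets) < 1L) stop("motif must have length >= 1", call. = FALSE)
  if (any(lengths(sets) == 0L)) {
    stop("motif has an empty position set", call. = FALSE)
  }
  sets <- lapply(sets, function(s) sort(unique(s)))
  structure(list(id = id, sets = sets, source = source),
            class = "degenerate_motif")
}

#' @export
length.degenerate_motif <- function(x) length(x$sets)

#' Render a motif back to a pattern string
#'
#' Wildcard positions render as `x`; the ambiguity classes \{D,N\}, \{E,Q\}
#' and \{I,L\} render as `B`, `Z` and `J`. A position set not expressible in
#' the pattern alphabet is an error.
#'
#' @param motif A `degenerate_motif`.
#' @return A pattern string such that `parse_pattern(render_pattern(m))`
#'   reproduces `m`.
#' @export
render_pattern <- function(motif) {
  stopifnot(inherits(motif, "degenerate_motif"))
  vapply(seq_along(motif$sets), function(i) {
    s <- motif$sets[[i]]
    if (length(s) == 20L) return("x")
    if (length(s) == 1L) return(s)
    if (setequal(s, c("D", "N"))) return("B")
    if (setequal(s, c("E", "Q"))) return("Z")
    if (setequal(s, c("I", "L"))) return("J")
    stop(sprintf("motif position %d (%s) is not expressible as a pattern",
                 i, paste(s, collapse = "")), call. = FALSE)
  }, character(1)) |> paste(collapse = "")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("degenerate_motif '%s' (%s), %d positions: %s\n",
              x$id, x$source, length(x$sets),
              tryCatch(render_pattern(x), error = function(e) "<custom sets>")))
  invisible(x)
}

# Positions whose set is smaller than the full alphabet; only these can be
# violated and only these count toward mismatches.
constrained_positions <- function(motif) {
  which(lengths(motif$sets) < 20L)
}

# Logical match table: rows = motif positions, cols = extended residue codes.
# match iff intersect(position set, residue ambiguity set) is non-empty.
motif_match_table <- function(motif) {
  tab <- matrix(FALSE, nrow = length(motif$sets), ncol = length(AA_EXTENDED))
  expansions <- lapply(AA_EXTENDED, residue_set)
  for (p in seq_along(motif$sets)) {
    s <- motif$sets[[p]]
    tab[p, ] <- vapply(expansions, function(e) any(e %in% s), logical(1))
  }
  tab
}

# Mismatch count per window for an integer-coded sequence; returns an
# integer vector of length n - m + 1 (empty if the sequence is too short).
window_mismatches <- function(codes, tab, constrained) {
  m <- nrow(tab)
  n <- length(codes)
  if (n < m) return(integer(0))
  w <- n - m + 1L
  mism <- integer(w)
  for (p in constrained) {
    mism <- mism + !tab[p, codes[p:(p + w - 1L)]]
  }
  mism
}

as_single_sequence <- function(seq) {
  if (is.data.frame(seq)) {
    if (nrow(seq) != 1L) {
      stop("expected a single sequence record", call. = FALSE)
    }
    return(list(id = seq$id[1L], residues = seq$residues[1L]))
  }
  if (is.character(seq) && length(seq) == 1L) {
    id <- names(seq)
    if (is.null(id) || !nzchar(id)) id <- "seq1"
    return(list(id = id, residues = toupper(seq)))
  }
  stop("sequence must be a single string or a one-row aa_records", call. = FALSE)
}

empty_hits <- function() {
  structure(
    data.frame(sequence_id = character(), motif_id = character(),
               offset = integer(), length = integer(), mismatches = integer(),
               per_position = character(), stringsAsFactors = FALSE),
    class = c("motif_hits", "data.frame")
  )
}

#' Scan a sequence with a degenerate motif
#'
#' Slides the motif over every window of the sequence and reports each window
#' whose number of violated constrained positions is at most
#' `max_mismatches`. Wildcard positions can never be violated. A position
#' matches when the motif's residue set and the sequence residue's ambiguity
#' set intersect, so ambiguity codes on either side behave symmetrically.
#' Overlapping hits are all reported, sorted by offset.
#'
#' @param motif A `degenerate_motif`.
#' @param seq A residue string (optionally named) or a one-row [aa_records].
#' @param max_mismatches Maximum number of violated constrained positions.
#' @return A data frame of class `motif_hits` with columns `sequence_id`,
#'   `motif_id`, `offset` (0-based), `length`, `mismatches` and
#'   `per_position` (`|` satisfied, `.` wildcard, `x` violated). A sequence
#'   shorter than the motif yields zero rows.
#' @examples
#' scan_motif(parse_pattern("RxxxxPxxYW"), "NVRRTKRXRLKPLEYWRGERVBY")
#' @export
scan_motif <- function(motif, seq, max_mismatches = 0L) {
  stopifnot(inherits(motif, "degenerate_motif"))
  if (!is.numeric(max_mismatches) || length(max_mismatches) != 1L ||
      max_mismatches < 0) {
    stop("'max_mismatches' must be a non-negative integer", call. = FALSE)
  }
  rec <- as_single_sequence(seq)
  codes <- encode_residues(rec$residues)
  m <- length(motif$sets)
  tab <- motif_match_table(motif)
  constrained <- constrained_positions(motif)
  mism <- window_mismatches(codes, tab, constrained)
  keep <- which(mism <= max_mismatches)
  if (length(keep) == 0L) return(empty_hits())
  wild <- setdiff(seq_len(m), constrained)
  per_pos <- vapply(keep, function(w) {
    marks <- character(m)
    marks[wild] <- "."
    for (p in constrained) {
      marks[p] <- if (tab[p, codes[w + p - 1L]]) "|" else "x"
    }
    paste(marks, collapse = "")
  }, character(1))
  structure(
    data.frame(sequence_id = rec$id, motif_id = motif$id,
               offset = keep - 1L, length = m,
               mismatches = mism[keep], per_position = per_pos,
               stringsAsFactors = FALSE),
    class = c("motif_hits", "data.frame")
  )
}

#' Consensus-derivation policy
#'
#' Controls [derive_consensus()]. `min_fraction` is relative to each column's
#' modal (most frequent) residue: a residue is admitted when its frequency is
#' at least `min_fraction` times the modal frequency, so the strict default
#' (`1.0`) keeps exactly the residues tied for the mode. Columns whose gap
#' fraction exceeds `max_gap_fraction` are dropped (default: any gap drops
#' the column).
#'
#' @param min_fraction Fraction of the modal frequency required, in (0, 1].
#' @param allow_ambiguity_codes Collapse \{D,N\} to B, \{E,Q\} to Z and
#'   \{I,L\} to J; otherwise such columns become wildcards.
#' @param max_gap_fraction Maximum tolerated per-column gap fraction.
#' @return A `consensus_policy` object.
#' @export
consensus_policy <- function(min_fraction = 1.0, allow_ambiguity_codes = TRUE,
                             max_gap_fraction = 0.0) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("'min_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(max_gap_fraction) || max_gap_fraction < 0 ||
      max_gap_fraction > 1) {
    stop("'max_gap_fraction' must be in [0, 1]", call. = FALSE)
  }
  structure(list(min_fraction = min_fraction,
                 allow_ambiguity_codes = isTRUE(allow_ambiguity_codes),
                 max_gap_fraction = max_gap_fraction),
            class = "consensus_policy")
}

#' Derive a degenerate consensus motif from a multiple alignment
#'
#' Per column: the column is dropped if its gap fraction exceeds the policy's
#' `max_gap_fraction`; otherwise the admissible residues (frequency at least
#' `min_fraction` of the modal frequency, ambiguity codes expanded) are
#' collapsed to a single residue, an ambiguity code (B/Z/J) when the set
#' falls inside one ambiguity class, or a wildcard. The retained columns are
#' concatenated into a motif flagged `source = "derived"`.
#'
#' @param aln An `aa_alignment`.
#' @param policy A [consensus_policy()].
#' @param id Identifier for the derived motif.
#' @return A `degenerate_motif`.
#' @examples
#' aln <- aa_alignment(c("a", "b"), c("RDPW", "RNPW"))
#' render_pattern(derive_consensus(aln))
#' @export
derive_consensus <- function(aln, policy = consensus_policy(),
                             id = "consensus") {
  stopifnot(inherits(aln, "aa_alignment"), inherits(policy, "consensus_policy"))
  mat <- alignment_matrix(aln)
  sets <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gap_frac <- mean(col %in% c("-", "*"))
    if (gap_frac > policy$max_gap_fraction) next
    sym <- col[!(col %in% c("-", "*"))]
    freq <- table(sym)
    admissible <- names(freq)[freq >= policy$min_fraction * max(freq)]
    set <- sort(unique(unlist(lapply(admissible, residue_set))))
    sets[[length(sets) + 1L]] <- collapse_consensus_set(
      set, policy$allow_ambiguity_codes)
  }
  if (length(sets) == 0L) stop("no consensus columns", call. = FALSE)
  new_motif(id, sets, source = "derived")
}

collapse_consensus_set <- function(set, allow_ambiguity_codes) {
  if (length(set) == 1L) return(set)
  if (allow_ambiguity_codes) {
    for (code in c("B", "Z", "J")) {
      if (all(set %in% AMBIGUITY[[code]])) return(AMBIGUITY[[code]])
    }
  }
  AA20
}

#' Per-column conservation profile of an alignment
#'
#' @param aln An `aa_alignment`.
#' @return A list with one element per column: `column` (1-based index),
#'   `frequencies` (named numeric over non-gap symbols, summing to 1; empty
#'   for an all-gap column) and `gap_fraction`.
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  mat <- alignment_matrix(aln)
  lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    is_gap <- col == "-"
    sym <- col[!is_gap]
    freq <- if (length(sym) == 0L) {
      setNames(numeric(0), character(0))
    } else {
      tab <- table(sym)
      setNames(as.numeric(tab) / length(sym), names(tab))
    }
    list(column = j, frequencies = freq, gap_fraction = mean(is_gap))
  })
}

#' Bundled CENP-C motif patterns
#'
#' The degenerate patterns central to CENP-C architecture screening, shipped
#' as a JSON fixture: the 23-residue vertebrate CENP-C motif consensus
#' (`cenpc_motif_vertebrate`, NVRRTKRXRLKPLEYWRGERVBY), the identity pattern
#' within it (`cenpc_motif_identities`, RxxRxxxxPLxYWxGERxxY), the core
#' CENP-C motif (`cenpc_motif_core`, RxxxxPxxYW), the central-region
#' consensus (`central_region_consensus`, RxSxxPSxWW) and its core
#' (`central_region_core`, RxxxxPxxWW).
#'
#' @return Named list of `degenerate_motif` objects.
#' @export
cenpc_motifs <- function() {
  path <- system.file("extdata", "motifs.json", package = "cenpcscan",
                      mustWork = TRUE)
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  motifs <- lapply(entries, function(e) parse_pattern(e$pattern, id = e$id))
  setNames(motifs, vapply(entries, `[[`, character(1), "id"))
}
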