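#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under a substitution matrix with affine gap
#' penalties (gap of length L costs `gap_open + L * gap_extend`). Traceback
#' ties are broken deterministically (diagonal, then gap in the target, then
#' gap in the query) so repeated runs produce identical output. A best score
#' of zero yields an empty alignment.
#'
#' @param a,b Residue strings (optionally named) or one-row [aa_records];
#'   both must be non-empty.
#' @param scheme A [scoring_scheme()]; defaults to BLOSUM62 with gap
#'   open 11 / extend 1.
#' @return An object of class `local_alignment`: `score` (non-negative
#'   integer), `query_interval` and `target_interval` (0-based half-open,
#'   on `a` and `b`), `query_aln`/`target_aln` (aligned strings with `-`
#'   gaps), `ncol` (alignment columns) and `identity_fraction` (identical
#'   residue pairs over alignment columns; `NA` for an empty alignment).
#' @examples
#' smith_waterman("WGERAAA", "TTWGER")
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  ra <- as_single_sequence(a)
  rb <- as_single_sequence(b)
  if (nchar(ra$residues) == 0L || nchar(rb$residues) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  ca <- encode_residues(ra$residues)
  cb <- encode_residues(rb$residues)
  res <- .sw_align(ca, cb, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  decode <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(v == 0L, "-", AA_EXTENDED[pmax(v, 1L)]), collapse = "")
  }
  qa <- decode(res$a_aln)
  ta <- decode(res$b_aln)
  ncol <- length(res$a_aln)
  ident <- if (ncol == 0L) NA_real_ else {
    mean(res$a_aln == res$b_aln & res$a_aln != 0L)
  }
  structure(list(
    score = res$score,
    query_id = ra$id, target_id = rb$id,
    query_interval = c(res$a_start, res$a_end),
    target_interval = c(res$b_start, res$b_end),
    query_aln = qa, target_aln = ta,
    ncol = ncol, identity_fraction = ident,
    gap_open = scheme$gap_open, gap_extend = scheme$gap_extend
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local_alignment: score %d, %d columns, identity %s\n",
              x$score, x$ncol,
              ifelse(is.na(x$identity_fraction), "NA",
                     sprintf("%.2f", x$identity_fraction))))
  if (x$ncol > 0) {
    cat(sprintf("  query  [%d, %d): %s\n", x$query_interval[1],
                x$query_interval[2], x$query_aln))
    cat(sprintf("  target [%d, %d): %s\n", x$target_interval[1],
                x$target_interval[2], x$target_aln))
  }
  invisible(x)
}

# Recompute an alignment's score from its aligned strings (consistency
# check: must equal the reported DP score).
score_alignment <- function(query_aln, target_aln, scheme) {
  qa <- strsplit(query_aln, "", fixed = TRUE)[[1]]
  ta <- strsplit(target_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(qa) == length(ta))
  score <- 0L
  gap_q <- FALSE  # gap character in query
  gap_t <- FALSE  # gap character in target
  for (k in seq_along(qa)) {
    if (qa[k] == "-") {
      score <- score - scheme$gap_extend - (if (gap_q) 0L else scheme$gap_open)
      gap_q <- TRUE; gap_t <- FALSE
    } else if (ta[k] == "-") {
      score <- score - scheme$gap_extend - (if (gap_t) 0L else scheme$gap_open)
      gap_t <- TRUE; gap_q <- FALSE
    } else {
      score <- score + scheme$matrix[qa[k], ta[k]]
      gap_q <- FALSE; gap_t <- FALSE
    }
  }
  score
}
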