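# Substitution scoring. The bundled matrix is BLOSUM62 in NCBI text format
# (the standard protein-BLAST default, used with gap open 11 / extend 1).
# Ambiguity rows are NOT taken from the file: scores involving B, Z, J or X
# are recomputed as the mean of the member-pair scores, rounded toward zero,
# so that scoring and motif-matching semantics agree on the same residue sets.

#' Read a substitution matrix in NCBI text format
#'
#' @param path Path to a matrix file (comment lines start with `#`, first
#'   non-comment line is the column header).
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("malformed matrix file", call. = FALSE)
  header <- strsplit(lines[1L], "\\s+")[[1]]
  body <- lines[-1L]
  rows <- lapply(body, function(ln) strsplit(ln, "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1L)
  values <- lapply(rows, function(r) as.integer(r[-1L]))
  if (any(vapply(values, length, integer(1)) != length(header))) {
    stop("malformed matrix file: row length does not match header",
         call. = FALSE)
  }
  mat <- do.call(rbind, values)
  dimnames(mat) <- list(labels, header)
  storage.mode(mat) <- "integer"
  mat
}

#' Substitution score between (possibly ambiguous) residues
#'
#' For ambiguity codes the score is the mean of all member-pair scores from
#' the core matrix, rounded toward zero; `X` averages over all 20 residues.
#' The definition is symmetric in its arguments.
#'
#' @param x,y Single residue letters from the extended alphabet.
#' @param matrix A substitution matrix covering the 20 standard residues.
#' @return Integer score.
#' @examples
#' m <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
#'                                    package = "cenpcscan"))
#' ambiguity_score("B", "D", m)
#' @export
ambiguity_score <- function(x, y, matrix) {
  sx <- residue_set(x)
  sy <- residue_set(y)
  vals <- matrix[sx, sy, drop = FALSE]
  as.integer(trunc(mean(vals)))
}

#' Construct a local-alignment scoring scheme
#'
#' Bundles a substitution matrix with affine gap penalties. A gap of length
#' L costs `gap_open + L * gap_extend`. The matrix is extended over the
#' ambiguity codes B, Z, J and X via [ambiguity_score()].
#'
#' @param matrix 20x20 (or larger) substitution matrix with residue
#'   dimnames; `NULL` loads the bundled BLOSUM62.
#' @param gap_open Gap opening penalty (positive; default 11).
#' @param gap_extend Gap extension penalty (positive; default 1;
#'   must not exceed `gap_open`).
#' @return A `scoring_scheme` object with the extended 24x24 matrix.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L) {
  if (is.null(matrix)) {
    matrix <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                            package = "cenpcscan",
                                            mustWork = TRUE))
  }
  if (!all(AA20 %in% rownames(matrix)) || !all(AA20 %in% colnames(matrix))) {
    stop("substitution matrix must cover the 20 standard residues",
         call. = FALSE)
  }
  core <- matrix[AA20, AA20]
  if (!isTRUE(all.equal(core, t(core), check.attributes = FALSE))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  if (gap_open <= 0 || gap_extend <= 0 || gap_open < gap_extend) {
    stop("require gap_open >= gap_extend > 0", call. = FALSE)
  }
  ext <- extend_matrix(core)
  structure(list(matrix = ext, core = core,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

# Extend a 20x20 core matrix over the ambiguity codes by truncated means.
extend_matrix <- function(core) {
  n <- length(AA_EXTENDED)
  ext <- matrix(0L, n, n, dimnames = list(AA_EXTENDED, AA_EXTENDED))
  ext[AA20, AA20] <- core
  ambig <- names(AMBIGUITY)
  for (a in ambig) {
    for (b in AA_EXTENDED) {
      ext[a, b] <- ambiguity_score(a, b, core)
      ext[b, a] <- ext[a, b]
    }
  }
  ext
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: %dx%d matrix, gap open %d, extend %d\n",
              nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend))
  invisible(x)
}
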