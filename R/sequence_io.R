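#' Construct a set of protein records
#'
#' The basic container used throughout the package: a data frame with one row
#' per protein and columns `id`, `description` and `residues`. Residues are
#' uppercased and validated against the extended amino-acid alphabet
#' (20 standard residues plus B, Z, J, X); a terminal stop (`*`) is stripped.
#'
#' @param id Character vector of non-empty record identifiers.
#' @param residues Character vector of residue strings, same length as `id`.
#' @param description Optional character vector of free-text descriptions.
#' @return A data frame of class `aa_records`.
#' @examples
#' aa_records("p1", "MKVRRTKW")
#' @export
aa_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- as.character(residues)
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length", call. = FALSE)
  }
  description <- rep_len(as.character(description), length(id))
  if (any(!nzchar(id)) || anyNA(id)) {
    stop("record ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    warning("duplicated record ids", call. = FALSE)
  }
  residues <- vapply(seq_along(id), function(i) {
    validate_residues(residues[i], id[i])
  }, character(1))
  structure(
    data.frame(id = id, description = description, residues = residues,
               stringsAsFactors = FALSE),
    class = c("aa_records", "data.frame")
  )
}

empty_aa_records <- function() {
  structure(
    data.frame(id = character(), description = character(),
               residues = character(), stringsAsFactors = FALSE),
    class = c("aa_records", "data.frame")
  )
}

#' @export
print.aa_records <- function(x, ...) {
  cat(sprintf("aa_records with %d sequence(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    shown <- utils::head(x, 10L)
    prev <- ifelse(nchar(shown$residues) > 40,
                   paste0(substr(shown$residues, 1, 37), "..."),
                   shown$residues)
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  %s  [%d aa]  %s\n", shown$id[i],
                  nchar(shown$residues[i]), prev[i]))
    }
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

# Split FASTA header names into id / description at the first whitespace.
split_fasta_names <- function(nm) {
  nm <- trimws(nm)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  list(id = id, description = desc)
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; records are then
#' validated against the package's extended alphabet (illegal residues such
#' as `O` or `U` are rejected with the record id and offset). The header text
#' after the first whitespace becomes the description. Record order is
#' preserved and residues are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return An [aa_records] data frame (zero rows for an empty file).
#' @seealso [read_alignment()], [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop(sprintf("failed to parse FASTA '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (length(set) == 0L) return(empty_aa_records())
  nm <- split_fasta_names(names(set))
  if (any(!nzchar(nm$id))) {
    stop(sprintf("malformed header (empty id) in '%s' at record %d",
                 path, which(!nzchar(nm$id))[1L]), call. = FALSE)
  }
  aa_records(nm$id, as.character(set), nm$description)
}

#' Write protein records to a FASTA file
#'
#' @param records An [aa_records] data frame.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records))
  nm <- ifelse(nzchar(records$description),
               paste(records$id, records$description),
               records$id)
  set <- Biostrings::AAStringSet(setNames(records$residues, nm))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' Rows must share a common length (ragged input is rejected with the
#' offending row named) and at least two rows are required. Gaps are `-`;
#' residues may use the extended alphabet.
#'
#' @param path Path to an aligned FASTA file.
#' @return An object of class `aa_alignment`: a list with `ids` (character),
#'   `rows` (aligned residue strings), `nrow` and `ncol`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop(sprintf("failed to parse alignment '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  nm <- split_fasta_names(names(set))
  aa_alignment(nm$id, toupper(as.character(set)))
}

#' Construct a validated multiple alignment
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of aligned residue strings (gap `-`).
#' @return An `aa_alignment` object.
#' @rdname read_alignment
#' @export
aa_alignment <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(rows) < 2L) {
    stop("alignment must contain at least 2 rows", call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                 ids[bad], widths[bad], widths[1L]), call. = FALSE)
  }
  if (widths[1L] < 1L) stop("alignment has zero columns", call. = FALSE)
  allowed <- c(AA_EXTENDED, "-", "*")
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    ok <- chars %in% allowed
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf("row '%s': illegal character '%s' at column %d",
                   ids[i], chars[bad], bad), call. = FALSE)
    }
  }
  structure(list(ids = ids, rows = rows, nrow = length(rows),
                 ncol = widths[1L]),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d rows x %d columns\n", x$nrow, x$ncol))
  invisible(x)
}

# Character matrix view of an alignment (rows x columns).
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Write architecture calls to a TSV or JSON report
#'
#' One row per protein; all coordinates are 1-based inclusive (the convention
#' used for protein positions in figures), converted from the package's
#' internal 0-based half-open intervals at serialization time only.
#'
#' @param calls An `architecture_calls` list, as returned by
#'   [scan_proteome()], or a single `architecture_call`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_architecture_report <- function(calls, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- architecture_table(calls)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a TSV architecture report
#'
#' @param path Path to a TSV written by [write_architecture_report()].
#' @return A data frame with the report columns.
#' @export
read_architecture_report <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  char_cols <- c("sequence_id", "class", "cupin_reference", "motif_id",
                 "degraded_positions")
  for (col in intersect(char_cols, names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  df
}
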