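# Architecture classification. A protein is called by combining two pieces
# of evidence: a C-terminal cupin domain located by local alignment against
# reference domain sequences, and degenerate CENP-C motif hits placed
# relative to it. Classes:
#   CANONICAL_CENPC     cupin + exact CENP-C motif identity pattern ending
#                       within canonical_gap_max residues upstream of the
#                       cupin start (vertebrate CENP-C architecture)
#   PUTATIVE_FISH_CENPC cupin + >= 1 (possibly degraded) central-region core
#                       match upstream (shark/teleost candidate architecture)
#   MOTIF_ONLY          CENP-C motif evidence without a cupin domain
#                       (M18BP1-like; motif evidence only, not an ortholog
#                       identification)
#   CUPIN_ONLY          cupin domain without motif evidence
#   NONE                neither

ARCH_CLASSES <- c("CANONICAL_CENPC", "PUTATIVE_FISH_CENPC", "MOTIF_ONLY",
                  "CUPIN_ONLY", "NONE")

#' Classifier configuration
#'
#' @param canonical_gap_max Maximum residues between the end of a canonical
#'   motif hit and the cupin start for the canonical architecture
#'   (default 100, the "within about 100 amino acids" placement).
#' @param canonical_motif Fixture id of the canonical identity pattern
#'   (default `"cenpc_motif_identities"`, RxxRxxxxPLxYWxGERxxY).
#' @param fish_motif Fixture id of the fish-architecture core pattern
#'   (default `"central_region_core"`, RxxxxPxxWW).
#' @param degraded_max_mismatches Mismatch tolerance for degraded motif
#'   detection (default 2: a match may lack both tryptophans).
#' @param min_domain_length Minimum aligned columns for a cupin hit.
#' @param min_score_per_column Minimum raw score per aligned column for a
#'   cupin hit.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(canonical_gap_max = 100L,
                              canonical_motif = "cenpc_motif_identities",
                              fish_motif = "central_region_core",
                              degraded_max_mismatches = 2L,
                              min_domain_length = 40L,
                              min_score_per_column = 2) {
  if (canonical_gap_max <= 0 || degraded_max_mismatches < 0 ||
      min_domain_length <= 0 || min_score_per_column <= 0) {
    stop("classifier thresholds must be positive", call. = FALSE)
  }
  structure(list(canonical_gap_max = as.integer(canonical_gap_max),
                 canonical_motif = canonical_motif,
                 fish_motif = fish_motif,
                 degraded_max_mismatches = as.integer(degraded_max_mismatches),
                 min_domain_length = as.integer(min_domain_length),
                 min_score_per_column = min_score_per_column),
            class = "classifier_config")
}

#' Locate a cupin domain by local alignment against references
#'
#' Aligns the query against every reference with [smith_waterman()] and
#' returns the best hit passing the significance thresholds (minimum aligned
#' length and minimum score per aligned column), or `NULL`. Ties are broken
#' by higher identity fraction, then lexicographic reference id.
#'
#' @param seq Query: residue string or one-row [aa_records].
#' @param references [aa_records] of reference domain sequences (>= 1 row).
#' @param scheme A [scoring_scheme()].
#' @param min_length Minimum aligned columns (default 40).
#' @param min_score_per_column Minimum raw score per column (default 2).
#' @return A `domain_hit` (list with `reference_id`, `start`, `end` on the
#'   query, 0-based half-open, `score`, `identity_fraction`, `ncol`) or
#'   `NULL` when no alignment passes.
#' @export
locate_cupin <- function(seq, references, scheme = scoring_scheme(),
                         min_length = 40L, min_score_per_column = 2) {
  if (!is.data.frame(references) || nrow(references) < 1L) {
    stop("at least one reference sequence is required", call. = FALSE)
  }
  rec <- as_single_sequence(seq)
  best <- NULL
  for (r in seq_len(nrow(references))) {
    aln <- smith_waterman(rec$residues, references[r, ], scheme)
    if (aln$ncol < min_length) next
    if (aln$score < min_score_per_column * aln$ncol) next
    cand <- structure(list(reference_id = references$id[r],
                           start = aln$query_interval[1],
                           end = aln$query_interval[2],
                           score = aln$score,
                           identity_fraction = aln$identity_fraction,
                           ncol = aln$ncol),
                      class = "domain_hit")
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score &&
         (cand$identity_fraction > best$identity_fraction ||
          (cand$identity_fraction == best$identity_fraction &&
           cand$reference_id < best$reference_id)))) {
      best <- cand
    }
  }
  best
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("domain_hit: %s at [%d, %d), score %d, identity %.2f\n",
              x$reference_id, x$start, x$end, x$score, x$identity_fraction))
  invisible(x)
}

# Greedy left-to-right count of non-overlapping hits (hits sorted by offset).
count_nonoverlapping <- function(hits) {
  if (nrow(hits) == 0L) return(0L)
  count <- 0L
  next_free <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$offset[i] >= next_free) {
      count <- count + 1L
      next_free <- hits$offset[i] + hits$length[i]
    }
  }
  count
}

# Violated motif positions (1-based within the motif) of a hit row.
violated_positions <- function(per_position) {
  which(strsplit(per_position, "", fixed = TRUE)[[1]] == "x")
}

#' Classify a protein's CENP-C architecture
#'
#' Applies the decision rules in order: (1) cupin plus an exact canonical
#' motif hit ending within `canonical_gap_max` residues upstream of the
#' cupin start is `CANONICAL_CENPC`; (2) cupin plus at least one
#' (possibly degraded, up to `degraded_max_mismatches`) fish-core hit
#' entirely upstream of the cupin is `PUTATIVE_FISH_CENPC`, with
#' `conserved_region_count` the greedy left-to-right number of
#' non-overlapping such hits; (3) a canonical hit (same mismatch tolerance)
#' without a cupin is `MOTIF_ONLY`; (4) otherwise `CUPIN_ONLY` or `NONE`.
#'
#' @param seq Residue string or one-row [aa_records].
#' @param config A [classifier_config()].
#' @param motifs Named motif list (default [cenpc_motifs()]).
#' @param references Cupin reference [aa_records].
#' @param scheme A [scoring_scheme()].
#' @return An `architecture_call`: list with `sequence_id`, `class`,
#'   `cupin` (domain hit or `NULL`), `motif_hits` (all canonical and fish
#'   hits within the mismatch tolerance), `primary_hit` (the evidence hit,
#'   one-row data frame or `NULL`), `motif_to_cupin_gap` (residues between
#'   the primary hit end and the cupin start, or `NA`),
#'   `conserved_region_count` and `degraded` (list of degraded upstream
#'   hits with their violated motif positions).
#' @export
classify_protein <- function(seq, config = classifier_config(),
                             motifs = cenpc_motifs(),
                             references = cupin_references(),
                             scheme = scoring_scheme()) {
  stopifnot(inherits(config, "classifier_config"))
  rec <- as_single_sequence(seq)
  for (nm in c(config$canonical_motif, config$fish_motif)) {
    if (!nm %in% names(motifs)) {
      stop(sprintf("motif '%s' not found in motif set", nm), call. = FALSE)
    }
  }
  cupin <- locate_cupin(rec$residues, references, scheme,
                        min_length = config$min_domain_length,
                        min_score_per_column = config$min_score_per_column)
  named_seq <- setNames(rec$residues, rec$id)
  canonical <- scan_motif(motifs[[config$canonical_motif]], named_seq,
                          config$degraded_max_mismatches)
  fish <- scan_motif(motifs[[config$fish_motif]], named_seq,
                     config$degraded_max_mismatches)
  all_hits <- rbind(canonical, fish)
  all_hits <- all_hits[order(all_hits$offset, all_hits$motif_id), ,
                       drop = FALSE]
  rownames(all_hits) <- NULL

  cls <- "NONE"
  primary <- NULL
  gap <- NA_integer_
  region_count <- 0L
  degraded <- list()

  upstream_fish <- if (!is.null(cupin)) {
    fish[fish$offset + fish$length <= cupin$start, , drop = FALSE]
  } else {
    fish[0, , drop = FALSE]
  }

  if (!is.null(cupin)) {
    exact <- canonical[canonical$mismatches == 0L, , drop = FALSE]
    gaps <- cupin$start - (exact$offset + exact$length)
    qualifying <- which(gaps >= 0L & gaps <= config$canonical_gap_max)
    if (length(qualifying) > 0L) {
      cls <- "CANONICAL_CENPC"
      pick <- qualifying[which.min(gaps[qualifying])]
      primary <- exact[pick, , drop = FALSE]
      gap <- as.integer(gaps[pick])
    } else if (nrow(upstream_fish) > 0L) {
      cls <- "PUTATIVE_FISH_CENPC"
      region_count <- count_nonoverlapping(upstream_fish)
      # distance is anchored on exact hits when any exist; degraded hits
      # support the class but are a fallback anchor only
      anchor <- upstream_fish[upstream_fish$mismatches == 0L, , drop = FALSE]
      if (nrow(anchor) == 0L) anchor <- upstream_fish
      pick <- which.max(anchor$offset + anchor$length)
      primary <- anchor[pick, , drop = FALSE]
      gap <- as.integer(cupin$start -
                          (primary$offset + primary$length))
    } else {
      cls <- "CUPIN_ONLY"
    }
  } else if (nrow(canonical) > 0L) {
    cls <- "MOTIF_ONLY"
    ord <- order(canonical$mismatches, canonical$offset)
    primary <- canonical[ord[1L], , drop = FALSE]
  }

  if (!is.null(cupin)) {
    deg <- upstream_fish[upstream_fish$mismatches > 0L, , drop = FALSE]
  } else {
    deg <- canonical[canonical$mismatches > 0L, , drop = FALSE]
  }
  if (nrow(deg) > 0L) {
    degraded <- lapply(seq_len(nrow(deg)), function(i) {
      list(motif_id = deg$motif_id[i], offset = deg$offset[i],
           violated = violated_positions(deg$per_position[i]))
    })
  }

  structure(list(sequence_id = rec$id, class = cls, cupin = cupin,
                 motif_hits = all_hits, primary_hit = primary,
                 motif_to_cupin_gap = gap,
                 conserved_region_count = region_count,
                 degraded = degraded),
            class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(sprintf("architecture_call: %s -> %s\n", x$sequence_id, x$class))
  if (!is.null(x$cupin)) {
    cat(sprintf("  cupin: %s [%d, %d) score %d identity %.2f\n",
                x$cupin$reference_id, x$cupin$start, x$cupin$end,
                x$cupin$score, x$cupin$identity_fraction))
  }
  if (!is.null(x$primary_hit)) {
    cat(sprintf("  primary motif hit: %s at offset %d (%d mismatches)\n",
                x$primary_hit$motif_id, x$primary_hit$offset,
                x$primary_hit$mismatches))
  }
  if (!is.na(x$motif_to_cupin_gap)) {
    cat(sprintf("  motif-to-cupin gap: %d residues\n", x$motif_to_cupin_gap))
  }
  if (x$conserved_region_count > 0L) {
    cat(sprintf("  conserved regions (non-overlapping): %d\n",
                x$conserved_region_count))
  }
  if (length(x$degraded) > 0L) {
    cat(sprintf("  degraded hits: %d\n", length(x$degraded)))
  }
  invisible(x)
}

#' Validate the internal consistency of an architecture call
#'
#' Checks that the class label is consistent with the recorded evidence
#' (cupin presence, qualifying hits, non-negative gap). Used as a standing
#' invariant over classifier output.
#'
#' @param call An `architecture_call`.
#' @param config The [classifier_config()] used to produce it.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_call <- function(call, config = classifier_config()) {
  stopifnot(inherits(call, "architecture_call"))
  fail <- function(msg) {
    stop(sprintf("inconsistent call for '%s' (%s): %s",
                 call$sequence_id, call$class, msg), call. = FALSE)
  }
  if (!call$class %in% ARCH_CLASSES) fail("unknown class")
  has_cupin <- !is.null(call$cupin)
  if (!is.na(call$motif_to_cupin_gap) && call$motif_to_cupin_gap < 0L) {
    fail("negative motif-to-cupin gap")
  }
  canonical_exact_near <- function() {
    hits <- call$motif_hits
    hits <- hits[hits$motif_id == config$canonical_motif &
                   hits$mismatches == 0L, , drop = FALSE]
    if (!has_cupin || nrow(hits) == 0L) return(FALSE)
    gaps <- call$cupin$start - (hits$offset + hits$length)
    any(gaps >= 0L & gaps <= config$canonical_gap_max)
  }
  upstream_fish_n <- function() {
    hits <- call$motif_hits
    hits <- hits[hits$motif_id == config$fish_motif, , drop = FALSE]
    if (!has_cupin) return(0L)
    sum(hits$offset + hits$length <= call$cupin$start)
  }
  switch(call$class,
    CANONICAL_CENPC = {
      if (!has_cupin) fail("canonical call without cupin")
      if (!canonical_exact_near()) fail("no qualifying canonical hit")
      if (is.na(call$motif_to_cupin_gap)) fail("missing gap")
    },
    PUTATIVE_FISH_CENPC = {
      if (!has_cupin) fail("fish call without cupin")
      if (canonical_exact_near()) fail("canonical rule should have fired")
      if (call$conserved_region_count < 1L) fail("no conserved regions")
      if (upstream_fish_n() < 1L) fail("no upstream fish-core hit")
    },
    MOTIF_ONLY = {
      if (has_cupin) fail("motif-only call with cupin")
      hits <- call$motif_hits
      if (!any(hits$motif_id == config$canonical_motif &
                 hits$mismatches <= config$degraded_max_mismatches)) {
        fail("no canonical hit within tolerance")
      }
    },
    CUPIN_ONLY = {
      if (!has_cupin) fail("cupin-only call without cupin")
      if (canonical_exact_near()) fail("canonical rule should have fired")
      if (upstream_fish_n() > 0L) fail("fish rule should have fired")
    },
    NONE = {
      if (has_cupin) fail("NONE with cupin present")
      hits <- call$motif_hits
      if (any(hits$motif_id == config$canonical_motif)) {
        fail("NONE with canonical hit present")
      }
    }
  )
  invisible(TRUE)
}

#' Ratio of motif-to-cupin spacings between two proteins
#'
#' Uses the cupin-proximal motif hit of each call (the hit ending closest to,
#' and entirely before, the cupin start), preferring exact hits over
#' degraded ones so that chance low-identity matches do not shrink the
#' measured distance. The teleost fish candidate architecture shows roughly
#' twice the spacing of canonical vertebrate CENP-C.
#'
#' @param call_a,call_b `architecture_call`s, both with a cupin domain and
#'   at least one motif hit upstream of it; `call_b`'s gap must be positive.
#' @return `gap(call_a) / gap(call_b)` as a double.
#' @export
spacing_ratio <- function(call_a, call_b) {
  gap_of <- function(call, which) {
    if (is.null(call$cupin)) {
      stop(sprintf("call %s has no cupin domain", which), call. = FALSE)
    }
    hits <- call$motif_hits
    hits <- hits[hits$offset + hits$length <= call$cupin$start, ,
                 drop = FALSE]
    if (nrow(hits) == 0L) {
      stop(sprintf("call %s has no motif hit upstream of the cupin", which),
           call. = FALSE)
    }
    exact <- hits[hits$mismatches == 0L, , drop = FALSE]
    if (nrow(exact) > 0L) hits <- exact
    call$cupin$start - max(hits$offset + hits$length)
  }
  ga <- gap_of(call_a, "a")
  gb <- gap_of(call_b, "b")
  if (gb <= 0) stop("denominator gap must be positive", call. = FALSE)
  ga / gb
}

#' Classify every protein in a FASTA file or record set
#'
#' @param x Path to a FASTA file, or an [aa_records] data frame.
#' @param config A [classifier_config()].
#' @param motifs Named motif list.
#' @param references Cupin reference [aa_records].
#' @param scheme A [scoring_scheme()].
#' @param verbose Emit per-class counts via [message()].
#' @return A list of `architecture_call`s (class `architecture_calls`), in
#'   input order.
#' @export
scan_proteome <- function(x, config = classifier_config(),
                          motifs = cenpc_motifs(),
                          references = cupin_references(),
                          scheme = scoring_scheme(), verbose = TRUE) {
  records <- if (is.character(x)) read_fasta(x) else x
  stopifnot(is.data.frame(records))
  calls <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      classify_protein(records[i, ], config, motifs, references, scheme),
      error = function(e) {
        stop(sprintf("record '%s': %s", records$id[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
  calls <- structure(calls, class = "architecture_calls", config = config)
  if (verbose) {
    counts <- table(factor(vapply(calls, `[[`, character(1), "class"),
                           levels = ARCH_CLASSES))
    message("class counts: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = " "))
  }
  calls
}

#' @export
print.architecture_calls <- function(x, ...) {
  counts <- table(factor(vapply(x, `[[`, character(1), "class"),
                         levels = ARCH_CLASSES))
  cat(sprintf("architecture_calls: %d protein(s)\n", length(x)))
  for (nm in names(counts)) cat(sprintf("  %-20s %d\n", nm, counts[[nm]]))
  invisible(x)
}

#' @export
summary.architecture_calls <- function(object, ...) {
  architecture_table(object)
}

#' Flatten architecture calls to a report table
#'
#' One row per protein; coordinates 1-based inclusive. Degraded hits are
#' serialized as `offset1:pos,pos;offset1:pos` (1-based hit starts and
#' violated motif positions).
#'
#' @param calls An `architecture_calls` list or a single call.
#' @return A data frame.
#' @export
architecture_table <- function(calls) {
  if (inherits(calls, "architecture_call")) calls <- list(calls)
  if (length(calls) == 0L) {
    return(data.frame(
      sequence_id = character(), class = character(),
      cupin_reference = character(), cupin_start = integer(),
      cupin_end = integer(), cupin_score = integer(),
      cupin_identity = numeric(), motif_hit_count = integer(),
      conserved_region_count = integer(), motif_to_cupin_gap = integer(),
      motif_id = character(), motif_start = integer(),
      motif_end = integer(), motif_mismatches = integer(),
      degraded_positions = character(), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(calls, function(call) {
    cupin <- call$cupin
    primary <- call$primary_hit
    deg <- if (length(call$degraded) == 0L) "" else {
      paste(vapply(call$degraded, function(d) {
        sprintf("%d:%s", d$offset + 1L, paste(d$violated, collapse = ","))
      }, character(1)), collapse = ";")
    }
    data.frame(
      sequence_id = call$sequence_id,
      class = call$class,
      cupin_reference = if (is.null(cupin)) NA_character_ else cupin$reference_id,
      cupin_start = if (is.null(cupin)) NA_integer_ else
        to_report_coords(cupin$start, cupin$end)$start,
      cupin_end = if (is.null(cupin)) NA_integer_ else
        to_report_coords(cupin$start, cupin$end)$end,
      cupin_score = if (is.null(cupin)) NA_integer_ else cupin$score,
      cupin_identity = if (is.null(cupin)) NA_real_ else
        round(cupin$identity_fraction, 4),
      motif_hit_count = nrow(call$motif_hits),
      conserved_region_count = call$conserved_region_count,
      motif_to_cupin_gap = call$motif_to_cupin_gap,
      motif_id = if (is.null(primary)) NA_character_ else primary$motif_id,
      motif_start = if (is.null(primary)) NA_integer_ else
        primary$offset + 1L,
      motif_end = if (is.null(primary)) NA_integer_ else
        primary$offset + primary$length,
      motif_mismatches = if (is.null(primary)) NA_integer_ else
        primary$mismatches,
      degraded_positions = deg,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
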