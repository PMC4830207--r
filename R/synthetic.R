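# Seeded synthetic proteomes with planted cupin copies and motif instances
# against i.i.d. background, plus machine-readable truth tables. The planted
# architectures mirror the three observed CENP-C-related layouts (canonical
# vertebrate, putative fish-type, M18BP1-like motif-only) plus unrelated
# background proteins.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Background amino-acid frequency presets
#'
#' `"uniform"` assigns 1/20 to every residue (unrealistic but analytically
#' convenient: closed-form motif hit probabilities are exact products).
#' `"swissprot"` is a Swiss-Prot-like composition for more realistic
#' backgrounds.
#'
#' @param preset `"uniform"` or `"swissprot"`.
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
aa_frequencies <- function(preset = c("uniform", "swissprot")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    return(setNames(rep(1 / 20, 20), AA20))
  }
  pct <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.08,
           H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
           P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
           W = 1.10, Y = 2.92)
  pct <- pct[AA20]
  pct / sum(pct)
}

#' Bundled synthetic cupin reference sequences
#'
#' Two fixed 110-residue synthetic stand-ins for cupin-domain reference
#' sequences (random sequences generated once under a fixed seed, shipped as
#' `inst/extdata/synthetic_cupin_refs.fasta`). They exercise domain
#' localization exactly like real references would, but carry no biological
#' signal; substitute real cupin-domain FASTA for production screens.
#'
#' @return An [aa_records] data frame.
#' @export
cupin_references <- function() {
  read_fasta(system.file("extdata", "synthetic_cupin_refs.fasta",
                         package = "cenpcscan", mustWork = TRUE))
}

# Sample one residue from a frequency table.
sample_background <- function(n, background) {
  sample(names(background), n, replace = TRUE, prob = background)
}

#' Realize a degenerate motif as a concrete residue string
#'
#' Constrained positions sample uniformly within the position's residue set;
#' wildcard positions sample from the background distribution.
#'
#' @param motif A `degenerate_motif`.
#' @param background Residue frequency table for wildcard positions.
#' @return A residue string of the motif's length.
#' @export
sample_motif_instance <- function(motif, background = aa_frequencies()) {
  stopifnot(inherits(motif, "degenerate_motif"))
  chars <- vapply(motif$sets, function(s) {
    if (length(s) == 20L) {
      sample_background(1L, background)
    } else {
      s[sample.int(length(s), 1L)]
    }
  }, character(1))
  paste(chars, collapse = "")
}

# Substitute `count` positions (or the given 1-based sites) of a residue
# string, always changing the residue. Returns list(residues, positions).
apply_substitutions <- function(residues, count, background,
                                sites = NULL) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (count == 0L) return(list(residues = residues, positions = integer(0)))
  pos <- if (is.null(sites)) {
    sample.int(length(chars), count)
  } else {
    if (count > length(sites)) {
      stop("more substitutions than available sites", call. = FALSE)
    }
    if (count == length(sites)) sites else sample(sites, count)
  }
  for (p in pos) {
    repeat {
      new <- sample_background(1L, background)
      if (new != chars[p]) break
    }
    chars[p] <- new
  }
  list(residues = paste(chars, collapse = ""), positions = sort(pos))
}

default_class_mixture <- function() {
  c(CANONICAL_CENPC = 0.25, PUTATIVE_FISH_CENPC = 0.25,
    MOTIF_ONLY = 0.25, NONE = 0.25)
}

#' Generate a synthetic proteome with planted architectures
#'
#' Produces `n` proteins with i.i.d. background residues and, per assigned
#' class, planted elements: `CANONICAL_CENPC` proteins carry a realized
#' canonical identity-pattern instance ending 40-80 residues upstream of a
#' planted cupin reference copy; `PUTATIVE_FISH_CENPC` proteins carry a
#' cupin copy plus two central-region core instances upstream (a
#' cupin-proximal one at gap 80-160 - about twice the canonical spacing -
#' and a distal one at gap 220-320); `MOTIF_ONLY` proteins carry a canonical
#' instance and no cupin; `NONE` proteins are pure background. Planted
#' intervals never overlap. All randomness flows from `seed`, and the output
#' is byte-identical across runs for a fixed seed.
#'
#' @param n Number of proteins.
#' @param length_range Integer vector `c(min, max)` of protein lengths;
#'   must accommodate the largest planted span (default 500-800).
#' @param background Residue frequency table (default uniform).
#' @param class_mixture Named fractions over the planted classes, summing
#'   to 1.
#' @param references Cupin reference [aa_records]; copies of the first rows
#'   are planted.
#' @param motifs Named motif list (default [cenpc_motifs()]).
#' @param cupin_substitution_rate Per-residue substitution probability
#'   applied to planted cupin copies (substitutions always change the
#'   residue).
#' @param fish_motif_substitutions Substitutions applied to every planted
#'   central-region core instance (default 0).
#' @param fish_motif_substitution_sites Optional 1-based motif positions the
#'   fish-motif substitutions are confined to (e.g. `c(9, 10)`, the two
#'   tryptophans of RxxxxPxxWW).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `synthetic_proteome`: `records` ([aa_records])
#'   and `truth` (data frame with columns `protein_id`, `class`, `element`,
#'   `source_id`, `start`, `end` (1-based inclusive), `substitutions`,
#'   `substituted_sites`).
#' @export
generate_proteome <- function(n,
                              length_range = c(500L, 800L),
                              background = aa_frequencies(),
                              class_mixture = default_class_mixture(),
                              references = cupin_references(),
                              motifs = cenpc_motifs(),
                              cupin_substitution_rate = 0,
                              fish_motif_substitutions = 0L,
                              fish_motif_substitution_sites = NULL,
                              seed = NULL) {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2])
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class mixture fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(class_mixture) %in% ARCH_CLASSES)) {
    stop("unknown class in mixture", call. = FALSE)
  }
  if (cupin_substitution_rate < 0 || cupin_substitution_rate >= 1) {
    stop("'cupin_substitution_rate' must be in [0, 1)", call. = FALSE)
  }
  canonical <- motifs[["cenpc_motif_identities"]]
  fish <- motifs[["central_region_core"]]
  ref_len <- max(nchar(references$residues))
  # largest span: distal fish gap (320) + motif + cupin + C-terminal tail
  min_needed <- 320L + length(fish) + ref_len + 30L
  if (length_range[1] < min_needed) {
    stop(sprintf(
      "infeasible plants: minimum length %d is below the largest planted span (%d)",
      length_range[1], min_needed), call. = FALSE)
  }

  with_seed(seed, {
    classes <- sample(names(class_mixture), n, replace = TRUE,
                      prob = class_mixture)
    records <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("synthetic_%04d", i)
      L <- length_range[1] + sample.int(length_range[2] - length_range[1] + 1L,
                                        1L) - 1L
      chars <- sample_background(L, background)
      cls <- classes[i]
      rows <- list()
      plant <- function(start0, residues, element, source_id, nsub, sites) {
        piece <- strsplit(residues, "", fixed = TRUE)[[1]]
        chars[(start0 + 1L):(start0 + length(piece))] <<- piece
        rows[[length(rows) + 1L]] <<- data.frame(
          protein_id = id, class = cls, element = element,
          source_id = source_id, start = start0 + 1L,
          end = start0 + length(piece), substitutions = nsub,
          substituted_sites = paste(sites, collapse = ","),
          stringsAsFactors = FALSE)
      }
      plant_cupin <- function() {
        r <- sample.int(nrow(references), 1L)
        ref <- references[r, ]
        rl <- nchar(ref$residues)
        tail_len <- sample(5:30, 1L)
        start0 <- L - tail_len - rl
        nsub <- rbinom(1L, rl, cupin_substitution_rate)
        sub <- apply_substitutions(ref$residues, nsub, background)
        plant(start0, sub$residues, "cupin_copy", ref$id, nsub,
              sub$positions)
        start0
      }
      plant_motif <- function(motif, end0, element = "motif_instance",
                              nsub = 0L, sites = NULL) {
        inst <- sample_motif_instance(motif, background)
        sub <- apply_substitutions(inst, nsub, background, sites)
        start0 <- end0 - length(motif)
        plant(start0, sub$residues, element, motif$id, nsub, sub$positions)
      }
      if (cls == "CANONICAL_CENPC") {
        cupin_start <- plant_cupin()
        gap <- sample(40:80, 1L)
        plant_motif(canonical, cupin_start - gap)
      } else if (cls == "PUTATIVE_FISH_CENPC") {
        cupin_start <- plant_cupin()
        gap_proximal <- sample(80:160, 1L)
        gap_distal <- sample(220:320, 1L)
        nsub <- as.integer(fish_motif_substitutions)
        plant_motif(fish, cupin_start - gap_proximal, nsub = nsub,
                    sites = fish_motif_substitution_sites)
        plant_motif(fish, cupin_start - gap_distal, nsub = nsub,
                    sites = fish_motif_substitution_sites)
      } else if (cls == "MOTIF_ONLY") {
        start0 <- sample(0:(L - length(canonical)), 1L)
        plant_motif(canonical, start0 + length(canonical))
      } else if (cls == "CUPIN_ONLY") {
        plant_cupin()
      } else {
        rows[[1L]] <- data.frame(
          protein_id = id, class = cls, element = "none",
          source_id = NA_character_, start = NA_integer_,
          end = NA_integer_, substitutions = 0L, substituted_sites = "",
          stringsAsFactors = FALSE)
      }
      records[[i]] <- data.frame(
        id = id, description = sprintf("synthetic %s", cls),
        residues = paste(chars, collapse = ""), stringsAsFactors = FALSE)
      truth[[i]] <- do.call(rbind, rows)
    }
    records <- do.call(rbind, records)
    records <- aa_records(records$id, records$residues, records$description)
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    structure(list(records = records, truth = truth),
              class = "synthetic_proteome")
  })
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  counts <- table(unique(x$truth[, c("protein_id", "class")])$class)
  cat(sprintf("synthetic_proteome: %d protein(s)\n", nrow(x$records)))
  for (nm in names(counts)) cat(sprintf("  %-20s %d\n", nm, counts[[nm]]))
  invisible(x)
}

#' Intended class per synthetic protein
#'
#' @param proteome A `synthetic_proteome` (or its `truth` data frame).
#' @return Data frame with `protein_id` and `class`, in generation order.
#' @export
truth_classes <- function(proteome) {
  truth <- if (inherits(proteome, "synthetic_proteome")) proteome$truth
           else proteome
  unique(truth[, c("protein_id", "class")])
}

#' Write a synthetic truth table
#'
#' @param proteome A `synthetic_proteome`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(proteome, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  truth <- proteome$truth
  if (format == "tsv") {
    write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Motif false-positive rate on random background
#'
#' Monte-Carlo fraction of random sequences of the stated length containing
#' at least one exact (zero-mismatch) motif hit, together with the analytic
#' per-window match probability `prod(sum(background[set_i]))` (which
#' reduces to `prod(|set_i| / 20)` under the uniform background) and the
#' per-sequence bound `1 - (1 - p)^windows` assuming independent windows.
#'
#' @param motif A `degenerate_motif`.
#' @param length Sequence length per trial.
#' @param trials Number of Monte-Carlo sequences (>= 1).
#' @param background Residue frequency table.
#' @param seed Integer seed.
#' @return A list of class `fp_estimate`: `mc_rate`, `se` (binomial standard
#'   error), `per_window_prob`, `seq_prob`, `n_windows`, `trials`.
#' @export
estimate_false_positive_rate <- function(motif, length = 200L,
                                         trials = 1000L,
                                         background = aa_frequencies(),
                                         seed = NULL) {
  stopifnot(inherits(motif, "degenerate_motif"), trials >= 1L,
            length >= 1L)
  m <- length(motif$sets)
  per_window <- prod(vapply(motif$sets, function(s) sum(background[s]),
                            numeric(1)))
  n_windows <- max(0L, length - m + 1L)
  seq_prob <- if (n_windows == 0L) 0 else 1 - (1 - per_window)^n_windows
  tab <- motif_match_table(motif)
  constrained <- constrained_positions(motif)
  hits <- with_seed(seed, {
    vapply(seq_len(trials), function(t) {
      codes <- match(sample_background(length, background), AA_EXTENDED)
      mism <- window_mismatches(codes, tab, constrained)
      any(mism == 0L)
    }, logical(1))
  })
  mc <- mean(hits)
  structure(list(mc_rate = mc,
                 se = sqrt(mc * (1 - mc) / trials),
                 per_window_prob = per_window,
                 seq_prob = seq_prob,
                 n_windows = n_windows,
                 trials = trials),
            class = "fp_estimate")
}

#' @export
print.fp_estimate <- function(x, ...) {
  cat(sprintf(
    "fp_estimate: MC rate %.3g (SE %.2g, %d trials), per-window %.3g, per-sequence %.3g over %d windows\n",
    x$mc_rate, x$se, x$trials, x$per_window_prob, x$seq_prob, x$n_windows))
  invisible(x)
}
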