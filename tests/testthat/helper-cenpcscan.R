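# Shared fixtures and independent oracles for the test suite.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

expand_residue <- function(ch) {
  switch(ch,
         B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
         X = AA20_T, ch)
}

random_protein <- function(len) {
  paste(sample(AA20_T, len, replace = TRUE), collapse = "")
}

random_pattern <- function(len, wildcard_prob = 0.5) {
  chars <- vapply(seq_len(len), function(i) {
    if (runif(1) < wildcard_prob) "x"
    else sample(c(AA20_T, "B", "Z", "J"), 1L)
  }, character(1))
  # guarantee at least one constrained position
  if (all(chars == "x")) chars[1] <- sample(AA20_T, 1L)
  paste(chars, collapse = "")
}

# Brute-force motif scan: checks every window position by position with
# explicit residue-set intersection; independent of the package's scanner.
naive_scan <- function(pattern, residues, max_mismatches = 0L) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  pat[pat == "x"] <- "X"
  seqc <- strsplit(residues, "", fixed = TRUE)[[1]]
  m <- length(pat)
  n <- length(seqc)
  out <- list()
  if (n >= m) {
    for (w in seq_len(n - m + 1L)) {
      mism <- 0L
      for (p in seq_len(m)) {
        pset <- expand_residue(pat[p])
        if (length(pset) == 20L) next
        sset <- expand_residue(seqc[w + p - 1L])
        if (!any(sset %in% pset)) mism <- mism + 1L
      }
      if (mism <= max_mismatches) {
        out[[length(out) + 1L]] <- c(offset = w - 1L, mismatches = mism)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(), mismatches = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Independent local-alignment oracle: best global affine-gap score over all
# substring pairs (Gotoh global, different structure from the package's
# clamped local DP with traceback), clamped at zero.
global_affine_score <- function(x, y, mat, open, ext) {
  nx <- nchar(x); ny <- nchar(y)
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  ys <- strsplit(y, "", fixed = TRUE)[[1]]
  NEG <- -1e9
  M <- matrix(NEG, nx + 1, ny + 1)
  Ix <- matrix(NEG, nx + 1, ny + 1)  # gap in y (consume x)
  Iy <- matrix(NEG, nx + 1, ny + 1)  # gap in x (consume y)
  M[1, 1] <- 0
  for (i in seq_len(nx)) Ix[i + 1, 1] <- -open - ext * i
  for (j in seq_len(ny)) Iy[1, j + 1] <- -open - ext * j
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      s <- mat[xs[i], ys[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[nx + 1, ny + 1], Ix[nx + 1, ny + 1], Iy[nx + 1, ny + 1])
}

local_score_oracle <- function(a, b, scheme) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    x <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      y <- substr(b, j1, j2)
      sc <- global_affine_score(x, y, scheme$matrix,
                                scheme$gap_open, scheme$gap_extend)
      if (sc > best) best <- sc
    }
  }
  best
}

write_temp_fasta <- function(ids, residues, descriptions = NULL) {
  path <- tempfile(fileext = ".fasta")
  headers <- if (is.null(descriptions)) paste0(">", ids)
             else paste0(">", ids, " ", descriptions)
  writeLines(as.vector(rbind(headers, residues)), path)
  path
}

# Build a test protein on a low-complexity background ('A' everywhere) so
# motif/domain placements are fully controlled.
build_protein <- function(length, plants) {
  chars <- rep("A", length)
  for (p in plants) {
    piece <- strsplit(p$residues, "", fixed = TRUE)[[1]]
    chars[(p$start0 + 1):(p$start0 + length(piece))] <- piece
  }
  paste(chars, collapse = "")
}
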