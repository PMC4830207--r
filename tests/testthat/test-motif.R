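test_that("pattern parsing expands wildcards and ambiguity codes", {
  m <- parse_pattern("RxxxxPxxWW")
  expect_equal(length(m), 10L)
  expect_equal(cenpcscan:::constrained_positions(m), c(1L, 6L, 9L, 10L))
  expect_equal(m$sets[[1]], "R")
  expect_equal(lengths(m$sets)[2:5], rep(20L, 4), ignore_attr = TRUE)

  v <- parse_pattern("NVRRTKRXRLKPLEYWRGERVBY")
  expect_equal(length(v), 23L)
  expect_equal(lengths(v$sets)[8], 20L, ignore_attr = TRUE)
  expect_setequal(v$sets[[22]], c("D", "N"))

  expect_error(parse_pattern(""), "non-empty")
  expect_error(parse_pattern("RK7W"), "'7' at position 3")
})

test_that("pattern rendering round-trips", {
  for (pat in c("RxxxxPxxYW", "RxSxxPSxWW", "NVRRTKRXRLKPLEYWRGERVBY",
                "BZJx", "W")) {
    m <- parse_pattern(pat)
    rendered <- render_pattern(m)
    m2 <- parse_pattern(rendered)
    expect_equal(m2$sets, m$sets, info = pat)
  }
  # uppercase X normalizes to the wildcard rendering
  expect_equal(render_pattern(parse_pattern("RXW")), "RxW")
})

test_that("scanning the vertebrate motif string reproduces the known offsets", {
  target <- setNames("NVRRTKRXRLKPLEYWRGERVBY", "vmotif")
  core <- scan_motif(parse_pattern("RxxxxPxxYW"), target, 0)
  expect_equal(nrow(core), 1L)
  expect_equal(core$offset, 6L)

  ident <- scan_motif(parse_pattern("RxxRxxxxPLxYWxGERxxY"), target, 0)
  expect_equal(nrow(ident), 1L)
  expect_equal(ident$offset, 3L)

  central <- scan_motif(parse_pattern("RxxxxPxxWW"), "RXSXXPSXWW", 0)
  expect_equal(central$offset, 0L)

  # brute-force oracle confirms all three placements
  expect_equal(naive_scan("RxxxxPxxYW", "NVRRTKRXRLKPLEYWRGERVBY")$offset, 6L)
  expect_equal(naive_scan("RxxRxxxxPLxYWxGERxxY",
                          "NVRRTKRXRLKPLEYWRGERVBY")$offset, 3L)
  expect_equal(naive_scan("RxxxxPxxWW", "RXSXXPSXWW")$offset, 0L)
})

test_that("sequences shorter than the motif yield no hits", {
  m <- parse_pattern("RxxxxPxxWW")
  hits <- scan_motif(m, "RKPAW", 0)
  expect_equal(nrow(hits), 0L)
})

test_that("per-position records are consistent with mismatch counts", {
  m <- parse_pattern("RxxxxPxxWW")
  hits <- scan_motif(m, "RAAAAPAAWARAAAAAAAWW", 2)
  expect_gt(nrow(hits), 0L)
  for (i in seq_len(nrow(hits))) {
    marks <- strsplit(hits$per_position[i], "", fixed = TRUE)[[1]]
    expect_equal(sum(marks == "x"), hits$mismatches[i])
    expect_equal(which(marks == "."), c(2:5, 7:8))
  }
})

test_that("scanner equals the brute-force oracle on random cases", {
  set.seed(101)
  for (case in 1:400) {
    len <- sample(5:200, 1)
    plen <- sample(2:12, 1)
    pat <- random_pattern(plen)
    seqres <- random_protein(len)
    k <- sample(0:2, 1)
    mine <- scan_motif(parse_pattern(pat), seqres, k)
    oracle <- naive_scan(pat, seqres, k)
    expect_equal(mine$offset, oracle$offset,
                 info = sprintf("case %d pat=%s k=%d", case, pat, k))
    expect_equal(mine$mismatches, oracle$mismatches,
                 info = sprintf("case %d pat=%s k=%d", case, pat, k))
  }
})

test_that("ambiguity codes in the sequence match by set intersection", {
  m <- parse_pattern("RB")
  # sequence B = {D,N} intersects motif {D,N}; X matches everything
  expect_equal(nrow(scan_motif(m, "RB", 0)), 1L)
  expect_equal(nrow(scan_motif(m, "RD", 0)), 1L)
  expect_equal(nrow(scan_motif(m, "RE", 0)), 0L)
  expect_equal(nrow(scan_motif(m, "XX", 0)), 1L)
  expect_equal(nrow(scan_motif(parse_pattern("RZ"), "RB", 0)), 0L)
  expect_equal(nrow(scan_motif(parse_pattern("RJ"), "RL", 0)), 1L)
})

test_that("hits are monotone in the mismatch tolerance", {
  set.seed(202)
  for (case in 1:50) {
    pat <- random_pattern(sample(4:10, 1), wildcard_prob = 0.3)
    seqres <- random_protein(sample(30:120, 1))
    m <- parse_pattern(pat)
    prev <- scan_motif(m, seqres, 0)$offset
    for (k in 1:3) {
      cur <- scan_motif(m, seqres, k)$offset
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("consensus of identical rows is the row itself", {
  aln <- aa_alignment(c("a", "b", "c"), rep("RKPW", 3))
  m <- derive_consensus(aln)
  expect_equal(render_pattern(m), "RKPW")
  expect_equal(m$source, "derived")

  set.seed(7)
  s <- random_protein(25)
  aln2 <- aa_alignment(paste0("r", 1:6), rep(s, 6))
  expect_equal(render_pattern(derive_consensus(aln2)), s)
})

test_that("consensus collapses ambiguity classes and mixed sets", {
  expect_equal(render_pattern(derive_consensus(
    aa_alignment(c("a", "b"), c("RDPW", "RNPW")))), "RBPW")
  expect_equal(render_pattern(derive_consensus(
    aa_alignment(c("a", "b"), c("RAPW", "RRPW")))), "RxPW")
  expect_equal(render_pattern(derive_consensus(
    aa_alignment(c("a", "b"), c("REPW", "RQPW")))), "RZPW")
  # ambiguity codes disabled -> wildcard instead of B
  expect_equal(render_pattern(derive_consensus(
    aa_alignment(c("a", "b"), c("RDPW", "RNPW")),
    consensus_policy(allow_ambiguity_codes = FALSE))), "RxPW")
})

test_that("gapped columns are dropped under the default policy", {
  aln <- aa_alignment(c("a", "b"), c("R-PW", "RKPW"))
  expect_equal(render_pattern(derive_consensus(aln)), "RPW")
  aln_all_gap <- aa_alignment(c("a", "b"), c("--", "--"))
  expect_error(derive_consensus(aln_all_gap), "no consensus columns")
  # permissive gap policy keeps the column
  m <- derive_consensus(aln, consensus_policy(max_gap_fraction = 0.5))
  expect_equal(render_pattern(m), "RKPW")
})

test_that("min_fraction below 1 admits sub-modal residues", {
  aln <- aa_alignment(paste0("r", 1:4), c("RD", "RD", "RD", "RN"))
  # strict: D is the sole mode
  expect_equal(render_pattern(derive_consensus(aln)), "RD")
  # N at 1/3 of the modal frequency is admitted -> {D,N} -> B
  m <- derive_consensus(aln, consensus_policy(min_fraction = 1 / 3))
  expect_equal(render_pattern(m), "RB")
})

test_that("a permissive consensus over sampled motif instances scans its own rows", {
  set.seed(31)
  motifs <- cenpc_motifs()
  rows <- vapply(1:25, function(i) {
    sample_motif_instance(motifs$cenpc_motif_vertebrate)
  }, character(1))
  aln <- aa_alignment(paste0("sp", 1:25), rows)
  # admit every observed residue so the consensus covers all source rows
  cons <- derive_consensus(aln, consensus_policy(min_fraction = 0.01))
  for (r in rows) {
    expect_gte(nrow(scan_motif(cons, r, 0)), 1L)
  }
  # identity columns of the source motif stay literal in the consensus
  lit <- which(lengths(motifs$cenpc_motif_vertebrate$sets) == 1L)
  expect_equal(cons$sets[lit], motifs$cenpc_motif_vertebrate$sets[lit])
})

test_that("conservation profile frequencies are normalized per column", {
  aln <- aa_alignment(c("a", "b"), c("RD-", "RN-"))
  prof <- conservation_profile(aln)
  expect_equal(length(prof), 3L)
  expect_equal(prof[[1]]$frequencies, c(R = 1.0))
  expect_equal(sort(names(prof[[2]]$frequencies)), c("D", "N"))
  expect_equal(unname(prof[[2]]$frequencies), c(0.5, 0.5))
  expect_equal(prof[[3]]$gap_fraction, 1.0)
  expect_equal(length(prof[[3]]$frequencies), 0L)
})

test_that("bundled motif fixtures parse to the expected shapes", {
  motifs <- cenpc_motifs()
  expect_setequal(names(motifs),
                  c("cenpc_motif_vertebrate", "cenpc_motif_identities",
                    "cenpc_motif_core", "central_region_consensus",
                    "central_region_core"))
  expect_equal(length(motifs$cenpc_motif_vertebrate), 23L)
  expect_equal(render_pattern(motifs$central_region_core), "RxxxxPxxWW")
  # the central-region consensus satisfies its own core pattern at offset 0
  hit <- scan_motif(motifs$central_region_core,
                    toupper(render_pattern(motifs$central_region_consensus)),
                    0)
  expect_equal(hit$offset, 0L)
})
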