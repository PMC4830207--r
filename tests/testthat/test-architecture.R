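refs <- cupin_references()
ref1 <- refs$residues[1]
ref_len <- nchar(ref1)
motifs <- cenpc_motifs()
scheme <- scoring_scheme()
cfg <- classifier_config()

test_that("an exact planted reference copy is located precisely", {
  seqres <- build_protein(400, list(list(start0 = 200, residues = ref1)))
  hit <- locate_cupin(seqres, refs, scheme)
  expect_equal(hit$reference_id, refs$id[1])
  expect_equal(hit$start, 200L)
  expect_equal(hit$end, 200L + ref_len)
  expect_equal(hit$identity_fraction, 1.0)
})

test_that("random sequences yield no significant domain hit", {
  set.seed(808)
  for (i in 1:10) {
    expect_null(locate_cupin(random_protein(500), refs, scheme))
  }
})

test_that("a 20%-mutated reference copy is still recovered (Jaccard >= 0.8)", {
  set.seed(909)
  for (i in 1:5) {
    chars <- strsplit(ref1, "", fixed = TRUE)[[1]]
    nmut <- round(0.2 * ref_len)
    pos <- sample(ref_len, nmut)
    for (p in pos) {
      repeat {
        new <- sample(AA20_T, 1)
        if (new != chars[p]) break
      }
      chars[p] <- new
    }
    mutated <- paste(chars, collapse = "")
    start0 <- sample(50:250, 1)
    seqres <- build_protein(500, list(list(start0 = start0,
                                           residues = mutated)))
    hit <- locate_cupin(seqres, refs, scheme)
    expect_false(is.null(hit))
    inter <- max(0, min(hit$end, start0 + ref_len) - max(hit$start, start0))
    uni <- max(hit$end, start0 + ref_len) - min(hit$start, start0)
    expect_gte(inter / uni, 0.8)
  }
})

test_that("locate_cupin requires references", {
  expect_error(locate_cupin("MKW", refs[0, ]), "at least one reference")
})

test_that("a canonical motif 80 residues upstream of a cupin is canonical", {
  set.seed(12)
  inst <- sample_motif_instance(motifs$cenpc_motif_identities)
  cupin_start <- 300L
  motif_end <- cupin_start - 80L
  seqres <- build_protein(450, list(
    list(start0 = motif_end - 20L, residues = inst),
    list(start0 = cupin_start, residues = ref1)
  ))
  call <- classify_protein(setNames(seqres, "canon"), cfg, motifs, refs, scheme)
  expect_equal(call$class, "CANONICAL_CENPC")
  expect_equal(call$motif_to_cupin_gap, 80L)
  expect_true(isTRUE(validate_call(call, cfg)))
})

test_that("two exact central-region cores upstream of a cupin are fish-type", {
  seqres <- build_protein(500, list(
    list(start0 = 50, residues = "RCCCCPCCWW"),
    list(start0 = 200, residues = "RCCCCPCCWW"),
    list(start0 = 350, residues = ref1)
  ))
  call <- classify_protein(setNames(seqres, "fish"), cfg, motifs, refs, scheme)
  expect_equal(call$class, "PUTATIVE_FISH_CENPC")
  expect_equal(call$conserved_region_count, 2L)
  expect_equal(call$motif_to_cupin_gap, 350L - 210L)
  expect_true(isTRUE(validate_call(call, cfg)))
})

test_that("a degraded core lacking both tryptophans still counts as evidence", {
  # the fish-type candidate may lack the two W's: two violated positions
  seqres <- build_protein(500, list(
    list(start0 = 200, residues = "RCCCCPCCCC"),
    list(start0 = 350, residues = ref1)
  ))
  call <- classify_protein(setNames(seqres, "shark"), cfg, motifs, refs, scheme)
  expect_equal(call$class, "PUTATIVE_FISH_CENPC")
  expect_gte(length(call$degraded), 1L)
  offsets <- vapply(call$degraded, `[[`, integer(1), "offset")
  expect_true(200L %in% offsets)
  viol <- call$degraded[[which(offsets == 200L)]]$violated
  expect_equal(viol, c(9L, 10L))
  # three mismatches exceed the tolerance: no evidence left
  seqres3 <- build_protein(500, list(
    list(start0 = 200, residues = "RCCCCCCCCC"),
    list(start0 = 350, residues = ref1)
  ))
  call3 <- classify_protein(setNames(seqres3, "too_far"), cfg, motifs, refs,
                            scheme)
  expect_equal(call3$class, "CUPIN_ONLY")
})

test_that("canonical motif without a cupin is M18BP1-like motif-only", {
  set.seed(13)
  inst <- sample_motif_instance(motifs$cenpc_motif_identities)
  seqres <- build_protein(300, list(list(start0 = 100, residues = inst)))
  call <- classify_protein(setNames(seqres, "m18"), cfg, motifs, refs, scheme)
  expect_equal(call$class, "MOTIF_ONLY")
  expect_true(isTRUE(validate_call(call, cfg)))
})

test_that("cupin alone and background alone fall through to the tail classes", {
  only_cupin <- build_protein(400, list(list(start0 = 250, residues = ref1)))
  call <- classify_protein(setNames(only_cupin, "c"), cfg, motifs, refs, scheme)
  expect_equal(call$class, "CUPIN_ONLY")
  call2 <- classify_protein(setNames(strrep("A", 300), "bg"), cfg, motifs,
                            refs, scheme)
  expect_equal(call2$class, "NONE")
})

test_that("a motif too far upstream is not canonical, and the gap rule is monotone", {
  set.seed(14)
  inst <- sample_motif_instance(motifs$cenpc_motif_identities)
  cupin_start <- 400L
  gap <- 150L
  seqres <- build_protein(550, list(
    list(start0 = cupin_start - gap - 20L, residues = inst),
    list(start0 = cupin_start, residues = ref1)
  ))
  call100 <- classify_protein(setNames(seqres, "far"), cfg, motifs, refs,
                              scheme)
  expect_false(call100$class == "CANONICAL_CENPC")
  wide <- classifier_config(canonical_gap_max = 200L)
  call200 <- classify_protein(setNames(seqres, "far"), wide, motifs, refs,
                              scheme)
  expect_equal(call200$class, "CANONICAL_CENPC")
  expect_equal(call200$motif_to_cupin_gap, gap)
})

test_that("widening the canonical gap never loses canonical calls", {
  p <- generate_proteome(30, seed = 99)
  counts <- vapply(c(50L, 100L, 200L, 400L), function(g) {
    calls <- scan_proteome(p$records, classifier_config(canonical_gap_max = g),
                           motifs, refs, scheme, verbose = FALSE)
    sum(vapply(calls, `[[`, character(1), "class") == "CANONICAL_CENPC")
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("spacing ratio uses the cupin-proximal hit and guards its inputs", {
  fish <- build_protein(500, list(
    list(start0 = 50, residues = "RCCCCPCCWW"),
    list(start0 = 240, residues = "RCCCCPCCWW"),
    list(start0 = 350, residues = ref1)
  ))
  call_f <- classify_protein(setNames(fish, "f"), cfg, motifs, refs, scheme)
  canon <- build_protein(450, list(
    list(start0 = 230, residues = "RAARAAAAPLAYWAGERAAY"),
    list(start0 = 300, residues = ref1)
  ))
  call_c <- classify_protein(setNames(canon, "c"), cfg, motifs, refs, scheme)
  expect_equal(spacing_ratio(call_f, call_f), 1.0)
  # proximal gaps: fish 350-250=100, canonical 300-250=50
  expect_equal(spacing_ratio(call_f, call_c), 2.0)
  none <- classify_protein(setNames(strrep("A", 300), "n"), cfg, motifs,
                           refs, scheme)
  expect_error(spacing_ratio(none, call_c), "no cupin")
  only_cupin <- classify_protein(
    setNames(build_protein(400, list(list(start0 = 250, residues = ref1))),
             "oc"), cfg, motifs, refs, scheme)
  expect_error(spacing_ratio(call_f, only_cupin), "no motif hit")
})

test_that("zero-gap denominators are rejected", {
  adjacent <- build_protein(500, list(
    list(start0 = 340, residues = "RCCCCPCCWW"),
    list(start0 = 350, residues = ref1)
  ))
  call_adj <- classify_protein(setNames(adjacent, "adj"), cfg, motifs, refs,
                               scheme)
  expect_equal(call_adj$motif_to_cupin_gap, 0L)
  expect_error(spacing_ratio(call_adj, call_adj), "positive")
})

test_that("proteome scanning preserves order, is deterministic, and validates", {
  p <- generate_proteome(25, seed = 1234)
  calls1 <- scan_proteome(p$records, cfg, motifs, refs, scheme,
                          verbose = FALSE)
  calls2 <- scan_proteome(p$records, cfg, motifs, refs, scheme,
                          verbose = FALSE)
  expect_identical(architecture_table(calls1), architecture_table(calls2))
  expect_equal(vapply(calls1, `[[`, character(1), "sequence_id"),
               p$records$id)
  for (call in calls1) expect_true(isTRUE(validate_call(call, cfg)))
  expect_message(scan_proteome(p$records[1:3, ], cfg, motifs, refs, scheme),
                 "class counts")
})

test_that("empty input yields an empty call set", {
  path <- tempfile(fileext = ".fasta")
  file.create(path)
  calls <- scan_proteome(path, cfg, motifs, refs, scheme, verbose = FALSE)
  expect_equal(length(calls), 0L)
})
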