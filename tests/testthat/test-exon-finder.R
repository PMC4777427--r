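# The spliced protein-to-genome aligner, boundary curation, and the exon
# report.

test_that("an exact back-translation aligns as a single full-coverage exon", {
  p <- "MKTAYLHEWD"
  al <- spliced_align(p, back_translate(p))
  expect_equal(nrow(al$exons), 1)
  expect_equal(al$coverage, 1)
  expect_equal(al$strand, "+")
  expect_equal(al$exons$pstart, 0)
  expect_equal(al$exons$pend, 10)
  # reverse strand scores identically and is labelled "-"
  al2 <- spliced_align(p, revcomp(back_translate(p)))
  expect_equal(al2$score, al$score)
  expect_equal(al2$strand, "-")
  expect_equal(al2$exons$gstart, al$exons$gstart)
  expect_error(spliced_align("MK", "ACGTACGT"), "shorter")
})

test_that("planted exon structures are recovered exactly", {
  sim <- get_sim(7)
  r <- sim$truth$region
  al <- spliced_align(sim$truth$target_protein, target_region_seq(sim))
  truth <- sim$truth$target_exons
  expect_equal(nrow(al$exons), nrow(truth))
  expect_equal(al$exons$gstart + r[1], truth$start)
  expect_equal(al$exons$gend + r[1], truth$end)
  expect_equal(al$coverage, 1)
})

test_that("N gap runs are crossed inside introns, never inside exons", {
  p <- "MKTAYLHEWDCF"
  cds <- back_translate(p)
  d <- paste0(substr(cds, 1, 18), "GT", random_dna_str(10), strrep("N", 40),
              random_dna_str(10), "AG", substr(cds, 19, nchar(cds)))
  al <- spliced_align(p, d, scoring_scheme())
  expect_equal(nrow(al$exons), 2)
  expect_equal(al$coverage, 1)
  # no exon overlaps the N run
  gr <- gap_runs(d)
  for (i in seq_len(nrow(al$exons))) {
    expect_true(al$exons$gend[i] <= gr$start || al$exons$gstart[i] >= gr$end)
  }
})

test_that("the DP matches the exhaustive chain-enumeration oracle", {
  set.seed(41)
  sub <- blosum62()
  sch <- scoring_scheme(min_intron = 15, intron_penalty = -8)
  for (i in 1:15) {
    m <- sample(5:8, 1)
    p <- random_protein(m)
    d <- if (i %% 2 == 0) {
      random_dna_str(sample(36:50, 1))
    } else { # plant a spliced gene so intron states are exercised
      cds <- back_translate(p)
      k <- sample(2:4, 1) * 3
      paste0(substr(cds, 1, k), "GT", random_dna_str(12), "AG",
             substr(cds, k + 1, nchar(cds)))
    }
    al <- spliced_align(p, d, sch)
    o <- oracle_spliced_score(p, d, sub, go = -12, ge = -2, ip = -8,
                              min_intron = 15)
    expect_equal(al$score, o, tolerance = 1e-9)
  }
})

test_that("with introns forbidden the aligner reduces to 3-frame local alignment", {
  set.seed(42)
  sub <- blosum62()
  for (i in 1:8) {
    p <- random_protein(sample(6:12, 1))
    d <- random_dna_str(sample(40:80, 1))
    al <- spliced_align(p, d, scoring_scheme(intron_penalty = -1e7))
    frames <- unlist(lapply(c(d, revcomp(d)), function(s)
      lapply(0:2, function(f) translate_dna(s, f))))
    pa <- max(vapply(frames, function(tr) {
      if (nchar(tr) == 0) return(0)
      Biostrings::pairwiseAlignment(Biostrings::AAString(p),
        Biostrings::AAString(tr), substitutionMatrix = sub,
        gapOpening = 10, gapExtension = 2, type = "local",
        scoreOnly = TRUE)
    }, numeric(1)))
    expect_equal(al$score, max(0, pa), tolerance = 1e-6)
  }
})

test_that("the score is local: unrelated flanking DNA changes nothing", {
  sim <- get_sim(3)
  region <- target_region_seq(sim)
  a1 <- spliced_align(sim$truth$target_protein, region)
  set.seed(5)
  a2 <- spliced_align(sim$truth$target_protein,
                      paste0(random_dna_str(400, 0.4), region,
                             random_dna_str(400, 0.4)))
  expect_equal(a2$score, a1$score)
  expect_equal(nrow(a2$exons), nrow(a1$exons))
})

test_that("boundary curation snaps near-miss junctions to the reference", {
  # a two-exon gene whose junction the fixture deliberately mis-places
  p <- "MKTAVLHEWDCF" # V at position 5 makes the off-by-one junction codon GTG
  cds <- back_translate(p)
  k <- 15 # true junction after 5 aa
  intron <- paste0("GT", strrep("C", 31), "AG")
  d <- paste0(substr(cds, 1, k), intron, substr(cds, k + 1, nchar(cds)))
  true_al <- spliced_align(p, d)
  expect_equal(nrow(true_al$exons), 2)
  ref <- tibble::tibble(pstart = c(0, 5), pend = c(5, 12))
  # fixed point: an alignment already on the reference breakpoints
  cur <- curate_boundaries(true_al, ref, p, d)
  expect_equal(cur$exons, true_al$exons)
  # shift the junction one codon left and let curation snap it back
  shifted <- true_al
  shifted$exons$gend[1] <- shifted$exons$gend[1] - 3
  shifted$exons$pend[1] <- shifted$exons$pend[1] - 1
  shifted$exons$gstart[2] <- shifted$exons$gstart[2] - 3
  shifted$exons$pstart[2] <- shifted$exons$pstart[2] - 1
  snapped <- curate_boundaries(shifted, ref, p, d)
  expect_equal(snapped$exons, true_al$exons)
  expect_equal(snapped$score, true_al$score)
  expect_equal(length(snapped$curation_flags), 0)
  # an unreachable breakpoint is flagged, alignment untouched
  ref_bad <- tibble::tibble(pstart = c(0, 6), pend = c(6, 12))
  flagged <- curate_boundaries(true_al, ref_bad, p, d)
  expect_equal(flagged$exons, true_al$exons)
  expect_gt(length(flagged$curation_flags), 0)
  # overlapping reference intervals are rejected
  expect_error(curate_boundaries(true_al,
                                 tibble::tibble(pstart = c(0, 3), pend = c(5, 12)),
                                 p, d),
               "overlapping")
})

test_that("the exon report labels exons with the domains they span", {
  sim <- get_sim(7)
  al <- spliced_align(sim$truth$target_protein, target_region_seq(sim))
  lay <- sim$truth$target_layout
  dm <- tibble::tibble(domain = lay$region, start = lay$start, end = lay$end)
  er <- exon_report(al, dm)
  expect_equal(nrow(er), 11)
  expect_true(grepl("frk", er$domains[nrow(er)]))
  expect_true(grepl("nterm", er$domains[1]))
  expect_equal(sum(er$aligned_aa), 298)
  # empty alignment gives an empty table
  none <- spliced_align("WWWWW", strrep("C", 21)) # only P codons: all negative
  expect_equal(none$score, 0)
  expect_equal(nrow(exon_report(none, dm)), 0)
})
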