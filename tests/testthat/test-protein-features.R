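# Domain architecture, motif scanning, anchored alignment and signature
# residues.

test_that("proline fraction counts P over non-gap length", {
  expect_equal(proline_fraction("PPPP"), 1)
  expect_equal(proline_fraction("PAPA"), 0.5)
  expect_equal(proline_fraction("P-P-AA"), 0.5) # gaps out of the denominator
  expect_equal(proline_fraction("PXPX"), 0.5)   # X stays in
  expect_error(proline_fraction("PPPP", 2, 2), "empty region")
  # fraction of a concatenation is the length-weighted mean of the parts
  set.seed(6)
  for (i in 1:15) {
    a <- random_protein(sample(5:30, 1)); b <- random_protein(sample(5:30, 1))
    lhs <- proline_fraction(paste0(a, b))
    rhs <- (proline_fraction(a) * nchar(a) + proline_fraction(b) * nchar(b)) /
      (nchar(a) + nchar(b))
    expect_equal(lhs, rhs)
  }
})

test_that("the leucine-zipper motif matches its consensus and the I variant", {
  lz <- paste0("V", strrep("A", 6), "L", strrep("A", 6), "L",
               strrep("A", 6), "L")
  expect_equal(find_motif(lz, lz_pattern())$start, 0)
  lz_i <- sub("^V", "I", lz)
  expect_equal(find_motif(lz_i, lz_pattern())$start, 0)
  expect_equal(nrow(find_motif(lz_i, lz_pattern(first = "V"))), 0)
  expect_equal(nrow(find_motif(strrep("A", 30), lz_pattern())), 0)
  # overlapping matches are all reported
  two <- paste0("VV", strrep("A", 5), "LL", strrep("A", 5), "LL",
                strrep("A", 5), "LL")
  expect_equal(find_motif(two, lz_pattern())$start, c(0, 1))
})

test_that("architecture detection recovers planted domain layouts", {
  pr <- simulate_foxp_protein("ground_tit", seed = 11)
  arch <- detect_architecture(pr$protein)
  lay <- pr$layout
  expect_false(arch$zf$present)
  expect_equal(arch$lz$start, lay$start[lay$region == "lz"])
  expect_equal(arch$frk$start, lay$start[lay$region == "frk"])
  expect_equal(arch$frk$end, lay$end[lay$region == "frk"])
  expect_equal(arch$lz$first_position_residue, "I")
  expect_equal(arch$pror$end, lay$end[lay$region == "nterm"])
  expect_equal(round(100 * arch$pror$proline_fraction, 1), 25.2)
  # a mouse-like protein carries a detectable zinc finger
  mo <- simulate_foxp_protein("mouse", seed = 11)
  am <- detect_architecture(mo$protein)
  expect_true(am$zf$present)
  expect_equal(am$zf$start, mo$layout$start[mo$layout$region == "zf"])
  expect_equal(am$n_terminal_region[2], am$zf$start)
  # intervals are ordered N- to C-terminal
  td <- tidy(am)
  iv <- td[td$present & !is.na(td$start), ]
  expect_true(all(diff(iv$start) >= 0))
})

test_that("a scrambled ZF region is reported absent and an alien protein errors", {
  mo <- simulate_foxp_protein("mouse", seed = 3)
  lay <- mo$layout
  zf <- lay[lay$region == "zf", ]
  set.seed(8)
  scrambled <- paste0(substr(mo$protein, 1, zf$start),
                      paste(sample(c("P", "A", "S", "T", "Q"),
                                   zf$end - zf$start, TRUE), collapse = ""),
                      substr(mo$protein, zf$end + 1, nchar(mo$protein)))
  arch <- detect_architecture(scrambled)
  expect_false(arch$zf$present)
  expect_equal(arch$n_terminal_region[2], arch$lz$start)
  expect_error(detect_architecture(strrep("A", 300)), "not classifiable")
})

test_that("anchored alignment projects onto baseline columns", {
  aln <- anchor_align(c(b = "ACDEFG", o = "ACDEFG"), "b")
  expect_true(all(aln$matrix["o", ] == aln$matrix["b", ]))
  aln <- anchor_align(c(b = "ACDEFG", o = "ACEFG"), "b")
  expect_equal(paste(aln$matrix["o", ], collapse = ""), "AC-EFG")
  expect_error(anchor_align(c(b = "ACD", o = ""), "b"), "empty")
  # X runs become the missing-data mask
  aln <- anchor_align(c(b = "ACDEFGHIKL", o = "ACDXXXHIKL"), "b")
  expect_equal(which(aln$missing["o", ]), 4:6)
})

test_that("anchored alignment scores agree with a plain affine NW oracle", {
  set.seed(21)
  sub <- blosum62()
  for (i in 1:12) {
    a <- random_protein(sample(4:10, 1)); b <- random_protein(sample(4:10, 1))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sub, gapOpening = 10, gapExtension = 2,
      type = "global", scoreOnly = TRUE)
    expect_equal(pa, oracle_nw_score(a, b, sub, go = -12, ge = -2),
                 tolerance = 1e-6)
  }
})

test_that("signature columns require ingroup identity and exclusion absence", {
  mk <- function(...) c(...)
  seqs <- c(i1 = "AKCDE", i2 = "AKCDE", i3 = "AKCDE",
            x1 = "ARCDQ", x2 = "ARCDW")
  aln <- anchor_align(seqs, "i1")
  s <- signature_residues(aln, c("i1", "i2", "i3"), list(out = c("x1", "x2")))
  expect_equal(s$n_signature, 2)
  expect_equal(s$columns$position, c(1, 4))
  expect_equal(s$columns$ingroup_residue, c("K", "E"))
  # ingroup used as its own exclusion eliminates everything
  s0 <- signature_residues(aln, c("i1", "i2"), list(self = c("i1", "i2")))
  expect_equal(s0$n_signature, 0)
  expect_error(signature_residues(aln, character(0), list(out = "x1")),
               "empty")
  # a fully masked member neither helps nor hurts
  seqs2 <- c(seqs, i4 = "XXXXX")
  aln2 <- anchor_align(seqs2, "i1")
  s2 <- signature_residues(aln2, c("i1", "i2", "i3", "i4"),
                           list(out = c("x1", "x2")))
  expect_equal(s2$columns, s$columns)
  # order of ingroup and exclusion sets is irrelevant
  s3 <- signature_residues(aln, c("i3", "i1", "i2"),
                           list(b = "x2", a = "x1"))
  expect_equal(s3$columns, s$columns)
})

test_that("the shipped signature TSV matches the package reference list", {
  tsv <- system.file("extdata", "mammalian_signature_reference.tsv",
                     package = "missedgene")
  expect_true(nzchar(tsv))
  on_disk <- utils::read.delim(tsv)
  ref <- mammalian_signature_reference()
  expect_equal(on_disk$position, ref$position)
  expect_equal(on_disk$residue, ref$residue)
})

test_that("the FoxP panel yields the avian signature and its mammalian overlap", {
  panel <- simulate_foxp_panel()
  aln <- anchor_align(panel[, c("id", "sequence")], "mouse_foxp3")
  birds <- panel$id[panel$clade == "bird"]
  paras <- panel$id[panel$clade == "paralogue"]
  vs_paralogues <- signature_residues(
    aln, birds, list(paralogues = paras),
    reference_signature = mammalian_signature_reference())
  # columns conserved in birds and absent from FoxP1/2/4: the six avian
  # signature residues plus the five mammalian-signature residues birds share
  expect_equal(vs_paralogues$n_signature, 11)
  expect_equal(vs_paralogues$overlap_with_reference_signature, 5)
  strictly_avian <- signature_residues(
    aln, birds, list(paralogues = paras, mammal = "mouse_foxp3"))
  expect_equal(strictly_avian$n_signature, 6)
  # the saker-like row's masked gap does not break bird agreement
  expect_true(any(aln$missing["saker_falcon_foxp3", ]))
})
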