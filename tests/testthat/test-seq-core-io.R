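# Sequence primitives, assembly statistics, and standard-format I/O.

test_that("revcomp and translation follow the genetic code and frame rules", {
  expect_equal(revcomp("TTGTGCAGGCTCAGGTTG"), "CAACCTGAGCCTGCACAA")
  expect_equal(translate_dna("CAACCTGAGCCTGCACAA", frame = 1), "NLSLH")
  expect_equal(translate_dna("ATG", 0), "M")
  expect_equal(translate_dna("TAA", 0), "*")
  expect_equal(translate_dna("ANT", 0), "X")
  expect_equal(revcomp("ACgtN"), "NacGT") # per-base case preserved
  expect_error(revcomp("ACGR"), "non-IUPAC")
  expect_error(translate_dna("ACGT", 3))
  # double reverse complement is the identity; frame length arithmetic holds
  set.seed(1)
  for (i in 1:20) {
    s <- random_dna_str(sample(10:60, 1))
    expect_equal(revcomp(revcomp(s)), s)
    f <- sample(0:2, 1)
    expect_equal(nchar(translate_dna(s, f)), (nchar(s) - f) %/% 3)
    expect_equal(translate_dna(revcomp(s), f), oracle_revtrans(s, f))
  }
})

test_that("gc, masked and gap statistics match their definitions", {
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(gc_fraction("GCNNAT"), 0.5) # 2 of 4 unambiguous
  expect_true(is.na(gc_fraction("NNNN")))
  expect_error(gc_fraction("ACGT", 2, 2), "empty region")
  expect_equal(masked_fraction("acgtACGT"), 0.5)
  expect_equal(masked_fraction("ACGT"), 0)
  gr <- gap_runs("AANNNAA")
  expect_equal(gr$start, 2)
  expect_equal(gr$end, 5)
  expect_equal(nrow(gap_runs("ACGT")), 0)
  # gc + at partition the unambiguous bases
  set.seed(2)
  for (i in 1:25) {
    s <- paste0(random_dna_str(sample(20:80, 1)), "NN")
    ch <- strsplit(s, "")[[1]]
    at <- sum(ch %in% c("A", "T")) / sum(ch != "N")
    expect_equal(gc_fraction(s) + at, 1)
  }
})

test_that("n50 equals the brute-force definition", {
  expect_equal(n50(10), 10)
  expect_equal(n50(c(1, 2, 3, 4, 10)), 10)
  expect_equal(n50(c(5, 5, 5, 5)), 5)
  expect_error(n50(numeric(0)), "empty")
  set.seed(3)
  for (i in 1:1000) {
    lens <- sample.int(1000, sample(1:30, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("FASTA round trips preserve ids, order and soft-mask case", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "x.fa")
  sc <- tibble::tibble(id = c("s1", "s2"),
                       sequence = c("ACgtNNacGT", strrep("acGT", 40)))
  write_fasta(sc, fa)
  rf <- read_fasta(fa)
  expect_identical(rf$id, sc$id)
  expect_identical(rf$sequence, sc$sequence)
  expect_equal(rf$length, nchar(sc$sequence))
  # blank interleaved lines are tolerated; lengths concatenate
  writeLines(c(">a", "ACGT", "", "GG", ">b", "", "TTTT"), fa)
  rf <- read_fasta(fa)
  expect_equal(rf$length, c(6, 4))
  # malformed inputs name the line
  writeLines(c("ACGT", ">a", "ACGT"), fa)
  expect_error(read_fasta(fa), "line 1")
  writeLines(c(">empty", "", ">b", "ACGT"), fa)
  expect_error(read_fasta(fa), "empty")
})

test_that("GFF coordinates convert 1-based inclusive <-> 0-based half-open", {
  td <- withr::local_tempdir()
  gff <- file.path(td, "x.gff3")
  ann <- tibble::tibble(gene_id = "g1", scaffold_id = "s1", strand = "+",
                        biotype = "gene", exon_rank = 1:2,
                        start = c(0L, 60L), end = c(30L, 90L))
  write_gff(ann, gff)
  lines <- readLines(gff)
  expect_true(any(grepl("\texon\t1\t30\t", lines)))
  expect_true(any(grepl("\texon\t61\t90\t", lines)))
  back <- read_gff(gff)
  expect_equal(as.integer(back$start), c(0L, 60L))
  expect_equal(as.integer(back$end), c(30L, 90L))
  # round trip on simulator output is the identity
  sim <- get_sim(2)
  write_gff(sim$record$annotations, gff)
  rg <- read_gff(gff)
  a <- dplyr::arrange(sim$record$annotations, scaffold_id, gene_id, start)
  b <- dplyr::arrange(rg, scaffold_id, gene_id, start)
  expect_equal(as.integer(b$start), as.integer(a$start))
  expect_equal(as.integer(b$end), as.integer(a$end))
  expect_equal(b$gene_id, a$gene_id)
  expect_equal(b$strand, a$strand)
  expect_equal(b$biotype, a$biotype)
  # an exon whose Parent chain does not resolve is an error
  writeLines(c("##gff-version 3",
               "s1\ttest\texon\t1\t30\t.\t+\t.\tParent=rna-ghost"), gff)
  expect_error(read_gff(gff), "resolvable gene parent")
})

test_that("assembly statistics respect their invariants", {
  sim <- get_sim(2)
  st <- assembly_stats(sim$record)
  expect_equal(st$n_scaffolds, 1)
  expect_equal(st$total_length, nchar(sim$record$scaffolds$sequence[1]))
  expect_true(st$n50 >= min(sim$record$scaffolds$length) &&
                st$n50 <= max(sim$record$scaffolds$length))
  expect_true(st$gc_fraction > 0 && st$gc_fraction < 1)
  expect_true(st$masked_fraction >= 0 && st$masked_fraction <= 1)
  expect_true(st$gap_fraction == 0)
})

test_that("metadata TSV reads with the declared columns", {
  td <- withr::local_tempdir()
  tsv <- file.path(td, "meta.tsv")
  writeLines(c("genome_id\tcoverage_x\tn_scaffolds\tn50",
               "g1\t46\t67526\t931132"), tsv)
  m <- read_assembly_metadata(tsv)
  expect_equal(m$genome_id, "g1")
  expect_equal(m$n50, 931132)
})

test_that("assembly_record validates annotation consistency", {
  sc <- tibble::tibble(id = "s1", sequence = "ACGTACGTAC")
  good <- tibble::tibble(gene_id = "g", scaffold_id = "s1", strand = "+",
                         biotype = "gene", exon_rank = 1L, start = 0L, end = 5L)
  expect_s3_class(assembly_record("x", sc, good), "assembly_record")
  bad_sc <- good; bad_sc$scaffold_id <- "nope"
  expect_error(assembly_record("x", sc, bad_sc), "unknown scaffold")
  bad_end <- good; bad_end$end <- 99L
  expect_error(assembly_record("x", sc, bad_end), "beyond scaffold")
})
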