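# Locus classification from neighbourhood annotations and the survey
# summaries.

test_that("an intact simulated neighbourhood classifies as ANNOTATED", {
  for (s in 1:5) {
    la <- classify_locus(get_sim(s)$record)
    expect_equal(la$status, "ANNOTATED")
    expect_false(is.null(la$intergenic))
    expect_true(la$region_gc > 0.6)
  }
})

test_that("classification rejects a target id that collides with a flank", {
  expect_error(classify_locus(get_sim(1)$record, target_gene = "ccdc22"),
               "collides")
})

test_that("the crow-like fixture reproduces the gapped-region configuration", {
  cr <- crow_like_record()
  la <- classify_locus(cr, upstream_flank = "naa10",
                       fallback_upstream = "hsd17b10")
  expect_equal(la$status, "GAP_IN_REGION")
  expect_equal(la$intergenic$width, 36546)
  expect_equal(la$gap_largest, 23713)
  # the fallback flank was used
  expect_equal(la$flank_evidence$gene_id[la$flank_evidence$role == "upstream"],
               "hsd17b10")
  expect_equal(masked_fraction(cr$scaffolds$sequence[1]), 0.547)
})

test_that("flanks on different scaffolds give FLANKS_SPLIT, absent flanks FLANK_MISSING", {
  cr <- crow_like_record()
  mid <- 25000L
  seqn <- cr$scaffolds$sequence[1]
  ann <- cr$annotations
  left <- ann[ann$end <= mid, ]; right <- ann[ann$start >= mid, ]
  right$start <- right$start - mid; right$end <- right$end - mid
  right$scaffold_id <- "s_right"; left$scaffold_id <- "s_left"
  split_rec <- assembly_record("crow_split",
    scaffolds = tibble::tibble(id = c("s_left", "s_right"),
                               sequence = c(substr(seqn, 1, mid),
                                            substr(seqn, mid + 1, nchar(seqn)))),
    annotations = dplyr::bind_rows(left, right))
  la <- classify_locus(split_rec, upstream_flank = "naa10",
                       fallback_upstream = "hsd17b10")
  expect_equal(la$status, "FLANKS_SPLIT")
  # drop the downstream flank entirely
  miss <- assembly_record("crow_miss",
    scaffolds = cr$scaffolds,
    annotations = ann[ann$gene_id != "cacna1f", ])
  expect_equal(classify_locus(miss, upstream_flank = "naa10",
                              fallback_upstream = "hsd17b10")$status,
               "FLANK_MISSING")
})

test_that("classification is invariant under reverse-complementing the record", {
  for (s in c(1, 3)) {
    rec <- get_sim(s)$record
    expect_equal(classify_locus(revcomp_record(rec))$status,
                 classify_locus(rec)$status)
  }
  cr <- crow_like_record()
  expect_equal(classify_locus(revcomp_record(cr), upstream_flank = "naa10",
                              fallback_upstream = "hsd17b10")$status,
               "GAP_IN_REGION")
})

test_that("fuzzed fragmented assemblies always get exactly one valid status", {
  statuses <- c("ANNOTATED", "SPANNED_UNANNOTATED", "GAP_IN_REGION",
                "FLANKS_SPLIT", "FLANK_MISSING")
  seen <- character(0)
  for (s in 1:30) {
    fr <- fragment_assembly(get_sim((s %% 5) + 1)$record,
                            fragmentation_model(
                              base_break_rate = stats::runif(1, 0, 0.3),
                              gc_break_multiplier = sample(c(1, 5, 20), 1),
                              seed = s))
    la <- classify_locus(fr)
    expect_true(la$status %in% statuses)
    seen <- c(seen, la$status)
  }
  expect_gt(length(unique(seen)), 2) # the fuzz actually explores the space
})

test_that("co-annotation contingency counts concordance and discordance", {
  recs <- lapply(1:3, function(i) get_sim(i)$record)
  cc <- co_annotation_contingency(recs)
  expect_equal(cc$n_genomes, 3)
  expect_equal(cc$target_annotated, 3)
  expect_equal(cc$flank_a_annotated, 3)
  expect_equal(cc$a_without_target, 0)
  # removing the target from one genome moves one discordance cell
  recs[[2]] <- drop_target(recs[[2]])
  cc2 <- co_annotation_contingency(recs)
  expect_equal(cc2$target_annotated, 2)
  expect_equal(cc2$a_without_target, 1)
  expect_equal(cc2$b_without_target, 1)
  # the mammal-like survey reproduces the published marginal structure
  mm <- co_annotation_contingency(mammal_survey_records())
  expect_equal(mm$n_genomes, 105)
  expect_equal(mm$flank_a_annotated, 87)
  expect_equal(mm$flank_b_annotated, 86)
  expect_equal(mm$target_annotated, 88)
  expect_equal(mm$target_without_a, 1)
  expect_equal(mm$target_without_b, 2)
  expect_equal(mm$a_without_target, 0)
  expect_equal(mm$b_without_target, 0)
})

test_that("quality stratification groups genomes and averages metadata", {
  sim <- get_sim(1)
  rec <- sim$record
  rec$metadata <- list(coverage_x = 50, n_scaffolds = 1, declared_n50 = 1e6)
  qs <- quality_stratify(list(rec), neighborhood_genes = c("naa10", "cacna1f"))
  expect_equal(qs$n_genomes[qs$group == "multi_gene"], 1)
  # three genomes averaging in one group
  recs <- lapply(c(40, 50, 60), function(cv) {
    r <- rec; r$genome_id <- paste0("g", cv)
    r$metadata$coverage_x <- cv; r
  })
  qs <- quality_stratify(recs, neighborhood_genes = c("naa10", "cacna1f"))
  expect_equal(qs$mean_coverage[qs$group == "multi_gene"], 50)
  # genomes without metadata are excluded with a warning
  nometa <- rec; nometa$genome_id <- "nm"
  nometa$metadata <- list(coverage_x = NA_real_, n_scaffolds = NA,
                          declared_n50 = NA_real_)
  expect_warning(qs <- quality_stratify(c(recs, list(nometa)),
                                        neighborhood_genes = c("naa10", "cacna1f")),
                 "nm")
  expect_equal(attr(qs, "excluded"), "nm")
})
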