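# Synthetic survey fixtures. These emulate published survey configurations
# so the counting, stratification and classification machinery can be
# exercised offline; they are constructed stand-ins, not downloads.

two_exon_gene <- function(gene_id, scaffold_id, start, strand = "+",
                          exon = 250, intron = 100) {
  s <- c(start, start + exon + intron)
  tibble(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
         biotype = "gene", exon_rank = 1:2,
         start = s, end = s + exon)
}

#' Crow-like gapped-region fixture
#'
#' A single scaffold emulating the American-crow configuration: the
#' upstream flank is a related gene standing in for the usual one, the
#' intergenic region between the flanks spans 36,546 bp and contains a
#' single soft-masked assembly-gap run of 23,713 bp, and repeat tracts
#' bring the scaffold's masked fraction to 54.7%. The target gene is not
#' annotated.
#'
#' @param seed Integer seed for the background sequence.
#' @return An [assembly_record()].
#' @export
crow_like_record <- function(seed = 42) {
  with_rng(derive_seed(seed, "crow"), {
    span <- 36546L; gap <- 23713L
    gene_len <- 600L
    total <- 50000L
    masked_target <- round(0.547 * total) # 27,350
    extra_mask <- masked_target - gap     # lowercase repeat bases needed
    margin <- (total - 2L * gene_len - span) %/% 2L
    up_gene <- two_exon_gene("hsd17b10", "scaffold_crow", margin,
                             strand = "+", exon = 250, intron = 100)
    dn_start <- margin + gene_len + span
    dn_gene <- two_exon_gene("cacna1f", "scaffold_crow", dn_start,
                             strand = "+", exon = 250, intron = 100)
    gap_offset <- 5000L # gap position within the intergenic region
    inter <- paste0(
      random_dna(gap_offset, 0.66),
      strrep("n", gap),
      tolower(random_dna(extra_mask, 0.66)), # repeat tract
      random_dna(span - gap_offset - gap - extra_mask, 0.66))
    seqn <- paste0(random_dna(margin + gene_len, 0.42), inter,
                   random_dna(total - margin - gene_len - span, 0.42))
    assembly_record("american_crow_like",
                    scaffolds = tibble(id = "scaffold_crow", sequence = seqn),
                    annotations = bind_rows(up_gene, dn_gene))
  })
}

one_gene_record <- function(genome_id, genes, scaffold_of = NULL,
                            coverage_x = NA_real_, n_scaffolds = NA,
                            declared_n50 = NA_real_) {
  if (length(genes) == 0) {
    ann <- NULL
  } else {
    if (is.null(scaffold_of)) scaffold_of <- setNames(rep("s1", length(genes)),
                                                      genes)
    ann <- bind_rows(lapply(seq_along(genes), function(i) {
      tibble(gene_id = genes[i], scaffold_id = scaffold_of[[genes[i]]],
             strand = "+", biotype = "gene", exon_rank = 1L,
             start = 1000L * i, end = 1000L * i + 500L)
    }))
  }
  assembly_record(genome_id, scaffolds = NULL, annotations = ann,
                  coverage_x = coverage_x, n_scaffolds = n_scaffolds,
                  declared_n50 = declared_n50)
}

#' Mammal-like co-annotation survey fixture
#'
#' 105 annotation-only genome records emulating the mammalian survey
#' structure: 88 with the target annotated (85 with both downstream
#' flanks, 2 lacking the opposite-strand flank, 1 lacking the same-strand
#' flank), none with a flank but no target, and 17 with none of the three
#' genes.
#'
#' @return A list of [assembly_record()]s.
#' @export
mammal_survey_records <- function() {
  sets <- c(
    rep(list(c("foxp3", "cacna1f", "ccdc22")), 85),
    rep(list(c("foxp3", "cacna1f")), 2),
    rep(list(c("foxp3", "ccdc22")), 1),
    rep(list(character(0)), 17))
  lapply(seq_along(sets), function(i) {
    one_gene_record(sprintf("mammal_%03d", i), sets[[i]])
  })
}

# deviations that keep each group's arithmetic mean exactly on target
spread <- function(n, mean, dev) {
  v <- rep(mean, n); v[1] <- mean - dev; v[2] <- mean + dev; v
}

#' Avian-like genome-quality survey fixture
#'
#' 60 metadata-bearing genome records emulating the avian survey: 31 with
#' no neighbourhood gene annotated, 15 with neighbourhood genes only on
#' single-gene scaffolds, 14 with a multi-gene scaffold, and per-group
#' metadata whose means reproduce the published group statistics
#' (coverage 46x/59x/92x; N50 931,132/4,481,081/7,011,777; scaffold counts
#' 67,526/47,461/47,280).
#'
#' @return A list of [assembly_record()]s.
#' @export
avian_survey_records <- function() {
  n <- c(zero = 31L, single = 15L, multi = 14L)
  cov <- list(spread(n[1], 46, 5), spread(n[2], 59, 8), spread(n[3], 92, 10))
  n50s <- list(spread(n[1], 931132, 120000), spread(n[2], 4481081, 500000),
               spread(n[3], 7011777, 900000))
  nsc <- list(spread(n[1], 67526, 9000), spread(n[2], 47461, 6000),
              spread(n[3], 47280, 5000))
  recs <- list()
  for (g in 1:3) {
    for (i in seq_len(n[g])) {
      id <- sprintf("avian_%s_%02d", names(n)[g], i)
      genes <- switch(g, character(0), c("ccdc22", "cacna1f"),
                      c("ccdc22", "cacna1f"))
      scaffold_of <- switch(g, NULL,
                            list(ccdc22 = "sA", cacna1f = "sB"),
                            list(ccdc22 = "sA", cacna1f = "sA"))
      recs[[length(recs) + 1]] <- one_gene_record(
        id, genes, scaffold_of,
        coverage_x = cov[[g]][i], n_scaffolds = nsc[[g]][i],
        declared_n50 = n50s[[g]][i])
    }
  }
  recs
}
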