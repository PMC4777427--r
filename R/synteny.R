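# Synteny-based locus classification: decide the state of a target locus
# from the annotations of its conserved gene neighbourhood, and compile
# co-annotation and genome-quality surveys across many genomes.

gene_spans <- function(ann) {
  ann |> group_by(.data$gene_id, .data$scaffold_id, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
}

resolve_flank <- function(spans, ids) {
  for (id in ids) {
    hit <- spans |> filter(.data$gene_id == id)
    if (nrow(hit) > 0) return(hit)
  }
  NULL
}

#' Classify the target locus of one genome
#'
#' Applies the synteny evidence cascade: the locus is `ANNOTATED` when the
#' target gene is annotated between its two flanking genes;
#' `SPANNED_UNANNOTATED` when both flanks lie on one scaffold with a mostly
#' intact intergenic region; `GAP_IN_REGION` when the spanning region's
#' largest assembly-gap run reaches `gap_threshold` of the intergenic span
#' (the "uninterrogable" configuration); `FLANKS_SPLIT` when the flanks land
#' on different scaffolds; and `FLANK_MISSING` otherwise. Fallback flank ids
#' cover the case where the primary flank itself is unannotated (as a
#' related upstream gene can stand in for it). Region statistics (gap, GC,
#' repeat-mask content) are computed whenever the intergenic interval
#' exists and sequences are available.
#'
#' @param record An [assembly_record()].
#' @param target_gene Target gene id.
#' @param upstream_flank,downstream_flank Primary flank gene ids.
#' @param fallback_upstream,fallback_downstream Ordered fallback ids tried
#'   when the primary flank is absent.
#' @param gap_threshold Largest-gap fraction of the intergenic span at and
#'   above which the region counts as gapped.
#' @return A `locus_assessment` object.
#' @export
classify_locus <- function(record, target_gene = "foxp3",
                           upstream_flank = "ppp1r3f",
                           downstream_flank = "ccdc22",
                           fallback_upstream = c("naa10", "hsd17b10"),
                           fallback_downstream = c("cacna1f"),
                           gap_threshold = 0.2) {
  stopifnot(inherits(record, "assembly_record"))
  if (target_gene %in% c(upstream_flank, downstream_flank,
                         fallback_upstream, fallback_downstream)) {
    stop("target gene id collides with a flank id", call. = FALSE)
  }
  ann <- record$annotations
  spans <- gene_spans(ann)
  per_scaffold_genes <- spans |> group_by(.data$scaffold_id) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  up <- resolve_flank(spans, c(upstream_flank, fallback_upstream))
  dn <- resolve_flank(spans, c(downstream_flank, fallback_downstream))
  flank_row <- function(role, hit) {
    if (is.null(hit)) {
      return(tibble(role = role, gene_id = NA_character_, present = FALSE,
                    scaffold_id = NA_character_,
                    single_gene_scaffold = NA))
    }
    sg <- per_scaffold_genes$n_genes[match(hit$scaffold_id[1],
                                           per_scaffold_genes$scaffold_id)] == 1
    tibble(role = role, gene_id = hit$gene_id[1], present = TRUE,
           scaffold_id = hit$scaffold_id[1], single_gene_scaffold = sg)
  }
  res <- list(genome_id = record$genome_id, target_gene = target_gene,
              status = NA_character_, intergenic = NULL,
              gap_total = NA_real_, gap_largest = NA_real_,
              region_gc = NA_real_, region_masked = NA_real_,
              gap_threshold = gap_threshold,
              flank_evidence = bind_rows(flank_row("upstream", up),
                                         flank_row("downstream", dn)))
  finish <- function(res, status) {
    res$status <- status
    structure(res, class = "locus_assessment")
  }
  if (is.null(up) || is.null(dn)) return(finish(res, "FLANK_MISSING"))
  # choose the pair of flank copies closest to each other on one scaffold
  pairs <- merge(up, dn, by = "scaffold_id",
                 suffixes = c("_up", "_dn"))
  if (nrow(pairs) == 0) {
    res$flank_evidence <- bind_rows(flank_row("upstream", up[1, ]),
                                    flank_row("downstream", dn[1, ]))
    return(finish(res, "FLANKS_SPLIT"))
  }
  gapbp <- pmax(pairs$start_dn, pairs$start_up) -
    pmin(pairs$end_dn, pairs$end_up)
  best <- pairs[which.min(gapbp), ]
  res$flank_evidence <- bind_rows(
    flank_row("upstream", tibble(gene_id = best$gene_id_up,
                                 scaffold_id = best$scaffold_id)),
    flank_row("downstream", tibble(gene_id = best$gene_id_dn,
                                   scaffold_id = best$scaffold_id)))
  lo <- min(best$end_up, best$end_dn)
  hi <- max(best$start_up, best$start_dn)
  if (hi < lo) { lo <- hi } # overlapping flanks: empty interval
  res$intergenic <- tibble(scaffold_id = best$scaffold_id,
                           start = lo, end = hi, width = hi - lo)
  seqn <- NULL
  if (!is.null(record$scaffolds)) {
    i <- match(best$scaffold_id, record$scaffolds$id)
    if (!is.na(i)) seqn <- record$scaffolds$sequence[i]
  }
  if (!is.null(seqn) && hi > lo) {
    region <- substr(seqn, lo + 1, hi)
    gr <- gap_runs(region)
    res$gap_total <- sum(gr$width)
    res$gap_largest <- if (nrow(gr) > 0) max(gr$width) else 0
    res$region_gc <- gc_fraction(region)
    res$region_masked <- masked_fraction(region)
  } else {
    res$gap_total <- 0; res$gap_largest <- 0
  }
  # target annotated between the flanks?
  tgt <- spans |> filter(.data$gene_id == target_gene,
                         .data$scaffold_id == best$scaffold_id)
  span_lo <- min(best$start_up, best$start_dn)
  span_hi <- max(best$end_up, best$end_dn)
  if (nrow(tgt) > 0 && any(tgt$start >= span_lo & tgt$end <= span_hi)) {
    return(finish(res, "ANNOTATED"))
  }
  if (hi > lo && res$gap_largest >= gap_threshold * (hi - lo)) {
    return(finish(res, "GAP_IN_REGION"))
  }
  finish(res, "SPANNED_UNANNOTATED")
}

#' @export
print.locus_assessment <- function(x, ...) {
  cat(sprintf("<locus_assessment> %s: %s\n", x$genome_id, x$status))
  if (!is.null(x$intergenic)) {
    cat(sprintf("  intergenic %s:[%d,%d) span %d bp; largest gap %s bp; GC %s; masked %s\n",
                x$intergenic$scaffold_id, x$intergenic$start,
                x$intergenic$end, x$intergenic$width,
                format(x$gap_largest), format(round(x$region_gc, 3)),
                format(round(x$region_masked, 3))))
  }
  invisible(x)
}

#' Co-annotation contingency of a target gene and two flanks
#'
#' Counts, over a set of genomes, how often the target and each flanking
#' gene are annotated and the four discordance cells (target without flank,
#' flank without target).
#'
#' @param records List of [assembly_record()]s.
#' @param target_gene,flank_a,flank_b Gene ids.
#' @return A one-row tibble of counts.
#' @export
co_annotation_contingency <- function(records, target_gene = "foxp3",
                                      flank_a = "cacna1f",
                                      flank_b = "ccdc22") {
  stopifnot(length(records) >= 1)
  has <- function(rec, g) g %in% rec$annotations$gene_id
  t_ <- vapply(records, has, logical(1), g = target_gene)
  a_ <- vapply(records, has, logical(1), g = flank_a)
  b_ <- vapply(records, has, logical(1), g = flank_b)
  tibble(
    n_genomes = length(records),
    target_annotated = sum(t_),
    flank_a_annotated = sum(a_),
    flank_b_annotated = sum(b_),
    target_without_a = sum(t_ & !a_),
    target_without_b = sum(t_ & !b_),
    a_without_target = sum(a_ & !t_),
    b_without_target = sum(b_ & !t_)
  )
}

#' Stratify genomes by neighbourhood assembly quality
#'
#' Assigns each genome to one of three groups by how well the target gene
#' neighbourhood is assembled and annotated: no scaffold carries any
#' neighbourhood gene; neighbourhood genes occur only on single-gene
#' scaffolds; or at least one scaffold carries two or more of them. Reports
#' per-group arithmetic means of coverage, scaffold N50 and scaffold count
#' (mean coverage rounded to integer fold). Genomes lacking metadata are
#' excluded with a warning and listed in the `excluded` attribute.
#'
#' @param records List of [assembly_record()]s with metadata.
#' @param neighborhood_genes Gene ids that define the neighbourhood.
#' @return A tibble with one row per group.
#' @export
quality_stratify <- function(records,
                             neighborhood_genes = c("hsd17b10", "naa10",
                                                    "tspyl2", "ppp1r3f",
                                                    "ccdc22", "cacna1f")) {
  meta_ok <- vapply(records, function(r) {
    m <- r$metadata
    !is.na(m$coverage_x) && !is.na(m$n_scaffolds) && !is.na(m$declared_n50)
  }, logical(1))
  if (any(!meta_ok)) {
    excluded <- vapply(records[!meta_ok], function(r) r$genome_id, character(1))
    warning("excluding genome(s) without metadata: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  } else excluded <- character(0)
  recs <- records[meta_ok]
  grp <- vapply(recs, function(r) {
    ann <- r$annotations |> filter(.data$gene_id %in% neighborhood_genes)
    if (nrow(ann) == 0) return("zero_annotated")
    per_sc <- ann |> group_by(.data$scaffold_id) |>
      summarise(n = dplyr::n_distinct(.data$gene_id), .groups = "drop")
    if (max(per_sc$n) >= 2) "multi_gene" else "single_gene_only"
  }, character(1))
  df <- tibble(
    genome_id = vapply(recs, function(r) r$genome_id, character(1)),
    group = factor(grp, levels = c("zero_annotated", "single_gene_only",
                                   "multi_gene")),
    coverage_x = vapply(recs, function(r) r$metadata$coverage_x, numeric(1)),
    n_scaffolds = vapply(recs, function(r) as.numeric(r$metadata$n_scaffolds),
                         numeric(1)),
    n50 = vapply(recs, function(r) r$metadata$declared_n50, numeric(1)))
  out <- df |> group_by(.data$group) |>
    summarise(n_genomes = dplyr::n(),
              mean_coverage = round(mean(.data$coverage_x)),
              mean_n50 = mean(.data$n50),
              mean_n_scaffolds = mean(.data$n_scaffolds),
              .groups = "drop") |>
    tidyr::complete(group = factor(levels(df$group), levels = levels(df$group)),
                    fill = list(n_genomes = 0L))
  attr(out, "excluded") <- excluded
  out
}
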