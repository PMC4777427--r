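# broom-style tidiers: tidy() returns the per-component table of a result,
# glance() a one-row summary.

#' @rdname tidiers
#' @param x A result object.
#' @param ... Unused.
#' @method tidy spliced_alignment
#' @export
tidy.spliced_alignment <- function(x, ...) {
  if (nrow(x$exons) == 0) return(x$exons)
  x$exons |> mutate(exon = row_number(), strand = x$strand) |>
    select("exon", "gstart", "gend", "pstart", "pend", "phase", "strand")
}

#' @rdname tidiers
#' @method glance spliced_alignment
#' @export
glance.spliced_alignment <- function(x, ...) {
  tibble(n_exons = nrow(x$exons), strand = x$strand, score = x$score,
         coverage = x$coverage, protein_length = x$protein_length)
}

#' @rdname tidiers
#' @method tidy locus_assessment
#' @export
tidy.locus_assessment <- function(x, ...) {
  x$flank_evidence |> mutate(genome_id = x$genome_id, status = x$status) |>
    select("genome_id", "status", dplyr::everything())
}

#' @rdname tidiers
#' @method glance locus_assessment
#' @export
glance.locus_assessment <- function(x, ...) {
  tibble(genome_id = x$genome_id, status = x$status,
         intergenic_span = if (!is.null(x$intergenic)) x$intergenic$width
                           else NA_integer_,
         gap_total = x$gap_total, gap_largest = x$gap_largest,
         region_gc = x$region_gc, region_masked = x$region_masked)
}

#' @rdname tidiers
#' @method tidy domain_architecture
#' @export
tidy.domain_architecture <- function(x, ...) {
  tibble(
    domain = c("pror", "zf", "lz", "frk"),
    start = c(x$pror$start, x$zf$start, x$lz$start, x$frk$start),
    end = c(x$pror$end, x$zf$end, x$lz$end, x$frk$end),
    present = c(x$pror$end > 0, x$zf$present, !is.na(x$lz$start), TRUE))
}

#' @rdname tidiers
#' @method glance domain_architecture
#' @export
glance.domain_architecture <- function(x, ...) {
  tibble(protein_length = x$protein_length,
         pror_end = x$pror$end,
         pror_proline_fraction = x$pror$proline_fraction,
         zf_present = x$zf$present,
         lz_start = x$lz$start,
         lz_first_residue = x$lz$first_position_residue,
         frk_start = x$frk$start, frk_end = x$frk$end,
         frk_identity = x$frk$identity)
}

#' @rdname tidiers
#' @method tidy coverage_profile
#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble(codon = seq_len(x$n_codons) - 1L, count = x$counts)
}

#' @rdname tidiers
#' @method glance coverage_profile
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble(n_codons = x$n_codons, covered = covered_aa(x),
         covered_fraction = covered_aa(x) / x$n_codons,
         max_depth = max(x$counts))
}

#' @rdname tidiers
#' @method tidy signature_result
#' @export
tidy.signature_result <- function(x, ...) x$columns

#' @rdname tidiers
#' @method glance signature_result
#' @export
glance.signature_result <- function(x, ...) {
  tibble(n_signature = x$n_signature,
         overlap_with_reference = x$overlap_with_reference_signature,
         n_ingroup = length(x$ingroup_ids),
         n_exclusion = length(x$exclusion_ids))
}

#' @rdname tidiers
#' @method tidy evidence_report
#' @export
tidy.evidence_report <- function(x, ...) {
  tibble(rule = x$rationale)
}

#' Tidiers for missedgene result objects
#'
#' @name tidiers
#' @rdname tidiers
#' @method glance evidence_report
#' @export
glance.evidence_report <- function(x, ...) {
  tibble(genome_id = x$locus$genome_id, verdict = x$verdict,
         locus_status = x$locus$status,
         n_exons = if (!is.null(x$exons)) nrow(x$exons$exons) else NA_integer_,
         covered_codons = if (!is.null(x$coverage)) covered_aa(x$coverage)
                          else NA_integer_,
         n_rules = length(x$rationale))
}
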