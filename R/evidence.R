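# Transcript-read support, in-silico primer checks, and the rule cascade
# that integrates all evidence into a missed-versus-missing verdict.

#' Exact-match read coverage of a coding sequence
#'
#' A read supports every codon fully contained in an exact substring match
#' of the whole read (or its reverse complement) to the CDS; overlapping
#' matches accumulate. Mismatched reads contribute nothing — this mirrors
#' a 100%-identity transcriptome search rather than heuristic mapping.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param cds Coding sequence; length must be divisible by 3.
#' @param domains Optional tibble (`domain`, `start`, `end`) in codon
#'   coordinates, carried along for plotting.
#' @return A `coverage_profile` with per-codon counts.
#' @export
exact_match_coverage <- function(reads, cds, domains = NULL) {
  if (is.data.frame(reads)) reads <- reads$sequence
  check_dna(cds)
  if (nchar(cds) %% 3 != 0) {
    stop("cds length not divisible by 3", call. = FALSE)
  }
  up <- toupper(cds)
  ncod <- nchar(up) %/% 3
  counts <- integer(ncod)
  for (r in reads) {
    r <- toupper(r)
    hits <- list()
    for (q in unique(c(r, revcomp(r)))) {
      m <- gregexpr(q, up, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      for (s in as.integer(m)) hits[[length(hits) + 1]] <- c(s - 1L, s - 1L + nchar(q))
    }
    if (length(hits) == 0) next
    hits <- unique(hits)
    for (h in hits) {
      first <- ceiling(h[1] / 3)          # first codon fully inside
      last <- (h[2] %/% 3) - 1            # last codon fully inside
      if (last >= first) counts[(first:last) + 1] <- counts[(first:last) + 1] + 1L
    }
  }
  structure(list(counts = counts, n_codons = ncod, cds = cds,
                 domains = domains),
            class = "coverage_profile")
}

#' Count covered codons in a region of a coverage profile
#'
#' @param profile An [exact_match_coverage()] result.
#' @param start,end Codon interval (0-based half-open); defaults to the
#'   whole profile.
#' @return Number of codons with at least one supporting read.
#' @export
covered_aa <- function(profile, start = 0, end = profile$n_codons) {
  stopifnot(inherits(profile, "coverage_profile"),
            start >= 0, end <= profile$n_codons, end >= start)
  if (end == start) return(0L)
  sum(profile$counts[(start + 1):end] >= 1)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d codons, %d covered (%.1f%%), max depth %d\n",
              x$n_codons, covered_aa(x), 100 * covered_aa(x) / x$n_codons,
              max(x$counts)))
  invisible(x)
}

#' In-silico primer match against a template
#'
#' Best ungapped full-length match of the primer over both orientations,
#' scored as identity over the primer length. When the match is perfect,
#' the template's in-frame peptide across the matched interval is reported
#' (frame 0 of the template, i.e. the codon structure of a CDS template).
#'
#' @param primer Primer sequence (at least 10 bases).
#' @param dna Template sequence (e.g. a CDS or genomic region).
#' @return A `primer_check`: one-row tibble with `primer`,
#'   `best_identity`, `orientation`, `match_start`, `match_end`,
#'   `matched_peptide`.
#' @export
insilico_primer_match <- function(primer, dna) {
  check_dna(primer); check_dna(dna)
  if (nchar(primer) < 10) stop("primer shorter than 10 bases", call. = FALSE)
  up_p <- toupper(primer); up_d <- toupper(dna)
  fw <- .cpp_best_ungapped(up_p, up_d)
  rv <- .cpp_best_ungapped(revcomp(up_p), up_d)
  use_rev <- rv[1] > fw[1]
  best <- if (use_rev) rv else fw
  identity <- best[1] / nchar(primer)
  ms <- best[2]; me <- best[2] + nchar(primer)
  peptide <- NA_character_
  if (!is.na(ms) && ms >= 0 && identity == 1) {
    first <- ceiling(ms / 3); last <- (me %/% 3) - 1
    if (last >= first) {
      peptide <- translate_dna(substr(up_d, first * 3 + 1, (last + 1) * 3))
    }
  }
  out <- tibble(primer = primer, best_identity = identity,
                orientation = if (use_rev) "reverse" else "forward",
                match_start = if (best[2] >= 0) best[2] else NA_integer_,
                match_end = if (best[2] >= 0) me else NA_integer_,
                matched_peptide = peptide)
  class(out) <- c("primer_check", class(out))
  out
}

#' Integrate locus, exon, domain and read evidence into a verdict
#'
#' A deterministic rule cascade over whatever evidence is available:
#' an annotated locus is `PRESENT_ANNOTATED`; recovered exons meeting the
#' forkhead-coverage threshold in a spanned or gapped region give
#' `PRESENT_UNANNOTATED`; a gapped or split region with conserved flanks
#' and no exon evidence is `LIKELY_MISSED` (the assembly, not the genome,
#' explains the absence); a cleanly spanned region with neither exons nor
#' read support is `LIKELY_ABSENT`; anything else is `INDETERMINATE`.
#' Every verdict cites the rules that fired.
#'
#' @param locus A [classify_locus()] result.
#' @param exons Optional [spliced_align()] result.
#' @param architecture Optional [detect_architecture()] result for the
#'   reference protein, supplying the forkhead interval.
#' @param coverage Optional [exact_match_coverage()] profile.
#' @param frk_interval Optional protein interval of the reference forkhead
#'   domain (taken from `architecture` when given).
#' @param thresholds List: `frk_exon_aa_min` (residues of forkhead an exon
#'   must cover to count as exon evidence), `read_min_aa` (covered codons
#'   for read support).
#' @return An `evidence_report`.
#' @export
integrate_evidence <- function(locus, exons = NULL, architecture = NULL,
                               coverage = NULL, frk_interval = NULL,
                               thresholds = list(frk_exon_aa_min = 15,
                                                 read_min_aa = 30)) {
  stopifnot(inherits(locus, "locus_assessment"))
  rationale <- character(0)
  note <- function(r) rationale <<- c(rationale, r)
  if (is.null(frk_interval) && !is.null(architecture)) {
    frk_interval <- c(architecture$frk$start, architecture$frk$end)
  }
  exon_evidence <- FALSE
  if (!is.null(exons) && nrow(exons$exons) > 0) {
    if (!is.null(frk_interval)) {
      ov <- pmin(exons$exons$pend, frk_interval[2]) -
        pmax(exons$exons$pstart, frk_interval[1])
      exon_evidence <- any(ov >= thresholds$frk_exon_aa_min)
      if (exon_evidence)
        note(sprintf("exon(s) cover >= %d aa of the reference forkhead domain",
                     thresholds$frk_exon_aa_min))
    } else {
      exon_evidence <- sum(exons$exons$pend - exons$exons$pstart) >=
        thresholds$frk_exon_aa_min
      if (exon_evidence) note("recovered exons align a substantial protein span")
    }
  }
  read_support <- !is.null(coverage) &&
    covered_aa(coverage) >= thresholds$read_min_aa
  if (read_support)
    note(sprintf("transcript reads exactly cover >= %d codons",
                 thresholds$read_min_aa))
  flanks_conserved <- all(locus$flank_evidence$present)
  verdict <- if (locus$status == "ANNOTATED") {
    note("target gene annotated between conserved flanks")
    "PRESENT_ANNOTATED"
  } else if (locus$status %in% c("SPANNED_UNANNOTATED", "GAP_IN_REGION") &&
             exon_evidence) {
    note(sprintf("region %s but spliced alignment recovers exons",
                 tolower(locus$status)))
    "PRESENT_UNANNOTATED"
  } else if (locus$status %in% c("GAP_IN_REGION", "FLANKS_SPLIT") &&
             flanks_conserved && !exon_evidence) {
    note(sprintf("region %s with conserved flanks and no recoverable exons: assembly quality explains the absence",
                 tolower(locus$status)))
    "LIKELY_MISSED"
  } else if (locus$status == "SPANNED_UNANNOTATED" && !exon_evidence &&
             !read_support) {
    note("region cleanly assembled yet no exon or read evidence found")
    "LIKELY_ABSENT"
  } else {
    note("evidence insufficient or conflicting")
    "INDETERMINATE"
  }
  structure(list(locus = locus, exons = exons, architecture = architecture,
                 coverage = coverage, verdict = verdict,
                 rationale = rationale, thresholds = thresholds),
            class = "evidence_report")
}

#' @export
print.evidence_report <- function(x, ...) {
  cat(sprintf("<evidence_report> %s: %s\n", x$locus$genome_id, x$verdict))
  cat(sprintf("  locus status: %s\n", x$locus$status))
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}
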