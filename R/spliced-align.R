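# Spliced protein-to-genome alignment (exon recovery). The dynamic program
# lives in src/spliced_align.cpp; this file prepares sequences, tries both
# strands, maps coordinates back to the forward strand and wraps results in
# a tidy object.

#' Scoring scheme for spliced alignment
#'
#' @param substitution Amino-acid substitution matrix (default BLOSUM62).
#' @param gap_open Cost of the first residue/codon of a gap (negative).
#' @param gap_extend Cost of each further gap unit (negative).
#' @param intron_penalty Flat cost of introducing an intron (negative).
#' @param min_intron Minimum intron length in bases (>= 4).
#' @param splice_donor,splice_acceptor Splice-site dinucleotides; only the
#'   canonical GT–AG model is implemented.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(substitution = blosum62(), gap_open = -12,
                           gap_extend = -2, intron_penalty = -20,
                           min_intron = 30, splice_donor = "GT",
                           splice_acceptor = "AG") {
  stopifnot(min_intron >= 4, gap_open < 0, gap_extend < 0, intron_penalty < 0)
  if (splice_donor != "GT" || splice_acceptor != "AG") {
    stop("only the canonical GT-AG splice model is implemented", call. = FALSE)
  }
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend, intron_penalty = intron_penalty,
                 min_intron = as.integer(min_intron),
                 splice_donor = splice_donor,
                 splice_acceptor = splice_acceptor),
            class = "scoring_scheme")
}

prep_dna <- function(dna, submat) {
  up <- toupper(dna)
  n <- nchar(up)
  ch <- strsplit(up, "")[[1]]
  gc_tab <- Biostrings::GENETIC_CODE
  codon_aa <- rep(-1L, n)
  if (n >= 3) {
    starts <- 1:(n - 2)
    codons <- substring(up, starts, starts + 2)
    aa <- unname(gc_tab[codons]) # NA for codons containing N
    idx <- match(aa, rownames(submat)) - 1L
    idx[is.na(idx)] <- -1L
    codon_aa[starts] <- idx
  }
  is_gt <- c(ch[-n] == "G" & ch[-1] == "T", FALSE)
  is_ag_end <- rep(FALSE, n)
  if (n >= 2) is_ag_end[3:n] <- ch[1:(n - 2)] == "A" & ch[2:(n - 1)] == "G"
  list(codon_aa = codon_aa, is_gt = is_gt, is_ag_end = is_ag_end)
}

run_one_strand <- function(pidx, dna, scheme) {
  pd <- prep_dna(dna, scheme$substitution)
  .cpp_spliced_align(pidx, pd$codon_aa, pd$is_gt, pd$is_ag_end,
                     scheme$substitution, scheme$gap_open, scheme$gap_extend,
                     scheme$intron_penalty, scheme$min_intron)
}

#' Spliced alignment of a protein against genomic DNA
#'
#' Finds the optimal chain of exons aligning the protein to the DNA (local
#' in both sequences) with codon-level matches, affine gaps, and GT–AG
#' introns of at least `min_intron` bases; codons containing N are
#' impassable, so assembly gaps can only be crossed inside introns. Both
#' strands are tried and the better one returned (forward wins ties).
#'
#' @param protein Amino-acid string (at least 5 residues).
#' @param dna Genomic DNA string; may contain N runs.
#' @param scheme A [scoring_scheme()].
#' @return A `spliced_alignment` with an exon table (`gstart`, `gend`
#'   forward-strand genomic, `pstart`, `pend` protein, `phase`; 0-based
#'   half-open), `strand`, `score` and protein `coverage`.
#' @export
spliced_align <- function(protein, dna, scheme = scoring_scheme()) {
  if (nchar(protein) < 5) stop("protein shorter than 5 aa", call. = FALSE)
  if (nchar(dna) < 3) stop("empty or too-short dna", call. = FALSE)
  check_dna(dna)
  pidx <- match(strsplit(toupper(protein), "")[[1]],
                rownames(scheme$substitution)) - 1L
  if (anyNA(pidx)) stop("protein contains residues absent from the scoring matrix",
                        call. = FALSE)
  n <- nchar(dna)
  fw <- run_one_strand(pidx, dna, scheme)
  rv <- run_one_strand(pidx, revcomp(dna), scheme)
  use_rev <- rv$score > fw$score
  res <- if (use_rev) rv else fw
  em <- res$exons
  if (nrow(em) > 0) {
    ex <- tibble(gstart = em[, 1], gend = em[, 2],
                 pstart = em[, 3], pend = em[, 4], phase = 0L)
    if (use_rev) {
      ex <- ex |> mutate(tmp = n - .data$gend, gend = n - .data$gstart,
                         gstart = .data$tmp) |> select(-"tmp") |>
        arrange(.data$gstart)
    }
  } else {
    ex <- tibble(gstart = integer(0), gend = integer(0), pstart = integer(0),
                 pend = integer(0), phase = integer(0))
  }
  structure(list(exons = ex, strand = if (use_rev) "-" else "+",
                 score = res$score,
                 coverage = res$n_aligned / nchar(protein),
                 protein_length = nchar(protein), dna_length = n,
                 scheme = scheme[c("gap_open", "gap_extend", "intron_penalty",
                                   "min_intron")],
                 curation_flags = character(0)),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> %d exon(s), strand %s, score %.0f, coverage %.1f%%\n",
              nrow(x$exons), x$strand, x$score, 100 * x$coverage))
  if (nrow(x$exons) > 0) print(as.data.frame(x$exons))
  if (length(x$curation_flags) > 0)
    cat("  curation flags:", paste(x$curation_flags, collapse = "; "), "\n")
  invisible(x)
}

# score of a fixed, gap-free exon chain (used when re-scoring after
# boundary curation)
rescore_chain <- function(protein, dna, exons, scheme) {
  up <- toupper(dna)
  total <- 0
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    aa <- translate_dna(substr(up, e$gstart + 1, e$gend))
    res <- strsplit(substr(protein, e$pstart + 1, e$pend), "")[[1]]
    cod <- strsplit(aa, "")[[1]]
    if (length(res) != length(cod)) return(NA_real_)
    total <- total + sum(scheme$substitution[cbind(res, cod)])
  }
  total + (nrow(exons) - 1) * scheme$intron_penalty
}

#' Curate exon boundaries against a trusted reference exon structure
#'
#' Exon junctions whose protein position lies within two residues (six
#' bases) of a reference breakpoint are snapped to the splice site
#' consistent with that breakpoint, provided a valid GT donor and AG
#' acceptor exist there and the intron stays at least `min_intron` long.
#' The score is recomputed; protein coverage never decreases (the snap only
#' moves residues between adjacent exons). Junctions that cannot be snapped
#' are left unchanged and recorded in `curation_flags`.
#'
#' @param alignment A [spliced_align()] result on the forward strand.
#' @param reference_exons Tibble with protein intervals (`pstart`, `pend`)
#'   of the trusted homolog's exons; intervals must not overlap.
#' @param protein,dna The sequences the alignment was computed from.
#' @param scheme The [scoring_scheme()] used.
#' @return The curated `spliced_alignment`.
#' @export
curate_boundaries <- function(alignment, reference_exons, protein, dna,
                              scheme = scoring_scheme()) {
  stopifnot(inherits(alignment, "spliced_alignment"))
  ref <- as_tibble(reference_exons) |> arrange(.data$pstart)
  if (nrow(ref) > 1 && any(ref$pstart[-1] < ref$pend[-nrow(ref)])) {
    stop("reference exon structure has overlapping protein intervals",
         call. = FALSE)
  }
  if (alignment$strand == "-") dna <- revcomp(dna)
  ex <- alignment$exons
  if (alignment$strand == "-") {
    n <- alignment$dna_length
    ex <- ex |> mutate(tmp = n - .data$gend, gend = n - .data$gstart,
                       gstart = .data$tmp) |> select(-"tmp") |>
      arrange(.data$gstart)
  }
  flags <- alignment$curation_flags
  breakpoints <- ref$pend[-nrow(ref)]
  up <- toupper(dna)
  if (nrow(ex) >= 2 && length(breakpoints) > 0) {
    for (t in seq_len(nrow(ex) - 1)) {
      p_obs <- ex$pend[t]
      b <- breakpoints[which.min(abs(breakpoints - p_obs))]
      delta <- b - p_obs
      if (delta == 0 || abs(delta) > 2) next
      new_dend <- ex$gend[t] + 3 * delta
      new_astart <- ex$gstart[t + 1] + 3 * delta
      ok <- new_dend > ex$gstart[t] && new_astart < ex$gend[t + 1] &&
        new_astart - new_dend >= alignment$scheme$min_intron &&
        new_dend + 2 <= nchar(up) && new_astart >= 2 &&
        substr(up, new_dend + 1, new_dend + 2) == "GT" &&
        substr(up, new_astart - 1, new_astart) == "AG"
      if (!ok) {
        flags <- c(flags, sprintf("junction %d: no valid GT-AG site within window of reference breakpoint %d", t, b))
        next
      }
      ex$gend[t] <- new_dend; ex$pend[t] <- b
      ex$gstart[t + 1] <- new_astart; ex$pstart[t + 1] <- b
    }
  }
  new_score <- rescore_chain(protein, up, ex, scheme)
  if (alignment$strand == "-") {
    n <- alignment$dna_length
    ex <- ex |> mutate(tmp = n - .data$gend, gend = n - .data$gstart,
                       gstart = .data$tmp) |> select(-"tmp") |>
      arrange(.data$gstart)
  }
  alignment$exons <- ex
  if (!is.na(new_score)) alignment$score <- new_score
  alignment$curation_flags <- flags
  alignment
}

#' Per-exon report with overlapped domains
#'
#' @param alignment A [spliced_align()] result.
#' @param domain_map Tibble with columns `domain`, `start`, `end` (protein
#'   coordinates, 0-based half-open).
#' @return A tibble with one row per exon: genomic and protein intervals,
#'   aligned residue count and the overlapped domain names.
#' @export
exon_report <- function(alignment, domain_map = NULL) {
  stopifnot(inherits(alignment, "spliced_alignment"))
  ex <- alignment$exons
  if (nrow(ex) == 0) {
    return(tibble(exon = integer(0), gstart = integer(0), gend = integer(0),
                  pstart = integer(0), pend = integer(0),
                  aligned_aa = integer(0), domains = character(0)))
  }
  doms <- vapply(seq_len(nrow(ex)), function(i) {
    if (is.null(domain_map)) return("")
    hit <- domain_map |> filter(!is.na(.data$start),
                                .data$start < ex$pend[i],
                                .data$end > ex$pstart[i])
    paste(hit$domain, collapse = ",")
  }, character(1))
  ex |> mutate(exon = row_number(), aligned_aa = .data$pend - .data$pstart,
               domains = doms) |>
    select("exon", "gstart", "gend", "pstart", "pend", "aligned_aa",
           "domains")
}
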