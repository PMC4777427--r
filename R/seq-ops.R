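# Sequence primitives. All coordinates in this package are 0-based,
# half-open; GFF's 1-based inclusive convention exists only at the I/O
# boundary. Lowercase bases carry the soft-mask (repeat) state; N/n runs are
# assembly gaps. Ambiguity codes other than N are rejected.

.valid_dna_chars <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")

check_dna <- function(dna, what = "sequence") {
  stopifnot(is.character(dna), length(dna) == 1)
  bad <- setdiff(unique(strsplit(dna, "")[[1]]), .valid_dna_chars)
  if (length(bad) > 0) {
    stop(sprintf("non-IUPAC (or unsupported ambiguity) character(s) in %s: %s",
                 what, paste(bad, collapse = " ")), call. = FALSE)
  }
  invisible(dna)
}

check_region <- function(len, start, end) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (end <= start) stop("empty region [", start, ",", end, ")", call. = FALSE)
  if (start < 0 || end > len) {
    stop(sprintf("region [%d,%d) out of bounds for length-%d sequence",
                 start, end, len), call. = FALSE)
  }
  invisible(NULL)
}

#' Reverse complement of a DNA sequence
#'
#' Case is preserved, so soft-mask state survives the operation. Only
#' A/C/G/T/N (either case) are accepted.
#'
#' @param dna A single DNA string.
#' @return The reverse complement string.
#' @examples
#' revcomp("TTGTGCAGGCTCAGGTTG")
#' @export
revcomp <- function(dna) {
  check_dna(dna)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", dna)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Translate DNA to protein in a fixed frame
#'
#' Uses the standard genetic code. Codons containing N translate to `X`;
#' stop codons are rendered `*`. Trailing bases that do not fill a codon are
#' dropped, so the protein has `floor((nchar(dna) - frame) / 3)` residues.
#'
#' @param dna A single DNA string (case-insensitive).
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return The translated protein string.
#' @examples
#' translate_dna("CAACCTGAGCCTGCACAA", frame = 1) # "NLSLH" plus nothing
#' @export
translate_dna <- function(dna, frame = 0) {
  check_dna(dna)
  stopifnot(frame %in% 0:2)
  s <- toupper(substring(dna, frame + 1))
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  starts <- (seq_len(n_codon) - 1) * 3 + 1
  codons <- substring(s, starts, starts + 2)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  paste(aa, collapse = "")
}

#' GC fraction of a sequence region
#'
#' Computed as (G+C) over unambiguous (non-N) bases, counting soft-masked
#' lowercase bases. Returns `NA` when the region contains no unambiguous
#' base (e.g. an all-N assembly gap).
#'
#' @param seq A single DNA string.
#' @param start,end 0-based half-open region; defaults to the whole sequence.
#' @return GC fraction in `[0, 1]`, or `NA`.
#' @export
gc_fraction <- function(seq, start = 0, end = nchar(seq)) {
  check_dna(seq)
  check_region(nchar(seq), start, end)
  s <- toupper(substr(seq, start + 1, end))
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  unamb <- sum(counts[c("A", "C", "G", "T")])
  if (unamb == 0) return(NA_real_)
  unname((counts[["G"]] + counts[["C"]]) / unamb)
}

#' Repeat-masked fraction of a sequence region
#'
#' Fraction of bases in the region that are lowercase (soft-masked).
#'
#' @inheritParams gc_fraction
#' @return Masked fraction in `[0, 1]`.
#' @export
masked_fraction <- function(seq, start = 0, end = nchar(seq)) {
  check_dna(seq)
  check_region(nchar(seq), start, end)
  s <- substr(seq, start + 1, end)
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% c("a", "c", "g", "t", "n"))
}

#' Assembly gap runs of a sequence
#'
#' Maximal runs of N/n, returned as sorted disjoint 0-based half-open
#' intervals.
#'
#' @param seq A single DNA string.
#' @return A tibble with columns `start`, `end`, `width`.
#' @export
gap_runs <- function(seq) {
  check_dna(seq)
  ch <- strsplit(toupper(seq), "")[[1]]
  r <- rle(ch == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep],
         width = r$lengths[keep])
}

#' Scaffold N50
#'
#' The smallest length L such that scaffolds of length at least L together
#' contain at least half the assembly.
#'
#' @param lengths Positive scaffold lengths.
#' @return The N50 in bases.
#' @examples
#' n50(c(1, 2, 3, 4, 10)) # 10
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1]]
}

#' Whole-assembly summary statistics
#'
#' @param record An [assembly_record()].
#' @return A one-row tibble with `n50`, `total_length`, `n_scaffolds`,
#'   `gc_fraction`, `masked_fraction` and `gap_fraction`.
#' @export
assembly_stats <- function(record) {
  stopifnot(inherits(record, "assembly_record"))
  sc <- record$scaffolds
  if (is.null(sc) || nrow(sc) == 0) stop("record carries no scaffolds", call. = FALSE)
  total <- sum(sc$length)
  ch <- strsplit(toupper(paste(sc$sequence, collapse = "")), "")[[1]]
  gap <- sum(ch == "N")
  gc <- sum(ch %in% c("G", "C"))
  unamb <- length(ch) - gap
  ml <- vapply(sc$sequence, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("a", "c", "g", "t", "n"))
  }, numeric(1))
  tibble(
    n50 = n50(sc$length),
    total_length = total,
    n_scaffolds = nrow(sc),
    gc_fraction = if (unamb > 0) gc / unamb else NA_real_,
    masked_fraction = sum(ml) / total,
    gap_fraction = gap / total
  )
}
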