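# FoxP-style domain architecture and clade signature-residue analysis:
# ProR proline enrichment, leucine-zipper motif scanning, template-anchored
# ZF/FRK location, reference-anchored alignment, and signature columns.

#' Proline fraction of a protein region
#'
#' Count of P over the region length; alignment gaps (`-`) are excluded
#' from the denominator, `X` is included.
#'
#' @param protein Amino-acid string (may contain `-` if aligned).
#' @param start,end 0-based half-open region; defaults to the whole
#'   sequence.
#' @return Fraction in `[0, 1]`.
#' @export
proline_fraction <- function(protein, start = 0, end = nchar(protein)) {
  check_region(nchar(protein), start, end)
  ch <- strsplit(substr(protein, start + 1, end), "")[[1]]
  ch <- ch[ch != "-"]
  if (length(ch) == 0) stop("region contains only gaps", call. = FALSE)
  sum(ch == "P") / length(ch)
}

#' Build a spaced-anchor motif pattern
#'
#' Anchors are sets of allowed residues separated by fixed-length spacers,
#' e.g. the leucine-zipper consensus `[VI]-x(6)-L-x(6)-L-x(6)-L`.
#'
#' @param anchors List of character vectors of allowed residues.
#' @param spacers Integer spacer lengths between consecutive anchors.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(anchors, spacers) {
  stopifnot(length(spacers) == length(anchors) - 1, all(spacers >= 0))
  len <- length(anchors) + sum(spacers)
  regex <- paste0(vapply(seq_along(anchors), function(i) {
    a <- paste0("[", paste(anchors[[i]], collapse = ""), "]")
    if (i < length(anchors)) paste0(a, sprintf(".{%d}", spacers[i])) else a
  }, character(1)), collapse = "")
  structure(list(anchors = anchors, spacers = spacers, length = len,
                 regex = regex),
            class = "motif_pattern")
}

#' Leucine-zipper consensus pattern
#'
#' The `V-x(6)-L-x(6)-L-x(6)-L` consensus; `first` widens the first anchor
#' (ground tit and coelacanth carry I instead of V).
#'
#' @param first Residues allowed at the first anchor position.
#' @return A [motif_pattern()].
#' @export
lz_pattern <- function(first = c("V", "I")) {
  motif_pattern(list(first, "L", "L", "L"), c(6, 6, 6))
}

#' Find all motif matches in a protein
#'
#' Overlapping matches are reported; anchors are compared by identity.
#'
#' @param protein Amino-acid string.
#' @param pattern A [motif_pattern()].
#' @return A tibble of 0-based half-open `start`, `end` intervals (empty
#'   when there is no match).
#' @export
find_motif <- function(protein, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  m <- gregexpr(paste0("(?=", pattern$regex, ")"), protein, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(start = integer(0), end = integer(0)))
  tibble(start = as.integer(m) - 1L,
         end = as.integer(m) - 1L + pattern$length)
}

# locate a template within a protein window by global-local alignment;
# returns 0-based interval and identity over the template span
locate_template <- function(template, protein, lo = 0, hi = nchar(protein)) {
  if (hi - lo < 3) return(list(identity = 0, start = NA_integer_, end = NA_integer_))
  win <- substr(protein, lo + 1, hi)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(template), Biostrings::AAString(win),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 2,
    type = "global-local")
  pm <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  sm <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  ident <- sum(pm == sm & pm != "-") / nchar(template)
  s <- Biostrings::start(Biostrings::subject(pa)) - 1L + lo
  e <- Biostrings::end(Biostrings::subject(pa)) + lo
  list(identity = ident, start = as.integer(s), end = as.integer(e))
}

#' Detect FoxP-style domain architecture
#'
#' Locates the forkhead (FRK) domain and, when present, the zinc finger
#' (ZF) by template-anchored alignment with a per-domain identity floor;
#' the leucine zipper (LZ) by its consensus motif (falling back to the
#' template when the motif is degenerate). The N-terminal (ProR) region
#' runs from the N-terminus to the ZF, or to the LZ when no ZF is
#' detectable, and carries its proline fraction. A sequence in which no
#' FRK can be located is not classifiable as FoxP-family and raises an
#' error.
#'
#' @param protein Amino-acid string.
#' @param templates Domain templates (see [foxp_templates()]).
#' @param identity_floor Minimum identity over the template span for a
#'   domain to count as present.
#' @return A `domain_architecture` object.
#' @export
detect_architecture <- function(protein, templates = foxp_templates(),
                                identity_floor = 0.35) {
  frk <- locate_template(templates$frk, protein)
  if (frk$identity < identity_floor) {
    stop("no forkhead (FRK) domain locatable: sequence is not classifiable as FoxP-family",
         call. = FALSE)
  }
  lz_hits <- find_motif(substr(protein, 1, frk$start), lz_pattern())
  if (nrow(lz_hits) > 0) {
    s <- max(lz_hits$start) # the match nearest the forkhead domain
    lz <- list(start = s, end = s + lz_pattern()$length)
    lz_source <- "motif"
  } else {
    loc <- locate_template(templates$lz, protein, 0, frk$start)
    if (loc$identity >= identity_floor) {
      lz <- list(start = loc$start, end = loc$end); lz_source <- "template"
    } else { lz <- list(start = NA_integer_, end = NA_integer_); lz_source <- "none" }
  }
  zf_hi <- if (!is.na(lz$start)) lz$start else frk$start
  zf <- locate_template(templates$zf, protein, 0, zf_hi)
  zf_present <- zf$identity >= identity_floor
  nterm_end <- if (zf_present) zf$start else if (!is.na(lz$start)) lz$start else frk$start
  pror_frac <- if (nterm_end > 0) proline_fraction(protein, 0, nterm_end) else NA_real_
  lz_first <- if (!is.na(lz$start)) substr(protein, lz$start + 1, lz$start + 1)
              else NA_character_
  structure(list(
    protein_length = nchar(protein),
    pror = list(start = 0L, end = as.integer(nterm_end),
                proline_fraction = pror_frac),
    zf = list(present = zf_present,
              start = if (zf_present) zf$start else NA_integer_,
              end = if (zf_present) zf$end else NA_integer_,
              identity = zf$identity),
    lz = list(start = lz$start, end = lz$end, source = lz_source,
              first_position_residue = lz_first),
    frk = list(start = frk$start, end = frk$end, identity = frk$identity),
    n_terminal_region = c(0L, as.integer(nterm_end))),
    class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<domain_architecture> %d aa; ProR [0,%d) proline %.1f%%; ZF %s; LZ %s (first %s); FRK [%d,%d)\n",
              x$protein_length, x$pror$end, 100 * x$pror$proline_fraction,
              if (x$zf$present) sprintf("[%d,%d)", x$zf$start, x$zf$end) else "absent",
              if (!is.na(x$lz$start)) sprintf("[%d,%d)", x$lz$start, x$lz$end) else "absent",
              x$lz$first_position_residue %||% "?", x$frk$start, x$frk$end))
  invisible(x)
}

#' Reference-anchored multiple alignment
#'
#' Aligns every sequence globally against the baseline (affine gaps,
#' BLOSUM62) and projects the result onto baseline columns, the standard
#' star-alignment substitute for a full multiple aligner when one sequence
#' is a trusted reference. Columns are indexed by baseline position;
#' insertions relative to the baseline are dropped (counted per sequence).
#' `X` runs are treated as missing data and masked.
#'
#' @param sequences Named character vector of protein sequences, or a
#'   tibble with `id` and `sequence` columns.
#' @param baseline_id Name of the baseline sequence.
#' @return An `anchored_alignment` with a character matrix (`rows` =
#'   sequences x baseline columns), a logical `missing` mask and the
#'   0-based `column_map` of baseline positions.
#' @export
anchor_align <- function(sequences, baseline_id) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  stopifnot(length(sequences) >= 2, baseline_id %in% names(sequences))
  if (any(nchar(sequences) == 0)) stop("empty sequence", call. = FALSE)
  base <- sequences[[baseline_id]]
  L <- nchar(base)
  ids <- names(sequences)
  mat <- matrix("-", nrow = length(ids), ncol = L, dimnames = list(ids, NULL))
  ins <- setNames(integer(length(ids)), ids)
  mat[baseline_id, ] <- strsplit(base, "")[[1]]
  for (id in setdiff(ids, baseline_id)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sequences[[id]]), Biostrings::AAString(base),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 2,
      type = "global")
    pm <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
    sm <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
    keep <- sm != "-"
    ins[id] <- sum(!keep)
    mat[id, ] <- pm[keep]
  }
  structure(list(baseline_id = baseline_id, matrix = mat,
                 missing = mat == "X", insertions_dropped = ins,
                 column_map = 0:(L - 1)),
            class = "anchored_alignment")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("<anchored_alignment> %d sequences x %d baseline columns (baseline %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$baseline_id))
  invisible(x)
}

#' Clade signature residues from an anchored alignment
#'
#' A signature column is one where every ingroup member with data carries
#' the same residue (up to `max_ingroup_mismatch` exceptions) and that
#' residue does not occur at the homologous column in any exclusion-set
#' sequence with data. Missing-data columns (masked `X` runs) count as
#' agreeing as long as at least one ingroup member has data.
#'
#' @param alignment An [anchor_align()] result.
#' @param ingroup_ids Sequence ids forming the clade of interest.
#' @param exclusion_sets Named list of id vectors the signature must be
#'   absent from (e.g. the FoxP1/2/4 paralogue rows, optionally also the
#'   non-clade FoxP3s).
#' @param reference_signature Optional tibble (`position`, `residue`);
#'   overlap of the discovered signature with it is reported.
#' @param max_ingroup_mismatch Allowed number of disagreeing ingroup
#'   members per column (0 = strict identity).
#' @return A `signature_result` with the column table and counts.
#' @export
signature_residues <- function(alignment, ingroup_ids, exclusion_sets,
                               reference_signature = NULL,
                               max_ingroup_mismatch = 0) {
  stopifnot(inherits(alignment, "anchored_alignment"))
  if (length(ingroup_ids) == 0) stop("ingroup is empty", call. = FALSE)
  mat <- alignment$matrix
  stopifnot(all(ingroup_ids %in% rownames(mat)))
  excl_ids <- unique(unlist(exclusion_sets))
  stopifnot(all(excl_ids %in% rownames(mat)))
  has_data <- function(v) v != "-" & v != "X"
  cols <- integer(0); res <- character(0)
  for (c in seq_len(ncol(mat))) {
    ing <- mat[ingroup_ids, c]
    ing <- ing[has_data(ing)]
    if (length(ing) == 0) next
    tabu <- sort(table(ing), decreasing = TRUE)
    r <- names(tabu)[1]
    if (length(ing) - tabu[[1]] > max_ingroup_mismatch) next
    exc <- mat[excl_ids, c, drop = TRUE]
    exc <- exc[has_data(exc)]
    if (r %in% exc) next
    cols <- c(cols, alignment$column_map[c]); res <- c(res, r)
  }
  columns <- tibble(position = cols, ingroup_residue = res)
  overlap <- NA_integer_
  if (!is.null(reference_signature)) {
    ref <- as_tibble(reference_signature)
    overlap <- nrow(dplyr::inner_join(
      columns, ref, by = c("position" = "position",
                           "ingroup_residue" = "residue")))
  }
  structure(list(columns = columns, n_signature = nrow(columns),
                 overlap_with_reference_signature = overlap,
                 ingroup_ids = ingroup_ids,
                 exclusion_ids = excl_ids),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %d signature column(s)", x$n_signature))
  if (!is.na(x$overlap_with_reference_signature))
    cat(sprintf("; %d shared with the reference signature",
                x$overlap_with_reference_signature))
  cat("\n")
  invisible(x)
}
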