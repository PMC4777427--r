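# A small reader (and matching writer used by the simulator) for
# FGENESH-style ab-initio gene prediction reports: a coordinate table of
# CDS segments followed by the predicted protein. Predictions are parsed,
# never re-derived.

#' Write an FGENESH-style prediction report
#'
#' Emits the coordinate table (CDSf/CDSi/CDSl rows, 1-based inclusive) and
#' predicted protein of a simulated gene, in the classic ab-initio
#' predictor text layout. Used to exercise [read_fgenesh()] offline.
#'
#' @param truth A `ground_truth` from [simulate_neighborhood()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fgenesh_like <- function(truth, path) {
  ex <- truth$target_exons
  k <- nrow(ex)
  feature <- if (k == 1) "CDSo" else c("CDSf", rep("CDSi", k - 2), "CDSl")
  lines <- c(
    " FGENESH-like prediction of potential genes (synthetic report)",
    sprintf(" Seq name: scaffold_1  Length of sequence: %d",
            max(truth$genes$end)),
    " Number of predicted genes 1",
    "  G Str   Feature   Start        End    Score",
    sprintf("  1 +     %s   %8d - %8d   %6.2f", feature, ex$start + 1, ex$end,
            10 + seq_len(k) / 10),
    "",
    sprintf(">FGENESH-like:[mRNA]  1  %d exon(s)   %d - %d   %d aa, chain +",
            k, min(ex$start) + 1, max(ex$end), nchar(truth$target_protein)),
    substring(truth$target_protein,
              seq(1, nchar(truth$target_protein), 60),
              pmin(nchar(truth$target_protein),
                   seq(1, nchar(truth$target_protein), 60) + 59)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an FGENESH-style prediction report
#'
#' Parses the CDS coordinate rows and the predicted protein.
#'
#' @param path Path to the report.
#' @return A list: `exons` (0-based half-open tibble), `n_exons`,
#'   `protein`, `protein_length`.
#' @export
read_fgenesh <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  cds <- grep("CDS[fiol]", lines, value = TRUE)
  if (length(cds) == 0) stop("no CDS rows found in ", path, call. = FALSE)
  m <- regmatches(cds, regexec("CDS[fiol]\\s+(\\d+)\\s*-\\s*(\\d+)", cds))
  starts <- vapply(m, function(x) as.integer(x[2]), integer(1))
  ends <- vapply(m, function(x) as.integer(x[3]), integer(1))
  hdr <- grep("aa, chain", lines)
  protein <- ""
  if (length(hdr) == 1 && hdr < length(lines)) {
    body <- lines[(hdr + 1):length(lines)]
    stop_at <- which(grepl("^>", body))[1]
    if (!is.na(stop_at)) body <- body[seq_len(stop_at - 1)]
    protein <- gsub("\\s", "", paste(body, collapse = ""))
  }
  list(exons = tibble(start = starts - 1L, end = ends),
       n_exons = length(starts), protein = protein,
       protein_length = nchar(protein))
}
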