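# Standard-format I/O: case-preserving FASTA via Biostrings, GFF3 via
# rtracklayer, and the per-genome metadata TSV. GFF coordinates are 1-based
# inclusive on disk and converted to 0-based half-open exactly once, here.

#' Assembly record
#'
#' Bundles the scaffolds, gene annotations and assembly metadata of one
#' genome. Scaffolds may be omitted for annotation-only surveys.
#'
#' @param genome_id Genome identifier.
#' @param scaffolds Tibble with columns `id`, `sequence` (may be `NULL`).
#' @param annotations Tibble with one row per exon: `gene_id`, `scaffold_id`,
#'   `strand` ("+"/"-"), `biotype` ("gene" or "pseudogene"), `exon_rank`,
#'   `start`, `end` (0-based half-open).
#' @param coverage_x Fold coverage (optional).
#' @param n_scaffolds Declared scaffold count (optional; defaults to the
#'   number of scaffolds supplied).
#' @param declared_n50 Declared scaffold N50 in bases (optional).
#' @return An `assembly_record` object.
#' @export
assembly_record <- function(genome_id, scaffolds = NULL, annotations = NULL,
                            coverage_x = NA_real_, n_scaffolds = NULL,
                            declared_n50 = NA_real_) {
  if (!is.null(scaffolds)) {
    stopifnot(all(c("id", "sequence") %in% names(scaffolds)))
    scaffolds <- as_tibble(scaffolds)
    scaffolds$length <- nchar(scaffolds$sequence)
    if (any(scaffolds$length == 0)) stop("zero-length scaffold", call. = FALSE)
    if (anyDuplicated(scaffolds$id)) stop("duplicate scaffold ids", call. = FALSE)
  }
  if (is.null(annotations)) {
    annotations <- tibble(gene_id = character(), scaffold_id = character(),
                          strand = character(), biotype = character(),
                          exon_rank = integer(), start = integer(), end = integer())
  }
  annotations <- as_tibble(annotations)
  if (is.null(n_scaffolds)) {
    n_scaffolds <- if (!is.null(scaffolds)) nrow(scaffolds) else NA_integer_
  }
  rec <- structure(list(genome_id = genome_id, scaffolds = scaffolds,
                        annotations = annotations,
                        metadata = list(coverage_x = coverage_x,
                                        n_scaffolds = n_scaffolds,
                                        declared_n50 = declared_n50)),
                   class = "assembly_record")
  validate_assembly_record(rec)
}

validate_assembly_record <- function(rec) {
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    stopifnot(all(ann$strand %in% c("+", "-")),
              all(ann$end > ann$start), all(ann$start >= 0))
    if (!is.null(rec$scaffolds)) {
      miss <- setdiff(unique(ann$scaffold_id), rec$scaffolds$id)
      if (length(miss) > 0) {
        stop("annotation references unknown scaffold(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      len <- setNames(rec$scaffolds$length, rec$scaffolds$id)
      if (any(ann$end > len[ann$scaffold_id])) {
        stop("exon beyond scaffold bounds", call. = FALSE)
      }
    }
    by_gene <- split(ann, paste(ann$gene_id, ann$scaffold_id))
    for (g in by_gene) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
        stop("overlapping exons within gene ", g$gene_id[1], call. = FALSE)
      }
    }
  }
  rec
}

#' @export
print.assembly_record <- function(x, ...) {
  n_sc <- if (is.null(x$scaffolds)) x$metadata$n_scaffolds else nrow(x$scaffolds)
  cat(sprintf("<assembly_record> %s: %s scaffold(s), %d gene(s) annotated\n",
              x$genome_id, n_sc %||% "?",
              length(unique(x$annotations$gene_id))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a FASTA file into a scaffold table
#'
#' Case (soft-mask state) is preserved. Malformed input (a record body before
#' any header, or a header with an empty body) raises an error naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  nonblank <- nzchar(trimws(lines))
  first_real <- which(nonblank)[1]
  if (is.na(first_real)) stop("empty FASTA file: ", path, call. = FALSE)
  if (!hdr[first_real]) {
    stop(sprintf("FASTA parse error at line %d: sequence before any '>' header",
                 first_real), call. = FALSE)
  }
  rec <- cumsum(hdr)
  for (h in which(hdr)) {
    body <- lines[rec == rec[h]][-1]
    if (sum(nchar(trimws(body))) == 0) {
      stop(sprintf("FASTA parse error at line %d: record '%s' has no sequence",
                   h, sub("^>", "", lines[h])), call. = FALSE)
    }
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- unname(as.character(ss))
  tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write a scaffold table to FASTA
#'
#' @param scaffolds Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (fixed so round trips are byte-stable).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(scaffolds, path, width = 70) {
  ss <- Biostrings::BStringSet(setNames(scaffolds$sequence, scaffolds$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Reads gene/mRNA/exon features with ID/Parent linkage and converts to the
#' internal 0-based half-open convention (one row per exon). Exons whose
#' Parent chain does not resolve to a gene raise an error listing the
#' feature.
#'
#' @param path Path to a GFF3 file.
#' @return An annotation tibble (see [assembly_record()]).
#' @export
read_gff <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (is.null(df$ID)) df$ID <- rep(NA_character_, nrow(df))
  df$ID <- as.character(df$ID)
  parent <- vapply(as.list(df$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  df$parent <- parent
  id2row <- match(df$parent, df$ID)
  genes <- df[df$type == "gene", ]
  is_exon <- df$type == "exon"
  if (!any(is_exon)) {
    return(tibble(gene_id = character(), scaffold_id = character(),
                  strand = character(), biotype = character(),
                  exon_rank = integer(), start = integer(), end = integer()))
  }
  exon_gene <- character(sum(is_exon))
  exi <- which(is_exon)
  for (k in seq_along(exi)) {
    i <- exi[k]
    cur <- i
    repeat {
      pr <- id2row[cur]
      if (is.na(pr)) {
        stop("exon without resolvable gene parent: ",
             sprintf("%s:%d-%d (Parent=%s)", df$seqnames[i], df$start[i],
                     df$end[i], df$parent[i] %||% "<none>"), call. = FALSE)
      }
      if (df$type[pr] == "gene") { exon_gene[k] <- df$ID[pr]; break }
      cur <- pr
    }
  }
  bt <- setNames(as.character(genes$biotype %||% rep("gene", nrow(genes))), genes$ID)
  ex <- df[is_exon, ]
  out <- tibble(
    gene_id = sub("^gene-", "", exon_gene),
    scaffold_id = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    biotype = unname(bt[exon_gene]) %||% "gene",
    start = ex$start - 1L, # GFF 1-based inclusive -> 0-based half-open
    end = ex$end
  )
  out$biotype[is.na(out$biotype)] <- "gene"
  out <- out |> arrange(.data$scaffold_id, .data$gene_id, .data$start) |>
    group_by(.data$gene_id, .data$scaffold_id) |>
    mutate(exon_rank = row_number()) |> ungroup() |>
    select("gene_id", "scaffold_id", "strand", "biotype", "exon_rank",
           "start", "end")
  out
}

#' Write gene annotations to GFF3
#'
#' Emits a gene, an mRNA and exon features per gene, converting back to
#' GFF's 1-based inclusive coordinates.
#'
#' @param annotations An annotation tibble (see [assembly_record()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotations, path) {
  ann <- as_tibble(annotations) |> arrange(.data$scaffold_id, .data$start)
  genes <- ann |> group_by(.data$gene_id, .data$scaffold_id, .data$strand,
                           .data$biotype) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$scaffold_id, .data$start)
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- paste0("gene-", g$gene_id)
    rid <- paste0("rna-", g$gene_id)
    ex <- ann |> filter(.data$gene_id == g$gene_id,
                        .data$scaffold_id == g$scaffold_id)
    rows[[length(rows) + 1]] <- data.frame(
      seqnames = g$scaffold_id,
      start = c(g$start, g$start, ex$start) + 1L,
      end = c(g$end, g$end, ex$end),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", nrow(ex))),
      ID = c(gid, rid, rep(NA_character_, nrow(ex))),
      parent = c(NA_character_, gid, rep(rid, nrow(ex))),
      biotype = c(g$biotype, rep(NA_character_, 1 + nrow(ex)))
    )
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    Parent = S4Vectors::unname(IRanges::CharacterList(
      lapply(df$parent, function(p) if (is.na(p)) character(0) else p))),
    biotype = df$biotype)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an assembly metadata table
#'
#' Tab-separated with columns `genome_id`, `coverage_x`, `n_scaffolds`,
#' `n50`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_assembly_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    genome_id = readr::col_character(),
    coverage_x = readr::col_double(),
    n_scaffolds = readr::col_double(),
    n50 = readr::col_double()
  ))
}

#' Reverse-complement a whole assembly record
#'
#' Flips every scaffold and remaps all annotations; used to check that locus
#' classification is strand-symmetric.
#'
#' @param record An [assembly_record()].
#' @return The flipped record.
#' @export
revcomp_record <- function(record) {
  stopifnot(inherits(record, "assembly_record"), !is.null(record$scaffolds))
  len <- setNames(record$scaffolds$length, record$scaffolds$id)
  sc <- record$scaffolds
  sc$sequence <- vapply(sc$sequence, revcomp, character(1), USE.NAMES = FALSE)
  ann <- record$annotations
  if (nrow(ann) > 0) {
    L <- len[ann$scaffold_id]
    new_start <- L - ann$end
    ann$end <- unname(L - ann$start)
    ann$start <- unname(new_start)
    ann$strand <- ifelse(ann$strand == "+", "-", "+")
    ann <- ann |> arrange(.data$scaffold_id, .data$gene_id, .data$start) |>
      group_by(.data$gene_id, .data$scaffold_id) |>
      mutate(exon_rank = row_number()) |> ungroup()
  }
  assembly_record(record$genome_id, sc, ann,
                  coverage_x = record$metadata$coverage_x,
                  n_scaffolds = record$metadata$n_scaffolds,
                  declared_n50 = record$metadata$declared_n50)
}
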