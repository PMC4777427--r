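# Synthetic archosaur-like gene neighbourhoods with known ground truth.
# The generator emulates the study conditions of the avian foxp3 case: the
# conserved gene order naa10(+), ppp1r3f(-), foxp3(+), ccdc22(-), cacna1f(+)
# on one scaffold, elevated GC (66%) in the region hosting the target gene,
# soft-masked repeat tracts, a planted multi-exon target (298 aa over 11
# exons by default, FoxP-style domain layout), and GC-linked assembly
# fragmentation into scaffolds and N-gap runs.

.species_presets <- list(
  ground_tit       = list(length = 298L, n_term = 131L, pror = 0.252,
                          zf = "absent", lz_first = "I"),
  mouse            = list(length = 277L, n_term = 100L, pror = 0.300,
                          zf = "present", lz_first = "V"),
  american_alligator = list(length = 302L, n_term = 133L, pror = 0.203,
                          zf = "absent", lz_first = "V"),
  chinese_alligator  = list(length = 291L, n_term = 128L, pror = 0.219,
                          zf = "absent", lz_first = "V"),
  gharial          = list(length = 186L, n_term = 55L, pror = 0.255,
                          zf = "absent", lz_first = "V"),
  green_anole      = list(length = 273L, n_term = 120L, pror = 0.108,
                          zf = "absent", lz_first = "V"),
  burmese_python   = list(length = 261L, n_term = 115L, pror = 0.087,
                          zf = "absent", lz_first = "V"))

#' Species presets for the FoxP3-style protein simulator
#'
#' Each preset fixes the protein length, the N-terminal (ProR) region length
#' and its proline fraction, whether a zinc finger is present, and the first
#' residue of the leucine zipper, emulating the reported per-species
#' conditions (e.g. the ground tit: 298 aa, no detectable ZF, isoleucine at
#' the first zipper position, 25.2% proline in the N-terminal region).
#'
#' @return A tibble of presets.
#' @export
foxp3_presets <- function() {
  tibble(
    species = names(.species_presets),
    length = vapply(.species_presets, function(p) p$length, integer(1)),
    n_term = vapply(.species_presets, function(p) p$n_term, integer(1)),
    pror_fraction = vapply(.species_presets, function(p) p$pror, numeric(1)),
    zf = vapply(.species_presets, function(p) p$zf, character(1)),
    lz_first = vapply(.species_presets, function(p) p$lz_first, character(1))
  )
}

# filler alphabet free of V/I so the leucine-zipper anchor can only fire at
# the planted motif
.filler_alphabet <- c("A", "S", "T", "G", "Q", "E", "D", "N", "K", "R", "H")

#' Build a FoxP3-style protein with a planted domain architecture
#'
#' Assembles N-terminal ProR region (with an exact planted proline count),
#' optional zinc finger, leucine zipper, linker and forkhead domain from the
#' package templates. Returns the protein and its true domain layout.
#'
#' @param species A preset name from [foxp3_presets()].
#' @param seed Integer seed for the filler-region composition.
#' @param frk Forkhead sequence to plant (defaults to the ground-tit-like
#'   panel row for bird presets, the template otherwise).
#' @return A list with `protein` and `layout` (tibble of `region`, `start`,
#'   `end`, 0-based half-open in protein coordinates).
#' @export
simulate_foxp_protein <- function(species = "ground_tit", seed = 1, frk = NULL) {
  p <- .species_presets[[species]]
  if (is.null(p)) stop("unknown species preset: ", species, call. = FALSE)
  tmpl <- foxp_templates()
  if (is.null(frk)) {
    panel <- simulate_foxp_panel()
    frk <- if (species == "ground_tit") {
      panel$sequence[panel$id == "ground_tit_foxp3"]
    } else if (species == "mouse") {
      panel$sequence[panel$id == "mouse_foxp3"]
    } else tmpl$frk
  }
  lz <- sub("^V", p$lz_first, tmpl$lz)
  zf <- if (p$zf == "present") tmpl$zf else ""
  frk_len <- nchar(frk)
  lz_len <- nchar(lz)
  linker_len <- p$length - p$n_term - nchar(zf) - lz_len - frk_len
  if (linker_len < 5) stop("preset layout leaves no linker", call. = FALSE)
  with_rng(derive_seed(seed, paste0("prot", species)), {
    n_pro <- round(p$pror * p$n_term)
    nt <- sample(.filler_alphabet, p$n_term, replace = TRUE)
    nt[sample.int(p$n_term, n_pro)] <- "P"
    nterm <- paste(nt, collapse = "")
    linker <- paste(sample(c(.filler_alphabet, "P", "L"), linker_len,
                           replace = TRUE), collapse = "")
    protein <- paste0(nterm, zf, lz, linker, frk)
    o <- c(0L, p$n_term, p$n_term + nchar(zf),
           p$n_term + nchar(zf) + lz_len,
           p$n_term + nchar(zf) + lz_len + linker_len)
    layout <- tibble(
      region = c("nterm", "zf", "lz", "linker", "frk"),
      start = c(o[1], if (nchar(zf) > 0) o[2] else NA_integer_, o[3], o[4], o[5]),
      end = c(o[2], if (nchar(zf) > 0) o[3] else NA_integer_, o[4], o[5],
              o[5] + frk_len)
    )
    list(protein = protein, layout = layout)
  })
}

#' Specification of a synthetic gene neighbourhood
#'
#' Defaults encode the emulated study conditions: the archosaur foxp3 gene
#' order, a 298-aa target over 11 exons, 66% GC in the region hosting the
#' target, and moderate repeat density elsewhere.
#'
#' @param gene_order Tibble with columns `gene_id`, `strand`.
#' @param target_gene Which gene in `gene_order` is the target.
#' @param target_exon_count Number of exons for the target gene.
#' @param species_preset Preset controlling the target protein (see
#'   [foxp3_presets()]).
#' @param intergenic_lengths Length in bases of each intergenic stretch
#'   (recycled across the `nrow(gene_order) - 1` gaps).
#' @param target_region_gc GC fraction generated in the region between the
#'   target's two neighbouring genes.
#' @param background_gc GC fraction generated elsewhere.
#' @param repeat_density Fraction of intergenic sequence soft-masked as
#'   repeat tracts.
#' @param intron_length Range (min, max) of intron lengths; introns always
#'   begin GT, end AG and are at least 30 bases.
#' @param margin Unannotated flank length at each scaffold end.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `neighborhood_spec` list.
#' @export
neighborhood_spec <- function(gene_order = tibble(
                                gene_id = c("naa10", "ppp1r3f", "foxp3",
                                            "ccdc22", "cacna1f"),
                                strand = c("+", "-", "+", "-", "+")),
                              target_gene = "foxp3",
                              target_exon_count = 11,
                              species_preset = "ground_tit",
                              intergenic_lengths = 2500,
                              target_region_gc = 0.66,
                              background_gc = 0.42,
                              repeat_density = 0.15,
                              intron_length = c(60, 300),
                              margin = 800,
                              seed = 1) {
  stopifnot(target_gene %in% gene_order$gene_id,
            target_region_gc >= 0, target_region_gc <= 1,
            background_gc >= 0, background_gc <= 1,
            repeat_density >= 0, repeat_density <= 1,
            target_exon_count >= 1)
  preset <- .species_presets[[species_preset]]
  if (target_exon_count * 5 > preset$length) {
    stop("requested exon structure does not fit the target protein",
         call. = FALSE)
  }
  if (any(intergenic_lengths < 200)) {
    stop("intergenic lengths too short to host the requested gene structure",
         call. = FALSE)
  }
  structure(list(gene_order = gene_order, target_gene = target_gene,
                 target_exon_count = as.integer(target_exon_count),
                 species_preset = species_preset,
                 intergenic_lengths = intergenic_lengths,
                 target_region_gc = target_region_gc,
                 background_gc = background_gc,
                 repeat_density = repeat_density,
                 intron_length = intron_length, margin = margin,
                 seed = seed),
            class = "neighborhood_spec")
}

random_dna <- function(n, gc) {
  if (n == 0) return("")
  base <- sample(c("G", "C", "A", "T"), n, replace = TRUE,
                 prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  paste(base, collapse = "")
}

# soft-mask ~density of a sequence in tracts of 150-600 bases
mask_repeats <- function(seq, density) {
  n <- nchar(seq)
  target <- round(density * n)
  if (target < 1 || n < 50) return(seq)
  ch <- strsplit(seq, "")[[1]]
  masked <- 0
  guard <- 0
  while (masked < target && guard < 1000) {
    guard <- guard + 1
    w <- min(sample(150:600, 1), target - masked + 49, n)
    s <- sample.int(max(1, n - w), 1)
    seg <- s:(s + w - 1)
    fresh <- seg[ch[seg] %in% c("A", "C", "G", "T")]
    ch[fresh] <- tolower(ch[fresh])
    masked <- masked + length(fresh)
  }
  paste(ch, collapse = "")
}

# split a protein of `len` aa into k exon sizes, each >= 5 aa
draw_exon_sizes <- function(len, k) {
  if (k == 1) return(len)
  extra <- len - 5 * k
  cuts <- sort(sample.int(extra + k - 1, k - 1))
  sizes <- diff(c(0, cuts, extra + k)) - 1 + 5
  stopifnot(sum(sizes) == len, all(sizes >= 5))
  sizes
}

# build one gene: CDS split over exons with GT..AG introns; returns the
# gene's forward-strand sequence and exon intervals local to it
build_gene_sequence <- function(protein, n_exons, intron_range, intron_gc) {
  cds <- back_translate(protein)
  sizes_aa <- draw_exon_sizes(nchar(protein), n_exons)
  sizes_nt <- sizes_aa * 3
  parts <- character(0)
  exons <- tibble(start = integer(0), end = integer(0))
  pos <- 0L
  cds_off <- 0L
  for (i in seq_len(n_exons)) {
    ex <- substr(cds, cds_off + 1, cds_off + sizes_nt[i])
    parts <- c(parts, ex)
    exons <- bind_rows(exons, tibble(start = pos, end = pos + sizes_nt[i]))
    pos <- pos + sizes_nt[i]
    cds_off <- cds_off + sizes_nt[i]
    if (i < n_exons) {
      ilen <- sample(max(30, intron_range[1]):max(34, intron_range[2]), 1)
      intron <- paste0("GT", random_dna(ilen - 4, intron_gc), "AG")
      parts <- c(parts, intron)
      pos <- pos + nchar(intron)
    }
  }
  list(sequence = paste(parts, collapse = ""), exons = exons)
}

#' Simulate a gene neighbourhood with known ground truth
#'
#' Generates a single contiguous scaffold carrying the specified gene order,
#' with the target gene's exon structure, protein and per-gene intervals
#' recorded as ground truth. Deterministic given `spec$seed`.
#'
#' @param spec A [neighborhood_spec()].
#' @return A list with elements `record` (an [assembly_record()]) and
#'   `truth` (a `ground_truth` list: `target_protein`, `target_exons`,
#'   `genes`, `region`, `target_layout`, `target_cds`).
#' @export
simulate_neighborhood <- function(spec = neighborhood_spec()) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  go <- spec$gene_order
  k <- nrow(go)
  ig <- rep_len(spec$intergenic_lengths, k - 1)
  t_idx <- which(go$gene_id == spec$target_gene)
  # the elevated-GC region spans from the end of the gene before the target's
  # upstream neighbour to the start of the gene after its downstream
  # neighbour, emulating the GC-rich intergenic region of the study
  hot <- seq(max(1, t_idx - 1), min(k, t_idx + 1))
  with_rng(derive_seed(spec$seed, "neighborhood"), {
    prot <- simulate_foxp_protein(spec$species_preset, seed = spec$seed)
    genes <- vector("list", k)
    for (i in seq_len(k)) {
      gc_i <- if (i %in% hot) spec$target_region_gc else spec$background_gc
      if (i == t_idx) {
        genes[[i]] <- build_gene_sequence(prot$protein,
                                          spec$target_exon_count,
                                          spec$intron_length, gc_i)
      } else {
        flank_prot <- paste(sample(.filler_alphabet, 80, replace = TRUE),
                            collapse = "")
        genes[[i]] <- build_gene_sequence(flank_prot, 2,
                                          c(60, 120), gc_i)
      }
    }
    segs <- character(0)
    ann <- list()
    truth_genes <- list()
    target_exons <- NULL
    pos <- 0L
    add_seg <- function(s) { segs <<- c(segs, s); pos <<- pos + nchar(s) }
    add_seg(mask_repeats(random_dna(spec$margin, spec$background_gc),
                         spec$repeat_density))
    for (i in seq_len(k)) {
      g <- genes[[i]]
      glen <- nchar(g$sequence)
      gene_start <- pos
      if (go$strand[i] == "+") {
        add_seg(g$sequence)
        ex <- tibble(start = gene_start + g$exons$start,
                     end = gene_start + g$exons$end)
      } else {
        add_seg(revcomp(g$sequence))
        ex <- tibble(start = gene_start + glen - g$exons$end,
                     end = gene_start + glen - g$exons$start)
        ex <- ex[order(ex$start), ]
      }
      ann[[i]] <- tibble(gene_id = go$gene_id[i], scaffold_id = "scaffold_1",
                         strand = go$strand[i], biotype = "gene",
                         exon_rank = seq_len(nrow(ex)),
                         start = ex$start, end = ex$end)
      truth_genes[[i]] <- tibble(gene_id = go$gene_id[i],
                                 start = gene_start, end = pos,
                                 strand = go$strand[i])
      if (i == t_idx) {
        target_exons <- mutate(ex, phase = 0L,
                               aa_start = cumsum(c(0, head((end - start) / 3,
                                                           -1))),
                               aa_end = cumsum((end - start) / 3))
      }
      if (i < k) {
        gc_i <- if (i %in% hot || (i + 1) %in% hot) spec$target_region_gc
                else spec$background_gc
        add_seg(mask_repeats(random_dna(ig[i], gc_i), spec$repeat_density))
      }
    }
    add_seg(mask_repeats(random_dna(spec$margin, spec$background_gc),
                         spec$repeat_density))
    seqn <- paste(segs, collapse = "")
    gene_tbl <- bind_rows(truth_genes)
    region <- c(gene_tbl$end[t_idx - 1], gene_tbl$start[t_idx + 1])
    record <- assembly_record(
      genome_id = paste0("sim_", spec$seed),
      scaffolds = tibble(id = "scaffold_1", sequence = seqn),
      annotations = bind_rows(ann))
    truth <- structure(list(target_protein = prot$protein,
                            target_cds = back_translate(prot$protein),
                            target_exons = target_exons,
                            target_layout = prot$layout,
                            genes = gene_tbl,
                            region = region,
                            spec = spec),
                       class = "ground_truth")
    list(record = record, truth = truth)
  })
}

#' GC-linked fragmentation model
#'
#' Per 1-kb window, the scaffold breaks with probability
#' `base_break_rate * gc_break_multiplier` when the window's GC exceeds
#' `gc_threshold`, and `base_break_rate` otherwise (clamped to 1). A break
#' becomes an internal N-gap run with probability 0.5, otherwise the
#' scaffold splits. All window draws derive from `(seed, window)`, so the
#' breakpoint set at a higher multiplier is a superset of the set at a lower
#' one.
#'
#' @param base_break_rate Per-kb break probability.
#' @param gc_break_multiplier Multiplier (>= 1) applied in GC-rich windows.
#' @param gap_length Range of inserted N-gap lengths.
#' @param gc_threshold Window GC above which the multiplier applies.
#' @param seed Integer seed.
#' @return A `fragmentation_model` list.
#' @export
fragmentation_model <- function(base_break_rate = 0.05,
                                gc_break_multiplier = 1,
                                gap_length = c(500, 5000),
                                gc_threshold = 0.55, seed = 1) {
  stopifnot(base_break_rate >= 0, base_break_rate <= 1,
            gc_break_multiplier >= 1)
  structure(list(base_break_rate = base_break_rate,
                 gc_break_multiplier = gc_break_multiplier,
                 gap_length = gap_length, gc_threshold = gc_threshold,
                 seed = seed),
            class = "fragmentation_model")
}

#' Fragment a simulated assembly
#'
#' Applies the fragmentation model to every scaffold: sampled breakpoints
#' become internal N-gap runs or scaffold splits; annotations are re-mapped,
#' truncated (exons overlapping a gap or a cut are dropped) or lost
#' entirely. Deterministic given `model$seed`.
#'
#' @param record An [assembly_record()] with sequences.
#' @param model A [fragmentation_model()].
#' @return A fragmented [assembly_record()].
#' @export
fragment_assembly <- function(record, model) {
  stopifnot(inherits(record, "assembly_record"),
            inherits(model, "fragmentation_model"),
            !is.null(record$scaffolds))
  out_sc <- list(); out_ann <- list()
  for (si in seq_len(nrow(record$scaffolds))) {
    sid <- record$scaffolds$id[si]
    seqn <- record$scaffolds$sequence[si]
    L <- nchar(seqn)
    ann <- record$annotations |> filter(.data$scaffold_id == sid)
    n_win <- max(1L, ceiling(L / 1000))
    gaps <- list(); cuts <- integer(0)
    for (w in seq_len(n_win) - 1L) {
      ws <- w * 1000L; we <- min(L, ws + 1000L)
      draws <- with_rng(derive_seed(model$seed, paste0(sid, "w", w)),
                        runif(4))
      win_gc <- gc_fraction(seqn, ws, we)
      p <- model$base_break_rate *
        if (!is.na(win_gc) && win_gc > model$gc_threshold)
          model$gc_break_multiplier else 1
      if (draws[1] >= min(1, p)) next
      bp <- ws + floor(draws[2] * (we - ws))
      if (draws[3] < 0.5) {
        glen <- model$gap_length[1] +
          floor(draws[4] * diff(model$gap_length))
        gaps[[length(gaps) + 1]] <- c(bp, min(L, bp + glen))
      } else {
        cuts <- c(cuts, bp)
      }
    }
    # apply gap runs (coordinates unchanged: bases replaced by N)
    if (length(gaps) > 0) {
      ch <- strsplit(seqn, "")[[1]]
      for (g in gaps) if (g[2] > g[1]) ch[(g[1] + 1):g[2]] <- "N"
      seqn <- paste(ch, collapse = "")
      if (nrow(ann) > 0) {
        hit <- rep(FALSE, nrow(ann))
        for (g in gaps) hit <- hit | (ann$start < g[2] & ann$end > g[1])
        ann <- ann[!hit, ]
      }
    }
    # apply splits
    cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
    bounds <- cbind(c(0L, cuts), c(cuts, L))
    for (p in seq_len(nrow(bounds))) {
      a <- bounds[p, 1]; b <- bounds[p, 2]
      pid <- if (nrow(bounds) == 1) sid else paste0(sid, "_p", p)
      out_sc[[length(out_sc) + 1]] <-
        tibble(id = pid, sequence = substr(seqn, a + 1, b))
      if (nrow(ann) > 0) {
        keep <- ann$start >= a & ann$end <= b
        if (any(keep)) {
          pa <- ann[keep, ]
          pa$scaffold_id <- pid
          pa$start <- pa$start - a
          pa$end <- pa$end - a
          out_ann[[length(out_ann) + 1]] <- pa
        }
      }
    }
  }
  sc <- bind_rows(out_sc)
  ann <- if (length(out_ann) > 0) {
    bind_rows(out_ann) |>
      arrange(.data$scaffold_id, .data$gene_id, .data$start) |>
      group_by(.data$gene_id, .data$scaffold_id) |>
      mutate(exon_rank = row_number()) |> ungroup()
  } else NULL
  assembly_record(record$genome_id, sc, ann,
                  coverage_x = record$metadata$coverage_x,
                  declared_n50 = record$metadata$declared_n50)
}

#' Simulate short reads from a coding sequence
#'
#' Reads are drawn uniformly from both strands with independent per-base
#' substitution errors. Deterministic given `seed`.
#'
#' @param cds Coding sequence (DNA string).
#' @param read_length Read length; must not exceed `nchar(cds)`.
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A tibble with columns `read_id`, `sequence`.
#' @export
simulate_reads <- function(cds, read_length = 100, n_reads = 100,
                           error_rate = 0, seed = 1) {
  check_dna(cds)
  if (n_reads < 0) stop("n_reads must be non-negative", call. = FALSE)
  stopifnot(read_length <= nchar(cds), read_length >= 1)
  if (n_reads == 0) return(tibble(read_id = character(0), sequence = character(0)))
  with_rng(derive_seed(seed, "reads"), {
    starts <- sample.int(nchar(cds) - read_length + 1, n_reads, replace = TRUE)
    rc <- runif(n_reads) < 0.5
    seqs <- substring(toupper(cds), starts, starts + read_length - 1)
    seqs[rc] <- vapply(seqs[rc], revcomp, character(1), USE.NAMES = FALSE)
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        err <- which(runif(length(ch)) < error_rate)
        for (i in err) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble(read_id = sprintf("read_%05d", seq_len(n_reads)), sequence = seqs)
  })
}

#' Tile error-free reads over a span of a coding sequence
#'
#' Emulates a transcriptome read set with perfect-identity reads covering a
#' chosen codon span, optionally leaving one uncovered codon block (as seen
#' for the 8 uncovered codons of the emulated transcript evidence). This is
#' a synthetic stand-in for a real read archive.
#'
#' @param cds Coding sequence.
#' @param span Codon interval (0-based half-open) to tile.
#' @param uncovered Optional codon interval left without reads.
#' @param read_length Read length in bases (a multiple of 3 keeps tiles
#'   codon-aligned).
#' @param step Tile step in bases.
#' @return A tibble with columns `read_id`, `sequence`.
#' @export
synthetic_transcript_reads <- function(cds, span, uncovered = NULL,
                                       read_length = 75, step = 60) {
  blocks <- if (is.null(uncovered)) list(span * 3) else {
    list(c(span[1], uncovered[1]) * 3, c(uncovered[2], span[2]) * 3)
  }
  seqs <- character(0)
  for (b in blocks) {
    if (b[2] - b[1] < read_length) next
    starts <- seq(b[1], b[2] - read_length, by = step)
    if (tail(starts, 1) < b[2] - read_length)
      starts <- c(starts, b[2] - read_length)
    seqs <- c(seqs, substring(toupper(cds), starts + 1, starts + read_length))
  }
  tibble(read_id = sprintf("tread_%04d", seq_along(seqs)), sequence = seqs)
}
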