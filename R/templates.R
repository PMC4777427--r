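# Curated domain templates and signature reference used across the package.
# These are synthetic FoxP-style consensus sequences constructed for this
# package (not database-derived): a C2H2-style zinc finger, a leucine zipper
# matching the V-x(6)-L-x(6)-L-x(6)-L consensus, and a forkhead-like (FRK)
# block that carries the NLSLH peptide characteristic of the FoxP forkhead
# domain. The forkhead block deliberately contains no V or I so that the
# leucine-zipper anchor can never fire inside it.

.zf_template <- "CPICGKAFSRPWLLQGHIRTHTGEKP"
.lz_template <- "VAEKSPQLEAQTRGLSDNKPEL"
.frk_template <- paste0(
  "PYQSRDFPAWQ", "NRTANLSLHKC", "FERWQNSMRHN", "MSHDKCFQRET",
  "SPDGKGSWWTM", "NPQAEDMFENG", "SFRRQRQWSAK", "DMTGAWKKQRES")

# positions are 0-based offsets within the FRK template
.mam_sig_pos <- c(2L, 8L, 23L, 29L, 36L, 42L, 47L, 53L, 58L, 64L, 70L, 81L)
.mam_sig_res <- c("K", "T", "Q", "F", "N", "G", "R", "S", "D", "H", "E", "M")
.avian_sig_pos <- c(5L, 26L, 40L, 50L, 61L, 74L)
.avian_sig_res <- c("W", "Y", "H", "F", "K", "M")
.avian_shared_mam <- 1:5 # indices into the mammalian list shared by birds

#' Domain templates for FoxP-style architecture detection
#'
#' Synthetic consensus sequences for the zinc finger (ZF), leucine zipper
#' (LZ) and forkhead (FRK) domains used by [detect_architecture()] and by the
#' protein simulator.
#'
#' @return A list with character elements `zf`, `lz`, `frk`.
#' @export
foxp_templates <- function() {
  list(zf = .zf_template, lz = .lz_template, frk = .frk_template)
}

#' Mammalian FoxP3 signature reference
#'
#' The twelve-residue mammalian signature used as the reference list for
#' signature-residue overlap counts, as FRK-relative 0-based positions. This
#' is the synthetic analogue planted by [simulate_foxp_panel()].
#'
#' @return A tibble with columns `position`, `residue`.
#' @export
mammalian_signature_reference <- function() {
  tibble(position = .mam_sig_pos, residue = .mam_sig_res)
}

apply_subs <- function(seq, pos, res) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos + 1] <- res
  paste(ch, collapse = "")
}

#' Simulate a FoxP forkhead-domain panel with planted signature residues
#'
#' Builds a panel of synthetic forkhead (FRK) domain sequences emulating the
#' comparative setting of the avian FoxP3 analysis: a mammalian baseline
#' FoxP3 carrying a twelve-residue signature, three bird FoxP3s sharing five
#' of those twelve plus six avian-specific signature residues, and FoxP1/2/4
#' paralogue sequences carrying none of them. One bird (the saker-like row)
#' has a masked segment (`X` run) emulating a partial sequence over an
#' assembly gap.
#'
#' @param saker_gap 0-based half-open interval masked in the saker-like row.
#' @return A tibble with columns `id`, `clade`, `family`, `sequence`.
#' @export
simulate_foxp_panel <- function(saker_gap = c(30L, 50L)) {
  tmpl <- .frk_template
  frk_mouse <- apply_subs(tmpl, .mam_sig_pos, .mam_sig_res)
  shared <- .avian_shared_mam
  frk_bird <- apply_subs(tmpl, c(.mam_sig_pos[shared], .avian_sig_pos),
                         c(.mam_sig_res[shared], .avian_sig_res))
  saker <- strsplit(frk_bird, "")[[1]]
  saker[(saker_gap[1] + 1):saker_gap[2]] <- "X"
  sub_or <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos + 1] <- ifelse(ch[pos + 1] == "G", "A", "G")
    paste(ch, collapse = "")
  }
  tibble(
    id = c("mouse_foxp3", "ground_tit_foxp3", "peregrine_falcon_foxp3",
           "saker_falcon_foxp3", "foxp1", "foxp2", "foxp4"),
    clade = c("mammal", "bird", "bird", "bird", "paralogue", "paralogue",
              "paralogue"),
    family = c("FoxP3", "FoxP3", "FoxP3", "FoxP3", "FoxP1", "FoxP2", "FoxP4"),
    sequence = c(frk_mouse, frk_bird, frk_bird, paste(saker, collapse = ""),
                 sub_or(tmpl, c(10L, 33L, 55L, 77L)),
                 sub_or(tmpl, c(4L, 34L, 56L, 78L)),
                 sub_or(tmpl, c(9L, 35L, 66L, 80L)))
  )
}

# GC-rich vertebrate-style preferred codon per amino acid; deterministic
# back-translation keeps simulated coding sequence reproducible and matches
# the elevated GC of the emulated genomic region.
.preferred_codon <- c(
  A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG", `*` = "TGA")

#' Deterministic back-translation of a protein
#'
#' Each residue maps to a fixed, GC-rich vertebrate-preferred codon, so the
#' coding sequence of a simulated protein is reproducible and its GC content
#' resembles the GC-rich genomic region being emulated.
#'
#' @param protein Amino-acid string (standard 20 letters).
#' @return The coding DNA string (no stop codon appended).
#' @export
back_translate <- function(protein) {
  ch <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(ch), names(.preferred_codon))
  if (length(bad) > 0) stop("cannot back-translate residue(s): ",
                            paste(bad, collapse = " "), call. = FALSE)
  paste(.preferred_codon[ch], collapse = "")
}
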