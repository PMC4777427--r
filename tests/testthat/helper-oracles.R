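# Independent oracles used to validate the package's algorithms on small
# instances: exhaustive enumeration of legal exon chains with a plain
# Needleman-Wunsch inner scorer (for the spliced aligner), a recursive
# global-alignment scorer (for the anchored aligner), and brute-force
# recomputations of the summary statistics.

.codon_tab <- Biostrings::GENETIC_CODE

oracle_translate_codon <- function(codon) {
  aa <- .codon_tab[codon]
  if (is.na(aa)) "X" else unname(aa)
}

# base-by-base reverse-strand translation oracle
oracle_revtrans <- function(dna, frame = 0) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- rev(comp[strsplit(toupper(dna), "")[[1]]])
  s <- paste(ch, collapse = "")
  s <- substring(s, frame + 1)
  k <- nchar(s) %/% 3
  if (k == 0) return("")
  paste(vapply(seq_len(k), function(i) {
    oracle_translate_codon(substr(s, 3 * i - 2, 3 * i))
  }, character(1)), collapse = "")
}

# brute-force N50: largest scaffold length L whose >=L scaffolds hold at
# least half the assembly
oracle_n50 <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  min(lengths)
}

# inner scorer: align the protein (local) against the full codon chain
# (global), affine gaps, gap runs and insertions never touching an exon
# junction, intron penalty charged at each junction crossing
oracle_chain_score <- function(pidx, codons, exon_id, submat, go, ge, ip) {
  m <- length(pidx); T <- length(codons)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, T + 1); I <- matrix(NEG, m + 1, T + 1)
  D <- matrix(NEG, m + 1, T + 1)
  for (t in 1:T) {
    cross <- t > 1 && exon_id[t] != exon_id[t - 1]
    extra <- if (cross) ip else 0
    for (i in 0:m) {
      ii <- i + 1
      if (i >= 1) {
        s <- submat[pidx[i], codons[t]]
        best <- if (t == 1) 0 else NEG # fresh local start at first codon
        if (t > 1) {
          best <- max(best, M[ii - 1, t], D[ii - 1, t])
          if (!cross) best <- max(best, I[ii - 1, t])
        }
        if (best > NEG / 2) M[ii, t + 1] <- best + s + extra
      }
      bd <- NEG
      if (t > 1) {
        if (M[ii, t] > NEG / 2) bd <- max(bd, M[ii, t] + go)
        if (D[ii, t] > NEG / 2) bd <- max(bd, D[ii, t] + (if (cross) go else ge))
        if (!cross && I[ii, t] > NEG / 2) bd <- max(bd, I[ii, t] + go)
      }
      if (bd > NEG / 2) D[ii, t + 1] <- bd + extra
      # insertion after codon t, only away from junctions and chain ends
      if (i >= 1 && t < T && exon_id[t + 1] == exon_id[t]) {
        bi <- max(M[ii - 1, t + 1] + go, I[ii - 1, t + 1] + ge,
                  D[ii - 1, t + 1] + go)
        if (bi > NEG / 2) I[ii, t + 1] <- bi
      }
    }
  }
  max(M[, T + 1], NEG)
}

# exhaustive enumeration of all legal exon chains (up to two introns) and
# their best alignment scores; the independent check of the spliced DP
oracle_spliced_score <- function(protein, dna, submat, go = -12, ge = -2,
                                 ip = -20, min_intron = 15,
                                 both_strands = TRUE) {
  score_one_strand <- function(dna) {
    up <- toupper(dna)
    n <- nchar(up)
    ch <- strsplit(up, "")[[1]]
    pidx <- match(strsplit(protein, "")[[1]], rownames(submat))
    codon_at <- function(s) substr(up, s + 1, s + 3) # 0-based start
    n_free <- !vapply(0:(n - 1), function(i) ch[i + 1] == "N", logical(1))
    ok_run <- function(s, e) all(n_free[(s + 1):e])
    exons_from <- function(s) {
      out <- list()
      e <- s + 3
      while (e <= n) {
        if (!ok_run(s, e)) break
        out[[length(out) + 1]] <- c(s, e)
        e <- e + 3
      }
      out
    }
    gt_at <- function(j) j + 2 <= n && ch[j + 1] == "G" && ch[j + 2] == "T"
    ag_before <- function(j) j >= 2 && ch[j - 1] == "A" && ch[j] == "G"
    chains <- list()
    for (s in 0:(n - 3)) for (e in exons_from(s)) {
      chains[[length(chains) + 1]] <- list(e)
    }
    add_next <- function(chain) {
      d <- chain[[length(chain)]][2]
      out <- list()
      if (!gt_at(d)) return(out)
      a_min <- d + min_intron
      if (a_min + 3 > n) return(out)
      for (a in a_min:(n - 3)) {
        if (!ag_before(a)) next
        for (e2 in exons_from(a)) {
          out[[length(out) + 1]] <- c(chain, list(e2))
        }
      }
      out
    }
    one <- unlist(lapply(chains, add_next), recursive = FALSE)
    two <- unlist(lapply(one, add_next), recursive = FALSE)
    best <- 0
    for (chain in c(chains, one, two)) {
      cods <- integer(0); eid <- integer(0)
      for (k in seq_along(chain)) {
        ex <- chain[[k]]
        starts <- seq(ex[1], ex[2] - 3, by = 3)
        cods <- c(cods, vapply(starts, function(s) {
          match(oracle_translate_codon(codon_at(s)), rownames(submat))
        }, integer(1)))
        eid <- c(eid, rep(k, length(starts)))
      }
      sc <- oracle_chain_score(pidx, cods, eid, submat, go, ge, ip)
      if (sc > best) best <- sc
    }
    best
  }
  s <- score_one_strand(dna)
  if (both_strands) {
    rc <- missedgene::revcomp(dna)
    s <- max(s, score_one_strand(rc))
  }
  s
}

# plain three-state affine-gap global alignment score (first gap unit `go`,
# extension `ge`), the oracle for the anchored aligner
oracle_nw_score <- function(a, b, submat, go = -12, ge = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); A <- matrix(NEG, n + 1, m + 1)
  B <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) A[i, 1] <- go + (i - 2) * ge
  for (j in 2:(m + 1)) B[1, j] <- go + (j - 2) * ge
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], A[i - 1, j - 1], B[i - 1, j - 1]) +
        submat[av[i - 1], bv[j - 1]]
      A[i, j] <- max(M[i - 1, j] + go, A[i - 1, j] + ge, B[i - 1, j] + go)
      B[i, j] <- max(M[i, j - 1] + go, B[i, j - 1] + ge, A[i, j - 1] + go)
    }
  }
  max(M[n + 1, m + 1], A[n + 1, m + 1], B[n + 1, m + 1])
}

# brute-force exact-match codon coverage: for every read and orientation,
# scan every offset for substring equality
oracle_coverage <- function(reads, cds) {
  up <- toupper(cds)
  ncod <- nchar(up) %/% 3
  counts <- integer(ncod)
  for (r in reads) {
    ivs <- list()
    for (q in unique(c(toupper(r), missedgene::revcomp(toupper(r))))) {
      w <- nchar(q)
      if (w > nchar(up)) next
      for (s in 0:(nchar(up) - w)) {
        if (substr(up, s + 1, s + w) == q) ivs[[length(ivs) + 1]] <- c(s, s + w)
      }
    }
    ivs <- unique(ivs)
    for (h in ivs) {
      for (c in 0:(ncod - 1)) {
        if (3 * c >= h[1] && 3 * c + 3 <= h[2]) counts[c + 1] <- counts[c + 1] + 1L
      }
    }
  }
  counts
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
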