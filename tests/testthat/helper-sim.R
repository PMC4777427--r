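# memoised simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_neighborhood(neighborhood_spec(seed = seed, ...))
  }
  .sim_cache[[key]]
}

target_region_seq <- function(sim) {
  r <- sim$truth$region
  substr(sim$record$scaffolds$sequence[1], r[1] + 1, r[2])
}

# drop the target gene's annotation, emulating an unannotated locus
drop_target <- function(record, target = "foxp3") {
  record$annotations <- record$annotations[record$annotations$gene_id != target, ]
  record
}
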