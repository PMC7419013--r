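# In-code fixtures shared across test files.

# one-liner count table builder: nt/nc vectors over positions
make_cell <- function(pos, nt, nc, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             count_C = as.integer(nc), count_T = as.integer(nt))
}

# minimal fc_calls stand-in for functions that only consume site sets
fake_calls <- function(fc_pos, unmod_pos, chrom = "chr1", cell_id = "cell",
                       abundance = NA_real_) {
  structure(list(
    cell_id = cell_id,
    fc_sites = data.frame(chrom = rep(chrom, length(fc_pos)),
                          pos = as.integer(fc_pos)),
    unmod_sites = data.frame(chrom = rep(chrom, length(unmod_pos)),
                             pos = as.integer(unmod_pos)),
    sequenced_cpg = length(fc_pos) + length(unmod_pos),
    abundance = abundance),
    class = "fc_calls")
}

fake_stage <- function(fc, unmod, label = "stage") {
  structure(list(label = label, merged_fc = fc, merged_unmod = unmod),
            class = "fc_stage")
}

# window-profile stand-in: levels over consecutive 1-kb windows
fake_profile <- function(levels, owner, n_fc = 1L, chrom = "chr1") {
  structure(data.frame(chrom = chrom,
                       start = seq(0L, by = 1000L,
                                   length.out = length(levels)),
                       n_fc = n_fc, n_unmod = 9L, level = levels),
            owner = owner)
}

# small simulated world under the study conditions, reused across tests
small_world <- function(seed = 1L, chrom_len = 2e5, n_treated = 4L,
                        n_untreated = 2L, base_rate = 5e-3, ...) {
  gen <- make_genome(1L, chrom_len, 10, seed = seed)
  truth <- make_truth(gen$genome, gen$annotation, class_rates = numeric(0),
                      base_rate = base_rate, seed = seed + 1L, ...)
  sim <- simulate_cells(truth, n_treated, n_untreated, seed = seed + 2L)
  c(gen, list(truth = truth), sim)
}

call_all <- function(world, cfg = calling_config()) {
  treated <- world$manifest$cell_id[world$manifest$treatment == "treated"]
  untreated <- world$manifest$cell_id[world$manifest$treatment ==
                                        "untreated"]
  qc <- compute_qc(world$controls, world$manifest, cfg)
  cand <- build_pool(world$counts[treated], "candidate", cfg)
  noise <- if (length(untreated)) {
    build_pool(world$counts[untreated], "noise", cfg)
  } else NULL
  calls <- lapply(world$manifest$cell_id, function(id) {
    call_cell(world$counts[[id]], cand, noise, NULL,
              qc[qc$cell_id == id, ], cfg, cell_id = id)
  })
  names(calls) <- world$manifest$cell_id
  list(qc = qc, candidate = cand, noise = noise, calls = calls,
       treated = treated, untreated = untreated)
}
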