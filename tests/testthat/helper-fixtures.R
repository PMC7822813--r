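# Shared fixtures: small seeded genomes and a naive digestion oracle.

# Naive full-scan digestion oracle: cut before every motif occurrence.
oracle_digest <- function(seq, motif) {
  L <- nchar(seq); k <- nchar(motif)
  cuts <- integer(0)
  for (p in seq_len(L - k + 1L))
    if (substr(seq, p, p + k - 1L) == motif) cuts <- c(cuts, p - 1L)
  cuts <- cuts[cuts > 0L]
  starts <- c(0L, cuts); ends <- c(cuts, L)
  data.frame(start = starts, end = ends)
}

random_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  stats::setNames(s, name)
}

# A small single-species simulation shared by round-trip style tests.
small_sim <- function(seed = 42, n_events = 2000, rho = 0, ...) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = list(A = c(chr1 = 6e4, chr2 = 3e4)),
                    species_mix = c(A = 1),
                    events_per_viewpoint = n_events, rho = rho, ...)
  vps <- function(map) {
    sub <- map[map$chrom == "A_chr1", ]
    mid <- sub$index[which.min(abs((sub$start + sub$end) / 2 - 3e4))]
    data.frame(viewpoint_id = "vp1", fragment_index = mid)
  }
  simulate_library(cfg, vps)
}
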