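test_that("generated genomes are seeded, unique-k-mer and motif-dense as expected", {
  cfg <- sim_config(seed = 71, chrom_lengths = list(A = c(chr1 = 1e5)))
  g1 <- make_genomes(cfg)
  g2 <- make_genomes(cfg)
  expect_identical(as.character(g1$A), as.character(g2$A))
  # motif density ~ 1/256: fragment count within 3 binomial SD
  fm <- digest_genome(g1$A, "GATC")
  p <- 1 / 256
  expect_lt(abs(nrow(fm) - 1e5 * p), 3 * sqrt(1e5 * p * (1 - p)) + 1)
  # two species: disjoint chromosome name spaces
  cfg2 <- sim_config(seed = 72,
                     chrom_lengths = list(A = c(chr1 = 2e4), B = c(chr1 = 2e4)),
                     species_mix = c(A = 0.5, B = 0.5))
  gs <- make_genomes(cfg2)
  expect_length(intersect(names(gs$A), names(gs$B)), 0)
  # all 20-mers of the combined reference unique
  comb <- as.character(combine_genomes(gs))
  kmers <- unlist(lapply(comb, function(s) {
    n <- nchar(s) - 19L
    substring(s, 1:n, 20:(n + 19L))
  }))
  expect_false(anyDuplicated(kmers) > 0)
})

test_that("event simulation respects the configured noise structure", {
  cfg <- sim_config(seed = 73,
                    chrom_lengths = list(A = c(chr1 = 5e4, chr2 = 2e4)),
                    rho = 0, trans_rate = 0.1, events_per_viewpoint = 4000)
  genomes <- make_genomes(cfg)
  map <- digest_genome(combine_genomes(genomes), cfg$motif)
  sub <- map[map$chrom == "A_chr1", ]
  vp <- sub$index[which.min(abs((sub$start + sub$end) / 2 - 2.5e4))]
  truth <- simulate_events(cfg, map, data.frame(viewpoint_id = "v",
                                                fragment_index = vp))
  expect_equal(nrow(truth), 4000L)
  expect_equal(sum(truth$origin == "internuclear"), 0L)
  # trans fraction within binomial CI of the configured rate
  tr <- mean(truth$origin == "trans")
  expect_lt(abs(tr - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  # cis partners concentrate near the viewpoint (decay)
  mids <- fragment_midpoints(map)
  d <- abs(mids[truth$reporter_fragment[truth$origin == "cis"]] - mids[vp])
  expect_gt(mean(d < 5000), mean(d > 20000))
})

test_that("spike-ins multiply the local contact frequency by the configured fold", {
  base_cfg <- sim_config(seed = 74, chrom_lengths = list(A = c(chr1 = 6e4)),
                         trans_rate = 0, events_per_viewpoint = 30000)
  genomes <- make_genomes(base_cfg)
  map <- digest_genome(combine_genomes(genomes), base_cfg$motif)
  mids <- fragment_midpoints(map)
  vp <- map$index[which.min(abs(mids - 3e4))]
  cand <- map$index[abs(mids - 3e4) > 5000 & abs(mids - 3e4) < 15000 &
                      (map$end - map$start) > 100]
  spike <- cand[5]
  vps <- data.frame(viewpoint_id = "v", fragment_index = vp)
  t0 <- simulate_events(base_cfg, map, vps)
  cfg5 <- base_cfg
  cfg5$spikes <- data.frame(fragment_index = spike, fold = 5)
  t5 <- simulate_events(cfg5, map, vps)
  f0 <- mean(t0$reporter_fragment == spike)
  f5 <- mean(t5$reporter_fragment == spike)
  ratio <- f5 / f0
  # ~5x the baseline frequency (weights renormalise; spike mass is small)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 6.5)
})

test_that("the capture step retains events at the closed-form probability", {
  cfg <- sim_config(seed = 75, chrom_lengths = list(A = c(chr1 = 4e4)),
                    events_per_viewpoint = 8000, trans_rate = 0)
  genomes <- make_genomes(cfg)
  map <- digest_genome(combine_genomes(genomes), cfg$motif)
  mids <- fragment_midpoints(map)
  vp <- map$index[which.min(abs(mids - 2e4))]
  truth <- simulate_events(cfg, map, data.frame(viewpoint_id = "v",
                                                fragment_index = vp))
  cand <- names(sort(table(truth$reporter_fragment), decreasing = TRUE))[1]
  cotgt <- as.integer(cand)
  eff <- stats::setNames(c(0.5, 0.5), c(vp, cotgt))
  kept <- simulate_capture(truth, eff, rounds = 1, seed = 76)
  # co-targeted pair retained at 0.75, others at 0.5 (within binomial CI)
  n_pair <- sum(truth$reporter_fragment == cotgt)
  k_pair <- sum(kept$reporter_fragment == cotgt)
  expect_lt(abs(k_pair / n_pair - 0.75), 3 * sqrt(0.75 * 0.25 / n_pair))
  n_oth <- sum(truth$reporter_fragment != cotgt)
  k_oth <- sum(kept$reporter_fragment != cotgt)
  expect_lt(abs(k_oth / n_oth - 0.5), 3 * sqrt(0.25 / n_oth))
  # boundary cases: e = 1 retains everything, e_i = 0 nothing
  all_eff <- stats::setNames(1, vp)
  expect_equal(nrow(simulate_capture(truth, all_eff, 1, seed = 1)), nrow(truth))
  none_eff <- stats::setNames(0, vp)
  expect_equal(nrow(simulate_capture(truth, none_eff, 1, seed = 1)), 0L)
})

test_that("emitted molecules carry exactly one junction motif copy and dedup matches the duplication model", {
  sim <- small_sim(seed = 78, n_events = 1000, dup_rate = 0.5)
  originals <- sim$truth[is.na(sim$truth$duplicate_of), ]
  dups <- sim$truth[!is.na(sim$truth$duplicate_of), ]
  # duplicate count ~ Binomial(n, 0.5)
  expect_lt(abs(nrow(dups) / nrow(originals) - 0.5),
            3 * sqrt(0.25 / nrow(originals)))
  # duplicates are verbatim copies
  expect_identical(unname(sim$reads[dups$read_id[1]]),
                   unname(sim$reads[dups$duplicate_of[1]]))
  # junction: motif at the boundary between viewpoint piece and reporter piece
  map <- sim$map
  one <- originals[originals$origin == "cis", ][1, ]
  rd <- sim$reads[[one$read_id]]
  sl <- split_at_motif(rd, "GATC")
  expect_gte(length(sl), 2L)
  # the last slice is the reporter piece and starts with the motif
  expect_equal(substr(sl[[length(sl)]], 1, 4), "GATC")
})

test_that("identical configurations give byte-identical libraries", {
  s1 <- small_sim(seed = 79, n_events = 300, dup_rate = 0.2)
  s2 <- small_sim(seed = 79, n_events = 300, dup_rate = 0.2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
})

test_that("FASTQ emission and reading round-trip including gzip", {
  sim <- small_sim(seed = 80, n_events = 50)
  path <- tempfile(fileext = ".fq.gz")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_equal(length(back), length(sim$reads))
  expect_identical(as.character(back[[1]]), unname(sim$reads[[1]]))
  # paired-end emission covers both molecule ends
  cfg <- sim_config(seed = 81, chrom_lengths = list(A = c(chr1 = 3e4)),
                    events_per_viewpoint = 20, read_length = 50)
  genomes <- make_genomes(cfg)
  map <- digest_genome(combine_genomes(genomes), cfg$motif)
  mids <- fragment_midpoints(map)
  vp <- map$index[which.min(abs(mids - 1.5e4))]
  truth <- simulate_events(cfg, map, data.frame(viewpoint_id = "v",
                                                fragment_index = vp))
  em <- emit_fastq(truth, combine_genomes(genomes), map, cfg, paired = TRUE)
  expect_equal(unname(nchar(em$reads1[1])), min(50, unname(nchar(em$reads[1]))))
  r2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(em$reads2[[1]])))
  expect_identical(r2rc,
                   substr(em$reads[[1]], nchar(em$reads[[1]]) - nchar(r2rc) + 1,
                          nchar(em$reads[[1]])))
})
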