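test_that("read splitting mirrors the digestion cut convention", {
  expect_equal(split_at_motif("ACGATCGGATCA", "GATC"), c("AC", "GATCG", "GATCA"))
  expect_equal(split_at_motif("AAAA", "GATC"), "AAAA")
  expect_equal(split_at_motif("GATC", "GATC"), "GATC")
  expect_error(split_at_motif("", "GATC"), "empty")
  # agreement with the digestion oracle on random sequence
  g <- random_genome(2000, seed = 13)
  sl <- split_at_motif(unname(g), "GATC")
  oracle <- oracle_digest(unname(g), "GATC")
  expect_equal(nchar(sl), oracle$end - oracle$start)
  expect_identical(paste(sl, collapse = ""), unname(g))
})

test_that("exact-match placement recovers planted slices on both strands", {
  g <- random_genome(5000, seed = 17)
  idx <- build_kmer_index(g)
  fwd <- substr(unname(g), 101, 180)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(unname(g), 301, 360))))
  placed <- place_slices(c(fwd, rc, "ACGT", paste(rep("A", 40), collapse = "")),
                         idx)
  expect_equal(placed$start[1], 100)
  expect_equal(placed$end[1], 180)
  expect_equal(placed$strand[1], "+")
  expect_equal(placed$start[2], 300)
  expect_equal(placed$strand[2], "-")
  expect_true(is.na(placed$chrom[3]))  # shorter than the seed
  expect_true(is.na(placed$chrom[4]))  # absent from the genome
})

test_that("classification is exhaustive, exclusive and geometry-driven", {
  fm <- digest_genome(random_genome(30000, seed = 19), "GATC")
  tgt <- fm$index[which.min(abs(fm$start - 15000))]
  design <- data.frame(viewpoint_id = "vp", chrom = "chr1",
                       start = fm$start[tgt], end = fm$end[tgt],
                       strand = "+", fragment_index = tgt)
  mk <- function(frag) {
    data.frame(chrom = fm$chrom[frag],
               start = fm$start[frag], end = fm$start[frag] + 10,
               strand = "+", ambiguous = FALSE)
  }
  near <- fm$index[max(1, tgt - 1)]                  # adjacent fragment
  far_candidates <- fm$index[fm$start > fm$end[tgt] + 5000]
  far <- far_candidates[1]
  placed <- rbind(mk(tgt), mk(near), mk(far),
                  data.frame(chrom = NA, start = NA, end = NA,
                             strand = NA, ambiguous = FALSE))
  cl <- classify_slices(placed, design, fm, exclusion_radius = 1000)
  expect_equal(cl$label, c("capture", "exclusion", "reporter", "unmapped"))
  expect_equal(cl$viewpoint_id[1], "vp")
  # labels partition the slices
  expect_equal(sum(table(cl$label)), nrow(cl))
})

test_that("event building drops multi-viewpoint reads and requires a capture slice", {
  slices <- data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r2", "r3"),
    slice_idx = c(1L, 2L, 1L, 2L, 3L, 1L),
    chrom = "c1", start = c(0, 60, 0, 120, 60, 200),
    end = c(50, 110, 50, 170, 110, 250), strand = "+", ambiguous = FALSE,
    fragment_index = c(1L, 2L, 1L, 3L, 2L, 4L),
    label = c("capture", "reporter", "capture", "capture", "reporter",
              "reporter"),
    viewpoint_id = c("vpA", NA, "vpA", "vpB", NA, NA),
    stringsAsFactors = FALSE)
  fm <- structure(data.frame(chrom = "c1", start = c(0, 50, 110, 170),
                             end = c(50, 110, 170, 260), index = 1:4),
                  class = c("fragment_map", "data.frame"))
  design <- data.frame(viewpoint_id = c("vpA", "vpB"), chrom = "c1",
                       start = c(0, 110), end = c(50, 170), strand = "+",
                       fragment_index = c(1L, 3L))
  be <- build_events(slices, design, fm)
  # r2 hits two viewpoints -> ambiguous, dropped; r3 has no capture slice
  expect_equal(be$n_ambiguous_viewpoint, 1L)
  expect_equal(be$events$read_id, "r1")
  expect_equal(be$events$fragment_index, 2L)
  expect_true(be$events$cis)
})

test_that("dedup collapses identical breakpoint keys and is idempotent", {
  ev <- data.frame(read_id = c("r1", "r1", "r2", "r3"),
                   viewpoint_id = "vp",
                   fragment_index = c(5L, 9L, 5L, 5L),
                   chrom = "c1", cis = TRUE, distance = 0,
                   duplicate_key = c("K1", "K1", "K1", "K2"),
                   stringsAsFactors = FALSE)
  dd <- dedup_events(ev)
  # r2 is a PCR copy of r1 (same key) and collapses; r1 keeps both its events
  expect_equal(sort(unique(dd$read_id)), c("r1", "r3"))
  expect_equal(nrow(dd), 3L)
  expect_identical(dedup_events(dd), dd)
  expect_equal(nrow(dedup_events(ev[0, ])), 0L)
  # same fragment pair, different sonication ends -> both kept
  ev2 <- ev[c(1, 3), ]; ev2$duplicate_key <- c("K1", "K1b")
  expect_equal(nrow(dedup_events(ev2)), 2L)
})

test_that("enrichment fold reproduces the million-fold figure and the uniform identity", {
  fold <- enrichment_fold(0.9770, 1, 6415222)
  expect_equal(fold / 1e6, 6.26, tolerance = 0.005)
  expect_equal(enrichment_fold(10 / 100, 10, 100), 1)
  expect_equal(enrichment_fold(0.5, 10, 100), 5)
  expect_error(enrichment_fold(1.5, 1, 10), "\\[0,1\\]")
})

test_that("round trip: extraction recovers >=99% of simulated truth and invents none", {
  sim <- small_sim(seed = 424, n_events = 2000, dup_rate = 0.2)
  design <- data.frame(viewpoint_id = "vp1",
                       chrom = sim$map$chrom[sim$viewpoints$fragment_index],
                       start = sim$map$start[sim$viewpoints$fragment_index],
                       end = sim$map$end[sim$viewpoints$fragment_index],
                       strand = "+",
                       fragment_index = sim$viewpoints$fragment_index)
  res <- extract_reporters(sim$reads, design, sim$map, genome = sim$genome,
                           exclusion_radius = 0)
  truth <- sim$truth[is.na(sim$truth$duplicate_of), ]
  got <- res$events_dedup
  truth_key <- paste(truth$viewpoint_id, truth$reporter_fragment)
  got_key <- paste(got$viewpoint_id, got$fragment_index)
  # every unique event recovered (>= 99%)
  recovered <- sum(truth_key %in% got_key) / length(truth_key)
  expect_gte(recovered, 0.99)
  # nothing invented: every called reporter fragment exists in the truth
  expect_true(all(got_key %in% truth_key))
  # dedup removed the PCR copies; rare breakpoint collisions between
  # independent molecules may collapse a handful more
  expect_lte(nrow(got), nrow(truth))
  expect_gte(nrow(got), 0.99 * nrow(truth))
  # cis/trans flags agree with the simulator's chromosome assignment
  m <- match(got$read_id, paste0("rd_", truth$event_id))
  expect_equal(got$chrom, sim$map$chrom[truth$reporter_fragment[m]])
  # stats are internally consistent
  expect_equal(res$stats$n_cis + res$stats$n_trans,
               res$stats$reporters_post_dedup)
  expect_equal(res$stats$percent_reads_with_motif, 100)
})

test_that("capture stats handle empty extractions without division errors", {
  fm <- digest_genome(random_genome(12000, seed = 23), "GATC")
  design <- data.frame(viewpoint_id = "vp", chrom = "chr1",
                       start = fm$start[2], end = fm$end[2], strand = "+",
                       fragment_index = 2L)
  # reads with no motif and no capture content
  reads <- c(r1 = strrep("A", 60), r2 = strrep("C", 60))
  res <- extract_reporters(reads, design, fm,
                           genome = random_genome(12000, seed = 23))
  expect_equal(res$stats$reporters_post_dedup, 0L)
  expect_equal(res$stats$n_capture_reads, 0L)
  expect_equal(res$stats$reporters_per_100_capture_reads, 0)
})
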