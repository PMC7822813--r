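make_map <- function(n = 100, len = 200) {
  structure(data.frame(chrom = "c1", start = (0:(n - 1)) * len,
                       end = (1:n) * len, index = 1:n),
            class = c("fragment_map", "data.frame"))
}

test_that("call/annotation intersection emits one pair per element with max MPPC", {
  map <- make_map()
  ann <- data.frame(chrom = "c1", start = c(1000, 1100, 5000),
                    end = c(1200, 1500, 5100),
                    class = c("E_S", "E_W", "P_S"))
  ann$element_id <- paste0("el", 1:3)
  calls <- data.frame(viewpoint_id = "vp1",
                      fragment_index = c(6L, 7L, 26L, 40L),
                      mppc = c(0.5, 0.9, 0.02, 0.005))
  pairs <- intersect_calls(calls, ann, map)
  # fragment 6 = [1000,1200) overlaps el1 and el2 -> two pairs;
  # fragment 7 = [1200,1400) overlaps el2 only; el2 keeps max MPPC 0.9
  expect_equal(sort(unique(pairs$element_id)), c("el1", "el2", "el3"))
  expect_equal(pairs$mppc[pairs$element_id == "el2"], 0.9)
  # sub-threshold fragment 40 contributes nothing
  expect_equal(nrow(intersect_calls(calls[4, ], ann, map)), 0L)
})

test_that("hub size and enhancer summaries are duplication- and order-invariant", {
  pairs <- data.frame(
    viewpoint_id = c("vp1", "vp1", "vp1", "vp1", "vp2"),
    element_id = c("p1", "p2", "p3", "p1", "e1"),
    class = c("P_S", "P_W", "PC", "P_S", "E_S"),
    element_start = 1:5, element_end = 2:6, chrom = "c1",
    mppc = 0.5, stringsAsFactors = FALSE)
  h <- hub_size(pairs)
  expect_equal(unname(h[c("vp1", "vp2")]), c(3L, 0L))
  expect_equal(hub_size(pairs[sample(nrow(pairs)), ])[names(h)], h)
  es <- enhancer_summary(pairs)
  expect_equal(es$per_promoter$n_enhancers[es$per_promoter$viewpoint_id == "vp2"], 1L)
  expect_equal(es$per_promoter$group[es$per_promoter$viewpoint_id == "vp1"], "0")
  # 2 strong + 1 weak enhancer -> count 3; six enhancers -> ">=4"
  p2 <- data.frame(viewpoint_id = "vp", element_id = paste0("e", 1:6),
                   class = c("E_S", "E_S", "E_W", "E_W", "E_W", "E_W"),
                   element_start = 1:6, element_end = 2:7, chrom = "c1",
                   mppc = 0.5)
  expect_equal(enhancer_summary(p2[1:3, ])$per_promoter$group, "3")
  expect_equal(enhancer_summary(p2)$per_promoter$group, ">=4")
})

test_that("directionality is strand-aware and mirror-symmetric", {
  # + strand, enhancers both 5' of the TSS -> unidirectional upstream
  r <- directionality(1000, "+", c(500, 700))
  expect_equal(r$n_upstream, 2L)
  expect_equal(r$n_downstream, 0L)
  expect_true(r$unidirectional)
  # same geometry on - strand mirrors
  r2 <- directionality(1000, "-", c(500, 700))
  expect_equal(r2$n_downstream, 2L)
  expect_equal(r2$n_upstream, 0L)
  # 3 up + 1 down: e_max 0.75, imbalance2
  r3 <- directionality(5000, "+", c(1000, 2000, 3000, 6000))
  expect_equal(r3$e_max_fraction, 0.75)
  expect_true(r3$imbalance2)
  expect_false(r3$unidirectional)
  # enhancer exactly at the TSS is excluded with a counter
  r4 <- directionality(1000, "+", c(1000, 500, 700))
  expect_equal(r4$n_at_tss, 1L)
  expect_equal(r4$n_upstream + r4$n_downstream, 2L)
  # fewer than two usable enhancers -> no record
  expect_null(directionality(1000, "+", c(1000, 500)))

  # full mirror symmetry: strand flip + coordinate reflection
  set.seed(61)
  for (i in 1:20) {
    tss <- runif(1, 4000, 6000)
    mids <- runif(sample(2:6, 1), 0, 10000)
    a <- directionality(tss, "+", mids)
    b <- directionality(-tss, "-", -mids)
    expect_equal(a$n_upstream, b$n_upstream)
    expect_equal(a$n_downstream, b$n_downstream)
  }
})

test_that("directionality aggregates reproduce printed-count proportions", {
  # records with known composition: 3 unidirectional of 4 multi-enhancer,
  # 1 of 2 >=4-enhancer promoters imbalanced
  recs <- data.frame(
    viewpoint_id = paste0("vp", 1:4),
    n_upstream = c(2L, 0L, 3L, 2L),
    n_downstream = c(0L, 3L, 2L, 2L),
    unidirectional = c(TRUE, TRUE, FALSE, FALSE),
    e_max_fraction = c(1, 1, 0.6, 0.5),
    imbalance2 = c(TRUE, TRUE, FALSE, FALSE),
    n_at_tss = 0L)
  agg <- aggregate_directionality(recs)
  expect_equal(agg$fraction_unidirectional, 0.5)
  expect_equal(agg$n_multi_enhancer, 4L)
  expect_equal(agg$n_ge4, 2L)       # rows 3 and 4 have >= 4 enhancers
  expect_equal(agg$fraction_imbalance2, 0)
  expect_error(aggregate_directionality(recs[0, ]), "no directionality")
})

test_that("super-enhancer gene sets come from significant prey overlap", {
  map <- make_map()
  se <- data.frame(chrom = "c1", start = c(2000, 8000), end = c(2600, 8400),
                   se_id = c("SE1", "SE2"))
  calls <- data.frame(
    viewpoint_id = c("g1", "g2", "g3", "g4"),
    fragment_index = c(11L, 12L, 13L, 50L),   # 11-13 overlap SE1
    mppc = c(0.5, 0.5, 0.5, 0.5))
  r <- se_interacting_genes(se, calls, map)
  expect_setequal(r$genes_per_se$SE1, c("g1", "g2", "g3"))
  expect_length(r$genes_per_se$SE2, 0)
  expect_equal(r$n_interacting_genes, 3L)
  expect_equal(r$n_interacting_ses, 1L)
  expect_equal(r$se_per_gene$g1, "SE1")
})

test_that("class enrichment is ~1 under the null and elevated for targeted classes", {
  set.seed(62)
  chrom_sizes <- c(c1 = 100000)
  # annotations: E_S covers 10% of the chromosome in 10 blocks
  ann <- data.frame(chrom = "c1", start = seq(0, 90000, by = 10000),
                    end = seq(0, 90000, by = 10000) + 1000, class = "E_S")
  ann <- rbind(ann, data.frame(chrom = "c1", start = seq(5000, 95000, by = 10000),
                               end = seq(5000, 95000, by = 10000) + 1000,
                               class = "C2"))
  ann$element_id <- paste0("el", seq_len(nrow(ann)))
  # null prey: uniform random
  prey0 <- data.frame(chrom = "c1",
                      start = s0 <- floor(runif(300, 0, 99800)),
                      end = s0 + 200)
  f0 <- class_enrichment(prey0, ann, chrom_sizes, n_shuffles = 100, seed = 5)
  expect_true(all(f0 > 0.8 & f0 < 1.25))
  # prey placed inside E_S -> ~10x enrichment for E_S
  starts <- sample(ann$start[ann$class == "E_S"], 300, replace = TRUE) + 400
  prey1 <- data.frame(chrom = "c1", start = starts, end = starts + 200)
  f1 <- class_enrichment(prey1, ann, chrom_sizes, n_shuffles = 100, seed = 5)
  expect_gt(f1["E_S"], 7)
  expect_equal(unname(attr(f1, "observed")["E_S"]), 1)  # all prey inside E_S
  # seeded reproducibility
  expect_identical(f1, class_enrichment(prey1, ann, chrom_sizes,
                                        n_shuffles = 100, seed = 5))
})

test_that("metaprofiles average coverage with strand flipping and anchoring", {
  cov <- list(c1 = rep(2, 10000), c2 = rep(10, 10000))
  iv <- data.frame(chrom = c("c1", "c2"), start = c(3000, 4000),
                   end = c(3500, 4500), strand = c("+", "+"))
  mp <- metaprofile(cov, iv, flank = 1000)
  expect_length(mp, 1000 + 500 + 1000)
  expect_equal(unique(mp), 6)      # mean of 2 and 10
  # single interval returns its own coverage
  mp1 <- metaprofile(cov, iv[1, ], flank = 100)
  expect_equal(unique(mp1), 2)
  # strand flip reverses an asymmetric profile
  cov2 <- list(c1 = c(rep(0, 5000), rep(4, 5000)))
  ivp <- data.frame(chrom = "c1", start = 4800, end = 5200, strand = "+")
  ivm <- transform(ivp, strand = "-")
  expect_equal(metaprofile(cov2, ivp, flank = 200),
               rev(metaprofile(cov2, ivm, flank = 200)))
  expect_error(metaprofile(cov, data.frame(chrom = "c1", start = 50,
                                           end = 100, strand = "+"),
                           flank = 1000), "off the coverage")
})

test_that("expression grouping reports group means and inclusive fold flags", {
  groups <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                       group = c("0", "1", "1", "2", "2"))
  expr <- rbind(
    data.frame(gene = c("g1", "g2", "g3", "g4"), stage = "S0",
               value = c(2, 2, 1, 5)),
    data.frame(gene = c("g1", "g2", "g3", "g4"), stage = "S3",
               value = c(8, 7.9, 4, 5)))
  r <- expression_grouping(groups, expr, stage = "S3",
                           fold_stages = c("S0", "S3"), fold = 4)
  expect_equal(r$n_missing, 1L)    # g5 absent from the table
  gm <- r$group_means
  expect_equal(gm$mean_expression[gm$group == "1"], mean(c(7.9, 4)))
  expect_equal(gm$mean_expression[gm$group == "2"], 5)
  ff <- r$fold_flags
  expect_true(ff$flag[ff$gene == "g1"])     # 2 -> 8: exactly 4-fold, inclusive
  expect_false(ff$flag[ff$gene == "g2"])    # 2 -> 7.9
})
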