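#' Read element annotations from BED (4th column = class)
#'
#' Classes follow the 8-label open-chromatin vocabulary: `E_S`, `E_W` (strong
#' / weak-H3K27ac enhancers), `P_S`, `P_W` (promoters), `PC` (promoter with
#' CTCF), `C1`, `C2` (CTCF), `Bg` (background).
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `class`, `element_id`.
#' @export
read_elements_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:4]
  names(d) <- c("chrom", "start", "end", "class")
  d$element_id <- paste0(d$chrom, ":", d$start, "-", d$end, "/", d$class)
  d
}

element_classes <- c("E_S", "E_W", "P_S", "P_W", "PC", "C1", "C2", "Bg")
promoter_classes <- c("P_S", "P_W", "PC")
enhancer_classes <- c("E_S", "E_W")

as_granges <- function(d) {
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(start = d$start + 1L, end = d$end))
}

#' Intersect significant contact calls with element annotations
#'
#' Emits a (viewpoint, element) pair whenever a significant prey fragment
#' overlaps an element interval by at least `min_overlap` bp. A prey fragment
#' under two elements yields two pairs; several prey fragments under one
#' element collapse to one pair retaining the maximum MPPC. Co-targeted
#' fragments must have been masked upstream.
#'
#' @param calls data.frame with `viewpoint_id`, `fragment_index`, `mppc`
#'   (e.g. stacked `as.data.frame(mppc_fit)` results plus a viewpoint column).
#' @param annotations Element table ([read_elements_bed()]).
#' @param map A `fragment_map`.
#' @param threshold MPPC significance threshold (default 0.01).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return data.frame of pairs: `viewpoint_id`, `element_id`, `class`,
#'   `chrom`, `element_start`, `element_end`, `mppc`.
#' @export
intersect_calls <- function(calls, annotations, map, threshold = 0.01,
                            min_overlap = 1L) {
  sig <- calls[!is.na(calls$mppc) & calls$mppc >= threshold, , drop = FALSE]
  empty <- data.frame(viewpoint_id = character(0), element_id = character(0),
                      class = character(0), chrom = character(0),
                      element_start = integer(0), element_end = integer(0),
                      mppc = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  prey <- data.frame(chrom = map$chrom[sig$fragment_index],
                     start = map$start[sig$fragment_index],
                     end = map$end[sig$fragment_index])
  hits <- GenomicRanges::findOverlaps(as_granges(prey), as_granges(annotations),
                                      minoverlap = min_overlap)
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(viewpoint_id = sig$viewpoint_id[q],
                      element_id = annotations$element_id[s],
                      class = annotations$class[s],
                      chrom = annotations$chrom[s],
                      element_start = annotations$start[s],
                      element_end = annotations$end[s],
                      mppc = sig$mppc[q], stringsAsFactors = FALSE)
  # one pair per (viewpoint, element): keep max MPPC
  key <- paste(pairs$viewpoint_id, pairs$element_id)
  o <- order(key, -pairs$mppc)
  pairs <- pairs[o, , drop = FALSE]
  pairs <- pairs[!duplicated(key[o]), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Promoter-hub size: distinct interacting promoters per viewpoint
#'
#' Invariant to pair duplication and ordering.
#'
#' @param pairs Pair table from [intersect_calls()].
#' @return Named integer vector, one entry per viewpoint present in `pairs`
#'   (viewpoints with no promoter pairs get 0).
#' @export
hub_size <- function(pairs) {
  vps <- unique(pairs$viewpoint_id)
  pp <- pairs[pairs$class %in% promoter_classes, , drop = FALSE]
  n <- vapply(split(pp$element_id, factor(pp$viewpoint_id, levels = vps)),
              function(e) length(unique(e)), 0L)
  n[is.na(n)] <- 0L
  n
}

#' Per-promoter interacting-enhancer counts and grouping
#'
#' Counts distinct enhancer elements (strong or weak H3K27ac) per promoter
#' viewpoint and assigns the group label `0, 1, 2, 3, >=4`.
#'
#' @param pairs Pair table from [intersect_calls()].
#' @return List with `per_promoter` (data.frame `viewpoint_id`, `n_enhancers`,
#'   `group`) and `summary` (mean, sd, max over promoters).
#' @export
enhancer_summary <- function(pairs) {
  vps <- unique(pairs$viewpoint_id)
  ep <- pairs[pairs$class %in% enhancer_classes, , drop = FALSE]
  n <- vapply(split(ep$element_id, factor(ep$viewpoint_id, levels = vps)),
              function(e) length(unique(e)), 0L)
  n[is.na(n)] <- 0L
  grp <- ifelse(n >= 4L, ">=4", as.character(n))
  list(per_promoter = data.frame(viewpoint_id = vps, n_enhancers = unname(n),
                                 group = unname(grp), stringsAsFactors = FALSE),
       summary = c(mean = mean(n), sd = stats::sd(n), max = max(n)))
}

#' Directional organisation of a promoter's interacting enhancers
#'
#' Upstream/downstream is defined in gene orientation: an enhancer 5' of the
#' TSS on the promoter's strand is upstream (the coordinate test is flipped
#' for minus-strand promoters). A promoter qualifies with >= 2 distinct
#' enhancers; enhancers whose midpoint falls exactly on the TSS are excluded
#' and counted.
#'
#' @param tss TSS position (0-based) of the promoter.
#' @param strand `"+"` or `"-"`.
#' @param enhancer_mid Midpoints of the distinct interacting enhancers.
#' @return List: `n_upstream`, `n_downstream`, `unidirectional`,
#'   `e_max_fraction`, `imbalance2` (|up - down| >= 2), `n_at_tss`; or NULL
#'   when fewer than 2 usable enhancers remain.
#' @export
directionality <- function(tss, strand, enhancer_mid) {
  delta <- enhancer_mid - tss
  at_tss <- delta == 0
  delta <- delta[!at_tss]
  if (length(delta) < 2L) return(NULL)
  if (strand == "-") delta <- -delta
  n_up <- sum(delta < 0); n_down <- sum(delta > 0)
  list(n_upstream = n_up, n_downstream = n_down,
       unidirectional = n_up == 0L || n_down == 0L,
       e_max_fraction = max(n_up, n_down) / (n_up + n_down),
       imbalance2 = abs(n_up - n_down) >= 2L,
       n_at_tss = sum(at_tss))
}

#' Directionality records for all multi-enhancer promoters
#'
#' @param pairs Pair table from [intersect_calls()].
#' @param viewpoints data.frame `viewpoint_id`, `tss` (0-based), `strand`.
#' @return data.frame of [directionality()] records, one row per qualifying
#'   promoter.
#' @export
directionality_records <- function(pairs, viewpoints) {
  ep <- pairs[pairs$class %in% enhancer_classes, , drop = FALSE]
  rows <- lapply(unique(ep$viewpoint_id), function(vp) {
    vrow <- viewpoints[viewpoints$viewpoint_id == vp, , drop = FALSE]
    if (!nrow(vrow)) return(NULL)
    sub <- ep[ep$viewpoint_id == vp, , drop = FALSE]
    sub <- sub[!duplicated(sub$element_id), , drop = FALSE]
    mid <- (sub$element_start + sub$element_end) / 2
    rec <- directionality(vrow$tss[1], vrow$strand[1], mid)
    if (is.null(rec)) return(NULL)
    cbind(data.frame(viewpoint_id = vp, stringsAsFactors = FALSE),
          as.data.frame(rec))
  })
  do.call(rbind, rows)
}

#' Aggregate directionality proportions
#'
#' Among all multi-enhancer promoters, the fraction whose enhancers all lie on
#' one side (unidirectional co-location); among bidirectional promoters with
#' >= 4 enhancers (promoters lying between numerous enhancers), the fraction
#' with at least two more enhancers on one side than the other.
#'
#' @param records data.frame from [directionality_records()].
#' @return List with `fraction_unidirectional` (+ counts) and
#'   `fraction_imbalance2` (+ counts over bidirectional >= 4-enhancer
#'   promoters).
#' @export
aggregate_directionality <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no directionality records")
  n_multi <- nrow(records)
  n_uni <- sum(records$unidirectional)
  ge4 <- !records$unidirectional &
    records$n_upstream + records$n_downstream >= 4L
  n_ge4 <- sum(ge4)
  n_imb <- sum(records$imbalance2[ge4])
  list(fraction_unidirectional = n_uni / n_multi,
       n_unidirectional = n_uni, n_multi_enhancer = n_multi,
       fraction_imbalance2 = if (n_ge4 > 0) n_imb / n_ge4 else NaN,
       n_imbalance2 = n_imb, n_ge4 = n_ge4)
}

#' Super-enhancer / gene interaction sets
#'
#' A gene "interacts with" a super-enhancer when any of its significant prey
#' fragments overlaps the SE interval.
#'
#' @param super_enhancers data.frame `chrom`, `start`, `end` (+ optional
#'   `se_id`).
#' @param calls Significant-call table as for [intersect_calls()].
#' @param map A `fragment_map`.
#' @param threshold MPPC threshold.
#' @return List: `genes_per_se` (named list SE -> gene ids), `se_per_gene`
#'   (named list gene -> SE ids), `n_interacting_genes`,
#'   `n_interacting_ses`.
#' @export
se_interacting_genes <- function(super_enhancers, calls, map, threshold = 0.01) {
  if (is.null(super_enhancers$se_id))
    super_enhancers$se_id <- paste0("SE", seq_len(nrow(super_enhancers)))
  sig <- calls[!is.na(calls$mppc) & calls$mppc >= threshold, , drop = FALSE]
  genes_per_se <- stats::setNames(vector("list", nrow(super_enhancers)),
                                  super_enhancers$se_id)
  if (nrow(sig)) {
    prey <- data.frame(chrom = map$chrom[sig$fragment_index],
                       start = map$start[sig$fragment_index],
                       end = map$end[sig$fragment_index])
    hits <- GenomicRanges::findOverlaps(as_granges(prey),
                                        as_granges(super_enhancers))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (i in seq_along(q))
      genes_per_se[[s[i]]] <- union(genes_per_se[[s[i]]],
                                    sig$viewpoint_id[q[i]])
  }
  all_pairs <- data.frame(
    se_id = rep(names(genes_per_se), lengths(genes_per_se)),
    gene = unlist(genes_per_se, use.names = FALSE))
  se_per_gene <- if (nrow(all_pairs)) split(all_pairs$se_id, all_pairs$gene)
                 else list()
  list(genes_per_se = genes_per_se, se_per_gene = se_per_gene,
       n_interacting_genes = length(se_per_gene),
       n_interacting_ses = sum(lengths(genes_per_se) > 0))
}

#' Class enrichment of prey fragments against a shuffle background
#'
#' For each element class, the fraction of prey intervals overlapping that
#' class is divided by the mean fraction over `n_shuffles` random placements
#' of intervals with the same number and sizes, placed uniformly within the
#' same chromosome. Seeded and reproducible.
#'
#' @param prey data.frame `chrom`, `start`, `end` of prey fragments.
#' @param annotations Element table.
#' @param chrom_sizes Named vector chromosome -> length (bp).
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed RNG seed.
#' @return Named numeric vector of fold enrichments per class present in the
#'   annotations, with attribute `observed` (observed overlap fractions).
#' @export
class_enrichment <- function(prey, annotations, chrom_sizes,
                             n_shuffles = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  classes <- sort(unique(annotations$class))
  sizes <- prey$end - prey$start
  if (any(sizes >= chrom_sizes[prey$chrom]))
    stop("region too small to shuffle prey intervals")
  ann_gr <- as_granges(annotations)

  frac_by_class <- function(p) {
    gr <- as_granges(p)
    vapply(classes, function(cl) {
      sel <- ann_gr[annotations$class == cl]
      mean(IRanges::overlapsAny(gr, sel))
    }, 0)
  }

  obs <- frac_by_class(prey)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  bg <- matrix(0, n_shuffles, length(classes),
               dimnames = list(NULL, classes))
  for (s in seq_len(n_shuffles)) {
    lim <- chrom_sizes[prey$chrom] - sizes
    start <- floor(stats::runif(nrow(prey), 0, lim + 1))
    bg[s, ] <- frac_by_class(data.frame(chrom = prey$chrom, start = start,
                                        end = start + sizes))
  }
  mu <- colMeans(bg)
  fold <- obs / mu
  fold[mu == 0] <- NA_real_
  attr(fold, "observed") <- obs
  fold
}

#' Mean coverage metaprofile over intervals
#'
#' Averages a per-base coverage track over a set of intervals, anchored at the
#' interval edges: the body of each interval is length-normalised to a common
#' grid by linear interpolation, the flanks are kept at base resolution, and
#' minus-strand intervals are flipped so the profile reads 5' to 3'.
#'
#' @param coverage Named list chromosome -> numeric per-base coverage vector
#'   (position 1 = genomic position 0), or a bedGraph data.frame.
#' @param intervals data.frame `chrom`, `start`, `end` and optional `strand`.
#' @param flank Flank size in bp (default 1000).
#' @param body_points Grid size for the normalised interval body (default:
#'   the median interval span).
#' @return Numeric vector of length `flank + body_points + flank`: the
#'   position-wise mean across intervals.
#' @export
metaprofile <- function(coverage, intervals, flank = 1000, body_points = NULL) {
  if (is.data.frame(coverage)) coverage <- bedgraph_to_coverage(coverage)
  if (is.null(intervals$strand)) intervals$strand <- "+"
  if (is.null(body_points))
    body_points <- max(1L, round(stats::median(intervals$end - intervals$start)))
  profs <- matrix(NA_real_, nrow(intervals), flank + body_points + flank)
  for (i in seq_len(nrow(intervals))) {
    cv <- coverage[[intervals$chrom[i]]]
    if (is.null(cv)) stop("no coverage for chromosome ", intervals$chrom[i])
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s - flank < 0 || e + flank > length(cv))
      stop("interval (plus flank) runs off the coverage track")
    left <- cv[(s - flank + 1L):s]
    body <- cv[(s + 1L):e]
    right <- cv[(e + 1L):(e + flank)]
    if (length(body) != body_points)
      body <- stats::approx(seq_along(body), body,
                            xout = seq(1, length(body), length.out = body_points))$y
    row <- c(left, body, right)
    if (intervals$strand[i] == "-") row <- rev(row)
    profs[i, ] <- row
  }
  colMeans(profs)
}

# Expand a bedGraph data.frame into per-base coverage vectors.
bedgraph_to_coverage <- function(bg) {
  out <- list()
  for (chr in unique(bg$chrom)) {
    sub <- bg[bg$chrom == chr, , drop = FALSE]
    v <- numeric(max(sub$end))
    for (i in seq_len(nrow(sub)))
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    out[[chr]] <- v
  }
  out
}

#' Expression summaries by interaction grouping
#'
#' Joins an expression table onto per-gene interaction groups and reports
#' group means plus per-gene fold-change flags between two named stages
#' (inclusive >= `fold` threshold). Genes absent from the expression table
#' are dropped and counted; no hypothesis testing is performed.
#'
#' @param groups data.frame `gene`, `group` (e.g. enhancer-count group or
#'   promoter class).
#' @param expression data.frame `gene`, `stage`, `value`.
#' @param stage Stage whose expression is averaged per group.
#' @param fold_stages Length-2 character vector `c(from, to)` for the
#'   fold-change flag; NULL skips it.
#' @param fold Fold-change threshold (default 4, boundary inclusive).
#' @return List: `group_means` (data.frame `group`, `mean_expression`, `n`),
#'   `fold_flags` (data.frame `gene`, `fold_change`, `flag`), `n_missing`.
#' @export
expression_grouping <- function(groups, expression, stage,
                                fold_stages = NULL, fold = 4) {
  expr_stage <- expression[expression$stage == stage, , drop = FALSE]
  m <- match(groups$gene, expr_stage$gene)
  n_missing <- sum(is.na(m))
  ok <- !is.na(m)
  d <- data.frame(gene = groups$gene[ok], group = groups$group[ok],
                  value = expr_stage$value[m[ok]], stringsAsFactors = FALSE)
  gm <- stats::aggregate(value ~ group, d, mean)
  names(gm) <- c("group", "mean_expression")
  gm$n <- as.vector(table(d$group)[gm$group])

  fold_flags <- NULL
  if (!is.null(fold_stages)) {
    from <- expression[expression$stage == fold_stages[1], , drop = FALSE]
    to <- expression[expression$stage == fold_stages[2], , drop = FALSE]
    genes <- intersect(groups$gene, intersect(from$gene, to$gene))
    fc <- to$value[match(genes, to$gene)] / from$value[match(genes, from$gene)]
    fold_flags <- data.frame(gene = genes, fold_change = fc,
                             flag = fc >= fold, stringsAsFactors = FALSE)
  }
  list(group_means = gm, fold_flags = fold_flags, n_missing = n_missing)
}
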