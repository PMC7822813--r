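#' Library-complexity fold between two cutter resolutions
#'
#' Under a uniform-base genome model a k-bp motif occurs every 4^k bases, so
#' moving from a coarse cutter (e.g. 6-bp HindIII) to a fine one (4-bp DpnII)
#' multiplies the expected fragment count -- and hence 3C library complexity --
#' by 4^(k_coarse - k_fine). For 4 vs 6 bp this is the familiar 16-fold.
#'
#' @param k_fine Fine-cutter motif length (bp).
#' @param k_coarse Coarse-cutter motif length (bp); must be >= `k_fine`.
#' @return The fold-increase in expected fragment count.
#' @examples complexity_fold(4, 6)  # 16
#' @export
complexity_fold <- function(k_fine, k_coarse) {
  if (k_fine < 1 || k_coarse < 1) stop("motif lengths must be positive")
  if (k_coarse < k_fine) stop("k_coarse must be >= k_fine")
  4^(k_coarse - k_fine)
}

#' Audit the cost of masking co-targeted fragments
#'
#' Co-targeted fragments (fragments enriched by probes for more than one
#' viewpoint) carry enrichment bias and are masked from downstream analysis;
#' this reports how much of the fragment map such masking discards. Duplicate
#' target indices are ignored and ordering is irrelevant.
#'
#' @param map A `fragment_map`, or the total fragment count as a single number.
#' @param targets Fragment indices targeted by the design (any order,
#'   duplicates allowed), or for the count form, the number targeted.
#' @return List with `n_targeted`, `n_total`, `fraction_of_genome_fragments`
#'   and `percent` (rounded to 2 decimals).
#' @examples
#' cotarget_exclusion_stats(6415222, 59575)$percent  # 0.93
#' @export
cotarget_exclusion_stats <- function(map, targets) {
  if (inherits(map, "fragment_map") || is.data.frame(map)) {
    n_total <- nrow(map)
    targets <- unique(as.integer(targets))
    if (length(targets) && (any(targets < 1L) || any(targets > n_total)))
      stop("target index outside fragment map")
    n_targeted <- length(targets)
  } else {
    n_total <- as.numeric(map)
    n_targeted <- as.numeric(targets)[1]
  }
  if (n_total < 1) stop("fragment map is empty")
  frac <- n_targeted / n_total
  list(n_targeted = n_targeted, n_total = n_total,
       fraction_of_genome_fragments = frac,
       percent = round(100 * frac, 2))
}

#' Validate viewpoint target fragments
#'
#' Short viewpoint fragments tend to show elevated trans ligation even in
#' nuclear-isolated libraries, so fragments under `min_length` (default
#' 300 bp, strict `<`) are flagged, as are fragments too short to host a
#' full-length probe.
#'
#' @param design A viewpoint design `data.frame` with columns `viewpoint_id`
#'   and `fragment_index` (one row per target fragment).
#' @param map A `fragment_map`.
#' @param min_length Minimum recommended fragment length in bp.
#' @param probe_length Probe length in bp used for the too-short-for-probe check.
#' @return Character vector of warnings (empty when the design is clean).
#' @export
validate_viewpoints <- function(design, map, min_length = 300, probe_length = 120) {
  idx <- as.integer(design$fragment_index)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(map)))
    stop("viewpoint design refers to unknown fragment index")
  len <- map$end[idx] - map$start[idx]
  warnings <- character(0)
  short <- which(len < min_length)
  if (length(short))
    warnings <- c(warnings, sprintf(
      "viewpoint '%s': target fragment %d is %d bp (< %d bp); expect elevated trans signal",
      design$viewpoint_id[short], idx[short], len[short], min_length))
  tiny <- which(len < probe_length)
  if (length(tiny))
    warnings <- c(warnings, sprintf(
      "viewpoint '%s': target fragment %d (%d bp) is shorter than the %d bp probe",
      design$viewpoint_id[tiny], idx[tiny], len[tiny], probe_length))
  warnings
}

#' Place capture probes at the end(s) of a restriction fragment
#'
#' Probes are laid flush with the fragment ends. When the fragment is no
#' longer than the probe, the two end probes would coincide or overhang, so a
#' single fragment-spanning probe is emitted instead (with a warning).
#'
#' @param fragment One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param probe_length Probe length in bp (default 120).
#' @param ends `"both"` or `"one"` (one = the 5' end only).
#' @return data.frame of probe intervals `chrom`, `start`, `end`.
#' @examples
#' place_probes(list(chrom = "c1", start = 1000, end = 1500), 120, "both")
#' @export
place_probes <- function(fragment, probe_length = 120, ends = c("both", "one")) {
  ends <- match.arg(ends)
  if (probe_length < 1) stop("probe_length must be >= 1")
  s <- as.numeric(fragment$start); e <- as.numeric(fragment$end)
  chrom <- as.character(fragment$chrom)
  if (e - s <= probe_length) {
    warning("fragment shorter than probe; emitting one fragment-spanning probe")
    return(data.frame(chrom = chrom, start = s, end = e, stringsAsFactors = FALSE))
  }
  out <- data.frame(chrom = chrom, start = s, end = s + probe_length,
                    stringsAsFactors = FALSE)
  if (ends == "both")
    out <- rbind(out, data.frame(chrom = chrom, start = e - probe_length,
                                 end = e, stringsAsFactors = FALSE))
  out
}

#' Titrated capture-pool dosing arithmetic
#'
#' The titrated pool is assembled by multiplying the number of unique
#' oligonucleotides by the per-oligo stock concentration; the amount of each
#' oligo in a reaction is concentration x volume (nM x uL = fmol).
#'
#' @param n_unique Number of unique oligos in the pool.
#' @param per_oligo_stock Per-oligo stock concentration (nM), default 2.9.
#' @param reaction_volume Volume of stock per capture reaction (uL), default 4.5.
#' @return List with `total_stock` (nM) and `per_oligo_amount` (fmol).
#' @examples
#' pool_dosing(1)$per_oligo_amount  # 13.05 fmol, c.f. the quoted 13 fmol
#' @export
pool_dosing <- function(n_unique, per_oligo_stock = 2.9, reaction_volume = 4.5) {
  if (n_unique < 1) stop("n_unique must be >= 1")
  if (per_oligo_stock < 0 || reaction_volume < 0)
    stop("concentration and volume must be non-negative")
  list(total_stock = n_unique * per_oligo_stock,
       per_oligo_amount = per_oligo_stock * reaction_volume)
}

#' Maximum off-target identity of a probe sequence
#'
#' Slides the probe ungapped along both strands of every chromosome and
#' returns the maximum percent identity outside the design position. Short
#' probes trade informative capture for specificity: near-identical paralogous
#' sequence shows up here as off-target identity approaching 100%.
#'
#' @param probe Probe sequence (character or DNAString).
#' @param genome Genome as for [digest_genome()].
#' @param design_chrom,design_start Design placement to exclude (0-based start
#'   on the forward strand); omit to scan everything.
#' @return Maximum off-target percent identity (0-100).
#' @export
probe_specificity <- function(probe, genome, design_chrom = NULL,
                              design_start = NULL) {
  genome <- as_genome(genome)
  probe <- toupper(as.character(probe))
  L <- nchar(probe)
  if (L > min(Biostrings::nchar(genome)))
    stop("probe longer than the shortest chromosome")
  p <- Biostrings::DNAString(probe)
  rc <- Biostrings::reverseComplement(p)
  best <- 0
  for (chr in names(genome)) {
    subject <- genome[[chr]]
    n <- Biostrings::nchar(subject) - L + 1L
    at <- seq_len(n)
    mm_f <- Biostrings::neditStartingAt(p, subject, starting.at = at,
                                        with.indels = FALSE)
    mm_r <- Biostrings::neditStartingAt(rc, subject, starting.at = at,
                                        with.indels = FALSE)
    id_f <- (L - mm_f) / L * 100
    id_r <- (L - mm_r) / L * 100
    if (!is.null(design_chrom) && identical(chr, design_chrom) &&
        !is.null(design_start)) {
      hit <- which(at - 1L == design_start)
      if (length(hit)) id_f[hit] <- 0
    }
    best <- max(best, id_f, id_r)
  }
  best
}

#' Read / write viewpoint designs as TSV
#'
#' Columns: `viewpoint_id`, `chrom`, `start`, `end`, `strand`,
#' `fragment_index` (one row per target fragment; a viewpoint may have
#' several).
#' @param design Viewpoint design data.frame.
#' @param path File path.
#' @export
write_viewpoints_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_viewpoints_tsv
#' @export
read_viewpoints_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Assign TSS positions to target fragments
#'
#' Two conventions are supported: `"point"` assigns the single fragment
#' containing the TSS base; `"window"` assigns every fragment overlapping a
#' promoter window `[tss - flank, tss + flank)`. Several TSSs can land on one
#' fragment, so the number of distinct target fragments is typically smaller
#' than the number of TSSs.
#'
#' @param map A `fragment_map`.
#' @param tss data.frame with `chrom`, `pos` (0-based TSS base) and optionally
#'   `viewpoint_id`, `strand`.
#' @param rule `"point"` or `"window"`.
#' @param flank Promoter half-window in bp for `rule = "window"`.
#' @return data.frame `viewpoint_id`, `chrom`, `start`, `end`, `strand`,
#'   `fragment_index`.
#' @export
tss_to_fragments <- function(map, tss, rule = c("point", "window"), flank = 500) {
  rule <- match.arg(rule)
  if (is.null(tss$viewpoint_id))
    tss$viewpoint_id <- paste0("vp", seq_len(nrow(tss)))
  if (is.null(tss$strand)) tss$strand <- "+"
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    if (rule == "point") {
      idx <- locate_fragment(map, tss$chrom[i], tss$pos[i])
    } else {
      sub <- map[map$chrom == tss$chrom[i], , drop = FALSE]
      lo <- tss$pos[i] - flank; hi <- tss$pos[i] + flank
      idx <- sub$index[sub$end > lo & sub$start < hi]
    }
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    data.frame(viewpoint_id = tss$viewpoint_id[i],
               chrom = map$chrom[idx], start = map$start[idx],
               end = map$end[idx], strand = tss$strand[i],
               fragment_index = idx, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
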