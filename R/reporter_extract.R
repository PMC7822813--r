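#' Split a read sequence at restriction motif occurrences
#'
#' Applies the same cut convention as [digest_genome()] (cut immediately 5' of
#' each motif) to read sequences, reconstructing the restriction slices that
#' were ligated into the chimeric molecule. A read with no motif yields one
#' slice; a motif at position 0 produces no empty leading slice.
#'
#' @param read_sequence Character vector of read sequences (A/C/G/T/N).
#' @param motif Restriction motif, as in [digest_genome()].
#' @return For a single read, a character vector of slices; for several reads,
#'   a list of such vectors.
#' @examples split_at_motif("ACGATCGGATCA", "GATC")  # "AC" "GATCG" "GATCA"
#' @export
split_at_motif <- function(read_sequence, motif) {
  if (any(!nzchar(read_sequence))) stop("empty read sequence")
  # lookahead regex finds overlapping occurrences
  pat <- paste0("(?=", motif, ")")
  hits <- gregexpr(pat, read_sequence, perl = TRUE)
  out <- mapply(function(s, h) {
    cuts <- h[h > 1L]                    # cut at pos 1 adds no slice
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, nchar(s))
    substring(s, starts, ends)
  }, read_sequence, hits, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (length(out) == 1L) out[[1]] else out
}

#' Build an exact-match k-mer index for slice placement
#'
#' Indexes every forward-strand k-mer of a genome so that read slices can be
#' placed by seed-and-verify exact matching. Intended for synthetic genomes
#' built with unique k-mers; k-mers occurring more than once are marked
#' ambiguous and never used as seeds. Alignment against real genomes is out of
#' scope -- use an external aligner and supply placements as a table.
#'
#' @param genome Genome as for [digest_genome()].
#' @param k Seed length (default 20).
#' @return A `kmer_index` list used by [place_slices()].
#' @export
build_kmer_index <- function(genome, k = 20L) {
  genome <- as_genome(genome)
  seqs <- as.character(genome)
  kmers <- character(0); chrom <- character(0); pos <- integer(0)
  for (chr in names(seqs)) {
    s <- seqs[[chr]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    kmers <- c(kmers, substring(s, 1:n, k:(n + k - 1L)))
    chrom <- c(chrom, rep(chr, n))
    pos <- c(pos, 0:(n - 1L))
  }
  dup <- kmers %in% kmers[duplicated(kmers)]
  structure(list(kmers = kmers, chrom = chrom, pos = pos, dup = dup,
                 k = k, seqs = seqs),
            class = "kmer_index")
}

#' Place read slices on a genome by exact matching
#'
#' Each slice is seeded by its first k-mer on the forward strand, then by the
#' first k-mer of its reverse complement, and the full slice is verified
#' against the genome. Slices shorter than k, failing verification, or seeded
#' on an ambiguous k-mer are reported unplaced (`chrom = NA`); a slice whose
#' seed is ambiguous between chromosomes is flagged in `ambiguous`.
#'
#' @param slices Character vector of slice sequences.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand` and `ambiguous` per slice.
#' @export
place_slices <- function(slices, index) {
  n <- length(slices)
  out <- data.frame(chrom = rep(NA_character_, n), start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  k <- index$k
  len <- nchar(slices)

  try_strand <- function(query, todo, strand) {
    seed <- substr(query[todo], 1L, k)
    m <- match(seed, index$kmers)
    hit <- which(!is.na(m))
    for (h in hit) {
      i <- todo[h]; mi <- m[h]
      if (index$dup[mi]) { out$ambiguous[i] <<- TRUE; next }
      chr <- index$chrom[mi]; p0 <- index$pos[mi]
      full <- substr(index$seqs[[chr]], p0 + 1L, p0 + len[i])
      if (identical(full, query[i])) {
        out$chrom[i] <<- chr
        out$start[i] <<- p0
        out$end[i] <<- p0 + len[i]
        out$strand[i] <<- strand
      }
    }
  }

  todo <- which(len >= k)
  if (length(todo)) try_strand(slices, todo, "+")
  left <- which(len >= k & is.na(out$chrom) & !out$ambiguous)
  if (length(left)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(slices[left])))
    q <- slices; q[left] <- rc
    try_strand(q, left, "-")
  }
  out
}

#' Classify placed slices as capture / exclusion / reporter / unmapped
#'
#' A slice is `capture` if it overlaps any target fragment of the design,
#' `exclusion` if it lies strictly closer than `exclusion_radius` bp to a
#' target fragment on the same chromosome without overlapping it (undigested
#' or re-ligated proximal material; a radius of 0 disables the zone),
#' `reporter` otherwise, and `unmapped` if unplaced.
#'
#' @param placed data.frame from [place_slices()] (or an external placement
#'   table with `chrom`, `start`, `end`).
#' @param design Viewpoint design (see [validate_viewpoints()]).
#' @param map A `fragment_map`.
#' @param exclusion_radius Exclusion zone half-width in bp (default 1000).
#' @return `placed` with added columns `fragment_index`, `label` and
#'   `viewpoint_id` (the viewpoint whose target a capture slice hit, else NA).
#' @export
classify_slices <- function(placed, design, map, exclusion_radius = 1000) {
  n <- nrow(placed)
  mid <- (placed$start + placed$end) / 2
  frag <- locate_fragment(map, placed$chrom, floor(mid))
  label <- rep("unmapped", n)
  vp <- rep(NA_character_, n)
  placed_ok <- !is.na(placed$chrom) & !is.na(frag)

  tgt <- design$fragment_index
  is_capture <- placed_ok & frag %in% tgt
  vp[is_capture] <- design$viewpoint_id[match(frag[is_capture], tgt)]
  label[is_capture] <- "capture"

  # exclusion: interval distance to nearest target fragment <= radius
  near <- rep(FALSE, n)
  for (chr in unique(design$chrom)) {
    ts <- design[design$chrom == chr, , drop = FALSE]
    sel <- which(placed_ok & placed$chrom == chr & !is_capture)
    if (!length(sel) || !nrow(ts)) next
    for (t in seq_len(nrow(ts))) {
      d <- pmax(ts$start[t] - placed$end[sel], placed$start[sel] - ts$end[t], 0)
      near[sel] <- near[sel] | d < exclusion_radius   # radius 0 disables the zone
    }
  }
  label[placed_ok & !is_capture & near] <- "exclusion"
  label[placed_ok & !is_capture & !near] <- "reporter"

  placed$fragment_index <- frag
  placed$label <- label
  placed$viewpoint_id <- vp
  placed
}

#' Assemble reporter events from classified slices
#'
#' Emits one event per reporter slice of every read that contains at least one
#' capture slice. Reads whose capture slices belong to two different
#' viewpoints are ambiguous and dropped (counted). The duplicate key is the
#' sorted tuple of all placed slice coordinates plus the sonication ends
#' (outermost placed coordinates of the molecule), so identical PCR copies
#' collapse while independent molecules with the same fragment pair survive.
#'
#' @param slices Classified slice table ([classify_slices()]) with a `read_id`
#'   column.
#' @param design Viewpoint design.
#' @param map A `fragment_map`.
#' @return List: `events` data.frame (`read_id`, `viewpoint_id`,
#'   `fragment_index`, `chrom`, `cis`, `distance`, `duplicate_key`) and
#'   counter `n_ambiguous_viewpoint`.
#' @export
build_events <- function(slices, design, map) {
  stopifnot(!is.null(slices$read_id))
  cap <- slices[slices$label == "capture", , drop = FALSE]
  nvp <- tapply(cap$viewpoint_id, cap$read_id,
                function(v) length(unique(v)))
  ambiguous_reads <- names(nvp)[nvp > 1L]
  good_reads <- names(nvp)[nvp == 1L]
  read_vp <- vapply(split(cap$viewpoint_id, cap$read_id), `[`, "", 1L)
  # capture fragment per read (first capture slice): anchors the viewpoint side
  read_capfrag <- vapply(split(cap$fragment_index, cap$read_id),
                         `[`, 0L, 1L)

  rep_sl <- slices[slices$label == "reporter" &
                   slices$read_id %in% good_reads, , drop = FALSE]

  # duplicate key per read over all placed slices + sonication ends
  pl <- slices[!is.na(slices$chrom), , drop = FALSE]
  key_of <- vapply(split(seq_len(nrow(pl)), pl$read_id), function(ix) {
    coords <- sprintf("%s:%d-%d", pl$chrom[ix], pl$start[ix], pl$end[ix])
    ends <- sprintf("%s:%d|%s:%d",
                    pl$chrom[ix][which.min(pl$start[ix])], min(pl$start[ix]),
                    pl$chrom[ix][which.max(pl$end[ix])], max(pl$end[ix]))
    paste(c(sort(coords), ends), collapse = ";")
  }, "")

  if (nrow(rep_sl) == 0L) {
    events <- data.frame(read_id = character(0), viewpoint_id = character(0),
                         fragment_index = integer(0), chrom = character(0),
                         cis = logical(0), distance = numeric(0),
                         duplicate_key = character(0), stringsAsFactors = FALSE)
    return(list(events = events,
                n_ambiguous_viewpoint = length(ambiguous_reads)))
  }

  vp_id <- read_vp[rep_sl$read_id]
  capfrag <- read_capfrag[rep_sl$read_id]
  mids <- fragment_midpoints(map)
  vp_chrom <- map$chrom[capfrag]
  cis <- rep_sl$chrom == vp_chrom
  dist <- ifelse(cis, mids[rep_sl$fragment_index] - mids[capfrag], NA_real_)

  events <- data.frame(read_id = rep_sl$read_id,
                       viewpoint_id = unname(vp_id),
                       fragment_index = rep_sl$fragment_index,
                       chrom = rep_sl$chrom,
                       cis = cis,
                       distance = dist,
                       duplicate_key = unname(key_of[rep_sl$read_id]),
                       stringsAsFactors = FALSE)
  list(events = events, n_ambiguous_viewpoint = length(ambiguous_reads))
}

#' Collapse PCR duplicates by sonication-breakpoint key
#'
#' Reads with identical duplicate keys (same slice coordinates and sonication
#' ends) collapse to the first occurrence; all events of that read are kept.
#' Idempotent: `dedup_events(dedup_events(x))` equals `dedup_events(x)`.
#'
#' @param events Event table from [build_events()].
#' @return Deduplicated event table.
#' @export
dedup_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  first_read <- tapply(events$read_id, events$duplicate_key, `[`, 1L)
  keep <- events$read_id == unname(first_read[events$duplicate_key])
  events[keep, , drop = FALSE]
}

#' Capture enrichment fold over the uniform expectation
#'
#' The observed on-target fraction divided by the fraction expected if reads
#' fell uniformly over all restriction fragments (n_target / n_total). A
#' 97.70% on-target run against a single DpnII fragment of ~6.4 million is a
#' ~6.3-million-fold enrichment.
#'
#' @param on_target_fraction Fraction of mapped reads containing a target
#'   fragment, in \[0, 1\].
#' @param n_target_fragments,n_total_fragments Fragment counts (>= 1).
#' @return Enrichment fold.
#' @examples enrichment_fold(0.977, 1, 6415222)  # ~6.27e6
#' @export
enrichment_fold <- function(on_target_fraction, n_target_fragments,
                            n_total_fragments) {
  if (on_target_fraction < 0 || on_target_fraction > 1)
    stop("on_target_fraction must be in [0,1]")
  if (n_target_fragments < 1 || n_total_fragments < 1)
    stop("fragment counts must be >= 1")
  on_target_fraction * n_total_fragments / n_target_fragments
}

#' Extract reporter events from chimeric reads
#'
#' The full extraction pipeline: split reads at the restriction motif, place
#' slices (built-in exact matcher for synthetic genomes, or a supplied
#' placement table for externally aligned data), classify against the design,
#' assemble events, and deduplicate on sonication breakpoints.
#'
#' @param reads Named character vector of read sequences (names = read ids),
#'   or a DNAStringSet (e.g. from [read_fastq()]).
#' @param design Viewpoint design table.
#' @param map A `fragment_map`.
#' @param genome Genome for built-in placement (synthetic genomes only);
#'   ignored when `placements` is given.
#' @param placements Optional pre-computed placement table with columns
#'   `read_id`, `slice_idx`, `chrom`, `start`, `end`, `strand`.
#' @param exclusion_radius Exclusion zone in bp around target fragments.
#' @param motif Restriction motif; defaults to the map's motif attribute.
#' @param index Optional prebuilt `kmer_index` (saves rebuilding per call).
#' @param species_map Optional named vector chrom -> species label; when
#'   given, events gain `capture_species`/`reporter_species` columns.
#' @return List with `events` (pre-dedup), `events_dedup`, `slices`
#'   (classified), `stats` ([capture_stats()] output) and counters.
#' @export
extract_reporters <- function(reads, design, map, genome = NULL,
                              placements = NULL, exclusion_radius = 1000,
                              motif = attr(map, "motif"), index = NULL,
                              species_map = NULL) {
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads); reads <- as.character(reads); names(reads) <- nm
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (is.na(motif) || is.null(motif)) stop("motif must be supplied")

  slc <- split_at_motif(unname(reads), motif)
  if (!is.list(slc)) slc <- list(slc)
  nsl <- lengths(slc)
  slices <- data.frame(read_id = rep(names(reads), nsl),
                       slice_idx = unlist(lapply(nsl, seq_len)),
                       seq = unlist(slc), stringsAsFactors = FALSE)
  has_motif <- grepl(motif, unname(reads), fixed = TRUE)

  if (!is.null(placements)) {
    key <- paste(slices$read_id, slices$slice_idx)
    pkey <- paste(placements$read_id, placements$slice_idx)
    m <- match(key, pkey)
    placed <- data.frame(chrom = placements$chrom[m],
                         start = placements$start[m],
                         end = placements$end[m],
                         strand = placements$strand[m],
                         ambiguous = FALSE, stringsAsFactors = FALSE)
  } else {
    if (is.null(index)) {
      if (is.null(genome)) stop("supply either a genome or a placement table")
      index <- build_kmer_index(genome)
    }
    placed <- place_slices(slices$seq, index)
  }
  slices <- cbind(slices[c("read_id", "slice_idx")], placed)
  slices <- classify_slices(slices, design, map, exclusion_radius)

  be <- build_events(slices, design, map)
  events <- be$events
  if (!is.null(species_map)) {
    cap <- slices[slices$label == "capture", , drop = FALSE]
    cap_chr <- vapply(split(cap$chrom, cap$read_id), `[`, "", 1L)
    events$capture_species <- unname(species_map[cap_chr[events$read_id]])
    events$reporter_species <- unname(species_map[events$chrom])
  }
  dedup <- dedup_events(events)
  stats <- capture_stats(n_reads = length(reads),
                         has_motif = has_motif,
                         slices = slices, events = events,
                         events_dedup = dedup,
                         n_target_fragments = length(unique(design$fragment_index)),
                         n_total_fragments = nrow(map))
  list(events = events, events_dedup = dedup, slices = slices, stats = stats,
       n_ambiguous_viewpoint = be$n_ambiguous_viewpoint)
}

#' Summary statistics for a capture experiment
#'
#' @param n_reads Total reads processed.
#' @param has_motif Logical per read: contains the restriction motif.
#' @param slices Classified slice table.
#' @param events,events_dedup Event tables pre/post deduplication.
#' @param n_target_fragments,n_total_fragments Design and map sizes for the
#'   enrichment fold.
#' @return A `capture_stats` list: mapped reads, capture-containing reads,
#'   reporters pre/post dedup, cis/trans counts, on-target fraction,
#'   enrichment fold, percent reads with motif, reporters per 100
#'   capture-containing reads.
#' @export
capture_stats <- function(n_reads, has_motif, slices, events, events_dedup,
                          n_target_fragments, n_total_fragments) {
  placed_reads <- unique(slices$read_id[!is.na(slices$chrom)])
  cap_reads <- unique(slices$read_id[slices$label == "capture"])
  n_mapped <- length(placed_reads)
  n_cap <- length(cap_reads)
  on_target <- if (n_mapped > 0) n_cap / n_mapped else 0
  fold <- if (n_mapped > 0)
    enrichment_fold(on_target, n_target_fragments, n_total_fragments) else 0
  n_cis <- sum(events_dedup$cis)
  n_trans <- sum(!events_dedup$cis)
  structure(list(
    n_reads = n_reads,
    n_mapped = n_mapped,
    n_capture_reads = n_cap,
    reporters_pre_dedup = nrow(events),
    reporters_post_dedup = nrow(events_dedup),
    n_cis = n_cis, n_trans = n_trans,
    on_target_fraction = on_target,
    enrichment_fold = fold,
    percent_reads_with_motif = 100 * mean(has_motif),
    reporters_per_100_capture_reads =
      if (n_cap > 0) 100 * nrow(events_dedup) / n_cap else 0
  ), class = "capture_stats")
}

#' @export
print.capture_stats <- function(x, ...) {
  cat("capture_stats\n")
  for (nm in names(x))
    cat(sprintf("  %-32s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

#' Read / write reporter event tables as TSV
#' @param events Event table.
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a FASTQ file (optionally gzipped)
#' @param path FASTQ path.
#' @return Named DNAStringSet.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
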