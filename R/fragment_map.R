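#' In-silico restriction digestion of a genome
#'
#' Scans every chromosome for occurrences of the restriction motif and places
#' a blunt cut immediately 5' of each occurrence (the `^GATC` convention of
#' 4-bp cutters such as DpnII). The resulting fragments tile each chromosome
#' with no gaps or overlaps: every fragment except the first on a chromosome
#' begins with the motif, and the fragment set is a partition of the genome.
#'
#' Runs of `N` receive no special handling; they simply contain no motif and
#' end up inside ordinary fragments. Overlapping motif occurrences (possible
#' for self-overlapping motifs) are found by scanning every position.
#'
#' @param genome A named list or character vector of chromosome sequences
#'   (alphabet `A,C,G,T,N`), or a [Biostrings::DNAStringSet].
#' @param motif Recognition motif over `A/C/G/T`, e.g. `"GATC"` for DpnII.
#' @param enzyme Optional enzyme name stored on the map (default the motif).
#'
#' @return A `fragment_map`: a `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based, half-open) and `index` (genome-wide ordinal, 1-based),
#'   carrying `enzyme` and `motif` attributes.
#'
#' @examples
#' fm <- digest_genome(c(c1 = "ACGATCGGATCA"), "GATC")
#' fm[, c("start", "end")]   # fragments [0,2), [2,7), [7,12)
#' @export
digest_genome <- function(genome, motif, enzyme = motif) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over A/C/G/T")
  chroms <- names(genome)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")

  pieces <- lapply(chroms, function(chr) {
    seq_len_chr <- Biostrings::nchar(genome[[chr]])
    if (seq_len_chr == 0L) stop("chromosome '", chr, "' has empty sequence")
    hits <- Biostrings::matchPattern(motif, genome[[chr]])
    cuts <- BiocGenerics::start(hits) - 1L          # 0-based cut positions
    cuts <- cuts[cuts > 0L]                         # cut at 0 makes no new fragment
    starts <- c(0L, cuts)
    ends <- c(cuts, seq_len_chr)
    data.frame(chrom = chr, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, pieces)
  frags$index <- seq_len(nrow(frags))
  structure(frags, enzyme = enzyme, motif = motif,
            class = c("fragment_map", "data.frame"))
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d fragments on %d chromosome(s), motif %s (%s)\n",
              nrow(x), length(unique(x$chrom)),
              attr(x, "motif"), attr(x, "enzyme")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Coerce genomes to DNAStringSet; accepts named character vectors/lists.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.list(genome)) genome <- unlist(genome)
  if (!is.character(genome)) stop("genome must be named sequences or a DNAStringSet")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("all chromosomes must be named")
  Biostrings::DNAStringSet(genome)
}

#' Map genomic positions to fragment indices
#'
#' @param map A `fragment_map`.
#' @param chrom Chromosome names (recycled against `pos`).
#' @param pos 0-based positions.
#' @return Genome-wide fragment indices; `NA` for positions off the map.
#' @export
locate_fragment <- function(map, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_integer_, n)
  for (chr in unique(chrom[!is.na(chrom)])) {
    sel <- which(!is.na(chrom) & chrom == chr & !is.na(pos))
    if (!length(sel)) next
    sub <- map[map$chrom == chr, , drop = FALSE]
    if (nrow(sub) == 0L) next
    i <- findInterval(pos[sel], sub$start)
    ok <- i >= 1L & pos[sel] >= 0L & pos[sel] < sub$end[nrow(sub)]
    out[sel[ok]] <- sub$index[i[ok]]
  }
  out
}

#' Fragment midpoints (0-based, possibly half-integer)
#' @param map A `fragment_map`.
#' @return Numeric midpoints indexed like the map rows.
#' @export
fragment_midpoints <- function(map) (map$start + map$end) / 2

#' Write / read a fragment map as BED4 (chrom, start, end, index)
#' @param map A `fragment_map`.
#' @param path Output file.
#' @export
write_fragment_bed <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "start", "end", "index")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_bed
#' @param motif,enzyme Motif/enzyme metadata to re-attach on read.
#' @export
read_fragment_bed <- function(path, motif = NA_character_, enzyme = motif) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "index"))
  structure(d, enzyme = enzyme, motif = motif,
            class = c("fragment_map", "data.frame"))
}
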