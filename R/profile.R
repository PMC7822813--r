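#' Normalise a fragment profile to reporters per 100,000 cis reporters
#'
#' Scales per-fragment unique reporter counts so the cis fragments sum to
#' 100,000, making profiles comparable across viewpoints and sequencing
#' depths. Masked (NA) fragments are excluded from both the numerator and the
#' denominator and stay NA in the output.
#'
#' @param counts Per-fragment counts; NA marks masked fragments.
#' @param cis Logical per fragment: on the viewpoint chromosome. Default all.
#' @return Normalised numeric vector, same length.
#' @examples normalize_per_100k(c(10, 0, 40))  # 20000 0 80000
#' @export
normalize_per_100k <- function(counts, cis = rep(TRUE, length(counts))) {
  tot <- sum(counts[cis], na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) stop("zero cis total; cannot normalise")
  counts * 1e5 / tot
}

#' Proportionally assign fragment counts to fixed-width bins
#'
#' Each fragment's count is distributed across the bins it overlaps in
#' proportion to the overlap length, so total signal is conserved exactly.
#' Bins tile `[region_start, region_end)`; fragments outside the region
#' contribute only their overlapping part.
#'
#' @param map A `fragment_map` (or data.frame with `chrom`, `start`, `end`,
#'   `index`) restricted to one chromosome, or the full map plus `chrom`.
#' @param counts Per-fragment counts aligned with `map$index`; NA fragments
#'   contribute nothing.
#' @param width Bin width in bp (default 250).
#' @param chrom Chromosome to bin (default: the map's single chromosome).
#' @param region_start,region_end Region to tile; defaults to the chromosome
#'   span rounded out to whole bins.
#' @return data.frame `chrom`, `start`, `end`, `value` -- a binned track.
#' @export
bin_proportional <- function(map, counts, width = 250, chrom = NULL,
                             region_start = NULL, region_end = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(map$chrom)
    if (length(chrom) != 1L) stop("supply `chrom` for a multi-chromosome map")
  }
  sub <- map[map$chrom == chrom, , drop = FALSE]
  val <- counts[sub$index]
  if (is.null(region_start)) region_start <- 0L
  if (is.null(region_end)) region_end <- max(sub$end)
  edges <- seq(region_start, region_start +
                 width * ceiling((region_end - region_start) / width), by = width)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (i in seq_len(nrow(sub))) {
    v <- val[i]
    if (is.na(v) || v == 0) next
    fs <- sub$start[i]; fe <- sub$end[i]; fl <- fe - fs
    b0 <- max(1L, findInterval(fs, edges))
    b1 <- min(nb, findInterval(fe - 1e-9, edges))
    for (b in b0:b1) {
      ov <- min(fe, edges[b + 1L]) - max(fs, edges[b])
      if (ov > 0) acc[b] <- acc[b] + v * ov / fl
    }
  }
  data.frame(chrom = chrom, start = edges[-length(edges)], end = edges[-1L],
             value = acc, stringsAsFactors = FALSE)
}

#' Windowed (moving-average) smoothing of a binned track
#'
#' Replaces each bin with the mean of the surrounding window (default 11 bins,
#' the bin plus five on each side). At the track edges the mean is taken over
#' the available bins, so the output has no missing leading or trailing
#' values. A window of 1 is the identity.
#'
#' @param track A binned track from [bin_proportional()], or a numeric vector
#'   of bin values.
#' @param n_bins Window size in bins; must be odd.
#' @return Same shape as the input with smoothed values.
#' @export
window_mean <- function(track, n_bins = 11) {
  if (n_bins %% 2 != 1) stop("window size must be odd")
  v <- if (is.data.frame(track)) track$value else track
  half <- (n_bins - 1L) / 2L
  n <- length(v)
  # running mean over available bins via cumulative sums
  cs <- cumsum(c(0, v))
  cn <- cumsum(c(0, rep(1, n)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (cn[hi + 1L] - cn[lo])
  if (is.data.frame(track)) { track$value <- sm; track } else sm
}

#' Mean profile across replicates
#'
#' @param replicates List of per-fragment count vectors (aligned indices), or
#'   a matrix with one column per replicate.
#' @return List with `mean` (per-fragment mean) and `n_replicates`.
#' @export
mean_profile <- function(replicates) {
  if (is.list(replicates)) {
    lens <- lengths(replicates)
    if (length(unique(lens)) != 1L) stop("replicates have misaligned indices")
    replicates <- do.call(cbind, replicates)
  }
  list(mean = rowMeans(replicates), n_replicates = ncol(replicates))
}

#' Pearson correlation between two profiles
#'
#' @param a,b Equal-length numeric vectors (typically windowed tracks).
#' @return List with `r` and `r_squared`.
#' @export
replicate_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("need at least 3 finite paired points")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    stop("zero variance in a profile")
  r <- stats::cor(a[ok], b[ok])
  list(r = r, r_squared = r^2)
}

#' Write a track as bedGraph (0-based half-open)
#' @param track data.frame `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param name Track name for the header line (omit header with `NULL`).
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(track[, c("chrom", "start", "end", "value")], con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path (optional `track` header line is skipped).
#' @return data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "track")) 1L else 0L
  utils::read.table(path, sep = "\t", skip = skip, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "value"))
}

#' Per-fragment profile from deduplicated events
#'
#' Tallies unique reporter events per fragment for one viewpoint.
#'
#' @param events Deduplicated event table.
#' @param map A `fragment_map`.
#' @param viewpoint Viewpoint id to profile (default: all events).
#' @param cis_only Keep cis events only (default TRUE).
#' @return Numeric vector of counts, length `nrow(map)`, indexed by fragment.
#' @export
fragment_profile <- function(events, map, viewpoint = NULL, cis_only = TRUE) {
  if (!is.null(viewpoint))
    events <- events[events$viewpoint_id == viewpoint, , drop = FALSE]
  if (cis_only) events <- events[events$cis, , drop = FALSE]
  counts <- numeric(nrow(map))
  if (nrow(events)) {
    t <- table(events$fragment_index)
    counts[as.integer(names(t))] <- as.numeric(t)
  }
  counts
}
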