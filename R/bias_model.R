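#' Capture probability for a ligation product under the either-probe model
#'
#' A ligation product between fragments i and j is retained by one round of
#' oligonucleotide pull-down if a probe on either constituent fragment binds:
#' by inclusion-exclusion the per-round retention is
#' \deqn{e_i + e_j - e_i e_j,}
#' and over r independent identical rounds (double capture: r = 2) the joint
#' retention is that quantity to the r-th power. For a partner that carries no
#' probe, set `e_j = 0`.
#'
#' @param e_i,e_j Capture efficiencies of the two fragments, in \[0, 1\].
#' @param rounds Number of capture rounds (1 = single, 2 = double capture).
#' @return Retention probability in \[0, 1\]. Vectorised over `e_i`/`e_j`.
#' @examples
#' capture_prob(0.5, 0.5, 1)  # 0.75
#' capture_prob(0.5, 0.5, 2)  # 0.5625
#' @export
capture_prob <- function(e_i, e_j, rounds = 1) {
  stopifnot(all(e_i >= 0 & e_i <= 1), all(e_j >= 0 & e_j <= 1), rounds >= 1)
  (e_i + e_j - e_i * e_j)^rounds
}

#' Co-targeting enrichment bias factor
#'
#' The fold by which co-targeting fragment j inflates the observed ligation
#' frequency between a viewpoint (efficiency `e_i`) and fragment j, relative
#' to the same fragment untargeted:
#' \deqn{B = \left(\frac{e_i + e_j - e_i e_j}{e_i}\right)^r.}
#' The factor is 1 when `e_j = 0` or `e_i = 1`, and grows as the viewpoint's
#' own efficiency falls -- a weakly captured viewpoint gains proportionally
#' more from its partner's probes.
#'
#' @inheritParams capture_prob
#' @return Bias fold >= 1. Vectorised.
#' @examples bias_factor(0.5, 0.5, 1)  # 1.5
#' @export
bias_factor <- function(e_i, e_j, rounds = 1) {
  if (any(e_i <= 0)) stop("e_i must be > 0 for a defined bias factor")
  # analytically >= 1 for valid efficiencies; pmax guards against
  # floating-point dips like (1 + e_j - 1*e_j) < 1
  pmax(capture_prob(e_i, e_j, rounds) / capture_prob(e_i, 0, rounds), 1)
}

#' Bias surface over an efficiency grid
#'
#' Evaluates [bias_factor()] over a grid of viewpoint and partner efficiencies.
#' Over the default 5%--100% grid with single capture the bias ranges from
#' 1-fold (untargeted partner) to 20-fold (5% viewpoint, fully captured
#' partner).
#'
#' @param efficiencies Grid of efficiencies for both axes; default
#'   `seq(0.05, 1, by = 0.05)`. The 0.05 floor is a toolkit constant: bias is
#'   unbounded as `e_i` tends to 0, so the grid starts at the smallest
#'   efficiency worth designing for.
#' @inheritParams capture_prob
#' @return Matrix of bias factors, rows `e_i`, columns `e_j`, dimnames set.
#' @export
bias_surface <- function(efficiencies = seq(0.05, 1, by = 0.05), rounds = 1) {
  m <- outer(efficiencies, efficiencies,
             function(a, b) bias_factor(a, b, rounds))
  dimnames(m) <- list(e_i = formatC(efficiencies), e_j = formatC(efficiencies))
  m
}

#' Expected observed profile under capture bias
#'
#' Given a true contact profile f and per-fragment capture efficiencies,
#' returns the expected observed (post-capture) profile: observed_j is
#' proportional to f_j x capture_prob(e_i, e_j, rounds), renormalised to the
#' input total so bias shows as redistribution, not loss.
#'
#' @param f Non-negative true interaction frequencies per fragment.
#' @param e_i Viewpoint capture efficiency (> 0).
#' @param e_j Per-fragment partner efficiencies aligned with `f` (0 where
#'   untargeted).
#' @inheritParams capture_prob
#' @return Numeric vector, same length and total as `f`.
#' @export
biased_profile <- function(f, e_i, e_j, rounds = 1) {
  stopifnot(length(f) == length(e_j), all(f >= 0))
  if (!any(f > 0)) stop("true profile is all zero")
  w <- f * capture_prob(e_i, e_j, rounds)
  w / sum(w) * sum(f)
}

#' Relative skew of counts at co-targeted fragments
#'
#' For each co-targeted fragment j the skew against the local background is
#' \deqn{(c_j - \bar c_{j\pm1}) / \bar c_{j\pm1}} where the bar is the mean of
#' the two flanking fragments. Fragments whose neighbours are absent or have
#' zero mean are skipped and counted.
#'
#' @param counts Observed counts in genome order (one chromosome or a
#'   contiguous region).
#' @param cotargets Integer positions (into `counts`) of co-targeted fragments.
#' @return List with `skew` (named numeric, names = positions) and `n_skipped`.
#' @examples cotarget_skew(c(10, 30, 10), 2)$skew  # 2
#' @export
cotarget_skew <- function(counts, cotargets) {
  cotargets <- as.integer(cotargets)
  skew <- numeric(0); skipped <- 0L
  for (j in cotargets) {
    if (j <= 1L || j >= length(counts)) { skipped <- skipped + 1L; next }
    m <- mean(c(counts[j - 1L], counts[j + 1L]))
    if (!is.finite(m) || m <= 0) { skipped <- skipped + 1L; next }
    skew[as.character(j)] <- (counts[j] - m) / m
  }
  list(skew = skew, n_skipped = skipped)
}

#' Mask co-targeted fragments in a profile
#'
#' Sets counts at other viewpoints' target fragments to `NA` (missing, not
#' zero) so they drop out of normalisation and calling, and reports the mask.
#'
#' @param counts Per-fragment counts indexed by fragment map row.
#' @param cotarget_index Fragment indices targeted by other viewpoints.
#' @return List with `counts` (masked vector) and `masked` (indices).
#' @export
mask_cotargeted <- function(counts, cotarget_index) {
  cotarget_index <- unique(as.integer(cotarget_index))
  cotarget_index <- cotarget_index[cotarget_index >= 1L &
                                   cotarget_index <= length(counts)]
  counts[cotarget_index] <- NA_real_
  list(counts = counts, masked = cotarget_index)
}
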