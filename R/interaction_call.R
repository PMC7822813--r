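#' Log-spaced distance bins for decay modelling
#'
#' @param min_dist,max_dist Span of callable distances in bp (defaults
#'   2.5 kb -- 1 Mb, the span over which targeted 3C interactions concentrate).
#' @param n_bins Number of log-spaced bins (default 16).
#' @return Numeric vector of bin edges, length `n_bins + 1`.
#' @export
distance_bins <- function(min_dist = 2500, max_dist = 1e6, n_bins = 16) {
  exp(seq(log(min_dist), log(max_dist), length.out = n_bins + 1))
}

#' Fit a monotone distance-decay expectation
#'
#' Contact frequency decays with genomic distance; the expectation is
#' estimated per log-spaced distance bin as a 10% trimmed mean of counts,
#' then made monotone non-increasing by pooled-adjacent-violators
#' (least-squares isotonic regression). Bins with no fragments inherit the
#' nearest fitted value, so a single occupied bin yields a constant
#' expectation.
#'
#' @param distance Absolute distances from the viewpoint midpoint (bp).
#' @param counts Per-fragment counts aligned with `distance`.
#' @param edges Bin edges from [distance_bins()].
#' @param trim Trim fraction for the per-bin mean.
#' @return A `decay_model`: list with `edges`, `expected` (per bin),
#'   `n_per_bin`.
#' @export
fit_decay <- function(distance, counts, edges = distance_bins(), trim = 0.1) {
  ok <- is.finite(distance) & is.finite(counts) &
    distance >= edges[1] & distance < edges[length(edges)]
  if (!any(ok)) stop("no fragments inside the distance span")
  b <- findInterval(distance[ok], edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  raw <- rep(NA_real_, nb)
  for (i in unique(b)) raw[i] <- mean(counts[ok][b == i], trim = trim)
  n_per_bin <- tabulate(b, nbins = nb)
  occ <- which(!is.na(raw))
  # monotone non-increasing via PAVA on the occupied bins
  if (length(occ) > 1L) {
    iso <- stats::isoreg(seq_along(occ), -raw[occ])
    raw[occ] <- -iso$yf
  }
  # empty bins inherit the nearest occupied bin's value
  if (length(occ) < nb) {
    for (i in seq_len(nb)[-occ]) {
      j <- occ[which.min(abs(occ - i))]
      raw[i] <- raw[j]
    }
  }
  structure(list(edges = edges, expected = raw, n_per_bin = n_per_bin),
            class = "decay_model")
}

#' Expected count at given distances under a decay model
#' @param decay A `decay_model`.
#' @param distance Absolute distances in bp.
#' @return Expected counts (NA outside the modelled span).
#' @export
expected_at <- function(decay, distance) {
  b <- findInterval(distance, decay$edges, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(distance))
  inside <- b >= 1L & b <= length(decay$expected) &
    distance >= decay$edges[1]
  out[inside] <- decay$expected[b[inside]]
  out
}

#' Z-normalise values within groups (bins)
#'
#' Centres and scales to mean 0, SD 1 (population SD) within each bin. Bins
#' whose values have zero spread come back as zeros with a warning. The
#' operation is exactly idempotent: applying it to its own output changes
#' nothing.
#'
#' @param x Numeric values.
#' @param bin Bin id per value.
#' @return Numeric vector of z-scores.
#' @export
znorm_by_bin <- function(x, bin) {
  z <- rep(NA_real_, length(x))
  warned <- FALSE
  for (g in unique(bin[!is.na(bin)])) {
    sel <- which(bin == g & is.finite(x))
    if (!length(sel)) next
    mu <- mean(x[sel])
    sdp <- sqrt(mean((x[sel] - mu)^2))
    if (sdp == 0) { z[sel] <- 0; warned <- TRUE }
    else z[sel] <- (x[sel] - mu) / sdp
  }
  if (warned) warning("bin with zero spread; residuals set to 0")
  z
}

#' Distance-binned residual z-normalisation
#'
#' The residual of each fragment against the decay expectation is
#' z-normalised to mean 0 / SD 1 within its distance bin, damping overcalling
#' in sparse distance strata. Bins holding fewer than `min_per_bin` fragments
#' are merged with their nearest occupied neighbour before normalisation.
#'
#' @param counts Observed per-fragment counts.
#' @param distance Absolute distance to the viewpoint midpoint (bp), aligned
#'   with `counts`.
#' @param decay A fitted `decay_model` on the same geometry.
#' @param min_per_bin Minimum fragments per bin before merging (default 5).
#' @return data.frame `residual`, `bin` (post-merge id), `z`; rows align with
#'   the input, NA outside the modelled span.
#' @export
znorm_residuals <- function(counts, distance, decay, min_per_bin = 5) {
  if (any(!is.finite(counts[!is.na(counts)]))) stop("non-finite counts")
  expd <- expected_at(decay, distance)
  residual <- counts - expd
  bin <- findInterval(distance, decay$edges, rightmost.closed = TRUE)
  bin[is.na(expd)] <- NA_integer_
  # merge sparse bins with nearest occupied neighbour
  repeat {
    tab <- table(bin[!is.na(residual)])
    small <- names(tab)[tab < min_per_bin]
    if (!length(small) || length(tab) <= 1L) break
    g <- as.integer(small[1])
    others <- as.integer(setdiff(names(tab), small[1]))
    tgt <- others[which.min(abs(others - g))]
    bin[bin == g & !is.na(bin)] <- tgt
  }
  z <- znorm_by_bin(residual, bin)
  data.frame(residual = residual, bin = bin, z = z)
}

#' Call contacts with a spike-and-slab model (MPPC)
#'
#' Fits the two-component model
#' \deqn{z_j = \gamma_j \beta_j + \epsilon_j,\quad \epsilon_j \sim N(0,1),}
#' \deqn{\gamma_j \sim \mathrm{Bernoulli}(\pi),\quad
#'       \beta_j \sim N(\mu_\beta, \sigma_\beta^2)}
#' to the z-normalised residuals by Gibbs sampling. The marginal posterior
#' probability of contact (MPPC) of fragment j is the posterior mean of
#' \eqn{\gamma_j}. The positive slab mean encodes that contacts are
#' enrichments; ties break toward no call. An optional exponential spatial
#' coupling \eqn{\omega = \exp(-\lambda |\Delta d|)} between adjacent
#' fragments can sharpen runs of signal; it is off by default.
#'
#' @param z Z-normalised residuals (finite; NA rows are skipped).
#' @param prior_pi Prior contact probability per fragment (0 < pi < 1).
#' @param slab_mean,slab_sd Slab (signal) component mean > 0 and SD.
#' @param n_iter,burn_in Gibbs iterations and burn-in.
#' @param seed RNG seed (mandatory; runs are deterministic given the seed).
#' @param coupling Spatial coupling strength on the prior log-odds (0 = off).
#' @param lambda Decay rate of the coupling with inter-fragment distance (per
#'   bp); used only when `coupling > 0` and `distance` is supplied.
#' @param distance Optional fragment distances for the coupling kernel.
#' @param fragment_index Optional genome-order fragment indices carried into
#'   the result.
#' @return An object of class `mppc_fit` with elements `mppc`, `z`,
#'   `fragment_index`, `distance`, the prior settings, and the seed.
#' @examples
#' set.seed(1)
#' z <- c(rnorm(50), 8)
#' fit <- call_mppc(z, prior_pi = 0.01, seed = 7)
#' fit$mppc[51] > 0.95
#' @export
call_mppc <- function(z, prior_pi = 0.01, slab_mean = 3, slab_sd = 2,
                      n_iter = 2000, burn_in = 500, seed,
                      coupling = 0, lambda = 1e-4, distance = NULL,
                      fragment_index = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (prior_pi <= 0 || prior_pi >= 1) stop("prior_pi must be in (0,1)")
  usable <- which(is.finite(z))
  if (!length(usable)) stop("no finite z values")
  if (any(is.na(z[usable]))) stop("non-finite z")
  zz <- z[usable]
  n <- length(zz)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  v1 <- 1 / (1 + 1 / slab_sd^2)           # posterior slab variance given z
  base_lo <- stats::qlogis(prior_pi)
  gamma <- rep(0L, n)
  beta <- rep(slab_mean, n)
  acc <- numeric(n)
  kept <- 0L
  dz <- if (!is.null(distance)) distance[usable] else NULL

  for (it in seq_len(n_iter)) {
    # beta | gamma, z
    mu1 <- v1 * (zz + slab_mean / slab_sd^2)
    beta <- ifelse(gamma == 1L,
                   stats::rnorm(n, mu1, sqrt(v1)),
                   stats::rnorm(n, slab_mean, slab_sd))
    # gamma | beta, z (+ optional neighbour coupling)
    lo <- base_lo +
      stats::dnorm(zz, beta, 1, log = TRUE) -
      stats::dnorm(zz, 0, 1, log = TRUE)
    if (coupling > 0 && n > 1L) {
      w_left <- w_right <- rep(1, n - 1L)
      if (!is.null(dz)) {
        w <- exp(-lambda * abs(diff(dz)))
        w_left <- w_right <- w
      }
      nb <- c(0, gamma[-n] * w_left) + c(gamma[-1L] * w_right, 0)
      lo <- lo + coupling * nb
    }
    gamma <- as.integer(stats::runif(n) < stats::plogis(lo))
    if (it > burn_in) { acc <- acc + gamma; kept <- kept + 1L }
  }

  mppc <- rep(NA_real_, length(z))
  mppc[usable] <- acc / kept
  structure(list(mppc = mppc, z = z,
                 fragment_index = fragment_index, distance = distance,
                 prior_pi = prior_pi, slab_mean = slab_mean,
                 slab_sd = slab_sd, n_iter = n_iter, burn_in = burn_in,
                 seed = seed, coupling = coupling, lambda = lambda),
            class = "mppc_fit")
}

#' @export
print.mppc_fit <- function(x, ...) {
  n <- sum(is.finite(x$mppc))
  cat(sprintf("mppc_fit: %d fragments, prior pi %.3g, slab N(%.2g, %.2g^2), %d iters (seed %d)\n",
              n, x$prior_pi, x$slab_mean, x$slab_sd, x$n_iter, x$seed))
  cat(sprintf("  MPPC >= 0.01: %d fragments; max MPPC %.3f\n",
              sum(x$mppc >= 0.01, na.rm = TRUE), max(x$mppc, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.mppc_fit <- function(object, threshold = 0.01, ...) {
  tm <- threshold_and_merge(object, threshold)
  out <- list(n = sum(is.finite(object$mppc)),
              n_significant = sum(tm$significant, na.rm = TRUE),
              n_runs = length(unique(tm$run_id[!is.na(tm$run_id)])),
              fraction_adjacent = attr(tm, "fraction_adjacent"),
              threshold = threshold,
              mppc_quantiles = stats::quantile(object$mppc, c(.5, .9, .99, 1),
                                              na.rm = TRUE))
  class(out) <- "summary.mppc_fit"
  out
}

#' @export
print.summary.mppc_fit <- function(x, ...) {
  cat(sprintf("spike-and-slab contact calls: %d fragments\n", x$n))
  cat(sprintf("  significant (MPPC >= %.3g): %d in %d adjacency runs (%.1f%% adjacent)\n",
              x$threshold, x$n_significant, x$n_runs,
              100 * ifelse(is.finite(x$fraction_adjacent), x$fraction_adjacent, 0)))
  print(x$mppc_quantiles)
  invisible(x)
}

#' @export
as.data.frame.mppc_fit <- function(x, ...) {
  idx <- if (is.null(x$fragment_index)) seq_along(x$mppc) else x$fragment_index
  tm <- threshold_and_merge(x)
  m <- match(idx, tm$fragment_index)
  data.frame(fragment_index = idx,
             distance = if (is.null(x$distance)) NA_real_ else x$distance,
             z = x$z, mppc = x$mppc,
             significant = tm$significant[m], run_id = tm$run_id[m])
}

#' @export
plot.mppc_fit <- function(x, threshold = 0.01, ...) {
  xs <- if (is.null(x$distance)) seq_along(x$mppc) else x$distance
  plot(xs, x$mppc, type = "h", xlab = "distance from viewpoint (bp)",
       ylab = "MPPC", ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(x)
}

#' Threshold MPPC calls and merge adjacent significant fragments
#'
#' Flags fragments at `MPPC >= threshold` and groups consecutive significant
#' fragments (consecutive genome-order indices) into runs. The fraction of
#' significant fragments directly adjacent to another significant fragment is
#' attached as the `fraction_adjacent` attribute.
#'
#' @param calls An `mppc_fit`, or a data.frame with `mppc` and optionally
#'   `fragment_index` sorted in genome order.
#' @param threshold Significance threshold on MPPC (default 0.01).
#' @return data.frame `fragment_index`, `mppc`, `significant`, `run_id` (NA
#'   when not significant), with attribute `fraction_adjacent`.
#' @export
threshold_and_merge <- function(calls, threshold = 0.01) {
  if (inherits(calls, "mppc_fit")) {
    idx <- if (is.null(calls$fragment_index)) seq_along(calls$mppc)
           else calls$fragment_index
    mppc <- calls$mppc
  } else {
    idx <- if (is.null(calls$fragment_index)) seq_len(nrow(calls))
           else calls$fragment_index
    mppc <- calls$mppc
  }
  o <- order(idx)
  idx <- idx[o]; mppc <- mppc[o]
  sig <- !is.na(mppc) & mppc >= threshold
  run_id <- rep(NA_integer_, length(idx))
  if (any(sig)) {
    s <- which(sig)
    new_run <- c(TRUE, diff(idx[s]) != 1L)
    run_id[s] <- cumsum(new_run)
  }
  out <- data.frame(fragment_index = idx, mppc = mppc,
                    significant = sig, run_id = run_id)
  rownames(out) <- NULL
  # fraction of significant fragments adjacent to another significant one
  s <- which(sig)
  frac <- if (length(s)) {
    adj <- (idx[s] - 1L) %in% idx[s] | (idx[s] + 1L) %in% idx[s]
    mean(adj)
  } else NaN
  attr(out, "fraction_adjacent") <- frac
  out
}

#' Fit contact calls for one viewpoint profile
#'
#' Convenience driver: computes distances from the viewpoint fragment
#' midpoint, restricts to the callable span, fits the decay model,
#' z-normalises residuals per distance bin, and runs the spike-and-slab
#' sampler. Masked (NA) fragments are excluded throughout.
#'
#' @param counts Per-fragment counts indexed by map row (NA = masked).
#' @param map A `fragment_map`.
#' @param viewpoint_fragment Fragment index of the viewpoint.
#' @param edges Distance-bin edges ([distance_bins()]).
#' @param ... Passed to [call_mppc()] (`prior_pi`, `seed`, ...).
#' @return An `mppc_fit` whose `fragment_index` are map row indices.
#' @export
call_contacts <- function(counts, map, viewpoint_fragment,
                          edges = distance_bins(), ...) {
  vp_chrom <- map$chrom[viewpoint_fragment]
  mids <- fragment_midpoints(map)
  cis <- which(map$chrom == vp_chrom)
  dist <- abs(mids[cis] - mids[viewpoint_fragment])
  span <- dist >= edges[1] & dist < edges[length(edges)] & !is.na(counts[cis])
  cis <- cis[span]; dist <- dist[span]
  decay <- fit_decay(dist, counts[cis], edges)
  zr <- znorm_residuals(counts[cis], dist, decay)
  fit <- call_mppc(zr$z, distance = dist, fragment_index = cis, ...)
  fit$decay <- decay
  fit
}
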