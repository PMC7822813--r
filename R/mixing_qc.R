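#' Probability that an inter-nuclear ligation is inter-species
#'
#' In an admixture of two species mixed at proportions (p_A, p_B), a ligation
#' joining DNA from two independent nuclei connects different species with
#' probability 2 p_A p_B -- 50% at a 1:1 mix. Inter-species chimeras are the
#' visible half of inter-nuclear noise; this factor converts between the two.
#'
#' @param p_A,p_B Mixture proportions; must sum to 1.
#' @return Probability in \[0, 0.5\].
#' @examples inter_species_prob(0.5, 0.5)  # 0.5
#' @export
inter_species_prob <- function(p_A, p_B = 1 - p_A) {
  if (p_A < 0 || p_A > 1 || p_B < 0 || p_B > 1 ||
      abs(p_A + p_B - 1) > 1e-9)
    stop("mixture proportions must lie in [0,1] and sum to 1")
  2 * p_A * p_B
}

#' Observed inter-species chimera rate
#'
#' The fraction of usable reporter-containing reads whose capture slice and
#' reporter slice carry different species tags. Reads with ambiguous species
#' assignment (placed in both genomes) must be filtered before this point.
#'
#' @param capture_species,reporter_species Species labels per read
#'   (e.g. `"A"`/`"B"`); equal length.
#' @return List with `rate`, `n_chimeric`, `n` and a Wilson 95% CI.
#' @export
chimera_rate <- function(capture_species, reporter_species) {
  stopifnot(length(capture_species) == length(reporter_species))
  usable <- !is.na(capture_species) & !is.na(reporter_species) &
    capture_species != "ambiguous" & reporter_species != "ambiguous"
  n <- sum(usable)
  if (n == 0L) stop("no usable reads")
  k <- sum(capture_species[usable] != reporter_species[usable])
  ci <- wilson_ci(k, n)
  list(rate = k / n, n_chimeric = k, n = n, ci = ci)
}

#' Invert the mixing model: implied inter-nuclear ligation rate
#'
#' Only a fraction 2 p_A p_B of inter-nuclear ligations are visible as
#' inter-species chimeras, so the implied total inter-nuclear rate is the
#' chimera rate divided by that factor: a 10--15% chimera rate at a 1:1 mix
#' implies 20--30% of reporters arise from ligation between two nuclei.
#'
#' @param chimera Observed chimera rate in \[0, 2 p_A p_B\].
#' @inheritParams inter_species_prob
#' @return Implied inter-nuclear proportion in \[0, 1\].
#' @examples implied_internuclear(0.15, 0.5)  # 0.30
#' @export
implied_internuclear <- function(chimera, p_A, p_B = 1 - p_A) {
  ceiling_ <- inter_species_prob(p_A, p_B)
  if (ceiling_ == 0) stop("single-species mix carries no chimera signal")
  if (chimera < 0 || chimera > ceiling_ + 1e-12)
    stop(sprintf("chimera rate %.4g exceeds the inter-species ceiling %.4g; inconsistent input",
                 chimera, ceiling_))
  chimera / ceiling_
}

#' Full admixture QC report
#'
#' Runs [chimera_rate()] and [implied_internuclear()] on tagged events and
#' propagates the Wilson CI through the (linear) inversion.
#'
#' @param events data.frame with `capture_species` and `reporter_species`
#'   columns (from the reporter extractor run on a combined two-genome
#'   reference).
#' @inheritParams inter_species_prob
#' @return List: `chimera_rate`, `chimera_ci`, `implied_internuclear_rate`,
#'   `implied_ci`, `n`.
#' @export
mixing_report <- function(events, p_A = 0.5, p_B = 1 - p_A) {
  cr <- chimera_rate(events$capture_species, events$reporter_species)
  f <- inter_species_prob(p_A, p_B)
  list(chimera_rate = cr$rate, chimera_ci = cr$ci,
       implied_internuclear_rate = cr$rate / f,
       implied_ci = pmin(cr$ci / f, 1), n = cr$n)
}

# Wilson 95% score interval; stable at small counts.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
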