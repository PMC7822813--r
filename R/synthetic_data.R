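#' Configuration for the 3C library simulator
#'
#' Collects every generative parameter of the synthetic 3C library: genome
#' sizes and composition, viewpoints, the distance-decay law, noise rates and
#' capture behaviour. The seed is mandatory -- identical configurations give
#' byte-identical output.
#'
#' Defaults encode a typical targeted 3C experiment: power-law contact decay
#' with exponent `alpha = 1` and offset `d0 = 1000` bp over the callable
#' 2.5 kb -- 1 Mb span, a 5% trans background within the nucleus, no
#' inter-nuclear noise unless requested, and sonication pieces of at least
#' 30 bp so slices remain placeable.
#'
#' @param seed RNG seed (mandatory).
#' @param chrom_lengths Named list: species -> named vector of chromosome
#'   lengths (bp, >= 10 kb each). Chromosome names are automatically
#'   prefixed with the species label so name spaces stay disjoint.
#' @param species_mix Named numeric of mixture proportions per species
#'   (must sum to 1). Single-species by default.
#' @param motif Restriction motif (default `"GATC"`).
#' @param alpha Distance-decay exponent (> 0).
#' @param d0 Decay offset in bp.
#' @param trans_rate Intra-nuclear trans ligation probability.
#' @param rho Inter-nuclear ligation fraction in \[0, 1\].
#' @param spikes data.frame `fragment_index`, `fold` of spike-in contacts
#'   (multiplies the decay weight at those fragments), or NULL.
#' @param efficiencies Named numeric: fragment index -> capture efficiency for
#'   targeted fragments (untargeted default 0); NULL disables the capture
#'   step.
#' @param rounds Capture rounds (default 2).
#' @param dup_rate Probability a molecule gains one verbatim PCR duplicate.
#' @param read_length Read length for paired-end emission.
#' @param events_per_viewpoint Ligation events drawn per viewpoint.
#' @param min_piece Minimum sonication piece length (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_lengths = list(A = c(chr1 = 2e5)),
                       species_mix = c(A = 1),
                       motif = "GATC",
                       alpha = 1, d0 = 1000,
                       trans_rate = 0.05,
                       rho = 0,
                       spikes = NULL,
                       efficiencies = NULL,
                       rounds = 2,
                       dup_rate = 0,
                       read_length = 150,
                       events_per_viewpoint = 10000,
                       min_piece = 30) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(species_mix) - 1) > 1e-9) stop("species_mix must sum to 1")
  if (!setequal(names(chrom_lengths), names(species_mix)))
    stop("chrom_lengths and species_mix must name the same species")
  if (any(unlist(chrom_lengths) < 1e4)) stop("chromosome lengths must be >= 10 kb")
  if (alpha <= 0) stop("alpha must be > 0")
  stopifnot(rho >= 0, rho <= 1, trans_rate >= 0, trans_rate <= 1,
            dup_rate >= 0, dup_rate <= 1)
  structure(list(seed = seed, chrom_lengths = chrom_lengths,
                 species_mix = species_mix, motif = motif,
                 alpha = alpha, d0 = d0, trans_rate = trans_rate, rho = rho,
                 spikes = spikes, efficiencies = efficiencies,
                 rounds = rounds, dup_rate = dup_rate,
                 read_length = read_length,
                 events_per_viewpoint = events_per_viewpoint,
                 min_piece = min_piece),
            class = "sim_config")
}

#' Generate seeded random genomes with unique seed k-mers
#'
#' Draws uniform-base random chromosomes for every species in the
#' configuration. Uniform bases give the expected motif density (1/256 for a
#' 4-bp motif). Generation is rejected and retried until every 20-mer across
#' all species is unique, so exact-match slice placement is unambiguous;
#' chromosome names are prefixed with the species label, keeping name spaces
#' disjoint.
#'
#' @param config A `sim_config`.
#' @param k Seed k-mer length that must be unique (default 20).
#' @param max_tries Rejection attempts before giving up.
#' @return Named list species -> DNAStringSet.
#' @export
make_genomes <- function(config, k = 20L, max_tries = 20L) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    genomes <- lapply(names(config$chrom_lengths), function(sp) {
      lens <- config$chrom_lengths[[sp]]
      seqs <- vapply(lens, function(L)
        paste(sample(bases, L, replace = TRUE), collapse = ""), "")
      names(seqs) <- paste0(sp, "_", names(lens))
      Biostrings::DNAStringSet(seqs)
    })
    names(genomes) <- names(config$chrom_lengths)
    all_seqs <- as.character(unlist(Biostrings::DNAStringSetList(genomes)))
    kmers <- unlist(lapply(all_seqs, function(s) {
      n <- nchar(s) - k + 1L
      substring(s, 1:n, k:(n + k - 1L))
    }))
    if (!anyDuplicated(kmers)) return(genomes)
  }
  stop("could not generate genomes with unique ", k, "-mers")
}

#' Combine per-species genomes into one reference
#' @param genomes List from [make_genomes()].
#' @return A single DNAStringSet with species-prefixed chromosome names.
#' @export
combine_genomes <- function(genomes) {
  do.call(c, unname(genomes))
}

#' Species label of each chromosome in a combined reference
#' @param chroms Chromosome names (`<species>_<chrom>`).
#' @return Character vector of species labels.
#' @export
species_of_chrom <- function(chroms) {
  sub("_.*$", "", chroms)
}

#' Simulate 3C ligation events with a per-event truth table
#'
#' For each event from a viewpoint: with probability `rho` the partner comes
#' from a second, independent nucleus (species drawn from the mixture, then a
#' uniform fragment of that species -- maximum-entropy inter-nuclear noise);
#' otherwise the ligation is intra-nuclear, trans with probability
#' `trans_rate` (uniform fragment on another chromosome of the same species)
#' and cis otherwise, with the cis partner drawn with probability
#' proportional to `(|d| + d0)^(-alpha)` times any spike-in multiplier.
#' First fragments of each chromosome (which do not start with the motif and
#' so cannot form a canonical junction) are never drawn as partners, and
#' neither are fragments shorter than `min_piece`, which could not yield a
#' placeable sequenced slice.
#'
#' @param config A `sim_config`.
#' @param map Combined `fragment_map` (digest of [combine_genomes()]).
#' @param viewpoints data.frame `viewpoint_id`, `fragment_index` (combined
#'   map indices); events are allocated across viewpoints in proportion to
#'   the species mixture of their chromosomes when several species carry
#'   viewpoints.
#' @return data.frame truth table: `event_id`, `viewpoint_id`,
#'   `vp_fragment`, `reporter_fragment`, `origin`
#'   (`cis`/`trans`/`internuclear`), `vp_species`, `reporter_species`,
#'   `inter_species` flag.
#' @export
simulate_events <- function(config, map, viewpoints) {
  set.seed(config$seed + 1L)
  mids <- fragment_midpoints(map)
  sp <- species_of_chrom(map$chrom)
  # unusable as partners: chromosome-first fragments (no leading motif) and
  # fragments too short to produce a placeable slice
  first_of_chrom <- !duplicated(map$chrom) |
    (map$end - map$start) < config$min_piece
  mix <- config$species_mix

  rows <- lapply(seq_len(nrow(viewpoints)), function(v) {
    vp_frag <- viewpoints$fragment_index[v]
    vp_chrom <- map$chrom[vp_frag]
    vp_sp <- sp[vp_frag]
    n <- config$events_per_viewpoint

    # cis sampling weights on the viewpoint chromosome
    cis_idx <- which(map$chrom == vp_chrom & !first_of_chrom &
                     map$index != vp_frag)
    w <- (abs(mids[cis_idx] - mids[vp_frag]) + config$d0)^(-config$alpha)
    if (!is.null(config$spikes)) {
      m <- match(cis_idx, config$spikes$fragment_index)
      w[!is.na(m)] <- w[!is.na(m)] * config$spikes$fold[m[!is.na(m)]]
    }
    trans_idx <- which(sp == vp_sp & map$chrom != vp_chrom & !first_of_chrom)
    any_idx <- lapply(names(mix), function(s)
      which(sp == s & !first_of_chrom & map$index != vp_frag))
    names(any_idx) <- names(mix)

    origin <- ifelse(stats::runif(n) < config$rho, "internuclear",
                     ifelse(length(trans_idx) > 0 &
                              stats::runif(n) < config$trans_rate,
                            "trans", "cis"))
    rep_frag <- integer(n)
    is_cis <- origin == "cis"
    rep_frag[is_cis] <- sample(cis_idx, sum(is_cis), replace = TRUE, prob = w)
    is_tr <- origin == "trans"
    if (any(is_tr))
      rep_frag[is_tr] <- sample(trans_idx, sum(is_tr), replace = TRUE)
    is_in <- origin == "internuclear"
    if (any(is_in)) {
      part_sp <- sample(names(mix), sum(is_in), replace = TRUE, prob = mix)
      rep_frag[is_in] <- vapply(part_sp, function(s)
        sample(any_idx[[s]], 1L), 0L)
    }
    data.frame(viewpoint_id = viewpoints$viewpoint_id[v],
               vp_fragment = vp_frag,
               reporter_fragment = rep_frag,
               origin = origin,
               vp_species = vp_sp,
               reporter_species = sp[rep_frag],
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  truth$event_id <- sprintf("ev%06d", seq_len(nrow(truth)))
  truth$inter_species <- truth$vp_species != truth$reporter_species
  truth[c("event_id", "viewpoint_id", "vp_fragment", "reporter_fragment",
          "origin", "vp_species", "reporter_species", "inter_species")]
}

#' Apply the capture step to simulated events
#'
#' Each event survives oligonucleotide capture with probability
#' [capture_prob()] of its viewpoint and reporter fragment efficiencies
#' (reporter efficiency 0 unless co-targeted).
#'
#' @param truth Truth table from [simulate_events()].
#' @param efficiencies Named numeric: fragment index -> efficiency.
#' @param rounds Capture rounds.
#' @param seed RNG seed.
#' @return Truth table restricted to retained events, with a `p_capture`
#'   column.
#' @export
simulate_capture <- function(truth, efficiencies, rounds = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  eff <- function(idx) {
    e <- efficiencies[as.character(idx)]
    e[is.na(e)] <- 0
    unname(e)
  }
  p <- capture_prob(eff(truth$vp_fragment), eff(truth$reporter_fragment),
                    rounds)
  keep <- stats::runif(nrow(truth)) < p
  out <- truth[keep, , drop = FALSE]
  out$p_capture <- p[keep]
  rownames(out) <- NULL
  out
}

#' Emit chimeric reads (FASTQ) for simulated events
#'
#' Each retained event becomes one sequenced molecule: a sonication-trimmed
#' suffix of the viewpoint fragment ligated to a sonication-trimmed prefix of
#' the reporter fragment, joined at the restriction motif (the reporter
#' prefix starts with the motif by the digest cut convention, so the junction
#' carries exactly one motif copy). Piece lengths are uniform between
#' `min_piece` and the fragment length; fragments shorter than `min_piece`
#' contribute whole. PCR duplicates are emitted verbatim with probability
#' `dup_rate` and recorded in the truth table via `duplicate_of`.
#'
#' @param truth Truth table of retained events.
#' @param genome Combined reference (DNAStringSet).
#' @param map Combined `fragment_map`.
#' @param config A `sim_config`.
#' @param paired Emit paired-end reads (R1 + reverse-complement R2) instead
#'   of full-molecule single-end reads. Default FALSE: single-end molecules,
#'   equivalent to perfectly flashed pairs.
#' @return List: `reads` (named character; for paired, `reads1`/`reads2`),
#'   `truth` (with `read_id` and `duplicate_of` columns).
#' @export
emit_fastq <- function(truth, genome, map, config, paired = FALSE) {
  set.seed(config$seed + 2L)
  seqs <- as.character(genome)
  n <- nrow(truth)
  frag_seq <- function(idx) substr(seqs[[map$chrom[idx]]],
                                   map$start[idx] + 1L, map$end[idx])
  mols <- character(n)
  for (i in seq_len(n)) {
    vs <- frag_seq(truth$vp_fragment[i])
    rs <- frag_seq(truth$reporter_fragment[i])
    lv <- nchar(vs); lr <- nchar(rs)
    keep_v <- if (lv <= config$min_piece) lv else
      sample(config$min_piece:lv, 1L)
    keep_r <- if (lr <= config$min_piece) lr else
      sample(config$min_piece:lr, 1L)
    mols[i] <- paste0(substr(vs, lv - keep_v + 1L, lv),
                      substr(rs, 1L, keep_r))
  }
  read_id <- paste0("rd_", truth$event_id)
  dup <- stats::runif(n) < config$dup_rate
  out_truth <- truth
  out_truth$read_id <- read_id
  out_truth$duplicate_of <- NA_character_
  if (any(dup)) {
    d <- out_truth[dup, , drop = FALSE]
    d$duplicate_of <- d$read_id
    d$read_id <- paste0(d$read_id, "_dup")
    out_truth <- rbind(out_truth, d)
    mols <- c(mols, mols[dup])
    read_id <- c(read_id, d$read_id)
  }
  names(mols) <- read_id
  if (!paired) return(list(reads = mols, truth = out_truth))
  L <- config$read_length
  r1 <- substr(mols, 1L, pmin(L, nchar(mols)))
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(mols, pmax(1L, nchar(mols) - L + 1L), nchar(mols)))))
  names(r1) <- names(r2) <- read_id
  list(reads1 = r1, reads2 = r2, reads = mols, truth = out_truth)
}

#' Write reads to FASTQ (optionally gzipped)
#' @param reads Named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), "")
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Run the full simulator
#'
#' Convenience driver: genomes, digestion of the combined reference, event
#' simulation, optional capture, and read emission.
#'
#' @param config A `sim_config`.
#' @param viewpoints Either a data.frame `viewpoint_id`, `chrom` (unprefixed),
#'   `species`, `pos` (0-based) -- resolved to fragments after digestion --
#'   or a function `function(map)` returning a viewpoint table with
#'   `fragment_index`.
#' @param paired Passed to [emit_fastq()].
#' @return List: `genomes`, `genome` (combined), `map`, `viewpoints`,
#'   `truth` (post-capture, with read ids), `reads`, `species_map`.
#' @export
simulate_library <- function(config, viewpoints, paired = FALSE) {
  genomes <- make_genomes(config)
  genome <- combine_genomes(genomes)
  map <- digest_genome(genome, config$motif)
  if (is.function(viewpoints)) {
    vps <- viewpoints(map)
  } else {
    vps <- viewpoints
    if (is.null(vps$fragment_index)) {
      chrom <- paste0(vps$species, "_", vps$chrom)
      vps$fragment_index <- locate_fragment(map, chrom, vps$pos)
    }
  }
  truth <- simulate_events(config, map, vps)
  if (!is.null(config$efficiencies))
    truth <- simulate_capture(truth, config$efficiencies, config$rounds,
                              config$seed + 3L)
  em <- emit_fastq(truth, genome, map, config, paired = paired)
  species_map <- stats::setNames(species_of_chrom(unique(map$chrom)),
                                 unique(map$chrom))
  list(genomes = genomes, genome = genome, map = map, viewpoints = vps,
       truth = em$truth, reads = em$reads, species_map = species_map)
}

#' Write a genome to FASTA
#' @param genome DNAStringSet or named character vector.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return DNAStringSet.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
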