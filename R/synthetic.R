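#' Specify a simulated population
#'
#' Populations drift away from an ancestral allele-frequency pool under the
#' Balding-Nichols model. A population may instead descend from a named
#' `parent` population (serial drift) or be an admixture of several `sources`
#' with mixing weights, followed by its own post-admixture drift. `n` diploid
#' individuals are genotyped from the population's frequencies (n = 0 keeps
#' the population frequency-only, e.g. an unsampled internal ancestor).
#'
#' @param label population name.
#' @param F drift parameter in [0, 1); variance of the frequency around its
#'   parent value is `F * p * (1 - p)`. F = 0 copies the parent exactly.
#' @param n diploid sample size (default 0).
#' @param parent optional label of the population drifted from (default: the
#'   ancestral pool).
#' @param sources,weights optional admixture sources and proportions
#'   (non-negative, summing to 1).
#' @return A list of class `pop_spec`.
#' @export
pop_spec <- function(label, F = 0, n = 0, parent = NULL,
                     sources = NULL, weights = NULL) {
  stopifnot(F >= 0, F < 1, n >= 0)
  if (!is.null(sources)) {
    stopifnot(length(sources) == length(weights), all(weights >= 0))
    if (abs(sum(weights) - 1) > 1e-8) stop("admixture weights must sum to 1")
    if (!is.null(parent)) stop("a population has either a parent or sources")
  }
  structure(list(label = label, F = F, n = as.integer(n), parent = parent,
                 sources = sources, weights = weights),
            class = "pop_spec")
}

#' Specify the low-coverage test pair
#'
#' @param source label of the population the pair is drawn from.
#' @param relatedness one of `"unrelated"`, `"parent_offspring"`,
#'   `"full_sib"`, `"identical"`; the implied kinship coefficients are
#'   0, 1/4, 1/4 and 1/2.
#' @param depth mean sequencing depth per site (Poisson).
#' @param error per-read probability of flipping to the other panel allele.
#' @param damage per-read C-to-T / G-to-A deamination probability, applied to
#'   endogenous reads at transition sites only.
#' @param contamination probability a read derives from the contaminant
#'   population instead of the individual.
#' @param contaminant label of the contaminant population (required when
#'   `contamination > 0`).
#' @return A list of class `pair_spec`.
#' @export
pair_spec <- function(source, relatedness = "unrelated", depth = 5,
                      error = 0, damage = 0, contamination = 0,
                      contaminant = NULL) {
  relatedness <- match.arg(relatedness, c("unrelated", "parent_offspring",
                                          "full_sib", "identical"))
  stopifnot(depth > 0, error >= 0, error <= 1, damage >= 0, damage <= 1,
            contamination >= 0, contamination <= 1)
  if (contamination > 0 && is.null(contaminant)) {
    stop("contamination > 0 requires a contaminant population label")
  }
  structure(list(source = source, relatedness = relatedness, depth = depth,
                 error = error, damage = damage,
                 contamination = contamination, contaminant = contaminant),
            class = "pair_spec")
}

#' Kinship coefficient implied by a relatedness class
#' @param relatedness class label as in [pair_spec()].
#' @return theta: 0, 1/4, 1/4 or 1/2.
#' @export
kinship_theta <- function(relatedness) {
  c(unrelated = 0, parent_offspring = 0.25, full_sib = 0.25,
    identical = 0.5)[[relatedness]]
}

#' Assemble a simulation configuration
#'
#' @param n_snps number of panel SNPs.
#' @param pops list of [pop_spec()] objects, ordered so that parents and
#'   admixture sources precede their descendants.
#' @param pair optional [pair_spec()] for the low-coverage test pair.
#' @param freq_range interval the ancestral frequencies are drawn from.
#' @param n_chrom number of chromosomes the panel is spread over.
#' @param seed integer seed for the single RNG stream of the run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps, pops, pair = NULL,
                       freq_range = c(0.05, 0.95), n_chrom = 22L, seed = 1L) {
  stopifnot(n_snps >= 1, length(freq_range) == 2,
            freq_range[1] > 0, freq_range[2] < 1,
            freq_range[1] < freq_range[2])
  if (inherits(pops, "pop_spec")) pops <- list(pops)
  labels <- vapply(pops, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate population labels")
  known <- character()
  for (p in pops) {
    dep <- c(p$parent, p$sources)
    if (length(dep) && !all(dep %in% known)) {
      stop(sprintf("population '%s' depends on undefined population(s): %s",
                   p$label, paste(setdiff(dep, known), collapse = ", ")))
    }
    known <- c(known, p$label)
  }
  if (!is.null(pair)) {
    if (!pair$source %in% labels) {
      stop("pair source population '", pair$source, "' not defined")
    }
    if (pair$contamination > 0 && !pair$contaminant %in% labels) {
      stop("contaminant population '", pair$contaminant, "' not defined")
    }
  }
  structure(list(n_snps = as.integer(n_snps), pops = pops, pair = pair,
                 freq_range = freq_range, n_chrom = as.integer(n_chrom),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one Balding-Nichols drift step; p0 may be a vector
bn_drift <- function(p0, F) {
  if (F <= 0) return(p0)
  out <- p0
  free <- p0 > 0 & p0 < 1
  out[free] <- stats::rbeta(sum(free),
                            p0[free] * (1 - F) / F,
                            (1 - p0[free]) * (1 - F) / F)
  out
}

#' Simulate a SNP map
#'
#' Sites are spread contiguously over `n_chrom` chromosomes; allele pairs are
#' drawn uniformly from the six unordered nucleotide pairs (so about one third
#' of sites are transitions); genetic positions are physical positions times
#' 1e-8 morgans per base pair.
#'
#' @param n_snps,n_chrom panel size and chromosome count.
#' @return A [snp_panel].
#' @export
simulate_panel <- function(n_snps, n_chrom = 22L) {
  chrom <- rep(seq_len(n_chrom), length.out = n_snps)
  chrom <- sort(chrom)
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- cumsum(sample(1000:20000, k, replace = TRUE))
  }
  pairs <- utils::combn(c("A", "C", "G", "T"), 2)
  pick <- sample.int(6L, n_snps, replace = TRUE)
  snp_panel(snp_id = sprintf("snp%06d", seq_len(n_snps)),
            chrom = chrom, physical_pos = pos,
            genetic_pos = pos * 1e-8,
            allele1 = pairs[1, pick], allele2 = pairs[2, pick])
}

#' Simulate drift-structured population allele frequencies
#'
#' Draws ancestral frequencies uniformly on `freq_range`, then walks the
#' population list: plain populations drift from their parent (default the
#' ancestral pool) under Balding-Nichols; admixed populations first mix their
#' sources' frequencies with the given weights and then apply their own
#' post-admixture drift. Frequencies are of allele1.
#'
#' @param config a [sim_config()]. The RNG seed is set from `config$seed`.
#' @return A list with `ancestral` (vector) and `freq` (matrix sites x
#'   populations, columns named by label).
#' @export
simulate_frequencies <- function(config) {
  set.seed(config$seed)
  simulate_frequencies_stream(config)
}

# same, but uses the current RNG stream (for single-stream pipeline runs)
simulate_frequencies_stream <- function(config) {
  n <- config$n_snps
  p0 <- stats::runif(n, config$freq_range[1], config$freq_range[2])
  freq <- matrix(NA_real_, n, length(config$pops),
                 dimnames = list(NULL, vapply(config$pops, `[[`, "", "label")))
  for (p in config$pops) {
    base <- if (!is.null(p$sources)) {
      as.vector(freq[, p$sources, drop = FALSE] %*% p$weights)
    } else if (!is.null(p$parent)) {
      freq[, p$parent]
    } else p0
    freq[, p$label] <- bn_drift(base, p$F)
  }
  list(ancestral = p0, freq = freq)
}

#' Simulate a diploid genotype panel from population frequencies
#'
#' Each genotype is Binomial(2, p) independently across sites and
#' individuals, counting copies of allele1. Uses the current RNG stream.
#'
#' @param panel a [snp_panel].
#' @param freq matrix sites x populations of allele1 frequencies.
#' @param sizes named integer vector of diploid sample sizes per population;
#'   populations with 0 are skipped.
#' @return A [genotype_panel].
#' @export
simulate_genotype_panel <- function(panel, freq, sizes) {
  sizes <- sizes[sizes > 0]
  n_ind <- sum(sizes)
  g <- matrix(NA_integer_, nrow(panel), n_ind)
  ids <- character(n_ind)
  pops <- character(n_ind)
  col <- 0L
  for (pop in names(sizes)) {
    p <- freq[, pop]
    for (k in seq_len(sizes[[pop]])) {
      col <- col + 1L
      g[, col] <- stats::rbinom(nrow(panel), 2L, p)
      ids[col] <- sprintf("%s_%d", pop, k)
      pops[col] <- pop
    }
  }
  genotype_panel(panel, data.frame(id = ids, pop = pops,
                                   stringsAsFactors = FALSE), g)
}

# gene-dropping for the four relatedness classes; returns two n x 2 logical
# matrices, TRUE = chromosome carries allele1
drop_pair_genotypes <- function(p, relatedness) {
  n <- length(p)
  draw <- function() stats::runif(n) < p
  switch(relatedness,
    unrelated = list(cbind(draw(), draw()), cbind(draw(), draw())),
    parent_offspring = {
      parent <- cbind(draw(), draw())
      from_parent <- ifelse(stats::runif(n) < 0.5, parent[, 1], parent[, 2])
      list(parent, cbind(from_parent, draw()))
    },
    full_sib = {
      mo <- cbind(draw(), draw()); fa <- cbind(draw(), draw())
      sib <- function() cbind(
        ifelse(stats::runif(n) < 0.5, mo[, 1], mo[, 2]),
        ifelse(stats::runif(n) < 0.5, fa[, 1], fa[, 2]))
      list(sib(), sib())
    },
    identical = {
      g <- cbind(draw(), draw())
      list(g, g)
    })
}

# reads for one individual; alleles: n x 2 logical (TRUE = allele1)
sim_reads <- function(panel, alleles, pair, freq) {
  n <- nrow(panel)
  depth <- stats::rpois(n, pair$depth)
  site <- rep.int(seq_len(n), depth)
  m <- length(site)
  chrom_pick <- stats::runif(m) < 0.5
  is_a1 <- ifelse(chrom_pick, alleles[site, 1], alleles[site, 2])
  endo <- rep(TRUE, m)
  if (pair$contamination > 0) {
    endo <- stats::runif(m) >= pair$contamination
    pc <- freq[, pair$contaminant][site]
    is_a1[!endo] <- stats::runif(sum(!endo)) < pc[!endo]
  }
  if (pair$error > 0) {
    flip <- stats::runif(m) < pair$error
    is_a1 <- xor(is_a1, flip)
  }
  if (pair$damage > 0) {
    # deamination converts C->T and G->A: at transition sites the C/G member
    # of the allele pair can be misread as the T/A member on endogenous reads
    ts <- panel$mutation_class == "transition"
    src_is_a1 <- panel$allele1 %in% c("C", "G")
    read_is_src <- ts[site] & (is_a1 == src_is_a1[site]) & endo
    dmg <- read_is_src & stats::runif(m) < pair$damage
    is_a1[dmg] <- !is_a1[dmg]
  }
  pileup_data(individual_id = "sim",
              site = site, base = ifelse(is_a1, 1L, 2L),
              bq = sample(30:40, m, replace = TRUE),
              mq = sample(30:60, m, replace = TRUE),
              filters = list(q_min = 30, Q_min = 30,
                             n_dropped_quality = 0L,
                             n_dropped_offpanel = 0L))
}

#' Simulate a low-coverage pair of individuals
#'
#' Gene-drops two genomes from the source population's frequencies under the
#' configured relatedness class, then generates per-site reads with Poisson
#' depth, sequencing error, optional contamination and optional deamination
#' damage (endogenous reads at transition sites only). All emitted qualities
#' pass the default q/Q >= 30 filters. Uses the current RNG stream.
#'
#' @param panel a [snp_panel].
#' @param freq frequency matrix as from [simulate_frequencies()].
#' @param pair a [pair_spec()].
#' @param ids identifiers for the two individuals.
#' @return A list with `pileup1`, `pileup2` ([pileup_data]) and `truth`
#'   (genotypes as allele1 counts, relatedness label and theta).
#' @export
simulate_pair <- function(panel, freq, pair, ids = c("ind1", "ind2")) {
  p <- freq[, pair$source]
  gt <- drop_pair_genotypes(p, pair$relatedness)
  pu1 <- sim_reads(panel, gt[[1]], pair, freq)
  pu2 <- sim_reads(panel, gt[[2]], pair, freq)
  pu1$individual_id <- ids[1]
  pu2$individual_id <- ids[2]
  list(pileup1 = pu1, pileup2 = pu2,
       truth = list(g1 = rowSums(gt[[1]]), g2 = rowSums(gt[[2]]),
                    relatedness = pair$relatedness,
                    theta = kinship_theta(pair$relatedness)))
}

#' Run a full simulation from a configuration
#'
#' Seeds the single RNG stream from `config$seed`, then generates the SNP
#' map, population frequencies, the diploid genotype panel and (if
#' configured) the low-coverage pair, recording all ground truth.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_result` with `panel`, `freqs`, `geno`,
#'   `pair` (or NULL) and `truth`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  panel <- simulate_panel(config$n_snps, config$n_chrom)
  freqs <- simulate_frequencies_stream(config)
  sizes <- vapply(config$pops, `[[`, 0L, "n")
  names(sizes) <- vapply(config$pops, `[[`, "", "label")
  geno <- simulate_genotype_panel(panel, freqs$freq, sizes)
  pair <- if (!is.null(config$pair)) {
    simulate_pair(panel, freqs$freq, config$pair)
  }
  admix <- Filter(function(p) !is.null(p$sources), config$pops)
  structure(list(
    panel = panel, freqs = freqs, geno = geno, pair = pair,
    truth = list(
      frequencies = freqs$freq,
      admixture = lapply(admix, function(p)
        list(label = p$label, sources = p$sources, weights = p$weights)),
      theta = if (!is.null(config$pair))
        kinship_theta(config$pair$relatedness),
      seed = config$seed)
  ), class = "sim_result")
}
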