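#' Specify a simulated F2 intercross
#'
#' Defines the genotyping design for [sim_f2_cross()]: number of F2
#' individuals, chromosome layout (markers per chromosome and map length),
#' and observation noise (symmetric genotyping errors, missing calls).
#'
#' @param n_individuals Number of F2 offspring.
#' @param chromosomes Data frame with columns `n_markers` (>= 2) and
#'   `length_cM` (> 0), one row per chromosome.
#' @param genotyping_error_rate Probability an observed call is replaced by one
#'   of the two other genotype classes (each with half this probability).
#' @param missing_rate Probability an observed call is missing.
#' @param seed Integer seed; identical seed + spec gives identical output.
#' @return A `cross_spec` list.
#' @export
cross_spec <- function(n_individuals, chromosomes,
                       genotyping_error_rate = 0, missing_rate = 0, seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("n_markers", "length_cM") %in% names(chromosomes)))
  if (any(!is.finite(chromosomes$n_markers)) || any(chromosomes$n_markers < 2) ||
      any(chromosomes$n_markers != floor(chromosomes$n_markers))) {
    abort("each chromosome needs an integer n_markers >= 2")
  }
  if (any(!is.finite(chromosomes$length_cM)) || any(chromosomes$length_cM <= 0)) {
    abort("each chromosome needs length_cM > 0")
  }
  check_prob(genotyping_error_rate, "genotyping_error_rate")
  check_prob(missing_rate, "missing_rate")
  structure(
    list(n_individuals = n_individuals, chromosomes = chromosomes,
         genotyping_error_rate = genotyping_error_rate,
         missing_rate = missing_rate, seed = seed),
    class = "cross_spec"
  )
}

#' Specify a planted QTL
#'
#' @param chromosome Chromosome index (1-based, into the cross spec layout).
#' @param position_cM Position on that chromosome, within `[0, length_cM]`.
#' @param additive_effect Half the difference between the two homozygote means,
#'   in phenotype units.
#' @param dominance_effect Deviation of the heterozygote from the homozygote
#'   midpoint, in phenotype units.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chromosome, position_cM, additive_effect,
                     dominance_effect = 0) {
  stopifnot(is.finite(position_cM), position_cM >= 0,
            is.finite(additive_effect), is.finite(dominance_effect))
  structure(
    list(chromosome = check_count(chromosome, "chromosome"),
         position_cM = position_cM, additive_effect = additive_effect,
         dominance_effect = dominance_effect),
    class = "qtl_spec"
  )
}

#' Additive effect needed for a target proportion of variance explained
#'
#' In an F2, a purely additive biallelic QTL with effect `a` contributes
#' genetic variance `a^2 / 2` (genotype values `-a, 0, a` with probabilities
#' 1:2:1). Solving `a^2/2 / (a^2/2 + sd^2) = pve` gives
#' `a = sd * sqrt(2 pve / (1 - pve))`.
#'
#' @param pve Target proportion of variance explained in `(0, 1)`.
#' @param residual_sd Residual standard deviation in phenotype units.
#' @return Additive effect size in phenotype units.
#' @export
additive_effect_for_pve <- function(pve, residual_sd) {
  stopifnot(pve > 0, pve < 1, residual_sd > 0)
  residual_sd * sqrt(2 * pve / (1 - pve))
}

# Simulate one F1 gamete pool: matrix n_ind x n_markers of founder-allele
# indicators (0 = A, 1 = B), using Haldane (no-interference) recombination.
#' @noRd
sim_gametes <- function(n_ind, r_adj) {
  n_mar <- length(r_adj) + 1L
  alleles <- matrix(0L, n_ind, n_mar)
  alleles[, 1] <- rbinom(n_ind, 1, 0.5)
  for (j in seq_along(r_adj)) {
    sw <- rbinom(n_ind, 1, r_adj[j])
    alleles[, j + 1] <- (alleles[, j] + sw) %% 2L
  }
  alleles
}

#' Simulate an F2 intercross
#'
#' Forms each F2 individual from two independent F1 gametes generated by a
#' Markov recombination process along each chromosome with adjacent-interval
#' recombination fractions from the Haldane map function (no interference).
#' Marker-wise, true genotypes follow the 1:2:1 F2 expectation. The observed
#' copy adds independent symmetric genotyping errors and missingness.
#'
#' Markers are equally spaced along each chromosome; each chromosome is a
#' single scaffold with bp positions at 500 kb per cM.
#'
#' @param spec A [cross_spec()].
#' @return List with elements `truth` and `observed` (both [marker_geno()])
#'   and `true_map` (a [genetic_map()] with the generating marker positions).
#' @export
sim_f2_cross <- function(spec) {
  stopifnot(inherits(spec, "cross_spec"))
  set.seed(stage_seed(spec$seed, "cross"))
  n <- spec$n_individuals
  ids <- sprintf("F2_%03d", seq_len(n))

  per_chr <- purrr::pmap(
    list(seq_len(nrow(spec$chromosomes)), spec$chromosomes$n_markers,
         spec$chromosomes$length_cM),
    function(chr, n_mar, len) {
      pos_cM <- seq(0, len, length.out = n_mar)
      r_adj <- haldane_r(diff(pos_cM))
      geno <- sim_gametes(n, r_adj) + sim_gametes(n, r_adj) # 0/1/2 B-dosage
      markers <- tibble(
        marker_id = sprintf("chr%d_m%02d", chr, seq_len(n_mar)),
        scaffold = sprintf("scaffold_%d", chr),
        pos_bp = pmax(1L, as.integer(round(pos_cM * 5e5))),
        chrom_class = "autosomal"
      )
      list(markers = markers, geno = t(geno), pos_cM = pos_cM, group = chr)
    }
  )

  markers <- bind_rows(purrr::map(per_chr, "markers"))
  geno <- do.call(rbind, purrr::map(per_chr, "geno")) # markers x individuals
  truth_calls <- matrix(GENO_LEVELS[geno + 1L], nrow(geno), ncol(geno))

  obs_calls <- truth_calls
  if (spec$genotyping_error_rate > 0) {
    u <- matrix(runif(length(obs_calls)), nrow(obs_calls))
    flip <- u < spec$genotyping_error_rate
    # symmetric: each of the two wrong classes with probability e/2
    pick2 <- u < spec$genotyping_error_rate / 2
    idx <- match(obs_calls, GENO_LEVELS)
    others <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)) # wrong classes per truth
    obs_calls[flip] <- GENO_LEVELS[ifelse(pick2[flip],
                                          others[idx[flip], 1], others[idx[flip], 2])]
  }
  if (spec$missing_rate > 0) {
    obs_calls[matrix(runif(length(obs_calls)) < spec$missing_rate,
                     nrow(obs_calls))] <- NA_character_
  }

  true_map <- genetic_map(bind_rows(purrr::map(per_chr, function(p) {
    tibble(group = p$group, order = seq_len(nrow(p$markers)),
           marker_id = p$markers$marker_id, scaffold = p$markers$scaffold,
           pos_bp = p$markers$pos_bp, cM = p$pos_cM)
  })))

  list(
    truth = marker_geno(markers, ids, truth_calls),
    observed = marker_geno(markers, ids, obs_calls),
    true_map = true_map
  )
}

#' Simulate phenotypes from planted QTLs
#'
#' Builds a latent trait as the sum over QTLs of
#' `additive_effect * (n_B - 1) + dominance_effect * [het]` plus Gaussian
#' residual noise, shifted by `baseline`, then clamps to `[0, 1]` (observed
#' phenotypes are proportions of white plumage). Each QTL acts through the
#' true genotype at the nearest marker on its chromosome.
#'
#' @param truth True [marker_geno()] from [sim_f2_cross()].
#' @param map The generating [genetic_map()].
#' @param qtls List of [qtl_spec()] objects (may be empty).
#' @param residual_sd Residual standard deviation (>= 0), phenotype units.
#' @param baseline Phenotype mean for the all-heterozygote-free midpoint
#'   (default 0.5, mid-scale).
#' @param seed Integer seed.
#' @param region Region name used as the phenotype column label.
#' @return Tibble with columns `individual_id` and the phenotype, carrying
#'   attributes `realized_pve` (genetic variance over total latent variance,
#'   computed from truth) and `n_clamped`.
#' @export
sim_phenotypes <- function(truth, map, qtls, residual_sd, baseline = 0.5,
                           seed = 1L, region = "dorsal body") {
  stopifnot(inherits(truth, "marker_geno"), residual_sd >= 0)
  set.seed(stage_seed(seed, "phenotype"))
  n <- length(truth$individuals)
  genetic <- rep(0, n)
  placed <- list()
  for (q in qtls) {
    stopifnot(inherits(q, "qtl_spec"))
    chr_markers <- map[map$group == q$chromosome, ]
    if (!nrow(chr_markers)) abort("QTL chromosome not on map")
    if (q$position_cM > max(chr_markers$cM) + 1e-9) abort("QTL position off the map")
    at <- which.min(abs(chr_markers$cM - q$position_cM))
    nearest <- chr_markers$marker_id[at]
    placed[[length(placed) + 1]] <- tibble(
      chromosome = q$chromosome, marker_id = nearest, cM = chr_markers$cM[at]
    )
    g <- truth$calls[nearest, ]
    dosage <- match(g, GENO_LEVELS) - 2L # -1, 0, 1
    genetic <- genetic + q$additive_effect * dosage +
      q$dominance_effect * (g == "AB")
  }
  latent <- baseline + genetic + rnorm(n, 0, residual_sd)
  pheno <- pmin(1, pmax(0, latent))
  n_clamped <- sum(pheno != latent)
  if (n_clamped > 0) {
    warn(sprintf("%d phenotype value(s) clamped to [0, 1]", n_clamped))
  }
  realized_pve <- if (var(latent) > 0) var(genetic) / var(latent) else 0
  out <- tibble(individual_id = truth$individuals, phenotype = pheno)
  names(out)[2] <- region
  attr(out, "realized_pve") <- realized_pve
  attr(out, "n_clamped") <- n_clamped
  attr(out, "qtl_positions") <- bind_rows(placed)
  out
}
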