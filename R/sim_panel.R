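#' Specify a simulated case/background genotype panel
#'
#' @param n_case,n_background Sample counts per group (>= 1).
#' @param n_sites Number of biallelic sites.
#' @param planted_sites Integer site indices carrying the planted fixed
#'   haplotype: homozygous-alt in every case sample, never homozygous-alt in
#'   background.
#' @param gl_error_rate Probability a sample's genotype-likelihood vector
#'   supports a different genotype than its recorded call.
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_case, n_background, n_sites, planted_sites = integer(),
                       gl_error_rate = 0, missing_rate = 0, seed = 1L) {
  n_case <- check_count(n_case, "n_case")
  n_background <- check_count(n_background, "n_background")
  n_sites <- check_count(n_sites, "n_sites")
  check_prob(gl_error_rate, "gl_error_rate")
  check_prob(missing_rate, "missing_rate")
  planted_sites <- as.integer(planted_sites)
  if (length(planted_sites) &&
      (any(planted_sites < 1) || any(planted_sites > n_sites))) {
    abort("planted site indices must lie in 1..n_sites")
  }
  structure(
    list(n_case = n_case, n_background = n_background, n_sites = n_sites,
         planted_sites = planted_sites, gl_error_rate = gl_error_rate,
         missing_rate = missing_rate, seed = seed),
    class = "panel_spec"
  )
}

# Phred-scaled genotype-likelihood vector supporting genotype `s`:
# PL(s) = 0, the others get large phred values (GATK-style confident calls).
#' @noRd
pl_vector <- function(s) {
  pl <- c(60, 60, 60)
  pl[s + 1L] <- 0
  # the genotype one het-step away is less strongly excluded than two steps
  if (s == 0L) pl[3] <- 90
  if (s == 2L) pl[1] <- 90
  pl
}

#' Simulate a case/background population site panel
#'
#' Non-planted sites draw a shared alt-allele frequency
#' `p ~ Uniform(0.05, 0.95)` and Hardy-Weinberg genotypes in both groups
#' (the differentiation-test null). Planted sites are homozygous-alt in every
#' case sample and carry only ref/het genotypes in background samples.
#' Genotype likelihoods are phred-scaled confident vectors supporting the
#' call, except that with probability `gl_error_rate` a vector supports a
#' different genotype (miscall noise).
#'
#' @param spec A [panel_spec()].
#' @return A [site_panel()]; the truth (planted site indices) is attached as
#'   attribute `planted_sites`.
#' @export
sim_population_sites <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  if (length(spec$planted_sites) && spec$n_case < 1) {
    abort("planted haplotype infeasible without case samples")
  }
  set.seed(stage_seed(spec$seed, "panel"))
  n_s <- spec$n_sites
  n_case <- spec$n_case; n_bg <- spec$n_background
  n_all <- n_case + n_bg
  planted <- logical(n_s); planted[spec$planted_sites] <- TRUE

  p_shared <- runif(n_s, 0.05, 0.95)
  gt <- matrix(0L, n_s, n_all)
  for (j in seq_len(n_all)) gt[, j] <- rbinom(n_s, 2, p_shared)
  # planted sites: fixed alt in cases, never hom-alt in background
  if (any(planted)) {
    gt[planted, seq_len(n_case)] <- 2L
    n_pl <- sum(planted)
    for (j in seq_len(n_bg)) {
      gt[planted, n_case + j] <- rbinom(n_pl, 1, 0.2) # ref hom or het only
    }
  }

  supported <- gt
  if (spec$gl_error_rate > 0) {
    mis <- matrix(runif(n_s * n_all) < spec$gl_error_rate, n_s, n_all)
    shift <- matrix(sample(1:2, n_s * n_all, replace = TRUE), n_s, n_all)
    supported[mis] <- (gt[mis] + shift[mis]) %% 3L
  }
  pl <- array(NA_real_, c(n_s, n_all, 3))
  for (s in 0:2) {
    sel <- supported == s
    v <- pl_vector(s)
    for (k in 1:3) {
      slice <- pl[, , k]
      slice[sel] <- v[k]
      pl[, , k] <- slice
    }
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(runif(n_s * n_all) < spec$missing_rate, n_s, n_all)
    gt[miss] <- NA_integer_
    for (k in 1:3) {
      slice <- pl[, , k]
      slice[miss] <- NA_real_
      pl[, , k] <- slice
    }
  }

  sites <- tibble(
    scaffold = "scaffold_507", pos = sort(sample.int(n_s * 100, n_s)),
    ref = sample(c("A", "C", "G", "T"), n_s, replace = TRUE),
    alt = NA_character_
  )
  sites$alt <- vapply(sites$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("bg_%02d", seq_len(n_bg)))
  groups <- c(rep("case", n_case), rep("background", n_bg))
  out <- site_panel(sites, samples, gt, pl, groups)
  attr(out, "planted_sites") <- spec$planted_sites
  out
}
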