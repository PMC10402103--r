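# Simulation-study drivers: run a pipeline stage on freshly generated
# synthetic data with planted truth and report recovery/calibration metrics.
# These back the package's reproducibility experiments; each call regenerates
# everything from the given seed.

#' QTL recovery experiment
#'
#' For each seed, simulates an F2 cross (5 chromosomes x 50 markers, 100 cM
#' each by default), plants one additive QTL with the given target PVE,
#' scans, and records whether the planted position falls inside the 2-LOD
#' support interval and the error of the LOD-based PVE estimate.
#'
#' @param n_seeds Number of replicate crosses.
#' @param n_ind F2 individuals per cross.
#' @param target_pve Planted proportion of variance explained.
#' @param n_chr,n_markers,length_cM Genome layout.
#' @param step_cM Scan grid step.
#' @param seed Base seed; replicate s uses `seed * 1000 + s`.
#' @return Tibble with one row per seed: `covered`, `pve_est`, `pve_err`,
#'   `peak_cM`, `true_cM`.
#' @export
eval_qtl_recovery <- function(n_seeds = 20, n_ind = 150, target_pve = 0.55,
                              n_chr = 5, n_markers = 50, length_cM = 100,
                              step_cM = 1, seed = 1) {
  residual_sd <- 0.1
  a <- additive_effect_for_pve(target_pve, residual_sd)
  purrr::map(seq_len(n_seeds), function(s) {
    sd_s <- (seed * 1000 + s) %% 2147480000
    chr <- tibble(n_markers = rep(n_markers, n_chr),
                  length_cM = rep(length_cM, n_chr))
    sim <- sim_f2_cross(cross_spec(n_ind, chr, genotyping_error_rate = 0.005,
                                   missing_rate = 0.05, seed = sd_s))
    qtl_chr <- (s %% n_chr) + 1
    ph <- suppressWarnings(sim_phenotypes(
      sim$truth, sim$true_map, list(qtl_spec(qtl_chr, length_cM * 0.4, a)),
      residual_sd = residual_sd, seed = sd_s
    ))
    true_cM <- attr(ph, "qtl_positions")$cM[1]
    pr <- calc_genoprob(sim$observed, sim$true_map, step_cM = step_cM)
    sc <- hk_scan(pr, ph)
    iv <- lod_interval(sc, qtl_chr)
    tibble(
      seed = sd_s, covered = iv$low_cM <= true_cM & true_cM <= iv$high_cM,
      pve_est = iv$pve, pve_err = abs(iv$pve - target_pve),
      peak_cM = iv$peak_cM, true_cM = true_cM
    )
  }) %>% bind_rows()
}

#' Permutation-threshold calibration experiment
#'
#' Simulates null crosses (no QTL, pure noise phenotypes), computes each
#' replicate's own permutation threshold, and reports the fraction of
#' replicates whose observed maximum LOD exceeds it — the empirical
#' genome-wide type-I error at the nominal level.
#'
#' @param n_rep Null replicates.
#' @param n_perm Permutations per replicate.
#' @param n_ind Individuals.
#' @param alpha Nominal genome-wide level.
#' @param seed Base seed.
#' @return List with `rate` and the per-replicate tibble.
#' @export
eval_perm_calibration <- function(n_rep = 100, n_perm = 200, n_ind = 100,
                                  alpha = 0.05, seed = 1) {
  res <- purrr::map(seq_len(n_rep), function(s) {
    sd_s <- (seed * 2000 + s) %% 2147480000
    chr <- tibble(n_markers = rep(20, 3), length_cM = rep(60, 3))
    sim <- sim_f2_cross(cross_spec(n_ind, chr, seed = sd_s))
    set.seed(stage_seed(sd_s, "noise"))
    y <- rnorm(n_ind)
    pr <- calc_genoprob(sim$observed, sim$true_map, step_cM = 2)
    thr <- perm_threshold(pr, y, n_perm = n_perm, alpha = alpha, seed = sd_s)
    tibble(seed = sd_s, max_lod = max(hk_scan(pr, y)$lod),
           threshold = as.numeric(thr))
  }) %>% bind_rows()
  list(rate = mean(res$max_lod > res$threshold), detail = res)
}

#' Null calibration of the differentiation test
#'
#' Simulates shared-frequency sites (no group difference) and reports the
#' empirical type-I error of [pfst_scan()] at the given per-site level.
#'
#' @param n_sites Sites simulated.
#' @param n_case,n_background Group sizes.
#' @param level Per-site significance level checked (default 0.05).
#' @param seed Seed.
#' @return List with `type_i` and the scan result.
#' @export
eval_pfst_null <- function(n_sites = 5000, n_case = 20, n_background = 30,
                           level = 0.05, seed = 1) {
  p <- sim_population_sites(panel_spec(n_case, n_background, n_sites,
                                       seed = seed))
  res <- pfst_scan(p)
  list(type_i = mean(res$p_value < level, na.rm = TRUE), scan = res)
}

#' Recombination-fraction estimator accuracy experiment
#'
#' Simulates marker pairs at known recombination fractions and reports the
#' mean absolute error of [estimate_rf()] per true value.
#'
#' @param r_values True recombination fractions.
#' @param n_rep Replicates per value.
#' @param n_ind Individuals per replicate.
#' @param seed Seed.
#' @return Tibble `r_true`, `mae`, `bias`.
#' @export
eval_rf_recovery <- function(r_values = c(0.05, 0.2, 0.35), n_rep = 100,
                             n_ind = 200, seed = 1) {
  set.seed(stage_seed(seed, "noise"))
  purrr::map(r_values, function(r) {
    err <- replicate(n_rep, {
      gam <- function() {
        h1 <- rbinom(n_ind, 1, 0.5)
        cbind(h1, (h1 + rbinom(n_ind, 1, r)) %% 2)
      }
      g <- gam() + gam()
      est <- estimate_rf(GENO_LEVELS[g[, 1] + 1], GENO_LEVELS[g[, 2] + 1])
      est$r_hat - r
    })
    tibble(r_true = r, mae = mean(abs(err)), bias = mean(err))
  }) %>% bind_rows()
}

#' Tandem-duplication recovery experiment
#'
#' For each seed, plants a heterozygous 37-kb tandem duplication in a 1-Mb
#' scaffold at 30x Poisson depth, calls it from normalized coverage, and
#' checks window-level boundary accuracy plus soft-clip breakpoint
#' refinement; additionally screens a mixed cohort for genotype accuracy.
#'
#' @param n_seeds Replicate tracks for boundary recovery.
#' @param n_samples Cohort size for the genotype screen.
#' @param seed Base seed.
#' @return List: `boundary_hit_rate`, `refined_exact_rate`,
#'   `screen_accuracy`, plus per-replicate detail.
#' @export
eval_dup_recovery <- function(n_seeds = 20, n_samples = 100, seed = 1) {
  dup_start <- 500000; dup_end <- 537000; window <- 5000
  rep_res <- purrr::map(seq_len(n_seeds), function(s) {
    sd_s <- (seed * 3000 + s) %% 2147480000
    spec <- dup_plant_spec(1e6, window, dup_start = dup_start,
                           dup_end = dup_end, copy_state = "heterozygous",
                           mean_depth = 30, noise_model = "poisson",
                           seed = sd_s)
    cov <- sim_coverage(spec)
    calls <- call_duplication(normalize_coverage(cov$track))
    if (!nrow(calls)) {
      return(tibble(hit = FALSE, refined_exact = FALSE))
    }
    main <- calls[which.max(calls$n_windows), ]
    hit <- abs(main$start - dup_start) <= window &&
      abs(main$end - dup_end) <= window && main$genotype == "het"
    ref <- refine_breakpoints(main, cov$evidence)
    tibble(hit = hit,
           refined_exact = ref$refined &&
             abs(ref$start - dup_start) <= 1 && abs(ref$end - dup_end) <= 1)
  }) %>% bind_rows()

  set.seed(stage_seed(seed, "noise"))
  states <- sample(rep(c("absent", "het", "hom"), c(50, 30, 20))[
    seq_len(n_samples)])
  region <- list(scaffold = "scaffold_507", start = dup_start, end = dup_end)
  tracks <- purrr::map(seq_along(states), function(i) {
    st <- states[i]
    spec <- dup_plant_spec(
      1e6, window,
      dup_start = if (st == "absent") NULL else dup_start,
      dup_end = if (st == "absent") NULL else dup_end,
      copy_state = if (st == "hom") "homozygous" else "heterozygous",
      mean_depth = 30, noise_model = "poisson",
      seed = (seed * 4000 + i) %% 2147480000
    )
    normalize_coverage(sim_coverage(spec)$track)
  })
  names(tracks) <- sprintf("b%03d", seq_along(states))
  screened <- screen_samples(tracks, region)
  list(
    boundary_hit_rate = mean(rep_res$hit),
    refined_exact_rate = mean(rep_res$refined_exact),
    screen_accuracy = mean(screened$genotype == states),
    detail = rep_res
  )
}

#' Error-LOD ranking experiment
#'
#' Plants a known rate of genotyping errors on a dense simulated map and
#' reports the AUC of the error-LOD score for separating planted errors from
#' correct calls.
#'
#' @param n_ind Individuals.
#' @param n_markers Markers on one chromosome.
#' @param length_cM Chromosome length (dense map: ~1 cM spacing by default).
#' @param error_rate Planted genotyping error rate.
#' @param seed Seed.
#' @return List with `auc`, `n_errors`, and the scored call table.
#' @export
eval_error_lod_auc <- function(n_ind = 100, n_markers = 51, length_cM = 50,
                               error_rate = 0.02, seed = 1) {
  sim <- sim_f2_cross(cross_spec(n_ind, tibble(n_markers = n_markers,
                                               length_cM = length_cM),
                                 genotyping_error_rate = error_rate,
                                 seed = seed))
  el <- error_lod(sim$observed, sim$true_map)
  err <- sim$observed$calls != sim$truth$calls
  key <- paste(rep(rownames(err), ncol(err)), rep(colnames(err), each = nrow(err)))
  is_err <- err[match(paste(el$marker_id, el$individual), key)]
  list(auc = rank_auc(el$error_lod, is_err), n_errors = sum(is_err),
       detail = mutate(el, planted_error = is_err))
}
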