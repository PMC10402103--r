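# The synthetic-data generators: determinism, planted truth, and the
# statistical structure downstream stages assume.

chrom1 <- function(n_markers, length_cM) {
  tibble::tibble(n_markers = n_markers, length_cM = length_cM)
}

test_that("identical seed and spec give identical cross output", {
  spec <- cross_spec(30, chrom1(10, 50), genotyping_error_rate = 0.05,
                     missing_rate = 0.1, seed = 123)
  a <- sim_f2_cross(spec)
  b <- sim_f2_cross(spec)
  expect_identical(a, b)
  spec2 <- cross_spec(30, chrom1(10, 50), genotyping_error_rate = 0.05,
                      missing_rate = 0.1, seed = 124)
  expect_false(identical(sim_f2_cross(spec2)$observed$calls, a$observed$calls))
})

test_that("noise-free observation equals truth and cospositioned markers co-inherit", {
  sim <- sim_f2_cross(cross_spec(50, chrom1(8, 40), seed = 5))
  expect_identical(sim$observed$calls, sim$truth$calls)

  # two markers 0 cM apart: r = 0 forces identical genotypes
  sim0 <- sim_f2_cross(cross_spec(200, chrom1(2, 1e-9), seed = 6))
  expect_identical(sim0$truth$calls[1, ], sim0$truth$calls[2, ])
})

test_that("adjacent-marker recombination fraction matches the Haldane closed form", {
  sim <- sim_f2_cross(cross_spec(10000, chrom1(2, 10), seed = 11))
  g <- sim$truth$calls
  # count recombinant meioses between the two markers from homozygote rows:
  # each individual carries two meioses; use dosage difference as a proxy
  # only for unambiguous configurations (hom at first marker)
  d1 <- match(g[1, ], c("AA", "AB", "BB")) - 1L
  d2 <- match(g[2, ], c("AA", "AB", "BB")) - 1L
  hom <- d1 %in% c(0L, 2L)
  # from a hom parent-pair state, each meiosis switching is directly visible
  # in the dosage change; |d2 - d1| counts recombinant gametes except the
  # double-recombinant-to-het case, negligible at r ~ 0.09 for a 3-SD check
  n_meioses <- 2 * sum(hom)
  n_rec <- sum(abs(d2[hom] - d1[hom]))
  r_expected <- 0.5 * (1 - exp(-0.2))
  se <- sqrt(r_expected * (1 - r_expected) / n_meioses)
  expect_lt(abs(n_rec / n_meioses - r_expected), 3 * se + 2 * r_expected^2)
})

test_that("single-marker genotype frequencies are 1:2:1 across seeds", {
  for (seed in c(1, 2, 3)) {
    sim <- sim_f2_cross(cross_spec(1000, chrom1(3, 50), seed = seed))
    for (m in 1:3) {
      counts <- table(factor(sim$truth$calls[m, ], levels = c("AA", "AB", "BB")))
      p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
      expect_gt(p, 0.001)
    }
  }
})

test_that("cross_spec rejects invalid fields", {
  expect_error(cross_spec(0, chrom1(5, 50)), "n_individuals")
  expect_error(cross_spec(10, chrom1(1, 50)), "n_markers")
  expect_error(cross_spec(10, chrom1(5, 0)), "length_cM")
  expect_error(cross_spec(10, chrom1(5, 50), genotyping_error_rate = 1.5),
               "probability")
  expect_error(cross_spec(10, chrom1(5, 50), missing_rate = NaN), "probability")
})

test_that("phenotypes follow the planted QTL architecture", {
  sim <- sim_f2_cross(cross_spec(120, chrom1(11, 50), seed = 21))
  # no QTL, no noise: constant
  ph0 <- sim_phenotypes(sim$truth, sim$true_map, list(), residual_sd = 0, seed = 1)
  expect_equal(length(unique(ph0[[2]])), 1L)
  # one additive QTL, no noise: exactly 3 values grouped by QTL genotype
  q <- qtl_spec(1, 25, additive_effect = 0.1)
  ph1 <- sim_phenotypes(sim$truth, sim$true_map, list(q), residual_sd = 0, seed = 1)
  expect_equal(length(unique(ph1[[2]])), 3L)
  qg <- sim$truth$calls["chr1_m06", ] # marker at 25 cM
  expect_equal(length(unique(paste(qg, ph1[[2]]))), 3L)
})

test_that("realized PVE lands near its target", {
  sim <- sim_f2_cross(cross_spec(500, chrom1(11, 50), seed = 31))
  a <- additive_effect_for_pve(0.5, residual_sd = 0.08)
  ph <- sim_phenotypes(sim$truth, sim$true_map,
                       list(qtl_spec(1, 25, a)), residual_sd = 0.08, seed = 3)
  expect_lt(abs(attr(ph, "realized_pve") - 0.5), 0.1)
})

test_that("off-map QTLs are rejected and clamping is reported", {
  sim <- sim_f2_cross(cross_spec(30, chrom1(5, 20), seed = 41))
  expect_error(
    sim_phenotypes(sim$truth, sim$true_map, list(qtl_spec(1, 90, 0.1)), 0.1),
    "off the map"
  )
  expect_warning(
    sim_phenotypes(sim$truth, sim$true_map, list(qtl_spec(1, 10, 0.6)),
                   residual_sd = 0.4, seed = 2),
    "clamped"
  )
})

test_that("population panel respects planted fixation and likelihood calls", {
  spec <- panel_spec(8, 12, 100, planted_sites = c(10, 60), seed = 17)
  p <- sim_population_sites(spec)
  expect_identical(attr(p, "planted_sites"), c(10L, 60L))
  for (s in c(10, 60)) {
    expect_true(all(p$gt[s, p$groups == "case"] == 2L))
    expect_false(any(p$gt[s, p$groups == "background"] == 2L, na.rm = TRUE))
  }
  # gl_error_rate = 0: the maximum-likelihood genotype equals every call
  ml <- apply(p$pl, c(1, 2), which.min) - 1L
  expect_true(all(ml == p$gt))
  # determinism
  expect_identical(sim_population_sites(spec)$pl, p$pl)
  # candidate filter recovers exactly the planted set
  cand <- candidate_snp_filter(p)
  expect_equal(sort(match(cand$pos, p$sites$pos)), c(10L, 60L))
})

test_that("panel_spec rejects infeasible configurations", {
  expect_error(panel_spec(0, 5, 10), "n_case")
  expect_error(panel_spec(2, 5, 10, planted_sites = 11), "1..n_sites")
  expect_error(panel_spec(2, 5, 10, gl_error_rate = -0.1), "probability")
})

test_that("alignment generator plants identity structure faithfully", {
  # background identity 1: every base conserved for every species
  al <- sim_alignment(3, 2, background_identity = 1, ref_length = 500,
                      gap_rate = 0, seed = 3)
  for (sp in al$block$species$species) {
    regions <- species_conserved_regions(al$block, sp)
    expect_equal(nrow(regions), 1L)
    expect_equal(c(regions$start, regions$end), c(0L, 500L))
  }
  # overlap rejection
  expect_error(
    sim_alignment(3, 2, planted_cnes = tibble::tibble(
      start = c(0, 50), end = c(100, 150), identity = 0.9, n_species = 2),
      ref_length = 500, seed = 1),
    "overlap"
  )
  # determinism
  a1 <- sim_alignment(5, 2, background_identity = 0.4, ref_length = 300, seed = 9)
  a2 <- sim_alignment(5, 2, background_identity = 0.4, ref_length = 300, seed = 9)
  expect_identical(a1$block$species$seq, a2$block$species$seq)
})

test_that("coverage generator scales depth with planted copy number", {
  # zero-variance noise, no duplication: exactly 2.0 everywhere
  s0 <- dup_plant_spec(1e5, 5000, dup_start = NULL, dup_end = NULL,
                       mean_depth = 30, noise_model = "none", seed = 1)
  tr0 <- normalize_coverage(sim_coverage(s0)$track)
  expect_true(all(tr0$copy_number == 2))
  # homozygous dup, zero variance: exactly 4 inside, 2 outside
  s1 <- dup_plant_spec(1e5, 5000, dup_start = 20000, dup_end = 50000,
                       copy_state = "homozygous", mean_depth = 30,
                       noise_model = "none", seed = 1)
  cov <- sim_coverage(s1)
  tr1 <- normalize_coverage(cov$track)
  inside <- tr1$start >= 20000 & tr1$end <= 50000
  expect_true(all(tr1$copy_number[inside] == 4))
  expect_true(all(tr1$copy_number[!inside] == 2))
  # evidence sits at the planted breakpoints and remaps to the partner edge
  expect_setequal(unique(cov$evidence$clips$pos), c(20000L, 50000L))
  expect_true(all(cov$evidence$clips$remap_pos[cov$evidence$clips$pos == 20000] == 50000))
})

test_that("coverage spec guards degenerate geometry", {
  expect_error(dup_plant_spec(1000, 5000, dup_start = 1, dup_end = 10), "window larger")
  expect_error(dup_plant_spec(1e5, 5000, dup_start = -1, dup_end = 10), "within the genome")
})

test_that("allele-count generator plants copy-specific structure", {
  ac <- sim_allele_counts(30, 1000, 1000, copy_specific = c(2, 7), seed = 13)
  cls <- classify_copy_specific(ac)
  expect_setequal(cls$snp_id[cls$class == "copy_specific"],
                  attr(ac, "copy_specific"))
  # no planted SNPs: nothing classified at default thresholds
  ac0 <- sim_allele_counts(30, 200, 200, seed = 14)
  expect_false(any(classify_copy_specific(ac0)$class == "copy_specific"))
  expect_error(sim_allele_counts(10, 0, 50), "depths")
})
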