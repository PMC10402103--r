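# Staged map construction: filters, pairwise linkage, grouping, ordering,
# and HMM-based genotype cleaning.

test_that("segregation filter keeps 1:2:1 markers and drops gross distortion", {
  calls <- rbind(
    rep(c("AA", "AB", "BB"), c(25, 50, 25)),  # perfect 1:2:1
    rep("AA", 100)                             # all one class
  )
  g <- make_geno(calls)
  out <- segregation_filter(g, alpha = 0.01)
  rep <- attr(out, "report")
  expect_equal(rep$chisq[1], 0)
  expect_equal(rep$status[1], "retained")
  # chi-square oracle for counts (100, 0, 0): 225 + 50 + 25 = 300
  expect_equal(rep$chisq[2], 300)
  expect_lt(rep$p_value[2], pchisq(300, 2, lower.tail = FALSE) + 1e-60)
  expect_equal(rep$status[2], "dropped")
  expect_equal(nrow(out$calls), 1L)
})

test_that("Z-linked markers are never distortion-tested", {
  calls <- rbind(rep("AA", 60), rep(c("AA", "AB", "BB"), 20))
  g <- make_geno(calls, chrom_class = c("Z", "autosomal"))
  out <- segregation_filter(g)
  expect_true("m01" %in% out$markers$marker_id)
  expect_equal(attr(out, "report")$status[1], "untested")
})

test_that("duplicate collapse uses strict identity including missing pattern", {
  base <- rep(c("AA", "AB", "BB"), c(5, 10, 5))
  with_na <- base; with_na[3] <- NA
  g <- make_geno(rbind(base, base, base, with_na))
  out <- collapse_duplicates(g)
  expect_equal(nrow(out$calls), 2L)                      # k copies -> 1 kept
  expect_equal(nrow(attr(out, "duplicates")), 2L)        # k - 1 recorded
  expect_true(all(attr(out, "duplicates")$representative == "m01"))
  expect_true("m04" %in% out$markers$marker_id)          # differs by one NA
})

test_that("two-pass genotyping-rate filter honours scaffold size", {
  n_ind <- 100
  mk_rate <- function(rate) {
    x <- rep("AB", n_ind)
    x[seq_len(round((1 - rate) * n_ind))] <- NA
    x
  }
  # small scaffold: 10 markers at 60%; large scaffold: 60 markers at 60%
  calls <- rbind(
    mk_rate(0.49),
    do.call(rbind, replicate(10, mk_rate(0.60), simplify = FALSE)),
    do.call(rbind, replicate(60, mk_rate(0.60), simplify = FALSE))
  )
  scaf <- c("s0", rep("small", 10), rep("large", 60))
  g <- make_geno(calls, scaffold = scaf, pos_bp = seq_len(71) * 100L)
  out <- genotyping_rate_filter(g)
  expect_false("m01" %in% out$markers$marker_id)               # pass 1
  expect_equal(sum(out$markers$scaffold == "small"), 10L)      # pass 2 skipped
  expect_equal(sum(out$markers$scaffold == "large"), 0L)       # pass 2 applied
})

test_that("estimate_rf recovers coupling, independence, and planted r", {
  calls <- rep(c("AA", "AB", "BB"), c(12, 26, 12))
  same <- estimate_rf(calls, calls)
  expect_equal(same$r_hat, 0, tolerance = 1e-6)
  expect_gt(same$lod_linkage, 0)

  set.seed(99)
  a <- sample(c("AA", "AB", "BB"), 10000, TRUE, prob = c(.25, .5, .25))
  b <- sample(c("AA", "AB", "BB"), 10000, TRUE, prob = c(.25, .5, .25))
  ind <- estimate_rf(a, b)
  expect_lt(abs(ind$r_hat - 0.5), 0.02)
  expect_lt(ind$lod_linkage, 1)

  # parameter recovery at r = 0.10, n = 200
  sim_pair <- function(r, n) {
    gam <- function() {
      h1 <- rbinom(n, 1, 0.5)
      h2 <- (h1 + rbinom(n, 1, r)) %% 2
      cbind(h1, h2)
    }
    g <- gam() + gam()
    list(a = c("AA", "AB", "BB")[g[, 1] + 1], b = c("AA", "AB", "BB")[g[, 2] + 1])
  }
  set.seed(7)
  errs <- replicate(60, {
    p <- sim_pair(0.10, 200)
    estimate_rf(p$a, p$b)$r_hat - 0.10
  })
  expect_lt(mean(abs(errs)), 0.02)
})

test_that("estimate_rf flags monomorphic and low-information pairs", {
  mono <- estimate_rf(rep("AA", 20), rep(c("AA", "AB"), 10))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$r_hat))
  few <- estimate_rf(c("AA", "BB", rep(NA, 18)), c("AA", "BB", rep(NA, 18)))
  expect_true(few$low_information)
})

test_that("rf estimates match the likelihood-grid oracle", {
  set.seed(15)
  for (i in 1:5) {
    n <- 80
    h <- function(r) {
      h1 <- rbinom(n, 1, 0.5); cbind(h1, (h1 + rbinom(n, 1, r)) %% 2)
    }
    r_true <- runif(1, 0.02, 0.45)
    g <- h(r_true) + h(r_true)
    a <- c("AA", "AB", "BB")[g[, 1] + 1]
    b <- c("AA", "AB", "BB")[g[, 2] + 1]
    est <- estimate_rf(a, b)
    oracle <- rf_grid_oracle(a, b)
    expect_lt(abs(est$r_hat - oracle$r_hat), 1e-3)
    expect_lt(abs(est$lod_linkage - oracle$lod), 0.01)
  }
})

test_that("form_groups joins by transitive closure under both criteria", {
  pairs <- tibble::tibble(
    marker_A = c("A", "B", "A", "C"),
    marker_B = c("B", "C", "C", "D"),
    r_hat = c(0.05, 0.05, 0.40, 0.10),
    lod_linkage = c(10, 10, 10, 3)  # C-D fails the LOD criterion
  )
  out <- form_groups(pairs, c("A", "B", "C", "D"))
  grp <- setNames(out$group, out$marker_id)
  expect_equal(grp[["A"]], grp[["B"]])
  expect_equal(grp[["B"]], grp[["C"]])   # via chain, despite weak A-C
  expect_false(grp[["D"]] == grp[["C"]]) # lod 3 < 6 not joined
  expect_equal(attr(out, "singletons"), "D")
})

test_that("two simulated chromosomes give exactly two groups", {
  sim <- sim_f2_cross(cross_spec(150, tibble::tibble(
    n_markers = c(8, 8), length_cM = c(40, 40)), seed = 12))
  pairs <- pairwise_linkage(sim$observed)
  out <- form_groups(pairs, sim$observed$markers$marker_id)
  expect_equal(length(unique(out$group)), 2L)
  expect_equal(length(unique(out$group[1:8])), 1L)
})

test_that("order_and_space orders by bp within a scaffold and spaces by Haldane", {
  sim <- sim_f2_cross(cross_spec(200, tibble::tibble(n_markers = 6,
                                                     length_cM = 25), seed = 33))
  frag <- order_and_space(sim$observed, sim$observed$markers$marker_id)
  expect_equal(frag$marker_id, sim$observed$markers$marker_id) # bp order
  expect_equal(frag$cM[1], 0)
  # identical duplicate columns -> r = 0 -> 0 cM spacing
  calls <- sim$observed$calls[c(1, 1, 3), ]
  g <- make_geno(calls)
  frag0 <- order_and_space(g, g$markers$marker_id)
  expect_equal(frag0$cM[2] - frag0$cM[1], 0)
  # closed form: r = 0.15 -> -50 ln(0.7) cM
  expect_equal(haldane_d(0.15), -50 * log(0.7))
  expect_equal(haldane_d(0.15), 17.8337, tolerance = 1e-4)
})

test_that("error LOD matches brute-force path enumeration and cleans planted artifacts", {
  # 5 markers 1 cM apart; individual 1 has a planted double recombinant at
  # the middle marker. With two flanking markers per side the "all flanks
  # miscalled" alternative is suppressed and the artifact clears threshold 5.
  calls <- rbind(rep("AA", 40), rep("AA", 40), c("BB", rep("AA", 39)),
                 rep("AA", 40), rep("AA", 40))
  g <- make_geno(calls)
  map <- genetic_map(tibble::tibble(
    group = 1, order = 1:5, marker_id = sprintf("m%02d", 1:5),
    scaffold = "s1", pos_bp = (1:5) * 1000, cM = 0:4
  ))
  el <- error_lod(g, map, genotype_error_prob = 0.01)
  bad <- el[el$marker_id == "m03" & el$individual == "i01", ]
  expect_gt(bad$error_lod, 5)
  # oracle: leave-one-out posterior from 3^5 path enumeration with the middle
  # marker's emission removed (uniform), for individual 1
  post <- hmm_enum_oracle(c(1L, 1L, NA, 1L, 1L), c(0, 1, 2, 3, 4), 0.01)
  expect_equal(bad$error_lod, log10((1 - post[3, 3]) / post[3, 3]),
               tolerance = 1e-6)
  cleaned <- error_lod_clean(g, map, threshold = 5)
  expect_true(is.na(cleaned$calls["m03", "i01"]))
  expect_equal(nrow(attr(cleaned, "report")), 1L)
})

test_that("isolated markers and clean data yield no removals", {
  sim <- sim_f2_cross(cross_spec(80, tibble::tibble(n_markers = 6,
                                                    length_cM = 30), seed = 44))
  cleaned <- error_lod_clean(sim$observed, sim$true_map, threshold = 5)
  expect_equal(nrow(attr(cleaned, "report")), 0L) # zero-noise: zero removals

  # single-marker map: posterior = prior, nothing removable at any threshold
  g1 <- make_geno(matrix(rep(c("AA", "AB", "BB"), 10), nrow = 1))
  map1 <- genetic_map(tibble::tibble(group = 1, order = 1, marker_id = "m01",
                                     scaffold = "s1", pos_bp = 1000, cM = 0))
  el <- error_lod(g1, map1)
  expect_lt(max(el$error_lod), 0.5) # log10(3) for hom calls is the maximum
})

test_that("drop-one-marker removes a planted bad marker but not clean ones", {
  set.seed(61)
  sim <- sim_f2_cross(cross_spec(150, tibble::tibble(n_markers = 8,
                                                     length_cM = 35), seed = 55))
  g <- sim$observed
  # clean map: no drops
  m0 <- drop_one_marker_eval(sim$true_map, g)
  expect_equal(nrow(attr(m0, "dropped")), 0L)
  # plant 30% genotyping errors in a middle marker; markers physically tight
  # (scaffold gap far below 1 Mb) so the inflated genetic length is
  # unsupported by physical distance
  bad <- g$calls
  flip <- sample(ncol(bad), 45)
  bad[4, flip] <- sample(c("AA", "AB", "BB"), 45, TRUE)
  meta <- g$markers
  meta$pos_bp <- seq_len(nrow(meta)) * 1000L
  gbad <- marker_geno(meta, g$individuals, bad)
  frag <- order_and_space(gbad, gbad$markers$marker_id)
  m1 <- drop_one_marker_eval(genetic_map(frag), gbad)
  expect_true("chr1_m04" %in% attr(m1, "dropped")$marker_id)

  # the shrinkage rule never removes a terminal marker
  bad2 <- g$calls
  bad2[1, flip] <- sample(c("AA", "AB", "BB"), 45, TRUE)
  gbad2 <- marker_geno(meta, g$individuals, bad2)
  frag2 <- order_and_space(gbad2, gbad2$markers$marker_id)
  m2 <- drop_one_marker_eval(genetic_map(frag2), gbad2)
  d2 <- attr(m2, "dropped")
  expect_false(any(d2$rule == "shrinkage" &
                     d2$marker_id %in% c(frag2$marker_id[1],
                                         frag2$marker_id[nrow(frag2)])))
})

test_that("noise-free map recovery: true order and length within 15%", {
  sim <- sim_f2_cross(cross_spec(200, tibble::tibble(
    n_markers = c(10, 10), length_cM = c(45, 45)), seed = 66))
  built <- build_linkage_map(sim$observed)
  expect_equal(length(unique(built$map$group)), 2L)
  for (grp in unique(built$map$group)) {
    mm <- built$map[built$map$group == grp, ]
    chr_ids <- sort(mm$marker_id)
    truth_ids <- sort(sim$true_map$marker_id[
      sim$true_map$scaffold == mm$scaffold[1]])
    expect_equal(chr_ids, truth_ids)
    ord <- mm$marker_id
    truth_ord <- sim$true_map$marker_id[sim$true_map$scaffold == mm$scaffold[1]]
    expect_true(identical(ord, truth_ord) || identical(ord, rev(truth_ord)))
    expect_lt(abs(max(mm$cM) - 45) / 45, 0.15)
  }
})

test_that("pipeline is idempotent on already-clean input", {
  sim <- sim_f2_cross(cross_spec(120, tibble::tibble(n_markers = 8,
                                                     length_cM = 35), seed = 77))
  b1 <- build_linkage_map(sim$observed)
  b2 <- build_linkage_map(b1$genotypes)
  expect_equal(b2$map$marker_id, b1$map$marker_id)
  expect_equal(b2$map$cM, b1$map$cM, tolerance = 1e-6)
  expect_identical(b2$genotypes$calls, b1$genotypes$calls)
})
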