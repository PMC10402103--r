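# Coverage normalization, duplication calling, breakpoint refinement,
# sample screening, and copy-specific expression.

flat_track <- function(depth, n = 20, window = 5000) {
  tibble::tibble(scaffold = "s507", start = (seq_len(n) - 1) * window,
                 end = seq_len(n) * window, depth = depth)
}

test_that("normalization scales constant depth to exactly 2", {
  tr <- normalize_coverage(flat_track(30))
  expect_true(all(tr$copy_number == 2))
  tr2 <- normalize_coverage(flat_track(c(rep(30, 19), 45)))
  expect_equal(tr2$copy_number[20], 3)
  expect_error(normalize_coverage(flat_track(0)), "zero")
  expect_error(normalize_coverage(flat_track(30, n = 5)), "at least 10")
})

test_that("normalized Poisson depth has median near 2", {
  set.seed(3)
  tr <- normalize_coverage(flat_track(rpois(400, 30), n = 400))
  expect_lt(abs(median(tr$copy_number) - 2), 0.1)
})

test_that("exclusion masks keep the reference statistic clean", {
  depth <- c(rep(30, 15), rep(60, 15)) # half the windows duplicated
  tr <- flat_track(depth, n = 30)
  masked <- normalize_coverage(tr, exclude = tibble::tibble(start = 75000,
                                                            end = 150000))
  expect_equal(masked$copy_number[1], 2)
  expect_equal(masked$copy_number[20], 4)
})

test_that("duplication calls follow runs, thresholds and genotype bins", {
  tr <- normalize_coverage(flat_track(30))
  expect_equal(nrow(call_duplication(tr)), 0L)

  hom <- flat_track(c(rep(30, 8), rep(60, 5), rep(30, 7)))
  calls <- call_duplication(normalize_coverage(hom))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$genotype, "hom")
  expect_equal(c(calls$start, calls$end), c(8 * 5000, 13 * 5000))
  expect_equal(calls$mean_copy_number, 4)

  het <- flat_track(c(rep(30, 8), rep(45, 5), rep(30, 7)))
  expect_equal(call_duplication(normalize_coverage(het))$genotype, "het")

  # runs shorter than min_windows do not call
  short <- flat_track(c(rep(30, 9), rep(60, 2), rep(30, 9)))
  expect_equal(nrow(call_duplication(normalize_coverage(short))), 0L)
})

test_that("binning boundaries are half-open with no double assignment", {
  tr <- normalize_coverage(flat_track(30))
  region <- list(scaffold = "s507", start = 0, end = 100000)
  for (cn in c(2.4999, 2.5, 3.4999, 3.5)) {
    tr2 <- dplyr::mutate(tr, copy_number = cn)
    got <- screen_samples(list(s = tr2), region)$genotype
    want <- if (cn < 2.5) "absent" else if (cn < 3.5) "het" else "hom"
    expect_equal(got, want)
  }
})

test_that("breakpoint refinement uses concordant soft-clip clusters", {
  spec <- dup_plant_spec(5e5, 5000, dup_start = 200000, dup_end = 237000,
                         copy_state = "heterozygous", mean_depth = 30,
                         noise_model = "none", seed = 5)
  cov <- sim_coverage(spec)
  call <- call_duplication(normalize_coverage(cov$track))
  refined <- refine_breakpoints(call[1, ], cov$evidence)
  expect_true(refined$refined)
  expect_equal(c(refined$start, refined$end), c(200000L, 237000L))
  expect_equal(refined$bp_uncertainty, 1L)

  # no evidence: depth-only flag, interval unchanged
  bare <- refine_breakpoints(call[1, ], list(clips = tibble::tibble()))
  expect_false(bare$refined)
  expect_equal(c(bare$start, bare$end), c(call$start[1], call$end[1]))

  # conflicting equal-count clip modes: unrefined with a warning
  tie_clips <- tibble::tibble(
    scaffold = "scaffold_507",
    pos = c(200000L, 200400L, 237000L, 237000L),
    side = c("left", "left", "right", "right"),
    remap_pos = c(237000L, 237000L, 200000L, 200000L)
  )
  expect_warning(
    tied <- refine_breakpoints(call[1, ], list(clips = tie_clips)),
    "tied"
  )
  expect_false(tied$refined)

  # evidence on the wrong scaffold is ignored with a warning
  wrong <- dplyr::mutate(cov$evidence$clips, scaffold = "other")
  expect_warning(w <- refine_breakpoints(call[1, ], list(clips = wrong)),
                 "different scaffold")
  expect_false(w$refined)
})

test_that("unequal-count clip modes resolve to the better-supported mode", {
  spec <- dup_plant_spec(5e5, 5000, dup_start = 200000, dup_end = 237000,
                         copy_state = "heterozygous", mean_depth = 30,
                         noise_model = "none", seed = 6)
  cov <- sim_coverage(spec)
  call <- call_duplication(normalize_coverage(cov$track))
  extra <- dplyr::bind_rows(
    cov$evidence$clips,
    tibble::tibble(scaffold = "scaffold_507", pos = 200700L, side = "left",
                   remap_pos = 237000L)
  )
  refined <- refine_breakpoints(call[1, ], list(clips = extra))
  expect_true(refined$refined)
  expect_equal(refined$start, 200000L)
})

test_that("planted duplication recovery under Poisson noise is window-accurate", {
  hits <- 0
  for (seed in 1:6) {
    spec <- dup_plant_spec(5e5, 5000, dup_start = 250000, dup_end = 287000,
                           copy_state = "heterozygous", mean_depth = 30,
                           noise_model = "poisson", seed = seed)
    cov <- sim_coverage(spec)
    calls <- call_duplication(normalize_coverage(cov$track))
    if (nrow(calls) >= 1) {
      main <- calls[which.max(calls$n_windows), ]
      if (abs(main$start - 250000) <= 5000 && abs(main$end - 287000) <= 5000 &&
          main$genotype == "het") {
        hits <- hits + 1
      }
    }
  }
  expect_gte(hits, 5)
})

test_that("sample screening recovers mixed planted copy states", {
  set.seed(9)
  states <- c(rep("absent", 10), rep("het", 6), rep("hom", 4))
  region <- list(scaffold = "scaffold_507", start = 250000, end = 287000)
  tracks <- purrr::map(states, function(st) {
    spec <- dup_plant_spec(
      5e5, 5000,
      dup_start = if (st == "absent") NULL else 250000,
      dup_end = if (st == "absent") NULL else 287000,
      copy_state = if (st == "hom") "homozygous" else "heterozygous",
      mean_depth = 30, noise_model = "poisson",
      seed = sample.int(1e6, 1)
    )
    normalize_coverage(sim_coverage(spec)$track)
  })
  names(tracks) <- sprintf("b%02d", seq_along(states))
  screened <- screen_samples(tracks, region)
  expect_gte(mean(screened$genotype == states), 0.95)
  expect_error(screen_samples(tracks, list(scaffold = "nope", start = 0, end = 1)),
               "outside")
})

test_that("normalized expression is the scaled read ratio", {
  expect_equal(normalized_expression(500, 1e7), 50)
  expect_equal(normalized_expression(0, 123), 0)
  expect_equal(normalized_expression(500, 1e7), normalized_expression(1000, 2e7))
  expect_error(normalized_expression(1, 0), "total_sample_reads")
})

test_that("copy-specific classification follows its thresholds", {
  tab <- tibble::tibble(
    snp_id = rep(c("s1", "s2", "s3"), each = 2),
    sample = rep(c("w1", "p1"), 3),
    tissue = rep(c("white", "pigmented"), 3),
    ref_count = c(50, 26, 25, 24, 2, 25),
    alt_count = c(0, 24, 25, 26, 3, 25)
  )
  out <- classify_copy_specific(tab)
  expect_equal(out$class[out$snp_id == "s1"], "copy_specific")
  expect_equal(out$white_allele[out$snp_id == "s1"], "ref")
  expect_equal(out$class[out$snp_id == "s2"], "shared")
  expect_equal(out$class[out$snp_id == "s3"], "uninformative") # depth 5 white
})

test_that("classification is symmetric under ref/alt relabeling", {
  ac <- sim_allele_counts(40, 80, 80, copy_specific = c(4, 11), seed = 23)
  swapped <- dplyr::rename(ac, ref_count = alt_count, alt_count = ref_count)
  a <- classify_copy_specific(ac)
  b <- classify_copy_specific(swapped)
  expect_equal(a$class, b$class)
  cs <- a$class == "copy_specific"
  expect_true(all(a$white_allele[cs] != b$white_allele[cs]))
})

test_that("high depth recovers all planted copy-specific SNPs with no extras", {
  ac <- sim_allele_counts(200, 1000, 1000, copy_specific = c(10, 50, 150),
                          seed = 29)
  out <- classify_copy_specific(ac)
  expect_setequal(out$snp_id[out$class == "copy_specific"],
                  attr(ac, "copy_specific"))
})
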