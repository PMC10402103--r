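#' Segregation-distortion filter
#'
#' Tests each autosomal marker's non-missing calls against the 1:2:1 F2
#' expectation with a chi-square goodness-of-fit test (df = 2) and drops
#' markers significant after Bonferroni correction across the markers tested
#' (p < alpha / M). Z-linked markers are never tested at this stage and are
#' always retained. Markers with fewer than 2 non-missing calls are excluded
#' from testing and flagged.
#'
#' @param g A [marker_geno()].
#' @param alpha Nominal significance level before Bonferroni (default 0.01).
#' @return The retained [marker_geno()], with attribute `report`: a tibble of
#'   all markers with counts, chi-square statistic, p-value and status
#'   (`retained` / `dropped` / `untested`).
#' @export
segregation_filter <- function(g, alpha = 0.01) {
  stopifnot(inherits(g, "marker_geno"))
  counts <- t(apply(g$calls, 1, function(x) {
    c(sum(x == "AA", na.rm = TRUE), sum(x == "AB", na.rm = TRUE),
      sum(x == "BB", na.rm = TRUE))
  }))
  n_obs <- rowSums(counts)
  autosomal <- g$markers$chrom_class == "autosomal"
  testable <- autosomal & n_obs >= 2
  M <- sum(testable)
  expected <- cbind(n_obs / 4, n_obs / 2, n_obs / 4)
  chisq <- unname(rowSums((counts - expected)^2 / expected))
  pval <- pchisq(chisq, df = 2, lower.tail = FALSE)
  chisq[!testable] <- NA_real_
  pval[!testable] <- NA_real_
  drop <- testable & pval < alpha / max(M, 1)
  drop[is.na(drop)] <- FALSE
  report <- tibble(
    marker_id = g$markers$marker_id,
    n_AA = counts[, 1], n_AB = counts[, 2], n_BB = counts[, 3],
    chisq = chisq, p_value = pval,
    status = dplyr::case_when(
      !testable & autosomal ~ "untested",
      !autosomal ~ "untested",
      drop ~ "dropped",
      TRUE ~ "retained"
    )
  )
  out <- subset_markers(g, !drop)
  attr(out, "report") <- report
  out
}

#' Collapse markers with identical genotyping information
#'
#' Markers whose call vectors are identical across all individuals (including
#' the missing pattern) carry no independent information; one representative
#' per identity class is retained (lowest scaffold name, then lowest bp).
#'
#' @param g A [marker_geno()].
#' @return Retained [marker_geno()], with attribute `duplicates`: tibble
#'   mapping each collapsed marker to its retained representative.
#' @export
collapse_duplicates <- function(g) {
  stopifnot(inherits(g, "marker_geno"))
  key <- apply(g$calls, 1, function(x) paste(ifelse(is.na(x), "-", x), collapse = ""))
  ord <- order(key, g$markers$scaffold, g$markers$pos_bp)
  first_of_key <- !duplicated(key[ord])
  rep_for_key <- setNames(g$markers$marker_id[ord][first_of_key],
                          key[ord][first_of_key])
  keep <- g$markers$marker_id %in% rep_for_key
  dup_map <- tibble(
    marker_id = g$markers$marker_id[!keep],
    representative = unname(rep_for_key[key[!keep]])
  )
  out <- subset_markers(g, keep)
  attr(out, "duplicates") <- dup_map
  out
}

#' Two-pass genotyping-rate filter
#'
#' Pass 1 removes markers genotyped in fewer than `first_pass` of individuals.
#' Pass 2 applies only to large scaffolds (more than `large_scaffold` markers
#' remaining after pass 1) and removes markers genotyped in fewer than
#' `second_pass` of individuals.
#'
#' @param g A [marker_geno()].
#' @param first_pass,second_pass Minimum genotyping rates (fractions).
#' @param large_scaffold Marker-count threshold defining a large scaffold.
#' @return Retained [marker_geno()] with attribute `report` (markers removed
#'   per pass).
#' @export
genotyping_rate_filter <- function(g, first_pass = 0.50, second_pass = 0.66,
                                   large_scaffold = 40) {
  stopifnot(inherits(g, "marker_geno"))
  rate <- rowMeans(!is.na(g$calls))
  keep1 <- rate >= first_pass
  g1 <- subset_markers(g, keep1)
  rate1 <- rowMeans(!is.na(g1$calls))
  scaf_n <- table(g1$markers$scaffold)
  big <- g1$markers$scaffold %in% names(scaf_n)[scaf_n > large_scaffold]
  keep2 <- !(big & rate1 < second_pass)
  out <- subset_markers(g1, keep2)
  attr(out, "report") <- tibble(
    pass = c(1L, 2L),
    removed = c(sum(!keep1), sum(!keep2))
  )
  out
}

# F2 two-locus joint genotype probability table (3 x 3, rows = locus A
# genotype dosage 0/1/2, cols = locus B) at recombination fraction r,
# phase-known intercross: both parental meioses recombine independently.
#' @noRd
f2_joint_table <- function(r) {
  # gamete haplotypes (a, b) each in {0, 1}: parental (0,0), (1,1) w.p.
  # (1-r)/2; recombinant (0,1), (1,0) w.p. r/2
  hap <- cbind(a = c(0, 1, 0, 1), b = c(0, 1, 1, 0))
  hp <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  T <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    ga <- hap[i, 1] + hap[j, 1]
    gb <- hap[i, 2] + hap[j, 2]
    T[ga + 1, gb + 1] <- T[ga + 1, gb + 1] + hp[i] * hp[j]
  }
  T
}

#' Pairwise recombination fraction by maximum likelihood
#'
#' Estimates the recombination fraction between two F2 markers by maximizing
#' the phase-known intercross two-locus likelihood over `r` in `[0, 0.5]`
#' (1-D numerical optimization), using pairwise-complete individuals only.
#' The linkage LOD is `log10 L(r_hat) - log10 L(0.5)`.
#'
#' @param calls_A,calls_B Character vectors of calls in `{AA, AB, BB, NA}`.
#' @param tol Optimizer tolerance.
#' @return Tibble with `r_hat`, `lod_linkage`, `n_informative` and
#'   `low_information` (fewer than 10 jointly non-missing individuals) /
#'   `monomorphic` flags.
#' @export
estimate_rf <- function(calls_A, calls_B, tol = 1e-9) {
  ok <- !is.na(calls_A) & !is.na(calls_B)
  a <- match(calls_A[ok], GENO_LEVELS)
  b <- match(calls_B[ok], GENO_LEVELS)
  n_inf <- sum(ok)
  mono <- length(unique(a)) < 2 || length(unique(b)) < 2
  if (n_inf == 0 || mono) {
    return(tibble(r_hat = NA_real_, lod_linkage = NA_real_,
                  n_informative = n_inf, low_information = n_inf < 10,
                  monomorphic = mono))
  }
  counts <- matrix(0, 3, 3)
  for (k in seq_along(a)) counts[a[k], b[k]] <- counts[a[k], b[k]] + 1
  ll <- function(r) sum(counts * log(f2_joint_table(r)))
  opt <- optimize(ll, c(0, 0.5), maximum = TRUE, tol = tol)
  # check the boundaries too; optimize() only searches the interior
  cand_r <- c(opt$maximum, 1e-12, 0.5)
  cand_ll <- c(opt$objective, ll(1e-12), ll(0.5))
  best <- which.max(cand_ll)
  r_hat <- if (best == 2) 0 else cand_r[best]
  lod <- (cand_ll[best] - ll(0.5)) / log(10)
  tibble(r_hat = r_hat, lod_linkage = max(lod, 0),
         n_informative = n_inf, low_information = n_inf < 10,
         monomorphic = FALSE)
}

#' All pairwise linkage estimates
#'
#' Runs [estimate_rf()] over every marker pair (or only pairs within a
#' supplied candidate set) and returns a long tibble.
#'
#' @param g A [marker_geno()].
#' @param pairs Optional two-column matrix/data frame of marker-id pairs;
#'   default all pairs.
#' @return Tibble with `marker_A`, `marker_B` and the [estimate_rf()] columns.
#' @export
pairwise_linkage <- function(g, pairs = NULL) {
  stopifnot(inherits(g, "marker_geno"))
  ids <- g$markers$marker_id
  if (is.null(pairs)) {
    if (length(ids) < 2) return(tibble())
    idx <- utils::combn(length(ids), 2)
    pairs <- cbind(ids[idx[1, ]], ids[idx[2, ]])
  } else {
    pairs <- as.matrix(pairs)
  }
  res <- purrr::map2(pairs[, 1], pairs[, 2], function(a, b) {
    estimate_rf(g$calls[a, ], g$calls[b, ])
  })
  bind_rows(res) %>%
    mutate(marker_A = pairs[, 1], marker_B = pairs[, 2], .before = 1)
}

#' Form linkage groups
#'
#' Two markers are linked iff `r_hat <= max_rf` and `lod_linkage >= min_lod`;
#' linkage groups are the connected components of the resulting graph.
#'
#' @param pairs Tibble from [pairwise_linkage()].
#' @param marker_ids All marker ids (so unlinked markers appear as singletons).
#' @param max_rf,min_lod Linkage criteria (defaults 0.15 and 6).
#' @return Tibble `marker_id`, `group` (groups numbered by decreasing size),
#'   with singleton markers reported in attribute `singletons`.
#' @export
form_groups <- function(pairs, marker_ids, max_rf = 0.15, min_lod = 6) {
  linked <- pairs %>%
    filter(!is.na(.data$r_hat), .data$r_hat <= max_rf,
           .data$lod_linkage >= min_lod)
  edges <- cbind(match(linked$marker_A, marker_ids),
                 match(linked$marker_B, marker_ids))
  comp <- connected_components(length(marker_ids), edges)
  sizes <- table(comp)
  # renumber groups by decreasing size, ties by first appearance
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  out <- tibble(marker_id = marker_ids,
                group = unname(relabel[as.character(comp)]))
  singles <- names(sizes)[sizes == 1]
  attr(out, "singletons") <- marker_ids[comp %in% as.integer(singles)]
  out
}

# Greedy chain of scaffolds within one linkage group: repeatedly append the
# scaffold whose terminal marker has the smallest r to the open end of the
# chain, orienting each scaffold so its nearer end connects.
#' @noRd
chain_scaffolds <- function(scaffolds, end_rf) {
  n <- length(scaffolds)
  if (n == 1) return(list(order = 1L, flip = FALSE))
  used <- rep(FALSE, n)
  # start at the scaffold with the smallest inter-scaffold end rf
  rmin <- apply(end_rf, 1, min, na.rm = TRUE)
  cur <- which.min(rmin)
  used[cur] <- TRUE
  ord <- cur; flips <- FALSE
  while (any(!used)) {
    last <- ord[length(ord)]
    cand <- which(!used)
    # end_rf[i, j] holds min over end-combination rfs; orientation resolved below
    best <- cand[which.min(end_rf[last, cand])]
    ord <- c(ord, best); flips <- c(flips, attr(end_rf, "flip")[last, best])
    used[best] <- TRUE
  }
  list(order = ord, flip = flips)
}

#' Order markers within a linkage group and assign cM positions
#'
#' Within each scaffold, markers are ordered by bp. Scaffolds are then chained
#' greedily: the next scaffold appended is the one whose terminal marker shows
#' the smallest recombination fraction to the current chain end, and each
#' scaffold is oriented so its nearer terminal connects (this automates manual
#' ordering from recombination fractions). Adjacent-marker spacing is the
#' Haldane transform `-50 log(1 - 2 r)` of the re-estimated adjacent
#' recombination fraction, capped at `cap_cM` when `r` approaches 0.5.
#'
#' @param g A [marker_geno()] restricted to (or containing) the group markers.
#' @param group_markers Character vector of marker ids in this group.
#' @param group Group label for the output.
#' @param cap_cM Cap on a single adjacent interval (default 50 cM); capped
#'   intervals are flagged in attribute `capped`.
#' @return [genetic_map()] fragment for this group.
#' @export
order_and_space <- function(g, group_markers, group = 1L, cap_cM = 50) {
  meta <- g$markers %>%
    filter(.data$marker_id %in% group_markers) %>%
    arrange(.data$scaffold, .data$pos_bp)
  scafs <- unique(meta$scaffold)
  by_scaf <- split(meta$marker_id, factor(meta$scaffold, levels = scafs))

  if (length(scafs) > 1) {
    # rf between every pair of scaffold terminals, plus best orientation
    ends <- purrr::map(by_scaf, function(m) c(first = m[1], last = m[length(m)]))
    n <- length(scafs)
    end_rf <- matrix(Inf, n, n)
    flip <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      # connect i's last end to j; orientation of j: first (no flip) or last (flip)
      r_nf <- estimate_rf(g$calls[ends[[i]]["last"], ], g$calls[ends[[j]]["first"], ])$r_hat
      r_fl <- estimate_rf(g$calls[ends[[i]]["last"], ], g$calls[ends[[j]]["last"], ])$r_hat
      r_nf <- ifelse(is.na(r_nf), 0.5, r_nf); r_fl <- ifelse(is.na(r_fl), 0.5, r_fl)
      end_rf[i, j] <- min(r_nf, r_fl); flip[i, j] <- r_fl < r_nf
      # reverse direction: j's last connects into i
      r_nf2 <- estimate_rf(g$calls[ends[[j]]["last"], ], g$calls[ends[[i]]["first"], ])$r_hat
      r_fl2 <- estimate_rf(g$calls[ends[[j]]["last"], ], g$calls[ends[[i]]["last"], ])$r_hat
      r_nf2 <- ifelse(is.na(r_nf2), 0.5, r_nf2); r_fl2 <- ifelse(is.na(r_fl2), 0.5, r_fl2)
      end_rf[j, i] <- min(r_nf2, r_fl2); flip[j, i] <- r_fl2 < r_nf2
    }
    attr(end_rf, "flip") <- flip
    chain <- chain_scaffolds(scafs, end_rf)
    ordered <- purrr::map2(chain$order, chain$flip, function(k, fl) {
      m <- by_scaf[[k]]
      if (fl) rev(m) else m
    })
    marker_order <- unlist(ordered, use.names = FALSE)
  } else {
    marker_order <- by_scaf[[1]]
  }

  # adjacent spacing from re-estimated rf, Haldane transform
  n_mar <- length(marker_order)
  d <- numeric(max(n_mar - 1, 0))
  capped <- logical(length(d))
  for (k in seq_len(n_mar - 1)) {
    r <- estimate_rf(g$calls[marker_order[k], ], g$calls[marker_order[k + 1], ])$r_hat
    if (is.na(r)) r <- 0.5
    r <- min(r, 0.5)
    d[k] <- haldane_d(r, cap_cM = cap_cM)
    capped[k] <- r >= 0.5 - 1e-12 || d[k] >= cap_cM
  }
  if (any(capped)) {
    warn(sprintf("%d adjacent interval(s) capped at %g cM", sum(capped), cap_cM))
  }
  meta2 <- g$markers[match(marker_order, g$markers$marker_id), ]
  frag <- genetic_map(tibble(
    group = group, order = seq_len(n_mar), marker_id = marker_order,
    scaffold = meta2$scaffold, pos_bp = meta2$pos_bp,
    cM = cumsum(c(0, d))
  ))
  attr(frag, "capped") <- capped
  frag
}

#' HMM-based genotype cleaning by error LOD
#'
#' For every observed genotype on the map, computes an error LOD: the log10
#' posterior odds that the true genotype differs from the observed call, where
#' the posterior comes from the F2 genotype HMM conditioned on the flanking
#' markers only (the call's own observation is left out). Calls with error LOD
#' above `threshold` are set to missing.
#'
#' @param g A [marker_geno()].
#' @param map A [genetic_map()] covering (a subset of) the markers; markers
#'   not on the map are skipped with a warning.
#' @param genotype_error_prob Assumed genotyping error rate for the HMM
#'   emissions (default 0.01).
#' @param threshold Error-LOD threshold above which a call is removed.
#' @return Cleaned [marker_geno()], with attribute `report`: tibble of removed
#'   calls (marker, individual, call, error_lod).
#' @export
error_lod_clean <- function(g, map, genotype_error_prob = 0.01, threshold = 5) {
  stopifnot(inherits(g, "marker_geno"))
  off_map <- setdiff(g$markers$marker_id, map$marker_id)
  if (length(off_map)) {
    warn(sprintf("%d marker(s) not on map skipped by error_lod_clean", length(off_map)))
  }
  elod <- error_lod(g, map, genotype_error_prob)
  removed <- elod %>% filter(.data$error_lod > threshold)
  calls <- g$calls
  if (nrow(removed)) {
    calls[cbind(match(removed$marker_id, g$markers$marker_id),
                match(removed$individual, g$individuals))] <- NA_character_
  }
  out <- marker_geno(g$markers, g$individuals, calls)
  attr(out, "report") <- removed
  out
}

#' Error LOD scores for all observed calls on a map
#'
#' @inheritParams error_lod_clean
#' @return Tibble with one row per non-missing call on the map:
#'   `marker_id`, `individual`, `call`, `error_lod`.
#' @export
error_lod <- function(g, map, genotype_error_prob = 0.01) {
  stopifnot(inherits(g, "marker_geno"))
  out <- list()
  for (grp in unique(map$group)) {
    mm <- map[map$group == grp, ]
    mm <- mm[mm$marker_id %in% g$markers$marker_id, ]
    if (!nrow(mm)) next
    post <- f2_hmm_posteriors(g, mm$marker_id, mm$cM, genotype_error_prob,
                              leave_one_out = TRUE)
    obs <- g$calls[mm$marker_id, , drop = FALSE]
    oidx <- match(obs, GENO_LEVELS) # vector over matrix
    n_mar <- nrow(mm); n_ind <- length(g$individuals)
    p_obs <- matrix(NA_real_, n_mar, n_ind)
    for (s in 1:3) {
      sel <- which(oidx == s)
      p_obs[sel] <- post[, , s][sel]
    }
    el <- log10((1 - p_obs) / pmax(p_obs, 1e-300))
    keep <- !is.na(obs)
    out[[length(out) + 1]] <- tibble(
      marker_id = rep(mm$marker_id, times = n_ind)[keep],
      individual = rep(g$individuals, each = n_mar)[keep],
      call = obs[keep],
      error_lod = el[keep]
    )
  }
  bind_rows(out)
}

# Multipoint log-likelihood of one linkage group's genotype data under the F2
# HMM with the given marker order/spacing; sums log forward scale factors.
#' @noRd
group_loglik <- function(g, marker_ids, pos_cM, error_prob) {
  fb <- f2_hmm_forward(g, marker_ids, pos_cM, error_prob)
  sum(fb$loglik)
}

#' Drop-one-marker map refinement
#'
#' For each marker in each group, re-evaluates the map without it and drops
#' the marker if (a) the multipoint likelihood of the data is higher with the
#' marker treated as unlinked (its calls scored under the 1:2:1 stationary
#' prior) than with it on the map, or (b) it is non-terminal and removing it
#' shrinks the group length by more than `shrink_cM` without physical support
#' (flanking markers on the same scaffold within `gap_bp`). Iterates to a
#' fixpoint (bounded by `max_iter`).
#'
#' @param map A [genetic_map()].
#' @param g The [marker_geno()] behind it.
#' @param shrink_cM Length-decrease threshold in cM (default 10).
#' @param gap_bp Physical gap below which a long genetic interval is deemed
#'   unsupported (default 1e6).
#' @param error_prob HMM emission error rate.
#' @param max_iter Iteration cap.
#' @return Revised [genetic_map()] with attribute `dropped` (tibble of dropped
#'   markers and the rule that removed them).
#' @export
drop_one_marker_eval <- function(map, g, shrink_cM = 10, gap_bp = 1e6,
                                 error_prob = 0.01, max_iter = 10) {
  dropped <- tibble(marker_id = character(), rule = character())
  for (iter in seq_len(max_iter)) {
    any_drop <- FALSE
    for (grp in unique(map$group)) {
      mm <- map[map$group == grp, ]
      if (nrow(mm) < 3) next
      ll_with <- group_loglik(g, mm$marker_id, mm$cM, error_prob)
      len0 <- max(mm$cM) - min(mm$cM)
      for (k in seq_len(nrow(mm))) {
        rest <- mm[-k, ]
        # re-estimate the merged interval between the dropped marker's neighbors
        cM <- rest$cM
        if (k > 1 && k < nrow(mm)) {
          r <- estimate_rf(g$calls[mm$marker_id[k - 1], ],
                           g$calls[mm$marker_id[k + 1], ])$r_hat
          if (is.na(r)) r <- 0.5
          new_gap <- haldane_d(min(r, 0.4999), cap_cM = 50)
          shift <- new_gap - (cM[k] - cM[k - 1])
          cM[k:length(cM)] <- cM[k:length(cM)] + shift
        }
        ll_without <- group_loglik(g, rest$marker_id, cM, error_prob) +
          unlinked_marker_loglik(g, mm$marker_id[k], error_prob)
        rule <- NULL
        if (ll_without > ll_with + 1e-6) rule <- "likelihood"
        if (is.null(rule) && k > 1 && k < nrow(mm)) {
          shrink <- len0 - (max(cM) - min(cM))
          phys <- abs(mm$pos_bp[k + 1] - mm$pos_bp[k - 1])
          same_scaf <- mm$scaffold[k + 1] == mm$scaffold[k - 1]
          unsupported <- same_scaf && phys < gap_bp
          if (shrink > shrink_cM && unsupported) rule <- "shrinkage"
        }
        if (!is.null(rule)) {
          dropped <- bind_rows(dropped,
                               tibble(marker_id = mm$marker_id[k], rule = rule))
          keep <- map$marker_id != mm$marker_id[k]
          map <- respace_group(map[keep, ], g, grp, error_prob)
          any_drop <- TRUE
          break
        }
      }
      if (any_drop) break
    }
    if (!any_drop) break
  }
  out <- genetic_map(map)
  attr(out, "dropped") <- dropped
  out
}

# Log-likelihood of one marker's calls if it were unlinked: stationary 1:2:1
# prior filtered through the symmetric error model.
#' @noRd
unlinked_marker_loglik <- function(g, marker_id, error_prob) {
  x <- g$calls[marker_id, ]
  prior <- c(0.25, 0.5, 0.25)
  E <- matrix(error_prob / 2, 3, 3); diag(E) <- 1 - error_prob
  p_obs <- as.vector(prior %*% E) # marginal probability of each observed class
  sum(log(p_obs[match(x[!is.na(x)], GENO_LEVELS)]))
}

# Recompute cM spacing of one group after a marker removal (adjacent rf,
# Haldane), keeping the existing order.
#' @noRd
respace_group <- function(map, g, grp, error_prob) {
  mm <- map[map$group == grp, ]
  other <- map[map$group != grp, ]
  ord <- mm$marker_id
  d <- numeric(max(length(ord) - 1, 0))
  for (k in seq_along(d)) {
    r <- estimate_rf(g$calls[ord[k], ], g$calls[ord[k + 1], ])$r_hat
    if (is.na(r)) r <- 0.4999
    d[k] <- haldane_d(min(r, 0.4999), cap_cM = 50)
  }
  mm$cM <- cumsum(c(0, d))
  mm$order <- seq_len(nrow(mm))
  bind_rows(other, mm) %>% arrange(.data$group, .data$order)
}

#' Build a genetic map end to end
#'
#' Runs the staged pipeline: segregation-distortion filter, duplicate
#' collapse, two-pass genotyping-rate filter, pairwise linkage, grouping,
#' within-group ordering/spacing, HMM error-LOD genotype cleaning, and
#' drop-one-marker refinement. Z-linked markers are mapped in a separate pass
#' (no distortion test, own groups).
#'
#' @param g A [marker_geno()].
#' @param alpha Distortion-test level (Bonferroni-corrected internally).
#' @param max_rf,min_lod Grouping criteria.
#' @param error_prob HMM error rate for cleaning.
#' @param error_lod_threshold Error-LOD removal threshold.
#' @param min_group_size Groups smaller than this are reported but not mapped.
#' @return List: `map` ([genetic_map()]), `genotypes` (cleaned
#'   [marker_geno()]), `report` (list of per-stage drop counts).
#' @export
build_linkage_map <- function(g, alpha = 0.01, max_rf = 0.15, min_lod = 6,
                              error_prob = 0.01, error_lod_threshold = 5,
                              min_group_size = 2) {
  report <- list(n_input = nrow(g$calls))
  g1 <- segregation_filter(g, alpha = alpha)
  report$distortion_dropped <- report$n_input - nrow(g1$calls)
  g2 <- collapse_duplicates(g1)
  report$duplicates_collapsed <- nrow(g1$calls) - nrow(g2$calls)
  g3 <- genotyping_rate_filter(g2)
  report$rate_filtered <- nrow(g2$calls) - nrow(g3$calls)

  frags <- list()
  grp_counter <- 0L
  for (cls in intersect(c("autosomal", "Z"), unique(g3$markers$chrom_class))) {
    gc <- subset_markers(g3, g3$markers$chrom_class == cls)
    if (nrow(gc$calls) < 2) next
    pairs <- pairwise_linkage(gc)
    grouping <- form_groups(pairs, gc$markers$marker_id,
                            max_rf = max_rf, min_lod = min_lod)
    for (grp in sort(unique(grouping$group))) {
      ids <- grouping$marker_id[grouping$group == grp]
      if (length(ids) < min_group_size) next
      grp_counter <- grp_counter + 1L
      frags[[grp_counter]] <- order_and_space(gc, ids, group = grp_counter)
    }
  }
  if (!length(frags)) abort("no linkage groups of the minimum size were formed")
  map <- genetic_map(bind_rows(frags))
  report$n_groups <- length(frags)

  on_map <- subset_markers(g3, g3$markers$marker_id %in% map$marker_id)
  cleaned <- error_lod_clean(on_map, map, genotype_error_prob = error_prob,
                             threshold = error_lod_threshold)
  report$calls_removed <- nrow(attr(cleaned, "report"))
  final_map <- drop_one_marker_eval(map, cleaned, error_prob = error_prob)
  report$markers_dropped_final <- nrow(attr(final_map, "dropped"))

  keep <- cleaned$markers$marker_id %in% final_map$marker_id
  list(map = final_map, genotypes = subset_markers(cleaned, keep), report = report)
}
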