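#' Genotype probabilities on a pseudo-marker grid
#'
#' Runs the F2 genotype HMM (forward-backward) along each linkage group with
#' pseudo-markers inserted every `step_cM`, returning the posterior
#' probability of each genotype class at every evaluation position for every
#' individual. At a typed marker with `error_prob = 0` the posterior puts
#' probability 1 on the observed genotype; positions with no information
#' return the stationary prior (1/4, 1/2, 1/4).
#'
#' @param g A [marker_geno()].
#' @param map A [genetic_map()]; only markers present in `g` are used.
#' @param step_cM Pseudo-marker spacing in cM (default 1); `0` evaluates at
#'   marker positions only.
#' @param error_prob Assumed genotyping error rate in `[0, 0.5)`.
#' @return A `genoprob` object: list with `positions` (tibble `group`,
#'   `pos_cM`, `marker_id`, NA for pseudo-markers), `prob` (array
#'   individuals x positions x 3) and `individuals`.
#' @export
calc_genoprob <- function(g, map, step_cM = 1, error_prob = 1e-4) {
  stopifnot(inherits(g, "marker_geno"), error_prob >= 0, error_prob < 0.5)
  groups <- unique(map$group)
  pos_list <- list(); prob_list <- list()
  n_ind <- length(g$individuals)
  for (grp in groups) {
    mm <- map[map$group == grp, ]
    mm <- mm[mm$marker_id %in% g$markers$marker_id, ]
    if (!nrow(mm)) abort(paste0("empty group after matching markers: ", grp))
    mm <- mm[order(mm$cM), ]
    grid <- if (step_cM > 0) {
      seq(min(mm$cM), max(mm$cM), by = step_cM)
    } else numeric(0)
    pos <- sort(unique(c(round(mm$cM, 9), round(grid, 9))))
    mk <- rep(NA_character_, length(pos))
    mk[match(round(mm$cM, 9), pos)] <- mm$marker_id # later marker wins ties
    obs <- matrix(NA_integer_, length(pos), n_ind)
    typed <- !is.na(mk)
    obs[typed, ] <- obs_matrix(g, mk[typed])
    eng <- f2_hmm_engine(obs, pos, error_prob)
    pr <- aperm(eng$post, c(2, 1, 3)) # individuals x positions x 3
    pos_list[[length(pos_list) + 1]] <- tibble(group = grp, pos_cM = pos,
                                               marker_id = mk)
    prob_list[[length(prob_list) + 1]] <- pr
  }
  positions <- bind_rows(pos_list)
  prob <- array(0, c(n_ind, nrow(positions), 3),
                dimnames = list(g$individuals, NULL, GENO_LEVELS))
  at <- 0
  for (pr in prob_list) {
    prob[, at + seq_len(dim(pr)[2]), ] <- pr
    at <- at + dim(pr)[2]
  }
  structure(list(positions = positions, prob = prob,
                 individuals = g$individuals),
            class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat(sprintf("<genoprob> %d individuals x %d positions (%d groups)\n",
              length(x$individuals), nrow(x$positions),
              length(unique(x$positions$group))))
  invisible(x)
}

# Resolve a phenotype argument to a named numeric vector over individuals.
#' @noRd
resolve_phenotype <- function(phenotype, individuals, column = NULL) {
  if (is.data.frame(phenotype)) {
    stopifnot("individual_id" %in% names(phenotype))
    if (is.null(column)) {
      column <- setdiff(names(phenotype), "individual_id")[1]
    }
    y <- phenotype[[column]][match(individuals, phenotype$individual_id)]
  } else {
    y <- if (!is.null(names(phenotype))) {
      unname(phenotype[individuals])
    } else {
      stopifnot(length(phenotype) == length(individuals))
      phenotype
    }
  }
  setNames(as.numeric(y), individuals)
}

# Haley-Knott regression LODs for one phenotype vector (no missing values)
# against precomputed design pieces; returns the LOD vector.
#' @noRd
hk_lods <- function(prob, y, lod_cap) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  n_pos <- dim(prob)[2]
  lod <- numeric(n_pos)
  for (p in seq_len(n_pos)) {
    X <- cbind(1, prob[, p, 3] - prob[, p, 1], prob[, p, 2])
    fit <- stats::lm.fit(X, y)
    rss1 <- sum(fit$residuals^2)
    lod[p] <- if (rss1 <= rss0 * 1e-12) lod_cap else {
      min((n / 2) * log10(rss0 / rss1), lod_cap)
    }
  }
  lod
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At each evaluation position, regresses the phenotype on the expected
#' additive dosage `P(BB) - P(AA)` and the expected dominance indicator
#' `P(AB)` from the genotype probabilities. The LOD score is
#' `(n/2) log10(RSS0 / RSS1)` against the intercept-only model. Individuals
#' with a missing phenotype are dropped listwise.
#'
#' @param probs A `genoprob` object from [calc_genoprob()].
#' @param phenotype Numeric vector (named by individual or in `probs` order)
#'   or a phenotype tibble with `individual_id` plus a value column.
#' @param column Phenotype column name when `phenotype` is a data frame.
#' @param lod_cap Cap for degenerate perfect fits (default 999).
#' @return A `scan_result`: tibble `group`, `pos_cM`, `marker_id`, `lod`,
#'   with attributes `n` (individuals used) and `phenotype` (label).
#' @export
hk_scan <- function(probs, phenotype, column = NULL, lod_cap = 999) {
  stopifnot(inherits(probs, "genoprob"))
  y <- resolve_phenotype(phenotype, probs$individuals, column)
  keep <- !is.na(y)
  n <- sum(keep)
  if (n < 10) abort("need at least 10 individuals with phenotypes")
  y <- y[keep]
  prob <- probs$prob[keep, , , drop = FALSE]
  out <- probs$positions
  if (var(y) == 0) {
    warn("zero phenotypic variance: all LOD scores set to 0")
    out$lod <- 0
  } else {
    out$lod <- hk_lods(prob, y, lod_cap)
  }
  label <- if (is.data.frame(phenotype)) {
    if (is.null(column)) setdiff(names(phenotype), "individual_id")[1] else column
  } else "phenotype"
  structure(out, class = c("scan_result", class(out)),
            n = n, phenotype = label)
}

#' Permutation threshold for a genome scan
#'
#' Permutes the phenotype vector against the intact genotype structure
#' `n_perm` times, records the genome-wide maximum LOD of each permutation,
#' and returns the empirical `1 - alpha` quantile (type-7 linear
#' interpolation, the documented fixed choice).
#'
#' @inheritParams hk_scan
#' @param n_perm Number of permutation replicates (default 1000; fewer than
#'   100 triggers a warning).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return The LOD threshold, with attribute `perm_max` (the permutation
#'   null distribution of maximum LOD).
#' @export
perm_threshold <- function(probs, phenotype, n_perm = 1000, alpha = 0.05,
                           seed = 1L, column = NULL, lod_cap = 999) {
  stopifnot(inherits(probs, "genoprob"))
  if (n_perm < 100) warn("n_perm < 100 gives an unstable quantile estimate")
  y <- resolve_phenotype(phenotype, probs$individuals, column)
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  if (n < 10) abort("need at least 10 individuals with phenotypes")
  prob <- probs$prob[keep, , , drop = FALSE]
  set.seed(stage_seed(seed, "perm"))
  if (var(y) == 0) {
    thr <- structure(0, perm_max = rep(0, n_perm))
    return(thr)
  }
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  yty <- colSums(Y^2)
  rss0 <- yty - n * colMeans(Y)^2
  n_pos <- dim(prob)[2]
  max_lod <- rep(0, n_perm)
  for (p in seq_len(n_pos)) {
    X <- cbind(1, prob[, p, 3] - prob[, p, 1], prob[, p, 2])
    Q <- qr.Q(qr(X))
    rss1 <- yty - colSums(crossprod(Q, Y)^2)
    rss1 <- pmax(rss1, rss0 * 1e-12)
    lod <- pmin((n / 2) * log10(rss0 / rss1), lod_cap)
    max_lod <- pmax(max_lod, lod)
  }
  structure(unname(quantile(max_lod, 1 - alpha, type = 7)),
            perm_max = max_lod)
}

#' Proportion of variance explained from a LOD score
#'
#' `pve = 1 - 10^(-2 lod / n)`: the phenotypic variance fraction explained by
#' the fitted QTL model at a position with the given LOD in a sample of `n`.
#'
#' @param lod LOD score(s).
#' @param n Number of individuals (> 0).
#' @return Fraction(s) in `[0, 1)`.
#' @examples
#' pve(10, 100) # ~0.369
#' @export
pve <- function(lod, n) {
  if (any(n <= 0)) abort("`n` must be positive")
  1 - 10^(-2 * lod / n)
}

#' 2-LOD support interval around a group's peak
#'
#' Finds the group peak (ties broken toward the left-most position and
#' flagged), takes the widest contiguous span around it where
#' `LOD >= peak - drop`, and expands it to the flanking evaluated positions
#' just beyond the drop boundary.
#'
#' @param scan A `scan_result` from [hk_scan()].
#' @param group Linkage group to summarize.
#' @param drop LOD drop defining the support interval (default 2).
#' @return Tibble with `group`, `peak_marker`, `peak_cM`, `peak_lod`,
#'   `low_cM`, `high_cM`, `pve`, `peak_tie`.
#' @export
lod_interval <- function(scan, group, drop = 2) {
  ss <- scan[scan$group == group, ]
  if (!nrow(ss)) abort("group not in scan")
  if (all(ss$lod <= 0)) abort("all-zero LOD in group: interval undefined")
  peak_lod <- max(ss$lod)
  peaks <- which(ss$lod == peak_lod)
  peak <- peaks[1]
  tie <- length(peaks) > 1
  inside <- ss$lod >= peak_lod - drop
  runs <- true_runs(inside) # 0-based half-open index runs
  hit <- runs[runs$start < peak & peak <= runs$end, ]
  lo_i <- max(hit$start[1], 0) # index of first inside position (0-based)
  hi_i <- hit$end[1]           # one past last inside position
  lo <- max(lo_i, 1)           # expand one evaluated position beyond
  hi <- min(hi_i + 1, nrow(ss))
  peak_marker <- ss$marker_id[peak]
  # report nearest typed marker when the peak is a pseudo-marker
  if (is.na(peak_marker) && any(!is.na(ss$marker_id))) {
    typed <- which(!is.na(ss$marker_id))
    peak_marker <- ss$marker_id[typed[which.min(abs(ss$pos_cM[typed] - ss$pos_cM[peak]))]]
  }
  tibble(
    group = group, peak_marker = peak_marker, peak_cM = ss$pos_cM[peak],
    peak_lod = peak_lod, low_cM = ss$pos_cM[lo], high_cM = ss$pos_cM[hi],
    pve = pve(peak_lod, attr(scan, "n")), peak_tie = tie
  )
}

#' Summarize significant QTL across all groups
#'
#' @param scan A `scan_result`.
#' @param threshold Genome-wide LOD threshold (e.g. from [perm_threshold()]).
#' @param drop LOD drop for support intervals.
#' @return Tibble of [lod_interval()] rows for every group whose peak exceeds
#'   the threshold (possibly empty).
#' @export
summarize_qtl <- function(scan, threshold, drop = 2) {
  peaks <- scan %>%
    group_by(.data$group) %>%
    summarise(peak = max(.data$lod)) %>%
    filter(.data$peak >= threshold)
  if (!nrow(peaks)) {
    return(tibble(group = integer(), peak_marker = character(),
                  peak_cM = numeric(), peak_lod = numeric(), low_cM = numeric(),
                  high_cM = numeric(), pve = numeric(), peak_tie = logical()))
  }
  bind_rows(purrr::map(peaks$group, ~ lod_interval(scan, .x, drop = drop)))
}

#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble(
    n = attr(x, "n"), phenotype = attr(x, "phenotype"),
    n_positions = nrow(x), max_lod = max(x$lod),
    peak_group = x$group[which.max(x$lod)],
    peak_cM = x$pos_cM[which.max(x$lod)]
  )
}

#' Plot a genome scan
#'
#' LOD profile faceted by linkage group, with an optional genome-wide
#' threshold line.
#'
#' @param object A `scan_result`.
#' @param threshold Optional LOD threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$pos_cM, .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Map position (cM)", y = "LOD",
                  title = attr(object, "phenotype"))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "red",
                                 linetype = 2)
  }
  p
}
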