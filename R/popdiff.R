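# Genotype-likelihood allele-frequency differentiation (pFST-style).
#
# The statistic is a likelihood-ratio test on per-group alt-allele
# frequencies. Per sample, the site likelihood marginalizes the phred-scaled
# genotype likelihoods over Hardy-Weinberg genotype priors at frequency p:
#   L_i(p) = sum_g 10^(-PL_ig/10) * HWE(g | p).
# p is fitted by 1-D maximization separately per group (alternative) and
# pooled (null); the statistic is 2 (lnL_case + lnL_bg - lnL_pooled), with a
# chi-square df = 1 p-value. This is the package's documented interpretation
# of a genotype-likelihood "modified likelihood ratio test"; the original
# toolkit's exact formula is unpublished.

# log-likelihood of allele frequency p for a set of samples given linear-scale
# genotype likelihoods (rows = samples, cols = 0/1/2 alt copies)
#' @noRd
freq_loglik <- function(p, gl) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  sum(log(pmax(as.vector(gl %*% hwe), 1e-300)))
}

#' @noRd
fit_freq <- function(gl, tol = 1e-10) {
  opt <- optimize(function(p) freq_loglik(p, gl), c(0, 1),
                  maximum = TRUE, tol = tol)
  cand_p <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, freq_loglik(0, gl), freq_loglik(1, gl))
  best <- which.max(cand_ll)
  list(p = cand_p[best], loglik = cand_ll[best])
}

#' @noRd
pl_to_linear <- function(pl) 10^(-pl / 10)

#' Per-site allele-frequency differentiation test
#'
#' Likelihood-ratio test of equal alt-allele frequency in case vs background
#' samples, marginalizing phred-scaled genotype likelihoods over
#' Hardy-Weinberg genotype priors (see the package vignette for the model).
#'
#' @param pl_case,pl_background Numeric matrices (samples x 3) of phred-scaled
#'   genotype likelihoods for the two groups; each row's minimum should be 0.
#' @return Tibble with `lrt_stat` (>= 0), `p_value`, `p_case`, `p_background`,
#'   `p_pooled`.
#' @export
pfst_site <- function(pl_case, pl_background) {
  pl_case <- as.matrix(pl_case); pl_background <- as.matrix(pl_background)
  if (nrow(pl_case) < 2 || nrow(pl_background) < 2) {
    abort("need at least 2 non-missing samples per group")
  }
  gl_case <- pl_to_linear(pl_case)
  gl_bg <- pl_to_linear(pl_background)
  fc <- fit_freq(gl_case)
  fb <- fit_freq(gl_bg)
  fp <- fit_freq(rbind(gl_case, gl_bg))
  stat <- max(2 * (fc$loglik + fb$loglik - fp$loglik), 0)
  tibble(
    lrt_stat = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    p_case = fc$p, p_background = fb$p, p_pooled = fp$p
  )
}

#' Genome-wide pFST-style scan over a site panel
#'
#' Applies [pfst_site()] at every site of a [site_panel()], using each
#' sample's phred-scaled genotype likelihoods; samples labelled `excluded`
#' and samples with missing likelihoods at a site are dropped at that site.
#' Sites with fewer than 2 usable samples in either group get NA results.
#'
#' @param panel A [site_panel()].
#' @param alpha Genome-wide significance level for the Bonferroni threshold.
#' @return A `pfst_result`: per-site tibble with scaffold, position, test
#'   results and a `significant` flag against `alpha / n_sites`.
#' @export
pfst_scan <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "site_panel"))
  case <- which(panel$groups == "case")
  bg <- which(panel$groups == "background")
  n_sites <- nrow(panel$sites)
  res <- purrr::map(seq_len(n_sites), function(s) {
    plc <- panel$pl[s, case, , drop = TRUE]
    plb <- panel$pl[s, bg, , drop = TRUE]
    plc <- matrix(plc, ncol = 3); plb <- matrix(plb, ncol = 3)
    okc <- stats::complete.cases(plc); okb <- stats::complete.cases(plb)
    if (sum(okc) < 2 || sum(okb) < 2) {
      return(tibble(lrt_stat = NA_real_, p_value = NA_real_,
                    p_case = NA_real_, p_background = NA_real_,
                    p_pooled = NA_real_))
    }
    pfst_site(plc[okc, , drop = FALSE], plb[okb, , drop = FALSE])
  })
  thr <- genomewide_threshold(n_sites, alpha)
  out <- dplyr::bind_cols(panel$sites, bind_rows(res)) %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < thr)
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  class(out) <- c("pfst_result", class(out))
  out
}

#' Bonferroni genome-wide p-value threshold
#'
#' @param n_sites Number of SNPs tested (> 0).
#' @param alpha Genome-wide significance level (default 0.05).
#' @return `alpha / n_sites`.
#' @export
genomewide_threshold <- function(n_sites, alpha = 0.05) {
  if (n_sites <= 0) abort("`n_sites` must be positive")
  alpha / n_sites
}

#' @method glance pfst_result
#' @export
glance.pfst_result <- function(x, ...) {
  tibble(
    n_sites = nrow(x), threshold = attr(x, "threshold"),
    n_significant = sum(x$significant, na.rm = TRUE),
    max_stat = max(x$lrt_stat, na.rm = TRUE)
  )
}

#' Plot a genome-wide differentiation scan
#'
#' Manhattan-style plot of -log10 p by position, faceted by scaffold, with
#' the Bonferroni threshold line.
#'
#' @param object A `pfst_result` from [pfst_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pfst_result
#' @export
autoplot.pfst_result <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$p_value)),
                  ggplot2::aes(.data$pos, -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "threshold")),
                        colour = "red", linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$scaffold), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = expression(-log[10](p)))
}

#' Candidate-SNP fixation filter
#'
#' A site is a candidate iff (a) every non-missing case sample is
#' homozygous-alt and the case call rate is at least `min_case_callrate`, and
#' (b) no background sample is homozygous-alt (at any call rate).
#'
#' @param panel A [site_panel()].
#' @param min_case_callrate Minimum fraction of case samples with a call.
#' @return Tibble of candidate sites with per-candidate case/background call
#'   rates; empty when no site qualifies.
#' @export
candidate_snp_filter <- function(panel, min_case_callrate = 0.8) {
  stopifnot(inherits(panel, "site_panel"))
  case <- panel$groups == "case"
  bg <- panel$groups == "background"
  if (!any(case) || !any(bg)) abort("both case and background samples required")
  gt_case <- panel$gt[, case, drop = FALSE]
  gt_bg <- panel$gt[, bg, drop = FALSE]
  case_called <- rowMeans(!is.na(gt_case))
  case_fixed <- apply(gt_case, 1, function(x) {
    any(!is.na(x)) && all(x[!is.na(x)] == 2L)
  })
  bg_homalt <- apply(gt_bg, 1, function(x) any(!is.na(x) & x == 2L))
  cand <- case_fixed & case_called >= min_case_callrate & !bg_homalt
  dplyr::bind_cols(
    panel$sites,
    tibble(case_call_rate = case_called,
           background_call_rate = rowMeans(!is.na(gt_bg)))
  )[cand, ]
}

#' Delineate haplotype groups from shared homozygous-alt genotypes
#'
#' Clusters samples by the Jaccard similarity of their homozygous-alt site
#' sets within a region (average-linkage hierarchical clustering cut at
#' `1 - min_similarity`). Each cluster's defining SNP set is the sites
#' homozygous-alt in every member; clusters with fewer than
#' `min_defining_snps` defining sites are discarded. Deterministic given
#' input order and parameters.
#'
#' @param panel A [site_panel()] restricted to the region of interest.
#' @param samples Samples to cluster (default: all case samples).
#' @param min_defining_snps Minimum defining-set size (default 5).
#' @param min_similarity Jaccard similarity at which the dendrogram is cut
#'   (default 0.5).
#' @return Tibble with one row per group: `group`, `members` (list column),
#'   `n_members`, `defining_snps` (list column of site indices), `n_defining`,
#'   `scaffold`, `start`, `end` (span of the defining set, 1-based inclusive).
#' @export
delineate_groups <- function(panel, samples = NULL, min_defining_snps = 5,
                             min_similarity = 0.5) {
  stopifnot(inherits(panel, "site_panel"))
  if (is.null(samples)) samples <- panel$samples[panel$groups == "case"]
  idx <- match(samples, panel$samples)
  stopifnot(!anyNA(idx))
  homalt <- !is.na(panel$gt[, idx, drop = FALSE]) & panel$gt[, idx, drop = FALSE] == 2L
  keep <- colSums(homalt) > 0
  if (!any(keep)) return(tibble())
  samples <- samples[keep]
  homalt <- homalt[, keep, drop = FALSE]
  n <- length(samples)
  cl <- if (n == 1) rep(1L, 1) else {
    inter <- crossprod(homalt)
    sizes <- diag(inter)
    uni <- outer(sizes, sizes, "+") - inter
    jac <- ifelse(uni > 0, inter / uni, 0)
    hc <- stats::hclust(stats::as.dist(1 - jac), method = "average")
    stats::cutree(hc, h = 1 - min_similarity)
  }
  out <- purrr::map(sort(unique(cl)), function(k) {
    members <- samples[cl == k]
    n_members <- length(members)
    def <- which(rowSums(homalt[, cl == k, drop = FALSE]) == sum(cl == k))
    if (length(def) < min_defining_snps) return(NULL)
    tibble(
      members = list(members), n_members = n_members,
      defining_snps = list(def), n_defining = length(def),
      scaffold = panel$sites$scaffold[def[1]],
      start = min(panel$sites$pos[def]), end = max(panel$sites$pos[def])
    )
  })
  out <- bind_rows(purrr::compact(out))
  if (nrow(out)) out <- mutate(out, group = row_number(), .before = 1)
  out
}
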