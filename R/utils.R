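#' @noRd
GENO_LEVELS <- c("AA", "AB", "BB")

# Expand one user seed into named per-stage streams so each simulation stage is
# reproducible on its own. Streams stay below 2^31 - 1.
#' @noRd
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offsets <- c(
    cross = 11L, phenotype = 23L, panel = 37L, alignment = 53L,
    coverage = 71L, ase = 89L, perm = 101L, noise = 131L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown seed stage: ", stage))
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% 2147483629)
}

#' @noRd
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single probability in [0, 1]"))
  }
  invisible(x)
}

#' @noRd
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort(paste0("`", name, "` must be an integer >= ", min))
  }
  invisible(as.integer(x))
}

#' Haldane map function and its inverse
#'
#' `haldane_d()` converts a recombination fraction to map distance in
#' centimorgans, `d = -50 * log(1 - 2 r)`; `haldane_r()` converts a distance in
#' cM back to a recombination fraction, `r = (1 - exp(-d / 50)) / 2`. Both
#' assume no crossover interference.
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @param d Map distance in cM (non-negative).
#' @param cap_cM Distances for `r >= 0.5` are infinite; they are capped at this
#'   value (default `Inf`, i.e. uncapped).
#' @return A numeric vector of distances (cM) or recombination fractions.
#' @examples
#' haldane_d(0.15) # ~17.83 cM
#' haldane_r(haldane_d(0.2))
#' @export
haldane_d <- function(r, cap_cM = Inf) {
  stopifnot(all(r >= 0 & r <= 0.5, na.rm = TRUE))
  d <- ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * r))
  pmin(d, cap_cM)
}

#' @rdname haldane_d
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  0.5 * (1 - exp(-d / 50))
}

# Maximal runs of TRUE in a logical vector, as a tibble of 0-based half-open
# [start, end) intervals.
#' @noRd
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & !is.na(r$values)
  tibble(start = starts[keep], end = ends[keep])
}

# Connected components via union-find; edges as a two-column integer matrix
# over 1..n. Returns integer component labels (renumbered by first appearance).
#' @noRd
connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Rank-based (Mann-Whitney) AUC for a score that should be higher in the
# positive class. Used to evaluate error-LOD ranking of planted errors.
#' @noRd
rank_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
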