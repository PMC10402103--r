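#' Simulate a reference-anchored multi-species alignment with planted CNEs
#'
#' Generates a random reference sequence and per-species aligned copies.
#' Outside planted intervals each species matches the reference independently
#' at `background_identity` per base; within a planted interval the first
#' `n_species` species of the interval's clade match at the interval's
#' `identity` instead. Species-side deletion gaps are inserted at `gap_rate`
#' (gaps count as mismatches downstream), so reference coordinates are
#' preserved exactly.
#'
#' @param n_avian,n_tetrapod Number of species per clade.
#' @param planted_cnes Tibble with columns `start`, `end` (0-based half-open),
#'   `identity`, `n_species`, and optionally `clade` (default `"avian"`).
#'   Intervals must not overlap.
#' @param background_identity Per-base match probability outside planted
#'   intervals.
#' @param exons Optional tibble of exon intervals (`start`, `end`) returned
#'   alongside (they do not alter the sequence simulation).
#' @param ref_length Reference length in bp.
#' @param gap_rate Per-base species deletion probability (default 0.01).
#' @param seed Integer seed.
#' @return List with `block` (an [alignment_block()]) and `exons` (tibble).
#' @export
sim_alignment <- function(n_avian, n_tetrapod, planted_cnes = NULL,
                          background_identity = 0.4, exons = NULL,
                          ref_length = 10000, gap_rate = 0.01, seed = 1L) {
  check_prob(background_identity, "background_identity")
  set.seed(stage_seed(seed, "alignment"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ref_length, replace = TRUE)

  planted <- if (is.null(planted_cnes)) tibble() else as_tibble(planted_cnes)
  if (nrow(planted)) {
    if (!"clade" %in% names(planted)) planted$clade <- "avian"
    for (cl in unique(planted$clade)) {
      pc <- planted[planted$clade == cl, ]
      ord <- order(pc$start)
      if (nrow(pc) > 1 &&
          any(pc$end[ord][-nrow(pc)] > pc$start[ord][-1])) {
        abort("planted intervals must not overlap within a clade")
      }
    }
    if (any(planted$end > ref_length)) abort("planted interval outside reference")
  }

  species <- tibble(
    species = c(sprintf("avian_%02d", seq_len(n_avian)),
                sprintf("tetrapod_%02d", seq_len(n_tetrapod))),
    clade = c(rep("avian", n_avian), rep("tetrapod", n_tetrapod))
  )
  seqs <- character(nrow(species))
  for (i in seq_len(nrow(species))) {
    ident <- rep(background_identity, ref_length)
    if (nrow(planted)) {
      clade_rank <- cumsum(species$clade == species$clade[i])[i]
      for (k in seq_len(nrow(planted))) {
        if (planted$clade[k] == species$clade[i] &&
            clade_rank <= planted$n_species[k]) {
          ident[(planted$start[k] + 1):planted$end[k]] <- planted$identity[k]
        }
      }
    }
    m <- runif(ref_length) < ident
    s <- ref
    mism <- which(!m)
    if (length(mism)) {
      s[mism] <- vapply(ref[mism], function(b) sample(setdiff(bases, b), 1),
                        character(1))
    }
    if (gap_rate > 0) s[runif(ref_length) < gap_rate] <- "-"
    seqs[i] <- paste(s, collapse = "")
  }
  species$seq <- seqs
  list(
    block = alignment_block(paste(ref, collapse = ""), species),
    exons = if (is.null(exons)) tibble(start = integer(), end = integer())
            else as_tibble(exons)
  )
}
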