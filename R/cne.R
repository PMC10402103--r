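# Conserved-noncoding-element detection from reference-anchored alignments.
# All intervals are 0-based half-open in reference coordinates.

# Per-reference-base match indicator for one species (TRUE = same base as the
# reference, gaps and N mismatch). Alignment blocks here carry deletion-style
# gaps only, so columns map 1:1 to reference bases.
#' @noRd
species_match <- function(block, species) {
  row <- block$species[block$species$species == species, ]
  if (!nrow(row)) abort(paste0("species not in block: ", species))
  ref <- strsplit(toupper(block$ref_seq), "")[[1]]
  sp <- strsplit(toupper(row$seq), "")[[1]]
  sp == ref & sp %in% c("A", "C", "G", "T")
}

# Bases covered by at least one qualifying window: pass[s] says the window
# starting at 0-based s qualifies; each pass covers [s, s + window).
#' @noRd
dilate_windows <- function(pass, window, len) {
  qual <- logical(len)
  starts <- which(pass) - 1L
  for (s in starts) qual[(s + 1):min(s + window, len)] <- TRUE
  qual
}

# Maximal-scoring subarray (Kadane); returns 1-based first/last index of the
# first maximal segment, or NULL if all scores are negative.
#' @noRd
max_scoring_segment <- function(x) {
  best <- -Inf; cur <- 0; cur_start <- 1L; bs <- 1L; be <- 0L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; cur_start <- i } else cur <- cur + x[i]
    if (cur > best) { best <- cur; bs <- cur_start; be <- i }
  }
  if (best < 0) NULL else c(bs, be)
}

#' Conserved regions for one species
#'
#' Slides a `window`-bp reference-anchored window (step 1) along the
#' alignment; window identity is matches / window length with gaps counted as
#' mismatches. A reference base qualifies if any covering window has identity
#' strictly above `min_identity`; maximal qualifying runs of at least
#' `min_length` bp are returned.
#'
#' Because every base touched by a passing window qualifies, raw runs bleed
#' into the flanking background by up to several tens of bp. With
#' `refine_boundaries = TRUE` (default) each run is trimmed to its
#' maximal-scoring subsegment under per-base scores
#' `match - min_identity`, which places boundaries within a few bp of the
#' true identity change-point without shrinking the conserved core.
#'
#' @param block An [alignment_block()].
#' @param species Species name present in the block.
#' @param window Window length in reference bp (default 100).
#' @param min_identity Identity threshold, exclusive (default 0.70).
#' @param min_length Minimum run length in bp (default 100).
#' @param refine_boundaries Trim each run to its maximal-scoring subsegment.
#' @return Tibble of 0-based half-open `start`, `end` intervals (block-local
#'   coordinates).
#' @export
species_conserved_regions <- function(block, species, window = 100,
                                      min_identity = 0.70, min_length = 100,
                                      refine_boundaries = TRUE) {
  m <- species_match(block, species)
  len <- length(m)
  if (len < window) return(tibble(start = integer(), end = integer()))
  cs <- c(0, cumsum(m))
  win_sum <- cs[(window + 1):(len + 1)] - cs[1:(len - window + 1)]
  pass <- (win_sum / window) > min_identity
  qual <- dilate_windows(pass, window, len)
  runs <- true_runs(qual)
  if (refine_boundaries && nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      idx <- (runs$start[i] + 1):runs$end[i]
      seg <- max_scoring_segment(m[idx] - min_identity)
      if (!is.null(seg)) {
        runs$end[i] <- runs$start[i] + seg[2]
        runs$start[i] <- runs$start[i] + seg[1] - 1L
      }
    }
  }
  runs[runs$end - runs$start >= min_length, ]
}

#' Detect conserved noncoding elements
#'
#' For each clade, counts at every reference base how many species' conserved
#' regions (from [species_conserved_regions()]) cover it. Bases overlapping
#' any exon are removed first; CNEs are the maximal remaining runs of at
#' least `min_length` bp where the species count meets the clade threshold
#' (10+ avian species or 3+ non-avian tetrapods by default). Avian and
#' tetrapod CNEs are computed independently and may overlap each other.
#'
#' @param block An [alignment_block()].
#' @param exons Data frame of 0-based half-open exon intervals (`start`,
#'   `end`) in block-local coordinates; may be empty.
#' @param avian_min,tetrapod_min Minimum supporting species per clade.
#' @param window,min_identity,min_length Passed to
#'   [species_conserved_regions()].
#' @return Tibble with `clade`, `start`, `end`, `supporting_species` (minimum
#'   per-base count within the element) and `mean_identity` (mean per-base
#'   match fraction among clade species over the element).
#' @export
detect_cnes <- function(block, exons = NULL, avian_min = 10, tetrapod_min = 3,
                        window = 100, min_identity = 0.70, min_length = 100,
                        refine_boundaries = TRUE) {
  len <- nchar(block$ref_seq)
  exon_mask <- logical(len)
  if (!is.null(exons) && nrow(as_tibble(exons))) {
    exons <- as_tibble(exons)
    if (any(exons$end < exons$start) || any(exons$start < 0)) {
      abort("malformed exon intervals")
    }
    for (i in seq_len(nrow(exons))) {
      s <- max(exons$start[i], 0); e <- min(exons$end[i], len)
      if (e > s) exon_mask[(s + 1):e] <- TRUE
    }
  }
  thresholds <- c(avian = avian_min, tetrapod = tetrapod_min)
  out <- purrr::map(names(thresholds), function(clade) {
    sp <- block$species$species[block$species$clade == clade]
    if (!length(sp)) return(NULL)
    cover <- integer(len)
    match_sum <- numeric(len)
    for (s in sp) {
      regions <- species_conserved_regions(block, s, window = window,
                                           min_identity = min_identity,
                                           min_length = 1,
                                           refine_boundaries = refine_boundaries)
      for (i in seq_len(nrow(regions))) {
        idx <- (regions$start[i] + 1):regions$end[i]
        cover[idx] <- cover[idx] + 1L
      }
      match_sum <- match_sum + species_match(block, s)
    }
    ok <- cover >= thresholds[[clade]] & !exon_mask
    runs <- true_runs(ok)
    runs <- runs[runs$end - runs$start >= min_length, ]
    if (!nrow(runs)) return(NULL)
    runs %>%
      mutate(
        clade = clade,
        supporting_species = purrr::map2_int(.data$start, .data$end,
          ~ min(cover[(.x + 1):.y])),
        mean_identity = purrr::map2_dbl(.data$start, .data$end,
          ~ mean(match_sum[(.x + 1):.y]) / length(sp))
      ) %>%
      select("clade", "start", "end", "supporting_species", "mean_identity")
  })
  bind_rows(purrr::compact(out))
}

#' Annotate SNPs with the CNEs they fall in
#'
#' Interval-overlap join between SNP positions and CNE intervals (0-based
#' half-open: a SNP at a CNE's `start` is inside, at its `end` outside).
#'
#' @param snps Data frame with a 0-based `pos` column (other columns kept).
#' @param cnes Tibble from [detect_cnes()].
#' @return The subset of `snps` falling in at least one CNE, one row per
#'   (SNP, CNE) hit, with `clade`, `cne_start`, `cne_end` attached.
#' @export
snps_in_cnes <- function(snps, cnes) {
  snps <- as_tibble(snps)
  if (!nrow(snps) || !nrow(cnes)) {
    return(dplyr::bind_cols(snps[0, ], tibble(clade = character(),
                                              cne_start = integer(),
                                              cne_end = integer())))
  }
  hits <- purrr::map(seq_len(nrow(snps)), function(i) {
    p <- snps$pos[i]
    hit <- cnes[cnes$start <= p & p < cnes$end, ]
    if (!nrow(hit)) return(NULL)
    dplyr::bind_cols(
      snps[rep(i, nrow(hit)), ],
      tibble(clade = hit$clade, cne_start = hit$start, cne_end = hit$end)
    )
  })
  bind_rows(purrr::compact(hits))
}
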