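# Read-depth tandem-duplication detection and copy-specific expression.
# Coverage tracks are tibbles of non-overlapping windows (0-based half-open
# start/end) with a mean per-base depth column.

#' Normalize a coverage track to diploid copy number
#'
#' Scales per-window depth so the genome background sits at copy number 2:
#' `normalized = 2 * depth / stat(depth outside the exclusion mask)`. The
#' reference statistic defaults to the median, which is robust to the
#' duplication itself.
#'
#' @param track Tibble with `scaffold`, `start`, `end`, `depth`.
#' @param exclude Optional logical vector (or tibble of intervals with
#'   `start`/`end`) marking windows to leave out of the reference statistic.
#' @param reference_stat Function summarizing background depth (default
#'   [stats::median]).
#' @return The track with a `copy_number` column appended.
#' @export
normalize_coverage <- function(track, exclude = NULL,
                               reference_stat = stats::median) {
  track <- as_tibble(track)
  stopifnot(all(c("scaffold", "start", "end", "depth") %in% names(track)))
  if (nrow(track) < 10) abort("need at least 10 windows to normalize")
  mask <- rep(FALSE, nrow(track))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) {
      mask <- exclude
    } else {
      ex <- as_tibble(exclude)
      for (i in seq_len(nrow(ex))) {
        mask <- mask | (track$start < ex$end[i] & track$end > ex$start[i])
      }
    }
  }
  ref <- reference_stat(track$depth[!mask])
  if (!is.finite(ref) || ref <= 0) abort("reference depth statistic is zero")
  mutate(track, copy_number = 2 * .data$depth / ref)
}

#' Call tandem duplications from normalized coverage
#'
#' Candidate duplications are maximal runs of at least `min_windows`
#' consecutive windows with `copy_number >= gain_threshold`. Genotype is
#' binned from the segment mean copy number: `< 3.5` heterozygous, `>= 3.5`
#' homozygous (half-open bins; the midpoints between the expected 2/3/4
#' copy-number bands). Intervals are reported in window coordinates pending
#' breakpoint refinement.
#'
#' @param track Normalized track from [normalize_coverage()].
#' @param gain_threshold Copy-number threshold for a duplicated window
#'   (default 2.5).
#' @param min_windows Minimum run length in windows (default 3).
#' @return Tibble of calls: `scaffold`, `start`, `end`, `n_windows`,
#'   `mean_copy_number`, `genotype`, `refined` (FALSE), `bp_uncertainty`
#'   (window size). Empty when nothing qualifies.
#' @export
call_duplication <- function(track, gain_threshold = 2.5, min_windows = 3) {
  track <- as_tibble(track)
  stopifnot("copy_number" %in% names(track))
  out <- track %>%
    group_by(.data$scaffold) %>%
    dplyr::group_modify(function(tr, key) {
      tr <- arrange(tr, .data$start)
      runs <- true_runs(tr$copy_number >= gain_threshold)
      runs <- runs[runs$end - runs$start >= min_windows, ]
      if (!nrow(runs)) {
        return(tibble(start = integer(), end = integer(), n_windows = integer(),
                      mean_copy_number = numeric(), genotype = character()))
      }
      purrr::map2(runs$start, runs$end, function(s, e) {
        idx <- (s + 1):e
        mcn <- mean(tr$copy_number[idx])
        tibble(
          start = tr$start[s + 1], end = tr$end[e],
          n_windows = length(idx), mean_copy_number = mcn,
          genotype = if (mcn < 3.5) "het" else "hom"
        )
      }) %>% bind_rows()
    }) %>%
    ungroup()
  win <- if (nrow(track) > 1) max(track$end - track$start) else NA_integer_
  mutate(out, refined = FALSE, bp_uncertainty = win)
}

#' Refine duplication breakpoints from soft-clip evidence
#'
#' A tandem duplication of `[s, e)` creates a novel junction whose crossing
#' reads soft-clip at the two edges, with the clipped sequence remapping to
#' the partner edge. If clip clusters exist near both call edges (within
#' `search_bp`) whose modal positions remap to each other's side, the call's
#' breakpoints are replaced by the modal clip positions with +/- 1 bp
#' uncertainty; otherwise the call is kept with window-level uncertainty and
#' flagged depth-only. Ties between equally supported modes leave the call
#' unrefined with a warning.
#'
#' @param call One-row duplication call from [call_duplication()].
#' @param evidence List with elements `clips` (tibble `scaffold`, `pos`,
#'   `side` in `c("left", "right")`, `remap_pos`) and optionally `discordant`
#'   (tibble `scaffold`, `pos`, `count`, `mean_insert`).
#' @param search_bp Search radius around each call edge (default the call's
#'   `bp_uncertainty`, i.e. one window).
#' @return The call with refined `start`/`end`, `refined`, `bp_uncertainty`,
#'   `n_clip_left`, `n_clip_right`, `n_discordant` columns.
#' @export
refine_breakpoints <- function(call, evidence, search_bp = NULL) {
  stopifnot(nrow(call) == 1)
  if (is.null(search_bp)) search_bp <- call$bp_uncertainty
  clips <- as_tibble(evidence$clips %||% tibble())
  n_disc <- 0L
  if (!is.null(evidence$discordant) && nrow(evidence$discordant)) {
    disc <- as_tibble(evidence$discordant)
    wrong <- disc$scaffold != call$scaffold
    n_disc <- sum(disc$count[!wrong &
                               disc$pos >= call$start - search_bp &
                               disc$pos <= call$end + search_bp])
  }
  depth_only <- function(msg = NULL) {
    if (!is.null(msg)) warn(msg)
    mutate(call, refined = FALSE, n_clip_left = 0L, n_clip_right = 0L,
           n_discordant = n_disc)
  }
  if (!nrow(clips)) return(depth_only())
  if (any(clips$scaffold != call$scaffold)) {
    warn("soft-clip evidence on a different scaffold ignored")
    clips <- clips[clips$scaffold == call$scaffold, ]
    if (!nrow(clips)) return(depth_only())
  }
  near_start <- clips[abs(clips$pos - call$start) <= search_bp, ]
  near_end <- clips[abs(clips$pos - call$end) <= search_bp, ]
  if (!nrow(near_start) || !nrow(near_end)) return(depth_only())
  modal <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NULL) # tie
    as.integer(names(tab)[1])
  }
  ms <- modal(near_start$pos); me <- modal(near_end$pos)
  if (is.null(ms) || is.null(me)) {
    return(depth_only("tied soft-clip modes; breakpoints left unrefined"))
  }
  # tandem orientation: clips at the start remap near the end and vice versa
  remap_ok <- function(cl, partner) {
    any(abs(cl$remap_pos - partner) <= search_bp)
  }
  if (!remap_ok(near_start, me) || !remap_ok(near_end, ms)) {
    return(depth_only())
  }
  mutate(call,
         start = ms, end = me, refined = TRUE, bp_uncertainty = 1L,
         n_clip_left = sum(near_start$pos == ms),
         n_clip_right = sum(near_end$pos == me),
         n_discordant = n_disc)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen samples for a duplication by regional copy number
#'
#' Bins each sample's mean normalized copy number over the region:
#' `< 2.5` absent, `[2.5, 3.5)` heterozygous, `>= 3.5` homozygous.
#'
#' @param tracks Named list of normalized coverage tracks (one per sample),
#'   or a single combined tibble with a `sample` column.
#' @param region List or tibble row with `scaffold`, `start`, `end`.
#' @return Tibble `sample`, `mean_copy_number`, `genotype`.
#' @export
screen_samples <- function(tracks, region) {
  if (is.data.frame(tracks)) {
    stopifnot("sample" %in% names(tracks))
    tracks <- split(tracks, tracks$sample)
  }
  out <- purrr::imap(tracks, function(tr, nm) {
    sel <- tr$scaffold == region$scaffold &
      tr$start < region$end & tr$end > region$start
    if (!any(sel)) abort(paste0("region outside coverage track for ", nm))
    mcn <- mean(tr$copy_number[sel])
    tibble(sample = nm, mean_copy_number = mcn,
           genotype = if (mcn < 2.5) "absent" else if (mcn < 3.5) "het" else "hom")
  })
  bind_rows(out)
}

#' Library-size-normalized expression value
#'
#' `gene_read_count / total_sample_reads * scale` (reads per million by
#' default), computed from uniquely mapped reads within the gene model.
#'
#' @param gene_read_count Reads in the gene (>= 0).
#' @param total_sample_reads Total reads in the sample (> 0).
#' @param scale Scaling constant (default 1e6).
#' @return Normalized expression value(s).
#' @export
normalized_expression <- function(gene_read_count, total_sample_reads,
                                  scale = 1e6) {
  if (any(total_sample_reads <= 0)) abort("`total_sample_reads` must be > 0")
  gene_read_count / total_sample_reads * scale
}

#' Classify SNPs as copy-specific from tissue allele counts
#'
#' For each SNP, pools ref/alt counts within white-tissue and within
#' pigmented-tissue samples. A SNP is `copy_specific` iff the pooled white
#' minor-allele fraction is at most `mono_max_fraction` (mono-allelic in the
#' tissue expressing only the shared copy) and the pooled pigmented
#' minor-allele fraction is at least `bi_min_fraction` (both copies
#' expressed). SNPs lacking a white and a pigmented sample at depth
#' `min_depth` are `uninformative`; everything else is `shared`. For
#' copy-specific SNPs the white-expressed allele (assigned to the
#' both-tissues gene copy) is recorded.
#'
#' @param table Tibble with columns `snp_id`, `sample`, `tissue`
#'   (`"white"`/`"pigmented"`), `ref_count`, `alt_count`.
#' @param mono_max_fraction Maximum white minor-allele fraction (default 0.05).
#' @param bi_min_fraction Minimum pigmented minor-allele fraction (default
#'   0.20).
#' @param min_depth Minimum per-sample depth for a sample to count (default
#'   10).
#' @return Tibble per SNP: class, pooled fractions, `white_allele`
#'   (`"ref"`/`"alt"`/NA).
#' @export
classify_copy_specific <- function(table, mono_max_fraction = 0.05,
                                   bi_min_fraction = 0.20, min_depth = 10) {
  table <- as_tibble(table)
  need <- c("snp_id", "sample", "tissue", "ref_count", "alt_count")
  stopifnot(all(need %in% names(table)),
            all(table$tissue %in% c("white", "pigmented")),
            all(table$ref_count >= 0), all(table$alt_count >= 0))
  table %>%
    mutate(depth = .data$ref_count + .data$alt_count) %>%
    filter(.data$depth >= min_depth) %>%
    group_by(.data$snp_id) %>%
    dplyr::group_modify(function(d, key) {
      w <- d[d$tissue == "white", ]; p <- d[d$tissue == "pigmented", ]
      if (!nrow(w) || !nrow(p)) {
        return(tibble(class = "uninformative", white_minor_fraction = NA_real_,
                      pigmented_minor_fraction = NA_real_,
                      white_allele = NA_character_))
      }
      wf <- min(sum(w$ref_count), sum(w$alt_count)) / sum(w$depth)
      pf <- min(sum(p$ref_count), sum(p$alt_count)) / sum(p$depth)
      cs <- wf <= mono_max_fraction && pf >= bi_min_fraction
      tibble(
        class = if (cs) "copy_specific" else "shared",
        white_minor_fraction = wf, pigmented_minor_fraction = pf,
        white_allele = if (cs) {
          if (sum(w$ref_count) >= sum(w$alt_count)) "ref" else "alt"
        } else NA_character_
      )
    }) %>%
    ungroup() %>%
    # SNPs filtered out entirely by the depth guard are uninformative too
    (function(res) {
      missing <- setdiff(unique(table$snp_id), res$snp_id)
      if (length(missing)) {
        res <- bind_rows(res, tibble(
          snp_id = missing, class = "uninformative",
          white_minor_fraction = NA_real_, pigmented_minor_fraction = NA_real_,
          white_allele = NA_character_
        ))
      }
      arrange(res, .data$snp_id)
    })()
}
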