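#' Specify a planted tandem duplication for coverage simulation
#'
#' @param genome_length Scaffold length in bp.
#' @param window Tiling window size in bp (> 0; default 5000).
#' @param dup_start,dup_end Duplicated interval, 0-based half-open, within the
#'   genome.
#' @param copy_state `"heterozygous"` (3 copies inside) or `"homozygous"`
#'   (4 copies).
#' @param mean_depth Mean per-base depth at the diploid (2-copy) state (> 0).
#' @param noise_model `"poisson"`, `"negative_binomial"` or `"none"`
#'   (zero-variance, exact expected depth).
#' @param nb_dispersion Negative-binomial size parameter (only used for
#'   `"negative_binomial"`).
#' @param seed Integer seed.
#' @return A `dup_plant_spec` list.
#' @export
dup_plant_spec <- function(genome_length, window = 5000, dup_start, dup_end,
                          copy_state = c("heterozygous", "homozygous"),
                          mean_depth = 30,
                          noise_model = c("poisson", "negative_binomial", "none"),
                          nb_dispersion = 10, seed = 1L) {
  copy_state <- match.arg(copy_state)
  noise_model <- match.arg(noise_model)
  genome_length <- check_count(genome_length, "genome_length")
  window <- check_count(window, "window")
  if (window > genome_length) abort("window larger than genome")
  stopifnot(mean_depth > 0)
  if (!is.null(dup_start)) {
    if (dup_start < 0 || dup_end > genome_length || dup_end <= dup_start) {
      abort("dup interval must lie within the genome")
    }
  }
  structure(
    list(genome_length = genome_length, window = window,
         dup_start = dup_start, dup_end = dup_end, copy_state = copy_state,
         mean_depth = mean_depth, noise_model = noise_model,
         nb_dispersion = nb_dispersion, seed = seed),
    class = "dup_plant_spec"
  )
}

#' Simulate a coverage track and breakpoint evidence for a planted duplication
#'
#' Tiles the scaffold with non-overlapping windows and draws each window's
#' mean per-base depth from the noise model with expectation scaled by local
#' copy number (2 outside the duplication; 3 heterozygous / 4 homozygous
#' inside, pro-rated for partially overlapping windows). The evidence table
#' carries discordant-pair clusters at both duplication edges and soft-clip
#' records whose clipped sequence remaps to the partner breakpoint, with
#' counts proportional to depth.
#'
#' @param spec A [dup_plant_spec()]; set `dup_start = NULL` for a null track.
#' @param scaffold Scaffold name (default `"scaffold_507"`).
#' @return List with `track` (tibble `scaffold`, `start`, `end`, `depth`),
#'   `evidence` (list of `clips` and `discordant` tibbles; empty for a null
#'   track) and `truth` (the planted interval and copy state).
#' @export
sim_coverage <- function(spec, scaffold = "scaffold_507") {
  stopifnot(inherits(spec, "dup_plant_spec"))
  set.seed(stage_seed(spec$seed, "coverage"))
  starts <- seq(0, spec$genome_length - spec$window, by = spec$window)
  ends <- pmin(starts + spec$window, spec$genome_length)
  extra <- if (identical(spec$copy_state, "homozygous")) 2 else 1
  overlap <- if (is.null(spec$dup_start)) 0 else {
    pmax(0, pmin(ends, spec$dup_end) - pmax(starts, spec$dup_start)) /
      (ends - starts)
  }
  copy <- 2 + extra * overlap
  mu <- spec$mean_depth * copy / 2
  n_bases <- ends - starts
  depth <- switch(spec$noise_model,
    none = mu,
    # mean per-base depth of a window = total base coverage / window length
    poisson = rpois(length(mu), mu * n_bases) / n_bases,
    negative_binomial = stats::rnbinom(length(mu), mu = mu * n_bases,
                                       size = spec$nb_dispersion) / n_bases
  )
  track <- tibble(scaffold = scaffold, start = as.integer(starts),
                  end = as.integer(ends), depth = depth)

  evidence <- list(clips = tibble(scaffold = character(), pos = integer(),
                                  side = character(), remap_pos = integer()),
                   discordant = tibble(scaffold = character(), pos = integer(),
                                       count = integer(), mean_insert = numeric()))
  if (!is.null(spec$dup_start)) {
    # junction-crossing reads scale with depth of the duplicated copies
    rate <- spec$mean_depth * extra / 2 * 0.5
    n_clip_s <- max(rpois(1, rate), 1)
    n_clip_e <- max(rpois(1, rate), 1)
    evidence$clips <- bind_rows(
      tibble(scaffold = scaffold, pos = as.integer(spec$dup_start),
             side = "left", remap_pos = as.integer(spec$dup_end),
             .rows = n_clip_s),
      tibble(scaffold = scaffold, pos = as.integer(spec$dup_end),
             side = "right", remap_pos = as.integer(spec$dup_start),
             .rows = n_clip_e)
    )
    evidence$discordant <- tibble(
      scaffold = scaffold,
      pos = as.integer(c(spec$dup_start, spec$dup_end)),
      count = pmax(rpois(2, rate), 1L),
      mean_insert = (spec$dup_end - spec$dup_start) +
        stats::rnorm(2, 0, 50) + 500
    )
  }
  list(track = track, evidence = evidence,
       truth = list(start = spec$dup_start, end = spec$dup_end,
                    copy_state = spec$copy_state))
}

#' Simulate RNA-seq allele counts with planted copy-specific SNPs
#'
#' Copy-specific SNPs (variants distinguishing the two copies of a duplicated
#' gene) are mono-allelic in white-tissue samples (only the shared copy is
#' expressed there) and bi-allelic with allele fraction near 0.5 in
#' pigmented-tissue samples; all other SNPs are bi-allelic in both tissues.
#' Counts are binomial at the given depths.
#'
#' @param n_snps Number of SNPs.
#' @param white_depth,pigmented_depth Per-sample read depth per SNP (> 0).
#' @param copy_specific Integer indices of the planted copy-specific SNPs.
#' @param n_white,n_pigmented Samples per tissue.
#' @param seed Integer seed.
#' @return Tibble in [classify_copy_specific()] input format, with attribute
#'   `copy_specific` carrying the planted indices (the white-expressed allele
#'   is always `ref` in this generator).
#' @export
sim_allele_counts <- function(n_snps, white_depth, pigmented_depth,
                              copy_specific = integer(), n_white = 2,
                              n_pigmented = 2, seed = 1L) {
  if (white_depth <= 0 || pigmented_depth <= 0) abort("depths must be > 0")
  n_snps <- check_count(n_snps, "n_snps")
  copy_specific <- as.integer(copy_specific)
  stopifnot(all(copy_specific >= 1), all(copy_specific <= n_snps))
  set.seed(stage_seed(seed, "ase"))
  cs <- logical(n_snps); cs[copy_specific] <- TRUE
  samples <- tibble(
    sample = c(sprintf("white_%02d", seq_len(n_white)),
               sprintf("pigmented_%02d", seq_len(n_pigmented))),
    tissue = c(rep("white", n_white), rep("pigmented", n_pigmented))
  )
  out <- purrr::pmap(samples, function(sample, tissue) {
    depth <- if (tissue == "white") white_depth else pigmented_depth
    p_alt <- ifelse(cs & tissue == "white", 0, 0.5)
    alt <- rbinom(n_snps, depth, p_alt)
    tibble(snp_id = sprintf("snp_%04d", seq_len(n_snps)),
           sample = sample, tissue = tissue,
           ref_count = depth - alt, alt_count = alt)
  })
  res <- bind_rows(out)
  attr(res, "copy_specific") <- sprintf("snp_%04d", copy_specific)
  res
}
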