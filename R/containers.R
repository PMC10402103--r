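#' F2 marker genotypes
#'
#' A light container for an F2 intercross genotype matrix: a marker metadata
#' table plus a markers-by-individuals call matrix over `AA`/`AB`/`BB`/`NA`.
#' Calls are coded from the cross perspective: `AA` homozygous for the founder
#' A allele, `BB` for founder B, `AB` heterozygous.
#'
#' @param markers Tibble with columns `marker_id`, `scaffold`, `pos_bp` and
#'   optionally `chrom_class` (`"autosomal"` or `"Z"`; defaults to autosomal).
#' @param individuals Character vector of individual ids.
#' @param calls Character matrix (markers x individuals) with entries in
#'   `c("AA", "AB", "BB", NA)`.
#' @return An object of class `marker_geno`.
#' @export
marker_geno <- function(markers, individuals, calls) {
  markers <- as_tibble(markers)
  need <- c("marker_id", "scaffold", "pos_bp")
  if (!all(need %in% names(markers))) {
    abort("`markers` needs columns marker_id, scaffold, pos_bp")
  }
  if (!"chrom_class" %in% names(markers)) markers$chrom_class <- "autosomal"
  if (anyDuplicated(markers$marker_id)) abort("duplicate marker ids")
  if (any(markers$pos_bp < 1)) abort("bp positions must be >= 1")
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(markers) || ncol(calls) != length(individuals)) {
    abort("calls matrix dimensions must match markers x individuals")
  }
  bad <- !(calls %in% GENO_LEVELS | is.na(calls))
  if (any(bad)) abort("calls must be in {AA, AB, BB, NA}")
  dimnames(calls) <- list(markers$marker_id, individuals)
  structure(
    list(markers = markers, individuals = as.character(individuals), calls = calls),
    class = "marker_geno"
  )
}

#' @export
print.marker_geno <- function(x, ...) {
  cat(sprintf(
    "<marker_geno> %d markers x %d individuals (%.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.marker_geno <- function(x) dim(x$calls)

# Subset markers by logical/integer index, keeping metadata in step.
#' @noRd
subset_markers <- function(g, keep) {
  marker_geno(g$markers[keep, , drop = FALSE], g$individuals,
              g$calls[keep, , drop = FALSE])
}

#' Tidy a marker_geno into long format
#'
#' @param x A [marker_geno()] object.
#' @param ... Unused.
#' @return Tibble with one row per (marker, individual) call.
#' @method tidy marker_geno
#' @export
tidy.marker_geno <- function(x, ...) {
  tibble(
    marker_id = rep(x$markers$marker_id, times = length(x$individuals)),
    individual = rep(x$individuals, each = nrow(x$calls)),
    call = as.vector(x$calls)
  )
}

#' Construct a genetic map table
#'
#' A genetic map is a tibble with one row per mapped marker: linkage `group`,
#' `order` within group, `marker_id`, `scaffold`, `pos_bp` and cumulative
#' position `cM` (non-decreasing within a group).
#'
#' @param df Data frame with those columns.
#' @return The tibble with class `genetic_map`.
#' @export
genetic_map <- function(df) {
  df <- as_tibble(df)
  need <- c("group", "order", "marker_id", "scaffold", "pos_bp", "cM")
  if (!all(need %in% names(df))) {
    abort(paste("genetic map needs columns:", paste(need, collapse = ", ")))
  }
  df <- arrange(df, .data$group, .data$order)
  bad <- df %>%
    group_by(.data$group) %>%
    summarise(ok = all(diff(.data$cM) >= -1e-9) || n() == 1) %>%
    filter(!.data$ok)
  if (nrow(bad)) abort("cM positions must be non-decreasing within each group")
  class(df) <- c("genetic_map", class(df))
  df
}

#' @method glance genetic_map
#' @export
glance.genetic_map <- function(x, ...) {
  x %>%
    group_by(.data$group) %>%
    summarise(n_markers = n(), length_cM = max(.data$cM) - min(.data$cM)) %>%
    ungroup()
}

#' Population site panel
#'
#' Container for biallelic population variant sites with per-sample genotype
#' calls (alt-allele dosage 0/1/2, NA missing), phred-scaled genotype
#' likelihoods, and case/background group labels.
#'
#' @param sites Tibble with columns `scaffold`, `pos` (1-based), `ref`, `alt`.
#' @param samples Character vector of sample names.
#' @param gt Integer matrix sites x samples with entries 0, 1, 2 or NA.
#' @param pl Numeric array sites x samples x 3 of phred-scaled genotype
#'   likelihoods, normalized so the minimum per vector is 0.
#' @param groups Character vector per sample in
#'   `c("case", "background", "excluded")`.
#' @return An object of class `site_panel`.
#' @export
site_panel <- function(sites, samples, gt, pl, groups) {
  sites <- as_tibble(sites)
  stopifnot(
    all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
    nrow(gt) == nrow(sites), ncol(gt) == length(samples),
    identical(dim(pl), c(nrow(sites), length(samples), 3L)) ||
      identical(dim(pl), as.integer(c(nrow(sites), length(samples), 3))),
    length(groups) == length(samples),
    all(groups %in% c("case", "background", "excluded"))
  )
  if (!all(gt %in% c(0L, 1L, 2L) | is.na(gt))) abort("gt entries must be 0/1/2/NA")
  structure(
    list(sites = sites, samples = as.character(samples),
         gt = gt, pl = pl, groups = groups),
    class = "site_panel"
  )
}

#' @export
print.site_panel <- function(x, ...) {
  cat(sprintf(
    "<site_panel> %d sites x %d samples (%d case / %d background)\n",
    nrow(x$sites), length(x$samples),
    sum(x$groups == "case"), sum(x$groups == "background")
  ))
  invisible(x)
}

#' Multi-species alignment block
#'
#' Reference-anchored gapped alignment: the reference sequence (ungapped, its
#' coordinates are the block's coordinate system) and per-species aligned
#' sequences of equal length, each tagged with a clade.
#'
#' @param ref_seq Character scalar, ungapped reference sequence.
#' @param species Tibble with columns `species`, `clade`
#'   (`"avian"`/`"tetrapod"`) and `seq` (gapped, same length as `ref_seq`).
#' @param scaffold,start Reference scaffold name and 0-based start offset.
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(ref_seq, species, scaffold = "ref", start = 0L) {
  species <- as_tibble(species)
  stopifnot(all(c("species", "clade", "seq") %in% names(species)),
            all(species$clade %in% c("avian", "tetrapod")))
  L <- nchar(ref_seq)
  if (!all(nchar(species$seq) == L)) {
    abort("all aligned sequences must match the reference length")
  }
  structure(
    list(ref_seq = ref_seq, species = species,
         scaffold = scaffold, start = as.integer(start)),
    class = "alignment_block"
  )
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf(
    "<alignment_block> %s:%d-%d, %d species (%d avian, %d tetrapod)\n",
    x$scaffold, x$start, x$start + nchar(x$ref_seq), nrow(x$species),
    sum(x$species$clade == "avian"), sum(x$species$clade == "tetrapod")
  ))
  invisible(x)
}
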