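# Plain-text readers/writers for the pipeline's exchange formats. All
# writers are round-trippable through the matching readers.

#' Write / read F2 genotypes as TSV
#'
#' Rows are markers with `marker_id`, `scaffold`, `pos_bp`, `chrom_class`
#' metadata columns followed by one column per individual; calls are
#' `AA`/`AB`/`BB` with `-` for missing.
#'
#' @param g A [marker_geno()].
#' @param path File path.
#' @return `write_genotypes_tsv()` returns `path` invisibly;
#'   `read_genotypes_tsv()` returns a [marker_geno()].
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "marker_geno"))
  calls <- g$calls
  calls[is.na(calls)] <- "-"
  df <- dplyr::bind_cols(g$markers, as_tibble(as.data.frame(calls)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("marker_id", "scaffold", "pos_bp", "chrom_class")
  ind <- setdiff(names(df), meta_cols)
  calls <- as.matrix(df[, ind])
  calls[calls == "-"] <- NA_character_
  marker_geno(df[, meta_cols], ind, calls)
}

#' Write / read a phenotype table as TSV
#'
#' Wide format: `individual_id` plus one numeric column per phenotype/region.
#'
#' @param pheno Tibble from [score_table()] or [sim_phenotypes()].
#' @param path File path.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  readr::write_tsv(pheno, path)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a genetic map as TSV
#'
#' Columns: `group`, `order`, `marker_id`, `scaffold`, `pos_bp`, `cM`.
#'
#' @param map A [genetic_map()].
#' @param path File path.
#' @export
write_map_tsv <- function(map, path) {
  readr::write_tsv(as_tibble(map)[, c("group", "order", "marker_id",
                                      "scaffold", "pos_bp", "cM")], path)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  df$order <- as.integer(df$order)
  df$pos_bp <- as.integer(df$pos_bp)
  if (is.numeric(df$group) && all(df$group == floor(df$group))) {
    df$group <- as.integer(df$group)
  }
  genetic_map(df)
}

#' Write / read a site panel as VCF
#'
#' Writes a minimal VCFv4.2 with `GT:PL` sample fields; group labels go in a
#' side-car sample sheet (see [write_sample_sheet()]). Reading uses vcfR and
#' needs the matching sample sheet to restore group labels.
#'
#' @param panel A [site_panel()].
#' @param path VCF path (uncompressed `.vcf`).
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "site_panel"))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(panel$sites)), function(s) {
    fields <- vapply(seq_along(panel$samples), function(j) {
      g <- panel$gt[s, j]
      if (is.na(g)) return("./.")
      paste0(gt_str[g + 1L], ":",
             paste(round(panel$pl[s, j, ]), collapse = ","))
    }, character(1))
    paste(c(panel$sites$scaffold[s], panel$sites$pos[s], ".",
            panel$sites$ref[s], panel$sites$alt[s], ".", "PASS", ".",
            "GT:PL", fields), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @param sample_sheet Path to the sample sheet TSV (`sample`, `group`).
#' @export
read_vcf <- function(path, sample_sheet) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  pl_raw <- vcfR::extract.gt(v, element = "PL")
  samples <- colnames(gt_raw)
  gt <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  gt[gt_raw %in% c("0/0", "0|0")] <- 0L
  gt[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_raw %in% c("1/1", "1|1")] <- 2L
  pl <- array(NA_real_, c(nrow(gt_raw), ncol(gt_raw), 3))
  for (j in seq_len(ncol(pl_raw))) {
    parts <- strsplit(pl_raw[, j], ",")
    ok <- !is.na(pl_raw[, j])
    vals <- matrix(NA_real_, nrow(pl_raw), 3)
    vals[ok, ] <- t(vapply(parts[ok], as.numeric, numeric(3)))
    pl[, j, ] <- vals
  }
  sheet <- readr::read_tsv(sample_sheet, show_col_types = FALSE)
  groups <- sheet$group[match(samples, sheet$sample)]
  groups[is.na(groups)] <- "excluded"
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  site_panel(
    tibble(scaffold = fix$CHROM, pos = as.integer(fix$POS),
           ref = fix$REF, alt = fix$ALT),
    samples, gt, pl, groups
  )
}

#' Write a sample sheet TSV
#'
#' @param panel A [site_panel()].
#' @param path File path.
#' @export
write_sample_sheet <- function(panel, path) {
  readr::write_tsv(tibble(sample = panel$samples, group = panel$groups), path)
  invisible(path)
}

#' Write / read a coverage track as bedGraph-like TSV
#'
#' Four columns, 0-based half-open: `scaffold`, `start`, `end`, `depth`.
#'
#' @param track Coverage tibble.
#' @param path File path.
#' @export
write_coverage_tsv <- function(track, path) {
  readr::write_tsv(track[, c("scaffold", "start", "end", "depth")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("scaffold", "start", "end", "depth"),
                  show_col_types = FALSE)
}

#' Write / read BED intervals (0-based half-open)
#'
#' @param intervals Tibble with `scaffold` (optional; default `"ref"`),
#'   `start`, `end` and optionally `name`.
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  if (!"scaffold" %in% names(intervals)) intervals$scaffold <- "ref"
  cols <- c("scaffold", "start", "end", intersect("name", names(intervals)))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1)
  n_cols <- length(strsplit(first, "\t")[[1]])
  nm <- c("scaffold", "start", "end", "name")[seq_len(n_cols)]
  readr::read_tsv(path, col_names = nm, show_col_types = FALSE)
}

#' Write / read an alignment block as gapped FASTA plus species manifest
#'
#' The reference goes first (`>ref`), each species as a gapped sequence of
#' the same length; the manifest TSV maps species to clade.
#'
#' @param block An [alignment_block()].
#' @param fasta_path,manifest_path File paths.
#' @export
write_alignment_fasta <- function(block, fasta_path, manifest_path) {
  lines <- c(">ref", block$ref_seq)
  for (i in seq_len(nrow(block$species))) {
    lines <- c(lines, paste0(">", block$species$species[i]),
               block$species$seq[i])
  }
  writeLines(lines, fasta_path)
  readr::write_tsv(block$species[, c("species", "clade")], manifest_path)
  invisible(fasta_path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(fasta_path, manifest_path) {
  lines <- readLines(fasta_path)
  heads <- grep("^>", lines)
  ids <- sub("^>", "", lines[heads])
  seq_of <- function(k) {
    from <- heads[k] + 1
    to <- if (k < length(heads)) heads[k + 1] - 1 else length(lines)
    paste(lines[from:to], collapse = "")
  }
  seqs <- vapply(seq_along(heads), seq_of, character(1))
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  ref <- seqs[ids == "ref"]
  sp <- tibble(species = ids[ids != "ref"], seq = seqs[ids != "ref"]) %>%
    left_join(manifest, by = "species") %>%
    select("species", "clade", "seq")
  alignment_block(ref, sp)
}

#' Write a JSON truth side-car for a simulation
#'
#' @param truth A list of planted-truth values.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
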