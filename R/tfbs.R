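# Position-weight-matrix scanning and binding-site gain/loss between alleles.
#
# Scoring follows the information-weighted matrix-similarity scheme used by
# classical TFBS matchers: position information ci = sum_b f_ib ln(4 f_ib)
# (0 ln 0 = 0), score = (current - min) / (max - min) where
# current = sum_i ci * f(i, base_i), and min/max substitute the per-position
# minimum/maximum frequency. A core score is computed the same way over the
# 5 consecutive highest-information positions.

#' Build a position weight matrix object
#'
#' @param id Motif identifier.
#' @param name Motif name (transcription factor).
#' @param counts 4 x L numeric matrix of base counts or frequencies, rows
#'   named A, C, G, T.
#' @param pseudocount Added to counts before normalization (default 0.01 of
#'   the column total, avoids log(0) in the information weights).
#' @param core_width Number of consecutive positions in the core (default 5,
#'   or motif length if shorter).
#' @return A `pwm` object: list with `id`, `name`, `freq` (4 x L column-
#'   normalized), `info` (per-position information weights), `core`
#'   (position indices of the core).
#' @export
pwm <- function(id, name, counts, pseudocount = NULL, core_width = 5) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4)
  rownames(counts) <- c("A", "C", "G", "T")
  if (is.null(pseudocount)) pseudocount <- 0.01 * mean(colSums(counts))
  counts <- counts + pseudocount / 4
  freq <- sweep(counts, 2, colSums(counts), "/")
  info <- colSums(freq * log(4 * freq))
  w <- min(core_width, ncol(freq))
  core_start <- which.max(vapply(seq_len(ncol(freq) - w + 1),
                                 function(s) sum(info[s:(s + w - 1)]),
                                 numeric(1)))
  structure(list(id = id, name = name, freq = freq, info = info,
                 core = core_start:(core_start + w - 1)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), %d positions, core %d-%d\n", x$id, x$name,
              ncol(x$freq), min(x$core), max(x$core)))
  invisible(x)
}

#' Read JASPAR-style PWM text
#'
#' Parses the common JASPAR text layout: a `>ID NAME` header followed by four
#' lines `A [ counts... ]` (brackets optional), one file holding any number
#' of motifs.
#'
#' @param path File path.
#' @param ... Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no motif headers ('>') found")
  motifs <- purrr::map(heads, function(h) {
    hdr <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) hdr[2] else hdr[1]
    rows <- purrr::map(lines[(h + 1):(h + 4)], function(r) {
      r <- sub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("\\[|\\]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(paste0("ragged count rows in motif ", id))
    }
    pwm(id, name, do.call(rbind, rows), ...)
  })
  setNames(motifs, purrr::map_chr(motifs, "id"))
}

#' @noRd
revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# Matrix-similarity score of one PWM over given positions at one offset of an
# encoded sequence (integer codes 1-4, NA for non-ACGT).
#' @noRd
match_score <- function(p, seq_codes, offset, positions) {
  ci <- p$info[positions]
  b <- seq_codes[offset + positions - 1L]
  f <- p$freq[cbind(ifelse(is.na(b), 1L, b), positions)]
  f[is.na(b)] <- 0
  cur <- sum(ci * f)
  mn <- sum(ci * apply(p$freq[, positions, drop = FALSE], 2, min))
  mx <- sum(ci * apply(p$freq[, positions, drop = FALSE], 2, max))
  if (mx == mn) return(1)
  (cur - mn) / (mx - mn)
}

#' Scan a sequence for PWM hits on both strands
#'
#' A hit at an offset requires the core score (over the 5 consecutive
#' highest-information positions) to reach `core_cutoff` and the full matrix
#' score to reach `matrix_cutoff`. Minus-strand hits scan the reverse
#' complement; their `start` still refers to the forward-strand 0-based
#' offset of the motif's left edge.
#'
#' @param seq Character scalar (ACGT; other letters never match).
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param core_cutoff,matrix_cutoff Score thresholds (defaults 0.75 / 0.80).
#' @return Tibble with `motif`, `name`, `start` (0-based), `strand`,
#'   `core_score`, `matrix_score`. Motifs longer than the sequence are
#'   skipped.
#' @export
tfbs_scan <- function(seq, pwms, core_cutoff = 0.75, matrix_cutoff = 0.80) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  L <- nchar(seq)
  fwd <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  rev_codes <- match(strsplit(toupper(revcomp(seq)), "")[[1]],
                     c("A", "C", "G", "T"))
  out <- purrr::map(pwms, function(p) {
    w <- ncol(p$freq)
    if (w > L) return(NULL)
    hits <- list()
    for (strand in c("+", "-")) {
      codes <- if (strand == "+") fwd else rev_codes
      for (off in seq_len(L - w + 1)) {
        core <- match_score(p, codes, off, p$core)
        if (core < core_cutoff) next
        full <- match_score(p, codes, off, seq_len(w))
        if (full < matrix_cutoff) next
        start0 <- if (strand == "+") off - 1L else L - (off - 1L) - w
        hits[[length(hits) + 1]] <- tibble(
          motif = p$id, name = p$name, start = start0, strand = strand,
          core_score = core, matrix_score = full
        )
      }
    }
    bind_rows(hits)
  })
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(motif = character(), name = character(), start = integer(),
                  strand = character(), core_score = numeric(),
                  matrix_score = numeric())
  }
  res
}

#' Binding sites gained or lost between reference and alternate alleles
#'
#' Scans both sequences (which should differ only by the substitution(s)
#' under test, so offsets are homologous) and compares hit sets keyed by
#' (motif, offset, strand): `lost` are hits present in the reference but
#' absent in the alternate; `gained` the converse. Swapping the two
#' arguments swaps the two sets.
#'
#' @param ref_seq,alt_seq Equal-length character sequences.
#' @param pwms List of `pwm` objects.
#' @inheritParams tfbs_scan
#' @return List with tibbles `gained` and `lost` (columns as [tfbs_scan()]).
#' @export
tfbs_gain_loss <- function(ref_seq, alt_seq, pwms, core_cutoff = 0.75,
                           matrix_cutoff = 0.80) {
  if (nchar(ref_seq) != nchar(alt_seq)) {
    abort("ref and alt sequences must be equal length (substitutions only)")
  }
  ref_hits <- tfbs_scan(ref_seq, pwms, core_cutoff, matrix_cutoff)
  alt_hits <- tfbs_scan(alt_seq, pwms, core_cutoff, matrix_cutoff)
  key <- function(h) paste(h$motif, h$start, h$strand)
  list(
    gained = alt_hits[!key(alt_hits) %in% key(ref_hits), ],
    lost = ref_hits[!key(ref_hits) %in% key(alt_hits), ]
  )
}
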