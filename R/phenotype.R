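#' The 15 canonical plumage body regions
#'
#' Region names used for piebald phenotyping: the bird is divided into 15
#' regions (head, neck, body, tail and wing views) and each is scored for its
#' proportion of white (unpigmented) feathers.
#'
#' @return Character vector of 15 region names.
#' @export
plumage_regions <- function() {
  c(
    "dorsal head", "right lateral head", "left lateral head",
    "dorsal neck", "ventral neck", "right lateral neck", "left lateral neck",
    "dorsal body", "ventral body",
    "dorsal tail", "ventral tail",
    "dorsal right wing", "dorsal left wing",
    "ventral right wing", "ventral left wing"
  )
}

#' Proportion of white plumage in a region
#'
#' From segmentation pixel counts: the whole-region pixel count and the
#' pigmented-only pixel count. The white proportion is
#' `(whole - pigmented) / whole`.
#'
#' @param whole_pixels Pixel count of the entire region (> 0).
#' @param pigmented_pixels Pixel count of the pigmented feathers only
#'   (`0 <= pigmented_pixels <= whole_pixels`).
#' @return Fraction of white plumage in `[0, 1]`. Vectorized.
#' @examples
#' white_proportion(1000, 600) # 0.4
#' @export
white_proportion <- function(whole_pixels, pigmented_pixels) {
  if (any(whole_pixels <= 0)) {
    abort("undefined region: `whole_pixels` must be > 0")
  }
  if (any(pigmented_pixels < 0 | pigmented_pixels > whole_pixels)) {
    abort("inconsistent mask: need 0 <= pigmented_pixels <= whole_pixels")
  }
  (whole_pixels - pigmented_pixels) / whole_pixels
}

#' Score a table of region pixel counts into a phenotype table
#'
#' Takes long-format mask counts (one row per individual x region) and returns
#' a wide phenotype table of white proportions, one row per individual and one
#' column per canonical region. Region names must come from
#' [plumage_regions()]; a duplicate (individual, region) pair is an error;
#' absent pairs become missing values.
#'
#' @param records Data frame with columns `individual_id`, `region`,
#'   `whole_pixels`, `pigmented_pixels`.
#' @return Tibble with column `individual_id` plus one numeric column per
#'   region present in the canonical set (all 15, in canonical order).
#' @export
score_table <- function(records) {
  records <- as_tibble(records)
  need <- c("individual_id", "region", "whole_pixels", "pigmented_pixels")
  if (!all(need %in% names(records))) {
    abort(paste("records need columns:", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(records$region), plumage_regions())
  if (length(bad)) {
    abort(paste0("unknown region name(s): ", paste(bad, collapse = ", ")))
  }
  dup <- records %>% dplyr::count(.data$individual_id, .data$region) %>% filter(n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (individual, region) record(s), e.g. ",
                 dup$individual_id[1], " / ", dup$region[1]))
  }
  scored <- records %>%
    mutate(white = white_proportion(.data$whole_pixels, .data$pigmented_pixels)) %>%
    select("individual_id", "region", "white")
  wide <- tidyr::pivot_wider(scored, names_from = "region", values_from = "white")
  # fixed canonical column order; absent regions become all-missing columns
  for (r in setdiff(plumage_regions(), names(wide))) wide[[r]] <- NA_real_
  arrange(wide[, c("individual_id", plumage_regions())], .data$individual_id)
}
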