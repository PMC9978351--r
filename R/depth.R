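#' Per-replicon read depth and depth ratio to the chromosome
#'
#' Average read depth is the number of mapped reads on a replicon divided by
#' the replicon length; the ratio of a plasmid's depth to the chromosomal
#' depth estimates the plasmid copy number per chromosome copy. A multiread
#' (several tied-best placements) contributes weight 1 split equally across
#' its placements under the default `"fractional"` weighting — repeats
#' shared between replicons would otherwise bias plasmid depth — or is
#' dropped entirely under `"unique"` weighting.
#'
#' @param placements Placement tibble from [map_reads()] (or the
#'   `placements` element of an `mp_pairing`).
#' @param replicons Replicon tibble (columns `name`, `length`,
#'   `is_chromosome`), e.g. the `replicons` element of an `mp_genome` or an
#'   index's metadata.
#' @param weighting `"fractional"` (default) or `"unique"`.
#' @return Tibble with one row per replicon: `replicon`, `length`,
#'   `mapped_read_weight`, `average_depth`, `ratio_to_chromosome`,
#'   `is_chromosome`. The chromosome's ratio is 1 by construction.
#' @export
replicon_depths <- function(placements, replicons,
                            weighting = c("fractional", "unique")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("name", "length", "is_chromosome") %in% names(replicons)))
  if (any(replicons$length <= 0)) abort("Replicon lengths must be positive.")
  if (sum(replicons$is_chromosome) != 1L)
    abort("Exactly one replicon must be flagged as the chromosome.")
  pl <- placements
  if (weighting == "unique") {
    pl <- pl[pl$n_best == 1L, ]
    pl$weight <- 1
  } else {
    pl$weight <- 1 / pl$n_best
  }
  wsum <- pl %>%
    group_by(.data$replicon) %>%
    summarise(mapped_read_weight = sum(.data$weight), .groups = "drop")
  out <- tibble(replicon = replicons$name, length = replicons$length,
                is_chromosome = replicons$is_chromosome) %>%
    left_join(wsum, by = "replicon") %>%
    mutate(mapped_read_weight = tidyr::replace_na(.data$mapped_read_weight, 0),
           average_depth = .data$mapped_read_weight / .data$length)
  chrom_depth <- out$average_depth[out$is_chromosome]
  if (chrom_depth == 0) abort("Chromosome depth is zero; cannot form ratios.")
  out %>%
    mutate(ratio_to_chromosome = .data$average_depth / chrom_depth) %>%
    select("replicon", "length", "mapped_read_weight", "average_depth",
           "ratio_to_chromosome", "is_chromosome")
}

#' Per-replicon copy-number fold change between strains
#'
#' The ratio of depth ratios: how much a replicon's relative copy number
#' changed from strain A to strain B. The chromosome's fold is 1 by
#' construction.
#'
#' @param depth_a,depth_b Depth tables from [replicon_depths()] for the two
#'   strains; their replicon sets must match.
#' @return Tibble with columns `replicon`, `ratio_a`, `ratio_b`, `fold`.
#' @export
compare_strains <- function(depth_a, depth_b) {
  if (!setequal(depth_a$replicon, depth_b$replicon))
    abort("The two depth tables must cover the same replicons.")
  inner_join(
    depth_a %>% select("replicon", ratio_a = "ratio_to_chromosome"),
    depth_b %>% select("replicon", ratio_b = "ratio_to_chromosome"),
    by = "replicon") %>%
    mutate(fold = .data$ratio_b / .data$ratio_a)
}

#' Plot depth ratios per replicon
#'
#' @param depth Depth table from [replicon_depths()].
#' @return A ggplot object.
#' @export
plot_depth_ratios <- function(depth) {
  ggplot2::ggplot(depth,
                  ggplot2::aes(x = stats::reorder(.data$replicon,
                                                  -.data$ratio_to_chromosome),
                               y = .data$ratio_to_chromosome)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "depth ratio to chromosome") +
    ggplot2::theme_bw()
}
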