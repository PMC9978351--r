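# which pairs have a mate "on" a replicon, under the chosen ambiguity policy:
# strict (default) = the mate's unique best placement is there;
# permissive = any tied-best placement is there.
mate_on_replicon <- function(pairing, mate_no, replicons, require_unique) {
  pl <- pairing$placements
  hit <- pl$mate == mate_no & pl$replicon %in% replicons
  if (require_unique) {
    ids <- unique(pl$pair_id[hit])
    uniq <- pairing$pairs$pair_id[
      if (mate_no == 1L) pairing$pairs$unique1 else pairing$pairs$unique2]
    intersect(ids, uniq)
  } else {
    unique(pl$pair_id[hit])
  }
}

#' Select pairs anchored on one replicon
#'
#' First stage of the reciprocal anchored-pair procedure: keep every pair in
#' which one side maps to the anchor replicon (e.g. pSYSA). With
#' `require_unique = TRUE` (default) a mate counts as mapping to the anchor
#' only when its unique best placement is there; the permissive mode accepts
#' any tied-best placement. Strictness matters because plasmid-integration
#' junctions sit inside repeats shared between replicons, where tied
#' placements would otherwise fabricate cross-replicon evidence.
#'
#' @param pairing An `mp_pairing` from [map_pairs()].
#' @param anchor Anchor replicon name.
#' @param require_unique Ambiguity policy (see above).
#' @return The `pairs` tibble restricted to the anchored set, with columns
#'   `anchor_mate` (1/2, mate on the anchor) and `anchor_pos`.
#' @export
select_anchor_pairs <- function(pairing, anchor, require_unique = TRUE) {
  stopifnot(inherits(pairing, "mp_pairing"))
  known <- unique(pairing$placements$replicon)
  if (!anchor %in% known && nrow(pairing$placements) > 0 &&
      !anchor %in% c(pairing$pairs$rep1, pairing$pairs$rep2))
    abort(paste0("Unknown anchor replicon: ", anchor))
  on1 <- mate_on_replicon(pairing, 1L, anchor, require_unique)
  on2 <- mate_on_replicon(pairing, 2L, anchor, require_unique)
  pairs <- pairing$pairs
  a <- pairs[pairs$pair_id %in% union(on1, on2), ]
  a$anchor_mate <- ifelse(a$pair_id %in% on1, 1L, 2L)
  a$anchor_pos <- ifelse(a$anchor_mate == 1L, a$pos1, a$pos2)
  a
}

#' Narrow an anchored set to cross-replicon pairs
#'
#' Second stage: keep anchored pairs whose other side maps to one of the
#' target replicons (chromosome or another plasmid).
#'
#' @param pairing The `mp_pairing` the anchored set came from.
#' @param anchored Result of [select_anchor_pairs()].
#' @param targets Target replicon names; default: every replicon that
#'   appears in the placements except the anchor.
#' @param anchor Anchor replicon name (to exclude from default targets).
#' @param require_unique Ambiguity policy, as in [select_anchor_pairs()].
#' @return Tibble with columns `pair_id`, `anchor_pos`, `target_replicon`,
#'   `target_pos`, `both_unique`.
#' @export
cross_replicon_pairs <- function(pairing, anchored, anchor, targets = NULL,
                                 require_unique = TRUE) {
  stopifnot(inherits(pairing, "mp_pairing"))
  if (is.null(targets))
    targets <- setdiff(unique(pairing$placements$replicon), anchor)
  out <- list()
  for (m in c(1L, 2L)) {
    sub <- anchored[anchored$anchor_mate == m, ]
    if (nrow(sub) == 0) next
    other <- if (m == 1L) 2L else 1L
    ids <- mate_on_replicon(pairing, other, targets, require_unique)
    sub <- sub[sub$pair_id %in% ids, ]
    if (nrow(sub) == 0) next
    pl <- pairing$placements
    tp <- pl[pl$mate == other & pl$replicon %in% targets &
               pl$pair_id %in% sub$pair_id, ]
    # under the permissive policy a mate may touch several targets; keep
    # its best-supported single placement per target replicon
    tp <- tp %>%
      distinct(.data$pair_id, .data$replicon, .keep_all = TRUE) %>%
      select("pair_id", target_replicon = "replicon", target_pos = "start")
    sub <- sub %>%
      select("pair_id", "anchor_pos", "n1", "n2",
             "unique1", "unique2") %>%
      inner_join(tp, by = "pair_id")
    out[[length(out) + 1]] <- sub
  }
  if (length(out) == 0) {
    return(tibble(pair_id = character(), anchor_pos = numeric(),
                  target_replicon = character(), target_pos = numeric(),
                  both_unique = logical()))
  }
  bind_rows(out) %>%
    mutate(both_unique = .data$unique1 & .data$unique2) %>%
    select("pair_id", "anchor_pos", "target_replicon", "target_pos",
           "both_unique") %>%
    arrange(.data$pair_id, .data$target_replicon)
}

#' Reciprocal intersection of anchored cross-replicon pair sets
#'
#' Runs the anchored-pair selection in both directions — anchored on the
#' anchor with the other side on a target, then anchored on the targets with
#' the other side on the anchor — and keeps the read pairs common to both
#' subsets (intersection on pair identity). The set sizes |A|, |B|, |B'|
#' and |C| are attached as attribute `"set_sizes"`.
#'
#' @inheritParams cross_replicon_pairs
#' @param anchor Anchor replicon name.
#' @return The intersected cross-replicon pair tibble (as in
#'   [cross_replicon_pairs()], rows keyed by pair and target replicon).
#' @export
reciprocal_intersect <- function(pairing, anchor, targets = NULL,
                                 require_unique = TRUE) {
  stopifnot(inherits(pairing, "mp_pairing"))
  if (is.null(targets))
    targets <- setdiff(unique(pairing$placements$replicon), anchor)
  a_fwd <- select_anchor_pairs(pairing, anchor, require_unique)
  b_fwd <- cross_replicon_pairs(pairing, a_fwd, anchor, targets,
                                require_unique)
  # switched references: anchored on the target set, other side on the anchor
  on1 <- mate_on_replicon(pairing, 1L, targets, require_unique)
  on2 <- mate_on_replicon(pairing, 2L, targets, require_unique)
  a_rev_ids <- union(on1, on2)
  b_rev_ids <- union(
    intersect(on1, mate_on_replicon(pairing, 2L, anchor, require_unique)),
    intersect(on2, mate_on_replicon(pairing, 1L, anchor, require_unique)))
  cset <- b_fwd[b_fwd$pair_id %in% b_rev_ids, ]
  attr(cset, "set_sizes") <- c(
    A = nrow(a_fwd), B = nrow(b_fwd), B_rev = length(b_rev_ids),
    C = nrow(cset))
  cset
}

#' First-position scatter table of cross-replicon pairs
#'
#' One row per supporting pair: the first positions of the anchor-side and
#' target-side mates, ready for plotting (see [plot_fusion_scatter()]).
#'
#' @param cset Result of [reciprocal_intersect()] (or
#'   [cross_replicon_pairs()]).
#' @return Tibble with columns `anchor_pos`, `target_replicon`, `target_pos`.
#' @export
scatter_table <- function(cset) {
  as_tibble(cset)[, c("anchor_pos", "target_replicon", "target_pos")]
}

# interval from supporting positions on one axis: the supporting mates sit
# on both sides of the junction, which itself lies in a mapping dead zone
# (the homologous repeat). If the largest internal gap exceeds twice the
# read length, report the tightest interval bracketing that gap; otherwise
# fall back to the full span.
junction_interval <- function(pos, read_length) {
  p <- sort(unique(pos))
  if (length(p) == 1L) return(c(p, p + read_length))
  gaps <- diff(p)
  gi <- which.max(gaps)
  g2 <- if (length(gaps) > 1L) max(gaps[-gi]) else 0
  # bracket the dead zone only when it clearly dominates; with sparse
  # support the junction is only localized to the cluster span
  if (gaps[gi] > 2 * read_length && gaps[gi] > 2 * g2) {
    c(p[gi], p[gi + 1] + read_length)
  } else {
    c(p[1], p[length(p)] + read_length)
  }
}

overlap_repeat <- function(lo, hi, rep_sub) {
  if (nrow(rep_sub) == 0) return(NA_integer_)
  hit <- which(rep_sub$start <= hi & rep_sub$end >= lo)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Cluster supporting pairs into fusion calls
#'
#' Single-linkage clustering of the supporting pairs with linkage distance
#' `insert_max` on both the anchor and the target axis (per target
#' replicon). Clusters below `min_support` pairs are dropped. For each call
#' the anchor and target intervals are the tightest intervals bracketing the
#' junction dead zone (see Details). A crossover inside an identical repeat
#' is positionally unidentifiable within the repeat, so when a repeat
#' annotation is supplied and an interval overlaps a repeat copy, the
#' interval is widened to the repeat span and flagged `within_repeat`.
#'
#' @param cset Supporting pairs from [reciprocal_intersect()].
#' @param anchor Anchor replicon name (recorded in the calls).
#' @param insert_max Maximum library insert size (linkage distance).
#' @param min_support Minimum supporting pairs per call (default 5;
#'   singleton chimeras are library artifacts).
#' @param read_length Read length used to pad interval ends.
#' @param repeats Optional repeat annotation tibble (columns `family`,
#'   `replicon`, `start`, `end`).
#' @return Tibble of class `fusion_calls`: `anchor_replicon`,
#'   `anchor_start`, `anchor_end`, `target_replicon`, `target_start`,
#'   `target_end`, `support`, `within_repeat`, `anchor_repeat_family`,
#'   `target_repeat_family`.
#' @export
call_fusions <- function(cset, anchor, insert_max = 10000L, min_support = 5L,
                         read_length = 150L, repeats = NULL) {
  empty <- tibble(
    anchor_replicon = character(), anchor_start = numeric(),
    anchor_end = numeric(), target_replicon = character(),
    target_start = numeric(), target_end = numeric(), support = integer(),
    within_repeat = logical(), anchor_repeat_family = character(),
    target_repeat_family = character())
  class(empty) <- c("fusion_calls", class(empty))
  if (nrow(cset) == 0) return(empty)
  calls <- list()
  for (tr in unique(cset$target_replicon)) {
    sub <- cset[cset$target_replicon == tr, ]
    cl <- cpp_single_linkage2d(sub$anchor_pos, sub$target_pos,
                               as.double(insert_max))
    for (cid in unique(cl)) {
      pts <- sub[cl == cid, ]
      if (nrow(pts) < min_support) next
      ai <- junction_interval(pts$anchor_pos, read_length)
      ti <- junction_interval(pts$target_pos, read_length)
      afam <- tfam <- NA_character_
      if (!is.null(repeats)) {
        ra <- repeats[repeats$replicon == anchor, ]
        ha <- overlap_repeat(ai[1], ai[2], ra)
        if (!is.na(ha)) {
          afam <- ra$family[ha]
          ai <- c(min(ai[1], ra$start[ha]), max(ai[2], ra$end[ha]))
        }
        rt <- repeats[repeats$replicon == tr, ]
        ht <- overlap_repeat(ti[1], ti[2], rt)
        if (!is.na(ht)) {
          tfam <- rt$family[ht]
          ti <- c(min(ti[1], rt$start[ht]), max(ti[2], rt$end[ht]))
        }
      }
      calls[[length(calls) + 1]] <- tibble(
        anchor_replicon = anchor, anchor_start = ai[1], anchor_end = ai[2],
        target_replicon = tr, target_start = ti[1], target_end = ti[2],
        support = nrow(pts),
        within_repeat = !is.na(afam) || !is.na(tfam),
        anchor_repeat_family = afam, target_repeat_family = tfam)
    }
  }
  if (length(calls) == 0) return(empty)
  out <- bind_rows(calls) %>% arrange(.data$target_replicon, .data$anchor_start)
  class(out) <- c("fusion_calls", class(out))
  out
}

#' Plot the first-position scatter of fusion-supporting pairs
#'
#' Anchor-side first positions against target-side first positions, one
#' panel per target replicon; fusion-call intervals, if supplied, are drawn
#' as shaded bands.
#'
#' @param scatter Tibble from [scatter_table()] (or a `cset`).
#' @param calls Optional [call_fusions()] result.
#' @return A ggplot object.
#' @export
plot_fusion_scatter <- function(scatter, calls = NULL) {
  p <- ggplot2::ggplot(scatter,
                       ggplot2::aes(x = .data$anchor_pos,
                                    y = .data$target_pos)) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~target_replicon, scales = "free_y") +
    ggplot2::labs(x = "first position on anchor (nt)",
                  y = "first position on target (nt)") +
    ggplot2::theme_bw()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p +
      ggplot2::geom_rect(
        data = as_tibble(calls),
        ggplot2::aes(xmin = .data$anchor_start, xmax = .data$anchor_end,
                     ymin = .data$target_start, ymax = .data$target_end),
        inherit.aes = FALSE, fill = NA, colour = "black",
        linetype = "dashed")
  }
  p
}

#' @export
#' @method autoplot fusion_calls
#' @importFrom ggplot2 autoplot
autoplot.fusion_calls <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$anchor_start + .data$anchor_end) / 2,
                               y = .data$support)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$anchor_start,
                                       xend = .data$anchor_end,
                                       yend = .data$support)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~target_replicon) +
    ggplot2::labs(x = "anchor interval (nt)", y = "supporting pairs") +
    ggplot2::theme_bw()
}
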