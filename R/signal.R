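#' Two-probe signal-ratio quantification with a Student's t-test
#'
#' Quantifies relative plasmid copy number from blot signal intensities of a
#' plasmid-borne probe (e.g. a CRISPR locus fragment) and a chromosomal
#' probe (e.g. a single-copy gene fragment): each replicate's ratio is
#' `signal_a / signal_b`, each group is summarised by its mean ratio, and
#' each non-reference group is compared to the reference group by an
#' unpaired two-tailed Student's t-test (equal variances by default; set
#' `var_equal = FALSE` for Welch's variant) on the per-replicate ratios.
#'
#' Groups with a single replicate get a ratio but no test. When both groups
#' of a comparison have zero variance the t statistic is degenerate: equal
#' means give p = 1, unequal means give p = 0, each with a zero-variance
#' warning.
#'
#' @param data Tibble with one row per replicate.
#' @param group,signal_a,signal_b Columns of `data` (tidy-eval): group
#'   label, plasmid-probe intensity, chromosome-probe intensity.
#' @param ref_group Reference group label; default: first group in order of
#'   appearance.
#' @param var_equal Use the classical pooled-variance Student's t-test
#'   (default `TRUE`).
#' @return An object of class `signal_quant` with [tidy()] and [glance()]
#'   methods.
#' @examples
#' d <- tibble::tibble(
#'   strain = rep(c("WT", "OE"), each = 3),
#'   crispr3 = c(1.0, 1.1, 0.9, 3.0, 3.2, 2.8),
#'   cmpa = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0))
#' fit <- signal_ratio_test(d, strain, crispr3, cmpa, ref_group = "WT")
#' tidy(fit)
#' @export
signal_ratio_test <- function(data, group, signal_a, signal_b,
                              ref_group = NULL, var_equal = TRUE) {
  d <- tibble(
    group = as.character(dplyr::pull(data, {{ group }})),
    a = dplyr::pull(data, {{ signal_a }}),
    b = dplyr::pull(data, {{ signal_b }})
  )
  if (any(d$b == 0)) abort("Chromosome-probe signals must be non-zero.")
  d$ratio <- d$a / d$b
  groups <- d %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean_ratio = mean(.data$ratio),
              se_ratio = stats::sd(.data$ratio) / sqrt(dplyr::n()),
              .groups = "drop")
  order_seen <- unique(d$group)
  groups <- groups[match(order_seen, groups$group), ]
  if (is.null(ref_group)) ref_group <- order_seen[1]
  if (!ref_group %in% groups$group)
    abort(paste0("Unknown reference group: ", ref_group))

  ref <- d$ratio[d$group == ref_group]
  comps <- list()
  for (g in setdiff(order_seen, ref_group)) {
    x <- d$ratio[d$group == g]
    fold <- mean(x) / mean(ref)
    if (length(x) < 2 || length(ref) < 2) {
      warn(sprintf(
        "Group '%s' vs '%s': fewer than 2 replicates; test refused.",
        g, ref_group))
      tstat <- NA_real_; p <- NA_real_; df <- NA_real_
    } else if (stats::sd(x) == 0 && stats::sd(ref) == 0) {
      warn(sprintf("Group '%s' vs '%s': zero variance in both groups.",
                   g, ref_group))
      df <- length(x) + length(ref) - 2
      if (isTRUE(all.equal(mean(x), mean(ref)))) {
        tstat <- 0; p <- 1
      } else {
        tstat <- sign(mean(x) - mean(ref)) * Inf; p <- 0
      }
    } else {
      tt <- stats::t.test(x, ref, var.equal = var_equal,
                          alternative = "two.sided")
      tstat <- unname(tt$statistic); p <- tt$p.value
      df <- unname(tt$parameter)
    }
    comps[[length(comps) + 1]] <- tibble(
      group = g, ref_group = ref_group, fold = fold,
      t_statistic = tstat, df = df, p_value = p)
  }
  structure(
    list(groups = groups,
         comparisons = if (length(comps) > 0) bind_rows(comps) else tibble(),
         ref_group = ref_group, var_equal = var_equal),
    class = "signal_quant"
  )
}

#' @export
print.signal_quant <- function(x, ...) {
  cat("<signal_quant> reference group: ", x$ref_group,
      if (x$var_equal) " (Student's t-test)" else " (Welch's t-test)",
      "\n", sep = "")
  print(x$groups)
  if (nrow(x$comparisons) > 0) print(x$comparisons)
  invisible(x)
}

#' @export
#' @method tidy signal_quant
tidy.signal_quant <- function(x, ...) {
  x$comparisons
}

#' @export
#' @method glance signal_quant
glance.signal_quant <- function(x, ...) {
  tibble(
    n_groups = nrow(x$groups),
    ref_group = x$ref_group,
    var_equal = x$var_equal,
    min_p = if (nrow(x$comparisons) > 0) min(x$comparisons$p_value) else NA_real_
  )
}
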