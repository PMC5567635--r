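#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pair-join result into one row per complete pair
#' @param x A `pair_join` object.
#' @param ... Unused.
#' @return The `pair_rows` tibble.
#' @method tidy pair_join
#' @export
tidy.pair_join <- function(x, ...) x$pair_rows

#' One-row summary of a pair-join result
#' @param x A `pair_join` object.
#' @param ... Unused.
#' @method glance pair_join
#' @export
glance.pair_join <- function(x, ...) {
  tibble(total = x$total, at_only = x$at_only, aa_only = x$aa_only,
         pairs = x$pairs, at_total = x$at_total, aa_total = x$aa_total)
}

#' Tidy a permutation result into its null histogram
#' @param x A `pair_permutation` object.
#' @param ... Unused.
#' @method tidy pair_permutation
#' @export
tidy.pair_permutation <- function(x, ...) x$histogram

#' One-row summary of a permutation test
#' @param x A `pair_permutation` object.
#' @param ... Unused.
#' @method glance pair_permutation
#' @export
glance.pair_permutation <- function(x, ...) {
  tibble(observed = x$observed, replicates = x$replicates, p = x$p,
         null_max = x$null_max, null_mean = x$null_mean)
}

#' Tidy a ratio summary into one row per analyzed pair
#' @param x A `ratio_summary` object.
#' @param ... Unused.
#' @method tidy ratio_summary
#' @export
tidy.ratio_summary <- function(x, ...) x$pairs

#' One-row summary of a subgenome dominance analysis
#' @param x A `ratio_summary` object.
#' @param ... Unused.
#' @method glance ratio_summary
#' @export
glance.ratio_summary <- function(x, ...) {
  tibble(group = x$group, analyzed = x$analyzed, excluded = x$excluded,
         total_pairs = x$total_pairs, mean_log2 = x$mean_log2,
         median_log2 = x$median_log2)
}

#' Tidy a panel partition into a cell/count table
#' @param x A `panel_partition` object.
#' @param ... Unused.
#' @method tidy panel_partition
#' @export
tidy.panel_partition <- function(x, ...) {
  cells <- c("shared_in_panel", "shared_not_panel", "a_only_in_panel",
             "a_only_not_panel", "b_only_in_panel", "b_only_not_panel")
  tibble(cell = cells, n = unlist(x[cells], use.names = FALSE))
}

#' One-row summary of a panel partition (totals and not-in-panel margins)
#' @param x A `panel_partition` object.
#' @param ... Unused.
#' @method glance panel_partition
#' @export
glance.panel_partition <- function(x, ...) {
  tibble(a_total = x$a_total, b_total = x$b_total,
         a_not_in_panel = x$a_not_in_panel, b_not_in_panel = x$b_not_in_panel)
}

#' One-row summary of a DE analysis
#' @param x A `homeo_de` tibble.
#' @param ... Unused.
#' @method glance homeo_de
#' @export
glance.homeo_de <- function(x, ...) {
  tibble(tested = nrow(x), significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         group1 = attr(x, "groups")[1], group2 = attr(x, "groups")[2])
}
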