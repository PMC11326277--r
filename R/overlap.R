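## Overlap handling. Where capture areas overlap, the artificial array puts
## spots from different areas onto the same (array_row, array_col). All spots
## are kept; an exclude_overlapping flag marks, at each collision, every spot
## except the one from the deepest-sequenced area (highest mean UMI), for
## display or optional analysis exclusion.

#' Mean UMI count per in-tissue spot of a capture area
#'
#' Mean over the in-tissue spots of the per-spot total raw counts; `0` when no
#' spot is in tissue. This is the depth statistic deciding which capture area
#' supplies the retained spot at overlaps.
#'
#' @param counts Sparse genes x spots matrix of raw counts.
#' @param in_tissue Logical mask, one entry per matrix column.
#' @return Non-negative scalar.
#' @export
capture_area_mean_umi <- function(counts, in_tissue) {
  if (length(in_tissue) != ncol(counts)) {
    abort(paste0("in_tissue mask has length ", length(in_tissue),
                 " but counts has ", ncol(counts), " spots"))
  }
  if (!any(in_tissue)) return(0)
  mean(Matrix::colSums(counts[, in_tissue, drop = FALSE]))
}

#' Flag overlapping spots for exclusion by mean-UMI precedence
#'
#' Spots of one group sharing redefined `(array_row, array_col)` across two
#' or more distinct capture areas form a collision. In each collision exactly
#' one spot is retained (`exclude_overlapping = FALSE`): the one from the
#' area with the highest mean UMI, ties broken by lexicographically smallest
#' `capture_area` and then spot key. All other collision members are flagged
#' `TRUE`. No spot is ever removed. Spots outside collisions are `FALSE`.
#'
#' @param spots Stitched spot tibble with columns `barcode` (unique spot
#'   key), `capture_area`, `array_row`, `array_col` (redefined).
#' @param mean_umis Named numeric vector (or tibble with columns
#'   `capture_area`, `mean_umi`) giving each area's depth statistic.
#' @return The spot tibble with a logical `exclude_overlapping` column.
#' @export
flag_excluded_overlaps <- function(spots, mean_umis) {
  if (is.data.frame(mean_umis)) {
    mean_umis <- setNames(mean_umis$mean_umi, mean_umis$capture_area)
  }
  areas <- unique(spots$capture_area)
  missing <- setdiff(areas, names(mean_umis))
  if (length(missing)) {
    abort(paste0("no mean UMI supplied for capture area(s): ",
                 paste(missing, collapse = ", ")))
  }
  spots |>
    mutate(.order = row_number(), .depth = unname(mean_umis[.data$capture_area])) |>
    group_by(.data$array_row, .data$array_col) |>
    mutate(
      .collision = n_distinct(.data$capture_area) >= 2L,
      exclude_overlapping = .data$.collision &
        row_number() != order(-.data$.depth, .data$capture_area, .data$barcode)[[1L]]
    ) |>
    ungroup() |>
    arrange(.data$.order) |>
    select(-".order", -".depth", -".collision")
}

#' Identify collision groups among stitched spots
#'
#' @param spots Stitched spot tibble with `barcode` key, `capture_area`,
#'   `array_row`, `array_col`.
#' @return Tibble of collision members (`array_row`, `array_col`, `barcode`,
#'   `capture_area`), i.e. all spots at coordinates hosting >= 2 distinct
#'   capture areas.
#' @export
overlap_collisions <- function(spots) {
  spots |>
    group_by(.data$array_row, .data$array_col) |>
    filter(n_distinct(.data$capture_area) >= 2L) |>
    ungroup() |>
    select(all_of(c("array_row", "array_col", "barcode", "capture_area")))
}

#' Agreement of cluster labels at overlapping spots
#'
#' Over all collision groups (coordinates hosting spots from >= 2 capture
#' areas) with at least two labeled members, the proportion in which the
#' members agree. `method = "groupwise"` counts a group as concordant only if
#' all members share one label; `method = "pairwise"` scores the fraction of
#' concordant within-group pairs.
#'
#' @param spots Stitched spot tibble with `barcode`, `capture_area`,
#'   `array_row`, `array_col` and a `label` column, unless `labels` is given.
#' @param labels Optional labels: named vector keyed by spot key (`barcode`),
#'   overriding any `label` column. Unlabeled (`NA`) spots are dropped from
#'   the computation.
#' @param method `"groupwise"` (default) or `"pairwise"`.
#' @return Proportion in `[0, 1]`, or `NA` (with a message) when no collision
#'   group has >= 2 labeled members — meaning no overlap exists to assess.
#' @export
overlap_agreement <- function(spots, labels = NULL,
                              method = c("groupwise", "pairwise")) {
  method <- match.arg(method)
  if (!is.null(labels)) {
    spots$label <- unname(labels[spots$barcode])
  }
  if (is.null(spots[["label"]])) {
    abort("supply a `label` column or a named `labels` vector")
  }
  groups <- overlap_collisions(spots) |>
    left_join(spots[, c("barcode", "label")], by = "barcode") |>
    filter(!is.na(.data$label)) |>
    group_by(.data$array_row, .data$array_col) |>
    filter(n() >= 2L) |>
    summarise(
      n_members = n(),
      n_labels = n_distinct(.data$label),
      n_pairs_same = sum(choose(table(.data$label), 2L)),
      .groups = "drop"
    )
  if (nrow(groups) == 0L) {
    inform("no collision groups with >= 2 labeled spots; overlap agreement is undefined")
    return(NA_real_)
  }
  if (method == "groupwise") {
    mean(groups$n_labels == 1L)
  } else {
    sum(groups$n_pairs_same) / sum(choose(groups$n_members, 2L))
  }
}
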