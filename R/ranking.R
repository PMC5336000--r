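# Borda-count rank aggregation of per-algorithm quality indices into
# spectral, spatial and global rankings.

#' Orientation of the six quality indices
#'
#' Lower values are better for SAM and both ERGAS variants; higher values
#' are better for FC, Zhou and Q.
#'
#' @return Tibble with columns `index` and `higher_better`.
#' @export
index_orientations <- function() {
  tibble::tibble(
    index = c("sam", "ergas_spectral", "ergas_spatial", "fc", "zhou", "q"),
    higher_better = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Default index groupings for Borda aggregation
#'
#' Spectral: SAM and spectral ERGAS. Spatial: FC and Zhou — the pairing
#' under which reference spatial rank columns are arithmetically
#' self-consistent; spatial ERGAS can be added via a custom grouping.
#' Global: all six indices.
#'
#' @param spatial_includes_ergas Add spatial ERGAS to the spatial group.
#' @return Named list of character vectors.
#' @export
borda_groupings <- function(spatial_includes_ergas = FALSE) {
  spatial <- c("fc", "zhou")
  if (spatial_includes_ergas) spatial <- c("ergas_spatial", spatial)
  list(
    spectral = c("sam", "ergas_spectral"),
    spatial = spatial,
    global = c("sam", "ergas_spectral", "ergas_spatial", "fc", "zhou", "q")
  )
}

#' Borda points for one index
#'
#' With `N` items the best value receives `N` points and the worst 1.
#' Ties are resolved by policy: `"high"` awards every tied item the best
#' contested rank's points, `"low"` the worst, `"average"` their mean.
#'
#' @param values Numeric vector of index values, one per item.
#' @param higher_better Orientation of the index.
#' @param tie_policy `"high"`, `"low"` or `"average"`.
#' @return Numeric vector of points, same length as `values`.
#' @export
borda_points <- function(values, higher_better = TRUE,
                         tie_policy = c("high", "low", "average")) {
  tie_policy <- match.arg(tie_policy)
  if (!length(values)) abort("`values` must not be empty")
  if (length(values) < 2) abort("Borda scoring needs at least 2 items")
  oriented <- if (higher_better) values else -values
  ties <- switch(tie_policy, high = "min", low = "max", average = "average")
  r <- rank(-oriented, ties.method = ties)
  length(values) + 1 - r
}

#' Aggregate an index table into Borda scores
#'
#' Takes a data frame with one row per algorithm (an `algorithm` column
#' plus one column per index) and sums each algorithm's Borda points over
#' the indices of every grouping. Being rank-based, the aggregation is
#' invariant to strictly monotone transformations of any index.
#'
#' @param table Data frame with an `algorithm` column and numeric index
#'   columns named as in [index_orientations()].
#' @param grouping Named list of index-name vectors (default
#'   [borda_groupings()]); groups referencing indices absent from `table`
#'   raise an error.
#' @param tie_policy Tie policy passed to [borda_points()].
#' @return Object of class `borda_result`: list with `points` (long
#'   tibble: algorithm, index, points), `scores` (tibble: algorithm,
#'   grouping, score), `tie_policy` and `grouping`.
#' @export
borda_aggregate <- function(table, grouping = borda_groupings(),
                            tie_policy = c("high", "low", "average")) {
  tie_policy <- match.arg(tie_policy)
  table <- as.data.frame(table)
  if (!"algorithm" %in% names(table)) {
    abort("`table` must have an `algorithm` column")
  }
  orient <- index_orientations()
  index_cols <- intersect(orient$index, names(table))
  if (!length(index_cols)) abort("`table` contains no known index columns")
  wanted <- unique(unlist(grouping))
  if (!length(wanted)) abort("`grouping` must name at least one index")
  missing_idx <- setdiff(wanted, index_cols)
  if (length(missing_idx)) {
    abort(paste0("grouping references an index not in the table: ",
                 paste(missing_idx, collapse = ", ")))
  }
  points <- purrr::map(index_cols, function(ix) {
    hb <- orient$higher_better[orient$index == ix]
    tibble::tibble(
      algorithm = table$algorithm,
      index = ix,
      points = borda_points(table[[ix]], hb, tie_policy)
    )
  })
  points <- dplyr::bind_rows(points)
  scores <- purrr::imap(grouping, function(members, gname) {
    pts <- points[points$index %in% members, ]
    agg <- stats::aggregate(points ~ algorithm, data = pts, FUN = sum)
    tibble::tibble(algorithm = agg$algorithm, grouping = gname,
                   score = agg$points)
  })
  scores <- dplyr::bind_rows(scores)
  structure(
    list(points = points, scores = scores, tie_policy = tie_policy,
         grouping = grouping),
    class = "borda_result"
  )
}

#' Ranked listing of a Borda aggregation
#'
#' Items are sorted by descending score within each grouping. Tied items
#' share the same (best contested) rank — ties are reported jointly, never
#' silently broken.
#'
#' @param result A [borda_aggregate()] result.
#' @param grouping Grouping names to include (default all).
#' @return Tibble with `grouping`, `rank`, `algorithm`, `score` and a
#'   `tied` flag.
#' @export
rank_report <- function(result, grouping = NULL) {
  stopifnot(inherits(result, "borda_result"))
  keep <- grouping %||% names(result$grouping)
  bad <- setdiff(keep, unique(result$scores$grouping))
  if (length(bad) || !length(keep)) {
    abort("`grouping` must name groupings present in the result")
  }
  out <- result$scores %>%
    dplyr::filter(.data$grouping %in% keep) %>%
    dplyr::group_by(.data$grouping) %>%
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) %>%
    dplyr::mutate(
      rank = rank(-.data$score, ties.method = "min"),
      tied = duplicated(.data$score) | duplicated(.data$score, fromLast = TRUE)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("grouping", "rank", "algorithm", "score", "tied")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.borda_result <- function(x, ...) {
  cat(sprintf("<borda_result> %d algorithms, tie policy '%s'\n",
              length(unique(x$scores$algorithm)), x$tie_policy))
  print(rank_report(x))
  invisible(x)
}

#' Tidy a Borda result into per-index points
#'
#' @param x A `borda_result`.
#' @param ... Unused.
#' @return Long tibble with `algorithm`, `index` and `points`.
#' @export
tidy.borda_result <- function(x, ...) {
  x$points
}

#' One-row-per-grouping summary of a Borda result
#'
#' @param x A `borda_result`.
#' @param ... Unused.
#' @return Tibble with `grouping`, `winner`, `winner_score` and `tied`
#'   (whether the top score is shared).
#' @export
glance.borda_result <- function(x, ...) {
  rr <- rank_report(x)
  rr %>%
    dplyr::filter(.data$rank == 1) %>%
    dplyr::group_by(.data$grouping) %>%
    dplyr::summarise(
      winner = paste(.data$algorithm, collapse = " / "),
      winner_score = .data$score[1],
      tied = dplyr::n() > 1,
      .groups = "drop"
    )
}
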