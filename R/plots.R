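# ggplot2 visualisations for the result containers.

#' @export
autoplot.quality_map <- function(object, clamp = TRUE, ...) {
  df <- as.data.frame(object)
  if (clamp) df$q <- pmin(pmax(df$q, 0), 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block_col, y = .data$block_row,
                                   fill = .data$q)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = if (clamp) c(0, 1) else NULL,
                                  name = "Q") +
    ggplot2::facet_wrap(~band) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Block quality map (block = %d px)",
                                  attr(object, "block_size")))
}

#' @export
autoplot.borda_result <- function(object, ...) {
  rr <- rank_report(object)
  ggplot2::ggplot(rr, ggplot2::aes(x = stats::reorder(.data$algorithm,
                                                      .data$score),
                                   y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~grouping, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Borda score")
}

#' @export
autoplot.quality_report <- function(object, ...) {
  long <- object %>%
    dplyr::select("subset", "sam_deg", "ergas_spectral", "ergas_spatial",
                  "fc", "zhou", "q") %>%
    tidyr::pivot_longer(-"subset", names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subset, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "band subset", y = NULL)
}

#' Render a multispectral image as an RGB composite
#'
#' @param ms An [ms_image()].
#' @param bands Length-3 integer vector of band indices mapped to R, G, B
#'   (default the WorldView-2 true-colour triplet 5, 3, 2).
#' @param stretch Quantile used for contrast stretching (default 0.99).
#' @return A ggplot object.
#' @export
plot_ms_rgb <- function(ms, bands = c(5, 3, 2), stretch = 0.99) {
  pix <- as_ms_array(ms)
  stopifnot(length(bands) == 3, all(bands <= dim(pix)[3]))
  chan <- lapply(bands, function(k) {
    v <- pix[, , k]
    hi <- stats::quantile(v, stretch)
    pmin(v / max(hi, 1e-12), 1)
  })
  d <- dim(chan[[1]])
  df <- data.frame(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(chan[[1]], chan[[2]], chan[[3]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
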