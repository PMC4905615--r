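# ggplot2 views of the analysis results.

#' Plot a consensus ranking
#'
#' Horizontal bars of the percentage movement toward the top-ranked
#' candidates of a consensus.
#'
#' @param object A `towards_consensus`.
#' @param top_n How many top candidates to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.towards_consensus <- function(object, top_n = 10, ...) {
  df <- head(as_tibble(object), top_n)
  grp <- attr(object, "group")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pct_of_total,
    y = stats::reorder(.data$candidate, .data$pct_of_total))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "movement (% of total)", y = NULL,
      title = paste0("Top towards ", attr(object, "level"), "s",
                     if (!is.null(grp)) paste0(" — ", grp)),
      subtitle = paste0(attr(object, "n_voters"), " voters")) +
    ggplot2::theme_minimal()
}

#' Plot expected movement per clan across groups
#'
#' @param clan_tbl Long tibble with columns `group`, `clan`, `pct`
#'   (the `clan` element of a [towards_analysis()] result).
#' @return A ggplot object.
#' @export
plot_clan_movement <- function(clan_tbl) {
  ggplot2::ggplot(clan_tbl, ggplot2::aes(
    x = .data$group, y = .data$pct, fill = .data$clan)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "expected movement (%)", fill = "clan",
                  title = "Expected movement per clan") +
    ggplot2::theme_minimal()
}

#' Plot expected movement per functionality class across groups
#'
#' @param fun_tbl Long tibble with columns `group`, `functionality`,
#'   `pct` (the `functionality` element of a [towards_analysis()]
#'   result).
#' @return A ggplot object.
#' @export
plot_functionality_movement <- function(fun_tbl) {
  ggplot2::ggplot(fun_tbl, ggplot2::aes(
    x = .data$group, y = .data$pct, fill = .data$functionality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "average expected movement (%)",
                  fill = "functionality",
                  title = "Expected movement per functionality") +
    ggplot2::theme_minimal()
}

#' @rdname towards_analysis
#' @param object A `towards_analysis`.
#' @export
autoplot.towards_analysis <- function(object, ...) {
  plot_clan_movement(object$clan)
}
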