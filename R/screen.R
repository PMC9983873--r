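#' Run the matched-trio metastasis gene screen
#'
#' End-to-end screen over an expression table and its sample annotation:
#' assemble N/T/LN trios, optionally CPM-normalize, classify every gene in
#' every case by the fold-change rules, tally recurrence across cases, apply
#' the k-of-n selection and rank the leading genes.
#'
#' @param expr Expression tibble (`gene_id` + one column per sample).
#' @param annotation Sample annotation tibble (`sample_id`, `case_id`,
#'   `site`).
#' @param thresholds [filter_thresholds()] for the per-case rules.
#' @param k_select Minimum recurrent cases for the main lists (default 4).
#' @param k_leading Recurrence threshold for leading genes (default 6).
#' @param m_up,m_down Leading-list sizes (defaults 3 and 2).
#' @param normalize If `TRUE` (default) treat `expr` as raw counts and
#'   CPM-normalize; set `FALSE` for pre-normalized input.
#' @return A `trio_screen` object: a list with `trios`, `calls`,
#'   `recurrence`, `selected_up`, `selected_down`, `leading`, `universe`
#'   (genes evaluable in at least one case) and `params`.
#' @examples
#' sim <- simulate_trios(sim_config(n_cases = 4, n_genes = 200, n_up_spiked = 10,
#'                                  n_down_spiked = 10, seed = 2))
#' scr <- run_screen(sim$expression, sim$annotation)
#' glance(scr)
#' @export
run_screen <- function(expr, annotation, thresholds = filter_thresholds(),
                       k_select = 4, k_leading = 6, m_up = 3, m_down = 2,
                       normalize = TRUE) {
  expr <- validate_expression(expr)
  trios <- assemble_trios(annotation, expr)
  if (normalize) expr <- cpm_normalize(expr)
  calls <- call_cases(expr, trios, thresholds)
  rec <- count_recurrence(calls)
  universe <- rec$gene_id[rec$n_evaluable > 0]
  structure(list(
    trios = trios,
    calls = calls,
    recurrence = rec,
    selected_up = select_recurrent(rec, "up", k_select),
    selected_down = select_recurrent(rec, "down", k_select),
    leading = leading_genes(rec, k_leading, m_up, m_down),
    universe = universe,
    params = list(thresholds = thresholds, k_select = k_select,
                  k_leading = k_leading, m_up = m_up, m_down = m_down,
                  normalize = normalize)
  ), class = "trio_screen")
}

#' @export
print.trio_screen <- function(x, ...) {
  cat("Matched-trio metastasis gene screen\n")
  cat(sprintf("  cases: %d   genes: %d (%d evaluable in >=1 case)\n",
              nrow(x$trios), nrow(x$recurrence), length(x$universe)))
  cat(sprintf("  selected at k>=%d: %d up, %d down\n", x$params$k_select,
              nrow(x$selected_up), nrow(x$selected_down)))
  cat(sprintf("  leading at k>=%d: %s\n", x$params$k_leading,
              if (nrow(x$leading)) paste(x$leading$gene_id, collapse = ", ") else "none"))
  invisible(x)
}

#' Tidy the per-gene recurrence table of a screen
#'
#' @param x A `trio_screen` object.
#' @param ... Unused.
#' @return The recurrence tibble with logical `selected_up` / `selected_down`
#'   columns.
#' @export
tidy.trio_screen <- function(x, ...) {
  x$recurrence |>
    dplyr::mutate(selected_up = .data$gene_id %in% x$selected_up$gene_id,
                  selected_down = .data$gene_id %in% x$selected_down$gene_id)
}

#' One-row summary of a screen
#'
#' @param x A `trio_screen` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of cases, genes, evaluable genes, and
#'   selected/leading genes per direction.
#' @export
glance.trio_screen <- function(x, ...) {
  tibble::tibble(
    n_cases = nrow(x$trios),
    n_genes = nrow(x$recurrence),
    n_evaluable = length(x$universe),
    n_selected_up = nrow(x$selected_up),
    n_selected_down = nrow(x$selected_down),
    n_leading_up = sum(x$leading$direction == "up"),
    n_leading_down = sum(x$leading$direction == "down"),
    k_select = x$params$k_select,
    k_leading = x$params$k_leading
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Recurrence-spectrum plot of a screen
#'
#' Bar chart of how many genes reach each recurrence count, by direction,
#' with the k-of-n selection threshold marked — the summary behind a
#' Venn/upset view of per-case gene lists.
#'
#' @param object A `trio_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trio_screen <- function(object, ...) {
  rec <- object$recurrence
  df <- dplyr::bind_rows(
    rec |> dplyr::filter(.data$up_count > 0) |>
      dplyr::count(count = .data$up_count) |> dplyr::mutate(direction = "up"),
    rec |> dplyr::filter(.data$down_count > 0) |>
      dplyr::count(count = .data$down_count) |> dplyr::mutate(direction = "down")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$count), y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = object$params$k_select - 0.5, linetype = 2) +
    ggplot2::labs(x = "recurrent cases", y = "genes",
                  title = "Recurrence spectrum of per-case calls") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
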