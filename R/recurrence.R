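#' Tally per-case calls into a recurrence table
#'
#' Counts, for every gene, in how many cases it was called up and down, how
#' many cases were evaluable, and the median pseudocounted LN/T and LN/N
#' fold changes over the evaluable cases. Recurrence across cases is the
#' selection statistic of the screen.
#'
#' @param calls Call tibble from [call_cases()].
#' @return A tibble with columns `gene_id`, `up_count`, `down_count`,
#'   `n_evaluable`, `med_fold_ln_t`, `med_fold_ln_n`, one row per gene in
#'   input order.
#' @export
count_recurrence <- function(calls) {
  if (!nrow(calls)) rlang::abort("empty call table")
  calls |>
    dplyr::group_by(gene_id = factor(.data$gene_id, levels = unique(.data$gene_id))) |>
    dplyr::summarise(
      up_count = sum(.data$call == "up"),
      down_count = sum(.data$call == "down"),
      n_evaluable = sum(.data$call != "not_evaluable"),
      med_fold_ln_t = stats::median(.data$fold_ln_t[.data$call != "not_evaluable"]),
      med_fold_ln_n = stats::median(.data$fold_ln_n[.data$call != "not_evaluable"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(gene_id = as.character(.data$gene_id))
}

# shared ranking: recurrence count, then direction-consistent median LN/T
# fold (large folds first for up, small first for down), then gene ID
rank_recurrent <- function(tab, direction) {
  if (direction == "up") {
    dplyr::arrange(tab, dplyr::desc(.data$up_count), dplyr::desc(.data$med_fold_ln_t),
                   .data$gene_id)
  } else {
    dplyr::arrange(tab, dplyr::desc(.data$down_count), .data$med_fold_ln_t,
                   .data$gene_id)
  }
}

#' Select genes recurrent in at least k cases
#'
#' Keeps genes whose up (or down) call count reaches `k_select`, the k-of-n
#' rule of the screen (default: at least 4 of 8 cases). Genes that reach the
#' threshold in both directions across different cases are kept and flagged
#' `discordant` rather than silently assigned.
#'
#' @param recurrence Recurrence tibble from [count_recurrence()].
#' @param direction `"up"` or `"down"`.
#' @param k_select Minimum number of recurrent cases (default 4).
#' @return The selected rows, sorted by (count desc, direction-consistent
#'   median LN/T fold, gene ID), with a logical `discordant` column.
#' @export
select_recurrent <- function(recurrence, direction = c("up", "down"), k_select = 4) {
  direction <- match.arg(direction)
  if (k_select < 1) rlang::abort("k_select must be at least 1")
  cnt <- if (direction == "up") recurrence$up_count else recurrence$down_count
  out <- recurrence[cnt >= k_select, , drop = FALSE]
  out$discordant <- out$up_count >= k_select & out$down_count >= k_select
  rank_recurrent(out, direction)
}

#' Leading genes at a stricter recurrence threshold
#'
#' Restricts to genes recurrent in at least `k_leading` cases (default 6 of
#' 8), ranks them by the [select_recurrent()] ordering and truncates to the
#' requested list sizes — the "leading gene" lists of the screen (default: 3
#' up, 2 down).
#'
#' @param recurrence Recurrence tibble from [count_recurrence()].
#' @param k_leading Minimum recurrent cases for a leading gene (default 6).
#' @param m_up,m_down Maximum list sizes (defaults 3 and 2).
#' @return A tibble of at most `m_up + m_down` rows with a `direction`
#'   column, up genes first.
#' @export
leading_genes <- function(recurrence, k_leading = 6, m_up = 3, m_down = 2) {
  up <- select_recurrent(recurrence, "up", k_leading) |>
    utils::head(m_up) |>
    dplyr::mutate(direction = "up", .before = 1)
  down <- select_recurrent(recurrence, "down", k_leading) |>
    utils::head(m_down) |>
    dplyr::mutate(direction = "down", .before = 1)
  dplyr::bind_rows(up, down)
}

#' Per-subset gene counts for a Venn-style summary
#'
#' For every non-empty subset of cases, counts the genes called in exactly
#' that subset of cases (and no others) for the given direction — the exact
#' membership partition behind a Venn diagram of per-case gene lists.
#'
#' @param calls Call tibble from [call_cases()].
#' @param direction `"up"` or `"down"`.
#' @return A tibble with columns `subset` (case IDs joined by `+`), `mask`
#'   (integer bitmask over cases sorted by ID), `n_cases_in_subset` and
#'   `n_genes`; rows only for subsets containing at least one gene. The
#'   `n_genes` column sums to the number of genes with at least one call in
#'   the direction.
#' @export
venn_summary <- function(calls, direction = c("up", "down")) {
  direction <- match.arg(direction)
  cases <- sort(unique(calls$case_id))
  if (length(cases) > 12) {
    rlang::abort("venn_summary enumerates case subsets exactly; at most 12 cases supported")
  }
  hit <- calls |>
    dplyr::filter(.data$call == direction) |>
    dplyr::mutate(bit = 2^(match(.data$case_id, cases) - 1)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mask = sum(.data$bit), .groups = "drop")
  hit |>
    dplyr::count(.data$mask, name = "n_genes") |>
    dplyr::mutate(
      subset = vapply(.data$mask, function(m) {
        paste(cases[bitwAnd(m, 2^(seq_along(cases) - 1)) > 0], collapse = "+")
      }, ""),
      n_cases_in_subset = vapply(.data$mask, function(m) {
        sum(bitwAnd(m, 2^(seq_along(cases) - 1)) > 0)
      }, 0),
      mask = as.integer(.data$mask)
    ) |>
    dplyr::select("subset", "mask", "n_cases_in_subset", "n_genes") |>
    dplyr::arrange(.data$mask)
}
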