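#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing at least `overlap` members of a gene set among
#' `n_selected` genes drawn without replacement from a universe of
#' `n_universe` genes containing `n_set` set members:
#' `P(X >= overlap)` for `X ~ Hypergeometric(n_universe, n_set, n_selected)`.
#'
#' @param overlap Observed overlap between the selection and the set.
#' @param n_selected Size of the selected gene list.
#' @param n_set Number of set members in the universe.
#' @param n_universe Universe size.
#' @return The upper-tail p-value. Vectorized over its arguments.
#' @examples
#' hypergeom_test(3, 5, 4, 20)  # 496/15504
#' @export
hypergeom_test <- function(overlap, n_selected, n_set, n_universe) {
  if (any(n_universe < 1)) rlang::abort("universe must be non-empty")
  if (any(n_set > n_universe) || any(n_selected > n_universe)) {
    rlang::abort("set and selection cannot exceed the universe")
  }
  if (any(overlap > pmin(n_selected, n_set))) {
    rlang::abort("overlap cannot exceed min(selected, set)")
  }
  stats::phyper(overlap - 1, n_set, n_universe - n_set, n_selected, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate control; output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) rlang::abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene list against gene-set collections
#'
#' Tests each gene set for enrichment in the selected list by the one-sided
#' hypergeometric test, adjusting across sets with Benjamini-Hochberg. Sets
#' are intersected with the universe before testing; the selected list must
#' be contained in the universe (by default, all genes surviving the
#' expression floor).
#'
#' @param selected Character vector of selected gene IDs (a subset of
#'   `universe`).
#' @param gene_sets Gene-set tibble from [read_gene_sets()], or a named list
#'   of character vectors.
#' @param universe Character vector of background gene IDs.
#' @return A tibble with one row per set: `set_name`, `n_universe`,
#'   `n_selected`, `n_set`, `overlap`, `p_value`, `q_value`, in input set
#'   order.
#' @export
enrich_overrep <- function(selected, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) rlang::abort("universe must be non-empty")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    rlang::abort(paste0("selected genes outside the universe: ",
                        paste(utils::head(outside, 5), collapse = ", ")))
  }
  if (is.data.frame(gene_sets)) {
    set_names <- gene_sets$set_name
    members <- gene_sets$genes
  } else {
    set_names <- names(gene_sets)
    members <- gene_sets
  }
  res <- purrr::map_dfr(seq_along(set_names), function(i) {
    inset <- intersect(unique(members[[i]]), universe)
    ov <- length(intersect(selected, inset))
    tibble::tibble(
      set_name = set_names[i],
      n_universe = length(universe),
      n_selected = length(selected),
      n_set = length(inset),
      overlap = ov,
      p_value = hypergeom_test(ov, length(selected), length(inset), length(universe))
    )
  })
  res$q_value <- if (nrow(res)) bh_adjust(res$p_value) else numeric()
  res
}
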