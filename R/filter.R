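#' Fold-change thresholds for per-case classification
#'
#' Bundles the per-case screening rules. With pseudocounted values
#' `N' = n + c`, `T' = t + c`, `L' = ln + c`, a gene in a case is
#' \describe{
#'   \item{up}{`L' >= up_ln_vs_t * T'` and `L' >= up_ln_vs_n * N'` and
#'     (`T' > N'` when `require_t_gt_n_up`)}
#'   \item{down}{(`N' > T'` when `require_n_gt_t_down`) and
#'     `L' <= down_ln_vs_n * N'` and `L' <= down_ln_vs_t * T'`}
#'   \item{not_evaluable}{`max(n, t, ln) < min_expr` (checked first)}
#'   \item{neither}{otherwise}
#' }
#' Fold comparisons are inclusive at the thresholds; the within-primary
#' T-versus-N comparisons are strict.
#'
#' @param up_ln_vs_t Minimum LN/T fold for an up call (default 2).
#' @param up_ln_vs_n Minimum LN/N fold for an up call (default 2).
#' @param require_t_gt_n_up Require T above N for an up call (default TRUE).
#' @param down_ln_vs_n Maximum LN/N fold for a down call (default 0.5).
#' @param down_ln_vs_t Maximum LN/T fold for a down call (default 0.8).
#' @param require_n_gt_t_down Require N above T for a down call (default TRUE).
#' @param pseudocount Constant added to all three values before forming
#'   ratios (default 1, on the normalized scale); 0 is allowed for exact toy
#'   calculations.
#' @param min_expr Minimum of `max(N, T, LN)` for a gene-case to be
#'   evaluable (default 1 on the normalized scale).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(up_ln_vs_t = 2.0, up_ln_vs_n = 2.0,
                              require_t_gt_n_up = TRUE,
                              down_ln_vs_n = 0.5, down_ln_vs_t = 0.8,
                              require_n_gt_t_down = TRUE,
                              pseudocount = 1.0, min_expr = 1.0) {
  th <- list(up_ln_vs_t = up_ln_vs_t, up_ln_vs_n = up_ln_vs_n,
             require_t_gt_n_up = isTRUE(require_t_gt_n_up),
             down_ln_vs_n = down_ln_vs_n, down_ln_vs_t = down_ln_vs_t,
             require_n_gt_t_down = isTRUE(require_n_gt_t_down),
             pseudocount = pseudocount, min_expr = min_expr)
  if (th$up_ln_vs_t <= 1 || th$up_ln_vs_n <= 1) rlang::abort("up thresholds must exceed 1")
  if (th$down_ln_vs_n <= 0 || th$down_ln_vs_n >= 1 ||
      th$down_ln_vs_t <= 0 || th$down_ln_vs_t >= 1) {
    rlang::abort("down thresholds must lie in (0, 1)")
  }
  if (th$pseudocount < 0) rlang::abort("pseudocount must be non-negative")
  if (th$min_expr < 0) rlang::abort("min_expr must be non-negative")
  structure(th, class = "filter_thresholds")
}

call_levels <- c("up", "down", "neither", "not_evaluable")

#' Classify one gene in one case
#'
#' Applies the up-/down-regulation rules to the (N, T, LN) expression values
#' of a single gene in a single patient case. Vectorized over the three value
#' arguments.
#'
#' @param n_val,t_val,ln_val Non-negative expression in the N, T and LN
#'   samples (recycled to a common length).
#' @param thresholds A [filter_thresholds()] object.
#' @return A factor with levels `up`, `down`, `neither`, `not_evaluable`.
#' @examples
#' classify_gene_in_case(2, 5, 11, filter_thresholds(pseudocount = 0, min_expr = 0))
#' @export
classify_gene_in_case <- function(n_val, t_val, ln_val,
                                  thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  len <- max(length(n_val), length(t_val), length(ln_val))
  n <- rep_len(as.numeric(n_val), len)
  t <- rep_len(as.numeric(t_val), len)
  l <- rep_len(as.numeric(ln_val), len)
  if (any(!is.finite(c(n, t, l)))) rlang::abort("expression values must be finite")
  if (any(n < 0 | t < 0 | l < 0)) rlang::abort("expression values must be non-negative")

  evaluable <- pmax(n, t, l) >= thresholds$min_expr
  if (thresholds$pseudocount == 0 && any(evaluable & (n == 0 | t == 0))) {
    rlang::abort("zero denominator: N or T is 0 with pseudocount 0")
  }
  c0 <- thresholds$pseudocount
  np <- n + c0; tp <- t + c0; lp <- l + c0
  up <- lp >= thresholds$up_ln_vs_t * tp &
    lp >= thresholds$up_ln_vs_n * np &
    (!thresholds$require_t_gt_n_up | tp > np)
  down <- (!thresholds$require_n_gt_t_down | np > tp) &
    lp <= thresholds$down_ln_vs_n * np &
    lp <= thresholds$down_ln_vs_t * tp
  call <- rep("neither", len)
  call[down] <- "down"
  call[up] <- "up"  # with default flags up and down are mutually exclusive
  call[!evaluable] <- "not_evaluable"
  factor(call, levels = call_levels)
}

#' Classify every gene in every case
#'
#' Applies [classify_gene_in_case()] across the whole expression table and
#' trio list, returning a tidy gene-by-case call table together with the
#' pseudocounted LN/T and LN/N fold changes used downstream for ranking.
#'
#' @param expr Expression tibble (normalized so the three samples of a trio
#'   are on a comparable scale; see [cpm_normalize()]).
#' @param trios Trio tibble from [assemble_trios()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A tibble with columns `gene_id`, `case_id`, `call`, `fold_ln_t`,
#'   `fold_ln_n`, one row per gene-case.
#' @export
call_cases <- function(expr, trios, thresholds = filter_thresholds()) {
  expr <- validate_expression(expr)
  m <- expr_as_matrix(expr)
  missing_s <- setdiff(c(trios$n_sample, trios$t_sample, trios$ln_sample), colnames(m))
  if (length(missing_s)) {
    rlang::abort(paste0("trio references sample(s) absent from the matrix: ",
                        paste(missing_s, collapse = ", ")))
  }
  if (!nrow(trios)) {
    return(tibble::tibble(gene_id = character(), case_id = character(),
                          call = factor(character(), levels = call_levels),
                          fold_ln_t = numeric(), fold_ln_n = numeric()))
  }
  c0 <- thresholds$pseudocount
  purrr::map_dfr(seq_len(nrow(trios)), function(i) {
    n <- m[, trios$n_sample[i]]
    t <- m[, trios$t_sample[i]]
    l <- m[, trios$ln_sample[i]]
    tibble::tibble(
      gene_id = rownames(m),
      case_id = trios$case_id[i],
      call = classify_gene_in_case(n, t, l, thresholds),
      fold_ln_t = (l + c0) / (t + c0),
      fold_ln_n = (l + c0) / (n + c0)
    )
  })
}

#' Write per-case up/down gene lists
#'
#' Emits `case<id>_up.txt` and `case<id>_down.txt` (one gene ID per line) for
#' every case in a call table.
#'
#' @param calls Call tibble from [call_cases()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_case_gene_lists <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cc in sort(unique(calls$case_id))) {
    for (d in c("up", "down")) {
      genes <- calls$gene_id[calls$case_id == cc & calls$call == d]
      p <- file.path(dir, sprintf("%s_%s.txt", cc, d))
      writeLines(genes, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
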