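# Independent scalar oracles used to cross-check the vectorized implementation.

# Plain if/else re-statement of the per-case rules, written with explicit
# ratios rather than the package's multiplicative comparisons.
oracle_classify <- function(n, t, l,
                            up_ln_vs_t = 2, up_ln_vs_n = 2,
                            down_ln_vs_n = 0.5, down_ln_vs_t = 0.8,
                            pseudocount = 1, min_expr = 1) {
  if (max(n, t, l) < min_expr) return("not_evaluable")
  np <- n + pseudocount; tp <- t + pseudocount; lp <- l + pseudocount
  if (lp / tp >= up_ln_vs_t && lp / np >= up_ln_vs_n && tp > np) return("up")
  if (np > tp && lp / np <= down_ln_vs_n && lp / tp <= down_ln_vs_t) return("down")
  "neither"
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  labelings <- utils::combn(length(pooled), nA)
  us <- apply(labelings, 2, u_of)
  u_obs <- u_of(seq_len(nA))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# Hypergeometric upper tail by direct enumeration over overlap counts.
oracle_hyper_tail <- function(k, n_selected, n_set, n_universe) {
  hi <- min(n_selected, n_set)
  if (k > hi) return(0)
  i <- seq(max(0, k), hi)
  sum(choose(n_set, i) * choose(n_universe - n_set, n_selected - i)) /
    choose(n_universe, n_selected)
}

# Tiny deterministic expression table: one sample column per annotation row.
toy_expression <- function(values, gene_ids = sprintf("g%d", seq_len(nrow(values)))) {
  stopifnot(is.matrix(values))
  tibble::as_tibble(cbind(tibble::tibble(gene_id = gene_ids),
                          tibble::as_tibble(values)))
}

toy_annotation <- function(n_cases) {
  tibble::tibble(
    sample_id = as.vector(t(outer(sprintf("c%d", seq_len(n_cases)), c("N", "T", "LN"), paste, sep = "_"))),
    case_id = rep(sprintf("c%d", seq_len(n_cases)), each = 3),
    site = rep(c("N", "T", "LN"), n_cases)
  )
}

# Expression table in which gene g of case c has values (n, t, ln) given by
# rows of per-case value lists: vals[[case]][gene, c(n, t, ln)]
trio_expression <- function(vals) {
  n_cases <- length(vals)
  ann <- toy_annotation(n_cases)
  m <- do.call(cbind, lapply(vals, function(v) v[, c(1, 2, 3), drop = FALSE]))
  colnames(m) <- ann$sample_id
  list(expr = toy_expression(m), annotation = ann)
}
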