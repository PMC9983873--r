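# hand-built call table: 3 genes x 8 cases
mk_calls <- function(up_cases) {
  cases <- sprintf("c%d", 1:8)
  purrr::map_dfr(names(up_cases), function(g) {
    tibble::tibble(
      gene_id = g, case_id = cases,
      call = factor(ifelse(cases %in% up_cases[[g]], "up", "neither"),
                    levels = c("up", "down", "neither", "not_evaluable")),
      fold_ln_t = ifelse(cases %in% up_cases[[g]], 3, 1),
      fold_ln_n = ifelse(cases %in% up_cases[[g]], 4, 1)
    )
  })
}

test_that("recurrence tallies and k-of-n selection follow the counts", {
  calls <- mk_calls(list(g1 = sprintf("c%d", 1:5), g2 = sprintf("c%d", 1:4),
                         g3 = c("c1", "c2", "c5")))
  rec <- count_recurrence(calls)
  expect_equal(rec$up_count, c(5, 4, 3))
  expect_equal(rec$n_evaluable, rep(8, 3))

  expect_equal(select_recurrent(rec, "up", 4)$gene_id, c("g1", "g2"))
  expect_equal(nrow(select_recurrent(rec, "up", 9)), 0)   # unattainable threshold
  expect_equal(select_recurrent(rec, "up", 1)$gene_id, c("g1", "g2", "g3"))
  expect_equal(nrow(select_recurrent(rec, "down", 1)), 0)
})

test_that("selection size is anti-monotone in k and order-invariant", {
  set.seed(11)
  sim <- simulate_trios(sim_config(n_cases = 8, n_genes = 400, n_up_spiked = 30,
                                   n_down_spiked = 30, seed = 11))
  scr <- run_screen(sim$expression, sim$annotation)
  sizes <- vapply(1:9, function(k) nrow(select_recurrent(scr$recurrence, "up", k)), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[9], 0)

  # permuting gene rows (and case order within calls) leaves membership fixed
  shuffled <- scr$calls[sample.int(nrow(scr$calls)), ]
  rec2 <- count_recurrence(shuffled)
  expect_setequal(select_recurrent(rec2, "up", 4)$gene_id,
                  select_recurrent(scr$recurrence, "up", 4)$gene_id)
})

test_that("leading genes are ranked by count, then median fold, then ID", {
  cases <- sprintf("c%d", 1:8)
  tab <- tibble::tibble(
    gene_id = c("gB", "gA", "gC", "gD", "gE"),
    up_count = c(7, 6, 6, 6, 5),
    down_count = 0L,
    n_evaluable = 8L,
    med_fold_ln_t = c(2.5, 3.0, 4.0, 3.0, 9.0),
    med_fold_ln_n = 4
  )
  lead <- leading_genes(tab, k_leading = 6, m_up = 3, m_down = 2)
  # count first (gB), then larger median LN/T fold (gC), then ID tie-break (gA < gD)
  expect_equal(lead$gene_id, c("gB", "gC", "gA"))
  expect_equal(lead$direction, rep("up", 3))

  none <- leading_genes(tab, k_leading = 8)
  expect_equal(nrow(none), 0)

  three <- leading_genes(tab[tab$up_count >= 6, ], k_leading = 6, m_up = 3)
  expect_equal(nrow(three), 3)  # exactly three qualify -> all returned
})

test_that("down-direction ranking prefers the smallest LN/T fold", {
  tab <- tibble::tibble(
    gene_id = c("gA", "gB"), up_count = 0L, down_count = c(6L, 6L),
    n_evaluable = 8L, med_fold_ln_t = c(0.5, 0.2), med_fold_ln_n = 0.3
  )
  sel <- select_recurrent(tab, "down", 4)
  expect_equal(sel$gene_id, c("gB", "gA"))
})

test_that("venn summary partitions genes by exact case subset", {
  calls <- mk_calls(list(g1 = c("c1", "c2"), g2 = c("c1", "c2"), g3 = "c2",
                         g4 = sprintf("c%d", 1:3), g5 = character()))
  vs <- venn_summary(calls, "up")
  expect_equal(vs$n_genes[vs$subset == "c1+c2"], 2)
  expect_equal(vs$n_genes[vs$subset == "c2"], 1)
  expect_equal(vs$n_genes[vs$subset == "c1+c2+c3"], 1)
  # partition property: subset counts sum to genes with >= 1 up call
  expect_equal(sum(vs$n_genes), 4)

  wide <- tibble::tibble(gene_id = "g1", case_id = sprintf("c%02d", 1:13),
                         call = factor("up", levels = levels(calls$call)),
                         fold_ln_t = 2, fold_ln_n = 2)
  expect_error(venn_summary(wide, "up"), "12")
})

test_that("a gene recurrent in both directions is flagged discordant", {
  tab <- tibble::tibble(gene_id = "g1", up_count = 4L, down_count = 4L,
                        n_evaluable = 8L, med_fold_ln_t = 1, med_fold_ln_n = 1)
  expect_true(select_recurrent(tab, "up", 4)$discordant)
  expect_true(select_recurrent(tab, "down", 4)$discordant)
})

test_that("spiked-gene recurrence counts are binomial across cases", {
  # per gene, cases are independent trials; among well-expressed spiked-up
  # genes the per-case detection probability is near-constant, so up_count
  # should fit Binomial(n_cases, p_detect) with p_detect estimated from the
  # realized detection rate
  gof_p <- vapply(1:20, function(s) {
    sim <- simulate_trios(sim_config(seed = 100 + s, n_genes = 800,
                                     n_up_spiked = 80, n_down_spiked = 0))
    scr <- run_screen(sim$expression, sim$annotation)
    lab <- sim$truth$genes
    rec <- dplyr::inner_join(scr$recurrence, lab, by = "gene_id")
    # restrict to genes far from the pseudocount/floor regime
    cpm <- cpm_normalize(sim$expression)
    m <- as.matrix(cpm[, -1]); rownames(m) <- cpm$gene_id
    n_med <- apply(m[, grepl("_N$", colnames(m))], 1, median)
    keep <- rec$label == "up_spiked" & n_med[rec$gene_id] > 50
    x <- rec$up_count[keep]
    if (length(x) < 20) return(NA_real_)
    p_hat <- mean(x) / 8
    obs <- tabulate(x + 1, nbins = 9)
    expd <- length(x) * dbinom(0:8, 8, p_hat)
    # merge adjacent cells until each pooled cell has expected count >= 5
    bins <- list(); cur_o <- 0; cur_e <- 0
    for (i in 1:9) {
      cur_o <- cur_o + obs[i]; cur_e <- cur_e + expd[i]
      if (cur_e >= 5) { bins[[length(bins) + 1]] <- c(cur_o, cur_e); cur_o <- 0; cur_e <- 0 }
    }
    if (cur_e > 0 && length(bins)) {
      bins[[length(bins)]] <- bins[[length(bins)]] + c(cur_o, cur_e)
    }
    bm <- do.call(rbind, bins)
    if (nrow(bm) < 3) return(NA_real_)
    stat <- sum((bm[, 1] - bm[, 2])^2 / bm[, 2])
    pchisq(stat, df = nrow(bm) - 2, lower.tail = FALSE)
  }, 0)
  gof_p <- gof_p[!is.na(gof_p)]
  expect_gt(length(gof_p), 10)
  # at alpha = 0.01 we allow a small number of chance rejections
  expect_lte(sum(gof_p < 0.01), 3)
})
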