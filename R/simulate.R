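#' Configuration for the matched-trio simulator
#'
#' Defines the study conditions emulated by [simulate_trios()]: a cohort of
#' patient cases each contributing one adjacent non-tumor (N), one primary
#' tumor (T) and one metastatic lymph node (LN) library, negative-binomial
#' counts with per-gene log-normal baseline means and per-library size
#' factors, and two panels of spiked genes whose generating means satisfy the
#' up-/down-regulation screening rules in a random subset of cases.
#'
#' @param n_cases Number of patient cases (default 8, the cohort size of the
#'   matched-trio design).
#' @param n_genes Number of genes (default 10000).
#' @param n_up_spiked,n_down_spiked Number of spiked up-/down-regulated genes
#'   (default 100 each).
#' @param recurrence_prob Probability that a spiked gene expresses its effect
#'   in a given case (default 0.75), modelling hits that recur in only a
#'   subset of patients.
#' @param up_fold_ln,up_fold_t LN and T mean multipliers relative to N for a
#'   spiked-up gene in an effect-active case (defaults 4 and 2, so the
#'   generating signal has LN/N = 4, T/N = 2 and LN/T = 2).
#' @param down_fold_ln_vs_n,down_fold_t_vs_n LN and T mean multipliers
#'   relative to N for spiked-down genes (defaults 0.25 and 0.7, so
#'   LN/N = 0.25 and LN/T ~ 0.36).
#' @param nb_dispersion Negative-binomial dispersion phi with
#'   `variance = mu + phi * mu^2` (default 0.2); `0` gives Poisson counts.
#' @param libsize_range Range of per-sample library sizes; sizes are drawn
#'   uniformly on the log scale (default 5e5 to 2e6).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-gene baseline mean (defaults 4 and 1.5, a typical bulk RNA-seq
#'   abundance spread).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 8, n_genes = 10000,
                       n_up_spiked = 100, n_down_spiked = 100,
                       recurrence_prob = 0.75,
                       up_fold_ln = 4.0, up_fold_t = 2.0,
                       down_fold_ln_vs_n = 0.25, down_fold_t_vs_n = 0.7,
                       nb_dispersion = 0.2,
                       libsize_range = c(5e5, 2e6),
                       base_mean_meanlog = 4, base_mean_sdlog = 1.5,
                       seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_genes = as.integer(n_genes),
              n_up_spiked = as.integer(n_up_spiked),
              n_down_spiked = as.integer(n_down_spiked),
              recurrence_prob = recurrence_prob,
              up_fold_ln = up_fold_ln, up_fold_t = up_fold_t,
              down_fold_ln_vs_n = down_fold_ln_vs_n,
              down_fold_t_vs_n = down_fold_t_vs_n,
              nb_dispersion = nb_dispersion,
              libsize_range = as.numeric(libsize_range),
              base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              seed = as.integer(seed))
  folds <- c(cfg$up_fold_ln, cfg$up_fold_t, cfg$down_fold_ln_vs_n, cfg$down_fold_t_vs_n)
  if (any(!is.finite(folds)) || any(folds <= 0)) rlang::abort("all fold effects must be positive")
  if (cfg$recurrence_prob < 0 || cfg$recurrence_prob > 1) rlang::abort("recurrence_prob must be in [0, 1]")
  if (cfg$n_up_spiked + cfg$n_down_spiked > cfg$n_genes) {
    rlang::abort("n_up_spiked + n_down_spiked must not exceed n_genes")
  }
  if (cfg$nb_dispersion < 0) rlang::abort("nb_dispersion must be non-negative")
  if (length(cfg$libsize_range) != 2 || any(cfg$libsize_range <= 0) ||
      cfg$libsize_range[1] > cfg$libsize_range[2]) {
    rlang::abort("libsize_range must be an increasing pair of positive sizes")
  }
  if (cfg$n_cases < 1 || cfg$n_genes < 1) rlang::abort("n_cases and n_genes must be positive")
  structure(cfg, class = "sim_config")
}

# internal: NB draw that degrades gracefully to Poisson at dispersion 0
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a matched-trio expression study with known truth
#'
#' Draws a gene-by-sample count matrix for `n_cases` matched N/T/LN trios.
#' Counts are negative binomial with mean `base_mean * site_effect *
#' library_factor`. Spiked-up genes have LN and T means multiplied by
#' `up_fold_ln` and `up_fold_t` in effect-active cases; spiked-down genes
#' use `down_fold_ln_vs_n` and `down_fold_t_vs_n`; null genes share one mean
#' across the three sites of a case.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{expression}{count tibble (`gene_id` + one column per sample)}
#'     \item{annotation}{tibble `sample_id`, `case_id`, `site`}
#'     \item{truth}{list with `genes` (tibble `gene_id`, `label` in
#'       `up_spiked`/`down_spiked`/`null`) and `activity` (tibble `gene_id`,
#'       `case_id`, `active` for spiked genes only)}
#'   }
#' @examples
#' sim <- simulate_trios(sim_config(n_cases = 3, n_genes = 50, n_up_spiked = 5,
#'                                  n_down_spiked = 5, seed = 7))
#' dim(sim$expression)
#' @export
simulate_trios <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; nc <- config$n_cases
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  case_ids <- sprintf("case%02d", seq_len(nc))
  sites <- c("N", "T", "LN")

  label <- rep("null", ng)
  spiked_idx <- sample.int(ng, config$n_up_spiked + config$n_down_spiked)
  up_idx <- spiked_idx[seq_len(config$n_up_spiked)]
  down_idx <- setdiff(spiked_idx, up_idx)
  label[up_idx] <- "up_spiked"
  label[down_idx] <- "down_spiked"

  base_mean <- stats::rlnorm(ng, config$base_mean_meanlog, config$base_mean_sdlog)
  lr <- log(config$libsize_range)
  libsize <- exp(stats::runif(3 * nc, lr[1], lr[2]))
  lib_factor <- libsize / 1e6

  active <- matrix(FALSE, ng, nc)
  active[spiked_idx, ] <- stats::runif(length(spiked_idx) * nc) < config$recurrence_prob

  ann <- tibble::tibble(
    sample_id = as.vector(vapply(case_ids, function(cc) paste(cc, sites, sep = "_"), character(3))),
    case_id = rep(case_ids, each = 3),
    site = rep(sites, nc)
  )

  counts <- matrix(0L, ng, 3 * nc, dimnames = list(gene_ids, ann$sample_id))
  for (j in seq_len(nc)) {
    eff <- matrix(1, ng, 3)  # columns N, T, LN
    up_on <- up_idx[active[up_idx, j]]
    dn_on <- down_idx[active[down_idx, j]]
    eff[up_on, 2] <- config$up_fold_t
    eff[up_on, 3] <- config$up_fold_ln
    eff[dn_on, 2] <- config$down_fold_t_vs_n
    eff[dn_on, 3] <- config$down_fold_ln_vs_n
    for (k in 1:3) {
      col <- (j - 1) * 3 + k
      mu <- base_mean * eff[, k] * lib_factor[col]
      counts[, col] <- rcounts(ng, mu, config$nb_dispersion)
    }
  }

  expr <- tibble::as_tibble(cbind(tibble::tibble(gene_id = gene_ids),
                                  tibble::as_tibble(counts)))
  activity <- tibble::tibble(
    gene_id = rep(gene_ids[sort(spiked_idx)], each = nc),
    case_id = rep(case_ids, times = length(spiked_idx)),
    active = as.vector(t(active[sort(spiked_idx), , drop = FALSE]))
  )
  list(
    expression = expr,
    annotation = ann,
    truth = list(
      genes = tibble::tibble(gene_id = gene_ids, label = label),
      activity = activity
    )
  )
}

# half-point IHC grid helper
snap_ihc_grid <- function(x) pmin(4, pmax(0, round(x * 2) / 2))

#' Simulate linked clinical tables
#'
#' Generates the clinical observations the downstream statistics consume:
#' immunohistochemistry (IHC) scores on the 0-4 half-point grid for primary
#' tumors and metastatic lymph nodes (LN scores shifted upward by
#' `ihc_shift` on the latent scale), per-patient survival with an
#' exponential hazard increased by `hazard_ratio` in the marker-high group,
#' and positive/examined lymph-node counts in which a set fraction of
#' node-positive patients exceeds the 30% ratio cutoff.
#'
#' @param config A [sim_config()]; supplies the seed.
#' @param truth Optional truth list from [simulate_trios()], used to check
#'   that `marker_gene` exists.
#' @param marker_gene Identifier of the marker gene the clinical tables are
#'   linked to; must be present in `truth` when `truth` is given.
#' @param n_primary,n_ln Numbers of primary-tumor and metastatic-LN IHC
#'   specimens (defaults 179 and 56, a typical tissue-microarray cohort).
#' @param ihc_mean Latent mean IHC score of primary tumors (default 1.5).
#' @param ihc_shift Upward latent shift of LN scores (default 0.8; 0 makes
#'   the two tissues identical in law).
#' @param ihc_sd Latent score standard deviation (default 1).
#' @param n_patients Patients in the survival/LN tables (default 100).
#' @param hazard_ratio Hazard multiplier of the marker-high group (default
#'   2; 1 makes the two groups identical in law).
#' @param base_hazard Baseline exponential event hazard per month (default
#'   0.02).
#' @param followup_max Administrative censoring time in months (default 60).
#' @param prob_no_met Probability a patient has no positive node (default 0.3).
#' @param high_ratio_frac Fraction of node-positive patients whose positive /
#'   examined ratio exceeds 0.30 (default 0.5).
#' @return A list of tibbles `ihc` (`specimen_id`, `tissue`, `score`),
#'   `survival` (`patient_id`, `time`, `event`, `group`) and `ln_counts`
#'   (`patient_id`, `positive_ln`, `examined_ln`).
#' @export
simulate_clinical <- function(config = sim_config(), truth = NULL,
                              marker_gene = "gene00001",
                              n_primary = 179, n_ln = 56,
                              ihc_mean = 1.5, ihc_shift = 0.8, ihc_sd = 1,
                              n_patients = 100, hazard_ratio = 2,
                              base_hazard = 0.02, followup_max = 60,
                              prob_no_met = 0.3, high_ratio_frac = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(truth) && !marker_gene %in% truth$genes$gene_id) {
    rlang::abort(sprintf("marker gene '%s' not present in simulation truth", marker_gene))
  }
  if (hazard_ratio <= 0) rlang::abort("hazard_ratio must be positive")
  set.seed(config$seed + 104729L)  # offset so clinical draws are independent of the counts

  ihc <- tibble::tibble(
    specimen_id = c(sprintf("prim%03d", seq_len(n_primary)), sprintf("lnmet%03d", seq_len(n_ln))),
    tissue = c(rep("primary", n_primary), rep("ln_met", n_ln)),
    score = snap_ihc_grid(stats::rnorm(n_primary + n_ln,
                                       mean = ihc_mean + c(rep(0, n_primary), rep(ihc_shift, n_ln)),
                                       sd = ihc_sd))
  )

  group <- rep(c("low", "high"), length.out = n_patients)
  haz <- base_hazard * ifelse(group == "high", hazard_ratio, 1)
  t_event <- stats::rexp(n_patients, haz)
  t_cens <- pmin(followup_max, stats::rexp(n_patients, base_hazard / 2))
  surv <- tibble::tibble(
    patient_id = sprintf("pt%03d", seq_len(n_patients)),
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    group = group,
    marker = marker_gene
  )

  examined <- sample(8:40, n_patients, replace = TRUE)
  no_met <- stats::runif(n_patients) < prob_no_met
  high <- !no_met & stats::runif(n_patients) < high_ratio_frac
  boundary <- floor(0.30 * examined)  # largest positive count with ratio <= 0.30
  positive <- integer(n_patients)
  for (i in seq_len(n_patients)) {
    if (no_met[i]) next
    positive[i] <- if (high[i]) {
      sample(seq(boundary[i] + 1L, examined[i]), 1L)
    } else {
      sample(seq_len(max(1L, boundary[i])), 1L)
    }
  }
  ln_counts <- tibble::tibble(
    patient_id = surv$patient_id,
    positive_ln = positive,
    examined_ln = examined
  )

  list(ihc = ihc, survival = surv[, c("patient_id", "time", "event", "group")],
       ln_counts = ln_counts)
}

#' Write a simulated study to TSV files
#'
#' Writes the expression, annotation and truth tables in the formats the
#' readers consume; fixed seed in the config makes the files byte-identical
#' across runs.
#'
#' @param sim Result of [simulate_trios()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_table(sim$expression, paths[["expression"]])
  readr::write_tsv(sim$annotation, paths[["annotation"]], progress = FALSE)
  readr::write_tsv(sim$truth$genes, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
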