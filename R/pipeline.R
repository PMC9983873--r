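#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]. All stages
#' draw their randomness from the single `seed`, fanned out to fixed
#' per-stage offsets, so a config plus seed pins every output byte.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Global seed.
#' @param simulate If `TRUE` (default) generate the input study with
#'   [simulate_trios()]; otherwise `expression_path` / `annotation_path`
#'   must point at existing TSVs.
#' @param expression_path,annotation_path Input TSVs when `simulate = FALSE`.
#' @param gene_sets_path Optional GMT file; enables the enrichment stage.
#' @param normalize Treat expression input as raw counts and CPM-normalize
#'   (default `TRUE`).
#' @param sim Overrides for [sim_config()] fields, as a named list.
#' @param thresholds Overrides for [filter_thresholds()] fields.
#' @param k_select,k_leading,m_up,m_down Recurrence parameters.
#' @param clinical If `TRUE` (default) simulate linked clinical tables and
#'   run the clinical statistics stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "metscreen_run", seed = 1L,
                            simulate = TRUE,
                            expression_path = NULL, annotation_path = NULL,
                            gene_sets_path = NULL, normalize = TRUE,
                            sim = list(), thresholds = list(),
                            k_select = 4, k_leading = 6, m_up = 3, m_down = 2,
                            clinical = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
                 expression_path = expression_path,
                 annotation_path = annotation_path,
                 gene_sets_path = gene_sets_path, normalize = normalize,
                 sim = sim, thresholds = thresholds,
                 k_select = k_select, k_leading = k_leading,
                 m_up = m_up, m_down = m_down, clinical = clinical),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [pipeline_config()]; `sim`
#' and `thresholds` are nested mappings.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, y)
}

# stage-named abort so callers (and the CLI exit code) can identify the
# failing stage
stage_abort <- function(stage, parent) {
  rlang::abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)),
               class = paste0("metscreen_stage_", stage))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_abort(stage, e))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> normalize -> per-case filter ->
#' recurrence -> enrichment (if gene sets are configured) -> clinical
#' statistics, writing every stage output as TSV into `config$out_dir`
#' together with a machine-readable JSON manifest of parameters and output
#' MD5 hashes. The same config and seed reproduce identical hashes; no
#' stage mutates its inputs.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list with the `trio_screen` object, the manifest,
#'   and the output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(x, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  truth <- NULL
  if (isTRUE(config$simulate)) {
    sim <- run_stage("simulate", {
      cfg <- do.call(sim_config, utils::modifyList(list(seed = config$seed), config$sim))
      simulate_trios(cfg)
    })
    expr <- sim$expression; ann <- sim$annotation; truth <- sim$truth
    emit(truth$genes, "truth.tsv")
  } else {
    expr <- run_stage("io", {
      if (is.null(config$expression_path) || !file.exists(config$expression_path)) {
        rlang::abort(paste0("expression table not found: ",
                            config$expression_path %||% "<unset>"))
      }
      read_expression_table(config$expression_path)
    })
    ann <- run_stage("io", {
      if (is.null(config$annotation_path) || !file.exists(config$annotation_path)) {
        rlang::abort(paste0("annotation table not found: ",
                            config$annotation_path %||% "<unset>"))
      }
      read_sample_annotation(config$annotation_path)
    })
  }

  th <- run_stage("filter", do.call(filter_thresholds, config$thresholds))
  screen <- run_stage("screen", run_screen(
    expr, ann, thresholds = th, k_select = config$k_select,
    k_leading = config$k_leading, m_up = config$m_up, m_down = config$m_down,
    normalize = config$normalize))

  emit(screen$calls, "calls.tsv")
  emit(screen$recurrence, "recurrence.tsv")
  emit(screen$selected_up, "selected_up.tsv")
  emit(screen$selected_down, "selected_down.tsv")
  emit(screen$leading, "leading_genes.tsv")
  emit(venn_summary(screen$calls, "up"), "venn_up.tsv")
  emit(venn_summary(screen$calls, "down"), "venn_down.tsv")

  if (!is.null(config$gene_sets_path)) {
    enr <- run_stage("enrich", {
      if (!file.exists(config$gene_sets_path)) {
        rlang::abort(paste0("gene-set GMT not found: ", config$gene_sets_path))
      }
      sets <- read_gene_sets(config$gene_sets_path)
      selected <- unique(c(screen$selected_up$gene_id, screen$selected_down$gene_id))
      enrich_overrep(selected, sets, screen$universe)
    })
    emit(enr, "enrichment.tsv")
  }

  if (isTRUE(config$clinical) && isTRUE(config$simulate)) {
    clin <- run_stage("clinstats", {
      cfg <- do.call(sim_config, utils::modifyList(list(seed = config$seed), config$sim))
      marker <- if (nrow(screen$selected_up)) screen$selected_up$gene_id[1] else expr$gene_id[1]
      cl <- simulate_clinical(cfg, truth = truth, marker_gene = marker)
      emit(cl$ihc, "clinical_ihc.tsv")
      emit(cl$survival, "clinical_survival.tsv")
      emit(ln_ratio_group(cl$ln_counts), "clinical_ln_groups.tsv")
      ihc_bins <- cl$ihc |>
        dplyr::mutate(bin = bin_ihc(.data$score)) |>
        dplyr::count(.data$tissue, .data$bin, .drop = FALSE)
      mw <- mann_whitney(cl$ihc$score[cl$ihc$tissue == "ln_met"],
                         cl$ihc$score[cl$ihc$tissue == "primary"])
      lr <- logrank_test(cl$survival)
      emit(ihc_bins, "clinical_ihc_bins.tsv")
      emit(km_estimate(cl$survival), "clinical_km.tsv")
      emit(tibble::tibble(test = c("ihc_mann_whitney", "survival_logrank"),
                          statistic = c(mw$statistic, lr$statistic),
                          p_value = c(mw$p_value, lr$p_value)),
           "clinical_tests.tsv")
      cl
    })
  }

  manifest <- list(
    tool = "metscreen",
    version = as.character(utils::packageVersion("metscreen")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(md5 = unname(tools::md5sum(p)), bytes = unname(file.size(p)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(list(screen = screen, manifest = manifest, out_dir = config$out_dir,
                 manifest_path = manifest_path))
}
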