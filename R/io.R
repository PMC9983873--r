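#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated expression table with gene identifiers in the first
#' column (header `gene_id`) and one numeric column per sample. Values may be
#' raw counts or pre-normalized units; they must be finite and non-negative.
#'
#' @param path Path to a TSV file. The first column holds unique gene IDs,
#'   the remaining columns one sample each, with sample IDs in the header.
#' @return A tibble with a `gene_id` character column followed by one numeric
#'   column per sample, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t0\t5"), tf)
#' read_expression_table(tf)
#' @export
read_expression_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    rlang::abort("expression table needs a gene_id column plus at least one sample column")
  }
  names(raw)[1] <- "gene_id"
  x <- raw
  for (j in seq(2L, ncol(x))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad)) {
      rlang::abort(sprintf(
        "non-numeric expression value '%s' at gene '%s', sample '%s'",
        raw[[j]][bad[1]], raw[[1]][bad[1]], names(raw)[j]))
    }
    x[[j]] <- v
  }
  out <- tibble::as_tibble(x)
  validate_expression(out)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]; round-trips values at full precision.
#'
#' @param expr Expression tibble (`gene_id` + numeric sample columns).
#' @param path Output file path.
#' @return `expr`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(expr)
}

#' Validate an expression tibble
#'
#' Checks the invariants of the expression container: unique gene and sample
#' identifiers, numeric sample columns, and finite non-negative values.
#'
#' @param expr A data frame with `gene_id` first and numeric sample columns.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_expression <- function(expr) {
  expr <- tibble::as_tibble(expr)
  if (!"gene_id" %in% names(expr)[1]) {
    rlang::abort("first column of an expression table must be 'gene_id'")
  }
  dup_g <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup_g)) {
    rlang::abort(paste0("duplicated gene IDs: ", paste(utils::head(dup_g, 5), collapse = ", ")))
  }
  samp <- names(expr)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s)) {
    rlang::abort(paste0("duplicated sample IDs: ", paste(dup_s, collapse = ", ")))
  }
  for (s in samp) {
    v <- expr[[s]]
    if (!is.numeric(v)) rlang::abort(sprintf("sample column '%s' is not numeric", s))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      rlang::abort(sprintf("non-finite value at gene '%s', sample '%s'",
                           expr$gene_id[bad[1]], s))
    }
    neg <- which(v < 0)
    if (length(neg)) {
      rlang::abort(sprintf("negative value %g at gene '%s', sample '%s'",
                           v[neg[1]], expr$gene_id[neg[1]], s))
    }
  }
  expr
}

# internal: expression tibble -> numeric matrix with gene rownames
expr_as_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' Read a sample annotation table
#'
#' @param path TSV with columns `sample_id`, `case_id`, `site`
#'   (site one of `"N"`, `"T"`, `"LN"`).
#' @return A validated annotation tibble.
#' @export
read_sample_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_annotation(ann)
}

#' Validate a sample annotation tibble
#'
#' @param ann Data frame with `sample_id`, `case_id`, `site` columns.
#' @return The validated tibble.
#' @export
validate_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  need <- c("sample_id", "case_id", "site")
  miss <- setdiff(need, names(ann))
  if (length(miss)) rlang::abort(paste0("annotation missing column(s): ", paste(miss, collapse = ", ")))
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup)) rlang::abort(paste0("duplicated sample_id in annotation: ", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(ann$site), c("N", "T", "LN"))
  if (length(bad)) rlang::abort(paste0("site must be one of N, T, LN; found: ", paste(bad, collapse = ", ")))
  ann[need]
}

#' Assemble matched N/T/LN trios from sample annotations
#'
#' Pairs each patient case's adjacent non-tumor (N), primary tumor (T) and
#' metastatic lymph node (LN) samples into one trio. Cases missing any of the
#' three sites are dropped with a warning; a case with two samples of the same
#' site is an error (ambiguous pairing).
#'
#' @param ann Sample annotation tibble (`sample_id`, `case_id`, `site`).
#' @param expr Optional expression tibble; if supplied, every annotated sample
#'   must exist among its columns.
#' @return A tibble with columns `case_id`, `n_sample`, `t_sample`,
#'   `ln_sample`, sorted by `case_id`.
#' @export
assemble_trios <- function(ann, expr = NULL) {
  ann <- validate_annotation(ann)
  if (!is.null(expr)) {
    expr <- validate_expression(expr)
    missing_s <- setdiff(ann$sample_id, names(expr)[-1])
    if (length(missing_s)) {
      rlang::abort(paste0("annotated samples absent from expression table: ",
                          paste(missing_s, collapse = ", ")))
    }
  }
  dup_site <- ann |>
    dplyr::count(.data$case_id, .data$site, name = "n_samples") |>
    dplyr::filter(.data$n_samples > 1)
  if (nrow(dup_site)) {
    rlang::abort(sprintf("case '%s' has %d samples of site %s (ambiguous pairing)",
                         dup_site$case_id[1], dup_site$n_samples[1], dup_site$site[1]))
  }
  wide <- ann |>
    tidyr::pivot_wider(names_from = "site", values_from = "sample_id") |>
    dplyr::arrange(.data$case_id)
  for (s in c("N", "T", "LN")) if (!s %in% names(wide)) wide[[s]] <- NA_character_
  incomplete <- wide |>
    dplyr::filter(is.na(.data$N) | is.na(.data$T) | is.na(.data$LN))
  if (nrow(incomplete)) {
    rlang::warn(paste0("excluding case(s) missing a site: ",
                       paste(incomplete$case_id, collapse = ", ")))
  }
  wide |>
    dplyr::filter(!is.na(.data$N), !is.na(.data$T), !is.na(.data$LN)) |>
    dplyr::transmute(case_id = .data$case_id,
                     n_sample = .data$N, t_sample = .data$T, ln_sample = .data$LN)
}

#' Counts-per-million normalization
#'
#' Scales every sample column to sum to one million, putting all samples of a
#' trio on a comparable scale before fold-change classification.
#'
#' @param expr Expression tibble of raw counts.
#' @return Expression tibble on the CPM scale.
#' @export
cpm_normalize <- function(expr) {
  expr <- validate_expression(expr)
  for (s in names(expr)[-1]) {
    tot <- sum(expr[[s]])
    if (tot <= 0) rlang::abort(sprintf("sample '%s' has zero total counts; cannot CPM-normalize", s))
    expr[[s]] <- expr[[s]] / tot * 1e6
  }
  expr
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields tab-separated — set name,
#' description, then member gene IDs. Members are deduplicated, set order is
#' preserved, and duplicated set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description` and a list-column
#'   `genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(set_name = character(), description = character(),
                          genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short)) {
    rlang::abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  out <- tibble::tibble(
    set_name = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  dup <- unique(out$set_name[duplicated(out$set_name)])
  if (length(dup)) rlang::abort(paste0("duplicated gene-set name(s): ", paste(dup, collapse = ", ")))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Gene-set tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}
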