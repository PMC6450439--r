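#' Read gene sets from a GMT file
#'
#' Each line is `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate members within a set are collapsed; member order is
#' otherwise preserved. Gene symbols are matched case-sensitively
#' throughout the package.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per gene set).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    abort(paste0("GMT line(s) with fewer than 3 fields: ",
                 paste(which(short), collapse = ", ")),
          class = "immunopanel_format_error")
  }
  sets <- purrr::map(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (any(lengths(sets) == 0)) {
    abort("gene set with no members", class = "immunopanel_validation_error")
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- purrr::map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-interaction edge list
#'
#' Expects tab-separated columns `gene_a`, `gene_b`, `combined_score`.
#' Scores are either on the unit scale or the 0-1000 STRING-style scale;
#' if the file's maximum score exceeds 1 every score is divided by 1000.
#' Self-loops are dropped and duplicate undirected edges keep the
#' maximum score.
#'
#' @param path Path to a TSV edge list.
#' @return Tibble with `gene_a`, `gene_b`, `combined_score` in `[0, 1]`.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("gene_a", "gene_b", "combined_score")
  if (!all(required %in% names(df))) {
    abort("edge list needs columns gene_a, gene_b, combined_score",
          class = "immunopanel_format_error")
  }
  s <- df$combined_score
  if (any(is.na(s)) || any(s < 0) || any(s > 1000)) {
    abort("combined_score outside [0,1] and [0,1000]",
          class = "immunopanel_validation_error")
  }
  if (max(s) > 1) df$combined_score <- s / 1000
  as_edge_list(df)
}

#' Canonicalise an edge table
#'
#' Orders each pair lexicographically, drops self-loops, and keeps the
#' maximum score among duplicate undirected edges.
#'
#' @param df Data frame with `gene_a`, `gene_b`, `combined_score`.
#' @return Canonical edge tibble.
#' @export
as_edge_list <- function(df) {
  df <- as_tibble(df)
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  tibble(gene_a = a, gene_b = b, combined_score = df$combined_score) |>
    filter(.data$gene_a != .data$gene_b) |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(combined_score = max(.data$combined_score), .groups = "drop")
}

#' Read a cell-type marker map
#'
#' Tab-separated columns `cell_type` and `gene_symbol`, one marker per
#' row. A cell type with two or more markers is flagged `multi_marker`.
#'
#' @param path Path to the TSV.
#' @return Tibble with `cell_type`, `gene_symbol`, `multi_marker`.
#' @export
read_marker_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("cell_type", "gene_symbol") %in% names(df))) {
    abort("marker map needs columns cell_type and gene_symbol",
          class = "immunopanel_format_error")
  }
  df |>
    group_by(.data$cell_type) |>
    mutate(multi_marker = n() >= 2) |>
    ungroup()
}

#' The packaged immune cell-type marker map
#'
#' Marker genes expressed stably and specifically in immune cell types,
#' as used for relative-abundance profiling on mouse immune panels
#' (leukocytes through NK cells; mouse gene symbols).
#'
#' @return Tibble with `cell_type`, `gene_symbol`, `multi_marker`.
#' @export
default_marker_map <- function() {
  read_marker_map(system.file("extdata", "immune_cell_markers.tsv",
                              package = "immunopanel", mustWork = TRUE))
}

#' Phenotype endpoint names
#'
#' Ordinal histopathology scores (0-4) and percent-positive staining
#' endpoints used in the phenotype correlation screen.
#'
#' @export
phenotype_endpoints <- list(
  ordinal = c("lymphoid_aggregates", "ectopic_lymphoid_structures",
              "alveolar_proteinosis", "alveolitis",
              "type2_cell_hyperplasia", "mucus_cell_metaplasia"),
  percent = c("CD3", "CD45R", "CD21_35")
)

#' Read a phenotype table
#'
#' CSV with a `sample_id` column and one column per endpoint. Ordinal
#' endpoints must be non-negative; percent endpoints must lie in
#' `[0, 100]`.
#'
#' @param path Path to the CSV.
#' @return Wide tibble, one row per sample.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param df A phenotype data frame to validate in place.
#' @export
validate_phenotypes <- function(df) {
  df <- as_tibble(df)
  if (!"sample_id" %in% names(df)) {
    abort("phenotype table needs a sample_id column",
          class = "immunopanel_format_error")
  }
  ord <- intersect(names(df), phenotype_endpoints$ordinal)
  pct <- intersect(names(df), phenotype_endpoints$percent)
  for (e in ord) {
    if (any(df[[e]] < 0, na.rm = TRUE)) {
      abort(paste0("ordinal endpoint ", e, " has negative scores"),
            class = "immunopanel_validation_error")
    }
  }
  for (e in pct) {
    if (any(df[[e]] < 0 | df[[e]] > 100, na.rm = TRUE)) {
      abort(paste0("percent endpoint ", e, " outside [0,100]"),
            class = "immunopanel_validation_error")
    }
  }
  df
}

#' Read / write a counts CSV (probes as rows, samples as columns)
#'
#' @param path File path. The first column must be `probe_id`.
#' @return A numeric matrix with probe rownames.
#' @export
read_counts_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "probe_id") {
    abort("first column of a counts CSV must be probe_id",
          class = "immunopanel_format_error")
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- df$probe_id
  m
}

#' @rdname read_counts_csv
#' @param counts Matrix with probe rownames and sample colnames.
#' @export
write_counts_csv <- function(counts, path) {
  df <- as_tibble(counts, rownames = "probe_id")
  readr::write_csv(df, path)
  invisible(path)
}
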