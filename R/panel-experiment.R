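#' Probe classes recognised on a targeted counting panel
#'
#' Panels carry four probe classes: `endogenous` targets of interest,
#' `housekeeping` reference genes used for normalization, `positive`
#' spike-in controls following a known concentration ladder, and
#' `negative` probes measuring non-specific background.
#'
#' @export
probe_classes <- c("endogenous", "housekeeping", "positive", "negative")

#' Validate a panel annotation table
#'
#' A panel annotation maps probes to gene symbols and probe classes.
#' Positive-control probes must carry a strictly positive ladder
#' concentration (fM); other classes leave it as `NA`.
#'
#' @param panel A data frame with columns `probe_id`, `gene_symbol`,
#'   `probe_class`, and `ladder_concentration`.
#' @return The panel as a tibble, invisibly validated.
#' @export
validate_panel <- function(panel) {
  panel <- as_tibble(panel)
  required <- c("probe_id", "gene_symbol", "probe_class", "ladder_concentration")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel annotation is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "immunopanel_format_error")
  }
  if (anyDuplicated(panel$probe_id) > 0) {
    abort("probe_id values must be unique", class = "immunopanel_validation_error")
  }
  bad_class <- setdiff(unique(panel$probe_class), probe_classes)
  if (length(bad_class) > 0) {
    abort(paste0("unknown probe_class: ", paste(bad_class, collapse = ", ")),
          class = "immunopanel_validation_error")
  }
  pos <- panel$probe_class == "positive"
  if (any(pos) && any(is.na(panel$ladder_concentration[pos]) |
                      panel$ladder_concentration[pos] <= 0)) {
    abort("every positive probe needs a ladder_concentration > 0",
          class = "immunopanel_validation_error")
  }
  panel
}

#' Validate a sample metadata table
#'
#' @param samples A data frame with columns `sample_id`, `treatment`
#'   (`VEH` or `cSiO2`), `regimen` (`single` or `four_weekly`),
#'   `time_point` (`day1`, `W1`, `W5`, `W9`, `W13`), `tissue`
#'   (`lung`, `kidney`, `spleen`) and `replicate`.
#' @return The metadata as a tibble.
#' @export
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  required <- c("sample_id", "treatment", "regimen", "time_point", "tissue",
                "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample metadata is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "immunopanel_format_error")
  }
  if (anyDuplicated(samples$sample_id) > 0) {
    abort("sample_id values must be unique", class = "immunopanel_validation_error")
  }
  checks <- list(
    treatment  = c("VEH", "cSiO2"),
    regimen    = c("single", "four_weekly"),
    time_point = c("day1", "W1", "W5", "W9", "W13"),
    tissue     = c("lung", "kidney", "spleen")
  )
  for (col in names(checks)) {
    bad <- setdiff(unique(samples[[col]]), checks[[col]])
    if (length(bad) > 0 || anyNA(samples[[col]])) {
      abort(paste0("invalid ", col, " value: ", paste(bad, collapse = ", ")),
            class = "immunopanel_validation_error")
    }
  }
  samples
}

#' Construct a panel experiment
#'
#' Bundles a probes-by-samples count matrix with its panel annotation and
#' sample metadata, tracking the processing stage (`raw`,
#' `background_subtracted`, or `normalized`). Raw counts must be
#' non-negative integers; later stages hold floats.
#'
#' @param counts Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param panel Panel annotation (see [validate_panel()]).
#' @param samples Sample metadata (see [validate_samples()]).
#' @param stage Processing stage of `counts`.
#' @return An object of class `panel_experiment`.
#' @export
panel_experiment <- function(counts, panel, samples,
                             stage = c("raw", "background_subtracted",
                                       "normalized")) {
  stage <- match.arg(stage)
  panel <- validate_panel(panel)
  samples <- validate_samples(samples)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have probe rownames and sample colnames",
          class = "immunopanel_format_error")
  }
  if (!setequal(rownames(counts), panel$probe_id) ||
      nrow(counts) != nrow(panel)) {
    abort("count matrix rows must match panel probe_ids",
          class = "immunopanel_validation_error")
  }
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples)) {
    abort("count matrix columns must match sample_ids",
          class = "immunopanel_validation_error")
  }
  counts <- counts[panel$probe_id, samples$sample_id, drop = FALSE]
  if (stage == "raw") {
    if (any(counts < 0) || any(counts != round(counts))) {
      abort("raw counts must be non-negative integers",
            class = "immunopanel_validation_error")
    }
  }
  structure(
    list(counts = counts, panel = panel, samples = samples, stage = stage,
         norm_factors = NULL, background = NULL),
    class = "panel_experiment"
  )
}

#' @export
print.panel_experiment <- function(x, ...) {
  cls <- table(factor(x$panel$probe_class, levels = probe_classes))
  cat("<panel_experiment> stage:", x$stage, "\n")
  cat(sprintf("  %d probes (%s) x %d samples\n", nrow(x$counts),
              paste(sprintf("%s %d", names(cls), as.integer(cls)),
                    collapse = ", "),
              ncol(x$counts)))
  invisible(x)
}

#' @export
dim.panel_experiment <- function(x) dim(x$counts)

#' Long-format view of a panel experiment
#'
#' @param x A `panel_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per probe x sample, carrying probe class,
#'   gene symbol and sample metadata.
#' @export
tidy.panel_experiment <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "count")
  long |>
    left_join(x$panel, by = "probe_id") |>
    left_join(x$samples, by = "sample_id")
}

#' Extract counts for one probe class
#'
#' @param x A `panel_experiment`.
#' @param class One of [probe_classes].
#' @return Numeric matrix, probes of that class by samples.
#' @export
class_counts <- function(x, class) {
  stopifnot(inherits(x, "panel_experiment"))
  class <- match.arg(class, probe_classes)
  ids <- x$panel$probe_id[x$panel$probe_class == class]
  x$counts[ids, , drop = FALSE]
}

#' Gene-level expression matrix for endogenous and housekeeping probes
#'
#' Rows are gene symbols (the panel maps each probe to one gene).
#'
#' @param x A `panel_experiment`.
#' @param classes Probe classes to keep.
#' @param log2 If `TRUE`, return `log2(count + pseudocount)`.
#' @param pseudocount Added before the log to guard zero counts.
#' @return Numeric matrix, genes by samples.
#' @export
gene_matrix <- function(x, classes = c("endogenous", "housekeeping"),
                        log2 = FALSE, pseudocount = 0.5) {
  stopifnot(inherits(x, "panel_experiment"))
  keep <- x$panel$probe_class %in% classes
  m <- x$counts[x$panel$probe_id[keep], , drop = FALSE]
  rownames(m) <- x$panel$gene_symbol[keep]
  if (log2) m <- log2(m + pseudocount)
  m
}
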