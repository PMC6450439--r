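#' Read a single-lane RCC file
#'
#' Parses the sectioned comma-separated lane format used by digital
#' count instruments: `<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>` and `<Code_Summary>` sections, the last holding
#' `CodeClass,Name,Accession,Count` rows. Positive-control probe names may
#' carry the ladder concentration as a `Name(conc)` suffix, which is
#' parsed into `ladder_concentration`.
#'
#' @param path Path to one `.rcc` file (one lane / sample).
#' @return A list with `code_summary` (tibble: `probe_id`, `gene_symbol`,
#'   `probe_class`, `ladder_concentration`, `count`), `lane_attributes`
#'   and `sample_attributes` (named character vectors), and `header`.
#' @export
read_rcc <- function(path) {
  lines <- readLines(path)
  sections <- parse_rcc_sections(lines)
  if (is.null(sections$Code_Summary)) {
    abort(paste0("RCC file has no Code_Summary section: ", path),
          class = "immunopanel_format_error")
  }
  cs <- sections$Code_Summary
  header_row <- strsplit(cs[1], ",", fixed = TRUE)[[1]]
  if (!all(c("CodeClass", "Name", "Accession", "Count") %in% header_row)) {
    abort("Code_Summary must have CodeClass,Name,Accession,Count columns",
          class = "immunopanel_format_error")
  }
  body <- strsplit(cs[-1], ",", fixed = TRUE)
  mat <- do.call(rbind, body)
  colnames(mat) <- header_row
  count_chr <- mat[, "Count"]
  if (any(!grepl("^[0-9]+$", count_chr))) {
    abort("non-integer count in Code_Summary",
          class = "immunopanel_format_error")
  }
  name <- mat[, "Name"]
  class_raw <- mat[, "CodeClass"]
  probe_class <- c(Endogenous = "endogenous", Housekeeping = "housekeeping",
                   Positive = "positive", Negative = "negative")[class_raw]
  if (anyNA(probe_class)) {
    abort(paste0("unknown CodeClass: ",
                 paste(unique(class_raw[is.na(probe_class)]), collapse = ", ")),
          class = "immunopanel_format_error")
  }
  ladder <- rep(NA_real_, length(name))
  has_conc <- probe_class == "positive" & grepl("\\(([0-9.eE+-]+)\\)$", name)
  ladder[has_conc] <- as.numeric(sub("^.*\\(([0-9.eE+-]+)\\)$", "\\1",
                                     name[has_conc]))
  gene <- sub("\\(([0-9.eE+-]+)\\)$", "", name)
  list(
    code_summary = tibble(
      probe_id = unname(mat[, "Accession"]),
      gene_symbol = unname(gene),
      probe_class = unname(probe_class),
      ladder_concentration = ladder,
      count = as.integer(count_chr)
    ),
    lane_attributes = rcc_kv(sections$Lane_Attributes),
    sample_attributes = rcc_kv(sections$Sample_Attributes),
    header = rcc_kv(sections$Header)
  )
}

parse_rcc_sections <- function(lines) {
  out <- list()
  open <- regmatches(lines, regexpr("^<([A-Za-z_]+)>$", lines))
  current <- NULL
  for (ln in lines) {
    if (grepl("^<[A-Za-z_]+>$", ln)) {
      current <- gsub("[<>]", "", ln)
      out[[current]] <- character()
    } else if (grepl("^</[A-Za-z_]+>$", ln)) {
      current <- NULL
    } else if (!is.null(current) && nzchar(ln)) {
      out[[current]] <- c(out[[current]], ln)
    }
  }
  out
}

rcc_kv <- function(lines) {
  if (is.null(lines) || length(lines) == 0) return(character())
  parts <- strsplit(lines, ",", fixed = TRUE)
  setNames(vapply(parts, function(p) paste(p[-1], collapse = ","), ""),
           vapply(parts, `[[`, "", 1))
}

#' Write a single-lane RCC file
#'
#' Inverse of [read_rcc()]; the round trip is lossless for counts, probe
#' ids, probe classes, ladder concentrations and lane attributes.
#'
#' @param code_summary Tibble with `probe_id`, `gene_symbol`,
#'   `probe_class`, `ladder_concentration`, `count`.
#' @param path Output path.
#' @param lane_attributes,sample_attributes Named character vectors.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(code_summary, path,
                      lane_attributes = c(ID = "1"),
                      sample_attributes = c(ID = "sample")) {
  cs <- as_tibble(code_summary)
  if (nrow(cs) == 0) {
    abort("cannot write an RCC file with an empty probe set",
          class = "immunopanel_validation_error")
  }
  if (any(cs$count < 0) || any(cs$count != round(cs$count))) {
    abort("RCC counts must be non-negative integers",
          class = "immunopanel_validation_error")
  }
  class_out <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
                 positive = "Positive", negative = "Negative")[cs$probe_class]
  name <- cs$gene_symbol
  pos <- cs$probe_class == "positive" & !is.na(cs$ladder_concentration)
  name[pos] <- sprintf("%s(%g)", cs$gene_symbol[pos],
                       cs$ladder_concentration[pos])
  kv <- function(x) paste(names(x), unname(x), sep = ",")
  lines <- c(
    "<Header>", kv(c(FileVersion = "1.7", SoftwareVersion = "immunopanel")),
    "</Header>",
    "<Sample_Attributes>", kv(sample_attributes), "</Sample_Attributes>",
    "<Lane_Attributes>", kv(lane_attributes), "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste(class_out, name, cs$probe_id, as.integer(cs$count), sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write one RCC file per sample of an experiment
#'
#' @param x A raw-stage `panel_experiment`.
#' @param dir Output directory (created if absent).
#' @return Tibble of `sample_id` and `path`, invisibly.
#' @export
write_rcc_set <- function(x, dir) {
  stopifnot(inherits(x, "panel_experiment"))
  if (x$stage != "raw") {
    abort("RCC files hold raw counts; experiment stage must be 'raw'",
          class = "immunopanel_validation_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(seq_len(ncol(x$counts)), function(i) {
    sid <- colnames(x$counts)[i]
    cs <- x$panel |> mutate(count = as.integer(x$counts[, i]))
    p <- file.path(dir, paste0(sid, ".rcc"))
    write_rcc(cs, p, lane_attributes = c(ID = as.character(i)),
              sample_attributes = c(ID = sid))
    p
  })
  invisible(tibble(sample_id = colnames(x$counts), path = paths))
}

#' Read a directory of RCC lanes into a panel experiment
#'
#' All lanes must share the same probe set. The sample id is taken from
#' each lane's `Sample_Attributes` `ID` field.
#'
#' @param paths Character vector of `.rcc` paths, or a directory.
#' @param samples Sample metadata covering every lane (see
#'   [validate_samples()]).
#' @return A raw-stage `panel_experiment`.
#' @export
read_rcc_set <- function(paths, samples) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.rcc$", full.names = TRUE)
  }
  lanes <- purrr::map(paths, read_rcc)
  panel <- lanes[[1]]$code_summary |> select(-"count")
  counts <- vapply(lanes, function(l) {
    if (!identical(l$code_summary$probe_id, panel$probe_id)) {
      abort("RCC lanes have inconsistent probe sets",
            class = "immunopanel_format_error")
    }
    l$code_summary$count
  }, numeric(nrow(panel)))
  colnames(counts) <- vapply(lanes, function(l) {
    unname(l$sample_attributes[["ID"]])
  }, "")
  rownames(counts) <- panel$probe_id
  panel_experiment(counts, panel, samples, stage = "raw")
}
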