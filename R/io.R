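# Plain-text readers/writers for the pipeline's exchange formats:
# expression TSV (first column gene id, header = sample ids), label TSV,
# GMT classifier sets, pathology TSV and ground-truth JSON.

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#' @param values genes x samples matrix.
#' @param path output file.
#' @export
write_expression_tsv <- function(values, path) {
  # 17 significant digits so doubles round-trip bit-exactly through text
  fmt <- matrix(sprintf("%.17g", values), nrow = nrow(values),
                dimnames = dimnames(values))
  df <- data.frame(gene_id = rownames(values), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv()` returns the genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write and read per-sample label tables
#'
#' Columns: `sample_id`, `cohort`, `label` (0 = NR, 1 = R).
#' @param cohorts list of [expression_cohort()] objects.
#' @param path file path.
#' @export
write_labels_tsv <- function(cohorts, path) {
  df <- do.call(rbind, lapply(cohorts, function(co)
    data.frame(sample_id = colnames(co$values), cohort = co$cohort_id,
               label = unname(co$labels), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then tab-separated gene ids.
#' @param classifiers list of [gene_classifier()] objects.
#' @param path output file.
#' @export
write_gmt <- function(classifiers, path) {
  lines <- vapply(classifiers, function(cl)
    paste(c(cl$name, cl$provenance, cl$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @return `read_gmt()` returns a list of [gene_classifier()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("malformed GMT line in %s: %s", path, ln), call. = FALSE)
    prov <- if (parts[2] %in% c("data-driven", "literature", "top10",
                                "union", "reduced")) parts[2] else "literature"
    gene_classifier(parts[1], parts[-(1:2)], provenance = prov)
  })
}

#' Write and read pathology tables as TSV
#'
#' Columns: `patient_id`, `cohort`, `label`, `os_time`, `os_event`,
#' `pfs_time`, `pfs_event`, then one `<marker>__tumor` and one
#' `<marker>__stroma` column per marker (per-patient means; core replicates
#' are not serialized).
#' @param table a `pathology_table`.
#' @param path file path.
#' @export
write_pathology_tsv <- function(table, path) {
  stopifnot(inherits(table, "pathology_table"))
  fmt <- function(m) {
    out <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  tum <- table$tumor; colnames(tum) <- paste0(colnames(tum), "__tumor")
  str <- table$stroma; colnames(str) <- paste0(colnames(str), "__stroma")
  pat <- table$patients
  for (cl in c("os_time", "pfs_time")) pat[[cl]] <- sprintf("%.17g", pat[[cl]])
  df <- cbind(pat, fmt(tum), fmt(str))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathology_tsv
#' @export
read_pathology_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  clin_cols <- c("patient_id", "cohort", "label", "os_time", "os_event",
                 "pfs_time", "pfs_event")
  tum_cols <- grep("__tumor$", names(df), value = TRUE)
  str_cols <- grep("__stroma$", names(df), value = TRUE)
  tum <- as.matrix(df[, tum_cols, drop = FALSE])
  colnames(tum) <- sub("__tumor$", "", tum_cols)
  rownames(tum) <- df$patient_id
  str <- as.matrix(df[, str_cols, drop = FALSE])
  colnames(str) <- sub("__stroma$", "", str_cols)
  rownames(str) <- df$patient_id
  pathology_table(tum, str, df[, clin_cols], data_type = "raw")
}

#' Write a complete synthetic fixture to a directory
#'
#' Writes per-cohort expression TSVs, a combined label TSV, classifier GMT
#' files (when given), a pathology TSV and a ground-truth JSON. Everything
#' round-trips losslessly through the module readers.
#'
#' @param cohorts list of [expression_cohort()] objects (or NULL).
#' @param pathology a `pathology_table` (or NULL).
#' @param out_dir output directory (created if needed).
#' @param classifiers optional list of [gene_classifier()] objects.
#' @param ground_truth optional list serialized to `ground_truth.json`.
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(cohorts = NULL, pathology = NULL, out_dir,
                          classifiers = NULL, ground_truth = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  written <- character(0)
  if (!is.null(cohorts)) {
    for (co in cohorts) {
      p <- file.path(out_dir, sprintf("expr_%s.tsv", co$cohort_id))
      write_expression_tsv(co$values, p)
      written <- c(written, p)
    }
    p <- file.path(out_dir, "labels.tsv")
    write_labels_tsv(cohorts, p)
    written <- c(written, p)
  }
  if (!is.null(classifiers)) {
    p <- file.path(out_dir, "classifiers.gmt")
    write_gmt(classifiers, p)
    written <- c(written, p)
  }
  if (!is.null(pathology)) {
    p <- file.path(out_dir, "pathology.tsv")
    write_pathology_tsv(pathology, p)
    written <- c(written, p)
  }
  if (!is.null(ground_truth)) {
    p <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read cohorts back from a fixture directory
#'
#' @param dir directory written by [write_fixture()].
#' @return list of [expression_cohort()] objects.
#' @export
read_fixture_cohorts <- function(dir) {
  labels <- read_labels_tsv(file.path(dir, "labels.tsv"))
  files <- sort(list.files(dir, pattern = "^expr_.*\\.tsv$", full.names = TRUE))
  lapply(files, function(f) {
    cid <- sub("^expr_(.*)\\.tsv$", "\\1", basename(f))
    m <- read_expression_tsv(f)
    lab <- labels$label[match(colnames(m), labels$sample_id)]
    expression_cohort(m, lab, cid)
  })
}
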