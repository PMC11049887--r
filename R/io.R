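# Tabular I/O: the study bundle container, TSV readers/writers with
# validation, gene lists and external study summaries. All files are UTF-8,
# tab-delimited, "." decimal, with a mandatory header row; matrices carry
# probe_id as their first column.

#' Construct and validate a study bundle
#'
#' The study bundle is the unit the pipeline operates on: a probe x sample
#' expression matrix (log-intensity scale, no missing values), an optional
#' probe x sample detection p-value matrix, a sample metadata table and a
#' probe annotation table. All type invariants are enforced here, so a
#' bundle that exists is a bundle that is valid.
#'
#' @param expression numeric matrix, probes x samples, with dimnames.
#' @param samples data.frame with columns sample_id, pair_id, zygosity
#'   (MZ/DZ, case-insensitive), age, sex (F/M), batch, rin, wbc.
#' @param annotation data.frame with columns probe_id, gene_symbol,
#'   ensembl_id, chromosome, gc_percent, gene_length.
#' @param detection optional numeric matrix in [0,1] with the same dimnames
#'   as `expression`.
#' @return object of class `study_bundle`.
#' @export
study_bundle <- function(expression, samples, annotation, detection = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression matrix must have probe and sample names", call. = FALSE)
  dup <- rownames(expression)[duplicated(rownames(expression))]
  if (length(dup))
    stop("duplicated probe id(s) in expression: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- colnames(expression)[duplicated(colnames(expression))]
  if (length(dup))
    stop("duplicated sample id(s) in expression: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!is.finite(expression)))
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)

  samples <- validate_samples(samples)
  missing_meta <- setdiff(colnames(expression), samples$sample_id)
  if (length(missing_meta))
    stop("sample(s) in expression but absent from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s) in metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  # align metadata to expression column order, dropping unused rows
  samples <- samples[match(colnames(expression), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL

  annotation <- validate_annotation(annotation)
  missing_annot <- setdiff(rownames(expression), annotation$probe_id)
  if (length(missing_annot))
    stop("probe(s) in expression but absent from annotation: ",
         paste(missing_annot, collapse = ", "), call. = FALSE)
  annotation <- annotation[match(rownames(expression), annotation$probe_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL

  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dimnames(detection), dimnames(expression)))
      stop("detection matrix must have identical probe and sample ids as expression",
           call. = FALSE)
    if (any(!is.finite(detection)) || any(detection < 0) || any(detection > 1))
      stop("detection p-values must all lie in [0, 1]", call. = FALSE)
  }

  structure(list(expression = expression, detection = detection,
                 samples = samples, annotation = annotation),
            class = "study_bundle")
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "pair_id", "zygosity", "age", "sex", "batch",
            "rin", "wbc")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples$zygosity <- toupper(as.character(samples$zygosity))
  bad <- unique(samples$zygosity[!samples$zygosity %in% c("MZ", "DZ")])
  if (length(bad))
    stop("invalid zygosity label(s): ", paste(bad, collapse = ", "),
         " (must be MZ or DZ)", call. = FALSE)
  samples$sex <- toupper(as.character(samples$sex))
  bad <- unique(samples$sex[!samples$sex %in% c("F", "M")])
  if (length(bad))
    stop("invalid sex label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (col in c("age", "rin", "wbc")) {
    samples[[col]] <- as.numeric(samples[[col]])
    if (any(!is.finite(samples[[col]])))
      stop("missing or non-numeric values in covariate column '", col, "'",
           call. = FALSE)
  }
  if (any(samples$rin < 0))
    stop("rin must be >= 0", call. = FALSE)
  tab <- table(samples$pair_id)
  over <- names(tab)[tab > 2L]
  if (length(over))
    stop("pair_id with more than 2 members: ", paste(over, collapse = ", "),
         call. = FALSE)
  zyg_per_pair <- tapply(samples$zygosity, samples$pair_id,
                         function(z) length(unique(z)))
  mixed <- names(zyg_per_pair)[zyg_per_pair > 1L]
  if (length(mixed))
    stop("pair(s) with discordant zygosity labels: ",
         paste(mixed, collapse = ", "), call. = FALSE)
  samples
}

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "ensembl_id", "chromosome",
            "gc_percent", "gene_length")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- annotation$probe_id[duplicated(annotation$probe_id)]
  if (length(dup))
    stop("duplicated probe id(s) in annotation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  annotation$gc_percent <- as.numeric(annotation$gc_percent)
  annotation$gene_length <- as.numeric(annotation$gene_length)
  ok_gc <- is.na(annotation$gc_percent) |
    (annotation$gc_percent >= 0 & annotation$gc_percent <= 100)
  if (!all(ok_gc))
    stop("gc_percent outside [0, 100] for probe(s): ",
         paste(annotation$probe_id[!ok_gc], collapse = ", "), call. = FALSE)
  ok_len <- is.na(annotation$gene_length) | annotation$gene_length > 0
  if (!all(ok_len))
    stop("gene_length must be positive for probe(s): ",
         paste(annotation$probe_id[!ok_len], collapse = ", "), call. = FALSE)
  annotation
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Study bundle:", nrow(x$expression), "probes x", ncol(x$expression),
      "samples;", sum(x$samples$zygosity == "MZ") / 2, "MZ and",
      sum(x$samples$zygosity == "DZ") / 2, "DZ pairs",
      if (is.null(x$detection)) "(no detection matrix)" else "", "\n")
  invisible(x)
}

read_matrix_tsv <- function(path, what = "matrix") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(what, " file must have probe_id plus at least one sample column: ",
         path, call. = FALSE)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated probe row(s) in ", what, " file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Load a study from tab-delimited files
#'
#' @param expr_path TSV of the expression matrix, first column `probe_id`.
#' @param samples_path TSV of sample metadata.
#' @param annot_path TSV of probe annotation.
#' @param detect_path optional TSV of detection p-values, same layout as the
#'   expression matrix.
#' @return a validated [study_bundle()].
#' @export
load_study <- function(expr_path, samples_path, annot_path,
                       detect_path = NULL) {
  expression <- read_matrix_tsv(expr_path, "expression")
  samples <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  annotation <- utils::read.delim(annot_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE,
                                  colClasses = c(chromosome = "character"))
  detection <- if (!is.null(detect_path))
    read_matrix_tsv(detect_path, "detection") else NULL
  study_bundle(expression, samples, annotation, detection)
}

#' Write pipeline result tables
#'
#' Writes each element of `results` (data.frames) as `<name>.tsv` under
#' `out_dir`, tab-delimited with a header, floats at 8 significant digits
#' so a write/read round-trip reproduces values at that precision.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 8))
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write to ", path, call. = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a study bundle (and optionally its truth table) as TSV files
#'
#' Emits expression.tsv, samples.tsv, annotation.tsv and, when present,
#' detection.tsv and truth_table.tsv.
#'
#' @param bundle a [study_bundle()].
#' @param out_dir output directory.
#' @param truth optional truth table from [simulate_study()].
#' @return invisibly, the paths written.
#' @export
write_study <- function(bundle, out_dir, truth = NULL) {
  stopifnot(inherits(bundle, "study_bundle"))
  mat_df <- function(m) data.frame(probe_id = rownames(m), signif(m, 8),
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
  out <- list(expression = mat_df(bundle$expression),
              samples = bundle$samples,
              annotation = bundle$annotation)
  if (!is.null(bundle$detection)) out$detection <- mat_df(bundle$detection)
  if (!is.null(truth)) out$truth_table <- truth
  write_results(out, out_dir)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and `#` comment lines are skipped.
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read an external study heritability summary
#'
#' Expects a TSV with columns `ensembl_id`, `h2`, `pvalue`. When a gene
#' appears several times (multiple transcripts), the record with the
#' highest h2 is kept, mirroring the max-probe gene rule; the drop count
#' is logged.
#'
#' @param path TSV path.
#' @param study_label label for this cohort.
#' @param log optional provenance log.
#' @return object of class `study_summary`: `label` plus a data.frame with
#'   ensembl_id (version-stripped), h2, pvalue.
#' @export
read_study_summary <- function(path, study_label, log = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  study_summary(df, study_label, log = log)
}

#' @rdname read_study_summary
#' @param df data.frame with columns ensembl_id, h2, pvalue.
#' @export
study_summary <- function(df, study_label, log = NULL) {
  need <- c("ensembl_id", "h2", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("study summary lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  df$ensembl_id <- strip_ensembl_version(df$ensembl_id)
  if (any(!is.finite(df$h2)) || any(df$h2 < 0 | df$h2 > 1))
    stop("h2 values must be finite and in [0, 1]", call. = FALSE)
  if (any(!is.finite(df$pvalue)) || any(df$pvalue <= 0 | df$pvalue > 1))
    stop("p-values must be finite and in (0, 1]", call. = FALSE)
  n0 <- nrow(df)
  # keep the highest-h2 record per gene
  df <- df[order(df$ensembl_id, -df$h2, df$pvalue), ]
  df <- df[!duplicated(df$ensembl_id), ]
  rownames(df) <- NULL
  if (nrow(df) < n0)
    log_line(log, "study ", study_label, ": kept best of ", n0, " records for ",
             nrow(df), " genes (", n0 - nrow(df), " duplicates dropped)")
  structure(list(label = study_label, table = df), class = "study_summary")
}

strip_ensembl_version <- function(ids) toupper(sub("\\.\\d+$", "", ids))

# Minimal flat config parser: one "key: value" or "key = value" per line,
# "#" comments, values coerced to numeric where possible. There is no YAML
# parser in the supported runtime; this covers the flat dialect the CLI
# documents.
read_config <- function(path, allowed_keys) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    key <- m[2]
    val <- trimws(m[3])
    if (!key %in% allowed_keys)
      stop("unknown config key: '", key, "' (allowed: ",
           paste(allowed_keys, collapse = ", "), ")", call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}
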