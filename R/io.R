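# Canonical on-disk dialect for every tabular artifact: TSV, UTF-8, no quoting.
# Gene and sample identifiers are opaque, case-sensitive symbols; missing
# severity scores are written as the literal "NA" to distinguish ungraded
# samples from score zero.

#' Validate a count matrix
#'
#' Checks the structural contract of a gene-by-sample count matrix: an integer
#' (or integer-valued numeric) matrix with unique, non-empty gene and sample
#' identifiers and no negative entries.
#'
#' @param counts Matrix of counts, genes in rows, samples in columns.
#' @return The validated matrix, invisibly, with integer storage mode.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifier: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifier: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (anyNA(counts)) stop("counts contain missing values")
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 rownames(counts)[bad[1L, 1L]],
                 colnames(counts)[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read and write count matrices
#'
#' A count matrix is stored as TSV with genes as rows: the first column,
#' `gene_id`, holds gene identifiers and the header row holds sample
#' identifiers. Readers reject (rather than coerce) malformed input, naming
#' the offending cell; `read_counts(write_counts(x))` is the identity.
#'
#' @param path Path to a TSV file.
#' @return For `read_counts`, an integer matrix with gene rownames and sample
#'   colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count file must have a gene_id column and >= 1 sample")
  if (names(df)[1L] != "gene_id") stop("first column must be named 'gene_id'")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifier in ", path, ": ",
         genes[duplicated(genes)][1L])
  samples <- names(df)[-1L]
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric count at gene '%s', sample '%s': '%s'",
                   genes[bad], samples[j], col[bad]))
    }
    m[, j] <- col
  }
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Matrix of counts, genes in rows, samples in columns.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write expression matrices
#'
#' Same TSV layout as count matrices but with real-valued (log2-like scale)
#' entries, e.g. variance-stabilized expression.
#'
#' @param path Path to a TSV file.
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @return For `read_expression`, a numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be named 'gene_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("expression values must be finite numbers")
  m
}

#' @rdname read_expression
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (any(!is.finite(expr))) stop("expression values must be finite")
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Per-sample covariates used throughout the pipeline: `sample_id`, `batch`
#' (categorical), `sex` (binary categorical), `species` (`human`/`mouse`),
#' `nas` (integer 0-8 or NA), `fibrosis` (integer 0-4 or NA) and `group`
#' (free label, e.g. diet-week).
#'
#' @param samples Data frame of sample metadata.
#' @param counts Optional paired count matrix; sample identifiers must match
#'   its columns exactly (same order).
#' @return The validated data frame, invisibly.
#' @export
validate_sample_table <- function(samples, counts = NULL) {
  required <- c("sample_id", "batch", "sex", "species", "nas", "fibrosis", "group")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L)
    stop("sample table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (!all(samples$species %in% c("human", "mouse")))
    stop("species must be 'human' or 'mouse'")
  ok_range <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi & x == floor(x)))
  if (!ok_range(samples$nas, 0, 8)) stop("nas must be an integer in [0, 8] or NA")
  if (!ok_range(samples$fibrosis, 0, 4)) stop("fibrosis must be an integer in [0, 4] or NA")
  if (!is.null(counts)) {
    if (!identical(as.character(samples$sample_id), colnames(counts)))
      stop("sample_id must match the count matrix columns exactly")
  }
  invisible(samples)
}

#' Read and write sample metadata tables
#'
#' @param path Path to a TSV file with one row per sample.
#' @param samples Data frame as described in [validate_sample_table()].
#' @return For `read_sample_table`, a data frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  df$nas <- as.integer(df$nas)
  df$fibrosis <- as.integer(df$fibrosis)
  validate_sample_table(df)
  df
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' one or more member genes. Member order is preserved and the pair of
#' functions round-trips exactly.
#'
#' @param path Path to a GMT file.
#' @return For `read_gmt`, a named list of character vectors; each element
#'   carries its description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)))
    members <- fields[-(1:2)]
    attr(members, "description") <- fields[2L]
    sets[[fields[1L]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (gene sets), or a
#'   `gene_signature` object (written as one set named `MASLD_UNIFIED`).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_signature")) {
    sig <- sets
    sets <- list(MASLD_UNIFIED = sig$gene)
    attr(sets[["MASLD_UNIFIED"]], "description") <-
      "severity-associated unified human-mouse signature"
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    members <- sets[[nm]]
    if (length(members) == 0L) stop("gene set '", nm, "' has no members")
    desc <- attr(members, "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, as.character(members)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ortholog mapping table
#'
#' TSV with columns `human_gene` and `mouse_gene`. Duplicated pairs are
#' collapsed; the `one_to_one` flag marks pairs where the human gene maps to
#' exactly one mouse gene and vice versa.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `human_gene`, `mouse_gene`, `one_to_one`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("human_gene", "mouse_gene"), names(df))
  if (length(missing_cols) > 0L)
    stop("ortholog map missing column(s): ", paste(missing_cols, collapse = ", "))
  ortholog_map(df$human_gene, df$mouse_gene)
}

#' Construct an ortholog map from paired gene vectors
#'
#' @param human_gene,mouse_gene Character vectors of equal length giving
#'   ortholog pairs.
#' @return Data frame with columns `human_gene`, `mouse_gene`, `one_to_one`.
#' @export
ortholog_map <- function(human_gene, mouse_gene) {
  stopifnot(length(human_gene) == length(mouse_gene))
  df <- unique(data.frame(human_gene = as.character(human_gene),
                          mouse_gene = as.character(mouse_gene),
                          stringsAsFactors = FALSE))
  h_deg <- table(df$human_gene)
  m_deg <- table(df$mouse_gene)
  df$one_to_one <- as.vector(h_deg[df$human_gene] == 1L &
                             m_deg[df$mouse_gene] == 1L)
  rownames(df) <- NULL
  df
}

#' @rdname read_ortholog_map
#' @param orth Ortholog map data frame.
#' @export
write_ortholog_map <- function(orth, path) {
  stopifnot(all(c("human_gene", "mouse_gene") %in% names(orth)))
  utils::write.table(orth[, c("human_gene", "mouse_gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Timestamped log line on standard error; used by the pipeline driver.
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}
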