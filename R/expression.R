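#' Expression tables
#'
#' An expression table is a tibble whose first column, `gene_id`, holds unique
#' gene identifiers and whose remaining columns are numeric per-sample
#' expression values. The attribute `is_log2` records whether values are on
#' the log2 scale; loaders always start on the raw (non-negative) scale and
#' [log2_transform()] flips the flag. All pipeline stages accept this shape.
#'
#' @param x A data frame (first column gene IDs) or a numeric matrix with
#'   rownames as gene IDs.
#' @param is_log2 Logical scalar: are the values already log2-transformed?
#' @return A tibble of class `icp_expr` with attribute `is_log2`.
#' @examples
#' m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' as_expr(m)
#' @export
as_expr <- function(x, is_log2 = FALSE) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene IDs as rownames")
    x <- tibble::as_tibble(x, rownames = "gene_id")
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort("expression table needs a gene column and >=1 sample")
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene IDs: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(names(x)[-1])) abort("duplicate sample IDs in header")
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    abort("all sample columns must be numeric")
  }
  structure(x, is_log2 = isTRUE(is_log2),
            class = c("icp_expr", class(tibble::tibble())))
}

#' @rdname as_expr
#' @export
is_log2 <- function(x) isTRUE(attr(x, "is_log2"))

#' Extract the numeric genes-by-samples matrix of an expression table
#'
#' @param x An expression table (see [as_expr()]).
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

sample_ids <- function(x) names(x)[-1]

#' Read an expression matrix from a delimited text file
#'
#' Expects gene IDs in the first column and a header row of sample IDs.
#' Values must be non-negative raw-scale expression; transform afterwards
#' with [log2_transform()].
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @return An `icp_expr` table with `is_log2 = FALSE`.
#' @export
load_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort("parse error: empty or header-only expression file")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  width <- lengths(fields)
  # header may omit the gene-ID column name
  body_w <- width[-1]
  if (length(unique(body_w)) != 1L) {
    bad <- which(body_w != body_w[1])[1] + 1L
    abort(paste0("parse error: ragged row at line ", bad))
  }
  header <- fields[[1]]
  samples <- if (length(header) == body_w[1]) header[-1] else header
  if (length(samples) != body_w[1] - 1L) {
    abort("parse error: header width does not match data rows")
  }
  genes <- vapply(fields[-1], `[[`, character(1), 1L)
  vals <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(fields[-1], `[`, -1L)))),
    nrow = length(genes), byrow = TRUE,
    dimnames = list(genes, samples)
  )
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1] + 1L
    abort(paste0("parse error: non-numeric value at line ", bad))
  }
  if (any(vals < 0)) abort("raw expression values must be non-negative")
  as_expr(vals, is_log2 = FALSE)
}

#' Write an expression table to TSV
#'
#' @param x An expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Log2-transform an expression table
#'
#' Replaces each value by `log2(value + pseudocount)` and flips the
#' `is_log2` flag. Transforming twice is refused.
#'
#' @param x Raw-scale expression table.
#' @param pseudocount Offset added before taking logs (default 1, so zeros
#'   map to zero).
#' @return Log2-scale expression table.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (is_log2(x)) abort("expression is already log2-transformed")
  m <- expr_values(x)
  if (any(m < 0)) abort("raw values must be non-negative before log2")
  as_expr(log2(m + pseudocount), is_log2 = TRUE)
}

#' Drop genes not expressed in most samples
#'
#' A gene is removed when its fraction of zero-valued (raw-scale) samples is
#' strictly greater than `max_zero_fraction`. "Not expressed" means a raw
#' value of exactly zero by default; `epsilon` relaxes this to `value <=
#' epsilon`.
#'
#' @param x Raw-scale expression table.
#' @param max_zero_fraction Maximum tolerated zero fraction (default 0.70).
#' @param epsilon Values at or below this count as unexpressed (default 0).
#' @return Filtered expression table, gene order preserved.
#' @export
filter_low_expressed <- function(x, max_zero_fraction = 0.70, epsilon = 0) {
  if (is_log2(x)) abort("filter on the raw scale, before log2_transform()")
  m <- expr_values(x)
  frac0 <- rowMeans(m <= epsilon)
  keep <- frac0 <= max_zero_fraction
  if (!any(keep)) abort("all genes removed by the expression filter")
  as_expr(m[keep, , drop = FALSE], is_log2 = FALSE)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `group` (tumor/normal), `purity`
#' (in \[0,1\] or NA), `os_time`, `os_event`, `cancer_type`. Missing optional
#' columns are filled with NA.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with the canonical metadata columns.
#' @export
load_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("metadata needs at least sample_id and group columns")
  }
  for (col in c("purity", "os_time", "os_event", "cancer_type")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if (!all(meta$group %in% c("tumor", "normal"))) {
    abort("group must be 'tumor' or 'normal'")
  }
  ok <- is.na(meta$purity) | (meta$purity >= 0 & meta$purity <= 1)
  if (!all(ok)) abort("purity must lie in [0, 1] where present")
  meta
}

#' Align an expression table with sample metadata
#'
#' Samples present in the expression table but absent from the metadata are
#' dropped with a warning; samples in the metadata without expression are
#' ignored. Returns both objects restricted to the shared samples, in
#' expression-column order.
#'
#' @param expr An expression table.
#' @param meta A metadata tibble (see [load_metadata()]).
#' @return A list with elements `expr` and `meta`.
#' @export
align_samples <- function(expr, meta) {
  meta <- validate_metadata(meta)
  ids <- sample_ids(expr)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing) > 0L) {
    warn(paste0(length(missing), " expression sample(s) absent from metadata dropped: ",
                paste(head(missing, 5), collapse = ", ")))
    ids <- setdiff(ids, missing)
  }
  if (length(ids) == 0L) abort("no samples shared between expression and metadata")
  expr2 <- as_expr(expr_values(expr)[, ids, drop = FALSE], is_log2 = is_log2(expr))
  meta2 <- meta[match(ids, meta$sample_id), , drop = FALSE]
  list(expr = expr2, meta = meta2)
}

#' Build or read a gene role catalog
#'
#' Every gene carries exactly one role: `lncRNA`, `immune`, or `ICP`. When a
#' gene appears in more than one source list, the ICP role takes precedence
#' (checkpoint membership is the rarer, curated annotation).
#'
#' @param lncRNA,immune,icp Character vectors of gene IDs.
#' @return A tibble with columns `gene_id`, `role`.
#' @export
gene_catalog <- function(lncRNA = character(), immune = character(),
                         icp = character()) {
  icp <- unique(icp)
  immune <- setdiff(unique(immune), icp)
  lncRNA <- setdiff(unique(lncRNA), c(icp, immune))
  tibble::tibble(
    gene_id = c(lncRNA, immune, icp),
    role = c(rep("lncRNA", length(lncRNA)),
             rep("immune", length(immune)),
             rep("ICP", length(icp)))
  )
}

#' @rdname gene_catalog
#' @param path TSV with columns `gene_id`, `role`.
#' @export
load_gene_catalog <- function(path) {
  cat_tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "role") %in% names(cat_tbl))) {
    abort("catalog needs gene_id and role columns")
  }
  if (!all(cat_tbl$role %in% c("lncRNA", "immune", "ICP"))) {
    abort("role must be one of lncRNA, immune, ICP")
  }
  gene_catalog(lncRNA = cat_tbl$gene_id[cat_tbl$role == "lncRNA"],
               immune = cat_tbl$gene_id[cat_tbl$role == "immune"],
               icp = cat_tbl$gene_id[cat_tbl$role == "ICP"])
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate genes within a set are dropped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors.
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("parse error: empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(paste0("parse error: GMT line ", short[1], " has fewer than 3 fields"))
  }
  sets <- lapply(fields, function(f) f[-c(1, 2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  ndup <- vapply(sets, anyDuplicated, integer(1))
  if (any(ndup > 0)) {
    warn(paste0("duplicate genes dropped within set(s): ",
                paste(names(sets)[ndup > 0], collapse = ", ")))
    sets <- lapply(sets, unique)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field for every set.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
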