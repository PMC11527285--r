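#' Construct an expression matrix
#'
#' Container for a genes-by-samples matrix of log-scale expression values.
#' Gene and sample identifiers must be unique, dimensions must agree and all
#' values must be finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param sample_ids character vector of unique sample identifiers (columns).
#' @param platform_tag one of `"single_cell"`, `"bulk_rnaseq"`, `"microarray"`,
#'   `"synthetic"`.
#' @param normalization_tag free-form string describing the normalization
#'   applied (e.g. `"log2_tpm"`).
#' @return An object of class `expr_matrix` with fields `gene_ids`,
#'   `sample_ids`, `values`, `platform_tag`, `normalization_tag`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              platform_tag = c("synthetic", "single_cell",
                                               "bulk_rnaseq", "microarray"),
                              normalization_tag = "unknown") {
  platform_tag <- match.arg(platform_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("dimension mismatch: values is ", nrow(values), "x", ncol(values),
         " but there are ", length(gene_ids), " gene ids and ",
         length(sample_ids), " sample ids")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite value in expression matrix (NaN/Inf not allowed)")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 values = values, platform_tag = platform_tag,
                 normalization_tag = normalization_tag),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples [", x$platform_tag, ", ",
      x$normalization_tag, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# internal: subset an expr_matrix by gene / sample index keeping order
em_subset <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, rownames(v), colnames(v), m$platform_tag,
                    m$normalization_tag)
}

#' Construct a labelled expression dataset
#'
#' Bundles an [expression_matrix()] with per-sample binary condition labels
#' (0 = control, 1 = case) and optional cell-type, subject and cohort
#' annotations.
#'
#' @param matrix an `expr_matrix`.
#' @param labels integer/numeric vector of 0/1, one per sample.
#' @param cell_type,subject_id,cohort_id optional per-sample character vectors.
#' @return An object of class `labelled_dataset`.
#' @export
labelled_dataset <- function(matrix, labels, cell_type = NULL,
                             subject_id = NULL, cohort_id = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  labels <- as.integer(labels)
  n <- length(matrix$sample_ids)
  if (length(labels) != n)
    stop("labels length (", length(labels), ") != number of samples (", n, ")")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  chk <- function(v, nm) {
    if (is.null(v)) return(NULL)
    if (length(v) != n) stop(nm, " length != number of samples")
    as.character(v)
  }
  structure(list(matrix = matrix, labels = labels,
                 cell_type = chk(cell_type, "cell_type"),
                 subject_id = chk(subject_id, "subject_id"),
                 cohort_id = chk(cohort_id, "cohort_id")),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat("<labelled_dataset> ", length(x$matrix$gene_ids), " genes x ",
      length(x$labels), " samples (", sum(x$labels == 1L), " case / ",
      sum(x$labels == 0L), " control)\n", sep = "")
  invisible(x)
}

# internal: subset a labelled_dataset by sample index
ds_subset <- function(d, idx) {
  labelled_dataset(em_subset(d$matrix, samples = idx), d$labels[idx],
                   if (!is.null(d$cell_type)) d$cell_type[idx],
                   if (!is.null(d$subject_id)) d$subject_id[idx],
                   if (!is.null(d$cohort_id)) d$cohort_id[idx])
}

#' Read an expression matrix from disk
#'
#' Dense TSV/CSV matrices carry sample ids in the header row and gene ids in
#' the first column (or the transpose, with `orientation =
#' "samples_by_genes"`). MatrixMarket (`mtx`) input is a coordinate triplet
#' file with `genes.tsv` / `barcodes.tsv` sidecars (first column of each used
#' as identifiers). The returned matrix is always genes-by-samples.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param orientation layout of a dense file on disk.
#' @param genes_path,barcodes_path sidecar paths for `format = "mtx"`;
#'   default to `genes.tsv` / `barcodes.tsv` next to `path`.
#' @param platform_tag,normalization_tag tags stored on the result.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            orientation = c("genes_by_samples",
                                            "samples_by_genes"),
                            genes_path = NULL, barcodes_path = NULL,
                            platform_tag = "synthetic",
                            normalization_tag = "unknown") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(genes_path)) stop("missing gene sidecar: ", genes_path)
    if (!file.exists(barcodes_path))
      stop("missing barcode sidecar: ", barcodes_path)
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e)))
    vals <- as.matrix(mm)
    genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                               colClasses = "character")[[1]]
    cells <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                               colClasses = "character")[[1]]
    if (length(genes) != nrow(vals))
      stop("gene sidecar has ", length(genes), " entries but matrix has ",
           nrow(vals), " rows")
    if (length(cells) != ncol(vals))
      stop("barcode sidecar has ", length(cells), " entries but matrix has ",
           ncol(vals), " columns")
    rownames(vals) <- genes
    colnames(vals) <- cells
  } else {
    sep <- if (format == "tsv") "\t" else ","
    nf <- utils::count.fields(path, sep = sep, quote = "\"")
    if (length(unique(nf[!is.na(nf)])) > 1) {
      bad <- which(nf != nf[1])[1]
      stop("parse error in ", path, ": line ", bad, " has ", nf[bad],
           " fields, expected ", nf[1])
    }
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, quote = "\"",
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("parse error in ", path,
                                ": non-numeric cells in matrix body")
    rownames(vals) <- ids
    if (orientation == "samples_by_genes") vals <- t(vals)
  }
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("NaN/Inf cell in ", path)
  expression_matrix(vals, rownames(vals), colnames(vals),
                    platform_tag = platform_tag,
                    normalization_tag = normalization_tag)
}

#' Write an expression matrix as TSV
#'
#' Header row holds sample ids, first column (named `gene_id`) the gene ids.
#' Values are formatted with enough digits to round-trip through
#' [read_expression()] to better than 1e-9.
#'
#' @param m an `expr_matrix`.
#' @param path output path.
#' @param digits significant digits used for formatting (default 12).
#' @export
write_expression <- function(m, path, digits = 12) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = m$gene_ids,
                   signif(m$values, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter sparse samples and genes
#'
#' Removes samples in which fewer than `min_gene_fraction` of genes are
#' recorded (strictly positive), then genes recorded in fewer than
#' `min_cell_fraction` of the retained samples. Both thresholds default to
#' 0.20. Row/column order of survivors is preserved and the operation is
#' idempotent.
#'
#' @param m an `expr_matrix`.
#' @param min_gene_fraction minimum fraction of recorded genes a sample must
#'   have to be kept.
#' @param min_cell_fraction minimum fraction of retained samples in which a
#'   gene must be recorded to be kept.
#' @return Filtered `expr_matrix`.
#' @export
filter_matrix <- function(m, min_gene_fraction = 0.2,
                          min_cell_fraction = 0.2) {
  stopifnot(inherits(m, "expr_matrix"),
            min_gene_fraction >= 0, min_gene_fraction <= 1,
            min_cell_fraction >= 0, min_cell_fraction <= 1)
  pos <- m$values > 0
  keep_s <- colMeans(pos) >= min_gene_fraction
  if (!any(keep_s)) stop("filter removed all samples")
  keep_g <- rowMeans(pos[, keep_s, drop = FALSE]) >= min_cell_fraction
  if (!any(keep_g)) stop("filter removed all genes")
  em_subset(m, genes = which(keep_g), samples = which(keep_s))
}

#' Log-scale normalization of a count matrix
#'
#' `log2_tpm` rescales counts to per-kilobase rates, normalizes each sample to
#' one million, then applies `log2(x + 1)`; `log2_cpm` does the same without
#' the length correction; `passthrough` asserts values are already log-scale
#' (finite, non-negative) and only re-tags the matrix.
#'
#' @param m an `expr_matrix` of non-negative counts (or log values for
#'   passthrough).
#' @param gene_lengths named (or positionally ordered) positive lengths in
#'   base pairs, required for `log2_tpm`.
#' @param mode `"log2_tpm"`, `"log2_cpm"` or `"passthrough"`.
#' @return Normalized `expr_matrix` with `normalization_tag` set.
#' @export
log_normalize <- function(m, gene_lengths = NULL,
                          mode = c("log2_tpm", "log2_cpm", "passthrough")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  if (any(v < 0))
    stop("negative value found; ", mode, " requires non-negative input")
  if (mode == "passthrough") {
    m$normalization_tag <- "passthrough_log"
    return(m)
  }
  if (mode == "log2_tpm") {
    if (is.null(gene_lengths)) stop("gene_lengths required for log2_tpm")
    if (!is.null(names(gene_lengths))) {
      missing <- setdiff(m$gene_ids, names(gene_lengths))
      if (length(missing))
        stop("missing gene length for: ", missing[1])
      gene_lengths <- gene_lengths[m$gene_ids]
    }
    if (length(gene_lengths) != length(m$gene_ids))
      stop("gene_lengths must cover every gene (got ", length(gene_lengths),
           " for ", length(m$gene_ids), " genes)")
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene lengths must be positive and finite")
    v <- v / (gene_lengths / 1000)
  }
  lib <- colSums(v)
  scl <- ifelse(lib > 0, 1e6 / lib, 0)  # all-zero sample stays all-zero
  v <- sweep(v, 2, scl, "*")
  out <- log2(v + 1)
  expression_matrix(out, m$gene_ids, m$sample_ids, m$platform_tag,
                    normalization_tag = mode)
}

#' Restrict matrices to their common genes
#'
#' Intersects the gene sets of two or more expression matrices and returns
#' each matrix restricted to the shared genes in one canonical (lexicographic,
#' C-locale) order, so all outputs carry identical `gene_ids`.
#'
#' @param matrices list of `expr_matrix` objects (length >= 2).
#' @return List of `expr_matrix` objects over the common gene set.
#' @export
intersect_genes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2)
  lapply(matrices, function(m) stopifnot(inherits(m, "expr_matrix")))
  common <- Reduce(intersect, lapply(matrices, function(m) m$gene_ids))
  if (length(common) == 0) stop("empty gene intersection")
  common <- sort(common, method = "radix")
  lapply(matrices, function(m) em_subset(m, genes = match(common, m$gene_ids)))
}

#' Random train/validation/test split of a dataset
#'
#' Uniformly shuffles samples under `seed` and partitions them with the given
#' fractions (default 0.8/0.1/0.1). Validation and test sizes are floored;
#' the remainder goes to training. The same seed always yields the same
#' partition, and the three parts are disjoint and exhaustive.
#'
#' @param d a `labelled_dataset`.
#' @param fractions length-3 positive numeric summing to 1 (train, val, test).
#' @param seed integer RNG seed.
#' @return Named list with elements `train`, `val`, `test`.
#' @export
split_cells <- function(d, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(inherits(d, "labelled_dataset"), length(fractions) == 3,
            all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(d$labels)
  perm <- with_seed(seed, sample.int(n))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split produced an empty partition (n = ", n, ")")
  list(train = ds_subset(d, sort(perm[seq_len(n_train)])),
       val = ds_subset(d, sort(perm[n_train + seq_len(n_val)])),
       test = ds_subset(d, sort(perm[n_train + n_val + seq_len(n_test)])))
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Duplicate genes within a set are dropped; duplicate set names are an
#' error. Descriptions are kept as the `descriptions` attribute.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors), `source` and `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name at line ", i, ": ", nm)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set at line ", i, ": ", nm)
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, source = path, descriptions = desc)
}

#' Construct a gene-set collection
#' @param sets named list of character gene vectors.
#' @param source free-form provenance string.
#' @param descriptions optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "user", descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  if (any(vapply(sets, length, 1L) == 0)) stop("empty gene set")
  structure(list(sets = lapply(sets, as.character), source = source,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Read a sample annotation / label table
#'
#' TSV with a header; first column sample id, remaining columns looked up by
#' name (`label`, and optionally `cell_type`, `subject_id`, `cohort_id`).
#'
#' @param path TSV path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("label table needs >= 2 columns")
  colnames(df)[1] <- "sample_id"
  if (!"label" %in% colnames(df)) stop("label table needs a 'label' column")
  df
}

# internal: attach a label table to an expression matrix by sample id
attach_labels <- function(m, df) {
  idx <- match(m$sample_ids, df$sample_id)
  if (anyNA(idx))
    stop("samples missing from label table: ",
         paste(utils::head(m$sample_ids[is.na(idx)], 5), collapse = ", "))
  labelled_dataset(m, df$label[idx],
                   cell_type = if ("cell_type" %in% names(df)) df$cell_type[idx],
                   subject_id = if ("subject_id" %in% names(df)) df$subject_id[idx],
                   cohort_id = if ("cohort_id" %in% names(df)) df$cohort_id[idx])
}

# internal: run code under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
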