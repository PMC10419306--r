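#' Sparse gene-by-cell count matrix
#'
#' A light container around a sparse `Matrix::dgCMatrix` holding non-negative
#' integer UMI (or nucleus) counts, with genes as rows and cell barcodes as
#' columns (the 10x convention), plus a sample label.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts with
#'   genes as rows and cells as columns. Row and column names are used as gene
#'   symbols and barcodes; alternatively supply `genes` / `barcodes`.
#' @param sample_id Single string labelling the sample the matrix came from.
#' @param genes,barcodes Optional character vectors overriding the dimnames.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix with dimnames), and `sample_id`.
#' @export
#'
#' @examples
#' m <- count_matrix(matrix(c(3, 0, 0, 5), 2, 2,
#'   dimnames = list(c("G1", "G2"), c("c1", "c2"))), sample_id = "s1")
#' dim(m)
count_matrix <- function(counts, sample_id, genes = NULL, barcodes = NULL) {
  dn <- dimnames(counts)
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  # symmetric/triangular storage (e.g. from readMM) shares dimnames across
  # margins; force general storage so genes and barcodes stay independent
  counts <- methods::as(methods::as(counts, "generalMatrix"), "dMatrix")
  counts <- methods::as(counts, "CsparseMatrix")
  # the coercions drop dimnames on empty matrices; restore the originals
  if (!is.null(dn) && is.null(dimnames(counts))) dimnames(counts) <- dn
  if (!is.null(genes)) rownames(counts) <- genes
  if (!is.null(barcodes)) colnames(counts) <- barcodes
  # Matrix normalizes zero-length dimnames to NULL, so an empty margin is
  # exempt from the naming requirement
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    abort("count_matrix requires gene symbols (rownames) and barcodes (colnames)")
  }
  validate_count_matrix(counts)
  structure(
    list(counts = counts, sample_id = as.character(sample_id)[1]),
    class = "count_matrix"
  )
}

validate_count_matrix <- function(counts) {
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != trunc(x)))) {
    abort("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) abort("gene symbols must be unique")
  if (anyDuplicated(colnames(counts))) abort("barcodes must be unique")
  invisible(counts)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> sample '%s': %d genes x %d cells, %d nonzero entries\n",
    x$sample_id, nrow(x$counts), ncol(x$counts), length(x$counts@x)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene symbols / barcodes of a count matrix
#' @param m A [count_matrix].
#' @return Character vector.
#' @export
genes <- function(m) rownames(m$counts)

#' @rdname genes
#' @export
barcodes <- function(m) colnames(m$counts)

text_connection <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_entry_lines <- function(path) {
  con <- text_connection(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # 10x-style multi-column feature files: the first tab field is the identifier
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a 10x-style Matrix Market triplet
#'
#' Reads a coordinate-format Matrix Market file together with one-entry-per-line
#' feature and barcode files into a [count_matrix]. Genes are rows, cells are
#' columns; entries absent from the file are zero. Gzipped files (`.gz`) are
#' accepted transparently for all three members of the triplet.
#'
#' @param matrix_path Path to the `.mtx` (or `.mtx.gz`) file.
#' @param features_path,barcodes_path Paths to the feature and barcode lists.
#' @param sample_id Sample label attached to the result.
#'
#' @return A [count_matrix].
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path, sample_id) {
  con <- text_connection(matrix_path)
  on.exit(close(con))
  m <- tryCatch(Matrix::readMM(con),
    error = function(e) abort(paste0("not a readable Matrix Market file: ", conditionMessage(e)))
  )
  feats <- read_entry_lines(features_path)
  bcs <- read_entry_lines(barcodes_path)
  if (nrow(m) != length(feats)) {
    abort(sprintf(
      "matrix header declares %d rows but features file has %d entries",
      nrow(m), length(feats)
    ))
  }
  if (ncol(m) != length(bcs)) {
    abort(sprintf(
      "matrix header declares %d columns but barcodes file has %d entries",
      ncol(m), length(bcs)
    ))
  }
  count_matrix(m, sample_id = sample_id, genes = feats, barcodes = bcs)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, and `barcodes.tsv` under `dir_path`.
#' `read_mtx_triplet()` on the written files reproduces the matrix exactly.
#'
#' @param m A [count_matrix].
#' @param dir_path Output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_mtx_triplet <- function(m, dir_path) {
  stopifnot(inherits(m, "count_matrix"))
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", dir_path))
  }
  paths <- c(
    matrix = file.path(dir_path, "matrix.mtx"),
    features = file.path(dir_path, "features.tsv"),
    barcodes = file.path(dir_path, "barcodes.tsv")
  )
  Matrix::writeMM(m$counts, paths[["matrix"]])
  writeLines(genes(m), paths[["features"]])
  writeLines(barcodes(m), paths[["barcodes"]])
  invisible(paths)
}

#' Directed gene set
#'
#' A named gene set whose members each carry a direction: activators push the
#' set's activity with their own fold change, repressors against it (their
#' fold-change sign is inverted before enrichment scoring).
#'
#' @param name Set name.
#' @param genes Character vector of member symbols.
#' @param directions Character vector, one of `"activator"`/`"repressor"` per
#'   member (recycled if length 1).
#' @return An object of class `directed_gene_set`.
#' @export
directed_gene_set <- function(name, genes, directions = "activator") {
  directions <- rep_len(directions, length(genes))
  if (!all(directions %in% c("activator", "repressor"))) {
    abort("directions must be 'activator' or 'repressor'")
  }
  if (length(genes) == 0) abort(sprintf("gene set '%s' is empty", name))
  if (anyDuplicated(genes)) {
    abort(sprintf(
      "duplicate member '%s' in gene set '%s'",
      genes[duplicated(genes)][1], name
    ))
  }
  structure(
    list(name = name, members = tibble(gene = genes, direction = directions)),
    class = "directed_gene_set"
  )
}

#' @export
print.directed_gene_set <- function(x, ...) {
  cat(sprintf(
    "<directed_gene_set> '%s': %d genes (%d repressors)\n",
    x$name, nrow(x$members), sum(x$members$direction == "repressor")
  ))
  invisible(x)
}

#' Read directed gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated as
#' `name<TAB>description<TAB>member...`. A member token suffixed `|rep` is a
#' repressor; all others are activators. The suffix keeps the file valid GMT
#' for other tools.
#'
#' @param path Path to the GMT file (`.gz` accepted).
#' @return A named list of [directed_gene_set] objects, in file order.
#' @export
read_gene_sets <- function(path) {
  con <- text_connection(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("gene set line '%s...' has no members", substr(line, 1, 30)))
    }
    members <- fields[-(1:2)]
    is_rep <- grepl("\\|rep$", members)
    directed_gene_set(
      name = fields[1],
      genes = sub("\\|rep$", "", members),
      directions = ifelse(is_rep, "repressor", "activator")
    )
  })
  setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write directed gene sets as GMT
#' @param sets List of [directed_gene_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    tok <- ifelse(s$members$direction == "repressor",
      paste0(s$members$gene, "|rep"), s$members$gene
    )
    paste(c(s$name, "na", tok), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcription-factor catalog
#'
#' One gene symbol per line; blank lines ignored.
#'
#' @param path Path to the list (`.gz` accepted).
#' @return Character vector of unique symbols.
#' @export
read_tf_catalog <- function(path) {
  syms <- read_entry_lines(path)
  if (length(syms) == 0) abort("TF catalog is empty")
  if (anyDuplicated(syms)) {
    abort(sprintf("duplicate symbol '%s' in TF catalog", syms[duplicated(syms)][1]))
  }
  syms
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `condition`, `tissue`,
#' `path`; `condition` must be `control` or `disease`, and `path` points at
#' the sample's Matrix Market triplet directory.
#'
#' @param path Path to the TSV.
#' @return A tibble with the four columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("sample_id", "condition", "tissue", "path")
  if (!all(need %in% names(sheet))) {
    abort(paste0("sample sheet must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) abort("sample_id values must be unique")
  if (!all(sheet$condition %in% c("control", "disease"))) {
    abort("condition must be 'control' or 'disease'")
  }
  sheet[, need]
}

#' Read a marker map
#'
#' Tab-separated, two columns: cell-type label and a comma-separated marker
#' list. Returns the map in file order (declaration order breaks annotation
#' ties).
#'
#' @param path Path to the TSV (no header).
#' @return Named list of character marker vectors.
#' @export
read_marker_map <- function(path) {
  con <- text_connection(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) abort("marker map lines need a label and a marker list")
    trimws(strsplit(fields[2], ",", fixed = TRUE)[[1]])
  })
  labels <- vapply(
    lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE
  )
  if (any(lengths(out) == 0)) abort("every cell type needs at least one marker")
  setNames(out, labels)
}

#' Write a marker map
#' @param markers Named list of character marker vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_map <- function(markers, path) {
  writeLines(
    paste(names(markers), vapply(markers, paste, character(1), collapse = ","),
          sep = "\t"),
    path
  )
  invisible(path)
}
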