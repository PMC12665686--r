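#' Read a cell x gene expression matrix
#'
#' Supports the 10x MatrixMarket triplet convention (`matrix.mtx` with
#' `genes.tsv`/`barcodes.tsv` sidecars, genes as MTX rows), dense CSV/TSV
#' (header row of gene ids, first column of cell ids, cells as rows), and
#' H5AD containers (matrix + obs/var names only, read through the bundled
#' Python bridge). The result is a [SingleCellExperiment::SingleCellExperiment]
#' with a `counts` assay stored genes x cells (Bioconductor orientation);
#' cell and gene order is preserved from the file.
#'
#' @param path file path (for MTX, either the `.mtx` file or its directory).
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`, `"h5ad"`.
#' @return a `SingleCellExperiment` with assay `counts` (dgCMatrix).
#' @export
readExpression <- function(path, format = c("auto", "mtx", "csv", "tsv", "h5ad")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
      else switch(tolower(tools::file_ext(path)),
                  mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                  h5ad = "h5ad", h5 = "h5ad",
                  stop("cannot infer format from '", path, "'; pass format="))
  }
  sce <- switch(format,
    mtx = readExpressionMtx(path),
    csv = readExpressionDense(path, sep = ","),
    tsv = readExpressionDense(path, sep = "\t"),
    h5ad = readExpressionH5ad(path)
  )
  validateExpression(sce)
  sce
}

validateExpression <- function(sce) {
  m <- SummarizedExperiment::assay(sce, "counts")
  neg <- if (methods::is(m, "CsparseMatrix")) {
    sm <- Matrix::summary(m)
    as.matrix(sm[sm$x < 0, c("i", "j"), drop = FALSE])
  } else {
    which(as.matrix(m) < 0, arr.ind = TRUE)
  }
  if (nrow(neg)) {
    stop(sprintf("negative expression value at gene '%s', cell '%s'",
                 rownames(sce)[neg[1, 1]], colnames(sce)[neg[1, 2]]),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(sce))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(sce))) stop("duplicate cell ids", call. = FALSE)
  invisible(sce)
}

readExpressionMtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dirn <- path
  } else {
    mtx <- path
    dirn <- dirname(path)
  }
  if (!file.exists(mtx)) stop("MTX file not found: ", mtx, call. = FALSE)
  genesf <- file.path(dirn, "genes.tsv")
  barf <- file.path(dirn, "barcodes.tsv")
  if (!file.exists(genesf))
    stop("missing MTX sidecar file: ", genesf, call. = FALSE)
  if (!file.exists(barf))
    stop("missing MTX sidecar file: ", barf, call. = FALSE)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- data.table::fread(genesf, header = FALSE, sep = "\t")[[1]]
  bars <- data.table::fread(barf, header = FALSE, sep = "\t")[[1]]
  if (nrow(m) != length(genes))
    stop(sprintf("genes.tsv lists %d genes but matrix has %d rows",
                 length(genes), nrow(m)), call. = FALSE)
  if (ncol(m) != length(bars))
    stop(sprintf("barcodes.tsv lists %d cells but matrix has %d columns",
                 length(bars), ncol(m)), call. = FALSE)
  dimnames(m) <- list(genes, bars)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

readExpressionDense <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = sep, header = TRUE)
  cells <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])  # cells x genes on disk
  storage.mode(m) <- "double"
  mm <- methods::as(Matrix::Matrix(t(m), sparse = TRUE), "CsparseMatrix")
  dimnames(mm) <- list(colnames(dt)[-1], cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = mm))
}

h5adBridge <- function() {
  p <- system.file("python", "h5ad_bridge.py", package = "screformer")
  if (!nzchar(p)) stop("h5ad bridge script not found", call. = FALSE)
  p
}

readExpressionH5ad <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tmp <- tempfile("h5ad_")
  out <- suppressWarnings(system2("python",
    c(h5adBridge(), "read", shQuote(path), shQuote(tmp)),
    stdout = TRUE, stderr = TRUE))
  st <- attr(out, "status")
  if (!is.null(st) && st != 0)
    stop("H5AD read failed (python/anndata required): ",
         paste(out, collapse = "\n"), call. = FALSE)
  mat <- as.matrix(data.table::fread(paste0(tmp, "_X.csv"), header = FALSE))
  genes <- readLines(paste0(tmp, "_var.txt"))
  cells <- readLines(paste0(tmp, "_obs.txt"))
  unlink(paste0(tmp, c("_X.csv", "_var.txt", "_obs.txt")))
  storage.mode(mat) <- "double"
  mm <- methods::as(Matrix::Matrix(t(mat), sparse = TRUE), "CsparseMatrix")
  dimnames(mm) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = mm))
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]; writes MTX triplets (genes x cells on
#' disk, 1-based coordinates per the MatrixMarket standard), dense
#' CSV/TSV (cells x rows on disk), or H5AD via the Python bridge.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path output path; for MTX a directory that will receive
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(sce, path, format = c("mtx", "csv", "tsv", "h5ad")) {
  format <- match.arg(format)
  m <- SummarizedExperiment::assay(sce, "counts")
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "genes.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::data.table(cell_id = colnames(m))
    dt <- cbind(dt, data.table::as.data.table(as.matrix(Matrix::t(m))))
    data.table::setnames(dt, c("cell_id", rownames(m)))
    data.table::fwrite(dt, path, sep = sep)
  } else {
    tmp <- tempfile("h5ad_")
    dense <- as.matrix(Matrix::t(m))  # cells x genes
    data.table::fwrite(data.table::as.data.table(dense), paste0(tmp, "_X.csv"),
                       col.names = FALSE)
    writeLines(rownames(m), paste0(tmp, "_var.txt"))
    writeLines(colnames(m), paste0(tmp, "_obs.txt"))
    out <- suppressWarnings(system2("python",
      c(h5adBridge(), "write", shQuote(path), shQuote(tmp)),
      stdout = TRUE, stderr = TRUE))
    st <- attr(out, "status")
    unlink(paste0(tmp, c("_X.csv", "_var.txt", "_obs.txt")))
    if (!is.null(st) && st != 0)
      stop("H5AD write failed (python/anndata required): ",
           paste(out, collapse = "\n"), call. = FALSE)
  }
  invisible(path)
}

#' Read a hierarchical cell-label table
#'
#' The table is TSV with columns `cell_id, level1, level2, level3, level4`
#' (missing trailing columns allowed). Labels deeper than the deepest
#' assigned node are filled downward from it, so every cell carries four
#' levels: a cell annotated only to an internal node inherits that node's
#' label at all deeper levels. Labels are whitespace-trimmed; comparison is
#' case-sensitive.
#'
#' @param path TSV file path.
#' @return a [S4Vectors::DataFrame] with rownames = cell ids and columns
#'   `level1..level4`; `metadata()$classesLevel1` holds the sorted level-1
#'   vocabulary.
#' @export
readCellLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", fill = TRUE)
  if (ncol(dt) < 2L) stop("label table needs a cell id and >= 1 level column",
                          call. = FALSE)
  ids <- trimws(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate cell id in label table: ",
         ids[anyDuplicated(ids)], call. = FALSE)
  lv <- as.matrix(dt[, -1, drop = FALSE])
  lv[is.na(lv)] <- ""
  lv <- trimws(lv)
  if (ncol(lv) > 4L) stop("at most 4 label levels supported", call. = FALSE)
  if (ncol(lv) < 4L)
    lv <- cbind(lv, matrix("", nrow(lv), 4L - ncol(lv)))
  colnames(lv) <- paste0("level", 1:4)
  lv <- propagateLabels(lv)
  df <- S4Vectors::DataFrame(lv, row.names = ids)
  S4Vectors::metadata(df)$classesLevel1 <- sort(unique(lv[, "level1"]))
  df
}

#' Fill missing deeper labels from the deepest assigned node
#'
#' Idempotent: a cell labeled `("lymphoid", "B cells", "plasma B cells", "")`
#' gets level 4 `"plasma B cells"`; a cell labeled only at level 1 repeats
#' that label at levels 2-4.
#'
#' @param lv character matrix (cells x 4) of labels, `""` meaning unassigned.
#' @return the filled matrix.
#' @export
propagateLabels <- function(lv) {
  if (is(lv, "DataFrame")) {
    filled <- propagateLabels(as.matrix(as.data.frame(lv)))
    out <- S4Vectors::DataFrame(filled, row.names = rownames(lv))
    S4Vectors::metadata(out) <- S4Vectors::metadata(lv)
    return(out)
  }
  if (any(lv[, 1] == ""))
    stop("cell(s) with empty level-1 label: row ",
         paste(utils::head(which(lv[, 1] == "")), collapse = ", "),
         call. = FALSE)
  for (k in 2:ncol(lv)) {
    empty <- lv[, k] == ""
    lv[empty, k] <- lv[empty, k - 1L]
  }
  lv
}

#' Level-1 class vocabulary of a label table
#' @param labels a label DataFrame from [readCellLabels()].
#' @return sorted character vector of level-1 classes.
#' @export
levelOneClasses <- function(labels) {
  cls <- S4Vectors::metadata(labels)$classesLevel1
  if (is.null(cls)) cls <- sort(unique(labels$level1))
  cls
}

#' Write a label table
#' @param labels DataFrame with columns level1..level4, rownames cell ids.
#' @param path output TSV path.
#' @export
writeCellLabels <- function(labels, path) {
  dt <- data.table::data.table(cell_id = rownames(labels),
                               as.data.frame(labels))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write a gene-embedding table
#'
#' TSV with `gene_id` followed by the embedding coordinates.
#'
#' @param path TSV file path.
#' @return a [GeneEmbeddings-class].
#' @export
readGeneEmbeddings <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  v <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- dt[[1]]
  methods::new("GeneEmbeddings", ids = as.character(dt[[1]]), vectors = v)
}

#' @rdname readGeneEmbeddings
#' @param emb a [GeneEmbeddings-class] object.
#' @export
writeGeneEmbeddings <- function(emb, path) {
  dt <- data.table::data.table(gene_id = emb@ids,
                               data.table::as.data.table(emb@vectors))
  data.table::setnames(dt, c("gene_id", paste0("d", seq_len(ncol(emb@vectors)))))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Reproducible train/validation/test split
#'
#' Deterministic for a fixed seed. With `stratified = TRUE` (default) the
#' split is performed independently within each level-1 class, so realized
#' per-class fractions match the requested ratios to within one cell
#' (largest-remainder rounding). A class with fewer members than partitions
#' triggers a warning and a best-effort assignment.
#'
#' @param labels label DataFrame from [readCellLabels()] (rownames = cells).
#' @param ratios length-3 non-negative ratios summing to 1
#'   (train, val, test); the published protocol uses 6:2:2.
#' @param seed integer RNG seed.
#' @param stratified stratify by level-1 label?
#' @return a [SplitAssignment-class].
#' @export
splitCells <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 2022L,
                       stratified = TRUE) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  ids <- rownames(labels)
  strata <- if (stratified) labels$level1 else rep("all", length(ids))
  part <- character(length(ids))
  names(part) <- ids
  withSeed(seed, {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      n <- length(idx)
      if (stratified && n < sum(ratios > 0))
        warning(sprintf("class '%s' has %d cell(s), fewer than partitions; best-effort assignment", s, n))
      sizes <- largestRemainder(n, ratios)
      ord <- idx[sample.int(n)]
      part[ord] <- rep(c("train", "val", "test"), times = sizes)
    }
  })
  methods::new("SplitAssignment",
    partition = factor(part, levels = c("train", "val", "test")),
    ratios = as.numeric(ratios), seed = as.integer(seed),
    stratified = stratified)
}

largestRemainder <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Cell ids of one partition
#' @param split a [SplitAssignment-class].
#' @param which `"train"`, `"val"` or `"test"`.
#' @return character cell ids.
#' @export
splitIds <- function(split, which = c("train", "val", "test")) {
  which <- match.arg(which)
  names(split@partition)[split@partition == which]
}
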