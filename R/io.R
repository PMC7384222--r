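#' Read a genes x cells UMI count matrix
#'
#' Two layouts are supported: `"mtx_dir"`, a directory holding a Matrix
#' Market triplet file (`matrix.mtx`) with gene and barcode sidecar lists
#' (`genes.tsv`/`features.tsv` and `barcodes.tsv`, the CellRanger layout),
#' and `"csv"`, a dense table with gene ids in the first column and a
#' header row of cell ids. Entries must be non-negative integers; the
#' first offending coordinate is named otherwise.
#'
#' @param path Directory (`mtx_dir`) or file (`csv`).
#' @param format `"auto"` (directory implies `mtx_dir`), `"mtx_dir"` or
#'   `"csv"`.
#' @return Integer matrix with gene ids as rownames and cell ids as
#'   colnames (dense; sparse input is densified).
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing file or directory: ", path)
  if (format == "auto") format <- if (dir.exists(path)) "mtx_dir" else "csv"
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, c("genes.tsv", "features.tsv"))
    genes <- genes[file.exists(genes)][1]
    barcodes <- file.path(path, "barcodes.tsv")
    missing <- c(mtx, barcodes)[!file.exists(c(mtx, barcodes))]
    if (is.na(genes)) missing <- c(missing, file.path(path, "genes.tsv"))
    if (length(missing)) {
      stop("missing file(s): ", paste(missing, collapse = ", "))
    }
    m <- as.matrix(Matrix::readMM(mtx))
    gid <- utils::read.table(genes, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
    cid <- utils::read.table(barcodes, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
    dimnames(m) <- list(gid, cid)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-integer or negative count at gene ", rownames(m)[bad[1, 1]],
         ", cell ", colnames(m)[bad[1, 2]])
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix in either supported layout
#'
#' @param counts Integer genes x cells matrix with dimnames.
#' @param path Output directory (`mtx_dir`) or csv file path.
#' @param format `"mtx_dir"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("csv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "genes.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read per-cell metadata and align it to a count matrix
#'
#' Expects a TSV/CSV with a `cell_id` column and optional `cell_type`,
#' `sex` and `total_umi` columns. Rows are reordered to the matrix's cell
#' order; cells missing from the metadata are an error. A missing
#' `total_umi` column is computed from the matrix column sums; a present
#' but inconsistent one is kept with a warning (it may legitimately count
#' UMIs over genes removed by filtering).
#'
#' @param path Metadata file (`.tsv`/`.txt` tab-separated, otherwise
#'   comma-separated).
#' @param counts The count matrix to align against.
#' @return Data frame aligned to `colnames(counts)`.
#' @export
read_metadata <- function(path, counts) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(md)) stop("metadata needs a cell_id column")
  idx <- match(colnames(counts), md$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from metadata: ",
         paste(utils::head(colnames(counts)[is.na(idx)], 5), collapse = ", "))
  }
  md <- md[idx, , drop = FALSE]
  rownames(md) <- NULL
  depths <- unname(colSums(counts))
  if (!"total_umi" %in% names(md)) {
    md$total_umi <- depths
  } else if (any(md$total_umi != depths)) {
    warning("total_umi column differs from count-matrix column sums; ",
            "keeping the metadata values")
  }
  md
}

#' Pipeline configuration
#'
#' @param counts_path Count matrix location for [read_counts()].
#' @param metadata_path Optional metadata file for [read_metadata()].
#' @param out_dir Output directory.
#' @param covariate Metadata column to use as the GLM covariate
#'   (`NULL` = offset-only model).
#' @param format Count format passed to [read_counts()].
#' @param filter_min_frac Gene detection filter (default 0.10).
#' @param k_list SE thresholds (default `0:3`).
#' @param mode,prior,sampler Fitting settings.
#' @param offset_divisor Rate unit (default 1e4).
#' @param seed Integer seed.
#' @return A `zc_config` list.
#' @export
run_config <- function(counts_path, metadata_path = NULL, out_dir = ".",
                       covariate = NULL, format = "auto",
                       filter_min_frac = 0.10, k_list = 0:3,
                       mode = "approx", prior = prior_spec(),
                       sampler = sampler_config(), offset_divisor = 1e4,
                       seed = 1L) {
  structure(as.list(environment()), class = "zc_config")
}

#' Run the full classification pipeline
#'
#' Reads counts (and metadata), applies the gene detection filter, fits
#' all four families per gene, scores them by LOO ELPD and writes three
#' files to `out_dir`: `selection.tsv` (one row per gene x threshold),
#' `parameters.tsv` (fitted parameters per gene x family x group) and
#' `run_log.txt` (config echo, seed, non-convergent genes). Per-gene
#' failures are logged and do not abort the run.
#'
#' @param config A [run_config()].
#' @return The selection table, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_counts(config$counts_path, format = config$format)
  md <- if (!is.null(config$metadata_path)) {
    read_metadata(config$metadata_path, counts)
  } else NULL
  counts <- filter_genes(counts, config$filter_min_frac)
  total_umi <- if (!is.null(md)) md$total_umi else colSums(counts)
  groups <- if (!is.null(config$covariate)) {
    if (is.null(md) || !config$covariate %in% names(md)) {
      stop("covariate column '", config$covariate, "' not in metadata")
    }
    md[[config$covariate]]
  } else NULL
  calls <- classify_genes(counts, total_umi = total_umi, groups = groups,
                          k_list = config$k_list, mode = config$mode,
                          prior = config$prior, sampler = config$sampler,
                          offset_divisor = config$offset_divisor,
                          seed = config$seed)
  utils::write.table(calls, file.path(config$out_dir, "selection.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(attr(calls, "params"),
                     file.path(config$out_dir, "parameters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bad <- unique(calls$gene_id[!calls$converged])
  log_lines <- c(
    paste0("zicall run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    paste0("mode: ", config$mode),
    paste0("offset_divisor: ", config$offset_divisor),
    paste0("filter_min_frac: ", config$filter_min_frac),
    paste0("k_list: ", paste(config$k_list, collapse = ",")),
    paste0("covariate: ", if (is.null(config$covariate)) "(none)"
           else config$covariate),
    paste0("genes: ", nrow(counts), "  cells: ", ncol(counts)),
    if (length(bad)) paste0("WARNING non-convergent gene: ", bad)
      else "all fits converged"
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(calls)
}
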