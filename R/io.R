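# Readers and writers for the standard on-disk formats.

# deterministic disambiguation of duplicate identifiers: second and later
# occurrences get a ".k" suffix by occurrence index
.disambiguate <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  make.unique(ids, sep = ".")
}

#' Read a count matrix
#'
#' Supports the 10x-style MatrixMarket triplet (a directory holding
#' `matrix.mtx`, `features.tsv`, `barcodes.tsv`) and dense delimited tables.
#' Duplicate gene names are disambiguated deterministically by occurrence
#' suffix.
#'
#' @param path directory (for `format = "mtx"`) or file (for `"tsv"`).
#' @param format `"mtx"` or `"tsv"`.
#' @param orientation for `"tsv"`: `"genes_as_rows"` (10x convention) or
#'   `"samples_as_rows"`; never inferred.
#' @return list with `counts` (sparse gene x cell `dgCMatrix`) and
#'   `gene_meta` (data frame; from `features.tsv` when present).
#' @export
read_counts <- function(path, format = c("mtx", "tsv"),
                        orientation = c("genes_as_rows", "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx") {
    mtx_path <- file.path(path, "matrix.mtx")
    feat_path <- file.path(path, "features.tsv")
    bc_path <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_path, feat_path, bc_path))
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    m <- Matrix::Matrix(Matrix::readMM(mtx_path), sparse = TRUE)
    feats <- read.delim(feat_path, stringsAsFactors = FALSE)
    if (!"gene" %in% names(feats)) names(feats)[1] <- "gene"
    barcodes <- readLines(bc_path)
    if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
      stop("dimension mismatch between matrix (", nrow(m), " x ", ncol(m),
           ") and identifier files (", nrow(feats), " genes, ",
           length(barcodes), " barcodes)", call. = FALSE)
    genes <- .disambiguate(feats$gene)
    feats$gene <- genes
    dimnames(m) <- list(genes, barcodes)
    return(list(counts = methods::as(m, "dgCMatrix"), gene_meta = feats))
  }
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (orientation == "samples_as_rows") m <- t(m)
  rownames(m) <- .disambiguate(rownames(m))
  list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "dgCMatrix"),
       gene_meta = data.frame(gene = rownames(m), stringsAsFactors = FALSE))
}

#' Flag mitochondrial and hemoglobin genes by symbol prefix
#'
#' Mitochondrial genes by the `MT-` prefix; hemoglobin genes by the `HB`
#' family prefix (HBA/HBB/HBD/HBE/HBG/HBM/HBQ/HBZ).
#'
#' @param genes character vector of gene symbols.
#' @return list of two logical vectors, `is_mito` and `is_hemoglobin`.
#' @export
flag_genes_by_prefix <- function(genes) {
  list(is_mito = grepl("^MT-", genes),
       is_hemoglobin = grepl("^HB[ABDEGMQZ]", genes))
}

#' Read and validate a survival table
#'
#' Expects columns `sample_id`, `time`, `event`. Times must be strictly
#' positive; events are coerced to `{0, 1}` (accepting `Dead`/`Deceased`/
#' `1`/`TRUE` as an event and `Alive`/`Censored`/`0`/`FALSE` as censoring).
#' Invalid rows abort with their indices.
#'
#' @param path TSV path.
#' @return data frame `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$time <- as.numeric(df$time)
  bad_time <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_time) > 0)
    stop("non-positive or missing time in row(s): ",
         paste(head(bad_time, 10), collapse = ", "), call. = FALSE)
  ev <- tolower(as.character(df$event))
  dict <- c("1" = 1L, "dead" = 1L, "deceased" = 1L, "true" = 1L,
            "0" = 0L, "alive" = 0L, "censored" = 0L, "false" = 0L)
  mapped <- dict[ev]
  bad_ev <- which(is.na(mapped))
  if (length(bad_ev) > 0)
    stop("unrecognized event code in row(s): ",
         paste(head(bad_ev, 10), collapse = ", "), call. = FALSE)
  df$event <- unname(mapped)
  df[, need]
}

#' Write a table with a provenance header
#'
#' Prepends comment lines recording the package version, a config hash, and
#' the seed, then the TSV body.
#'
#' @param df data frame.
#' @param path output path.
#' @param config list used to derive the provenance hash (may be `NULL`).
#' @param seed integer seed to record (may be `NULL`).
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, config = NULL, seed = NULL) {
  hash <- if (is.null(config)) "none"
          else sprintf("%08x", sum(utf8ToInt(paste(deparse(config),
                                                   collapse = "")) *
                                   seq_along(utf8ToInt(paste(deparse(config),
                                                             collapse = "")))) %%
                       .Machine$integer.max)
  header <- c(
    sprintf("# necrostrat %s", as.character(packageVersion("necrostrat"))),
    sprintf("# config_hash: %s", hash),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
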