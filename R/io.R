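#' Write an ExpressionDataset to disk
#'
#' Serializes counts as MatrixMarket (genes x observations, the 10x
#' convention; MTX indices are 1-based per the format standard) together with
#' `obs.tsv` and `var.tsv`.
#'
#' @param ds ExpressionDataset
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  # doubles serialized at full precision so read_dataset round-trips exactly
  full_prec <- function(df) {
    for (j in seq_along(df)) if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
    df
  }
  utils::write.table(full_prec(ds$obs), file.path(dir, "obs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(full_prec(ds$var), file.path(dir, "var.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an ExpressionDataset from disk
#'
#' Accepts either the `matrix.mtx` + `obs.tsv` + `var.tsv` triplet written by
#' [write_dataset()], or a 10x-style directory (`matrix.mtx[.gz]`,
#' `barcodes.tsv[.gz]`, `features.tsv[.gz]`/`genes.tsv[.gz]`). Counts must be
#' nonnegative integers; metadata dimensions are validated against the matrix.
#'
#' @param path directory containing the files
#' @return ExpressionDataset
#' @export
read_dataset <- function(path) {
  pick <- function(...) {
    for (f in c(...)) {
      for (cand in c(file.path(path, f), file.path(path, paste0(f, ".gz"))))
        if (file.exists(cand)) return(cand)
    }
    NULL
  }
  mtx <- pick("matrix.mtx")
  if (is.null(mtx)) stop("no matrix.mtx[.gz] found in ", path)
  m <- read_mm(mtx)
  if (any(m@x != round(m@x))) stop("non-integer counts in ", mtx)
  obs_f <- pick("obs.tsv")
  if (!is.null(obs_f)) {
    obs <- utils::read.table(obs_f, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    var <- utils::read.table(pick("var.tsv"), sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    bc <- pick("barcodes.tsv")
    ft <- pick("features.tsv", "genes.tsv")
    if (is.null(bc) || is.null(ft)) stop("not a dataset directory: ", path)
    obs <- utils::read.table(bc, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    names(obs)[1] <- "barcode"
    ftab <- utils::read.table(ft, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    var <- data.frame(id = ftab[[min(2, ncol(ftab))]], stringsAsFactors = FALSE)
  }
  if (nrow(obs) != ncol(m))
    stop("obs metadata has ", nrow(obs), " rows but matrix has ", ncol(m),
         " observations (", mtx, ")")
  if (nrow(var) != nrow(m))
    stop("var metadata has ", nrow(var), " rows but matrix has ", nrow(m),
         " genes (", mtx, ")")
  expression_dataset(Matrix::t(m), obs, var)
}

read_mm <- function(f) {
  if (endsWith(f, ".gz")) {
    con <- gzfile(f, "rt"); on.exit(close(con))
    m <- Matrix::readMM(con)
  } else m <- Matrix::readMM(f)
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped; empty sets are rejected.
#'
#' @param path GMT file
#' @return named list of character vectors of gene ids
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, " in ", path, ": expected name, description, >=1 gene")
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("malformed GMT line ", i, " in ", path, ": empty set")
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
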