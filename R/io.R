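## Readers and writers for the plain-text formats the analyses consume:
## nest morphometry tables (CSV/TSV), expression matrices (dense CSV or an
## MTX triple), and gene signatures (GMT or one-gene-per-line).

#' Read a nest morphometry table
#'
#' @param path CSV or TSV file with header columns \code{field_id},
#'   \code{x_um}, \code{y_um}, \code{area_um2} (delimiter sniffed from the
#'   header line).
#' @return validated nest table (data.frame).
#' @export
readNestTable <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("field_id", "x_um", "y_um", "area_um2")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("nest table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("x_um", "y_um", "area_um2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(v))
      stop("missing ", col, " at data row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    df[[col]] <- v
  }
  bad <- which(df$area_um2 <= 0)
  if (length(bad))
    stop("non-positive area_um2 at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$field_id <- as.character(df$field_id)
  df[need]
}

#' Write a nest morphometry table
#'
#' @param fields nest table.
#' @param path output CSV path.
#' @export
writeNestTable <- function(fields, path) {
  .checkNestTable(fields)
  utils::write.csv(fields[c("field_id", "x_um", "y_um", "area_um2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix with cluster labels
#'
#' Two encodings are supported: a dense CSV (rows = cells, first column
#' \code{cell_id}, a \code{cluster} column, remaining columns = genes), or
#' a MatrixMarket triple (\code{path} = the .mtx of a genes x cells sparse
#' matrix, \code{genes_path} = one gene id per line, \code{cells_path} =
#' CSV with \code{cell_id} and \code{cluster}).
#'
#' @param path dense CSV or .mtx path.
#' @param genes_path,cells_path companions for the MTX triple.
#' @return \code{SummarizedExperiment} (genes x cells, assay
#'   \code{"normcounts"}) with a \code{cluster} colData column.
#' @export
readExpressionMatrix <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs genes_path and cells_path")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "cluster") %in% colnames(cells)))
      stop("cells metadata needs cell_id and cluster columns")
    if (nrow(m) != length(genes) || ncol(m) != nrow(cells))
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match gene/cell metadata")
    rownames(m) <- genes
    colnames(m) <- cells$cell_id
    cl <- cells$cluster
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("cell_id", "cluster") %in% colnames(df)))
      stop("dense expression CSV needs cell_id and cluster columns")
    cl <- df$cluster
    ids <- df$cell_id
    m <- t(as.matrix(df[, setdiff(colnames(df), c("cell_id", "cluster")),
                        drop = FALSE]))
    colnames(m) <- ids
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(rownames(m)[duplicated(rownames(m))]), 5),
               collapse = ", "))
  if (any(m < 0)) stop("expression values must be non-negative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(normcounts = m),
    colData = S4Vectors::DataFrame(cluster = as.character(cl),
                                   row.names = colnames(m)))
}

#' Write an expression matrix as a dense CSV
#'
#' @param se \code{SummarizedExperiment} with a cluster colData column.
#' @param path output path.
#' @param assay_index assay to write.
#' @export
writeExpressionMatrix <- function(se, path, assay_index = 1L) {
  m <- SummarizedExperiment::assay(se, assay_index)
  cl <- .getClusters(se)
  df <- data.frame(cell_id = colnames(m), cluster = cl,
                   t(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene signatures (GMT or one-gene-per-line)
#'
#' GMT: one set per line, tab-separated \code{name, description,
#' gene1, gene2, ...}; the description field may carry a direction tag
#' (\code{up}/\code{down}), otherwise direction is \code{neutral}. Plain
#' list: a \code{# name [direction]} header line followed by one gene per
#' line.
#'
#' @param path signature file.
#' @return named list of signatures, each
#'   \code{list(name =, direction =, genes =)}.
#' @export
readSignatures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("signature file ", path, " is empty")
  parse_dir <- function(x) {
    x <- tolower(trimws(x))
    if (x %in% c("up", "down")) x else "neutral"
  }
  if (any(grepl("\t", lines))) {           # GMT
    sets <- lapply(lines, function(ln) {
      parts <- strsplit(ln, "\t")[[1]]
      if (length(parts) < 3 || !nzchar(parts[1]))
        stop("malformed GMT line (need name, description, >=1 gene): ",
             substr(ln, 1, 40))
      list(name = parts[1], direction = parse_dir(parts[2]),
           genes = unique(parts[-(1:2)][nzchar(parts[-(1:2)])]))
    })
  } else {                                  # single plain list
    if (!grepl("^#", lines[1]))
      stop("plain signature list must start with a '# name [direction]' header")
    hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
    genes <- unique(trimws(lines[-1]))
    if (!length(genes)) stop("signature ", hdr[1], " has no genes")
    sets <- list(list(name = hdr[1],
                      direction = if (length(hdr) > 1) parse_dir(hdr[2])
                                  else "neutral",
                      genes = genes))
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write signatures as a GMT file
#'
#' @param signatures list of signatures (as from
#'   \code{\link{readSignatures}}).
#' @param path output path.
#' @export
writeSignaturesGMT <- function(signatures, path) {
  lines <- vapply(signatures, function(s)
    paste(c(s$name, s$direction, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a size distribution as a two-column CSV
#'
#' @param dist a \linkS4class{SizeDistribution}.
#' @param path output path (columns size, count).
#' @export
writeSizeDistribution <- function(dist, path) {
  stopifnot(is(dist, "SizeDistribution"))
  utils::write.csv(data.frame(size = dist@sizes, count = dist@counts), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a size distribution from a two-column CSV
#'
#' @param path CSV with columns size, count.
#' @param truncation_threshold threshold recorded on the object.
#' @return a \linkS4class{SizeDistribution}.
#' @export
readSizeDistribution <- function(path, truncation_threshold = 0) {
  df <- utils::read.csv(path)
  stopifnot(all(c("size", "count") %in% colnames(df)))
  o <- order(df$size)
  new("SizeDistribution", sizes = as.integer(df$size[o]),
      counts = as.integer(df$count[o]),
      n_clones = as.integer(sum(df$count)),
      truncation_threshold = as.numeric(truncation_threshold))
}
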