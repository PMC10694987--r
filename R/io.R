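needPkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this I/O operation")
}

#' Raster and table I/O
#'
#' Plain-format readers/writers for the pipeline's artifacts: RGB images as
#' PNG, gray rasters (stain channels, probability maps) as 32-bit float
#' TIFF, label masks as 16-bit single-channel TIFF, feature tables and
#' expression matrices as CSV/TSV, gene lists as plain text and stain
#' matrices as YAML.
#'
#' @param path file path.
#' @param image,mask,table,expr,stains object to write.
#' @return Readers return the parsed object; writers return `invisible(path)`.
#' @name gliopath-io
NULL

#' @rdname gliopath-io
#' @export
readRGBImage <- function(path) {
  needPkg("png")
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' @rdname gliopath-io
#' @export
writeRGBImage <- function(image, path) {
  needPkg("png")
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname gliopath-io
#' @export
readGrayTiff <- function(path) {
  needPkg("tiff")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' @rdname gliopath-io
#' @export
writeGrayTiff <- function(image, path) {
  needPkg("tiff")
  tiff::writeTIFF(image, path, bits.per.sample = 32, reduce = TRUE)
  invisible(path)
}

#' @rdname gliopath-io
#' @export
writeMaskTiff <- function(mask, path) {
  needPkg("tiff")
  if (max(mask) > 65535) stop("more than 65535 labels; 16-bit mask overflow")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname gliopath-io
#' @export
readMaskTiff <- function(path) {
  needPkg("tiff")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  out <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  attr(out, "nObjects") <- max(out)
  out
}

featureTableVersion <- "gliopath-cells-v1"

#' @rdname gliopath-io
#' @export
writeFeatureTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", featureTableVersion), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname gliopath-io
#' @export
readFeatureTable <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
}

#' @rdname gliopath-io
#' @param sep field separator; `NULL` guesses from the extension.
#' @export
readExpressionMatrix <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(duplicated(rownames(m)))) stop("duplicate gene ids")
  m
}

#' @rdname gliopath-io
#' @export
writeExpressionMatrix <- function(expr, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gliopath-io
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname gliopath-io
#' @export
readStainMatrixYaml <- function(path) {
  y <- yaml::read_yaml(path)
  m <- do.call(rbind, lapply(y, unlist))
  colnames(m) <- c("R", "G", "B")
  checkStainMatrix(m)
  m
}

#' @rdname gliopath-io
#' @export
writeStainMatrixYaml <- function(stains, path) {
  l <- lapply(seq_len(nrow(stains)), function(i) unname(stains[i, ]))
  names(l) <- rownames(stains)
  yaml::write_yaml(l, path, precision = 15)
  invisible(path)
}
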