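# FPKM expression tables: the strict FPKM > 0 expression call and the
# peak-condition summary per gene/homeolog.

#' Read an FPKM matrix from TSV
#'
#' Genes/homeologs in rows, conditions in columns with "tissue:stage"
#' headers.  Negative values are rejected at load time.
#'
#' @param path TSV file, first column gene ids
#' @return numeric matrix with gene rownames and condition colnames, plus a
#'   \code{conditions} attribute (data.frame condition/tissue/stage)
#' @export
read_fpkm <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing FPKM values")
  if (any(m < 0)) stop("negative FPKM values are invalid")
  cond <- colnames(m)
  parts <- strsplit(cond, ":", fixed = TRUE)
  attr(m, "conditions") <- data.frame(
    condition = cond,
    tissue = vapply(parts, `[`, "", 1L),
    stage = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""))
  m
}

#' Expression call: FPKM strictly greater than a threshold
#'
#' The survey convention calls a region expressed when its FPKM exceeds zero;
#' threshold is exposed because that rule is permissive.
#'
#' @param m FPKM matrix (genes x conditions, non-negative)
#' @param threshold call threshold (default 0, strict inequality)
#' @return logical matrix of the same shape
#' @export
call_expressed <- function(m, threshold = 0) {
  if (any(m < 0)) stop("negative FPKM values are invalid")
  m > threshold
}

#' Peak condition per gene
#'
#' @param m FPKM matrix with at least one condition
#' @return data.frame \code{gene}, \code{condition}, \code{fpkm},
#'   \code{tie} (TRUE when the maximum is shared; the first condition in
#'   file order is reported)
#' @export
peak_condition <- function(m) {
  if (ncol(m) < 1L) stop("need at least one condition")
  idx <- apply(m, 1L, which.max)
  tie <- apply(m, 1L, function(r) sum(r == max(r)) > 1L)
  data.frame(gene = rownames(m),
             condition = colnames(m)[idx],
             fpkm = m[cbind(seq_len(nrow(m)), idx)],
             tie = tie, row.names = NULL)
}
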