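#' Read a UMI count matrix
#'
#' Accepts MatrixMarket triplet format (with sidecar gene and barcode lists,
#' one id per line) or a dense TSV with gene ids in the first column and
#' barcodes as the header.
#'
#' @param path Matrix file (\code{.mtx} or TSV).
#' @param genes,barcodes Paths to gene/barcode lists (MTX input only).
#' @return Integer matrix genes x cells.
#' @export
read_umi <- function(path, genes = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes) || is.null(barcodes)) {
      stop("MTX input needs 'genes' and 'barcodes' sidecar files")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(barcodes)
  } else {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  storage.mode(m) <- "integer"
  m
}

#' Binarize a UMI matrix
#'
#' A gene is called "expressed" in a cell when its UMI count reaches
#' \code{min_umi}. The published analysis worked from raw UMI counts, so no
#' normalization is applied and the default threshold is a single UMI.
#'
#' @param umi Genes x cells matrix of non-negative integer counts (dense or
#'   \code{Matrix} sparse).
#' @param min_umi Minimum count to call expression (>= 1).
#' @return Logical matrix with attribute \code{"min_umi"}.
#' @export
binarize <- function(umi, min_umi = 1) {
  if (min_umi < 1) stop("min_umi must be >= 1")
  m <- as.matrix(umi)
  if (any(m < 0) || any(m != round(m))) {
    stop("UMI counts must be non-negative integers")
  }
  mask <- m >= min_umi
  attr(mask, "min_umi") <- min_umi
  mask
}

#' Per-cell expressed-target histogram
#'
#' Counts, per cell, how many of the target genes are expressed, and buckets
#' cells into 0 / 1 / 2 / >=3 expressed targets (an alternative strict
#' \code{">3"} bucketing, i.e. 0/1/2/3 vs more, is available since the
#' published figure legend is ambiguous on that point). Also reports the
#' maximum per-cell count.
#'
#' @param mask Logical expression mask (genes x cells).
#' @param targets Gene ids to count; must all be rows of \code{mask}.
#' @param bucket3 \code{">=3"} (default) or \code{">3"}.
#' @return List with \code{fractions} (named, sums to 1), \code{counts},
#'   \code{max_per_cell}.
#' @export
innexin_count_histogram <- function(mask, targets, bucket3 = c(">=3", ">3")) {
  bucket3 <- match.arg(bucket3)
  if (!length(targets)) stop("empty target set")
  missing <- setdiff(targets, rownames(mask))
  if (length(missing)) stop("targets not in matrix: ", paste(missing, collapse = ", "))
  per_cell <- colSums(mask[targets, , drop = FALSE])
  counts <- if (bucket3 == ">=3") {
    c("0" = sum(per_cell == 0), "1" = sum(per_cell == 1),
      "2" = sum(per_cell == 2), ">=3" = sum(per_cell >= 3))
  } else {
    c("0" = sum(per_cell == 0), "1" = sum(per_cell == 1),
      "2" = sum(per_cell == 2), "3" = sum(per_cell == 3),
      ">3" = sum(per_cell > 3))
  }
  list(fractions = counts / ncol(mask),
       counts = counts,
       max_per_cell = if (ncol(mask)) max(per_cell) else 0L)
}

#' Metacell marker calls
#'
#' A gene is a marker of a metacell when it is expressed in at least
#' \code{min_fraction} of the metacell's cells (inclusive boundary: exactly
#' 50\% qualifies at the default).
#'
#' @param mask Logical expression mask (genes x cells).
#' @param mc Data frame with columns \code{cell} and \code{metacell};
#'   unlabeled cells are ignored.
#' @param min_fraction Marker threshold (default 0.5).
#' @return Data frame \code{gene}, \code{metacell}, \code{fraction},
#'   \code{is_marker}.
#' @export
metacell_markers <- function(mask, mc, min_fraction = 0.5) {
  stopifnot(all(c("cell", "metacell") %in% names(mc)))
  mcs <- unique(mc$metacell)
  rows <- list()
  for (m in mcs) {
    cells <- intersect(mc$cell[mc$metacell == m], colnames(mask))
    if (!length(cells)) {
      warning("metacell ", m, " has no cells in the matrix; skipped")
      next
    }
    frac <- rowMeans(mask[, cells, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rownames(mask), metacell = m, fraction = as.numeric(frac),
      is_marker = frac >= min_fraction, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pairwise coexpression with minimum-denominator percentages
#'
#' For each pair of target genes, counts the cells expressing each gene and
#' both, and reports the coexpression percentage as 100 times the
#' joint count divided by the smaller of the two marginal counts. When
#' either gene is expressed in no cell the percentage is undefined and
#' reported as \code{NA}, never 0.
#'
#' @param mask Logical expression mask (genes x cells).
#' @param targets Gene ids (non-empty).
#' @return List of matrices \code{n} (marginal counts, named vector),
#'   \code{n_both}, \code{percent} (symmetric, 1 decimal).
#' @export
pairwise_coexpression <- function(mask, targets) {
  if (!length(targets)) stop("empty target set")
  sub <- mask[targets, , drop = FALSE] * 1L
  n <- rowSums(sub)
  n_both <- sub %*% t(sub)
  denom <- outer(n, n, pmin)
  percent <- ifelse(denom > 0, round(100 * n_both / denom, 1), NA_real_)
  dimnames(percent) <- dimnames(n_both)
  list(n = n, n_both = n_both, percent = percent)
}

#' High-coexpression gene pairs
#'
#' Unordered pairs whose coexpression percentage reaches \code{threshold}
#' (the published cutoff is 50\%), excluding self-pairs, each reported once.
#'
#' @param cm Result of \code{\link{pairwise_coexpression}}.
#' @param threshold Percentage cutoff (default 50).
#' @return Data frame \code{geneA}, \code{geneB}, \code{percent}.
#' @export
coexpression_pairs <- function(cm, threshold = 50) {
  p <- cm$percent
  g <- rownames(p)
  rows <- list()
  if (length(g) >= 2L) {
    for (i in 1:(length(g) - 1L)) {
      for (j in (i + 1L):length(g)) {
        if (!is.na(p[i, j]) && p[i, j] >= threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            geneA = g[i], geneB = g[j], percent = p[i, j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(geneA = character(0), geneB = character(0),
                      percent = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Per-sample expression ratio of two genes
#'
#' Ratio of gene A to gene B per sample (samples with B = 0 are skipped),
#' summarized by the median and the raw median absolute deviation.
#'
#' @param tpm Genes x samples numeric table (e.g. transcripts per million).
#' @param geneA,geneB Row ids.
#' @return List with \code{ratios} (named by sample), \code{median},
#'   \code{mad}.
#' @export
expression_ratio <- function(tpm, geneA, geneB) {
  a <- as.numeric(tpm[geneA, ])
  b <- as.numeric(tpm[geneB, ])
  if (all(b == 0)) stop("gene ", geneB, " is zero in every sample")
  ok <- b > 0
  r <- a[ok] / b[ok]
  names(r) <- colnames(tpm)[ok]
  list(ratios = r, median = stats::median(r),
       mad = stats::mad(r, constant = 1))
}
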