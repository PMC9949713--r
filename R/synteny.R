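#' Read a genome gene-order table
#'
#' Reads gene loci from GFF3 (only features of type \code{"gene"}) or BED.
#' GFF3 coordinates (1-based inclusive) are converted to the 0-based
#' half-open convention used internally; BED is already 0-based half-open.
#' Family labels come from an optional assignment table; unassigned genes
#' get family \code{"other"}.
#'
#' @param path GFF3 (\code{.gff}/\code{.gff3}) or BED file.
#' @param family_map Optional data frame (\code{gene}, \code{family}).
#' @param id_attr GFF3 attribute holding the gene id (default \code{"ID"}).
#' @return Data frame with columns \code{gene}, \code{seqid}, \code{start},
#'   \code{end}, \code{strand}, \code{family} (0-based half-open).
#' @export
read_gene_loci <- function(path, family_map = NULL, id_attr = "ID") {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) {
    df <- df[as.character(df$type) == "gene", , drop = FALSE]
  }
  id <- if ("name" %in% names(df)) {
    as.character(df$name)             # BED name column
  } else if (id_attr %in% names(df)) {
    as.character(df[[id_attr]])
  } else {
    stop("cannot find gene ids (no '", id_attr, "' attribute or BED name)")
  }
  # rtracklayer presents both formats 1-based inclusive; convert once
  loci <- data.frame(gene = id,
                     seqid = as.character(df$seqnames),
                     start = df$start - 1L,
                     end = df$end,
                     strand = as.character(df$strand),
                     stringsAsFactors = FALSE)
  loci$family <- "other"
  if (!is.null(family_map)) {
    idx <- match(loci$gene, family_map$gene)
    hit <- !is.na(idx)
    loci$family[hit] <- family_map$family[idx[hit]]
  }
  if (any(loci$start >= loci$end)) stop("locus with start >= end")
  loci
}

#' Detect tandem clusters of family members
#'
#' Chains target-family loci along each sequence: consecutive members (by
#' start coordinate) belong to one cluster when the boundary-to-boundary
#' distance from the end of the previous member to the start of the next is
#' at most \code{max_gap}. Singleton chains are reported too, so the
#' clusters partition the target loci. For each internal gap the number of
#' non-target genes lying strictly between the two members is recorded.
#'
#' @param loci Gene-locus data frame (see \code{\link{read_gene_loci}});
#'   coordinates 0-based half-open.
#' @param target_families Character vector of family labels to cluster.
#' @param max_gap Maximum inter-gene distance in bp (default 40000, the
#'   working threshold for the innexin clusters).
#' @return List of clusters; each has \code{members} (data frame of loci in
#'   order), \code{seqid}, \code{span} (bp), \code{intervening} (per-gap
#'   counts) and \code{n_intervening}.
#' @export
find_family_clusters <- function(loci, target_families,
                                 max_gap = 40000) {
  if (max_gap < 0) stop("max_gap must be non-negative")
  out <- list()
  for (sq in unique(loci$seqid)) {
    sub <- loci[loci$seqid == sq, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    tgt <- sub[sub$family %in% target_families, , drop = FALSE]
    oth <- sub[!(sub$family %in% target_families), , drop = FALSE]
    if (!nrow(tgt)) next
    chain_start <- 1L
    flush <- function(i0, i1) {
      mem <- tgt[i0:i1, , drop = FALSE]
      gaps <- integer(0)
      if (nrow(mem) > 1L) {
        for (j in seq_len(nrow(mem) - 1L)) {
          gaps <- c(gaps, sum(oth$start >= mem$end[j] &
                              oth$end <= mem$start[j + 1L]))
        }
      }
      list(members = mem, seqid = sq,
           span = max(mem$end) - min(mem$start),
           intervening = gaps, n_intervening = sum(gaps))
    }
    if (nrow(tgt) > 1L) {
      for (i in 2:nrow(tgt)) {
        if (tgt$start[i] - tgt$end[i - 1L] > max_gap) {
          out[[length(out) + 1L]] <- flush(chain_start, i - 1L)
          chain_start <- i
        }
      }
    }
    out[[length(out) + 1L]] <- flush(chain_start, nrow(tgt))
  }
  out
}

# per-sequence gene rank (order by start) for a locus table
gene_ranks <- function(loci) {
  rk <- integer(nrow(loci))
  for (sq in unique(loci$seqid)) {
    i <- which(loci$seqid == sq)
    rk[i] <- rank(loci$start[i], ties.method = "first")
  }
  rk
}

#' Detect conserved microsynteny blocks between two genomes
#'
#' A block is a maximal set of ortholog pairs whose genes occupy consecutive
#' gene ranks in both genomes (gene order within the block and strand are
#' ignored). Genes without an ortholog interrupt blocks. Blocks shorter than
#' \code{min_len} are dropped.
#'
#' @param genomeA,genomeB Gene-locus data frames.
#' @param orthologs Data frame with columns \code{geneA}, \code{geneB};
#'   must be one-to-one on the genes it covers.
#' @param min_len Minimum block length in genes (default 2).
#' @return List of blocks; each has \code{pairs} (data frame \code{geneA},
#'   \code{geneB}), \code{length}, \code{seqidA}, \code{seqidB}.
#' @export
microsynteny_blocks <- function(genomeA, genomeB, orthologs, min_len = 2) {
  if (anyDuplicated(orthologs$geneA) || anyDuplicated(orthologs$geneB)) {
    bad <- c(orthologs$geneA[duplicated(orthologs$geneA)],
             orthologs$geneB[duplicated(orthologs$geneB)])
    stop("ortholog map is not one-to-one: ", paste(unique(bad), collapse = ", "))
  }
  ordA <- order(genomeA$seqid, genomeA$start)
  A <- genomeA[ordA, , drop = FALSE]
  rkA <- gene_ranks(A)
  rkB <- gene_ranks(genomeB)
  # for each gene of A (in rank order): its partner's seqid and rank in B
  iB <- match(orthologs$geneB[match(A$gene, orthologs$geneA)], genomeB$gene)
  partner_seq <- genomeB$seqid[iB]
  partner_rank <- rkB[iB]

  blocks <- list()
  n <- nrow(A)
  i <- 1L
  while (i <= n) {
    if (is.na(iB[i])) { i <- i + 1L; next }
    best_j <- i
    j <- i
    lo <- hi <- partner_rank[i]
    while (j < n &&
           !is.na(iB[j + 1L]) &&
           A$seqid[j + 1L] == A$seqid[i] &&
           rkA[j + 1L] == rkA[j] + 1L &&
           partner_seq[j + 1L] == partner_seq[i]) {
      j <- j + 1L
      lo <- min(lo, partner_rank[j]); hi <- max(hi, partner_rank[j])
      if (hi - lo == j - i) best_j <- j   # B ranks form a consecutive run
    }
    j <- best_j
    # confirm the accepted window itself is consecutive in B
    win <- partner_rank[i:j]
    if (max(win) - min(win) == j - i) {
      blocks[[length(blocks) + 1L]] <- list(
        pairs = data.frame(geneA = A$gene[i:j],
                           geneB = genomeB$gene[iB[i:j]],
                           stringsAsFactors = FALSE),
        length = j - i + 1L,
        seqidA = A$seqid[i], seqidB = partner_seq[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  blocks[vapply(blocks, function(b) b$length >= min_len, logical(1))]
}

#' Write clusters or blocks to TSV
#'
#' @param clusters Result of \code{\link{find_family_clusters}}.
#' @param path Output TSV path.
#' @return \code{clusters}, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, seqid = cl$seqid,
               gene = cl$members$gene, family = cl$members$family,
               start = cl$members$start, end = cl$members$end,
               span = cl$span, n_intervening = cl$n_intervening,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(clusters)
}
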