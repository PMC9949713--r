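# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive enumeration rather than calling package internals.

# --- tree plumbing (standalone, edge-matrix based) -------------------------

h_parent <- function(phy) {
  p <- integer(ape::Ntip(phy) + phy$Nnode)
  p[phy$edge[, 2]] <- phy$edge[, 1]
  p
}

h_path_to_root <- function(phy, v) {
  p <- h_parent(phy)
  root <- ape::Ntip(phy) + 1L
  path <- v
  while (v != root) {
    v <- p[v]
    path <- c(path, v)
  }
  path
}

# tip ids below node v (inclusive for tips)
h_tips_below <- function(phy, v) {
  ntip <- ape::Ntip(phy)
  if (v <= ntip) return(v)
  kids <- phy$edge[phy$edge[, 1] == v, 2]
  unlist(lapply(kids, h_tips_below, phy = phy))
}

# all node ids strictly below v
h_desc_nodes <- function(phy, v) {
  kids <- phy$edge[phy$edge[, 1] == v, 2]
  if (!length(kids)) return(integer(0))
  c(kids, unlist(lapply(kids, h_desc_nodes, phy = phy)))
}

h_mrca <- function(phy, tip_ids) {
  paths <- lapply(tip_ids, h_path_to_root, phy = phy)
  common <- Reduce(intersect, paths)
  common[1]  # paths run leaf -> root, first common element is the MRCA
}

# --- Dollo: exhaustive minimal-loss search under a single gain -------------

oracle_dollo_min_losses <- function(presence, sp) {
  ntip <- ape::Ntip(sp)
  pres_ids <- match(presence, sp$tip.label)
  all_nodes <- seq_len(ntip + sp$Nnode)
  best <- Inf
  for (g in all_nodes) {
    clade <- h_tips_below(sp, g)
    if (!all(pres_ids %in% clade)) next
    cand <- h_desc_nodes(sp, g)   # candidate loss branches below the gain
    leaf_paths <- lapply(clade, function(l) h_path_to_root(sp, l))
    found <- NA
    for (k in 0:length(cand)) {
      combos <- if (k == 0) list(integer(0)) else
        utils::combn(cand, k, simplify = FALSE)
      for (cs in combos) {
        pred <- clade[vapply(leaf_paths, function(pp) {
          seg <- pp[seq_len(which(pp == g))]   # path leaf..gain
          !any(cs %in% seg)
        }, logical(1))]
        if (setequal(pred, pres_ids)) { found <- k; break }
      }
      if (!is.na(found)) break
    }
    if (!is.na(found) && found < best) best <- found
  }
  best
}

# --- isoform removal: repeated exhaustive sister-pair scan -----------------

oracle_dedup_tips <- function(tree, focal, tol = 1e-9) {
  repeat {
    ntip <- ape::Ntip(tree)
    tip_edge <- match(seq_len(ntip), tree$edge[, 2])
    len <- tree$edge.length[tip_edge]
    par <- tree$edge[tip_edge, 1]
    spp <- sub("_.*$", "", tree$tip.label)
    victim <- NULL
    for (a in seq_len(ntip - 1)) {
      for (b in (a + 1):ntip) {
        if (par[a] == par[b] && spp[a] == spp[b] && spp[a] %in% focal &&
            len[a] <= tol && len[b] <= tol) {
          victim <- if (tree$tip.label[a] < tree$tip.label[b]) b else a
          break
        }
      }
      if (!is.null(victim)) break
    }
    if (is.null(victim)) return(sort(tree$tip.label))
    tree <- ape::drop.tip(tree, victim)
  }
}

# --- synteny: O(n^2) chain enumeration and all-intervals block scan --------

oracle_chain_clusters <- function(loci, targets, max_gap) {
  out <- list()
  for (sq in unique(loci$seqid)) {
    tgt <- loci[loci$seqid == sq & loci$family %in% targets, , drop = FALSE]
    tgt <- tgt[order(tgt$start), , drop = FALSE]
    if (!nrow(tgt)) next
    # boolean chain links, then connected runs
    linked <- if (nrow(tgt) > 1)
      tgt$start[-1] - tgt$end[-nrow(tgt)] <= max_gap else logical(0)
    i <- 1
    while (i <= nrow(tgt)) {
      j <- i
      while (j < nrow(tgt) && linked[j]) j <- j + 1
      out[[length(out) + 1]] <- sort(tgt$gene[i:j])
      i <- j + 1
    }
  }
  out
}

oracle_blocks <- function(genomeA, genomeB, orthologs, min_len) {
  rk <- function(g) {
    r <- integer(nrow(g))
    for (sq in unique(g$seqid)) {
      i <- which(g$seqid == sq)
      r[i] <- rank(g$start[i])
    }
    r
  }
  A <- genomeA[order(genomeA$seqid, genomeA$start), ]
  rkA <- rk(A); rkB <- rk(genomeB)
  iB <- match(orthologs$geneB[match(A$gene, orthologs$geneA)], genomeB$gene)
  n <- nrow(A)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      w <- i:j
      if (any(is.na(iB[w]))) next
      if (length(unique(A$seqid[w])) > 1) next
      if (rkA[j] - rkA[i] != j - i) next
      bseq <- genomeB$seqid[iB[w]]
      if (length(unique(bseq)) > 1) next
      br <- rkB[iB[w]]
      if (max(br) - min(br) != j - i) next
      cand[[length(cand) + 1]] <- w
    }
  }
  # maximality: drop intervals contained in another candidate
  keep <- vapply(seq_along(cand), function(k) {
    !any(vapply(seq_along(cand), function(m) {
      m != k && cand[[k]][1] >= cand[[m]][1] &&
        cand[[k]][length(cand[[k]])] <= cand[[m]][length(cand[[m]])]
    }, logical(1)))
  }, logical(1))
  cand <- cand[keep]
  cand <- cand[vapply(cand, length, integer(1)) >= min_len]
  lapply(cand, function(w) sort(A$gene[w]))
}

# --- misc builders ---------------------------------------------------------

# random rooted gene tree whose tips are labeled "<Sp>_g<i>"
random_gene_tree <- function(n_tips, species_pool) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0(sample(species_pool, n_tips, replace = TRUE),
                         "_g", seq_len(n_tips))
  tr
}

# random rooted species tree over n uppercase species codes
random_species_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("S", seq_len(n))
  tr$node.label <- NULL
  tr
}

sorted_event_key <- function(df) {
  sort(paste(df$family, df$kind, df$branch, sep = "|"))
}
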