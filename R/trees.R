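#' Species tree for the four-ctenophore analysis
#'
#' Returns the rooted species tree used throughout the event-reconstruction
#' module. The default topology places *Beroe ovata* (Bo) with *Mnemiopsis
#' leidyi* (Ml) and *Pleurobrachia bachei* (Pb) with *Hormiphora
#' californensis* (Hc), i.e. ((Bo,Ml),(Pb,Hc)), which is the topology implied
#' by the stated family origins on the BoMl and PbHc ancestors.
#'
#' @param newick Optional Newick string overriding the default topology. The
#'   tree must be rooted and have unique tip labels.
#' @return An object of class \code{phylo}.
#' @examples
#' sp <- species_tree()
#' sp$tip.label
#' @export
species_tree <- function(newick = NULL) {
  if (is.null(newick)) {
    newick <- "((Bo,Ml)BoMl-ancestor,(Pb,Hc)PbHc-ancestor)root;"
  }
  sp <- ape::read.tree(text = newick)
  if (is.null(sp)) stop("could not parse species tree Newick")
  if (anyDuplicated(sp$tip.label)) stop("species tree tip labels must be unique")
  sp
}

# Root node id of a phylo object.
tree_root <- function(phy) {
  ape::Ntip(phy) + 1L
}

# children of each node, as a list indexed by node id
node_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

# for every node, the path of node ids from the root down to it (inclusive)
root_paths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- tree_root(phy)
  paths <- vector("list", n)
  for (v in seq_len(n)) {
    path <- v
    w <- v
    while (w != root) {
      w <- parent[w]
      path <- c(w, path)
    }
    paths[[v]] <- path
  }
  paths
}

# MRCA of a set of node ids given precomputed root paths
mrca_nodes <- function(paths, nodes) {
  nodes <- unique(nodes)
  common <- paths[[nodes[1L]]]
  for (v in nodes[-1L]) {
    common <- common[common %in% paths[[v]]]
  }
  common[length(common)]
}

# tip labels descending from each node
tips_under <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  kids <- node_children(phy)
  out <- vector("list", n)
  rec <- function(v) {
    if (v <= ntip) {
      out[[v]] <<- phy$tip.label[v]
    } else {
      acc <- character(0)
      for (k in kids[[v]]) {
        rec(k)
        acc <- c(acc, out[[k]])
      }
      out[[v]] <<- acc
    }
  }
  rec(tree_root(phy))
  out
}

#' Branch names of a species tree
#'
#' Every node of a rooted tree identifies the branch leading to it. Terminal
#' branches are named by their species code; internal branches by the node
#' label if present, otherwise by the concatenated sorted tip labels of the
#' clade plus \code{"-ancestor"}; the root branch (the stem of the whole
#' clade) is named \code{"root/stem"}.
#'
#' @param sp A species tree (\code{phylo}).
#' @return Character vector indexed by node id.
#' @export
branch_names <- function(sp) {
  ntip <- ape::Ntip(sp)
  n <- ntip + sp$Nnode
  root <- tree_root(sp)
  under <- tips_under(sp)
  nm <- character(n)
  nm[seq_len(ntip)] <- sp$tip.label
  for (v in (ntip + 1L):n) {
    lab <- if (!is.null(sp$node.label)) sp$node.label[v - ntip] else ""
    if (is.na(lab) || !nzchar(lab)) {
      lab <- paste0(paste(sort(under[[v]]), collapse = ""), "-ancestor")
    }
    nm[v] <- lab
  }
  nm[root] <- "root/stem"
  nm
}

# node id for a branch name (inverse of branch_names)
branch_node <- function(sp, branch) {
  nm <- branch_names(sp)
  idx <- match(branch, nm)
  if (anyNA(idx)) {
    stop("unknown branch name(s): ", paste(branch[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Species codes of gene-tree tips
#'
#' Tips follow the \code{"<SpeciesCode>_<geneid>"} convention; a sidecar
#' mapping (columns \code{tip}, \code{species}) overrides the convention for
#' any tip it names.
#'
#' @param labels Character vector of tip labels.
#' @param species_map Optional data frame with columns \code{tip} and
#'   \code{species}.
#' @return Character vector of species codes, same length as \code{labels}.
#' @export
tip_species <- function(labels, species_map = NULL) {
  sp <- sub("_.*$", "", labels)
  if (!is.null(species_map)) {
    idx <- match(labels, species_map$tip)
    hit <- !is.na(idx)
    sp[hit] <- species_map$species[idx[hit]]
  }
  sp
}
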