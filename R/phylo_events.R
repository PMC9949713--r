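#' Remove zero-length same-species isoform tips
#'
#' Transcriptome assemblies often carry several isoforms of one gene; on a
#' gene tree these appear as same-species sister tips joined by (near)
#' zero-length terminal branches. This collapses every such cherry to a
#' single representative, keeping the lexicographically smallest tip id, and
#' repeats until no qualifying cherry remains, so the operation is
#' idempotent. Only species in \code{focal_species} are touched.
#'
#' @param tree Gene tree (\code{phylo}) with branch lengths.
#' @param focal_species Character vector of species codes to deduplicate.
#' @param species_map Optional tip-to-species sidecar (see
#'   \code{\link{tip_species}}).
#' @param tol Terminal branch lengths \code{<= tol} count as zero. Default
#'   \code{1e-9}.
#' @return The pruned gene tree (\code{phylo}).
#' @export
dedup_isoforms <- function(tree, focal_species, species_map = NULL, tol = 1e-9) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("gene tree has no branch lengths (first tip: ", tree$tip.label[1L], ")")
  }
  repeat {
    ntip <- ape::Ntip(tree)
    term_len <- numeric(ntip)
    tip_edge <- match(seq_len(ntip), tree$edge[, 2L])
    term_len <- tree$edge.length[tip_edge]
    bad <- which(is.na(term_len))
    if (length(bad)) {
      stop("missing terminal branch length for tip ", tree$tip.label[bad[1L]])
    }
    parent <- tree$edge[tip_edge, 1L]
    spp <- tip_species(tree$tip.label, species_map)
    drop <- character(0)
    for (p in unique(parent)) {
      kids <- which(parent == p)
      for (s in unique(spp[kids])) {
        if (!(s %in% focal_species)) next
        grp <- kids[spp[kids] == s & term_len[kids] <= tol]
        if (length(grp) >= 2L) {
          keep <- grp[order(tree$tip.label[grp])][1L]
          drop <- c(drop, tree$tip.label[setdiff(grp, keep)])
        }
      }
    }
    if (!length(drop)) break
    if (length(drop) >= ape::Ntip(tree) - 1L) {
      # never drop down to an empty tree
      drop <- drop[seq_len(ape::Ntip(tree) - 2L)]
    }
    tree <- ape::drop.tip(tree, drop)
  }
  tree
}

#' Tabulate family copy numbers per species
#'
#' Counts, for every (family, species) pair, the number of gene-tree tips
#' assigned to that family in that species. Tips absent from the assignment
#' are reported separately, not counted.
#'
#' @param tree Gene tree (\code{phylo}).
#' @param fam Data frame with columns \code{gene} and \code{family}; every
#'   assigned gene must be a tip of \code{tree}.
#' @param sp Species tree; fixes the species (column) order.
#' @param species_map Optional tip-to-species sidecar.
#' @return Integer matrix families x species with attribute
#'   \code{"unassigned"} listing unassigned tip labels.
#' @export
build_presence_matrix <- function(tree, fam, sp = species_tree(),
                                  species_map = NULL) {
  stopifnot(is.data.frame(fam), all(c("gene", "family") %in% names(fam)))
  missing <- setdiff(fam$gene, tree$tip.label)
  if (length(missing)) {
    stop("assigned gene(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  species <- sp$tip.label
  fams <- sort(unique(fam$family))
  m <- matrix(0L, nrow = length(fams), ncol = length(species),
              dimnames = list(fams, species))
  spp <- tip_species(tree$tip.label, species_map)
  idx <- match(tree$tip.label, fam$gene)
  for (i in seq_along(tree$tip.label)) {
    if (is.na(idx[i])) next
    f <- fam$family[idx[i]]
    s <- spp[i]
    if (!(s %in% species)) {
      stop("tip ", tree$tip.label[i], " has species code '", s,
           "' not in the species tree")
    }
    m[f, s] <- m[f, s] + 1L
  }
  attr(m, "unassigned") <- tree$tip.label[is.na(idx)]
  m
}

#' LCA mapping of a gene (sub)tree onto the species tree
#'
#' Standard reconciliation primitive: each gene-tree tip maps to its species
#' leaf; each internal node maps to the most recent common ancestor (in the
#' species tree) of its children's images.
#'
#' @param subtree Gene tree (\code{phylo}), typically one family's subtree.
#' @param sp Species tree.
#' @param species_map Optional tip-to-species sidecar.
#' @return Integer vector of species-tree node ids indexed by gene-tree node
#'   id, with the corresponding branch names as names.
#' @export
lca_map <- function(subtree, sp = species_tree(), species_map = NULL) {
  ntip <- ape::Ntip(subtree)
  n <- ntip + subtree$Nnode
  spp <- tip_species(subtree$tip.label, species_map)
  leaf_idx <- match(spp, sp$tip.label)
  if (anyNA(leaf_idx)) {
    stop("unknown species code(s): ",
         paste(unique(spp[is.na(leaf_idx)]), collapse = ", "))
  }
  paths <- root_paths(sp)
  kids <- node_children(subtree)
  img <- integer(n)
  rec <- function(v) {
    if (v <= ntip) {
      img[v] <<- leaf_idx[v]
    } else {
      for (k in kids[[v]]) rec(k)
      img[v] <<- mrca_nodes(paths, img[kids[[v]]])
    }
  }
  rec(tree_root(subtree))
  names(img) <- branch_names(sp)[img]
  img
}

#' Infer duplication events by LCA mapping
#'
#' An internal gene-tree node is a duplication when it maps to the same
#' species-tree node as at least one of its children: the split predates no
#' speciation, so two co-resident copies must have arisen by duplication.
#' Each duplication is placed on the species-tree branch leading to the
#' node's image.
#'
#' @param family_subtree Gene tree restricted to one family's genes.
#' @param sp Species tree.
#' @param species_map Optional tip-to-species sidecar.
#' @return Character vector of species-tree branch names, one per
#'   duplication node (empty when the subtree has fewer than two tips).
#' @export
infer_duplications <- function(family_subtree, sp = species_tree(),
                               species_map = NULL) {
  ntip <- ape::Ntip(family_subtree)
  if (ntip < 2L) return(character(0))
  img <- lca_map(family_subtree, sp, species_map)
  kids <- node_children(family_subtree)
  nm <- branch_names(sp)
  out <- character(0)
  for (v in (ntip + 1L):(ntip + family_subtree$Nnode)) {
    if (any(img[kids[[v]]] == img[v])) {
      out <- c(out, nm[img[v]])
    }
  }
  out
}

#' Dollo gain and loss placement for one family
#'
#' Under Dollo parsimony a family is gained exactly once, on the branch
#' subtending the MRCA of the species that have it; absence from a clade
#' below that node is explained by a loss on the most ancestral (maximal)
#' branch whose entire descendant clade lacks the family. This placement
#' minimizes the loss count under the single-gain constraint.
#'
#' @param presence Character vector of species codes possessing the family.
#' @param sp Species tree.
#' @return List with \code{gain} (branch name) and \code{losses} (character
#'   vector of branch names, possibly empty).
#' @export
dollo_events <- function(presence, sp = species_tree()) {
  presence <- unique(as.character(presence))
  if (!length(presence)) stop("empty presence set")
  bad <- setdiff(presence, sp$tip.label)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  nm <- branch_names(sp)
  paths <- root_paths(sp)
  tips <- match(presence, sp$tip.label)
  gain_node <- mrca_nodes(paths, tips)
  under <- tips_under(sp)
  kids <- node_children(sp)
  losses <- character(0)
  visit <- function(v) {
    for (k in kids[[v]]) {
      if (!any(under[[k]] %in% presence)) {
        losses <<- c(losses, nm[k])
      } else if (k > ape::Ntip(sp)) {
        visit(k)
      }
    }
  }
  if (gain_node > ape::Ntip(sp)) visit(gain_node)
  list(gain = nm[gain_node], losses = losses)
}

#' Check family monophyly on the gene tree
#'
#' A family is monophyletic when the MRCA of its genes contains no gene
#' assigned to another family (tips without an assignment are ignored).
#'
#' @inheritParams build_presence_matrix
#' @return Data frame with columns \code{family}, \code{monophyletic}, and
#'   \code{intruders} (comma-separated intruding tip labels, \code{""} if
#'   none).
#' @export
validate_family_monophyly <- function(tree, fam) {
  fams <- sort(unique(fam$family))
  paths <- root_paths(tree)
  under <- tips_under(tree)
  assigned <- fam$family[match(tree$tip.label, fam$gene)]
  out <- data.frame(family = fams, monophyletic = NA,
                    intruders = "", stringsAsFactors = FALSE)
  for (i in seq_along(fams)) {
    genes <- fam$gene[fam$family == fams[i]]
    ids <- match(genes, tree$tip.label)
    node <- mrca_nodes(paths, ids)
    clade <- under[[node]]
    clade_fam <- assigned[match(clade, tree$tip.label)]
    intr <- clade[!is.na(clade_fam) & clade_fam != fams[i]]
    out$monophyletic[i] <- length(intr) == 0L
    out$intruders[i] <- paste(intr, collapse = ",")
  }
  out
}

#' Reconstruct the full event set and summary
#'
#' Runs \code{\link{dollo_events}} on each family's species presence and
#' \code{\link{infer_duplications}} on each family's gene subtree, then
#' assembles totals and the predicted terminal gene count per species. A
#' duplication is taken to propagate one extra copy to every descendant
#' species that retains the family, so the predicted count for species s is
#' the number of families present in s plus the number of duplication events
#' on branches ancestral to (or equal to) s's terminal branch in families s
#' retains.
#'
#' @param matrix Presence matrix from \code{\link{build_presence_matrix}}.
#' @param tree Gene tree containing all assigned genes.
#' @param fam Family assignment data frame (\code{gene}, \code{family}).
#' @param sp Species tree.
#' @param species_map Optional tip-to-species sidecar.
#' @return Object of class \code{innexin_events}: list with \code{events}
#'   (data frame \code{family}, \code{kind}, \code{branch}) and
#'   \code{summary} (totals, per-branch loss/duplication counts, predicted
#'   terminal counts).
#' @export
summarize_events <- function(matrix, tree, fam, sp = species_tree(),
                             species_map = NULL) {
  if (any(rowSums(matrix) == 0L)) {
    stop("family with zero copies everywhere: ",
         paste(rownames(matrix)[rowSums(matrix) == 0L], collapse = ", "))
  }
  species <- colnames(matrix)
  under <- tips_under(sp)
  events <- list()
  for (f in rownames(matrix)) {
    pres <- species[matrix[f, ] > 0L]
    de <- dollo_events(pres, sp)
    events[[length(events) + 1L]] <-
      data.frame(family = f, kind = "gain", branch = de$gain,
                 stringsAsFactors = FALSE)
    if (length(de$losses)) {
      events[[length(events) + 1L]] <-
        data.frame(family = f, kind = "loss", branch = de$losses,
                   stringsAsFactors = FALSE)
    }
    genes <- fam$gene[fam$family == f]
    if (length(genes) >= 2L) {
      sub <- ape::keep.tip(tree, genes)
      dups <- infer_duplications(sub, sp, species_map)
      if (length(dups)) {
        events[[length(events) + 1L]] <-
          data.frame(family = f, kind = "duplication", branch = dups,
                     stringsAsFactors = FALSE)
      }
    }
  }
  events <- do.call(rbind, events)
  rownames(events) <- NULL

  losses <- events[events$kind == "loss", ]
  dups <- events[events$kind == "duplication", ]
  gains <- events[events$kind == "gain", ]

  # predicted terminal counts: families present + ancestral duplications
  terminal <- stats::setNames(integer(length(species)), species)
  for (s in species) {
    n <- sum(matrix[, s] > 0L)
    if (nrow(dups)) {
      for (j in seq_len(nrow(dups))) {
        clade <- under[[branch_node(sp, dups$branch[j])]]
        if (s %in% clade && matrix[dups$family[j], s] > 0L) n <- n + 1L
      }
    }
    terminal[s] <- n
  }

  per_branch <- function(d) {
    if (!nrow(d)) return(integer(0))
    tab <- table(d$branch)
    stats::setNames(as.integer(tab), names(tab))
  }
  summary <- list(
    n_families = nrow(matrix),
    n_stem_gains = sum(gains$branch == "root/stem"),
    n_losses = nrow(losses),
    n_duplications = nrow(dups),
    losses_per_branch = per_branch(losses),
    duplications_per_branch = per_branch(dups),
    terminal_counts = terminal,
    observed_terminal_counts = colSums(matrix)
  )
  structure(list(events = events, summary = summary, presence = matrix),
            class = "innexin_events")
}

#' @export
print.innexin_events <- function(x, ...) {
  s <- x$summary
  cat("Gene-family event reconstruction\n")
  cat(sprintf("  families: %d (stem gains: %d)\n", s$n_families, s$n_stem_gains))
  cat(sprintf("  losses: %d  duplications: %d\n", s$n_losses, s$n_duplications))
  if (length(s$losses_per_branch)) {
    cat("  losses per branch: ",
        paste(sprintf("%s=%d", names(s$losses_per_branch), s$losses_per_branch),
              collapse = ", "), "\n", sep = "")
  }
  cat("  predicted terminal counts: ",
      paste(sprintf("%s=%d", names(s$terminal_counts), s$terminal_counts),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.innexin_events <- function(object, ...) object$summary

#' Write an event set to TSV and its summary to JSON
#'
#' @param x \code{innexin_events} object.
#' @param events_tsv,summary_json Output paths (either may be \code{NULL} to
#'   skip).
#' @return \code{x}, invisibly.
#' @export
write_events <- function(x, events_tsv = NULL, summary_json = NULL) {
  stopifnot(inherits(x, "innexin_events"))
  if (!is.null(events_tsv)) {
    utils::write.table(x$events, events_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_json)) {
    s <- x$summary
    s$losses_per_branch <- as.list(s$losses_per_branch)
    s$duplications_per_branch <- as.list(s$duplications_per_branch)
    s$terminal_counts <- as.list(s$terminal_counts)
    s$observed_terminal_counts <- as.list(s$observed_terminal_counts)
    jsonlite::write_json(s, summary_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(x)
}
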