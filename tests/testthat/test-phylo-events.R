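test_that("zero-length same-species cherries collapse to one representative", {
  tr <- ape::read.tree(text = "((Hc_A:0.0,Hc_B:0.0):0.1,Ml_1:0.2);")
  out <- dedup_isoforms(tr, focal_species = "Hc")
  expect_setequal(out$tip.label, c("Hc_A", "Ml_1"))  # lexicographic keep

  # trees without zero-length cherries are untouched
  tr2 <- ape::read.tree(text = "((Hc_A:0.01,Hc_B:0.02):0.1,Ml_1:0.2);")
  expect_setequal(dedup_isoforms(tr2, "Hc")$tip.label, tr2$tip.label)

  # non-focal species are never touched
  expect_setequal(dedup_isoforms(tr, focal_species = "Ml")$tip.label,
                  tr$tip.label)

  # missing branch lengths raise an error naming a tip
  tr3 <- tr; tr3$edge.length <- NULL
  expect_error(dedup_isoforms(tr3, "Hc"), "branch length")
})

test_that("isoform removal matches the exhaustive sister-pair oracle and is idempotent", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    tr <- random_gene_tree(n, c("Hc", "Ml", "Pb", "Bo"))
    # plant zero-length cherries by zeroing some cherry terminal branches
    tip_edge <- match(seq_len(n), tr$edge[, 2])
    par <- tr$edge[tip_edge, 1]
    for (p in unique(par[duplicated(par)])) {
      if (stats::runif(1) < 0.6) {
        k <- which(par == p)
        tr$edge.length[tip_edge[k]] <- 0
        # make the cherry same-species half the time
        if (stats::runif(1) < 0.5) {
          sp <- sub("_.*", "", tr$tip.label[k[1]])
          tr$tip.label[k] <- sub("^[^_]+", sp, tr$tip.label[k])
        }
      }
    }
    got <- dedup_isoforms(tr, c("Hc", "Ml", "Pb", "Bo"))
    expect_equal(sort(got$tip.label),
                 oracle_dedup_tips(tr, c("Hc", "Ml", "Pb", "Bo")))
    again <- dedup_isoforms(got, c("Hc", "Ml", "Pb", "Bo"))
    expect_equal(sort(again$tip.label), sort(got$tip.label))
  }
})

test_that("presence matrix tallies copies per family and species", {
  tr <- ape::read.tree(text = "((Ml_G1:1,Ml_G2:1):1,(Bo_G:1,Hc_x:1):1);")
  fam <- data.frame(gene = c("Ml_G1", "Ml_G2", "Bo_G"),
                    family = c("INXG", "INXG", "INXG"))
  m <- build_presence_matrix(tr, fam)
  expect_equal(m["INXG", ], c(Bo = 1L, Ml = 2L, Pb = 0L, Hc = 0L))
  expect_equal(attr(m, "unassigned"), "Hc_x")

  # empty assignment gives an empty matrix
  m0 <- build_presence_matrix(tr, data.frame(gene = character(0),
                                             family = character(0)))
  expect_equal(nrow(m0), 0L)

  # assigned gene missing from the tree errors
  expect_error(build_presence_matrix(
    tr, data.frame(gene = "nope", family = "INXA")), "absent")

  # random assignments equal a direct tally
  set.seed(4)
  tr2 <- random_gene_tree(100, c("Bo", "Ml", "Pb", "Hc"))
  fam2 <- data.frame(gene = sample(tr2$tip.label, 70),
                     family = sample(paste0("F", 1:8), 70, replace = TRUE))
  m2 <- build_presence_matrix(tr2, fam2)
  for (f in unique(fam2$family)) {
    for (s in c("Bo", "Ml", "Pb", "Hc")) {
      expect_identical(m2[f, s],
                       sum(startsWith(fam2$gene, paste0(s, "_")) &
                             fam2$family == f))
    }
  }
})

test_that("LCA mapping agrees with brute-force MRCA over tip sets", {
  sp <- species_tree()
  tr <- ape::read.tree(text = "((Pb_a:1,Hc_a:1):1,Bo_a:1);")
  img <- lca_map(tr, sp)
  expect_equal(names(img)[1], "Pb")        # tips map to their species leaf
  expect_equal(names(img)[5], "PbHc-ancestor")
  expect_equal(names(img)[4], "root/stem") # gene-tree root spans both sides

  expect_error(lca_map(ape::read.tree(text = "(Xx_1:1,Bo_1:1);"), sp),
               "unknown species")

  set.seed(7)
  sp6 <- random_species_tree(6)
  for (rep in 1:25) {
    tr6 <- random_gene_tree(10, sp6$tip.label)
    img6 <- lca_map(tr6, sp6)
    # brute force: every node maps to the MRCA of its tip species
    for (v in seq_len(ape::Ntip(tr6) + tr6$Nnode)) {
      tips <- h_tips_below(tr6, v)
      spcodes <- unique(sub("_.*", "", tr6$tip.label[tips]))
      expect_identical(unname(img6[v]),
                       h_mrca(sp6, match(spcodes, sp6$tip.label)))
    }
  }
})

test_that("duplication nodes are called where a node and child co-map", {
  sp <- species_tree()
  expect_equal(infer_duplications(
    ape::read.tree(text = "(Ml_G1:1,Ml_G2:1);"), sp), "Ml")
  expect_equal(infer_duplications(
    ape::read.tree(text = "((Pb_a:1,Hc_a:1):1,(Pb_b:1,Hc_b:1):1);"), sp),
    "PbHc-ancestor")
  # species-tree-concordant single-copy family: no duplications
  expect_length(infer_duplications(
    ape::read.tree(text = "((Bo_x:1,Ml_x:1):1,(Pb_x:1,Hc_x:1):1);"), sp), 0)
  # single tip: empty result, not an error
  expect_length(infer_duplications(
    ape::read.tree(text = "(Pb_a:1,Hc_a:1);") |> ape::keep.tip("Pb_a"), sp), 0)
})

test_that("Dollo placement puts the gain at the MRCA and losses on maximal absent clades", {
  sp <- species_tree()
  d <- dollo_events(c("Bo", "Hc"), sp)
  expect_equal(d$gain, "root/stem")
  expect_setequal(d$losses, c("Ml", "Pb"))

  d2 <- dollo_events(c("Bo", "Ml", "Pb", "Hc"), sp)
  expect_equal(d2$gain, "root/stem")
  expect_length(d2$losses, 0)

  d3 <- dollo_events("Hc", sp)
  expect_equal(d3$gain, "Hc")
  expect_length(d3$losses, 0)

  expect_error(dollo_events(character(0), sp), "empty")

  # every non-empty subset of the 4 species matches exhaustive search
  species <- sp$tip.label
  for (k in 1:4) {
    for (idx in utils::combn(4, k, simplify = FALSE)) {
      pres <- species[idx]
      expect_identical(length(dollo_events(pres, sp)$losses),
                       as.integer(oracle_dollo_min_losses(pres, sp)),
                       info = paste(pres, collapse = ","))
    }
  }
})

test_that("family monophyly report names intruding tips", {
  tr <- ape::read.tree(text = "((A_1:1,A_2:1):1,(B_1:1,B_2:1):1);")
  fam <- data.frame(gene = c("A_1", "A_2", "B_1", "B_2"),
                    family = c("F1", "F1", "F2", "F2"))
  rep1 <- validate_family_monophyly(tr, fam)
  expect_true(all(rep1$monophyletic))

  fam2 <- fam; fam2$family <- c("F1", "F2", "F2", "F1")  # swapped tips
  rep2 <- validate_family_monophyly(tr, fam2)
  expect_false(any(rep2$monophyletic))
  expect_true(all(nzchar(rep2$intruders)))

  set.seed(5)
  for (rep in 1:20) {
    tr3 <- random_gene_tree(12, c("Bo", "Ml"))
    fam3 <- data.frame(gene = tr3$tip.label,
                       family = sample(c("Fa", "Fb", "Fc"), 12, replace = TRUE))
    got <- validate_family_monophyly(tr3, fam3)
    for (i in seq_len(nrow(got))) {
      ids <- match(fam3$gene[fam3$family == got$family[i]], tr3$tip.label)
      clade <- tr3$tip.label[h_tips_below(tr3, h_mrca(tr3, ids))]
      intr <- clade[fam3$family[match(clade, fam3$gene)] != got$family[i]]
      expect_identical(got$monophyletic[i], length(intr) == 0L)
    }
  }
})

test_that("event summary on the packaged fixture reproduces the published reconstruction", {
  fx <- innexin_fixture()
  pm <- build_presence_matrix(fx$gene_tree, fx$family_map, fx$species_tree)
  res <- summarize_events(pm, fx$gene_tree, fx$family_map, fx$species_tree)
  s <- res$summary
  expect_identical(s$n_families, 17L)
  expect_identical(s$n_stem_gains, 14L)
  expect_identical(s$n_losses, 13L)
  expect_identical(s$n_duplications, 4L)
  expect_equal(s$losses_per_branch[c("Ml", "Bo", "Pb")],
               c(Ml = 4L, Bo = 2L, Pb = 7L))
  expect_false("Hc" %in% names(s$losses_per_branch))
  expect_equal(s$duplications_per_branch[c("Hc", "Ml", "PbHc-ancestor")],
               c(Hc = 2L, Ml = 1L, `PbHc-ancestor` = 1L))
  expect_equal(s$terminal_counts[c("Pb", "Hc", "Ml")],
               c(Pb = 9L, Hc = 19L, Ml = 12L))
  # all fixture families are clean clades
  expect_true(all(validate_family_monophyly(fx$gene_tree,
                                            fx$family_map)$monophyletic))
})

test_that("event reconstruction is invariant to child order in the input Newick", {
  fx <- innexin_fixture()
  relab <- ape::ladderize(fx$gene_tree, right = FALSE)
  pm1 <- build_presence_matrix(fx$gene_tree, fx$family_map, fx$species_tree)
  pm2 <- build_presence_matrix(relab, fx$family_map, fx$species_tree)
  r1 <- summarize_events(pm1, fx$gene_tree, fx$family_map, fx$species_tree)
  r2 <- summarize_events(pm2, relab, fx$family_map, fx$species_tree)
  expect_identical(sorted_event_key(r1$events), sorted_event_key(r2$events))
})

test_that("a family present everywhere with concordant topology yields one gain only", {
  sp <- species_tree()
  tr <- ape::read.tree(text = "((Bo_x:1,Ml_x:1):1,(Pb_x:1,Hc_x:1):1);")
  fam <- data.frame(gene = tr$tip.label, family = "F1")
  res <- summarize_events(build_presence_matrix(tr, fam), tr, fam, sp)
  expect_identical(res$summary$n_losses, 0L)
  expect_identical(res$summary$n_duplications, 0L)
  expect_equal(unname(res$summary$terminal_counts), rep(1L, 4))
  # a family absent everywhere is rejected
  m <- build_presence_matrix(tr, fam)
  m["F1", ] <- 0L
  expect_error(summarize_events(m, tr, fam, sp), "zero copies")
})
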