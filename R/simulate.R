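#' Derive a per-generator random stream seed
#'
#' Fans a single global seed out to independent per-generator streams.
#' Stream ids: 1 family evolution, 2 genome order, 3 UMI, 4 patch traces.
#'
#' @param seed Global integer seed.
#' @param stream Integer stream id.
#' @return An integer seed below 2^31.
#' @export
fanout_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

#' Simulate gene-family evolution on a species tree
#'
#' Each family is gained once at the root; on every other branch, while the
#' family survives, a loss occurs with probability \code{p_loss} (removing
#' the family from the whole descendant clade, Dollo-style: no regain) and
#' otherwise a duplication with probability \code{p_dup} (adding one extra
#' copy to every descendant species that retains the family). Families that
#' lose all species are regenerated and counted. The resulting tips are
#' embedded in a species-tree-concordant gene tree in which each duplication
#' appears as a node whose children map to the same species-tree node, and
#' the full event log is returned as an oracle, together with a
#' per-family flag saying whether the history is Dollo-identifiable
#' (gain presence spanning both root subtrees, every lost clade maximal,
#' every duplication's surviving species spanning its branch's clade).
#'
#' @param n_families Number of families to simulate.
#' @param p_loss,p_dup Per-branch event probabilities in [0, 1].
#' @param sp Species tree.
#' @param seed Integer seed.
#' @return List with \code{gene_tree}, \code{family_map}, \code{events}
#'   (data frame \code{family}, \code{kind}, \code{branch}),
#'   \code{identifiable} (named logical), \code{n_regenerated}.
#' @export
simulate_family_evolution <- function(n_families, p_loss = 0.15,
                                      p_dup = 0.1, sp = species_tree(),
                                      seed = 1) {
  stopifnot(p_loss >= 0, p_loss <= 1, p_dup >= 0, p_dup <= 1)
  set.seed(seed)
  ntip <- ape::Ntip(sp)
  root <- tree_root(sp)
  nm <- branch_names(sp)
  kids <- node_children(sp)
  under <- tips_under(sp)
  paths <- root_paths(sp)
  root_clades <- lapply(kids[[root]], function(k) under[[k]])

  subnwk <- character(0)
  fam_rows <- list()
  ev_rows <- list()
  ident <- logical(0)
  n_regen <- 0L

  for (f in seq_len(n_families)) {
    fname <- sprintf("FAM%03d", f)
    repeat {
      loss <- dup <- rep(FALSE, ntip + sp$Nnode)
      draw <- function(v) {
        for (k in kids[[v]]) {
          loss[k] <<- stats::runif(1) < p_loss
          if (!loss[k]) {
            dup[k] <<- stats::runif(1) < p_dup
            if (k > ntip) draw(k)
          }
        }
      }
      draw(root)
      # species retaining the family: no loss on the root-to-leaf path
      present <- sp$tip.label[vapply(seq_len(ntip), function(l) {
        !any(loss[paths[[l]]])
      }, logical(1))]
      if (length(present)) break
      n_regen <- n_regen + 1L
    }

    counter <- new.env()
    tip_tok <- function(species) {
      key <- species
      n <- (if (is.null(counter[[key]])) 0L else counter[[key]]) + 1L
      counter[[key]] <- n
      sprintf("%s_%s.%d:1", species, fname, n)
    }
    # one-tip-per-surviving-species subtree (an extra copy from a duplication)
    plain <- function(v) {
      if (v <= ntip) {
        if (sp$tip.label[v] %in% present) tip_tok(sp$tip.label[v]) else NULL
      } else {
        subs <- Filter(Negate(is.null), lapply(kids[[v]], function(k) {
          if (loss[k]) NULL else plain(k)
        }))
        if (!length(subs)) NULL
        else if (length(subs) == 1L) subs[[1L]]
        else paste0("(", paste(unlist(subs), collapse = ","), "):1")
      }
    }
    # copy-0 backbone; duplications attach an extra plain() copy
    backbone <- function(v) {
      if (v <= ntip) return(tip_tok(sp$tip.label[v]))
      subs <- list()
      for (k in kids[[v]]) {
        if (loss[k]) next
        b <- backbone(k)
        if (is.null(b)) next
        if (dup[k]) {
          extra <- plain(k)
          if (!is.null(extra)) b <- paste0("(", b, ",", extra, "):1")
        }
        subs[[length(subs) + 1L]] <- b
      }
      if (!length(subs)) NULL
      else if (length(subs) == 1L) subs[[1L]]
      else paste0("(", paste(unlist(subs), collapse = ","), "):1")
    }
    subnwk <- c(subnwk, backbone(root))

    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      family = fname, kind = "gain", branch = "root/stem",
      stringsAsFactors = FALSE)
    for (v in which(loss)) {
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        family = fname, kind = "loss", branch = nm[v],
        stringsAsFactors = FALSE)
    }
    for (v in which(dup)) {
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        family = fname, kind = "duplication", branch = nm[v],
        stringsAsFactors = FALSE)
    }

    # Dollo identifiability of this history, by set arithmetic on the log
    parent <- integer(ntip + sp$Nnode)
    parent[sp$edge[, 2L]] <- sp$edge[, 1L]
    ok <- all(vapply(root_clades, function(cl) any(cl %in% present), logical(1)))
    for (v in which(loss)) {
      sib_sp <- setdiff(under[[parent[v]]], under[[v]])
      if (!any(sib_sp %in% present)) ok <- FALSE
    }
    for (v in which(dup)) {
      surv <- intersect(under[[v]], present)
      if (!length(surv)) { ok <- FALSE; next }
      m <- mrca_nodes(paths, match(surv, sp$tip.label))
      if (m != v) ok <- FALSE
    }
    ident <- c(ident, stats::setNames(ok, fname))
  }

  nwk <- paste0("(", paste(subnwk, collapse = ","), "):0;")
  gene_tree <- ape::read.tree(text = nwk)
  family_map <- data.frame(
    gene = gene_tree$tip.label,
    family = sub("^[^_]+_([A-Z0-9]+)\\..*$", "\\1", gene_tree$tip.label),
    stringsAsFactors = FALSE)
  list(gene_tree = gene_tree,
       family_map = family_map,
       events = do.call(rbind, ev_rows),
       identifiable = ident,
       n_regenerated = n_regen)
}

#' Simulate two genomes with planted tandem clusters and conserved blocks
#'
#' Genome A carries background genes spaced farther apart than the cluster
#' threshold plus planted clusters of target-family genes with small
#' intra-cluster gaps (optionally with intervening non-target genes inside
#' gaps, and optionally extended by conserved non-target flanking genes).
#' Genome B contains a one-to-one ortholog of every gene; the planted
#' conserved runs stay contiguous while all other genes are shuffled.
#'
#' @param n_background Background ("other") genes per genome.
#' @param clusters List of cluster specs; each a list with \code{families}
#'   (member family labels, in order), \code{intra_gap} (bp between member
#'   boundaries), \code{intervening} (integer vector, one count per gap),
#'   and optional \code{conserved_flank} (non-target genes appended to the
#'   conserved run; default 0).
#' @param background_spacing Range (bp) of gaps between background genes;
#'   the minimum must exceed the clustering threshold for planted clusters
#'   to be recoverable.
#' @param gene_length Range (bp) of gene lengths.
#' @param ortholog_coverage Fraction of background genes with an ortholog
#'   (default 0.7); genes of conserved runs always have one. Genes without
#'   orthologs interrupt microsynteny blocks, as in real genomes, so the
#'   trivial whole-scaffold block does not arise.
#' @param seed Integer seed.
#' @return List with \code{genomeA}, \code{genomeB} (gene-locus data
#'   frames), \code{orthologs}, and \code{truth} (planted \code{clusters}:
#'   member gene ids; \code{blocks}: conserved-run gene ids in A).
#' @export
simulate_genome_order <- function(n_background = 40,
                                  clusters = list(list(
                                    families = c("INXB", "INXC", "INXD"),
                                    intra_gap = 5000,
                                    intervening = c(0, 0),
                                    conserved_flank = 1)),
                                  background_spacing = c(60000, 120000),
                                  gene_length = c(1000, 3000),
                                  ortholog_coverage = 0.7,
                                  seed = 1) {
  set.seed(seed)
  glen <- function(n) round(stats::runif(n, gene_length[1], gene_length[2]))
  bspace <- function(n) round(stats::runif(n, background_spacing[1],
                                           background_spacing[2]))

  # assemble gene order of genome A as a token list
  tokens <- list()   # each: gene, family, length, gap_before, run (conserved-run id)
  bg_ids <- sprintf("bg%03d", seq_len(n_background))
  for (g in bg_ids) {
    tokens[[length(tokens) + 1L]] <- list(gene = g, family = "other",
                                          len = glen(1), gap = bspace(1),
                                          run = 0L)
  }
  truth_clusters <- list()
  truth_blocks <- list()
  # insert clusters at distinct background boundaries, right to left so
  # earlier insertion points stay valid
  insert_at <- sort(sample(n_background, length(clusters)), decreasing = TRUE)
  for (ci in rev(seq_along(clusters))) {
    spec <- clusters[[ci]]
    k <- length(spec$families)
    if (length(spec$intervening) != k - 1L) {
      stop("cluster spec needs one intervening count per gap")
    }
    ctoks <- list()
    members <- character(0)
    for (j in seq_len(k)) {
      gid <- sprintf("cl%d_%s", ci, spec$families[j])
      members <- c(members, gid)
      gap <- if (j == 1L) bspace(1) else {
        n_int <- spec$intervening[j - 1L]
        need <- 200 + n_int * 700
        if (need > spec$intra_gap) stop("infeasible spacing: intervening genes do not fit in intra_gap")
        spec$intra_gap
      }
      if (j > 1L && spec$intervening[j - 1L] > 0L) {
        # intervening genes sit inside the gap before this member
        for (q in seq_len(spec$intervening[j - 1L])) {
          ctoks[[length(ctoks) + 1L]] <- list(
            gene = sprintf("cl%d_int%d_%d", ci, j, q), family = "other",
            len = 500, gap = 200, run = ci)
        }
        gap <- spec$intra_gap - spec$intervening[j - 1L] * 700
      }
      ctoks[[length(ctoks) + 1L]] <- list(gene = gid,
                                          family = spec$families[j],
                                          len = glen(1), gap = gap, run = ci)
    }
    flank <- if (is.null(spec$conserved_flank)) 0L else spec$conserved_flank
    for (q in seq_len(flank)) {
      ctoks[[length(ctoks) + 1L]] <- list(
        gene = sprintf("cl%d_flank%d", ci, q), family = "other",
        len = glen(1), gap = spec$intra_gap, run = ci)
    }
    tokens <- append(tokens, ctoks, after = insert_at[length(clusters) - ci + 1L])
    truth_clusters[[ci]] <- members
    truth_blocks[[ci]] <- vapply(ctoks, function(t) t$gene, character(1))
  }

  layout <- function(toks, prefix, seqid) {
    pos <- 0
    rows <- lapply(toks, function(t) {
      start <- pos + t$gap
      pos <<- start + t$len
      data.frame(gene = paste0(prefix, t$gene), seqid = seqid,
                 start = start, end = pos, strand = "+",
                 family = t$family, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  genomeA <- layout(tokens, "", "scafA1")

  # genome B: shuffle units (conserved runs stay intact, internal order kept)
  unit_of <- vapply(tokens, function(t) t$run, integer(1))
  units <- list()
  i <- 1L
  while (i <= length(tokens)) {
    if (unit_of[i] > 0L) {
      j <- i
      while (j < length(tokens) && unit_of[j + 1L] == unit_of[i]) j <- j + 1L
      units[[length(units) + 1L]] <- tokens[i:j]
      i <- j + 1L
    } else {
      units[[length(units) + 1L]] <- tokens[i]
      i <- i + 1L
    }
  }
  unitsB <- units[sample(length(units))]
  toksB <- do.call(c, unitsB)
  # re-draw gaps: small inside conserved runs, background elsewhere
  prev_run <- 0L
  for (q in seq_along(toksB)) {
    r <- toksB[[q]]$run
    toksB[[q]]$gap <- if (r > 0L && r == prev_run) 2000 else bspace(1)
    prev_run <- r
  }
  genomeB <- layout(toksB, "B_", "scafB1")

  in_run <- vapply(tokens, function(t) t$run > 0L, logical(1))
  run_genes <- vapply(tokens[in_run], function(t) t$gene, character(1))
  bg_free <- setdiff(genomeA$gene, run_genes)
  covered <- c(run_genes,
               sample(bg_free, round(ortholog_coverage * length(bg_free))))
  orthologs <- data.frame(geneA = covered,
                          geneB = paste0("B_", covered),
                          stringsAsFactors = FALSE)
  list(genomeA = genomeA, genomeB = genomeB, orthologs = orthologs,
       truth = list(clusters = truth_clusters, blocks = truth_blocks))
}

#' Simulate a sparse UMI matrix with planted metacell and coexpression structure
#'
#' Cells belong to metacells; every gene is "on" in a cell with a
#' per-(metacell, gene) probability (a baseline, raised for each metacell's
#' dedicated marker genes), and an "on" gene's count is drawn from a
#' negative binomial (overdispersed relative to Poisson); an "on" gene can
#' still yield zero counts (dropout). Planted gene pairs ignore the
#' metacell structure and instead share a latent on/off program active in a
#' fixed fraction of all cells, giving an analytic expected coexpression
#' percentage.
#'
#' @param n_genes Number of genes (ids \code{g01}, \code{g02}, ...).
#' @param metacell_sizes Integer vector of cells per metacell (labels
#'   \code{C1}, \code{C2}, ...).
#' @param base_prob Baseline on-probability.
#' @param marker_prob On-probability of a metacell's marker genes.
#' @param n_markers_per_mc Dedicated marker genes per metacell.
#' @param depth Negative binomial mean for "on" genes.
#' @param dispersion Negative binomial size parameter.
#' @param planted_pairs List of \code{list(geneA, geneB, fraction)}.
#' @param seed Integer seed.
#' @return List with \code{umi} (genes x cells integer matrix),
#'   \code{metacells} (data frame \code{cell}, \code{metacell}),
#'   \code{truth} (planted-pair table with \code{expected_percent}, and
#'   \code{q}, the probability an "on" gene yields a nonzero count).
#' @export
simulate_umi <- function(n_genes = 30, metacell_sizes = rep(50L, 10L),
                         base_prob = 0.1, marker_prob = 0.9,
                         n_markers_per_mc = 2, depth = 2, dispersion = 1,
                         planted_pairs = list(list(geneA = "g01",
                                                   geneB = "g02",
                                                   fraction = 0.3)),
                         seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  n_mc <- length(metacell_sizes)
  n_cells <- sum(metacell_sizes)
  cells <- sprintf("cell%05d", seq_len(n_cells))
  mc_lab <- rep(sprintf("C%d", seq_len(n_mc)), metacell_sizes)

  planted_genes <- unlist(lapply(planted_pairs, function(p) c(p$geneA, p$geneB)))
  if (!all(planted_genes %in% genes)) stop("planted pair gene not among gene ids")

  prob <- matrix(base_prob, n_genes, n_mc, dimnames = list(genes, NULL))
  free <- setdiff(genes, planted_genes)
  for (m in seq_len(n_mc)) {
    if (length(free) && n_markers_per_mc > 0) {
      mk <- free[((m - 1L) * n_markers_per_mc + seq_len(n_markers_per_mc) - 1L) %%
                   length(free) + 1L]
      prob[mk, m] <- marker_prob
    }
  }

  on <- matrix(FALSE, n_genes, n_cells, dimnames = list(genes, cells))
  for (m in seq_len(n_mc)) {
    idx <- which(mc_lab == sprintf("C%d", m))
    on[, idx] <- stats::runif(n_genes * length(idx)) <
      prob[, rep(m, length(idx))]
  }
  for (p in planted_pairs) {
    z <- stats::runif(n_cells) < p$fraction
    on[p$geneA, ] <- z
    on[p$geneB, ] <- z
  }

  umi <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
  k <- sum(on)
  umi[on] <- as.integer(stats::rnbinom(k, size = dispersion, mu = depth))

  q <- 1 - (dispersion / (dispersion + depth))^dispersion
  truth <- do.call(rbind, lapply(planted_pairs, function(p) {
    data.frame(geneA = p$geneA, geneB = p$geneB, fraction = p$fraction,
               expected_percent = 100 * q, stringsAsFactors = FALSE)
  }))
  list(umi = umi,
       metacells = data.frame(cell = cells, metacell = mc_lab,
                              stringsAsFactors = FALSE),
       truth = list(planted = truth, q = q))
}

#' Voltage-step protocol
#'
#' @param holding_mv Holding potential (mV).
#' @param prestep_mv Hyperpolarizing pre-step offset (mV).
#' @param step_mv Step increment (mV).
#' @param duration_ms Step duration (ms).
#' @param steps Step potentials (mV); must be consistent with
#'   \code{step_mv}.
#' @return List of class \code{voltage_protocol}.
#' @export
voltage_protocol <- function(holding_mv = -60, prestep_mv = -50,
                             step_mv = 10, duration_ms = 200,
                             steps = seq(-120, -40, by = 10)) {
  if (duration_ms <= 0) stop("duration must be positive")
  if (length(steps) > 1L && any(abs(diff(steps) - step_mv) > 1e-9)) {
    stop("step list inconsistent with step increment")
  }
  structure(list(holding_mv = holding_mv, prestep_mv = prestep_mv,
                 step_mv = step_mv, duration_ms = duration_ms,
                 steps = steps), class = "voltage_protocol")
}

# exact two-state dwell simulation for one channel over one sweep
sim_channel_dwells <- function(duration_ms, k_open, k_close) {
  p_open <- if (k_open + k_close > 0) k_open / (k_open + k_close) else 0
  s <- if (k_open > 0) stats::runif(1) < p_open else FALSE
  t <- 0
  rows <- list()
  repeat {
    rate <- if (s) k_close else k_open
    d_ms <- if (rate <= 0) Inf else stats::rexp(1, rate) * 1000
    dwell <- min(d_ms, duration_ms - t)
    rows[[length(rows) + 1L]] <- c(open = as.numeric(s), start_ms = t,
                                   duration_ms = dwell)
    t <- t + dwell
    if (t >= duration_ms - 1e-12) break
    s <- !s
  }
  as.data.frame(do.call(rbind, rows))
}

#' Simulate voltage-clamp sweeps of two-state gating channels
#'
#' Each of N identical channels gates as an independent two-state Markov
#' chain (opening rate \code{k_open}, closing rate \code{k_close}, both per
#' second), started from the stationary distribution. The zero-calcium
#' condition forces the opening rate to zero. The current of a sweep at
#' command voltage V is (open channels) x g (V - V_rev) / 1000 pA plus
#' Gaussian noise, low-pass filtered with a Butterworth filter at the
#' stated cutoff. The per-channel dwell log is returned as ground truth.
#'
#' @param n_channels Number of channels.
#' @param g_ps Unitary slope conductance (pS).
#' @param v_rev_mv Reversal potential (mV).
#' @param k_open,k_close Gating rates (per second).
#' @param calcium \code{"high"} or \code{"low"}; low forces
#'   \code{k_open = 0}.
#' @param noise_sd_pa Gaussian noise standard deviation (pA).
#' @param sampling_khz Sampling rate (kHz); must be at least twice
#'   \code{filter_khz}, and strictly greater for the filter to be
#'   realizable.
#' @param filter_khz Low-pass cutoff (kHz).
#' @param proto A \code{\link{voltage_protocol}}.
#' @param n_sweeps_per_step Sweeps recorded at each step potential.
#' @param seed Integer seed.
#' @return Sweep set: list with \code{sweeps} (each \code{time_ms},
#'   \code{current_pa}, \code{voltage_mv}), \code{sampling_khz},
#'   \code{filter_khz}, \code{metadata} (input/seal resistance, calcium),
#'   \code{dwells} (data frame \code{sweep}, \code{channel}, \code{open},
#'   \code{start_ms}, \code{duration_ms}), and the generating parameters in
#'   \code{params}.
#' @export
simulate_patch_traces <- function(n_channels = 1, g_ps = 340, v_rev_mv = 0,
                                  k_open = 10, k_close = 40,
                                  calcium = c("high", "low"),
                                  noise_sd_pa = 2, sampling_khz = 20,
                                  filter_khz = 5,
                                  proto = voltage_protocol(),
                                  n_sweeps_per_step = 1, seed = 1) {
  calcium <- match.arg(calcium)
  if (sampling_khz < 2 * filter_khz) {
    stop("sampling rate must be at least twice the filter cutoff")
  }
  if (calcium == "low") k_open <- 0
  set.seed(seed)
  n <- round(proto$duration_ms * sampling_khz)
  time_ms <- (seq_len(n) - 1L) / sampling_khz
  W <- filter_khz / (sampling_khz / 2)
  bf <- if (W < 1) signal::butter(2, W, type = "low") else NULL

  sweeps <- list()
  dw_rows <- list()
  sweep_id <- 0L
  for (v in proto$steps) {
    for (r in seq_len(n_sweeps_per_step)) {
      sweep_id <- sweep_id + 1L
      open_count <- numeric(n)
      for (ch in seq_len(n_channels)) {
        dw <- sim_channel_dwells(proto$duration_ms, k_open, k_close)
        dw$sweep <- sweep_id; dw$channel <- ch
        dw_rows[[length(dw_rows) + 1L]] <- dw
        op <- dw[dw$open == 1, , drop = FALSE]
        if (nrow(op)) {
          for (q in seq_len(nrow(op))) {
            i0 <- max(1L, floor(op$start_ms[q] * sampling_khz) + 1L)
            i1 <- min(n, ceiling((op$start_ms[q] + op$duration_ms[q]) *
                                   sampling_khz))
            if (i1 >= i0) open_count[i0:i1] <- open_count[i0:i1] + 1
          }
        }
      }
      cur <- open_count * g_ps * (v - v_rev_mv) / 1000 +
        stats::rnorm(n, 0, noise_sd_pa)
      if (!is.null(bf)) cur <- as.numeric(signal::filtfilt(bf, cur))
      sweeps[[sweep_id]] <- list(time_ms = time_ms, current_pa = cur,
                                 voltage_mv = v)
    }
  }
  list(sweeps = sweeps, sampling_khz = sampling_khz, filter_khz = filter_khz,
       metadata = list(r_in_mohm = 1100, r_seal_gohm = 1.5,
                       calcium = calcium),
       dwells = do.call(rbind, dw_rows)[, c("sweep", "channel", "open",
                                            "start_ms", "duration_ms")],
       params = list(n_channels = n_channels, g_ps = g_ps,
                     v_rev_mv = v_rev_mv, k_open = k_open,
                     k_close = k_close, calcium = calcium,
                     noise_sd_pa = noise_sd_pa, seed = seed))
}

#' Write / read a sweep set as per-sweep text files with JSON sidecars
#'
#' Each sweep becomes a two-column text file (time ms, current pA) plus a
#' JSON sidecar carrying the command voltage, sampling rate, filter cutoff
#' and cell metadata.
#'
#' @param ss Sweep set (see \code{\link{simulate_patch_traces}}).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep_set <- function(ss, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ss$sweeps)) {
    s <- ss$sweeps[[k]]
    base <- file.path(dir, sprintf("sweep_%03d", k))
    utils::write.table(data.frame(time_ms = s$time_ms,
                                  current_pa = s$current_pa),
                       paste0(base, ".txt"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(c(list(voltage_mv = s$voltage_mv,
                                sampling_khz = ss$sampling_khz,
                                filter_khz = ss$filter_khz),
                           ss$metadata),
                         paste0(base, ".json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "^sweep_\\d+\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no sweep files in ", dir)
  sweeps <- list()
  meta <- NULL
  for (f in files) {
    side <- jsonlite::read_json(sub("\\.txt$", ".json", f),
                                simplifyVector = TRUE)
    tab <- utils::read.delim(f)
    sweeps[[length(sweeps) + 1L]] <- list(time_ms = tab$time_ms,
                                          current_pa = tab$current_pa,
                                          voltage_mv = side$voltage_mv)
    meta <- side
  }
  list(sweeps = sweeps, sampling_khz = meta$sampling_khz,
       filter_khz = meta$filter_khz,
       metadata = meta[setdiff(names(meta),
                               c("voltage_mv", "sampling_khz", "filter_khz"))])
}
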