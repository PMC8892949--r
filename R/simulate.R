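#' Expected gene-tree concordance at an internode
#'
#' Under the multispecies coalescent, a gene tree resolves a species-tree
#' internode of length `T` (in coalescent units) concordantly with
#' probability `1 - (2/3) exp(-T)`: strictly increasing from 1/3 at `T = 0`
#' toward 1. This closed form is the oracle against which simulated gene
#' trees and empirical gCF values are checked.
#'
#' @param T Internode length(s) in coalescent units, `T >= 0`.
#' @return Probability vector of the same length.
#' @export
expected_concordance <- function(T) {
  if (any(T < 0)) stop("internode length must be nonnegative")
  1 - (2 / 3) * exp(-T)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage is sampled per tip of the species tree (branch
#' lengths in coalescent units). Within each species-tree branch, the
#' lineages present coalesce with exponential waiting times at rate
#' `choose(k, 2)`; lineages that fail to coalesce pass rootward, and the
#' root population extends to infinity, so every gene tree is a complete
#' binary genealogy. Gene-tree branch lengths are in coalescent units.
#'
#' @param species_tree Ultrametric `phylo` with branch lengths in
#'   coalescent units.
#' @param n_genes Number of independent gene trees.
#' @param seed Integer seed.
#' @return List of `phylo` gene trees.
#' @export
simulate_msc_gene_trees <- function(species_tree, n_genes, seed = NULL) {
  tr <- species_tree
  if (is.null(tr$edge.length)) stop("species tree needs branch lengths")
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  h <- max(depth[seq_len(ntip)])
  time <- h - depth # time before present of each node
  children <- .children_list(tr)
  post_nodes <- unique(stats::reorder(tr, "postorder")$edge[, 1])
  with_seed_if(seed, {
    lapply(seq_len(n_genes), function(g) {
      pools <- vector("list", max(tr$edge))
      for (i in seq_len(ntip)) {
        pools[[i]] <- list(list(str = tr$tip.label[i], h = time[i]))
      }
      for (v in post_nodes) {
        pool <- list()
        for (ch in children[[v]]) {
          pool <- c(pool, .coalesce_pool(pools[[ch]], time[ch], time[v]))
        }
        pools[[v]] <- pool
      }
      root <- ntip + 1L
      final <- .coalesce_pool(pools[[root]], time[root], Inf)
      ape::read.tree(text = paste0(final[[1]]$str, ";"))
    })
  })
}

# coalesce a set of lineages in one population from t0 to t1 (t1 may be Inf)
.coalesce_pool <- function(lineages, t0, t1) {
  t <- t0
  while (length(lineages) >= 2) {
    k <- length(lineages)
    dt <- rexp(1, rate = k * (k - 1) / 2)
    if (t + dt > t1) break
    t <- t + dt
    pick <- sample.int(k, 2)
    a <- lineages[[pick[1]]]; b <- lineages[[pick[2]]]
    merged <- list(str = sprintf("(%s:%.10g,%s:%.10g)", a$str, t - a$h,
                                 b$str, t - b$h),
                   h = t)
    lineages <- c(lineages[-pick], list(merged))
  }
  lineages
}

#' Simulate sequences along a tree
#'
#' Forward simulation of iid sites: root states drawn from the model's
#' equilibrium frequencies, child states via [transition_probability()] per
#' branch. Branch lengths must be in expected substitutions per site.
#'
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param n_sites Number of sites.
#' @param model A `subst_model` (default [jc69()]).
#' @param seed Integer seed.
#' @return Character matrix (tips x sites) over `A, C, G, T`.
#' @export
simulate_sequences <- function(tree, n_sites, model = jc69(), seed = NULL) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("missing branch length")
  }
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nn <- max(tr$edge)
  with_seed_if(seed, {
    seqs <- matrix(0L, nn, n_sites)
    seqs[ntip + 1L, ] <- sample.int(4, n_sites, replace = TRUE,
                                    prob = model$freqs)
    for (e in seq_len(nrow(tr$edge))) {
      par <- seqs[tr$edge[e, 1], ]
      t <- tr$edge.length[e]
      if (model$name == "JC69") {
        p_same <- 0.25 + 0.75 * exp(-4 * t / 3)
        mut <- which(runif(n_sites) > p_same)
        ch <- par
        if (length(mut) > 0) {
          ch[mut] <- ((par[mut] - 1L +
                         sample.int(3, length(mut), replace = TRUE)) %% 4L) + 1L
        }
      } else {
        P <- transition_probability(model, t)
        ch <- integer(n_sites)
        for (s in 1:4) {
          idx <- which(par == s)
          if (length(idx) > 0) {
            ch[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
          }
        }
      }
      seqs[tr$edge[e, 2], ] <- ch
    }
    out <- matrix(c("A", "C", "G", "T")[seqs[seq_len(ntip), ]], ntip, n_sites)
    rownames(out) <- tr$tip.label
    out
  })
}

#' Simulate a discrete trait forward along a time tree
#'
#' Forward Mk simulation root to tips with exponential waiting times; the
#' full character history is recorded in the same structure that
#' [stochastic_maps()] samples, so [count_transitions()] applies directly to
#' the truth.
#'
#' @param tree `phylo` with branch lengths (time units).
#' @param model An [mk_model()]; the root state is drawn from its root
#'   prior.
#' @param seed Integer seed.
#' @return List with `tip_states` (named character), `history` (a
#'   `char_history_list` of length 1) and `n_transitions` (realized count).
#' @export
simulate_mk_traits <- function(tree, model, seed = NULL) {
  tr <- stats::reorder(tree, "cladewise")
  states <- model$states
  k <- length(states)
  Q <- model$Q
  ntip <- length(tr$tip.label)
  prior <- .mk_root_prior(model)
  res <- with_seed_if(seed, {
    node_states <- integer(max(tr$edge))
    node_states[ntip + 1L] <- sample.int(k, 1, prob = prior)
    paths <- vector("list", nrow(tr$edge))
    n_trans <- 0L
    for (e in seq_len(nrow(tr$edge))) {
      s <- node_states[tr$edge[e, 1]]
      len <- tr$edge.length[e]
      t <- 0
      seg_s <- s; seg_d <- numeric(0); seg_states <- integer(0)
      repeat {
        rate <- -Q[s, s]
        dt <- if (rate > 0) rexp(1, rate) else Inf
        if (t + dt >= len) {
          seg_states <- c(seg_states, s); seg_d <- c(seg_d, len - t)
          break
        }
        seg_states <- c(seg_states, s); seg_d <- c(seg_d, dt)
        t <- t + dt
        s <- sample.int(k, 1, prob = pmax(Q[s, ], 0) *
                          (seq_len(k) != s))
        n_trans <- n_trans + 1L
      }
      node_states[tr$edge[e, 2]] <- s
      paths[[e]] <- data.frame(state = states[seg_states], duration = seg_d)
    }
    list(node_states = node_states, paths = paths, n_trans = n_trans)
  })
  history <- list(list(
    node_states = setNames(states[res$node_states],
                           as.character(seq_along(res$node_states))),
    paths = res$paths))
  history <- base::structure(history, class = "char_history_list",
                             tree = tr, model = model, seed = seed)
  tips <- setNames(states[res$node_states[seq_len(ntip)]], tr$tip.label)
  list(tip_states = tips, history = history, n_transitions = res$n_trans)
}

.fixture_defaults <- function() {
  list(
    clade_sizes = c(cladeA = 6L, cladeB = 5L, cladeC = 4L, cladeD = 4L,
                    cladeE = 2L),
    outgroup_size = 3L,
    clade_crown = 1,
    radiation_start = 3.5,
    base_internode = 0.25,
    ingroup_stem = 3,
    n_genes = 200L,
    sites_per_gene = 300L,
    subst_scale = 0.03,
    trait_states = c("bark", "leaf", "fungus"),
    trait_rate = 0.03,
    rearing_records = 12L
  )
}

# ultrametric caterpillar over `labels`, joins at `times` (increasing);
# returns list(str, h) in the lineage format of the coalescent builder
.caterpillar <- function(labels, times) {
  cur <- list(str = labels[1], h = 0)
  for (i in seq_along(times)) {
    cur <- list(str = sprintf("(%s:%.10g,%s:%.10g)", cur$str, times[i] - cur$h,
                              labels[i + 1], times[i]),
                h = times[i])
  }
  cur
}

# one clade's subtree: caterpillar with joins spread over [crown/2, crown]
.clade_subtree <- function(labels, crown) {
  n <- length(labels)
  if (n == 1) return(list(str = labels, h = 0))
  times <- if (n == 2) crown else seq(crown / 2, crown, length.out = n - 1)
  .caterpillar(labels, times)
}

#' Build a complete synthetic fixture
#'
#' Generates a bundle emulating a clade-level phylotranscriptomic data set
#' with known truth: an ultrametric species tree (coalescent units) with
#' five ingroup clades plus an outgroup on a planted ladder topology, short
#' internodes at the radiation base and long clade stems; gene trees under
#' the multispecies coalescent; per-gene JC69 alignments concatenated into a
#' supermatrix with a partition table; a clade map; and an Mk trait with its
#' true character history and a rearing-record table derived from the tip
#' states. Identical seeds give byte-identical bundles.
#'
#' @param config Named list overriding any of the defaults (see
#'   `cladescape:::.fixture_defaults()`): `clade_sizes`, `outgroup_size`,
#'   `clade_crown`, `radiation_start`, `base_internode`, `ingroup_stem`,
#'   `n_genes`, `sites_per_gene`, `subst_scale`, `trait_states`,
#'   `trait_rate`, `rearing_records`. Unknown keys are an error listing the
#'   accepted schema.
#' @param seed Integer master seed; every stage uses a sub-seed derived
#'   from it.
#' @param dir Optional directory; if given, all files (newick, FASTA,
#'   partition text, TSV, CSV, JSON manifest) are written there.
#' @return Object of class `simulation_bundle`: list with `species_tree`
#'   (coalescent units), `gene_trees` (coalescent units),
#'   `gene_trees_subs` (substitution units), `alignment` (supermatrix),
#'   `partitions`, `clade_map`, `planted` (clade-level canonical newick),
#'   `trait` (tip states, true history, realized transitions, model),
#'   `rearing`, `config`, `seed`, and `files` when written.
#' @export
make_fixture <- function(config = list(), seed = 1L, dir = NULL) {
  defaults <- .fixture_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("invalid config key(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(names(defaults), collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  cs <- cfg$clade_sizes
  if (length(cs) < 2) stop("need at least two ingroup clades")
  clades <- names(cs)
  taxa <- lapply(clades, function(cl)
    sprintf("%s_t%d", cl, seq_len(cs[[cl]])))
  names(taxa) <- clades
  og_taxa <- sprintf("outgroup_t%d", seq_len(cfg$outgroup_size))

  # species tree: clades joined ladder-wise at radiation_start + i*base
  sub <- lapply(clades, function(cl) .clade_subtree(taxa[[cl]],
                                                    cfg$clade_crown))
  cur <- sub[[1]]
  for (i in seq_along(clades)[-1]) {
    jt <- cfg$radiation_start + (i - 2) * cfg$base_internode
    cur <- list(str = sprintf("(%s:%.10g,%s:%.10g)", cur$str, jt - cur$h,
                              sub[[i]]$str, jt - sub[[i]]$h),
                h = jt)
  }
  og <- .clade_subtree(og_taxa, cfg$clade_crown)
  root_t <- cur$h + cfg$ingroup_stem
  full <- sprintf("(%s:%.10g,%s:%.10g);", cur$str, root_t - cur$h,
                  og$str, root_t - og$h)
  species_tree <- ape::read.tree(text = full)

  seeds <- derive_seeds(seed, 4L + cfg$n_genes)
  gene_trees <- simulate_msc_gene_trees(species_tree, cfg$n_genes,
                                        seed = seeds[1])
  gene_names <- sprintf("g%03d", seq_len(cfg$n_genes))
  names(gene_trees) <- gene_names
  gene_trees_subs <- lapply(gene_trees, function(g) {
    g$edge.length <- g$edge.length * cfg$subst_scale
    g
  })
  alns <- lapply(seq_len(cfg$n_genes), function(i) {
    a <- simulate_sequences(gene_trees_subs[[i]], cfg$sites_per_gene,
                            seed = seeds[4L + i])
    a[sort(rownames(a)), , drop = FALSE]
  })
  supermatrix <- do.call(cbind, alns)
  partitions <- tibble(gene = gene_names,
                       start = (seq_len(cfg$n_genes) - 1L) * cfg$sites_per_gene,
                       end = seq_len(cfg$n_genes) * cfg$sites_per_gene)
  cmap <- clade_map(
    tibble(taxon = c(unlist(taxa), og_taxa),
           clade = c(rep(clades, lengths(taxa)),
                     rep("outgroup", length(og_taxa)))),
    outgroup = "outgroup")

  trait_model <- mk_model(cfg$trait_states, "ER", rates = cfg$trait_rate)
  trait <- simulate_mk_traits(species_tree, trait_model, seed = seeds[2])
  rearing <- with_seed_if(seeds[3], {
    purrr::map_dfr(names(trait$tip_states), function(sp) {
      own <- trait$tip_states[[sp]]
      probs <- setNames(rep(0.15 / (length(cfg$trait_states) - 1),
                            length(cfg$trait_states)), cfg$trait_states)
      probs[own] <- 0.85
      counts <- as.integer(rmultinom(1, cfg$rearing_records, probs))
      tibble(species = sp, substrate = cfg$trait_states, count = counts)
    })
  })

  planted <- paste0("(",
                    sub(";$", "", canonical_form(ape::read.tree(
                      text = .skeleton_newick(clades)))),
                    ",outgroup);")

  bundle <- base::structure(list(
    species_tree = species_tree, gene_trees = gene_trees,
    gene_trees_subs = gene_trees_subs, alignment = supermatrix,
    partitions = partitions, clade_map = cmap, planted = planted,
    trait = list(tip_states = trait$tip_states, history = trait$history,
                 n_transitions = trait$n_transitions, model = trait_model),
    rearing = rearing, config = cfg, seed = seed),
    class = "simulation_bundle")
  if (!is.null(dir)) bundle <- write_bundle(bundle, dir)
  bundle
}

# ladder newick over clade labels (topology only)
.skeleton_newick <- function(clades) {
  cur <- clades[1]
  for (cl in clades[-1]) cur <- sprintf("(%s,%s)", cur, cl)
  paste0(cur, ";")
}

#' Write a simulation bundle to disk
#'
#' Writes the species tree and gene trees (newick), the supermatrix
#' (FASTA), the partition file (RAxML dialect), the clade map (TSV), the
#' rearing table (CSV) and a JSON manifest recording the seed and every
#' parameter; re-reads each file to confirm it parses.
#'
#' @param bundle A `simulation_bundle`.
#' @param dir Output directory (created if absent).
#' @return The bundle with a `files` element added, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    species_tree = file.path(dir, "species_tree.nwk"),
    gene_trees = file.path(dir, "gene_trees.nwk"),
    alignment = file.path(dir, "supermatrix.fasta"),
    partitions = file.path(dir, "partitions.txt"),
    clade_map = file.path(dir, "clade_map.tsv"),
    rearing = file.path(dir, "rearing.csv"),
    manifest = file.path(dir, "manifest.json"))
  write_trees(bundle$species_tree, files$species_tree)
  write_trees(bundle$gene_trees_subs, files$gene_trees)
  write_alignment(bundle$alignment, files$alignment, format = "fasta")
  write_partitions(bundle$partitions, files$partitions)
  write_clade_map(bundle$clade_map, files$clade_map)
  write_rearing_table(bundle$rearing, files$rearing)
  cfg <- bundle$config
  cfg$clade_sizes <- as.list(cfg$clade_sizes)
  jsonlite::write_json(
    list(seed = bundle$seed, planted = bundle$planted, config = cfg,
         trait_transitions = bundle$trait$n_transitions,
         files = lapply(files, basename)),
    files$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # every referenced file must exist and parse
  stopifnot(length(read_trees(files$gene_trees)) == length(bundle$gene_trees))
  stopifnot(nrow(read_alignment(files$alignment)) == nrow(bundle$alignment))
  stopifnot(nrow(read_partitions(files$partitions)) == nrow(bundle$partitions))
  bundle$files <- files
  invisible(bundle)
}

#' @export
print.simulation_bundle <- function(x, ...) {
  cat("Synthetic fixture:", length(x$clade_map$taxon), "taxa,",
      length(x$gene_trees), "genes x", x$config$sites_per_gene, "sites\n")
  cat("Planted clade topology:", x$planted, "\n")
  cat("True trait transitions:", x$trait$n_transitions, "\n")
  invisible(x)
}
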