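#' Quadripartition around an internal branch
#'
#' Every internal branch of an unrooted binary tree touches four subtrees:
#' two at each endpoint. Their taxon sets are the context in which gene and
#' site concordance are defined — the branch's bipartition is
#' `(set1 u set2) | (set3 u set4)`, and quartets are drawn one taxon per set.
#' Rooted trees are treated on their unrooted version.
#'
#' @param tree A binary `phylo` with >= 4 leaves.
#' @param branch A bipartition `key` (see [bipartition_set()]) or an integer
#'   index into the rows of `bipartition_set(tree)`.
#' @return An object of class `quadripartition`: a list with `sets` (four
#'   character vectors), `taxa` (all leaf labels) and `key` (the branch's
#'   bipartition key).
#' @export
quadripartition <- function(tree, branch) {
  quads <- quadripartitions(tree)
  if (is.character(branch)) {
    i <- match(branch, vapply(quads, `[[`, character(1), "key"))
    if (is.na(i)) stop("no internal branch with that bipartition key")
  } else {
    i <- as.integer(branch)
    if (i < 1 || i > length(quads)) stop("terminal or out-of-range branch")
  }
  quads[[i]]
}

#' @rdname quadripartition
#' @return For `quadripartitions()`: a list of `quadripartition` objects, one
#'   per internal branch, in [bipartition_set()] order.
#' @export
quadripartitions <- function(tree) {
  .validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("tree must have >= 4 leaves")
  tr <- tree
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  all_taxa <- tr$tip.label
  desc <- .desc_tips(tr)
  children <- .children_list(tr)
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  root <- ntip + 1L
  out <- list()
  internal_children <- tr$edge[tr$edge[, 2] > ntip, 2]
  for (v in internal_children) {
    u <- parent[v]
    below <- children[[v]]
    if (length(below) != 2) stop("tree must be binary (polytomy at node ", v, ")")
    others <- setdiff(children[[u]], v)
    above <- lapply(others, function(w) desc[[w]])
    if (u != root) {
      above <- c(above, list(setdiff(all_taxa, desc[[u]])))
    }
    if (length(above) != 2) stop("tree must be binary (polytomy at node ", u, ")")
    sets <- list(sort(above[[1]]), sort(above[[2]]),
                 sort(desc[[below[1]]]), sort(desc[[below[2]]]))
    key <- .split_key(desc[[v]], all_taxa)
    out[[length(out) + 1L]] <- structure(
      list(sets = sets, taxa = all_taxa, key = key),
      class = "quadripartition")
  }
  # align with bipartition_set() order (unique keys, first occurrence)
  keys <- vapply(out, `[[`, character(1), "key")
  out[!duplicated(keys)]
}

#' Build a quadripartition directly from four taxon sets
#'
#' @param set1,set2,set3,set4 Disjoint, nonempty character vectors of taxa;
#'   the implied branch separates `set1 + set2` from `set3 + set4`.
#' @return A `quadripartition` object.
#' @export
new_quadripartition <- function(set1, set2, set3, set4) {
  sets <- list(sort(set1), sort(set2), sort(set3), sort(set4))
  taxa <- sort(unlist(sets))
  if (anyDuplicated(taxa)) stop("quadripartition sets must be disjoint")
  structure(list(sets = sets, taxa = taxa,
                 key = .split_key(c(sets[[3]], sets[[4]]), taxa)),
            class = "quadripartition")
}

# cache gene-tree taxa and split keys once per gene-tree list
.gene_tree_cache <- function(gene_trees) {
  lapply(gene_trees, function(g) {
    list(taxa = g$tip.label, keys = .split_keys(g))
  })
}

# gCF machinery on a prebuilt cache
.gcf_from_cache <- function(quad, cache) {
  s12 <- c(quad$sets[[1]], quad$sets[[2]])
  gn <- 0L; conc <- 0L
  for (g in cache) {
    if (!all(vapply(quad$sets, function(s) any(s %in% g$taxa), logical(1)))) next
    gn <- gn + 1L
    key <- .split_key(intersect(s12, g$taxa), g$taxa)
    if (key %in% g$keys) conc <- conc + 1L
  }
  list(gcf = if (gn > 0) 100 * conc / gn else NA_real_,
       gcf_n = conc, gn = gn)
}

#' Gene concordance factor for one branch
#'
#' A gene tree is *decisive* for a branch iff it contains at least one taxon
#' from each of the branch's four adjacent subtrees; a decisive gene tree is
#' *concordant* iff its bipartition set, restricted to the taxa it shares
#' with the reference, contains the branch's induced bipartition. The gene
#' concordance factor is `100 * concordant / decisive`; with no decisive
#' gene trees it is undefined and reported as `NA`, never 0.
#'
#' @param quad A `quadripartition` (see [quadripartition()] or
#'   [new_quadripartition()]).
#' @param gene_trees List of `phylo` gene trees; taxa may be missing.
#' @return One-row tibble with `gcf` (percent, `NA` if undefined), `gcf_n`
#'   (concordant count) and `gn` (decisive count).
#' @export
gene_concordance <- function(quad, gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  res <- .gcf_from_cache(quad, .gene_tree_cache(gene_trees))
  tibble(gcf = res$gcf, gcf_n = res$gcf_n, gn = res$gn)
}

#' Per-site support for the three arrangements of a quartet
#'
#' A site is *decisive* for a quartet `(a, b, c, d)` iff all four characters
#' are unambiguous nucleotides and the pattern is a clean binary split:
#' `xxyy` (supports `ab|cd`), `xyxy` (`ac|bd`) or `xyyx` (`ad|bc`) with
#' `x != y`. Sites with gaps, `N`, three or four states, or singleton
#' patterns are not decisive.
#'
#' @param quartet Character vector of 4 taxa, ordered as one member of each
#'   quadripartition set (so `s1` counts support for the branch's own
#'   arrangement `ab|cd`).
#' @param aln Character alignment matrix containing the four taxa.
#' @return List with counts `s1`, `s2`, `s3` and `decisive`
#'   (`= s1 + s2 + s3`).
#' @export
site_support <- function(quartet, aln) {
  missing <- setdiff(quartet, rownames(aln))
  if (length(missing) > 0) stop("taxa absent from alignment: ",
                                paste(missing, collapse = ", "))
  enc <- if (is.numeric(aln)) aln else .encode_alignment(aln)
  .site_support_enc(enc[quartet[1], ], enc[quartet[2], ],
                    enc[quartet[3], ], enc[quartet[4], ])
}

.site_support_enc <- function(a, b, c, d) {
  ok <- !(is.na(a) | is.na(b) | is.na(c) | is.na(d))
  s1 <- sum(ok & a == b & c == d & a != c)
  s2 <- sum(ok & a == c & b == d & a != b)
  s3 <- sum(ok & a == d & b == c & a != b)
  list(s1 = s1, s2 = s2, s3 = s3, decisive = s1 + s2 + s3)
}

#' Site concordance factor for one branch
#'
#' Quartets are drawn one taxon per quadripartition set. If the number of
#' possible quartets is at most `n_quartets` they are enumerated
#' exhaustively; otherwise `n_quartets` quartets are sampled uniformly with
#' replacement. Each quartet with at least one decisive site contributes
#' `100 * s1 / (s1 + s2 + s3)`; the site concordance factor is the unweighted
#' mean over those retained quartets, and quartets with no decisive site are
#' skipped (not scored 0). With no retained quartet the factor is undefined
#' (`NA`).
#'
#' @inheritParams gene_concordance
#' @param aln Character alignment matrix.
#' @param n_quartets Number of quartets to sample (default 100).
#' @param seed Optional integer seed for reproducible sampling.
#' @return One-row tibble with `scf` (percent or `NA`), `sn` (mean decisive
#'   sites per retained quartet), `quartets` (retained count) and
#'   `exhaustive` (logical).
#' @export
site_concordance <- function(quad, aln, n_quartets = 100, seed = NULL) {
  enc <- if (is.numeric(aln)) aln else .encode_alignment(aln)
  sets <- lapply(quad$sets, intersect, y = rownames(enc))
  if (any(lengths(sets) == 0)) {
    stop("a quadripartition set has no taxon in the alignment")
  }
  n_comb <- prod(lengths(sets))
  if (n_comb <= n_quartets) {
    grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]], sets[[4]],
                        stringsAsFactors = FALSE)
    picks <- as.matrix(grid)
    exhaustive <- TRUE
  } else {
    picks <- with_seed_if(seed, {
      cbind(sample(sets[[1]], n_quartets, replace = TRUE),
            sample(sets[[2]], n_quartets, replace = TRUE),
            sample(sets[[3]], n_quartets, replace = TRUE),
            sample(sets[[4]], n_quartets, replace = TRUE))
    })
    exhaustive <- FALSE
  }
  ratios <- numeric(0); dec <- numeric(0)
  for (i in seq_len(nrow(picks))) {
    s <- .site_support_enc(enc[picks[i, 1], ], enc[picks[i, 2], ],
                           enc[picks[i, 3], ], enc[picks[i, 4], ])
    if (s$decisive > 0) {
      ratios <- c(ratios, 100 * s$s1 / s$decisive)
      dec <- c(dec, s$decisive)
    }
  }
  tibble(scf = if (length(ratios) > 0) mean(ratios) else NA_real_,
         sn = if (length(dec) > 0) mean(dec) else NA_real_,
         quartets = length(ratios), exhaustive = exhaustive)
}

# human-readable bipartition label "A,B|C,D,E"
.bipartition_label <- function(key, all_taxa) {
  side_b <- strsplit(key, .KEY_SEP, fixed = TRUE)[[1]]
  side_a <- sort(setdiff(all_taxa, side_b))
  paste0(paste(side_a, collapse = ","), "|", paste(side_b, collapse = ","))
}

#' Branch-wise gene and site concordance table
#'
#' Computes a [gene_concordance()] and [site_concordance()] record for every
#' internal branch of the reference tree (its unrooted version: n - 3
#' branches for n leaves). Deterministic given `seed`: each branch's quartet
#' sampling uses a sub-seed derived from it.
#'
#' @param ref_tree Reference `phylo` (binary).
#' @param gene_trees List of gene trees (may miss taxa).
#' @param aln Optional character alignment matrix; if `NULL`, site factors
#'   are skipped.
#' @param n_quartets Quartets sampled per branch for sCF.
#' @param seed Integer seed recorded in the result.
#' @return A tibble of class `concordance_df` with one row per internal
#'   branch: `branch_id`, `bipartition`, `gcf`, `gcf_n`, `gn`, `scf`, `sn`,
#'   `quartets`; attributes `seed` and `ref_tree`.
#' @export
concordance_table <- function(ref_tree, gene_trees, aln = NULL,
                              n_quartets = 100, seed = 1L) {
  quads <- quadripartitions(ref_tree)
  cache <- .gene_tree_cache(gene_trees)
  enc <- if (!is.null(aln) && !is.numeric(aln)) .encode_alignment(aln) else aln
  seeds <- derive_seeds(seed, length(quads))
  rows <- lapply(seq_along(quads), function(i) {
    q <- quads[[i]]
    g <- .gcf_from_cache(q, cache)
    row <- tibble(branch_id = i,
                  bipartition = .bipartition_label(q$key, q$taxa),
                  gcf = g$gcf, gcf_n = g$gcf_n, gn = g$gn,
                  scf = NA_real_, sn = NA_real_, quartets = NA_integer_)
    if (!is.null(enc)) {
      s <- site_concordance(q, enc, n_quartets = n_quartets, seed = seeds[i])
      row$scf <- s$scf; row$sn <- s$sn; row$quartets <- s$quartets
    }
    row
  })
  out <- bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "ref_tree") <- ref_tree
  class(out) <- c("concordance_df", class(out))
  out
}

#' Write a concordance report as TSV
#'
#' Undefined factors are printed as `NA`, never 0; the seed used for quartet
#' sampling is recorded in a header comment.
#'
#' @param x A `concordance_df` from [concordance_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", attr(x, "seed")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Annotate a tree's internal nodes with "gCF/sCF" labels
#'
#' @param x A `concordance_df` from [concordance_table()].
#' @param digits Decimal places in the labels.
#' @return A newick string of the (unrooted) reference tree with node labels
#'   of the form `"gCF/sCF"` (`NA` for undefined factors).
#' @export
concordance_newick <- function(x, digits = 1) {
  tree <- attr(x, "ref_tree")
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  desc <- .desc_tips(tr)
  labs <- rep("", tr$Nnode)
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, format = "f",
                                                    digits = digits))
  keys <- vapply(strsplit(x$bipartition, "|", fixed = TRUE), function(p) {
    .split_key(strsplit(p[2], ",", fixed = TRUE)[[1]], tr$tip.label)
  }, character(1))
  for (node in (ntip + 1L):(ntip + tr$Nnode)) {
    side <- desc[[node]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    i <- match(.split_key(side, tr$tip.label), keys)
    if (!is.na(i)) {
      labs[node - ntip] <- paste0(fmt(x$gcf[i]), "/", fmt(x$scf[i]))
    }
  }
  tr$node.label <- labs
  ape::write.tree(tr, digits = 12)
}
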