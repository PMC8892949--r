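#' Likelihood mapping of a single quartet
#'
#' Scores the three possible arrangements of four taxa —
#' `(1,2|3,4)`, `(1,3|2,4)`, `(1,4|2,3)` in row order of the alignment —
#' by maximizing the pruning likelihood over branch lengths on each quartet
#' topology, then places the normalized weights
#' `p_i = exp(lnL_i - max lnL) / sum` in the likelihood-mapping simplex.
#' The seven-region rule is a dominance rule with configurable threshold:
#' corner `i` iff `p_i > c * p_j` and `p_i > c * p_k`; otherwise side `ij`
#' iff both `p_i > c * p_k` and `p_j > c * p_k`; otherwise center. Ties
#' break toward the lower-numbered region. The basin is simply the argmax.
#'
#' @param aln4 Alignment matrix with exactly four rows; row order fixes
#'   arrangement numbering.
#' @param model A `subst_model` (default [jc69()]).
#' @param dominance Threshold `c` of the region rule (default 2).
#' @return List with `p` (length-3 weights summing to 1), `lnl` (the three
#'   optimized log-likelihoods), `region` (one of `"corner1".."corner3"`,
#'   `"side12"`, `"side13"`, `"side23"`, `"center"`) and `basin` (1, 2 or
#'   3).
#' @export
quartet_map_point <- function(aln4, model = jc69(), dominance = 2) {
  if (nrow(aln4) != 4) stop("need exactly 4 taxa, got ", nrow(aln4))
  tx <- rownames(aln4)
  tops <- c(sprintf("((%s,%s),(%s,%s));", tx[1], tx[2], tx[3], tx[4]),
            sprintf("((%s,%s),(%s,%s));", tx[1], tx[3], tx[2], tx[4]),
            sprintf("((%s,%s),(%s,%s));", tx[1], tx[4], tx[2], tx[3]))
  lnl <- vapply(tops, function(s) {
    optimize_branch_lengths(ape::read.tree(text = s), aln4, model)$loglik
  }, numeric(1), USE.NAMES = FALSE)
  w <- exp(lnl - max(lnl))
  p <- w / sum(w)
  list(p = p, lnl = lnl, region = .lmap_region(p, dominance),
       basin = which.max(p))
}

.lmap_region <- function(p, dominance = 2) {
  for (i in 1:3) {
    jk <- setdiff(1:3, i)
    if (p[i] > dominance * p[jk[1]] && p[i] > dominance * p[jk[2]]) {
      return(paste0("corner", i))
    }
  }
  sides <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (s in sides) {
    k <- setdiff(1:3, s)
    if (p[s[1]] > dominance * p[k] && p[s[2]] > dominance * p[k]) {
      return(paste0("side", s[1], s[2]))
    }
  }
  "center"
}

#' Likelihood-mapping census over genes
#'
#' For every gene (partition), draws quartets with one taxon per group —
#' exhaustively when the number of combinations is at most
#' `quartets_per_gene`, otherwise a uniform sample without replacement of
#' that size — maps each quartet with [quartet_map_point()] on the gene's
#' columns, and accumulates a census over the seven simplex regions and
#' the three basins. Arrangement 1 is fixed as `(group1+group2 |
#' group3+group4)`. A taxon counts as present in a gene iff it has at least
#' one unambiguous nucleotide in the gene's columns; a gene contributes only
#' if all four groups have a present taxon.
#'
#' @param aln Supermatrix (character matrix).
#' @param parts Partition tibble ([read_partitions()]).
#' @param groups List of four disjoint character vectors of taxa.
#' @param model A `subst_model`.
#' @param quartets_per_gene Cap per gene (default `Inf` = exhaustive).
#' @param dominance Region-rule threshold, see [quartet_map_point()].
#' @param seed Integer seed for the (optional) per-gene sampling.
#' @return Object of class `lmap_census`: list with `per_gene` (tibble of
#'   region/basin counts per contributing gene) and `totals` (named vector
#'   over the 7 regions, 3 basins and total quartets).
#' @export
lmap_scan <- function(aln, parts, groups, model = jc69(),
                      quartets_per_gene = Inf, dominance = 2, seed = 1L) {
  stopifnot(length(groups) == 4)
  if (anyDuplicated(unlist(groups))) stop("groups must be disjoint")
  enc <- .encode_alignment(aln)
  region_names <- c("corner1", "corner2", "corner3",
                    "side12", "side13", "side23", "center")
  seeds <- derive_seeds(seed, nrow(parts))
  rows <- list()
  any_present <- rep(FALSE, 4)
  for (gi in seq_len(nrow(parts))) {
    cols <- (parts$start[gi] + 1L):parts$end[gi]
    sub <- enc[, cols, drop = FALSE]
    present <- rownames(sub)[rowSums(!is.na(sub)) > 0]
    gsets <- lapply(groups, intersect, y = present)
    any_present <- any_present | lengths(gsets) > 0
    if (any(lengths(gsets) == 0)) next
    n_comb <- prod(lengths(gsets))
    if (n_comb <= quartets_per_gene) {
      grid <- as.matrix(expand.grid(gsets[[1]], gsets[[2]], gsets[[3]],
                                    gsets[[4]], stringsAsFactors = FALSE))
    } else {
      pick <- with_seed_if(seeds[gi],
                           sample.int(n_comb, quartets_per_gene))
      sizes <- lengths(gsets)
      grid <- t(vapply(pick - 1L, function(ix) {
        out <- character(4)
        for (k in 1:4) {
          out[k] <- gsets[[k]][ix %% sizes[k] + 1L]
          ix <- ix %/% sizes[k]
        }
        out
      }, character(4)))
    }
    counts <- setNames(integer(7), region_names)
    basins <- integer(3)
    for (qi in seq_len(nrow(grid))) {
      q <- grid[qi, ]
      pt <- quartet_map_point(sub[q, , drop = FALSE], model = model,
                              dominance = dominance)
      counts[pt$region] <- counts[pt$region] + 1L
      basins[pt$basin] <- basins[pt$basin] + 1L
    }
    rows[[length(rows) + 1L]] <- tibble(
      gene = parts$gene[gi], n_quartets = nrow(grid),
      !!!as.list(counts), basin1 = basins[1], basin2 = basins[2],
      basin3 = basins[3])
  }
  if (any(!any_present)) {
    stop("group(s) ", paste(which(!any_present), collapse = ", "),
         " empty in every gene")
  }
  per_gene <- if (length(rows) > 0) bind_rows(rows) else
    tibble(gene = character(0), n_quartets = integer(0))
  tot_cols <- c(region_names, paste0("basin", 1:3), "n_quartets")
  totals <- if (nrow(per_gene) > 0) {
    setNames(vapply(tot_cols, function(cn) sum(per_gene[[cn]]), numeric(1)),
             c(region_names, paste0("basin", 1:3), "total"))
  } else {
    setNames(rep(0, length(tot_cols)),
             c(region_names, paste0("basin", 1:3), "total"))
  }
  structure(list(per_gene = per_gene, totals = totals,
                 dominance = dominance, model = model$name, seed = seed),
            class = "lmap_census")
}

#' @export
print.lmap_census <- function(x, ...) {
  cat("Likelihood-mapping census over", nrow(x$per_gene), "gene(s),",
      x$totals[["total"]], "quartets\n")
  print(x$totals)
  invisible(x)
}
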