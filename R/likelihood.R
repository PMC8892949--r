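# pattern compression: encoded sub-alignment (tips x sites) -> unique
# patterns and weights, in tree tip order; tips absent from the alignment
# contribute all-missing rows
.compress_patterns <- function(tree, aln) {
  enc <- if (is.numeric(aln)) aln else .encode_alignment(aln)
  extra <- setdiff(rownames(enc), tree$tip.label)
  if (length(extra) > 0) stop("alignment taxa not in tree: ",
                              paste(extra, collapse = ", "))
  n_sites <- ncol(enc)
  m <- matrix(NA_integer_, length(tree$tip.label), n_sites,
              dimnames = list(tree$tip.label, NULL))
  present <- intersect(tree$tip.label, rownames(enc))
  m[present, ] <- enc[present, ]
  key <- apply(m, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(patterns = m[, first, drop = FALSE], weights = w)
}

# tip partial matrices (4 x npat) for each tip; missing chars get all-ones
.tip_partials <- function(patterns, freqs = NULL) {
  lapply(seq_len(nrow(patterns)), function(i) {
    p <- matrix(1, 4, ncol(patterns))
    obs <- !is.na(patterns[i, ])
    if (any(obs)) {
      p[, obs] <- 0
      p[cbind(patterns[i, obs], which(obs))] <- 1
    }
    p
  })
}

.postorder_edges <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  list(edge = tr$edge, elen = tr$edge.length)
}

#' Phylogenetic log-likelihood by pruning
#'
#' Felsenstein's pruning algorithm over compressed site patterns, with the
#' model's equilibrium frequencies as the root prior. Gaps and `N` are
#' treated as missing data (partial likelihood 1 for every state), as are
#' tree tips absent from the alignment. The JC69 path runs in compiled code;
#' other models use the generic R implementation with
#' [transition_probability()] — the two are interchangeable and tested
#' equal.
#'
#' @param tree A `phylo` with branch lengths.
#' @param aln Character (or pre-encoded integer) alignment matrix; taxa must
#'   be a subset of the tree's leaves.
#' @param model A `subst_model` (default [jc69()]).
#' @return The log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, aln, model = jc69()) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("missing branch length")
  }
  cp <- .compress_patterns(tree, aln)
  po <- .postorder_edges(tree)
  if (model$name == "JC69") {
    jc_loglik_cpp(po$edge, po$elen, length(tree$tip.label), tree$Nnode,
                  .tip_partials(cp$patterns), cp$weights)
  } else {
    .pruning_loglik_r(po, length(tree$tip.label), cp, model)
  }
}

# generic R pruning (any subst_model); reference implementation
.pruning_loglik_r <- function(po, ntip, cp, model) {
  npat <- length(cp$weights)
  tipp <- .tip_partials(cp$patterns)
  nnode_total <- max(po$edge)
  part <- vector("list", nnode_total)
  logsc <- matrix(0, nnode_total, npat)
  for (n in (ntip + 1L):nnode_total) part[[n]] <- matrix(1, 4, npat)
  for (i in seq_len(ntip)) part[[i]] <- tipp[[i]]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- transition_probability(model, po$elen[e])
    msg <- P %*% part[[ch]]
    part[[p]] <- part[[p]] * msg
    if (ch > ntip) logsc[p, ] <- logsc[p, ] + logsc[ch, ]
    mx <- apply(part[[p]], 2, max)
    pos <- mx > 0
    part[[p]][, pos] <- sweep(part[[p]][, pos, drop = FALSE], 2, mx[pos], "/")
    logsc[p, pos] <- logsc[p, pos] + log(mx[pos])
  }
  root <- ntip + 1L
  L <- as.numeric(model$freqs %*% part[[root]])
  sum(cp$weights * (log(L) + logsc[root, ]))
}

#' Optimize branch lengths on a fixed topology
#'
#' Cyclic per-branch scalar maximization of the pruning likelihood, each
#' branch bounded in `[min_len, max_len]`, sweeping until the improvement in
#' log-likelihood falls below `tol` or `max_sweeps` is hit (the result then
#' carries `converged = FALSE`). Ascent is monotone: a branch update is kept
#' only if it does not decrease the likelihood. All branches start at
#' `init`.
#'
#' @inheritParams pruning_loglik
#' @param init Initial length for every branch.
#' @param min_len,max_len Bounds for each branch length.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_sweeps Cap on full sweeps over the branches.
#' @return List with `tree` (lengths filled in), `loglik`, `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, model = jc69(), init = 0.1,
                                    min_len = 1e-8, max_len = 10,
                                    tol = 1e-6, max_sweeps = 100) {
  tr <- tree
  tr$edge.length <- rep(init, nrow(tr$edge))
  cp <- .compress_patterns(tr, aln)
  po <- .postorder_edges(tr)
  ntip <- length(tr$tip.label)
  if (model$name == "JC69") {
    fit <- jc_opt_edges_cpp(po$edge, po$elen, ntip, tr$Nnode,
                            .tip_partials(cp$patterns), cp$weights,
                            min_len, max_len, tol, max_sweeps)
    po$elen <- fit$lengths
    ll <- fit$loglik
    converged <- fit$converged
  } else {
    ll <- .pruning_loglik_r(po, ntip, cp, model)
    converged <- FALSE
    for (s in seq_len(max_sweeps)) {
      ll_before <- ll
      for (e in seq_along(po$elen)) {
        keep <- po$elen[e]
        opt <- optimize(function(x) {
          po$elen[e] <- exp(x)
          .pruning_loglik_r(po, ntip, cp, model)
        }, interval = log(c(min_len, max_len)), maximum = TRUE,
        tol = 1e-8)
        if (opt$objective >= ll) {
          po$elen[e] <- exp(opt$maximum)
          ll <- opt$objective
        } else {
          po$elen[e] <- keep
        }
      }
      if (ll - ll_before < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) warning("branch-length optimization hit the sweep cap")
  # map postorder lengths back onto the input tree's edge order
  tr2 <- stats::reorder(tr, "postorder")
  tr2$edge.length <- po$elen
  key_in <- paste(tr$edge[, 1], tr$edge[, 2])
  key_po <- paste(tr2$edge[, 1], tr2$edge[, 2])
  tr$edge.length <- po$elen[match(key_in, key_po)]
  list(tree = tr, loglik = ll, converged = converged)
}
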