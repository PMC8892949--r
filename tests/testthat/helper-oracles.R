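# Independent brute-force oracles. These re-derive every quantity from first
# principles (exhaustive enumeration, closed forms) without touching the
# package's pruning/bipartition internals.

# JC69 transition probability, written out from the closed form
oracle_jc_p <- function(t) {
  es <- exp(-4 * t / 3)
  P <- matrix(0.25 - 0.25 * es, 4, 4)
  diag(P) <- 0.25 + 0.75 * es
  P
}

# log-likelihood by exhaustive summation over all internal-node state
# assignments (complete data only)
oracle_jc_loglik <- function(tree, aln) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  internal <- (ntip + 1L):nn
  enc <- match(aln[tree$tip.label, , drop = FALSE], c("A", "C", "G", "T"))
  dim(enc) <- c(ntip, ncol(aln))
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) oracle_jc_p(tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  ll <- 0
  for (site in seq_len(ncol(enc))) {
    states <- integer(nn)
    states[seq_len(ntip)] <- enc[, site]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      states[internal] <- grid[g, ]
      p <- 0.25
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * Ps[[e]][states[tree$edge[e, 1]], states[tree$edge[e, 2]]]
      }
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

# Mk log-likelihood by exhaustive summation; P(t) via ape::matexpo so the
# kernel is independent of the package's closed-form ER path
oracle_mk_loglik <- function(tree, tip_states, Q, states,
                            prior = rep(1 / length(states), length(states))) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  internal <- (ntip + 1L):nn
  k <- length(states)
  enc <- match(tip_states[tree$tip.label], states)
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) ape::matexpo(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  stopifnot(!anyNA(enc)) # oracle handles complete data only
  st <- integer(nn)
  st[seq_len(ntip)] <- enc
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st[internal] <- grid[g, ]
    p <- prior[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + p
  }
  log(tot)
}

# exact per-node conditional state probabilities on a small tree by
# enumerating every assignment of internal-node states
oracle_mk_node_posterior <- function(tree, tip_states, Q, states,
                                     prior = rep(1 / length(states),
                                                 length(states))) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  internal <- (ntip + 1L):nn
  k <- length(states)
  enc <- match(tip_states[tree$tip.label], states)
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) ape::matexpo(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  st <- integer(nn)
  st[seq_len(ntip)] <- enc
  joint <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st[internal] <- grid[g, ]
    p <- prior[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    joint[g] <- p
  }
  joint <- joint / sum(joint)
  post <- matrix(0, length(internal), k,
                 dimnames = list(as.character(internal), states))
  for (g in seq_len(nrow(grid))) {
    for (ii in seq_along(internal)) {
      post[ii, grid[g, ii]] <- post[ii, grid[g, ii]] + joint[g]
    }
  }
  post
}

# gene concordance by brute force: decisiveness from the four sets,
# concordance by comparing tip-label sets of every split reported by
# phangorn (independent split machinery)
oracle_gcf <- function(sets, gene_trees) {
  s12 <- c(sets[[1]], sets[[2]])
  gn <- 0L; conc <- 0L
  for (g in gene_trees) {
    taxa <- g$tip.label
    if (!all(vapply(sets, function(s) any(s %in% taxa), logical(1)))) next
    gn <- gn + 1L
    target <- sort(intersect(s12, taxa))
    spl <- phangorn::as.splits(ape::unroot(g))
    labs <- attr(spl, "labels")
    hit <- FALSE
    for (sp in spl) {
      side <- sort(labs[sp])
      other <- sort(setdiff(taxa, side))
      if (length(side) < 2 || length(other) < 2) next
      if (identical(side, target) || identical(other, target)) hit <- TRUE
    }
    if (hit) conc <- conc + 1L
  }
  list(gcf = if (gn > 0) 100 * conc / gn else NA_real_, gcf_n = conc, gn = gn)
}

# per-site classification of one quartet by direct pattern matching
oracle_site_counts <- function(quartet_rows) {
  s <- c(0L, 0L, 0L)
  for (j in seq_len(ncol(quartet_rows))) {
    x <- quartet_rows[, j]
    if (!all(x %in% c("A", "C", "G", "T"))) next
    if (x[1] == x[2] && x[3] == x[4] && x[1] != x[3]) s[1] <- s[1] + 1L
    else if (x[1] == x[3] && x[2] == x[4] && x[1] != x[2]) s[2] <- s[2] + 1L
    else if (x[1] == x[4] && x[2] == x[3] && x[1] != x[2]) s[3] <- s[3] + 1L
  }
  s
}

# random binary tree with moderate branch lengths, reproducible
random_tree <- function(ntip, seed, min_len = 0.05, max_len = 0.4) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntip)
    tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
    tr
  })
}
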