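#' Stochastic character maps under an Mk model
#'
#' Samples full character histories conditional on the observed tip states
#' and a (fitted or supplied) Mk model. Node states are drawn from their
#' joint conditional distribution (root to tips, using the pruning
#' partials); each branch's path is then drawn conditional on its endpoint
#' states by uniformization with dominating rate `mu = max |Q_ii|`, which
#' bounds runtime even for unlikely endpoint pairs on short branches.
#' Histories are piecewise-constant state paths: per branch, an ordered set
#' of (state, duration) segments whose durations sum to the branch length,
#' with adjacent segments differing in state.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps to draw (default 1000).
#' @param seed Integer seed; maps are reproducible given it.
#' @return Object of class `char_history_list`: a list of histories, each a
#'   list with `node_states` (states of every node, tips included, indexed
#'   by node id) and `paths` (per edge of `tree$edge`, a data frame with
#'   columns `state`, `duration`). Attributes carry `tree` and `model`.
#' @export
stochastic_maps <- function(tree, tip_states, model, n_maps = 1000,
                            seed = 1L) {
  pr <- .mk_partials(tree, tip_states, model)
  states <- model$states
  k <- length(states)
  ntip <- pr$ntip
  root <- ntip + 1L
  prior <- .mk_root_prior(model)
  po <- pr$po
  # preorder = reversed postorder edge order
  pre <- rev(seq_len(nrow(po$edge)))
  Q <- model$Q
  mu <- max(-diag(Q))
  R <- if (mu > 0) diag(k) + Q / mu else diag(k)
  # cache R powers per distinct branch length as needed, per edge
  maps <- with_seed_if(seed, {
    lapply(seq_len(n_maps), function(m) {
      node_states <- integer(max(po$edge))
      w <- prior * pr$part[, root]
      node_states[root] <- sample.int(k, 1, prob = w)
      for (e in pre) {
        pnode <- po$edge[e, 1]; ch <- po$edge[e, 2]
        w <- pr$P_edges[[e]][node_states[pnode], ] * pr$part[, ch]
        node_states[ch] <- sample.int(k, 1, prob = w)
      }
      paths <- vector("list", nrow(po$edge))
      for (e in seq_len(nrow(po$edge))) {
        paths[[e]] <- .sample_path_uniformized(
          node_states[po$edge[e, 1]], node_states[po$edge[e, 2]],
          po$elen[e], Q, R, mu,
          pr$P_edges[[e]][node_states[po$edge[e, 1]],
                          node_states[po$edge[e, 2]]])
      }
      # re-map from postorder edge order to the input tree's edge order
      key_in <- paste(tree$edge[, 1], tree$edge[, 2])
      key_po <- paste(po$edge[, 1], po$edge[, 2])
      list(node_states = setNames(states[node_states],
                                  as.character(seq_along(node_states))),
           paths = lapply(paths[match(key_in, key_po)], function(p) {
             data.frame(state = states[p$state], duration = p$duration)
           }))
    })
  })
  base::structure(maps, class = "char_history_list", tree = tree,
                  model = model, seed = seed)
}

# endpoint-conditioned path by uniformization: sample the number of
# dominated jumps, then the jump chain, then uniform-order-statistic times;
# collapse virtual (self) jumps into segments
.sample_path_uniformized <- function(i, j, t, Q, R, mu, pij) {
  if (mu == 0 || t == 0) {
    if (i != j) stop("endpoint pair with zero transition probability")
    return(list(state = i, duration = t))
  }
  if (pij <= 0) stop("endpoint pair with zero transition probability")
  # number of jumps: P(n | i,j,t) prop dpois(n, mu t) * R^n[i,j] / pij
  u <- runif(1)
  Rn <- diag(nrow(R)) # R^0
  Rpows <- list(Rn)
  n <- 0L
  cum <- stats::dpois(0, mu * t) * Rn[i, j] / pij
  while (cum < u && n < 10000L) {
    n <- n + 1L
    Rn <- Rn %*% R
    Rpows[[n + 1L]] <- Rn
    cum <- cum + stats::dpois(n, mu * t) * Rn[i, j] / pij
  }
  if (n == 0L) {
    if (i != j) stop("zero jumps but different endpoints")
    return(list(state = i, duration = t))
  }
  # jump chain conditional on endpoints
  chain <- integer(n + 1L)
  chain[1] <- i
  for (m in seq_len(n)) {
    remain <- n - m
    w <- R[chain[m], ] * Rpows[[remain + 1L]][, j]
    chain[m + 1L] <- sample.int(length(w), 1, prob = w)
  }
  times <- sort(runif(n, 0, t))
  bounds <- c(0, times, t)
  durs <- diff(bounds)
  # collapse consecutive identical states (virtual jumps)
  keep_state <- chain[1]; out_s <- integer(0); out_d <- numeric(0)
  acc <- durs[1]
  for (m in seq_len(n)) {
    if (chain[m + 1L] == keep_state) {
      acc <- acc + durs[m + 1L]
    } else {
      out_s <- c(out_s, keep_state); out_d <- c(out_d, acc)
      keep_state <- chain[m + 1L]; acc <- durs[m + 1L]
    }
  }
  out_s <- c(out_s, keep_state); out_d <- c(out_d, acc)
  list(state = out_s, duration = out_d)
}

#' Transition census over stochastic maps
#'
#' Counts state changes along branches in every history, splits them into
#' changes on terminal branches (leading to tips) versus internal branches,
#' accumulates a state-pair transition matrix, and reports the fraction of
#' transitions with a designated generalist state as source or target.
#'
#' @param histories A `char_history_list` (or a list of single histories
#'   with a `tree` attribute).
#' @param generalist_state State label counted as "generalist" for the
#'   specialist/generalist fraction (default `"generalist"`; `NA` fraction
#'   if absent from the state set).
#' @return Object of class `transition_summary`: list with `mean_total`,
#'   `mean_terminal`, `mean_internal`, `pair_matrix` (mean per-map counts),
#'   `generalist_fraction`, and `per_map` (tibble: map, total, terminal,
#'   internal).
#' @export
count_transitions <- function(histories, generalist_state = "generalist") {
  tree <- attr(histories, "tree")
  if (is.null(tree)) stop("histories must carry a tree attribute")
  ntip <- length(tree$tip.label)
  terminal_edge <- tree$edge[, 2] <= ntip
  states <- if (!is.null(attr(histories, "model")))
    attr(histories, "model")$states
  else sort(unique(unlist(lapply(histories, function(h)
    unlist(lapply(h$paths, `[[`, "state"))))))
  k <- length(states)
  pair <- matrix(0, k, k, dimnames = list(states, states))
  per_map <- vector("list", length(histories))
  gen_trans <- 0; all_trans <- 0
  for (m in seq_along(histories)) {
    h <- histories[[m]]
    tot <- 0L; term <- 0L
    for (e in seq_along(h$paths)) {
      st <- h$paths[[e]]$state
      nch <- length(st) - 1L
      if (nch > 0) {
        tot <- tot + nch
        if (terminal_edge[e]) term <- term + nch
        for (x in seq_len(nch)) {
          pair[st[x], st[x + 1L]] <- pair[st[x], st[x + 1L]] + 1
          if (!is.na(generalist_state) &&
              (st[x] == generalist_state || st[x + 1L] == generalist_state)) {
            gen_trans <- gen_trans + 1
          }
        }
        all_trans <- all_trans + nch
      }
    }
    per_map[[m]] <- tibble(map = m, total = tot, terminal = term,
                           internal = tot - term)
  }
  per_map <- bind_rows(per_map)
  base::structure(list(
    mean_total = mean(per_map$total),
    mean_terminal = mean(per_map$terminal),
    mean_internal = mean(per_map$internal),
    pair_matrix = pair / length(histories),
    generalist_fraction = if (generalist_state %in% states && all_trans > 0)
      gen_trans / all_trans else NA_real_,
    per_map = per_map), class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Mean transitions per map: %.2f (terminal %.2f, internal %.2f)\n",
              x$mean_total, x$mean_terminal, x$mean_internal))
  if (!is.na(x$generalist_fraction)) {
    cat(sprintf("Fraction involving the generalist state: %.1f%%\n",
                100 * x$generalist_fraction))
  }
  invisible(x)
}

#' Posterior node-state summary of stochastic maps
#'
#' Per-node frequencies of each state across maps (summing to 1), the
#' maximum-posterior summary state per node, and the branches on which the
#' summary states of parent and child disagree — the likely transition
#' branches.
#'
#' @param histories A `char_history_list`.
#' @return Object of class `simmap_summary`: list with `node_posterior`
#'   (tibble: `node`, `state`, `prob`), `summary_states` (named by node id)
#'   and `transition_edges` (row indices into `tree$edge`).
#' @export
summarize_posterior <- function(histories) {
  tree <- attr(histories, "tree")
  model <- attr(histories, "model")
  states <- model$states
  nn <- max(tree$edge)
  counts <- matrix(0, nn, length(states),
                   dimnames = list(as.character(seq_len(nn)), states))
  for (h in histories) {
    s <- h$node_states
    counts[cbind(seq_len(nn), match(s, states))] <-
      counts[cbind(seq_len(nn), match(s, states))] + 1
  }
  post <- counts / length(histories)
  summary_states <- states[apply(post, 1, which.max)]
  names(summary_states) <- rownames(post)
  trans_edges <- which(summary_states[tree$edge[, 1]] !=
                         summary_states[tree$edge[, 2]])
  node_posterior <- as_tibble(as.data.frame.table(post,
                                                  stringsAsFactors = FALSE))
  names(node_posterior) <- c("node", "state", "prob")
  node_posterior$node <- as.integer(node_posterior$node)
  base::structure(list(node_posterior = arrange(node_posterior, .data$node),
                       summary_states = summary_states,
                       transition_edges = trans_edges, tree = tree),
                  class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("Max-posterior node states (", x$tree$Nnode, " internal nodes), ",
      length(x$transition_edges), " transition branch(es)\n", sep = "")
  invisible(x)
}
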