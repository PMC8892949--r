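#' Mk model for a discrete character
#'
#' Builds a continuous-time Markov (Mk) rate matrix over a state set under
#' one of the standard structures: `ER` (one rate for every transition),
#' `SYM` (symmetric pairwise rates) or `ARD` (all rates different). Rows of
#' `Q` sum to zero and off-diagonal entries are nonnegative.
#'
#' @param states Character vector of state labels.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param rates Free rates: a scalar for `ER`; `k(k-1)/2` values filling the
#'   upper triangle row-wise for `SYM`; `k(k-1)` values filling the
#'   off-diagonal row-wise for `ARD`.
#' @param root_prior `"flat"` (uniform over states) or `"stationary"` (the
#'   chain's stationary distribution).
#' @return Object of class `mk_model`: list with `states`, `structure`,
#'   `Q`, `root_prior`.
#' @export
mk_model <- function(states, structure = c("ER", "SYM", "ARD"), rates = 1,
                     root_prior = c("flat", "stationary")) {
  structure <- match.arg(structure)
  root_prior <- match.arg(root_prior)
  k <- length(states)
  stopifnot(k >= 2, all(rates >= 0))
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (structure == "ER") {
    stopifnot(length(rates) == 1)
    Q[] <- rates
  } else if (structure == "SYM") {
    stopifnot(length(rates) == k * (k - 1) / 2)
    Q[upper.tri(Q)] <- rates[order(row(Q)[upper.tri(Q)],
                                   col(Q)[upper.tri(Q)])]
    Q <- Q + t(Q)
  } else {
    stopifnot(length(rates) == k * (k - 1))
    off <- which(row(Q) != col(Q))
    off <- off[order(row(Q)[off], col(Q)[off])]
    Q[off] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure2 <- structure # avoid clash with base::structure
  base::structure(list(states = states, structure = structure2, Q = Q,
                       root_prior = root_prior),
                  class = "mk_model")
}

# root prior vector for an mk_model
.mk_root_prior <- function(model) {
  k <- length(model$states)
  if (model$root_prior == "flat") return(rep(1 / k, k))
  # stationary: left null vector of Q
  ns <- t(model$Q)
  pi <- abs(Re(eigen(ns)$vectors[, which.min(abs(eigen(ns)$values))]))
  pi / sum(pi)
}

# P(t) = exp(Qt); ER has a closed form, others go through ape::matexpo
.mk_pmat <- function(model, t) {
  k <- length(model$states)
  if (model$structure == "ER") {
    r <- model$Q[1, 2]
    e <- exp(-k * r * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- 1 / k + (k - 1) / k * e
  } else {
    P <- ape::matexpo(model$Q * t)
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- list(model$states, model$states)
  P
}

# tip partial matrix (k x ntip): unit vector per observed state, ones for NA
.mk_tip_partials <- function(tree, tip_states, states) {
  k <- length(states)
  x <- tip_states[tree$tip.label]
  bad <- !is.na(x) & !(x %in% states)
  if (any(bad)) stop("state(s) not in state set: ",
                     paste(unique(x[bad]), collapse = ", "))
  p <- matrix(1, k, length(x))
  obs <- !is.na(x)
  p[, obs] <- 0
  p[cbind(match(x[obs], states), which(obs))] <- 1
  p
}

# pruning partials for every node (list indexed by node id), plus per-node
# log scaling; shared by mk_loglik and stochastic_maps
.mk_partials <- function(tree, tip_states, model) {
  states <- model$states
  k <- length(states)
  ntip <- length(tree$tip.label)
  po <- .postorder_edges(tree)
  tipp <- .mk_tip_partials(tree, tip_states, states)
  nn <- max(po$edge)
  part <- matrix(1, k, nn)
  part[, seq_len(ntip)] <- tipp
  logsc <- numeric(nn)
  P_edges <- vector("list", nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    pnode <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- .mk_pmat(model, po$elen[e])
    P_edges[[e]] <- P
    part[, pnode] <- part[, pnode] * as.numeric(P %*% part[, ch])
    logsc[pnode] <- logsc[pnode] + logsc[ch]
    mx <- max(part[, pnode])
    if (mx > 0 && mx < 1e-100) {
      part[, pnode] <- part[, pnode] / mx
      logsc[pnode] <- logsc[pnode] + log(mx)
    }
  }
  list(part = part, logsc = logsc, po = po, P_edges = P_edges, ntip = ntip)
}

#' Mk log-likelihood on a time tree
#'
#' Felsenstein pruning over `exp(Q t)` per branch, with the model's root
#' prior. Tips with `NA` state are missing data (uniform partial
#' likelihood).
#'
#' @param tree A `phylo` with branch lengths (time units).
#' @param tip_states Named character vector (names = tip labels); `NA` =
#'   missing.
#' @param model An [mk_model()].
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  pr <- .mk_partials(tree, tip_states, model)
  root <- pr$ntip + 1L
  prior <- .mk_root_prior(model)
  L <- sum(prior * pr$part[, root])
  log(L) + pr$logsc[root]
}

#' Fit an Mk model by maximum likelihood
#'
#' Maximizes [mk_loglik()] over the free rates (log-parameterized, bounded)
#' for the chosen structure. With a single observed state the rate is pushed
#' to the lower bound with a warning.
#'
#' @inheritParams mk_loglik
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param states Optional state set; defaults to the sorted observed states.
#' @param root_prior `"flat"` or `"stationary"`.
#' @return A fitted [mk_model()] with elements `loglik`, `rates` and
#'   `convergence` added.
#' @export
fit_mk <- function(tree, tip_states, structure = c("ER", "SYM", "ARD"),
                   states = NULL, root_prior = c("flat", "stationary")) {
  structure <- match.arg(structure)
  root_prior <- match.arg(root_prior)
  obs <- unique(tip_states[!is.na(tip_states)])
  if (is.null(states)) states <- sort(obs)
  k <- length(states)
  n_rates <- switch(structure, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
                    ARD = as.integer(k * (k - 1)))
  if (length(obs) < 2) {
    warning("single observed state: rate(s) at lower bound")
    m <- mk_model(states, structure, rates = rep(1e-10, n_rates), root_prior)
    m$loglik <- mk_loglik(tree, tip_states, m)
    m$rates <- rep(1e-10, n_rates)
    m$convergence <- 0L
    return(m)
  }
  init <- length(obs) / sum(tree$edge.length) # order-of-magnitude start
  obj <- function(lr) {
    m <- mk_model(states, structure, rates = exp(lr), root_prior)
    -mk_loglik(tree, tip_states, m)
  }
  if (n_rates == 1L) {
    opt <- optimize(obj, interval = c(log(init) - 12, log(init) + 8))
    lr <- opt$minimum; nll <- opt$objective; conv <- 0L
  } else {
    opt <- nlminb(rep(log(init), n_rates), obj,
                  lower = log(init) - 12, upper = log(init) + 8)
    lr <- opt$par; nll <- opt$objective; conv <- opt$convergence
  }
  m <- mk_model(states, structure, rates = exp(lr), root_prior)
  m$loglik <- -nll
  m$rates <- exp(lr)
  m$convergence <- conv
  init_m <- mk_model(states, structure, rates = rep(init, n_rates), root_prior)
  if (m$loglik < mk_loglik(tree, tip_states, init_m) - 1e-8) {
    warning("fitted likelihood below initialization; optimization suspect")
  }
  m
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model (", x$structure, ", ", length(x$states), " states, root prior ",
      x$root_prior, ")\n", sep = "")
  print(round(x$Q, 6))
  if (!is.null(x$loglik)) cat("log-likelihood:", x$loglik, "\n")
  invisible(x)
}
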