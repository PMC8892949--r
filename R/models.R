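#' Nucleotide substitution models
#'
#' `jc69()` is the default scoring model: equal rates, equal frequencies,
#' with the closed-form transition kernel
#' `p_same = 1/4 + (3/4) exp(-4t/3)`, `p_diff = 1/4 - (1/4) exp(-4t/3)`
#' (branch lengths in expected substitutions per site). `gtr()` builds a
#' general time-reversible rate matrix from six exchangeabilities and
#' equilibrium frequencies, normalized so the expected rate is one
#' substitution per unit branch length; no rate heterogeneity.
#'
#' @param rates For `gtr()`: exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT.
#' @param freqs Equilibrium base frequencies (A, C, G, T); must sum to 1.
#' @return An object of class `subst_model`.
#' @export
jc69 <- function() {
  Q <- matrix(1 / 3, 4, 4)
  diag(Q) <- -1
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  structure(list(name = "JC69", Q = Q, freqs = rep(0.25, 4)),
            class = "subst_model")
}

#' @rdname jc69
#' @export
gtr <- function(rates = rep(1, 6), freqs = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, all(rates > 0), length(freqs) == 4,
            all(freqs > 0), abs(sum(freqs) - 1) < 1e-8)
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- Q[upper.tri(Q)] <- 0 # fill explicitly below
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (r in 1:6) {
    i <- idx[r, 1]; j <- idx[r, 2]
    Q[i, j] <- rates[r] * freqs[j]
    Q[j, i] <- rates[r] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  # symmetrized eigendecomposition for fast, stable exp(Qt)
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  ei <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = "GTR", Q = Q, freqs = freqs,
                 eig = list(values = ei$values,
                            left = diag(1 / sp) %*% ei$vectors,
                            right = t(ei$vectors) %*% diag(sp))),
            class = "subst_model")
}

#' Transition probability matrix
#'
#' @param model A `subst_model` from [jc69()] or [gtr()].
#' @param t Branch length in expected substitutions per site (t >= 0).
#' @return A 4x4 row-stochastic matrix, states ordered A, C, G, T.
#' @export
transition_probability <- function(model, t) {
  if (t < 0) stop("branch length must be nonnegative")
  if (model$name == "JC69") {
    es <- exp(-4 * t / 3)
    p_same <- 0.25 + 0.75 * es
    p_diff <- 0.25 - 0.25 * es
    P <- matrix(p_diff, 4, 4)
    diag(P) <- p_same
  } else {
    P <- model$eig$left %*% diag(exp(model$eig$values * t)) %*% model$eig$right
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}
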