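#' Tidy a concordance landscape
#'
#' @param x A `tree_landscape`.
#' @param ... Unused.
#' @return One row per clade arrangement: identifier, canonical newick,
#'   mean gCF/sCF and embedding coordinates.
#' @export
tidy.tree_landscape <- function(x, ...) {
  out <- x$records
  if (!is.null(x$mds)) {
    out <- left_join(out, x$mds[, c("topology_id", "axis1", "axis2")],
                     by = "topology_id")
  }
  out
}

#' @rdname tidy.tree_landscape
#' @export
glance.tree_landscape <- function(x, ...) {
  tibble(n_topologies = nrow(x$records),
         branches_per_topology = nrow(x$branches) / nrow(x$records),
         top_gcf_id = x$records$topology_id[which.max(x$records$mean_gcf)],
         top_gcf = max(x$records$mean_gcf),
         top_scf_id = if (all(is.na(x$records$mean_scf))) NA_character_ else
           x$records$topology_id[which.max(x$records$mean_scf)],
         top_scf = if (all(is.na(x$records$mean_scf))) NA_real_ else
           max(x$records$mean_scf, na.rm = TRUE),
         seed = x$seed)
}

#' Tidy a SOWH test result
#'
#' @param x A `sowh_result`.
#' @param ... Unused.
#' @return One row per bootstrap replicate with its null delta.
#' @export
tidy.sowh_result <- function(x, ...) {
  tibble(replicate = seq_along(x$null_deltas), delta = x$null_deltas)
}

#' @rdname tidy.sowh_result
#' @export
glance.sowh_result <- function(x, ...) {
  tibble(delta_obs = x$delta_obs, p_value = x$p_value, n_reps = x$n_reps,
         null_max = if (length(x$null_deltas) > 0) max(x$null_deltas)
         else NA_real_,
         model = x$model, seed = x$seed)
}

#' Tidy a likelihood-mapping census
#'
#' @param x An `lmap_census`.
#' @param ... Unused.
#' @return The per-gene region/basin count table.
#' @export
tidy.lmap_census <- function(x, ...) x$per_gene

#' @rdname tidy.lmap_census
#' @export
glance.lmap_census <- function(x, ...) {
  as_tibble(as.list(x$totals))
}

#' Tidy a fitted Mk model
#'
#' @param x An `mk_model`.
#' @param ... Unused.
#' @return One row per off-diagonal rate.
#' @export
tidy.mk_model <- function(x, ...) {
  k <- length(x$states)
  off <- which(row(x$Q) != col(x$Q))
  tibble(from = x$states[row(x$Q)[off]], to = x$states[col(x$Q)[off]],
         rate = x$Q[off])
}

#' @rdname tidy.mk_model
#' @export
glance.mk_model <- function(x, ...) {
  tibble(structure = x$structure, k = length(x$states),
         root_prior = x$root_prior,
         loglik = x$loglik %||% NA_real_,
         convergence = x$convergence %||% NA_integer_)
}

#' Tidy a transition summary
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return The per-map transition counts.
#' @export
tidy.transition_summary <- function(x, ...) x$per_map

#' @rdname tidy.transition_summary
#' @export
glance.transition_summary <- function(x, ...) {
  tibble(mean_total = x$mean_total, mean_terminal = x$mean_terminal,
         mean_internal = x$mean_internal,
         generalist_fraction = x$generalist_fraction)
}

#' Tidy a stochastic-map posterior summary
#'
#' @param x A `simmap_summary`.
#' @param ... Unused.
#' @return The per-node state posterior table.
#' @export
tidy.simmap_summary <- function(x, ...) x$node_posterior

#' Tidy a covariate summary
#'
#' @param x A `covariate_summary`.
#' @param ... Unused.
#' @return The pairwise test table.
#' @export
tidy.covariate_summary <- function(x, ...) x$tests

#' @rdname tidy.covariate_summary
#' @export
glance.covariate_summary <- function(x, ...) x$stats
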