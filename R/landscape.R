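#' Scan concordance across every clade arrangement
#'
#' The core landscape procedure: enumerate every rooted arrangement of the
#' ingroup clades (105 for five clades), attach the outgroup at the root,
#' expand each clade-level branch to a full-taxon quadripartition by pooling
#' clade members, and recompute gene and site concordance factors for every
#' scanned branch of every arrangement on the *same* fixed gene trees and
#' supermatrix. Per-topology means are taken over the clade-level internal
#' branches only (k - 2 of them for k ingroup clades), excluding the
#' ingroup/outgroup split and all within-clade branches, which are shared by
#' every arrangement and would only dilute the contrast.
#'
#' @param gene_trees List of `phylo` gene trees.
#' @param aln Character supermatrix (rows = taxa); `NULL` skips site factors.
#' @param cmap A [clade_map()].
#' @param n_quartets Quartets sampled per scanned branch for sCF.
#' @param seed Integer seed; every quartet draw uses a sub-seed derived from
#'   it, so reruns are byte-identical.
#' @param id_shuffle_seed Optional seed to shuffle the two-letter topology
#'   identifiers (default: canonical enumeration order).
#' @return An object of class `tree_landscape`: a list with `records`
#'   (tibble: `topology_id`, `newick`, `mean_gcf`, `mean_scf`), `branches`
#'   (per scanned branch: `topology_id`, `clade_split`, `gcf`, `gcf_n`, `gn`,
#'   `scf`, `sn`, `quartets`), `rf` (pairwise Robinson-Foulds matrix over
#'   skeletons), `mds` (two principal-coordinate axes), `eigenvalues`,
#'   `skeletons` (the clade-level trees) and the call parameters.
#' @export
scan_landscape <- function(gene_trees, aln, cmap, n_quartets = 100,
                           seed = 1L, id_shuffle_seed = NULL) {
  stopifnot(inherits(cmap, "clade_map"))
  ing <- sort(ingroup_clades(cmap))
  og <- outgroup_clade(cmap)
  data_taxa <- unique(c(unlist(lapply(gene_trees, `[[`, "tip.label")),
                        rownames(aln)))
  for (cl in c(ing, og)) {
    if (!any(clade_taxa(cmap, cl) %in% data_taxa)) {
      stop("clade '", cl, "' has no taxon present in the data")
    }
  }
  skels_in <- enumerate_rooted_topologies(ing)
  full <- lapply(skels_in, function(tr) {
    s <- sub(";$", "", canonical_form(tr))
    ape::read.tree(text = paste0("(", s, ",", og, ");"))
  })
  ids <- topology_ids(length(full), shuffle_seed = id_shuffle_seed)
  members <- lapply(setNames(c(ing, og), c(ing, og)),
                    function(cl) intersect(clade_taxa(cmap, cl), data_taxa))
  cache <- .gene_tree_cache(gene_trees)
  enc <- if (!is.null(aln) && !is.numeric(aln)) .encode_alignment(aln) else aln
  gcf_memo <- new.env(parent = emptyenv())

  quads_all <- lapply(full, quadripartitions)
  n_br <- lengths(quads_all)
  seeds <- derive_seeds(seed, sum(n_br))
  si <- 0L
  branch_rows <- list()
  for (t in seq_along(full)) {
    for (b in seq_len(n_br[t])) {
      si <- si + 1L
      q_cl <- quads_all[[t]][[b]]
      pooled <- new_quadripartition(
        unlist(members[q_cl$sets[[1]]], use.names = FALSE),
        unlist(members[q_cl$sets[[2]]], use.names = FALSE),
        unlist(members[q_cl$sets[[3]]], use.names = FALSE),
        unlist(members[q_cl$sets[[4]]], use.names = FALSE))
      # memo key covers all four sets: decisiveness depends on the full
      # quadripartition, not only on the bipartition
      set_key <- function(s) paste(s, collapse = ",")
      mkey <- paste(sort(c(set_key(pooled$sets[[1]]), set_key(pooled$sets[[2]]))),
                    collapse = "~")
      mkey <- paste(sort(c(mkey,
                           paste(sort(c(set_key(pooled$sets[[3]]),
                                        set_key(pooled$sets[[4]]))),
                                 collapse = "~"))), collapse = "#")
      if (is.null(gcf_memo[[mkey]])) {
        gcf_memo[[mkey]] <- .gcf_from_cache(pooled, cache)
      }
      g <- gcf_memo[[mkey]]
      ing_side_b <- setdiff(strsplit(q_cl$key, .KEY_SEP, fixed = TRUE)[[1]], og)
      ing_side_a <- setdiff(q_cl$taxa, c(ing_side_b, og))
      clade_side <- if (og %in% strsplit(q_cl$key, .KEY_SEP, fixed = TRUE)[[1]])
        ing_side_a else ing_side_b
      row <- tibble(topology_id = ids[t],
                    clade_split = paste(sort(clade_side), collapse = "+"),
                    gcf = g$gcf, gcf_n = g$gcf_n, gn = g$gn,
                    scf = NA_real_, sn = NA_real_, quartets = NA_integer_)
      if (!is.null(enc)) {
        s <- site_concordance(pooled, enc, n_quartets = n_quartets,
                              seed = seeds[si])
        row$scf <- s$scf; row$sn <- s$sn; row$quartets <- s$quartets
      }
      branch_rows[[si]] <- row
    }
  }
  branches <- bind_rows(branch_rows)
  records <- branches |>
    group_by(.data$topology_id) |>
    summarise(mean_gcf = mean(.data$gcf), mean_scf = mean(.data$scf),
              .groups = "drop")
  records <- tibble(topology_id = ids,
                    newick = vapply(full, canonical_form, character(1))) |>
    left_join(records, by = "topology_id")
  rf <- rf_matrix(full)
  dimnames(rf) <- list(ids, ids)
  obj <- structure(list(records = records, branches = branches, rf = rf,
                        mds = NULL, eigenvalues = NULL, skeletons = full,
                        clade_map = cmap, n_quartets = n_quartets,
                        seed = seed),
                   class = "tree_landscape")
  if (length(full) >= 3) {
    emb <- embed_treespace(obj)
    obj$mds <- emb
    obj$eigenvalues <- attr(emb, "eigenvalues")
  }
  obj
}

#' @export
print.tree_landscape <- function(x, ...) {
  cat("Concordance landscape over", nrow(x$records), "clade arrangements\n")
  cat("Scanned branches per arrangement:",
      nrow(x$branches) / nrow(x$records), "\n")
  best <- x$records[which.max(x$records$mean_gcf), ]
  cat(sprintf("Top mean gCF: %s (%.1f)\n", best$topology_id, best$mean_gcf))
  invisible(x)
}

#' Principal-coordinates embedding of a landscape
#'
#' Classical multidimensional scaling of the pairwise Robinson-Foulds matrix;
#' negative eigenvalues are truncated to zero in the reported spectrum. The
#' first two axes are joined with each arrangement's mean concordance so the
#' result can be plotted directly with point size = mean gCF and color =
#' mean sCF.
#'
#' @param x A `tree_landscape`, or a symmetric distance matrix with an
#'   accompanying `records` tibble via the `records` argument.
#' @param records Optional records tibble when `x` is a matrix.
#' @return Tibble with `topology_id`, `axis1`, `axis2`, `mean_gcf`,
#'   `mean_scf`; attribute `eigenvalues`.
#' @export
embed_treespace <- function(x, records = NULL) {
  if (inherits(x, "tree_landscape")) {
    d <- x$rf; records <- x$records
  } else {
    d <- x
  }
  if (nrow(d) < 3) stop("need at least 3 topologies to embed")
  fit <- cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  eig <- pmax(fit$eig, 0)
  coords <- fit$points
  out <- tibble(topology_id = if (!is.null(records)) records$topology_id
                else rownames(d),
                axis1 = coords[, 1], axis2 = coords[, 2])
  if (!is.null(records)) {
    out <- left_join(out, records[, c("topology_id", "mean_gcf", "mean_scf")],
                     by = "topology_id")
  }
  attr(out, "eigenvalues") <- eig
  out
}

#' Concordance by unique bipartition across the landscape
#'
#' Groups the scanned branches by their clade-level bipartition (identified
#' by the ingroup clade it defines). The gene concordance factor of a
#' bipartition is identical in every arrangement containing it — it depends
#' only on the bipartition — while sCF varies with the quadripartition
#' context and sampling, so sCF is kept per topology. Five ingroup clades
#' yield 25 distinct bipartitions (clades of sizes 2, 3 and 4).
#'
#' @param x A `tree_landscape`.
#' @return Tibble with one row per bipartition: `clade_split`, `size`
#'   (clades on the ingroup side), `n_topologies`, `gcf`, and `per_topology`
#'   (list-column of tibbles `topology_id`, `scf`, `sn`).
#' @export
bipartition_summary <- function(x) {
  stopifnot(inherits(x, "tree_landscape"))
  x$branches |>
    group_by(.data$clade_split) |>
    summarise(
      size = length(strsplit(.data$clade_split[1], "+", fixed = TRUE)[[1]]),
      n_topologies = dplyr::n(),
      gcf = .data$gcf[1],
      per_topology = list(dplyr::pick("topology_id", "scf", "sn")),
      .groups = "drop") |>
    arrange(.data$size, .data$clade_split)
}

#' Classify gene trees by the arrangement they support at a focal branch
#'
#' Each decisive gene tree (one containing at least one taxon from each of
#' the four sets) is labeled by which of the three pooled arrangements its
#' restricted bipartition set contains: `arr1` is the branch's own pairing
#' `(set1+set2 | set3+set4)`, `arr2` is `(set1+set3 | set2+set4)`, `arr3` is
#' `(set1+set4 | set2+set3)`. Genes that are not decisive, or decisive but
#' containing none of the three splits (e.g. clades non-monophyletic in that
#' gene), are `uninformative`.
#'
#' @inheritParams gene_concordance
#' @return Tibble with `gene` (index or name) and `label` (factor with
#'   levels `arr1`, `arr2`, `arr3`, `uninformative`).
#' @export
classify_gene_support <- function(quad, gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  cache <- .gene_tree_cache(gene_trees)
  s <- quad$sets
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  nm <- names(gene_trees)
  if (is.null(nm)) nm <- as.character(seq_along(gene_trees))
  labels <- vapply(cache, function(g) {
    if (!all(vapply(s, function(set) any(set %in% g$taxa), logical(1)))) {
      return("uninformative")
    }
    for (a in 1:3) {
      side <- intersect(c(s[[pairs[[a]][1]]], s[[pairs[[a]][2]]]), g$taxa)
      if (.split_key(side, g$taxa) %in% g$keys) return(paste0("arr", a))
    }
    "uninformative"
  }, character(1))
  tibble(gene = nm,
         label = factor(labels, levels = c("arr1", "arr2", "arr3",
                                           "uninformative")))
}

#' Gene covariates by supported arrangement
#'
#' Compares per-gene covariates (alignment length and conservation score)
#' between classes of genes labeled by [classify_gene_support()]. Reports
#' per-class medians and interquartile ranges, and pairwise Wilcoxon
#' rank-sum tests with Benjamini-Hochberg correction. Classes with fewer
#' than 2 genes get descriptive statistics only, with a warning.
#'
#' @param labels Factor (or character) of per-gene class labels.
#' @param gene_lengths Numeric vector of per-gene alignment lengths.
#' @param conservation_scores Numeric vector of per-gene [conservation_score()]
#'   values in `[0, 1]`.
#' @return Object of class `covariate_summary`: list with `stats` (per class
#'   and covariate: n, median, IQR) and `tests` (pairwise rank-sum tests,
#'   columns `covariate`, `class_a`, `class_b`, `p`, `p_adj`).
#' @export
covariate_summary <- function(labels, gene_lengths, conservation_scores) {
  labels <- as.factor(labels)
  df <- tibble(label = labels, length = gene_lengths,
               conservation = conservation_scores)
  long <- tidyr::pivot_longer(df, c("length", "conservation"),
                              names_to = "covariate", values_to = "value")
  stats <- long |>
    group_by(.data$covariate, .data$label) |>
    summarise(n = sum(!is.na(.data$value)),
              median = median(.data$value, na.rm = TRUE),
              iqr = IQR(.data$value, na.rm = TRUE), .groups = "drop")
  testable <- stats |>
    group_by(.data$covariate) |>
    filter(.data$n >= 2) |>
    ungroup()
  small <- setdiff(levels(labels), unique(testable$label))
  if (length(small) > 0) {
    warning("class(es) with < 2 genes excluded from tests: ",
            paste(small, collapse = ", "))
  }
  tests <- list()
  for (cv in unique(long$covariate)) {
    cls <- as.character(testable$label[testable$covariate == cv])
    if (length(cls) >= 2) {
      for (pair in utils::combn(sort(cls), 2, simplify = FALSE)) {
        a <- df[[if (cv == "length") "length" else "conservation"]][labels == pair[1]]
        b <- df[[if (cv == "length") "length" else "conservation"]][labels == pair[2]]
        p <- if (length(unique(c(a, b))) == 1) {
          1 # identical constant samples carry no evidence
        } else {
          tryCatch(wilcox.test(a, b, exact = FALSE)$p.value,
                   error = function(e) NA_real_)
        }
        tests[[length(tests) + 1L]] <- tibble(covariate = cv,
                                              class_a = pair[1],
                                              class_b = pair[2], p = p)
      }
    }
  }
  tests <- if (length(tests) > 0) bind_rows(tests) else
    tibble(covariate = character(0), class_a = character(0),
           class_b = character(0), p = numeric(0))
  tests$p_adj <- p.adjust(tests$p, method = "BH")
  structure(list(stats = stats, tests = tests), class = "covariate_summary")
}

#' @export
print.covariate_summary <- function(x, ...) {
  cat("Per-class covariate summary:\n")
  print(x$stats)
  cat("\nPairwise rank-sum tests (BH-adjusted):\n")
  print(x$tests)
  invisible(x)
}

#' Write a landscape as TSV
#'
#' @param x A `tree_landscape`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path) {
  df <- x$records
  if (!is.null(x$mds)) {
    df <- left_join(df, x$mds[, c("topology_id", "axis1", "axis2")],
                    by = "topology_id")
  }
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
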