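#' Read trees from a newick file
#'
#' Reads one or more newick trees (one per line or separated by semicolons)
#' into a list of `ape` `phylo` objects. Input is validated before parsing:
#' unbalanced parentheses are reported with the character offset at which the
#' imbalance occurs, and duplicate leaf labels within a tree are an error.
#'
#' @param path Path to a newick file, or a character scalar of newick text.
#' @return A list of `phylo` objects, in file order.
#' @seealso [write_trees()], [canonical_form()]
#' @export
read_trees <- function(path) {
  txt <- if (length(path) == 1L && !grepl(";", path) && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    paste(path, collapse = "\n")
  }
  .check_newick_balance(txt)
  trees <- ape::read.tree(text = txt)
  if (is.null(trees)) stop("no trees could be parsed from input")
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  attr(trees, "TipLabel") <- NULL
  names(trees) <- NULL
  for (i in seq_along(trees)) .validate_tree(trees[[i]], where = i)
  trees
}

# parenthesis balance scan; reports 1-based character offset of the defect
.check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed newick: unmatched ')' at character offset %d", i))
      }
    }
    if (chars[i] == ";" && depth != 0L) {
      stop(sprintf("malformed newick: %d unclosed '(' at character offset %d", depth, i))
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed newick: %d unclosed '(' at end of input (offset %d)",
                 depth, length(chars)))
  }
  invisible(TRUE)
}

.validate_tree <- function(tree, where = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate leaf label%s: %s%s",
                 if (length(dup) > 1) "s" else "",
                 paste(unique(dup), collapse = ", "),
                 if (is.null(where)) "" else sprintf(" (tree %d)", where)))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length")
  }
  invisible(TRUE)
}

#' Write trees to a newick file
#'
#' Branch lengths are written with 12 significant digits so that a
#' parse/serialize round trip preserves them to better than 1e-9 relative
#' precision; trees without branch lengths are written topology-only.
#'
#' @param trees A `phylo` object or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, function(tr) ape::write.tree(tr, digits = 12),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Canonical newick string of a rooted topology
#'
#' Produces a unique topology-only newick string: at every internal node the
#' children are ordered by their lexicographically smallest descendant leaf
#' label. Two trees have equal canonical strings iff they share the same
#' rooted topology, which makes the string usable as a de-duplication key and
#' a stable topology identifier.
#'
#' @param tree A `phylo` object (branch lengths, if any, are ignored).
#' @return A single newick string ending in `";"`.
#' @export
canonical_form <- function(tree) {
  .validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(paste0(tree$tip.label, ";"))
  children <- .children_list(tree)
  rec <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      return(list(str = lab, min = lab))
    }
    parts <- lapply(children[[node]], rec)
    ord <- order(vapply(parts, `[[`, character(1), "min"))
    parts <- parts[ord]
    list(str = paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min = parts[[1]]$min)
  }
  paste0(rec(ntip + 1L)$str, ";")
}

# children of each node, indexed by node id
.children_list <- function(tree) {
  n_nodes <- max(tree$edge)
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

# descendant tip labels of every node (list indexed by node id)
.desc_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  n_nodes <- max(tr$edge)
  out <- vector("list", n_nodes)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; c <- tr$edge[i, 2]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

#' Enumerate all rooted binary leaf-labeled topologies
#'
#' Generates every distinct rooted, binary, leaf-labeled tree topology on the
#' given labels by recursive insertion of each label (in input order) on every
#' branch, including above the root; the result is de-duplicated by
#' [canonical_form()] and returned sorted by canonical string, so the order is
#' deterministic. The count is the double factorial (2k-3)!! for k labels:
#' 1, 3, 15, 105, 945, ... for k = 2, 3, 4, 5, 6.
#'
#' @param labels Character vector of distinct leaf labels (k >= 1).
#' @return A list of topology-only `phylo` objects in canonical order.
#' @examples
#' length(enumerate_rooted_topologies(letters[1:5]))  # 105
#' @export
enumerate_rooted_topologies <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  k <- length(labels)
  if (k < 1) stop("need at least one label")
  if (k == 1) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = labels, Nnode = 1L),
                    class = "phylo")
    return(list(tr))
  }
  # nested-list representation: a leaf is a character scalar, an internal
  # node a list of two subtrees
  insert_all <- function(t, x) {
    res <- list(list(t, x))           # attach on the branch above t
    if (is.list(t)) {
      for (i in 1:2) {
        for (sub in insert_all(t[[i]], x)) {
          t2 <- t
          t2[[i]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  trees <- list(labels[1])
  for (x in labels[-1]) {
    trees <- unlist(lapply(trees, insert_all, x = x), recursive = FALSE)
  }
  to_newick <- function(t) {
    if (!is.list(t)) return(t)
    paste0("(", to_newick(t[[1]]), ",", to_newick(t[[2]]), ")")
  }
  strs <- vapply(trees, function(t) paste0(to_newick(t), ";"), character(1))
  canon <- vapply(strs, function(s) canonical_form(ape::read.tree(text = s)),
                  character(1), USE.NAMES = FALSE)
  canon <- sort(unique(canon))
  lapply(canon, function(s) ape::read.tree(text = s))
}

#' Two-letter topology identifiers
#'
#' Deterministic identifiers `aa`, `ab`, ..., assigned in canonical
#' enumeration order; an optional seeded shuffle randomizes the assignment
#' while keeping it reproducible.
#'
#' @param n Number of identifiers.
#' @param shuffle_seed Optional integer; if given, the identifier/topology
#'   pairing is shuffled reproducibly.
#' @return Character vector of length `n`.
#' @export
topology_ids <- function(n, shuffle_seed = NULL) {
  if (n > 676) stop("at most 676 two-letter identifiers available")
  ids <- as.vector(t(outer(letters, letters, paste0)))[seq_len(n)]
  if (!is.null(shuffle_seed)) ids <- with_seed_if(shuffle_seed, sample(ids))
  ids
}

# canonical key of a bipartition: the side not containing the reference
# (alphabetically smallest) taxon, sorted and pasted
.split_key <- function(side, all_taxa) {
  ref <- min(all_taxa)
  if (ref %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = .KEY_SEP)
}

# character vector of keys for all nontrivial splits of a tree
.split_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  all_taxa <- tree$tip.label
  desc <- .desc_tips(tree)
  root <- ntip + 1L
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  keys <- character(0)
  for (node in internal_children) {
    side <- desc[[node]]
    if (length(side) >= 2 && length(side) <= ntip - 2) {
      keys <- c(keys, .split_key(side, all_taxa))
    }
  }
  unique(keys)
}

#' Nontrivial bipartitions of a tree
#'
#' One bipartition per internal branch of the unrooted version of the tree;
#' a bipartition is nontrivial iff both sides contain at least two taxa. An
#' unrooted binary tree on n leaves has exactly n - 3 of them.
#'
#' @param tree A `phylo` object with >= 1 leaves. Trees with fewer than 4
#'   leaves yield an empty result.
#' @return A tibble with list-columns `side_a` and `side_b` (character
#'   vectors of taxa; `side_a` holds the alphabetically smallest taxon) and a
#'   string `key` identifying the bipartition.
#' @export
bipartition_set <- function(tree) {
  .validate_tree(tree)
  keys <- .split_keys(tree)
  all_taxa <- tree$tip.label
  if (length(keys) == 0) {
    return(tibble(side_a = list(), side_b = list(), key = character(0)))
  }
  side_b <- lapply(keys, function(k) strsplit(k, .KEY_SEP, fixed = TRUE)[[1]])
  side_a <- lapply(side_b, function(s) sort(setdiff(all_taxa, s)))
  tibble(side_a = side_a, side_b = side_b, key = keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference between the trees' nontrivial
#' bipartition sets. Zero iff the unrooted topologies are identical; at most
#' 2(n-3) for two binary unrooted trees on n leaves.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @return A nonnegative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    off <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ; offending taxa: ", paste(off, collapse = ", "))
  }
  k1 <- .split_keys(t1); k2 <- .split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Pairwise Robinson-Foulds distance matrix
#'
#' @param trees List of `phylo` objects on a common leaf set.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
rf_matrix <- function(trees) {
  n <- length(trees)
  keys <- lapply(trees, .split_keys)
  m <- matrix(0L, n, n)
  if (n < 2) return(m)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- length(setdiff(keys[[i]], keys[[j]])) +
        length(setdiff(keys[[j]], keys[[i]]))
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}
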