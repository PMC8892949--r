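# small shared fixture for landscape tests: 4 ingroup clades keeps the
# enumeration at 15 arrangements
make_small_bundle <- function() {
  make_fixture(list(
    clade_sizes = c(cA = 3L, cB = 2L, cC = 2L, cD = 2L),
    outgroup_size = 2L, n_genes = 30L, sites_per_gene = 120L), seed = 77)
}

test_that("a planted signal makes the true topology the unique optimum", {
  cm <- clade_map(tibble::tibble(
    taxon = c("a1", "a2", "b1", "b2", "c1", "d1", "o1"),
    clade = c("A", "A", "B", "B", "C", "D", "OUT")), outgroup = "OUT")
  truth <- ape::read.tree(text = "((((a1,a2),(b1,b2)),(c1,d1)),o1);")
  gts <- replicate(25, truth, simplify = FALSE)
  ls <- scan_landscape(gts, NULL, cm, seed = 3)
  expect_equal(nrow(ls$records), 15)
  expect_equal(nrow(ls$branches), 15 * 2) # k - 2 scanned branches
  best <- ls$records[which.max(ls$records$mean_gcf), ]
  expect_equal(best$mean_gcf, 100)
  expect_identical(sum(ls$records$mean_gcf == 100), 1L)
  expect_identical(best$newick, "(((A,B),(C,D)),OUT);")
})

test_that("scanned branch gCF equals independent recomputation", {
  bdl <- make_small_bundle()
  ls <- scan_landscape(bdl$gene_trees, bdl$alignment, bdl$clade_map,
                       n_quartets = 20, seed = 11)
  cm <- bdl$clade_map
  # recompute a handful of branch gCFs straight from the definitions
  set.seed(1)
  rows <- ls$branches[sample(nrow(ls$branches), 6), ]
  for (i in seq_len(nrow(rows))) {
    skel <- ls$skeletons[[match(rows$topology_id[i],
                                ls$records$topology_id)]]
    quads <- quadripartitions(skel)
    clades <- strsplit(rows$clade_split[i], "+", fixed = TRUE)[[1]]
    hit <- FALSE
    for (q in quads) {
      sideb <- setdiff(strsplit(q$key, "\x1f", fixed = TRUE)[[1]], "outgroup")
      sidea <- setdiff(q$taxa, c(sideb, "outgroup"))
      side <- if ("outgroup" %in% strsplit(q$key, "\x1f", fixed = TRUE)[[1]])
        sidea else sideb
      if (setequal(side, clades)) {
        pooled_sets <- lapply(q$sets, function(s)
          unlist(lapply(s, clade_taxa, x = cm)))
        oracle <- oracle_gcf(pooled_sets, bdl$gene_trees)
        expect_equal(rows$gcf[i], oracle$gcf)
        expect_identical(rows$gn[i], oracle$gn)
        hit <- TRUE
      }
    }
    expect_true(hit)
  }
  # per-record means equal recomputation from the branch table
  means <- tapply(ls$branches$gcf, ls$branches$topology_id, mean)
  expect_equal(as.numeric(means[ls$records$topology_id]),
               ls$records$mean_gcf)
})

test_that("bipartition summaries count clades and keep gCF constant", {
  bdl <- make_small_bundle()
  ls <- scan_landscape(bdl$gene_trees, NULL, bdl$clade_map, seed = 2)
  bs <- bipartition_summary(ls)
  # 4 ingroup clades: C(4,2) + C(4,3) = 10 distinct rooted ingroup clades
  expect_equal(nrow(bs), 10)
  expect_equal(as.integer(table(bs$size)), c(6L, 4L))
  # every size-2 clade appears in 3 of the 15 rooted arrangements
  expect_true(all(bs$n_topologies[bs$size == 2] == 3))
  expect_equal(sum(bs$n_topologies), nrow(ls$branches))
  # complete gene trees: gCF is a function of the bipartition only
  agg <- tapply(ls$branches$gcf, ls$branches$clade_split,
                function(v) length(unique(v)))
  expect_true(all(agg == 1))
})

test_that("treespace embedding respects the RF geometry", {
  bdl <- make_small_bundle()
  ls <- scan_landscape(bdl$gene_trees, NULL, bdl$clade_map, seed = 2)
  emb <- ls$mds
  expect_equal(nrow(emb), 15)
  expect_true(all(attr(emb, "eigenvalues") >= 0))
  d_emb <- as.matrix(stats::dist(cbind(emb$axis1, emb$axis2)))
  # embedding distance increases with RF distance
  expect_gt(cor(as.numeric(as.dist(ls$rf)), as.numeric(as.dist(d_emb)),
                method = "spearman"), 0)
  # identical RF rows (co-located topologies) map to identical coordinates
  same <- which(as.matrix(ls$rf) == 0, arr.ind = TRUE)
  same <- same[same[, 1] < same[, 2], , drop = FALSE]
  if (nrow(same) > 0) {
    i <- same[1, 1]; j <- same[1, 2]
    expect_equal(c(emb$axis1[i], emb$axis2[i]),
                 c(emb$axis1[j], emb$axis2[j]), tolerance = 1e-8)
  }
  # record order cannot change the embedded geometry's spectrum (the 2-D
  # axes themselves are arbitrary within degenerate eigenspaces)
  perm <- withr::with_seed(4, sample(15))
  emb2 <- embed_treespace(ls$rf[perm, perm],
                          records = ls$records[perm, ])
  expect_equal(sort(attr(emb2, "eigenvalues"), decreasing = TRUE),
               sort(attr(emb, "eigenvalues"), decreasing = TRUE),
               tolerance = 1e-8)
  # deterministic for a fixed input
  emb3 <- embed_treespace(ls)
  expect_identical(emb3$axis1, emb$axis1)
  expect_error(embed_treespace(ls$rf[1:2, 1:2]), "at least 3")
})

test_that("gene support labels are exhaustive and match gCF tallies", {
  bdl <- make_small_bundle()
  cm <- bdl$clade_map
  skel <- ape::read.tree(text = "(((cA,cB),(cC,cD)),outgroup);")
  q_cl <- quadripartitions(skel)[[1]]
  pooled <- new_quadripartition(
    unlist(lapply(q_cl$sets[[1]], clade_taxa, x = cm)),
    unlist(lapply(q_cl$sets[[2]], clade_taxa, x = cm)),
    unlist(lapply(q_cl$sets[[3]], clade_taxa, x = cm)),
    unlist(lapply(q_cl$sets[[4]], clade_taxa, x = cm)))
  labs <- classify_gene_support(pooled, bdl$gene_trees)
  expect_equal(nrow(labs), length(bdl$gene_trees))
  counts <- table(labs$label)
  expect_equal(sum(counts), length(bdl$gene_trees))
  g <- gene_concordance(pooled, bdl$gene_trees)
  expect_identical(as.integer(counts[["arr1"]]), g$gcf_n)
  # a gene missing an entire clade is uninformative
  dropped <- lapply(bdl$gene_trees[1:3], function(g2)
    ape::drop.tip(g2, clade_taxa(cm, "cB")))
  labs2 <- classify_gene_support(pooled, dropped)
  expect_true(all(labs2$label == "uninformative"))
})

test_that("covariate summaries detect planted differences and not nulls", {
  # identical values in all classes: medians equal, adjusted p ~ 1
  labels <- rep(c("arr1", "arr2", "arr3"), each = 30)
  len0 <- rep(300, 90); cons0 <- rep(0.8, 90)
  cs0 <- covariate_summary(labels, len0, cons0)
  expect_true(all(cs0$stats$median[cs0$stats$covariate == "length"] == 300))
  expect_true(all(cs0$tests$p_adj > 0.9))
  # planted length difference is detected
  set.seed(8)
  labels1 <- rep(c("arr1", "arr2"), each = 200)
  len1 <- c(rnorm(200, 300, 30), rnorm(200, 360, 30))
  cons1 <- runif(400, 0.7, 0.9)
  cs1 <- covariate_summary(labels1, len1, cons1)
  p_len <- cs1$tests$p_adj[cs1$tests$covariate == "length"]
  expect_lt(p_len, 0.05)
  p_cons <- cs1$tests$p_adj[cs1$tests$covariate == "conservation"]
  expect_gt(p_cons, 0.05)
  # tiny class: descriptive only, with warning
  expect_warning(cs2 <- covariate_summary(c("a", "b", "b"), c(1, 2, 3),
                                          c(.1, .2, .3)),
                 "excluded from tests")
  expect_equal(nrow(cs2$tests), 0)
})

test_that("conservation scores behave like mean pairwise identity", {
  aln <- rbind(a = c("A", "A", "A"), b = c("A", "C", "A"),
               c = c("A", "C", "-"))
  # col1: all same -> 1; col2: pairs AC,AC,CC -> 1/3; col3: A,A -> 1
  expect_equal(conservation_score(aln), mean(c(1, 1 / 3, 1)))
  expect_equal(conservation_score(rbind(a = "G", b = "G")), 1)
  expect_true(is.na(conservation_score(rbind(a = "-", b = "-"))))
})
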