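test_that("transition probabilities follow the JC69 closed form", {
  expect_equal(transition_probability(jc69(), 0), diag(4),
               ignore_attr = TRUE)
  P_far <- transition_probability(jc69(), 50)
  expect_equal(as.numeric(P_far), rep(0.25, 16), tolerance = 1e-8)
  P <- transition_probability(jc69(), 0.1)
  expect_equal(P[1, 1], 1 / 4 + 3 / 4 * exp(-0.4 / 3))
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_error(transition_probability(jc69(), -0.1), "nonnegative")
  # GTR rows are stochastic and satisfy detailed balance
  m <- gtr(rates = c(1, 2, 1, 1, 3, 1), freqs = c(.3, .2, .2, .3))
  Pg <- transition_probability(m, 0.2)
  expect_equal(rowSums(Pg), rep(1, 4), ignore_attr = TRUE)
  B <- diag(m$freqs) %*% Pg
  expect_equal(B, t(B), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pruning equals the exhaustive ancestral-state sum", {
  for (seed in 1:6) {
    ntip <- sample(3:4, 1)
    tr <- random_tree(ntip, seed)
    aln <- simulate_sequences(tr, 25, seed = seed + 50)
    expect_equal(pruning_loglik(tr, aln), oracle_jc_loglik(tr, aln),
                 tolerance = 1e-8)
  }
})

test_that("two-taxon and missing-data contracts hold", {
  tr <- ape::read.tree(text = "(a:0.07,b:0.05);")
  aln <- rbind(a = "A", b = "A")
  expect_equal(pruning_loglik(tr, aln),
               log(1 / 4 * (1 / 4 + 3 / 4 * exp(-4 * 0.12 / 3))))
  # an all-N column contributes exactly nothing
  tr4 <- random_tree(4, 3)
  aln4 <- simulate_sequences(tr4, 30, seed = 4)
  alnN <- cbind(aln4, matrix("N", 4, 5))
  expect_equal(pruning_loglik(tr4, alnN), pruning_loglik(tr4, aln4))
  # missing branch lengths are an error
  tr_nolen <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(pruning_loglik(tr_nolen, aln4), "branch length")
})

test_that("compiled JC path, generic R path, and phangorn agree", {
  for (seed in 1:3) {
    tr <- random_tree(6, seed)
    aln <- simulate_sequences(tr, 120, seed = seed + 9)
    ll <- pruning_loglik(tr, aln)
    cp <- cladescape:::.compress_patterns(tr, aln)
    po <- cladescape:::.postorder_edges(tr)
    expect_equal(cladescape:::.pruning_loglik_r(po, 6, cp, jc69()), ll,
                 tolerance = 1e-10)
    expect_equal(ll, phangorn::pml(tr, phangorn::phyDat(aln),
                                   model = "JC")$logLik,
                 tolerance = 1e-6)
  }
})

test_that("branch-length optimization ascends and recovers truth", {
  tr <- ape::read.tree(
    text = "((a:0.15,b:0.22):0.12,(c:0.18,d:0.3):0.09);")
  aln <- simulate_sequences(tr, 4000, seed = 21)
  ll_init <- {
    t0 <- tr; t0$edge.length <- rep(0.1, nrow(tr$edge))
    pruning_loglik(t0, aln)
  }
  fit <- optimize_branch_lengths(tr, aln)
  expect_true(fit$converged)
  expect_gte(fit$loglik, ll_init)
  key <- paste(tr$edge[, 1], tr$edge[, 2])
  keyf <- paste(fit$tree$edge[, 1], fit$tree$edge[, 2])
  rel <- abs(fit$tree$edge.length[match(key, keyf)] - tr$edge.length) /
    tr$edge.length
  expect_true(all(rel < 0.2))
  # zero-variation alignment drives lengths to the lower bound
  aln0 <- matrix("A", 4, 50, dimnames = list(c("a", "b", "c", "d"), NULL))
  fit0 <- optimize_branch_lengths(tr, aln0)
  expect_true(all(fit0$tree$edge.length < 1e-6))
})

test_that("quartet mapping scores all three arrangements and applies the region rule", {
  # degenerate weights
  expect_identical(cladescape:::.lmap_region(c(1, 0, 0)), "corner1")
  expect_identical(cladescape:::.lmap_region(c(1, 1, 1) / 3), "center")
  expect_identical(cladescape:::.lmap_region(c(0.45, 0.45, 0.10)), "side12")
  expect_identical(cladescape:::.lmap_region(c(0.1, 0.44, 0.46)), "side23")
  # a real quartet: strong internal branch lands in its corner
  qt <- ape::read.tree(text = "((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4);")
  aln <- simulate_sequences(qt, 500, seed = 13)
  pt <- quartet_map_point(aln)
  expect_length(pt$p, 3)
  expect_length(pt$lnl, 3)
  expect_equal(sum(pt$p), 1)
  expect_identical(pt$region, "corner1")
  expect_identical(pt$basin, 1L)
  expect_error(quartet_map_point(aln[1:3, ]), "4 taxa")
})

test_that("lmap censuses conserve counts and track signal", {
  qt <- ape::read.tree(text = "((a:0.05,b:0.05):0.5,(c:0.05,d:0.05):0.5);")
  set.seed(2)
  alns <- lapply(1:5, function(i) simulate_sequences(qt, 300, seed = i))
  supermat <- do.call(cbind, alns)
  parts <- tibble::tibble(gene = paste0("g", 1:5),
                          start = (0:4) * 300L, end = (1:5) * 300L)
  groups <- list("a", "b", "c", "d")
  cen <- lmap_scan(supermat, parts, groups)
  expect_equal(unname(cen$totals[["total"]]),
               sum(cen$per_gene$n_quartets))
  expect_equal(sum(cen$per_gene[, c("corner1", "corner2", "corner3",
                                    "side12", "side13", "side23",
                                    "center")]),
               unname(cen$totals[["total"]]))
  expect_equal(sum(cen$totals[c("basin1", "basin2", "basin3")]),
               unname(cen$totals[["total"]]))
  # strong internal branch: every quartet in the true corner
  expect_equal(unname(cen$totals[["corner1"]]),
               unname(cen$totals[["total"]]))
  # iid noise over many genes: center is the modal region
  noise <- withr::with_seed(6, matrix(sample(c("A", "C", "G", "T"),
                                             4 * 25 * 300, TRUE), 4,
                                      25 * 300,
                                      dimnames = list(letters[1:4], NULL)))
  parts1 <- tibble::tibble(gene = paste0("g", 1:25),
                           start = (0:24) * 300L, end = (1:25) * 300L)
  cen0 <- suppressWarnings(lmap_scan(noise, parts1, groups))
  reg <- cen0$totals[c("corner1", "corner2", "corner3", "side12",
                       "side13", "side23", "center")]
  expect_identical(names(which.max(reg)), "center")
  expect_error(lmap_scan(supermat, parts, list("a", "b", "c", "zz")),
               "empty in every gene")
})

test_that("the SOWH test honors its contracts", {
  qt <- ape::read.tree(text = "((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15);")
  aln <- simulate_sequences(qt, 400, seed = 3)
  same <- ape::read.tree(text = "((a,b),(c,d));")
  expect_warning(res <- sowh_test(aln, same, same, n_reps = 5),
                 "identical")
  expect_equal(res$p_value, 1)
  expect_equal(res$delta_obs, 0)
  # strong discriminating branch: p at the attainable minimum
  alt <- ape::read.tree(text = "((a,c),(b,d));")
  strong <- ape::read.tree(text = "((a:0.05,b:0.05):0.6,(c:0.05,d:0.05):0.6);")
  aln_s <- simulate_sequences(strong, 600, seed = 5)
  res_s <- sowh_test(aln_s, same, alt, n_reps = 19, seed = 11)
  expect_equal(res_s$p_value, 1 / 20)
  expect_length(res_s$null_deltas, 19)
  expect_gt(res_s$delta_obs, max(res_s$null_deltas))
  # determinism under the seed
  res_s2 <- sowh_test(aln_s, same, alt, n_reps = 19, seed = 11)
  expect_identical(res_s$null_deltas, res_s2$null_deltas)
})

test_that("the bootstrap delta machinery calibrates under known truth", {
  # oracle parametric bootstrap: null replicates drawn under the *true*
  # generating tree rather than the fitted one; the delta statistic is then
  # exchangeable between observed and replicate data, so the p-value is
  # uniform and the rejection rate at alpha sits at its nominal level
  truth <- ape::read.tree(text = "((a:0.1,b:0.1):0.08,(c:0.1,d:0.1):0.08);")
  topo_null <- ape::read.tree(text = "((a,b),(c,d));")
  topo_best <- ape::read.tree(text = "((a,c),(b,d));")
  delta_on <- function(aln) {
    b <- optimize_branch_lengths(topo_best, aln)$loglik
    n <- optimize_branch_lengths(topo_null, aln)$loglik
    b - n
  }
  n_meta <- 60
  ps <- vapply(seq_len(n_meta), function(i) {
    aln <- simulate_sequences(truth, 300, seed = 50000 + i)
    dobs <- suppressWarnings(delta_on(aln))
    dreps <- vapply(1:20, function(r) {
      suppressWarnings(
        delta_on(simulate_sequences(truth, 300, seed = 90000 + i * 100 + r)))
    }, numeric(1))
    (1 + sum(dreps >= dobs)) / 21
  }, numeric(1))
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_meta))
})
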