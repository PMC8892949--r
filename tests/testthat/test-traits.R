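test_that("substrate classification applies the 1/4 and 2/3 rules", {
  expect_identical(classify_substrate(c(bark = 10)),
                   list(class = "specialist", category = "bark"))
  expect_identical(classify_substrate(c(bark = 5, leaf = 5))$class,
                   "generalist")
  got <- classify_substrate(c(bark = 7, leaf = 2, fungus = 1))
  expect_identical(got$class, "specialist")
  expect_identical(got$category, "bark")
  # no category above 2/3 and no pair above 1/4 each: still generalist
  expect_identical(classify_substrate(c(bark = 6, leaf = 2, sap = 2))$class,
                   "generalist")
  expect_identical(classify_substrate(c(bark = 0))$class, "unknown")
  expect_error(classify_substrate(c(bark = -1)), "negative")
  # table interface: unlisted substrates mapped to other, with warning
  df <- tibble::tibble(species = c("s1", "s1", "s2"),
                       substrate = c("bark", "weird", "leaf"),
                       count = c(9, 1, 4))
  expect_warning(calls <- classify_substrates(df), "other")
  expect_identical(calls$state[calls$species == "s1"], "bark")
  expect_identical(calls$state[calls$species == "s2"], "leaf")
})

test_that("Mk pruning equals exhaustive enumeration for 2-4 states", {
  for (k in 2:4) {
    states <- letters[seq_len(k)]
    tr <- random_tree(4, k, min_len = 0.2, max_len = 1)
    withr::with_seed(k + 5, {
      tips <- setNames(sample(states, 4, TRUE), tr$tip.label)
    })
    m_er <- mk_model(states, "ER", rates = 0.7)
    expect_equal(mk_loglik(tr, tips, m_er),
                 oracle_mk_loglik(tr, tips, m_er$Q, states),
                 tolerance = 1e-8)
    m_ard <- mk_model(states, "ARD",
                      rates = seq(0.2, 1, length.out = k * (k - 1)))
    expect_equal(mk_loglik(tr, tips, m_ard),
                 oracle_mk_loglik(tr, tips, m_ard$Q, states),
                 tolerance = 1e-8)
  }
})

test_that("Mk limits and missing-data contracts hold", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  tips <- c(a = "x", b = "x", c = "x")
  m0 <- mk_model(c("x", "y"), "ER", rates = 1e-12)
  expect_equal(mk_loglik(tr, tips, m0), log(0.5), tolerance = 1e-6)
  # a missing-state tip on a zero-length branch changes nothing
  tr2 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):0.5,d:0);")
  m <- mk_model(c("x", "y"), "ER", rates = 0.4)
  base <- mk_loglik(tr, tips, m)
  withme <- mk_loglik(tr2, c(tips, d = NA), m)
  expect_equal(withme, base, tolerance = 1e-10)
  expect_error(mk_loglik(tr, c(a = "x", b = "z", c = "x"), m),
               "not in state set")
})

test_that("Mk fitting recovers rates and respects nesting", {
  tr <- withr::with_seed(9, ape::rcoal(200))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 8
  m_true <- mk_model(c("x", "y"), "ER", rates = 0.5)
  sim <- simulate_mk_traits(tr, m_true, seed = 14)
  fit <- fit_mk(attr(sim$history, "tree"), sim$tip_states, "ER")
  expect_lt(abs(fit$rates - 0.5) / 0.5, 0.3)
  # independent oracle: ape::ace arrives at the same rate
  ace_fit <- ape::ace(factor(sim$tip_states[tr$tip.label]), tr,
                      type = "discrete", model = "ER")
  expect_equal(unname(fit$rates), unname(ace_fit$rates), tolerance = 1e-3)
  # ARD on ER data cannot fit worse
  fit_ard <- fit_mk(attr(sim$history, "tree"), sim$tip_states, "ARD")
  expect_gte(fit_ard$loglik, fit$loglik - 1e-6)
  # monomorphic tips: rate pinned at the floor, with warning
  mono <- setNames(rep("x", 200), tr$tip.label)
  expect_warning(fit0 <- fit_mk(tr, mono, "ER",
                                states = c("x", "y")),
                 "single observed state")
  expect_lt(fit0$rates, 1e-8)
})

test_that("stochastic maps satisfy the history invariants", {
  tr <- withr::with_seed(3, ape::rcoal(10))
  m <- mk_model(c("x", "y"), "ER", rates = 1.2)
  sim <- simulate_mk_traits(tr, m, seed = 21)
  maps <- stochastic_maps(tr, sim$tip_states, m, n_maps = 40, seed = 5)
  for (h in maps[c(1, 20, 40)]) {
    for (e in seq_len(nrow(tr$edge))) {
      p <- h$paths[[e]]
      # durations tile the branch exactly
      expect_equal(sum(p$duration), tr$edge.length[e], tolerance = 1e-9)
      # adjacent segments differ in state
      if (nrow(p) > 1) expect_true(all(p$state[-1] != p$state[-nrow(p)]))
      # endpoint states match the sampled node states
      expect_identical(p$state[1],
                       unname(h$node_states[tr$edge[e, 1]]))
      expect_identical(p$state[nrow(p)],
                       unname(h$node_states[tr$edge[e, 2]]))
    }
    # tip states equal the observations
    expect_identical(unname(h$node_states[seq_len(10)]),
                     unname(sim$tip_states[tr$tip.label]))
  }
  # determinism under the seed
  maps2 <- stochastic_maps(tr, sim$tip_states, m, n_maps = 40, seed = 5)
  expect_identical(maps[[7]], maps2[[7]])
  # near-zero rates on monomorphic tips give zero transitions
  m0 <- mk_model(c("x", "y"), "ER", rates = 1e-10)
  maps0 <- stochastic_maps(tr, setNames(rep("x", 10), tr$tip.label), m0,
                           n_maps = 10, seed = 1)
  ts0 <- count_transitions(maps0, generalist_state = NA)
  expect_equal(ts0$mean_total, 0)
})

test_that("node posteriors match brute-force conditionals on 4 tips", {
  t4 <- ape::read.tree(text = "((a:0.4,b:0.4):0.5,(c:0.6,d:0.6):0.3);")
  states <- c("x", "y")
  tips <- c(a = "x", b = "y", c = "x", d = "x")
  m <- mk_model(states, "ER", rates = 0.9)
  oracle <- oracle_mk_node_posterior(t4, tips, m$Q, states)
  maps <- stochastic_maps(t4, tips, m, n_maps = 8000, seed = 31)
  sm <- summarize_posterior(maps)
  post <- tidy(sm)
  for (node in 5:7) {
    for (s in states) {
      got <- post$prob[post$node == node & post$state == s]
      # Monte-Carlo tolerance: 4 binomial SEs at n = 8000
      p <- oracle[as.character(node), s]
      expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / 8000) + 1e-6)
    }
  }
  # posteriors sum to one at every node
  sums <- as.numeric(tapply(post$prob, post$node, sum))
  expect_equal(sums, rep(1, length(sums)))
  # unanimous maps give degenerate posteriors
  m0 <- mk_model(states, "ER", rates = 1e-10)
  maps0 <- stochastic_maps(t4, c(a = "x", b = "x", c = "x", d = "x"), m0,
                           n_maps = 25, seed = 2)
  sm0 <- summarize_posterior(maps0)
  expect_true(all(tidy(sm0)$prob %in% c(0, 1)))
  expect_length(sm0$transition_edges, 0)
})

test_that("transition censuses attribute changes to the right branches", {
  # hand-built history on a 3-tip tree: 3 changes, 2 on terminal branches
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  h <- list(node_states = setNames(c("x", "y", "x", "x", "x"),
                                   as.character(1:5)),
            paths = list())
  # edge order in tr$edge: (4,5),(5,1),(5,2),(4,3)
  h$paths <- list(
    data.frame(state = "x", duration = 1),                      # 4 -> 5
    data.frame(state = c("x"), duration = 1),                   # 5 -> a
    data.frame(state = c("x", "y"), duration = c(0.6, 0.4)),    # 5 -> b
    data.frame(state = c("x", "y", "x"), duration = c(1, 0.5, 0.5)) # 4 -> c
  )
  hl <- structure(list(h), class = "char_history_list", tree = tr,
                  model = mk_model(c("x", "y"), "ER", rates = 1))
  ts <- count_transitions(hl, generalist_state = NA)
  expect_equal(ts$mean_total, 3)
  expect_equal(ts$mean_terminal, 3)
  expect_equal(ts$mean_internal, 0)
  expect_equal(ts$pair_matrix["x", "y"], 2)
  expect_equal(ts$pair_matrix["y", "x"], 1)
  # generalist fraction counts source-or-target involvement
  hg <- hl
  attr(hg, "model") <- mk_model(c("x", "generalist"), "ER", rates = 1)
  hg[[1]]$paths[[3]]$state <- c("x", "generalist")
  hg[[1]]$paths[[4]]$state <- c("x", "generalist", "x")
  tsg <- count_transitions(hg)
  expect_equal(tsg$generalist_fraction, 1)
})

test_that("mean transitions over maps track the generating process", {
  tr <- withr::with_seed(12, ape::rcoal(60))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 3
  m <- mk_model(c("x", "y", "z"), "ER", rates = 0.4)
  sim <- simulate_mk_traits(tr, m, seed = 77)
  truth <- count_transitions(sim$history, generalist_state = NA)
  expect_equal(truth$mean_total, sim$n_transitions)
  maps <- stochastic_maps(attr(sim$history, "tree"), sim$tip_states, m,
                          n_maps = 300, seed = 8)
  ts <- count_transitions(maps, generalist_state = NA)
  spread <- stats::sd(ts$per_map$total)
  expect_lt(abs(ts$mean_total - sim$n_transitions), 3 * spread)
})
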