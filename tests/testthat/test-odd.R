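test_that("compile_tree handles constants, single literals, and matches a truth-table oracle", {
  part <- partition(list(c(0), c(-1, 1)))
  mgr <- odd_manager(part)
  # leaf-only positive tree
  one <- compile_tree(list(leaf = "positive"), part, manager = mgr)
  expect_equal(model_count(one), prod(part$n_intervals))
  # stump: true iff feature 1 interval index >= 2 (the [0, Inf) side)
  stump <- list(feature = 1L, threshold = 0,
                low = list(leaf = "negative"), high = list(leaf = "positive"))
  odd <- compile_tree(stump, part, manager = mgr)
  for (j1 in 1:2) for (j2 in 1:3)
    expect_equal(odd_evaluate(odd, c(j1, j2)),
                 if (j1 >= 2) "positive" else "negative")
  # random depth-3 trees vs exhaustive evaluation of the tree itself
  set.seed(81)
  for (rep in 1:10) {
    pools <- lapply(1:3, function(i) sort(runif(2, -2, 2)))
    tree <- random_tree_node(pools, 3L)
    f1 <- forest(list(tree), toy_features(3), 3)
    p <- extract_partition(f1)
    got <- compile_tree(tree, p)
    cells <- all_cells(p)
    for (r in seq_len(nrow(cells)))
      expect_equal(odd_evaluate(got, cells[r, ]),
                   predict_tree(tree, cell_representative(p, cells[r, ])))
  }
  expect_error(compile_tree(stump, partition(list(c(5), c(-1, 1)))),
               "absent from the partition")
})

test_that("apply computes pointwise Boolean combinations and canonical identities", {
  set.seed(91)
  part <- partition(list(sort(runif(2)), sort(runif(3)), numeric(0)))
  mgr <- odd_manager(part)
  pools <- lapply(part$thresholds, identity)
  rand_odd <- function() {
    tr <- random_tree_node(lapply(pools, function(v) if (length(v)) v else 0.5), 3L)
    # trees may reference threshold 0.5 on feature 3 which is absent; retry
    tryCatch(compile_tree(tr, part, manager = mgr),
             error = function(e) rand_odd())
  }
  f <- rand_odd(); g <- rand_odd()
  expect_equal(odd_and(f, odd_not(f))$root, odd_constant(mgr, FALSE)$root)
  expect_equal(odd_or(f, odd_constant(mgr, FALSE))$root, f$root)  # identity element
  expect_equal(odd_or(f, odd_not(f))$root, odd_constant(mgr, TRUE)$root)
  cells <- all_cells(part)
  for (op in c("and", "or", "xor")) {
    h <- odd_apply(op, f, g)
    for (r in seq_len(nrow(cells))) {
      a <- odd_evaluate(f, cells[r, ]) == "positive"
      b <- odd_evaluate(g, cells[r, ]) == "positive"
      want <- switch(op, and = a && b, or = a || b, xor = xor(a, b))
      expect_equal(odd_evaluate(h, cells[r, ]) == "positive", want)
    }
  }
  # mismatched orders are a usage error
  mgr2 <- odd_manager(part, order = c(3, 2, 1))
  f2 <- compile_tree(list(feature = 1L, threshold = part$thresholds[[1]][1],
                          low = list(leaf = "negative"),
                          high = list(leaf = "positive")), part, manager = mgr2)
  expect_error(odd_and(f, f2), "mismatched")
})

test_that("compiled forests equal the majority vote on every cell, exhaustively", {
  set.seed(101)
  for (rep in 1:8) {
    f <- random_forest_fixture()
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    ref <- label_array(f, part)
    got <- array(odd_cell_values(odd), dim = part$n_intervals)
    expect_identical(got, ref)
  }
  # 1-tree forest compiles to the tree's own diagram
  set.seed(102)
  f1 <- random_forest_fixture(n_trees = 1)
  part <- extract_partition(f1)
  mgr <- odd_manager(part)
  expect_equal(compile_forest(f1, part)$root,
               compile_tree(f1$trees[[1]], part, manager = mgr)$root)
  # unanimous copies of one tree have the tree's function
  f3 <- forest(rep(f1$trees, 3), f1$features, f1$max_depth)
  expect_equal(compile_forest(f3, part)$root,
               compile_tree(f1$trees[[1]], part, manager = mgr)$root)
})

test_that("the fast vote oracle agrees with naive per-cell prediction", {
  set.seed(111)
  f <- random_forest_fixture(n_trees = 5)
  part <- extract_partition(f)
  expect_identical(label_array(f, part), label_array_slow(f, part))
})

test_that("canonicity: structurally different but equivalent forests compile to identical diagrams", {
  pos <- list(leaf = "positive"); neg <- list(leaf = "negative")
  # x1 >= 0, written as a stump and as a redundant depth-2 tree
  stump <- list(feature = 1L, threshold = 0, low = neg, high = pos)
  redundant <- list(feature = 2L, threshold = 1,
                    low = stump, high = list(feature = 1L, threshold = 0,
                                             low = neg, high = pos))
  fa <- forest(list(stump), toy_features(2), 3)
  fb <- forest(list(redundant), toy_features(2), 3)
  part <- partition(list(0, 1), toy_features(2))
  mgr <- odd_manager(part)
  a <- compile_tree(stump, part, manager = mgr)
  b <- compile_tree(redundant, part, manager = mgr)
  expect_identical(a$root, b$root)
  # reduced: no redundant nodes survive
  expect_equal(odd_size(b), 1L)
})

test_that("model counting matches enumeration and respects conservation", {
  mgr <- odd_manager(c(3L, 2L))
  expect_equal(model_count(odd_constant(mgr, TRUE)), 6)
  expect_equal(model_count(odd_constant(mgr, FALSE)), 0)
  set.seed(121)
  for (rep in 1:10) {
    f <- random_forest_fixture(n_trees = 5)
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    arr <- label_array(f, part)
    expect_equal(model_count(odd), sum(arr))
    expect_equal(model_count(odd) + model_count(odd_not(odd)),
                 prod(part$n_intervals))
    # total cell count equals the model count of the constant-true diagram
    expect_equal(model_count(odd_constant(odd$mgr, TRUE)),
                 prod(part$n_intervals))
  }
})

test_that("evaluation agrees with predicting at the cell representative", {
  set.seed(131)
  f <- random_forest_fixture()
  part <- extract_partition(f)
  odd <- compile_forest(f, part)
  for (rep in 1:200) {
    cell <- vapply(part$n_intervals, function(k) sample.int(k, 1), 0L)
    expect_equal(odd_evaluate(odd, cell),
                 predict_forest(f, cell_representative(part, cell)))
  }
})

test_that("conditioning restricts the function exactly", {
  set.seed(141)
  for (rep in 1:10) {
    f <- random_forest_fixture(n_trees = 7)
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    arr <- label_array(f, part)
    p <- length(part$n_intervals)
    # full assignment -> constant terminal equal to evaluate
    cell <- vapply(part$n_intervals, function(k) sample.int(k, 1), 0L)
    full <- odd_condition(odd, cell)
    expect_true(full$root <= 2)
    expect_equal(full$root == 2, odd_evaluate(odd, cell) == "positive")
    # empty assignment -> unchanged
    expect_equal(odd_condition(odd, rep(NA_integer_, p))$root, odd$root)
    # random partial vs enumeration over completions
    partial <- rep(NA_integer_, p)
    fix <- sample.int(p, sample(1:(p - 1), 1))
    partial[fix] <- vapply(part$n_intervals[fix], function(k) sample.int(k, 1), 0L)
    cond <- odd_condition(odd, partial)
    idx <- lapply(seq_len(p), function(i)
      if (is.na(partial[i])) seq_len(part$n_intervals[i]) else partial[i])
    sub <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    cells <- as.matrix(expand.grid(idx))
    for (r in seq_len(nrow(cells)))
      expect_equal(odd_evaluate(cond, cells[r, ]) == "positive",
                   unname(sub[r]))
  }
})
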