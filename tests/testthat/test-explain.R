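test_that("sufficiency matches enumeration over completions", {
  set.seed(151)
  for (rep in 1:10) {
    f <- random_forest_fixture(n_trees = 7)
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    arr <- label_array(f, part)
    p <- length(part$n_intervals)
    cell <- vapply(part$n_intervals, function(k) sample.int(k, 1), 0L)
    # full assignment is always sufficient for its own label
    expect_true(is_sufficient(odd, cell, odd_evaluate(odd, cell)))
    for (trial in 1:10) {
      partial <- rep(NA_integer_, p)
      fix <- sample.int(p, sample(0:p, 1))
      partial[fix] <- vapply(part$n_intervals[fix], function(k) sample.int(k, 1), 0L)
      for (lab in c("positive", "negative"))
        expect_equal(is_sufficient(odd, partial, lab),
                     oracle_sufficient(arr, partial, lab))
    }
  }
  # empty assignment on a non-constant diagram is never sufficient
  set.seed(152)
  f <- random_forest_fixture()
  odd <- compile_forest(f)
  if (odd$root > 2) {
    expect_false(is_sufficient(odd, rep(NA_integer_, 5), "positive"))
    expect_false(is_sufficient(odd, rep(NA_integer_, 5), "negative"))
  }
})

test_that("shortest compatible prime implicants match the subset-enumeration oracle", {
  set.seed(161)
  n_pairs <- 0
  for (rep in 1:20) {
    f <- random_forest_fixture()
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    arr <- label_array(f, part)
    for (trial in 1:10) {
      cell <- vapply(part$n_intervals, function(k) sample.int(k, 1), 0L)
      label <- odd_evaluate(odd, cell)
      imp <- shortest_prime_implicant(odd, cell)
      ora <- oracle_shortest(arr, cell, label)
      n_pairs <- n_pairs + 1
      expect_equal(length(imp$features), ora$size)       # minimum cardinality
      expect_equal(imp$features, ora$features)            # lexicographic tie-break
      expect_equal(imp$label, label)
      expect_true(oracle_sufficient(arr, imp$partial, label))  # sufficient
      for (d in imp$features) {                           # prime
        sub <- imp$partial; sub[d] <- NA_integer_
        expect_false(oracle_sufficient(arr, sub, label))
      }
      expect_equal(imp$intervals, cell[imp$features])     # compatible
    }
  }
  expect_gte(n_pairs, 200)
})

test_that("degenerate implicants: constant diagrams and single stumps", {
  mgr <- odd_manager(c(3L, 2L))
  const <- odd_constant(mgr, TRUE)
  imp <- shortest_prime_implicant(const, c(2L, 1L))
  expect_length(imp$features, 0)
  part <- partition(list(0, numeric(0)), toy_features(2))
  stump <- compile_tree(list(feature = 1L, threshold = 0,
                             low = list(leaf = "negative"),
                             high = list(leaf = "positive")), part)
  imp2 <- shortest_prime_implicant(stump, c(2L, 1L))
  expect_equal(imp2$features, 1L)
  expect_equal(imp2$label, "positive")
})

test_that("prime implicant enumeration returns the prime cover exactly", {
  # stump: the per-interval single-feature implicants of each label, none shorter
  part <- partition(list(c(0, 2), numeric(0)), toy_features(2))
  stump <- compile_tree(list(feature = 1L, threshold = 0,
                             low = list(leaf = "negative"),
                             high = list(leaf = "positive")), part)
  pos <- enumerate_prime_implicants(stump, "positive")
  expect_equal(lapply(pos, function(i) list(i$features, i$intervals)),
               list(list(1L, 2L), list(1L, 3L)))
  neg <- enumerate_prime_implicants(stump, "negative")
  expect_equal(lapply(neg, function(i) list(i$features, i$intervals)),
               list(list(1L, 1L)))
  # constant diagram: the single empty implicant
  mgr <- odd_manager(c(2L, 2L))
  all_imp <- enumerate_prime_implicants(odd_constant(mgr, TRUE), "positive")
  expect_length(all_imp, 1)
  expect_length(all_imp[[1]]$features, 0)
  # random diagrams: the disjunction of prime implicants reproduces the
  # positive set exactly (model-count reconstruction)
  set.seed(171)
  for (rep in 1:5) {
    f <- random_forest_fixture(n_trees = 5, p = 3)
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    imps <- enumerate_prime_implicants(odd, "positive")
    expect_false(attr(imps, "truncated"))
    cover <- odd_constant(odd$mgr, FALSE)
    for (im in imps) {
      term <- odd_constant(odd$mgr, TRUE)
      for (i in seq_along(im$features)) {
        nv <- odd$mgr$nvals[im$features[i]]
        kids <- rep(1L, nv); kids[im$intervals[i]] <- 2L
        lit <- primo:::new_odd(odd$mgr,
                               primo:::mk_node(odd$mgr, im$features[i], kids))
        term <- odd_and(term, lit)
      }
      cover <- odd_or(cover, term)
    }
    expect_identical(cover$root, odd$root)
    # truncation is flagged, never silent
    capped <- enumerate_prime_implicants(odd, "positive",
                                         cap = max(0L, length(imps) - 1L))
    expect_true(attr(capped, "truncated") || length(imps) == 0)
  }
})

test_that("widened ranges are prediction-invariant and boundary-maximal", {
  set.seed(181)
  for (rep in 1:12) {
    f <- random_forest_fixture()
    part <- extract_partition(f)
    odd <- compile_forest(f, part)
    arr <- label_array(f, part)
    cell <- vapply(part$n_intervals, function(k) sample.int(k, 1), 0L)
    imp <- shortest_prime_implicant(odd, cell)
    ex <- widen_ranges(odd, imp, cell)
    label <- ex$prediction
    sets <- lapply(seq_along(cell), function(f2)
      ex$interval_sets[[f2]] %||% seq_len(part$n_intervals[f2]))
    # monotone widening: region contains the implicant's region and the instance
    for (i in seq_along(imp$features))
      expect_true(imp$intervals[i] %in% sets[[imp$features[i]]])
    expect_true(all(mapply(function(s, c2) c2 %in% s, sets, cell)))
    # every cell of the region keeps the label
    vals <- do.call(`[`, c(list(arr), sets))
    expect_true(all(vals == (label == "positive")))
    # extending any single boundary by one interval admits a counterexample
    for (fi in imp$features) {
      s <- ex$interval_sets[[fi]]
      for (probe in c(s[1] - 1L, s[length(s)] + 1L)) {
        if (probe < 1L || probe > part$n_intervals[fi]) next
        trial <- sets; trial[[fi]] <- c(trial[[fi]], probe)
        vals2 <- do.call(`[`, c(list(arr), trial))
        expect_false(all(vals2 == (label == "positive")))
      }
    }
  }
})

test_that("explain_instance fuzzed within its displayed ranges never changes prediction", {
  set.seed(191)
  checked <- 0
  for (rep in 1:10) {
    cohort <- generate_cohort(cohort_config(n = 150, seed = rep))
    f <- train_forest(cohort, weight_loss_features(), n_trees = 7,
                      max_depth = 2, seed = rep)
    odd <- compile_forest(f)
    for (trial in 1:20) {
      x <- as.numeric(cohort[sample.int(nrow(cohort), 1), 1:5])
      ex <- explain_instance(odd, x)
      lo <- x; hi <- x
      if (nrow(ex$ranges)) {
        fidx <- ex$ranges$feature
        lo[fidx] <- pmax(ex$ranges$low, x[fidx] - 3 * f$features$z_sd[fidx])
        hi[fidx] <- pmin(ex$ranges$high - 1e-9, x[fidx] + 3 * f$features$z_sd[fidx])
      }
      # free features are perturbed arbitrarily; constrained ones inside range
      pert <- vapply(1:5, function(i) {
        if (i %in% ex$ranges$feature) runif(20, lo[i], hi[i])
        else rnorm(20, x[i], 5 * f$features$z_sd[i])
      }, numeric(20))
      expect_true(all(predict_forest(f, pert) == ex$prediction))
      expect_equal(unname(predict_forest(f, x)), ex$prediction)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 200)
})

test_that("explanations carry the structural contract for the archetypes", {
  cohort <- generate_cohort(cohort_config(n = 419, seed = 8))
  f <- train_forest(cohort, weight_loss_features(), seed = 8)
  odd <- compile_forest(f)
  a <- archetypes()
  for (arc in rownames(a$natural)) {
    x <- a$natural[arc, ]
    ex <- explain_instance(odd, x)
    expect_equal(ex$prediction, unname(predict_forest(f, x)))
    if (nrow(ex$ranges)) {
      # the instance point sits inside all displayed ranges
      fidx <- ex$ranges$feature
      expect_true(all(x[fidx] >= ex$ranges$low & x[fidx] < ex$ranges$high))
      # z and natural endpoints agree through the feature scaling
      expect_equal(ex$ranges$z_low,
                   (ex$ranges$low - f$features$z_mean[fidx]) / f$features$z_sd[fidx])
    }
    js <- jsonlite::fromJSON(explanation_json(ex))
    expect_equal(js$prediction, ex$prediction)
    expect_equal(length(js$instance$natural), 5)
  }
  # instance on a constant classifier yields zero ranges
  mgr <- odd_manager(extract_partition(f))
  const <- odd_constant(mgr, TRUE)
  ex0 <- explain_instance(const, a$natural[1, ])
  expect_equal(nrow(ex0$ranges), 0)
  expect_equal(ex0$prediction, "positive")
})
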