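test_that("productive filtering renormalizes frequencies", {
  rep <- as_repertoire(data.frame(
    cdr3_nt = c("a", "b", "c"), count = c(6, 4, 10),
    productive = c(TRUE, FALSE, TRUE)
  ))
  out <- filter_productive(rep)
  expect_equal(nrow(out), 2)
  expect_equal(sum(out$frequency), 1, tolerance = 1e-12)
  expect_equal(out$frequency[out$cdr3_nt == "a"], 6 / 16)

  all_prod <- make_rep(c(3, 7))
  expect_equal(filter_productive(all_prod), all_prod)
  none <- make_rep(c(3, 7), productive = FALSE)
  expect_error(filter_productive(none), class = "tilmonitor_empty_repertoire")
})

test_that("clonality matches hand entropy values and limits", {
  expect_equal(clonality(make_rep(5)), 1)           # monoclonal
  expect_equal(clonality(make_rep(rep(4, 10))), 0)  # uniform, maximal entropy
  # counts {8,2}: H = -(0.8 ln 0.8 + 0.2 ln 0.2), C = 1 - H/ln 2
  expect_equal(clonality(make_rep(c(8, 2))), 0.2780719, tolerance = 1e-6)
  expect_error(clonality(make_rep(c(1), productive = FALSE)),
               class = "tilmonitor_empty_repertoire")
})

test_that("clonality is relabeling-invariant and rises with concentration", {
  set.seed(41)
  for (i in 1:20) {
    counts <- sample.int(60, 12, replace = TRUE)
    c1 <- clonality(make_rep(counts))
    c2 <- clonality(make_rep(counts, ids = sprintf("zz%03d", rev(seq_along(counts)))))
    expect_equal(c1, c2, tolerance = 1e-12)
    # move a template from a rarer to the most common clone
    shifted <- counts
    i_max <- which.max(counts)
    i_min <- which.min(counts)
    if (counts[i_min] > 1 && i_max != i_min) {
      shifted[i_max] <- shifted[i_max] + 1
      shifted[i_min] <- shifted[i_min] - 1
      expect_gt(clonality(make_rep(shifted)), c1)
    }
  }
})

test_that("Morisita-Horn matches the hand case, bounds, and symmetry", {
  a <- make_rep(c(3, 1), ids = c("A", "B"))
  b <- make_rep(c(1, 3), ids = c("A", "B"))
  expect_equal(morisita_horn(a, b), 0.6, tolerance = 1e-12)
  expect_equal(morisita_horn(a, a), 1, tolerance = 1e-12)
  disjoint <- make_rep(c(5, 5), ids = c("X", "Y"))
  expect_equal(morisita_horn(a, disjoint), 0)
  # symmetry and scale invariance
  expect_equal(morisita_horn(a, b), morisita_horn(b, a), tolerance = 1e-15)
  a10 <- make_rep(c(30, 10), ids = c("A", "B"))
  expect_equal(morisita_horn(a10, b), morisita_horn(a, b), tolerance = 1e-12)
})

test_that("clonality and MH agree with naive oracles on random repertoires", {
  set.seed(7)
  for (i in 1:25) {
    r1 <- random_repertoire(sample(5:40, 1))
    expect_equal(clonality(r1), naive_clonality(r1$count), tolerance = 1e-12)
    shared <- sprintf("s%02d", 1:15)
    ca <- setNames(sample.int(50, 20, replace = TRUE),
                   c(shared, sprintf("a%02d", 1:5)))
    cb <- setNames(sample.int(50, 18, replace = TRUE),
                   c(shared[1:10], sprintf("b%02d", 1:8)))
    ra <- make_rep(unname(ca), ids = names(ca))
    rb <- make_rep(unname(cb), ids = names(cb))
    expect_equal(morisita_horn(ra, rb), naive_morisita_horn(ca, cb),
                 tolerance = 1e-12)
  }
})

test_that("Morisita-Horn agrees with vegan's Horn-Morisita dissimilarity", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:5) {
    keys <- sprintf("k%02d", 1:12)
    ca <- sample.int(40, 12, replace = TRUE)
    cb <- sample.int(40, 12, replace = TRUE)
    mh <- morisita_horn(make_rep(ca, ids = keys), make_rep(cb, ids = keys))
    d <- as.numeric(vegan::vegdist(rbind(ca, cb), method = "horn"))
    expect_equal(mh, 1 - d, tolerance = 1e-10)
  }
})

test_that("top_n_clones sorts, ties deterministic, cumulative frequency right", {
  rep <- make_rep(c(8, 2), ids = c("x", "y"))
  top1 <- top_n_clones(rep, 1)
  expect_equal(top1$cdr3_nt, "x")
  expect_equal(cumulative_frequency(top1), 0.8)
  expect_equal(cumulative_frequency(top_n_clones(rep, 2)), 1)
  # n beyond richness returns everything without error
  expect_equal(nrow(top_n_clones(rep, 10)), 2)
  # ties broken lexicographically on cdr3_nt
  tie <- make_rep(c(5, 5, 1), ids = c("bb", "aa", "cc"))
  expect_equal(top_n_clones(tie, 2)$cdr3_nt, c("aa", "bb"))
  # matches independent sort on a power-law fixture
  reps <- gen_repertoires(repertoire_config(n_clones = 300, depth = 2e4, seed = 7))
  dp <- filter_productive(reps$DP)
  top30 <- top_n_clones(dp, 30)
  oracle <- dp[order(-dp$count, dp$cdr3_nt), ][1:30, ]
  expect_equal(top30$cdr3_nt, oracle$cdr3_nt)
  expect_equal(cumulative_frequency(top30), sum(oracle$frequency),
               tolerance = 1e-12)
})

test_that("track_clones counts shared clones against comparators", {
  ref <- make_rep(c(10, 5, 2), ids = c("r1", "r2", "r3"))
  identical_cmp <- ref
  disjoint <- make_rep(c(4, 4), ids = c("q1", "q2"))
  planted <- make_rep(c(6, 1, 3), ids = c("r1", "r3", "q9")) # 2 of 3 shared
  out <- track_clones(ref, list(same = identical_cmp, none = disjoint,
                                partial = planted), n = 3)
  shared <- setNames(out$shared$shared_clones, out$shared$comparator)
  expect_equal(shared[["same"]], 3)
  expect_equal(shared[["none"]], 0)
  expect_equal(shared[["partial"]], 2)
  traj <- out$trajectory
  expect_equal(traj$frequency[traj$comparator == "partial" & traj$cdr3_nt == "r1"],
               0.6)
  expect_equal(traj$frequency[traj$comparator == "none"], rep(0, 3))
})

test_that("reactive-clone calls use a strict frequency cutoff", {
  uniform <- make_rep(rep(1, 100))
  expect_equal(nrow(call_reactive_clones(uniform, 0.02)), 0) # exactly 2% each
  rep4 <- make_rep(c(40, 30, 20, 10))
  expect_equal(nrow(call_reactive_clones(rep4, 0.02)), 4)
  expect_equal(nrow(call_reactive_clones(rep4, 0.35)), 1)
  expect_equal(call_reactive_clones(rep4, 0.35)$frequency, 0.4)
})
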