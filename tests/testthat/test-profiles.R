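test_that("profile enumeration matches the closed form and its invariants", {
  p51 <- enumerate_profiles(T = 5, c = 1)
  expect_equal(nrow(p51$profiles), 80)                # 3^4 - 1
  p21 <- enumerate_profiles(T = 2, c = 1)
  expect_equal(nrow(p21$profiles), 2)                 # up, down
  p32 <- enumerate_profiles(T = 3, c = 2)
  expect_equal(nrow(p32$profiles), 24)                # 5^2 - 1
  expect_true(all(p51$profiles[, 1] == 0))
  steps <- t(apply(p51$profiles, 1, diff))
  expect_true(all(abs(steps) <= 1))
  expect_false(any(rowSums(p51$profiles != 0) == 0))  # flat excluded
  expect_equal(anyDuplicated(p51$profiles), 0)
  expect_error(enumerate_profiles(T = 1), ">= 2")
})

test_that("enumeration count equals an independent recursion (T <= 6, c <= 2)", {
  for (T in 2:6) for (c in 1:2) {
    expect_equal(nrow(enumerate_profiles(T, c)$profiles),
                 count_profiles_rec(T, c),
                 info = sprintf("T=%d c=%d", T, c))
  }
})

test_that("representative selection is greedy max-min and deterministic", {
  ps <- enumerate_profiles(T = 5, c = 1)
  expect_identical(select_representatives(ps, m = 80)$profiles,
                   ps$profiles)
  expect_identical(select_representatives(ps, m = 500)$profiles,
                   ps$profiles)
  two <- select_representatives(ps, m = 2)$profiles
  # the seed pair is perfectly anti-correlated (max possible distance 2)
  expect_equal(stats::cor(two[1, ], two[2, ]), -1, tolerance = 1e-12)
  # exhaustive check that distance 2 is the global max-min pair value
  d <- 1 - stats::cor(t(ps$profiles))
  expect_equal(max(d), 2, tolerance = 1e-12)

  a <- select_representatives(ps, m = 20)
  b <- select_representatives(ps, m = 20)
  expect_identical(a$profiles, b$profiles)
  expect_error(select_representatives(ps, m = 0), ">= 1")
})

test_that("genes are assigned to their best-correlated profile with
           deterministic tie-breaks", {
  reps <- enumerate_profiles(T = 5, c = 1)
  # series exactly equal to a profile
  s <- rbind(x = reps$profiles["P042", ] + 5,
             y = -reps$profiles["P042", ] + 5,  # the mirrored profile
             flat = rep(3, 5))
  asg <- assign_genes(s, reps)
  expect_equal(asg$profile_id[asg$gene_id == "x"], "P042")
  expect_equal(asg$cor[asg$gene_id == "x"], 1, tolerance = 1e-12)
  # anti-equal series land on the negated template, which is also in
  # the family
  mirror <- asg$profile_id[asg$gene_id == "y"]
  expect_equal(unname(reps$profiles[mirror, ]),
               unname(-reps$profiles["P042", ]))
  # zero-variance series are excluded
  expect_false("flat" %in% asg$gene_id)
  # T mismatch is an error
  expect_error(assign_genes(s[, 1:4], reps), "time points")
})

test_that("noise-free planted-profile genes are all recovered", {
  d <- generate_dataset(sim_config(noise_sigma = 0, seed = 17))
  genes <- names(d$truth$planted_profiles)
  reps <- enumerate_profiles(T = 5, c = 1)  # full family: exact templates
  asg <- assign_genes(subset_genes(d$expr, genes), reps)
  expect_equal(nrow(asg), length(genes))
  for (g in genes) {
    planted <- d$truth$planted_profiles[[g]]
    got <- reps$profiles[asg$profile_id[asg$gene_id == g], ]
    expect_equal(stats::cor(got, planted), 1, tolerance = 1e-10)
  }
})

test_that("assignment partitions the eligible gene set", {
  set.seed(20)
  em <- make_expr(random_values(50, 10))
  reps <- select_representatives(enumerate_profiles(5, 1), 50)
  asg <- assign_genes(em, reps)
  expect_equal(anyDuplicated(asg$gene_id), 0)
  tc <- gene_timecourses(em)
  eligible <- rownames(tc)[apply(tc - tc[, 1], 1, stats::sd) > 0]
  expect_setequal(asg$gene_id, eligible)
})

test_that("permutation p-values are smoothed, bounded, and 1 for empty
           profiles", {
  set.seed(21)
  em <- make_expr(random_values(30, 10))
  sig <- profile_significance(em, enumerate_profiles(5, 1),
                              n_permutations = 99, seed = 2)
  expect_true(all(sig$p > 0 & sig$p <= 1))
  expect_gte(min(sig$p), 1 / 100)
  empty <- sig[sig$count == 0, ]
  if (nrow(empty) > 0) expect_true(all(empty$p == 1))
  # determinism of the permutation stream
  sig2 <- profile_significance(em, enumerate_profiles(5, 1),
                               n_permutations = 99, seed = 2)
  expect_identical(sig$p, sig2$p)
})

test_that("permutation p at T = 3 matches the exact ordering enumeration", {
  set.seed(30)
  tc <- matrix(rnorm(12 * 3, 5, 1), nrow = 12,
               dimnames = list(paste0("g", 1:12), NULL))
  reps <- enumerate_profiles(T = 3, c = 1)
  sig <- profile_significance(tc, reps, n_permutations = 1000, seed = 3)
  prob <- profile_null_exact(tc, reps)
  for (j in seq_len(nrow(reps$profiles))) {
    exact <- pois_binom_upper(prob[, j], sig$count[j])
    # Monte-Carlo error at B = 1000 plus the add-one smoothing bound
    expect_lt(abs(sig$p[j] - exact), 0.05)
    expect_lt(abs(sig$expected[j] - sum(prob[, j])), 0.35)
  }
})
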