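test_that("TOM handles the degenerate complete and empty graphs", {
  ones <- matrix(1, 3, 3); diag(ones) <- 0
  expect_equal(topological_overlap(ones),
               matrix(1, 3, 3), ignore_attr = TRUE)
  zeros <- matrix(0, 4, 4)
  tz <- topological_overlap(zeros)
  expect_equal(tz[upper.tri(tz)], rep(0, 6))
  expect_equal(unname(diag(tz)), rep(1, 4))
})

test_that("TOM rejects malformed adjacencies", {
  a <- matrix(runif(9), 3, 3)
  expect_error(topological_overlap(a), "symmetric|diagonal")
  s <- matrix(0.5, 3, 3); diag(s) <- 0; s[1, 2] <- s[2, 1] <- 1.5
  expect_error(topological_overlap(s), "\\[0, 1\\]")
})

test_that("TOM equals adjacency when the graph has no shared neighbours", {
  # single edge: no common neighbours, so TOM_12 = a_12/(min k + 1 - a)
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 0.6
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.6 / (0.6 + 1 - 0.6))
})

test_that("raising the power never increases adjacency entries", {
  set.seed(33)
  em <- make_expr(random_values(30, 10))
  a2 <- adjacency_matrix(em, 2)
  a6 <- adjacency_matrix(em, 6)
  expect_true(all(a6 <= a2 + 1e-12))
})

test_that("scale-free fit index is 1 for collinear log-log bins and the
           scan falls back when the target is unreachable", {
  k <- c(rep(1, 90), rep(95, 10))  # two occupied bins -> collinear
  expect_equal(ceRNAti:::scale_free_r2(k), 1)
  # a preferential-attachment degree sequence scores high
  set.seed(4)
  g <- igraph::sample_pa(500, m = 1)
  expect_gte(ceRNAti:::scale_free_r2(as.numeric(igraph::degree(g))), 0.9)

  set.seed(5)
  em <- make_expr(random_values(40, 10))
  ps <- suppressWarnings(select_power(em, target_r2 = 0.999999))
  expect_true(ps$flagged)
  expect_equal(ps$selected, ps$scan$power[which.max(ps$scan$r2)])
})

test_that("module detection separates noise-free planted blocks exactly", {
  set.seed(10)
  base1 <- rnorm(10); base2 <- rnorm(10)
  # expm1 keeps each gene's log1p profile an exact affine image of its
  # block's latent series, so within-block correlation is exactly 1
  v <- rbind(
    t(sapply(1:30, function(i) expm1(5 + runif(1, 0.5, 1.5) * base1))),
    t(sapply(1:30, function(i) expm1(5 + runif(1, 0.5, 1.5) * base2))))
  rownames(v) <- paste0("g", 1:60)
  em <- make_expr(v)
  tom <- topological_overlap(adjacency_matrix(em, 6))
  ms <- detect_modules(tom, min_size = 20, cut_height = 0.95)
  expect_length(ms$modules, 2)
  expect_setequal(lengths(ms$modules), c(30, 30))
  expect_setequal(unlist(ms$modules), rownames(v))

  # mutually uncorrelated genes: nothing reaches min_size
  set.seed(11)
  em0 <- make_expr(random_values(40, 10))
  tom0 <- topological_overlap(adjacency_matrix(em0, 6))
  expect_length(detect_modules(tom0, min_size = 20)$modules, 0)
  expect_length(detect_modules(tom, min_size = 100)$modules, 0)
  expect_error(detect_modules(tom, min_size = 1), ">= 2")
})

test_that("module membership is a partition of the gene set", {
  d <- generate_dataset(sim_config(seed = 6))
  g <- c(gene_ids(d$expr, "mRNA"), gene_ids(d$expr, "lncRNA"))
  sub <- subset_genes(d$expr, g)
  tom <- suppressWarnings(
    topological_overlap(adjacency_matrix(sub, 6)))
  ms <- detect_modules(tom)
  all_assigned <- c(unlist(ms$modules), ms$unassigned)
  expect_setequal(all_assigned, rownames(tom))
  expect_equal(anyDuplicated(all_assigned), 0)
})

test_that("eigengene matches a dense eigendecomposition oracle", {
  set.seed(12)
  em <- make_expr(random_values(15, 10))
  eg <- module_eigengene(em, rownames(em$values))
  z <- t(scale(t(log1p(em$values))))
  # first eigenvector of the sample-by-sample cross-product
  ev <- eigen(t(z) %*% z)$vectors[, 1]
  expect_equal(abs(as.numeric(eg$eigengene)), abs(ev), tolerance = 1e-8)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-12)
})

test_that("eigengene conventions: identical members, anti-correlated
           members, single member", {
  prof <- rep(c(1, 2, 4, 8, 16), 2)
  v <- rbind(a = prof, b = prof, c = prof)
  em <- make_expr(v)
  eg <- module_eigengene(em, c("a", "b", "c"))
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  zp <- as.numeric(scale(log1p(prof)))
  expect_equal(abs(stats::cor(eg$eigengene, zp)), 1, tolerance = 1e-12)
  expect_gte(stats::cor(eg$eigengene, zp), 0)  # orientation rule

  anti <- expm1(max(log1p(prof)) + min(log1p(prof)) - log1p(prof))
  v2 <- rbind(a = prof, b = anti)
  eg2 <- module_eigengene(make_expr(v2), c("a", "b"))
  expect_equal(eg2$var_explained, 1, tolerance = 1e-12)
  # sign fixed deterministically by the first member when the mean
  # profile vanishes
  expect_gte(stats::cor(eg2$eigengene, zp), 0)

  eg1 <- module_eigengene(em, "a")
  expect_equal(eg1$var_explained, 1)
  expect_equal(sum(eg1$eigengene^2), 1, tolerance = 1e-12)
})

test_that("module-trait association recovers exact and null correlations", {
  prof <- rep(c(1, 2, 4, 8, 16), 2)
  em <- make_expr(rbind(a = prof, b = prof))
  ms <- structure(list(modules = list(M1 = c("a", "b")),
                       unassigned = character(0), order = c("a", "b"),
                       min_size = 2, cut_height = 0.95),
                  class = "ModuleSet")
  tr <- as.numeric(scale(log1p(prof)))
  mt <- module_trait_association(em, ms, tr)
  expect_equal(abs(mt$r), 1, tolerance = 1e-10)
  expect_lt(mt$p, 1e-10)

  # trait orthogonal to the eigengene: r = 0, p = 1
  eg <- module_eigengene(em, c("a", "b"))$eigengene
  egc <- eg - mean(eg)
  set.seed(99)
  ortho <- rnorm(10)
  ortho <- ortho - egc * sum(ortho * egc) / sum(egc^2)
  mt0 <- module_trait_association(em, ms, ortho)
  expect_equal(mt0$r, 0, tolerance = 1e-8)
  expect_equal(mt0$p, 1, tolerance = 1e-6)

  expect_error(module_trait_association(em, ms, rep(1, 10)), "constant")
})
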