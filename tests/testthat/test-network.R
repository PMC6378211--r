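test_that("co-expression filter retains by |r| with recorded direction", {
  toy <- toy_fixture()
  co <- coexpressed_pairs(toy$expr, toy$pairs, min_abs_r = 0.9)
  key <- paste(co$lncRNA_id, co$mRNA_id)
  expect_true(all(c("L1 M1", "L2 M2") %in% key))
  expect_equal(co$r[key == "L1 M1"], 1, tolerance = 1e-12)
  expect_equal(co$direction[key == "L1 M1"], "positive")
  expect_equal(co$direction[key == "L2 M3"], "negative")
  expect_true(all(abs(co$r) >= 0.9))

  # no filter: every candidate with defined correlation is retained
  co0 <- coexpressed_pairs(toy$expr, toy$pairs, min_abs_r = 0)
  expect_equal(nrow(co0),
               sum(toy$pairs$type == "lncRNA-mRNA"))

  # missing endpoints are skipped with a count
  p_missing <- target_pairs(c("L1", "Lx"), c("M1", "M1"),
                            rep("lncRNA-mRNA", 2))
  expect_message(
    co_m <- coexpressed_pairs(toy$expr, p_missing, min_abs_r = 0),
    "skipped")
  expect_equal(attr(co_m, "n_skipped"), 1)
})

test_that("retained fraction under a random null matches the |r| tail", {
  set.seed(50)
  em <- make_expr(random_values(200, 10))
  bt <- stats::setNames(rep(c("lncRNA", "mRNA"), each = 100),
                        rownames(em$values))
  em <- expression_matrix(em$values, bt, em$sample_meta)
  cand <- suppressWarnings(
    target_pairs(sample(rownames(em$values)[1:100], 1000, TRUE),
                 sample(rownames(em$values)[101:200], 1000, TRUE),
                 rep("lncRNA-mRNA", 1000)))
  co <- coexpressed_pairs(em, cand, min_abs_r = 0.9)
  # null tail P(|r| >= 0.9) at n = 10 via direct simulation
  sim <- replicate(20000, stats::cor(rnorm(10), rnorm(10)))
  tail_p <- mean(abs(sim) >= 0.9)
  expect_lt(abs(nrow(co) / nrow(cand) - tail_p), 0.01)
})

test_that("minimal ceRNA assembly and the empty cases", {
  co <- data.frame(lncRNA_id = "L1", mRNA_id = "M1")
  p <- target_pairs(c("L1", "mi1"), c("mi1", "M1"),
                    c("lncRNA-miRNA", "miRNA-mRNA"))
  net <- assemble_cerna(co, p)
  expect_equal(nrow(net$triplets), 1)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_equal(sort(net$edges$type), sort(c("lncRNA-mRNA",
                                            "lncRNA-miRNA",
                                            "miRNA-mRNA")))

  # co-expressed but no shared miRNA: empty network
  p2 <- target_pairs(c("L1", "mi2"), c("mi1", "M1"),
                     c("lncRNA-miRNA", "miRNA-mRNA"))
  net2 <- assemble_cerna(co, p2)
  expect_equal(nrow(net2$triplets), 0)
  expect_equal(nrow(net2$nodes), 0)

  net3 <- assemble_cerna(co[0, ], p)
  expect_equal(nrow(net3$triplets), 0)
})

test_that("assembly equals brute-force triple-loop enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- paste0("L", 1:30); mi <- paste0("mi", 1:20); M <- paste0("M", 1:40)
    co <- unique(data.frame(lncRNA_id = sample(L, 60, TRUE),
                            mRNA_id = sample(M, 60, TRUE)))
    pr <- unique(data.frame(
      source = c(sample(L, 120, TRUE), sample(mi, 160, TRUE)),
      target = c(sample(mi, 120, TRUE), sample(M, 160, TRUE)),
      type = rep(c("lncRNA-miRNA", "miRNA-mRNA"), c(120, 160))))
    pairs <- target_pairs(pr$source, pr$target, pr$type)
    got <- assemble_cerna(co, pairs)
    want <- assemble_brute(co, pairs)
    expect_identical(triplet_keys(got$triplets), triplet_keys(want))
    # closure: every triplet edge exists, every endpoint is a node
    with(got, {
      expect_true(all(c(edges$source, edges$target) %in% nodes$id))
      expect_true(all(paste(triplets$lncRNA_id, triplets$mRNA_id) %in%
                        paste(edges$source[edges$type == "lncRNA-mRNA"],
                              edges$target[edges$type == "lncRNA-mRNA"])))
    })
  }
})

test_that("triplet count is monotone in each input edge set", {
  set.seed(60)
  L <- paste0("L", 1:10); mi <- paste0("mi", 1:8); M <- paste0("M", 1:12)
  co <- unique(data.frame(lncRNA_id = sample(L, 30, TRUE),
                          mRNA_id = sample(M, 30, TRUE)))
  pr <- unique(data.frame(
    source = c(sample(L, 40, TRUE), sample(mi, 40, TRUE)),
    target = c(sample(mi, 40, TRUE), sample(M, 40, TRUE)),
    type = rep(c("lncRNA-miRNA", "miRNA-mRNA"), c(40, 40))))
  pairs <- target_pairs(pr$source, pr$target, pr$type)
  full <- nrow(assemble_cerna(co, pairs)$triplets)
  for (drop in c(5, 15)) {
    fewer <- pairs[-sample(nrow(pairs), drop), ]
    expect_lte(nrow(assemble_cerna(co, fewer)$triplets), full)
    co_fewer <- co[-sample(nrow(co), 3), ]
    expect_lte(nrow(assemble_cerna(co_fewer, pairs)$triplets), full)
  }
})

test_that("gene-centred module extraction: closure, isolates, idempotence,
           bookkeeping", {
  toy <- toy_fixture()
  co <- coexpressed_pairs(toy$expr, toy$pairs, min_abs_r = 0.9)
  net <- assemble_cerna(co, toy$pairs)
  all_m <- net$nodes$id[net$nodes$biotype == "mRNA"]
  expect_identical(triplet_keys(extract_gene_module(net, all_m)$triplets),
                   triplet_keys(net$triplets))

  m1 <- extract_gene_module(net, "M1")
  expect_identical(triplet_keys(m1$triplets), "L1 mi1 M1")
  expect_identical(triplet_keys(extract_gene_module(m1, "M1")$triplets),
                   triplet_keys(m1$triplets))
  cnt <- network_counts(m1)
  expect_equal(sum(cnt$edges), cnt$n_edges)
  expect_equal(sum(cnt$nodes), cnt$n_nodes)

  expect_error(extract_gene_module(net, "NOPE"), "NOPE")
})

test_that("per-type counts of a hand-built two-family module are exact", {
  # two focus mRNAs, two lncRNAs, three miRNAs wired by hand
  co <- data.frame(lncRNA_id = c("L1", "L2"), mRNA_id = c("M1", "M2"))
  pairs <- target_pairs(
    c("L1", "L1", "L2", "mi1", "mi2", "mi2", "mi3"),
    c("mi1", "mi2", "mi3", "M1", "M1", "M2", "M2"),
    c(rep("lncRNA-miRNA", 3), rep("miRNA-mRNA", 4)))
  net <- assemble_cerna(co, pairs)
  # triplets: (L1,mi1,M1), (L1,mi2,M1), (L2,mi3,M2) -- mi2-M2 exists but
  # L2-mi2 does not
  expect_identical(triplet_keys(net$triplets),
                   sort(c("L1 mi1 M1", "L1 mi2 M1", "L2 mi3 M2")))
  cnt <- network_counts(net)
  expect_equal(as.integer(cnt$nodes), c(2L, 3L, 2L))  # lnc, mi, mRNA
  expect_equal(as.integer(cnt$edges), c(2L, 3L, 3L))
})

test_that("node trait profiles report sign and peak correctly", {
  toy <- toy_fixture()
  co <- coexpressed_pairs(toy$expr, toy$pairs, min_abs_r = 0.9)
  net <- assemble_cerna(co, toy$pairs)
  tr <- toy$trait
  np <- node_trait_profile(toy$expr, net, tr)
  # L1/M1 rise after reperfusion: positive; L2/M2 fall: negative
  expect_equal(np$trait_sign[np$id == "M1"], "positive")
  expect_equal(np$trait_sign[np$id == "M2"], "negative")
  expect_equal(np$peak_time_hours[np$id == "M1"], 72)
  expect_equal(np$peak_time_hours[np$id == "M2"], 0)
})

test_that("planted positively-correlated genes carry a positive sign", {
  hits <- vapply(1:20, function(s) {
    d <- generate_dataset(sim_config(seed = s))
    co <- data.frame(lncRNA_id = d$truth$planted_triplets$lncRNA_id,
                     mRNA_id = d$truth$planted_triplets$mRNA_id)
    net <- assemble_cerna(co, d$pairs)
    np <- node_trait_profile(d$expr, net, d$trait)
    g <- d$truth$planted_module_members[[1]]
    # module latent correlates +0.8 with the trait by construction
    mean(np$trait_sign[np$id %in% g] == "positive")
  }, 0)
  expect_gte(mean(hits), 0.95)
})
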