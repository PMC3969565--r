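test_that("oldest-hit rule assigns the most distant group, with discounting", {
  tr <- fixture_tree()
  pr <- build_profile(data.frame(), c("atmlike", "everywhere", "ubr5like"), tr)
  pr$matrix["atmlike", c("Ath", "Sce", "Dre", "Hsa")] <- 1L
  pr$matrix["everywhere", ] <- 1L
  pr$matrix["ubr5like", c("Eco", "Tad", "Nve", "Dme", "Dre", "Hsa")] <- 1L
  pr <- flag_isolated_hits(pr)
  expect_equal(assign_age_oldest_hit(pr, "atmlike")$rank, 3L)
  expect_equal(assign_age_oldest_hit(pr, "everywhere")$rank, 1L)
  # isolated prokaryote hit: counted by default, discounted on request
  off <- assign_age_oldest_hit(pr, "ubr5like", discount_isolated = FALSE)
  on <- assign_age_oldest_hit(pr, "ubr5like", discount_isolated = TRUE)
  expect_equal(off$rank, 1L)
  expect_equal(off$flags, "used_isolated_hit")
  expect_equal(on$rank, 6L)
  expect_equal(on$flags, "discounted_isolated_hit")
  # all-zero row errors
  pr$matrix["atmlike", ] <- 0L
  expect_error(assign_age_oldest_hit(pr, "atmlike"), "no homologs")
})

test_that("Dollo places the gain at the MRCA and minimal losses", {
  t4 <- balanced4()
  # clean clade: no losses
  d <- dollo_reconstruct(t4, c(A = 1L, B = 1L, C = 0L, D = 0L))
  expect_equal(d$cost, 0L)
  expect_length(d$gain_nodes, 1L)
  # scattered: gain at root, losses to B and D
  d2 <- dollo_reconstruct(t4, c(A = 1L, B = 0L, C = 1L, D = 0L))
  expect_equal(d2$cost, 2L)
  expect_equal(d2$gain_nodes, 5L)  # root of a 4-leaf binary tree
  expect_setequal(d2$loss_nodes, c(2L, 4L))
  expect_error(dollo_reconstruct(t4, c(A = 0L, B = 0L, C = 0L, D = 0L)),
               "no homologs|all-zero")
})

test_that("Dollo on a 6-leaf caterpillar matches the exhaustive oracle", {
  gm <- data.frame(species = paste0("s", 1:6),
                   age_group = rep("Mammalia", 6))
  tr <- parse_species_tree("(s1,(s2,(s3,(s4,(s5,s6)))));", gm)
  row <- c(s1 = 1L, s2 = 0L, s3 = 0L, s4 = 0L, s5 = 0L, s6 = 1L)
  d <- dollo_reconstruct(tr, row)
  oracle <- oracle_dollo(tr, row)
  expect_equal(d$cost, oracle$cost)
  expect_equal(d$cost, 4L)
  expect_equal(d$gain_nodes, oracle$gain_node)
})

test_that("Wagner matches exhaustive enumeration on the worked examples", {
  t4 <- balanced4()
  row <- c(A = 1L, B = 0L, C = 1L, D = 0L)
  w1 <- wagner_reconstruct(t4, row, 1, 1)
  expect_equal(w1$cost, oracle_parsimony_cost(t4, row, 1, 1))
  expect_equal(w1$cost, 2)
  expect_length(w1$gain_nodes, 2L)
  expect_length(w1$loss_nodes, 0L)
  w3 <- wagner_reconstruct(t4, row, 3, 1)
  expect_equal(w3$cost, oracle_parsimony_cost(t4, row, 3, 1))
  expect_equal(w3$cost, 5)
  expect_length(w3$gain_nodes, 1L)
  expect_length(w3$loss_nodes, 2L)
  # uniform presence: single root gain, no losses, any costs
  all1 <- c(A = 1L, B = 1L, C = 1L, D = 1L)
  for (gc in c(0.5, 1, 4)) {
    w <- wagner_reconstruct(t4, all1, gc, 1)
    expect_equal(w$gain_nodes, 5L)
    expect_length(w$loss_nodes, 0L)
    expect_equal(w$cost, gc)
  }
})

test_that("both engines agree with exhaustive oracles on random small trees", {
  set.seed(123)
  n_cases <- 150
  for (i in seq_len(n_cases)) {
    n <- sample(3:7, 1)
    tr <- random_species_tree(n, multifurcate = TRUE)
    row <- stats::setNames(rbinom(n, 1, 0.5), tr$phylo$tip.label)
    if (sum(row) == 0) row[sample(n, 1)] <- 1L
    gc <- sample(c(1, 2, 3), 1); lc <- sample(c(1, 2), 1)
    w <- wagner_reconstruct(tr, row, gc, lc)
    expect_equal(w$cost, oracle_parsimony_cost(tr, row, gc, lc))
    d <- dollo_reconstruct(tr, row)
    o <- oracle_dollo(tr, row)
    expect_equal(d$cost, o$cost)
    # Dollo gain is the MRCA of present leaves
    present <- unname(which(row == 1L))
    expect_equal(d$gain_nodes,
                 if (length(present) == 1L) present
                 else ape::getMRCA(tr$phylo, present))
  }
})

test_that("Dollo and Wagner coincide when gains are expensive", {
  set.seed(321)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tr <- random_species_tree(n)
    row <- stats::setNames(rbinom(n, 1, 0.5), tr$phylo$tip.label)
    if (sum(row) == 0) row[sample(n, 1)] <- 1L
    gc <- n + 1  # gain_cost >= leaves * loss_cost forces a single gain
    w <- wagner_reconstruct(tr, row, gc, 1)
    d <- dollo_reconstruct(tr, row)
    expect_length(w$gain_nodes, 1L)
    expect_equal(w$gain_nodes, d$gain_nodes)
    expect_setequal(w$loss_nodes, d$loss_nodes)
    expect_equal(w$cost, gc + d$cost)
    # and symmetric-cost Wagner is never worse than Dollo's event count
    w1 <- wagner_reconstruct(tr, row, 1, 1)
    expect_lte(w1$cost, 1 + d$cost)
  }
})

test_that("reconstruction age uses the gain clade, anchored at the reference", {
  tr <- fixture_tree()
  pr <- build_profile(data.frame(), "g", tr)
  pr$matrix["g", ] <- 1L
  d <- dollo_reconstruct(tr, pr$matrix["g", ])
  expect_equal(age_from_reconstruction(d, tr)$rank, 1L)
  # gain at the MRCA of the opisthokont clade
  pr$matrix["g", ] <- 0L
  pr$matrix["g", c("Sce", "Tad", "Nve", "Dme", "Cin", "Dre", "Hsa")] <- 1L
  d2 <- dollo_reconstruct(tr, pr$matrix["g", ])
  expect_equal(age_from_reconstruction(d2, tr)$rank, 5L)
  # two Wagner gains: the human-containing clade wins
  row <- stats::setNames(rep(0L, 12), tr$species)
  row[c("Sce", "Ddi")] <- 1L          # fungal-side gain
  row[c("Cin", "Dre", "Hsa")] <- 1L   # chordate gain
  w <- wagner_reconstruct(tr, row, 1, 1)
  expect_gte(length(w$gain_nodes), 2L)
  expect_equal(age_from_reconstruction(w, tr, reference = "Hsa")$rank, 9L)
})

test_that("oldest-hit equals Dollo age on a group-monophyletic tree", {
  tr <- fixture_tree()
  sim <- simulate_profile_set(tr, 80, loss_rate = 0.3, seed = 8)
  oh <- assign_ages(sim$profile, "oldest_hit")
  dl <- assign_ages(sim$profile, "dollo")
  expect_equal(oh$rank, dl$rank)
})

test_that("emergence curves cumulate correctly and are monotone", {
  ages <- data.frame(gene = paste0("g", 1:4), rank = c(1, 2, 2, 3))
  cv <- emergence_curves(ages)
  expect_equal(cv$cumulative_fraction[1:3], c(0.25, 0.75, 1.0))
  expect_equal(cv$cumulative_fraction[11], 1.0)
  expect_true(all(diff(cv$cumulative_fraction) >= 0))
  # constant curve when everything is rank 1
  cv1 <- emergence_curves(data.frame(gene = "a", rank = 1))
  expect_true(all(cv1$cumulative_fraction == 1))
  # stratified: multi-tier genes count once per stratum
  ann <- data.frame(gene = paste0("g", 1:4),
                    tier = c("sensor", "sensor,effector", "effector",
                             "effector"))
  cvt <- emergence_curves(ages, ann, stratify_by = "tier")
  eff <- cvt[cvt$stratum == "effector", ]
  expect_equal(eff$cumulative_fraction[3], 1.0)  # ranks 2,2,3 all <= 3
  expect_equal(eff$cumulative_fraction[1], 0)
  sen <- cvt[cvt$stratum == "sensor", ]
  expect_equal(sen$cumulative_fraction[2], 1.0)  # ranks 1,2
})

test_that("planted age mass shows up in the curve within binomial noise", {
  tr <- fixture_tree()
  w <- c(0.1, 0.7, rep(0.2 / 9, 9))
  sim <- simulate_profile_set(tr, 200, age_distribution = w, loss_rate = 0,
                              seed = 21)
  ages <- assign_ages(sim$profile, "oldest_hit")
  cv <- emergence_curves(ages)
  # cumulative at rank 2 ~ 0.8, binomial sd ~ 0.028; allow 3 sd
  expect_lt(abs(cv$cumulative_fraction[2] - 0.8), 3 * sqrt(0.8 * 0.2 / 200))
})
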