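# Independent oracles used across the suite. These deliberately use brute
# force or closed forms, never the package's own code paths.

# two-sided Fisher p by explicit hypergeometric enumeration from log-factorials
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1.0)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration over all labelings
oracle_mw <- function(xs, ys) {
  n1 <- length(xs); n2 <- length(ys)
  r <- rank(c(xs, ys))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# exhaustive minimum-cost gain/loss labeling: tries all 2^Nnode internal
# labelings; root presence costs one gain
oracle_parsimony_cost <- function(tree, row, gain_cost = 1, loss_cost = 1) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- phy$Nnode
  row <- row[phy$tip.label]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    states <- c(unname(row), as.integer(intToBits(mask))[seq_len(nn)])
    cost <- if (states[root] == 1L) gain_cost else 0
    for (e in seq_len(nrow(phy$edge))) {
      p <- states[phy$edge[e, 1]]; c <- states[phy$edge[e, 2]]
      if (p == 0L && c == 1L) cost <- cost + gain_cost
      if (p == 1L && c == 0L) cost <- cost + loss_cost
    }
    best <- min(best, cost)
  }
  best
}

# minimum losses over all single-gain placements (Dollo oracle); returns
# list(cost, gain_node)
oracle_dollo <- function(tree, row) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nn <- phy$Nnode
  row <- row[phy$tip.label]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  parent <- integer(ntip + nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  # tips below each node
  below <- function(v) {
    if (v <= ntip) return(v)
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    unlist(lapply(kids, below))
  }
  best <- list(cost = Inf, gain_node = NA)
  for (g in seq_len(ntip + nn)) {
    tips_g <- below(g)
    if (!all(which(row == 1L) %in% tips_g)) next
    # states: within clade, node is 1 iff a present tip lies below it
    states <- integer(ntip + nn)
    for (v in seq_len(ntip + nn)) {
      tv <- below(v)
      if (all(tv %in% tips_g) && any(row[tv] == 1L)) states[v] <- 1L
    }
    states[g] <- 1L
    losses <- 0
    for (e in seq_len(nrow(phy$edge))) {
      p <- states[phy$edge[e, 1]]; c <- states[phy$edge[e, 2]]
      if (p == 1L && c == 0L) losses <- losses + 1
    }
    if (losses < best$cost) best <- list(cost = losses, gain_node = g)
  }
  best
}

# random rooted tree with n leaves (possibly multifurcating), labels t1..tn,
# returned as a species_tree with groups drawn over the default scale
random_species_tree <- function(n, multifurcate = FALSE) {
  phy <- if (multifurcate && n >= 4 && stats::runif(1) < 0.5) {
    # collapse short internal edges of a random binary tree
    tr <- ape::di2multi(ape::rtree(n, rooted = TRUE), tol = 0.3)
    tr$edge.length <- NULL
    tr
  } else ape::rtree(n, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("t", seq_len(n))
  groups <- sample(default_age_scale()$name, n, replace = TRUE)
  gm <- data.frame(species = phy$tip.label, age_group = groups)
  parse_species_tree(ape::write.tree(phy), gm)
}

# small deterministic 4-leaf balanced tree used in many unit tests
balanced4 <- function() {
  gm <- data.frame(species = c("A", "B", "C", "D"),
                   age_group = c("Mammalia", "Mammalia",
                                 "Bilateria", "Bilateria"))
  parse_species_tree("((A,B),(C,D));", gm)
}
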