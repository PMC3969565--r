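#' Simulate one gene history: single gain, branch-wise loss
#'
#' The generative model behind Dollo parsimony: the gene is gained once,
#' on the stem branch of `gain_node`, and every branch below it loses the
#' gene independently with probability `loss_rate`; once lost it stays
#' lost. Leaves outside the gain clade are absent.
#'
#' @param tree a `species_tree`.
#' @param gain_node node id (tip or internal, `ape` indexing) whose stem
#'   branch carries the gain.
#' @param loss_rate per-branch loss probability in `[0, 1)`.
#' @return list with `row` (named 0/1 vector over species) and `truth`
#'   (list: `gain_node`, `true_rank` -- the rank of the oldest group with
#'   a leaf in the gain clade -- and `loss_branches`, child node ids of
#'   branches where loss occurred).
#' @export
simulate_gene_history <- function(tree, gain_node, loss_rate = 0) {
  stopifnot(inherits(tree, "species_tree"),
            loss_rate >= 0, loss_rate < 1)
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  if (gain_node < 1L || gain_node > nnode) stop("gain_node not in tree")
  ch <- .tree_children(phy)
  below <- .tips_below(phy)
  state <- integer(nnode)
  state[gain_node] <- 1L
  losses <- integer(0)
  # preorder from the gain node: child keeps the gene unless the branch loses it
  stack <- gain_node
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    for (k in ch[[v]]) {
      if (state[v] == 1L) {
        if (stats::runif(1) < loss_rate) {
          state[k] <- 0L
          losses <- c(losses, k)
        } else state[k] <- 1L
      }
      if (k > ntip) stack <- c(stack, k)
    }
  }
  row <- state[seq_len(ntip)]
  names(row) <- phy$tip.label
  truth <- list(gain_node = gain_node,
                true_rank = min(tree$group_rank[phy$tip.label[below[[gain_node]]]]),
                loss_branches = losses)
  list(row = row, truth = truth)
}

#' Replay a simulated history (truth oracle)
#'
#' Deterministically reconstructs the leaf presence vector from the
#' recorded gain node and loss branches; used to verify that emitted data
#' and truth agree, and to compute the MRCA-of-survivors rank.
#'
#' @param tree a `species_tree`.
#' @param truth a `truth` element from [simulate_gene_history()].
#' @return named 0/1 vector over species.
#' @export
replay_gene_history <- function(tree, truth) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  ch <- .tree_children(phy)
  state <- integer(ntip + phy$Nnode)
  state[truth$gain_node] <- 1L
  stack <- truth$gain_node
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    for (k in ch[[v]]) {
      state[k] <- if (k %in% truth$loss_branches) 0L else state[v]
      if (k > ntip) stack <- c(stack, k)
    }
  }
  row <- state[seq_len(ntip)]
  names(row) <- phy$tip.label
  row
}

#' Simulate a set of gene profiles with known ages
#'
#' Draws `n_genes` independent single-gain/loss histories. Gain branches
#' are drawn so that the true age (oldest group rank of the gain clade)
#' follows `age_distribution`; within an age class the gain node is drawn
#' uniformly among compatible branches. Genes whose carriers are all lost
#' are re-simulated (the analysis never sees empty rows).
#'
#' @param tree a `species_tree`.
#' @param n_genes number of genes.
#' @param age_distribution numeric weights over the scale's ranks (length
#'   G, sums to 1). Default: mass concentrated at the two oldest ranks,
#'   mirroring a network dominated by an ancient core (0.1 at rank 1,
#'   0.6 at rank 2, remainder spread uniformly).
#' @param loss_rate per-branch loss probability.
#' @param seed integer RNG seed.
#' @return list with `profile` (a `phylo_profile`) and `truth` (data frame
#'   `gene`, `gain_node`, `true_rank`, `losses` (comma-joined branch ids)).
#' @export
simulate_profile_set <- function(tree, n_genes,
                                 age_distribution = NULL,
                                 loss_rate = 0, seed = 1L) {
  stopifnot(inherits(tree, "species_tree"))
  set.seed(seed)
  G <- nrow(tree$scale)
  if (is.null(age_distribution)) {
    age_distribution <- rep(0.3 / (G - 2), G)
    age_distribution[1] <- 0.1
    age_distribution[2] <- 0.6
  }
  stopifnot(length(age_distribution) == G,
            abs(sum(age_distribution) - 1) < 1e-8)
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  below <- .tips_below(phy)
  nnode <- ntip + phy$Nnode
  node_rank <- vapply(seq_len(nnode), function(v)
    min(tree$group_rank[phy$tip.label[below[[v]]]]), numeric(1))
  nodes_by_rank <- split(seq_len(nnode), node_rank)
  if (n_genes == 0L) {
    prof <- build_profile(data.frame(), "placeholder", tree)
    prof$matrix <- prof$matrix[0, , drop = FALSE]
    prof$provenance <- prof$provenance[0, , drop = FALSE]
    prof$isolated <- prof$isolated[0, , drop = FALSE]
    return(list(profile = prof, truth = data.frame()))
  }
  rows <- matrix(0L, n_genes, ntip)
  truth <- vector("list", n_genes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  for (i in seq_len(n_genes)) {
    r <- sample.int(G, 1L, prob = age_distribution)
    pool <- nodes_by_rank[[as.character(r)]]
    if (is.null(pool))
      stop("no branch is compatible with age rank ", r, " on this tree")
    repeat {
      gn <- if (length(pool) == 1L) pool else sample(pool, 1L)
      sim <- simulate_gene_history(tree, gn, loss_rate)
      if (sum(sim$row) > 0L) break
    }
    rows[i, ] <- sim$row[phy$tip.label]
    truth[[i]] <- data.frame(gene = genes[i], gain_node = sim$truth$gain_node,
                             true_rank = sim$truth$true_rank,
                             losses = paste(sim$truth$loss_branches,
                                            collapse = ","),
                             stringsAsFactors = FALSE)
  }
  species <- tree$species[order(tree$group_rank[tree$species], tree$species)]
  mat <- rows
  colnames(mat) <- phy$tip.label
  mat <- mat[, species, drop = FALSE]
  rownames(mat) <- genes
  prof <- structure(list(matrix = mat,
                         provenance = matrix(ifelse(mat == 1L, "direct",
                                                    "absent"),
                                             nrow(mat),
                                             dimnames = dimnames(mat)),
                         isolated = matrix(FALSE, nrow(mat), ncol(mat),
                                           dimnames = dimnames(mat)),
                         tree = tree),
                    class = "phylo_profile")
  list(profile = prof, truth = do.call(rbind, truth))
}

#' Flatten a profile into an ortholog hit table
#'
#' Emits one perfect-score bidirectional hit per presence cell, so that
#' [build_profile()] on the result reproduces the matrix exactly
#' (round-trip property used in tests).
#'
#' @param profile a `phylo_profile`.
#' @param seed_species seed organism code stamped on each hit.
#' @return data frame in the hit-table dialect.
#' @export
profile_to_hits <- function(profile, seed_species = "Hsa") {
  idx <- which(profile$matrix == 1L, arr.ind = TRUE)
  data.frame(seed_gene = rownames(profile$matrix)[idx[, 1]],
             seed_species = seed_species,
             target_species = colnames(profile$matrix)[idx[, 2]],
             hit_id = sprintf("h%05d", seq_len(nrow(idx))),
             score = 1.0, bidirectional = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate an age-coupled modification network
#'
#' Draws `n_pairs` target-modifier pairs from a gene pool with known ages.
#' Each pair picks a target uniformly; with probability `assortativity`
#' the modifier is drawn from genes of the same age, otherwise uniformly
#' from all genes. Self-pairs are rejected and redrawn. Modification
#' types are drawn from `ptm_probs` (default matching the proportions of
#' the packaged pair table: P 0.77, U 0.14, S 0.06, A 0.02, deA 0.01).
#'
#' @param gene_ages named integer vector gene -> age rank (at least two
#'   distinct ages).
#' @param n_pairs number of pairs.
#' @param assortativity probability in `[0, 1]` that a pair is forced
#'   same-age.
#' @param seed integer RNG seed.
#' @param ptm_probs named numeric over P/U/S/A/deA, summing to 1.
#' @return list with `network` (a harmonizable `ptm_network`) and `truth`
#'   (data frame `pair`, `forced_same_age`).
#' @export
simulate_ptm_network <- function(gene_ages, n_pairs, assortativity = 0.5,
                                 seed = 1L,
                                 ptm_probs = c(P = 0.77, U = 0.14, S = 0.06,
                                               A = 0.02, deA = 0.01)) {
  stopifnot(assortativity >= 0, assortativity <= 1,
            length(unique(gene_ages)) >= 2,
            abs(sum(ptm_probs) - 1) < 1e-8)
  set.seed(seed)
  genes <- names(gene_ages)
  pairs <- vector("list", n_pairs)
  truth <- logical(n_pairs)
  lbl <- default_age_scale()$label
  for (i in seq_len(n_pairs)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      tg <- sample(genes, 1L)
      forced <- stats::runif(1) < assortativity
      pool <- if (forced) setdiff(genes[gene_ages == gene_ages[[tg]]], tg)
              else setdiff(genes, tg)
      if (!length(pool)) next  # no same-age partner: redraw target
      md <- if (length(pool) == 1L) pool else sample(pool, 1L)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not draw pair ", i, " after bounded retries")
    pairs[[i]] <- data.frame(
      target = tg, target_net = "SIM", modifier = md, modifier_net = "SIM",
      ptm = sample(names(ptm_probs), 1L, prob = ptm_probs),
      target_age = lbl[gene_ages[[tg]]],
      modifier_age = lbl[gene_ages[[md]]],
      target_rank = gene_ages[[tg]], modifier_rank = gene_ages[[md]],
      self = FALSE, stringsAsFactors = FALSE)
    truth[i] <- forced
  }
  net <- structure(list(pairs = do.call(rbind, pairs),
                        scale = default_age_scale(), harmonized = FALSE,
                        changes = data.frame()),
                   class = "ptm_network")
  list(network = net,
       truth = data.frame(pair = seq_len(n_pairs), forced_same_age = truth))
}
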