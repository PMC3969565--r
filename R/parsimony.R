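#' Dollo parsimony reconstruction of a gene's gain and losses
#'
#' Dollo parsimony assumes a gene family is gained exactly once and can
#' only be lost thereafter. The gain is placed on the branch leading to the
#' most recent common ancestor (MRCA) of all species carrying the gene;
#' inside that clade, every node with at least one carrier below it is
#' ancestrally present, and each maximal carrier-free subtree accounts for
#' one loss on its stem branch. The reported cost is the number of losses.
#'
#' @param tree a `species_tree`.
#' @param row named 0/1 vector over the tree's species (a profile row).
#' @param gene optional gene name carried through to the result.
#' @return An object of class `reconstruction`: list with `gene`, `method`,
#'   `states` (0/1 per node, indexed tips first then internal nodes as in
#'   `ape`), `gain_nodes` (node ids whose stem branch carries the gain;
#'   the root id means a gain on the root stem), `loss_nodes` (ids whose
#'   stem branch carries a loss), `cost`.
#' @export
dollo_reconstruct <- function(tree, row, gene = NULL) {
  stopifnot(inherits(tree, "species_tree"))
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  row <- row[phy$tip.label]
  if (anyNA(row)) stop("profile row must cover every tree species")
  if (sum(row) == 0L) stop("no homologs: all-zero profile row")
  present_tips <- unname(which(row == 1L))
  gain <- .mrca_node(phy, present_tips)
  below <- .tips_below(phy)
  nnode <- ntip + phy$Nnode
  states <- integer(nnode)
  # in a tree, v lies in the gain clade iff its tip set is nested in the gain's
  in_clade <- vapply(seq_len(nnode), function(v)
    all(below[[v]] %in% below[[gain]]), logical(1))
  for (v in seq_len(nnode))
    if (in_clade[v] && any(row[phy$tip.label[below[[v]]]] == 1L))
      states[v] <- 1L
  states[gain] <- 1L
  # losses: edges parent present -> child absent, within the gain clade
  losses <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    if (states[p] == 1L && states[c] == 0L) losses <- c(losses, c)
  }
  structure(list(gene = gene, method = "dollo", states = states,
                 gain_nodes = gain, loss_nodes = sort(losses),
                 cost = length(losses)),
            class = "reconstruction")
}

#' Wagner parsimony reconstruction (weighted gain/loss)
#'
#' Wagner parsimony allows any number of gains and losses and finds an
#' ancestral 0/1 labeling minimising
#' `gain_cost * gains + loss_cost * losses` by bottom-up cost propagation
#' (Sankoff recursion, multifurcations handled natively) with a top-down
#' backtrace. A present root is charged one gain on a virtual stem branch,
#' so a gene present everywhere still records a single ancestral gain.
#' Ties are broken by preferring absence: state 0 at the root, and on an
#' equal-cost backtrace the child keeps state 0 (a loss is preferred over
#' a gain).
#'
#' @inheritParams dollo_reconstruct
#' @param gain_cost,loss_cost positive event costs (defaults 1 and 1; the
#'   symmetric costs are the conventional Wagner default).
#' @return a `reconstruction` (see [dollo_reconstruct()]); `cost` is the
#'   total weighted cost including the root stem gain if any.
#' @export
wagner_reconstruct <- function(tree, row, gain_cost = 1, loss_cost = 1,
                               gene = NULL) {
  stopifnot(inherits(tree, "species_tree"), gain_cost > 0, loss_cost > 0)
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  row <- row[phy$tip.label]
  if (anyNA(row)) stop("profile row must cover every tree species")
  nnode <- ntip + phy$Nnode
  ch <- .tree_children(phy)
  root <- .tree_root(phy)
  trans <- function(s, t) if (s == t) 0 else if (t == 1L) gain_cost else loss_cost
  S <- matrix(Inf, nnode, 2L)  # S[v, s+1] = min cost of subtree of v given state s
  for (i in seq_len(ntip)) S[i, row[[phy$tip.label[i]]] + 1L] <- 0
  for (v in .postorder_nodes(phy)) {
    for (s in 0:1) {
      tot <- 0
      for (k in ch[[v]])
        tot <- tot + min(S[k, 1L] + trans(s, 0L), S[k, 2L] + trans(s, 1L))
      S[v, s + 1L] <- tot
    }
  }
  root_costs <- c(S[root, 1L], S[root, 2L] + gain_cost)
  root_state <- if (root_costs[1] <= root_costs[2]) 0L else 1L
  cost <- root_costs[root_state + 1L]
  states <- integer(nnode)
  states[root] <- root_state
  # preorder backtrace; prefer state 0 on ties
  stack <- root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    s <- states[v]
    for (k in ch[[v]]) {
      c0 <- S[k, 1L] + trans(s, 0L)
      c1 <- S[k, 2L] + trans(s, 1L)
      states[k] <- if (c0 <= c1) 0L else 1L
      if (k > ntip) stack <- c(stack, k)
    }
  }
  gains <- integer(0); losses <- integer(0)
  if (root_state == 1L) gains <- root
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    if (states[p] == 0L && states[c] == 1L) gains <- c(gains, c)
    if (states[p] == 1L && states[c] == 0L) losses <- c(losses, c)
  }
  structure(list(gene = gene, method = "wagner", states = states,
                 gain_nodes = sort(gains), loss_nodes = sort(losses),
                 cost = cost),
            class = "reconstruction")
}

#' Gene age implied by a parsimony reconstruction
#'
#' The age of a gene is the rank of the oldest age group with at least one
#' leaf inside the gain clade. With multiple Wagner gains, the gain whose
#' subtree contains the reference organism is used (the age is the age of
#' the copy the reference organism inherited).
#'
#' @param recon a `reconstruction` with at least one gain.
#' @param tree the `species_tree` it was computed on.
#' @param reference species code anchoring multi-gain reconstructions
#'   (default `"Hsa"`).
#' @return list with `gene`, `method`, `rank`, `group` (name), `gain_node`.
#' @export
age_from_reconstruction <- function(recon, tree, reference = "Hsa") {
  stopifnot(inherits(recon, "reconstruction"), inherits(tree, "species_tree"))
  if (!length(recon$gain_nodes)) stop("reconstruction has no gain event")
  phy <- tree$phylo
  below <- .tips_below(phy)
  gain <- recon$gain_nodes
  if (length(gain) > 1L) {
    ref_tip <- match(reference, phy$tip.label)
    if (is.na(ref_tip))
      stop("reference species ", reference, " not in tree")
    holds_ref <- vapply(gain, function(g) ref_tip %in% below[[g]], logical(1))
    if (!any(holds_ref))
      stop("no gain subtree contains the reference organism ", reference)
    gain <- gain[holds_ref][1L]
  }
  tips <- phy$tip.label[below[[gain]]]
  rank <- min(tree$group_rank[tips])
  list(gene = recon$gene, method = recon$method, rank = unname(rank),
       group = tree$scale$name[rank], gain_node = gain)
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(x$method, "reconstruction", if (!is.null(x$gene)) paste0("(", x$gene, ")"),
      ":", length(x$gain_nodes), "gain(s),", length(x$loss_nodes),
      "loss(es), cost", x$cost, "\n")
  invisible(x)
}
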