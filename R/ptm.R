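#' Load a target-modifier modification pair table
#'
#' Reads a TSV with columns `target`, `target_net`, `modifier`,
#' `modifier_net`, `ptm`, `target_age`, `modifier_age`. Modification types
#' are `P` (phosphorylation), `U` (ubiquitination), `S` (sumoylation),
#' `A` (acetylation) and `deA` (deacetylation); ages are short labels of
#' the [age_scale()]. A packaged transcription of a curated human
#' DNA-damage-response pair table is available via [ptm_fixture_path()].
#'
#' @param path TSV file path.
#' @param scale an [age_scale()].
#' @return An object of class `ptm_network`: list with `pairs` (data frame
#'   adding `target_rank`, `modifier_rank`, `self`), `scale`, `harmonized`
#'   (FALSE), `changes` (empty).
#' @examples
#' net <- load_ptm_pairs(ptm_fixture_path())
#' nrow(net$pairs)  # 99
#' @export
load_ptm_pairs <- function(path, scale = default_age_scale()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "target_net", "modifier", "modifier_net", "ptm",
            "target_age", "modifier_age")
  if (!all(need %in% names(d)))
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  valid_ptm <- c("P", "U", "S", "A", "deA")
  bad <- which(!d$ptm %in% valid_ptm)
  if (length(bad))
    stop("unknown ptm code '", d$ptm[bad[1]], "' in row ", bad[1])
  tr <- tryCatch(age_rank(scale, d$target_age), error = function(e)
    stop("bad target age label: ", conditionMessage(e)))
  mr <- tryCatch(age_rank(scale, d$modifier_age), error = function(e)
    stop("bad modifier age label: ", conditionMessage(e)))
  d$target_rank <- tr
  d$modifier_rank <- mr
  d$self <- d$target == d$modifier
  structure(list(pairs = d, scale = scale, harmonized = FALSE,
                 changes = data.frame()),
            class = "ptm_network")
}

#' Path to the packaged modification pair fixture
#'
#' @return file path of the bundled `table2_ptm_pairs.tsv`.
#' @export
ptm_fixture_path <- function() {
  system.file("extdata", "table2_ptm_pairs.tsv", package = "netage",
              mustWork = TRUE)
}

#' Harmonize gene ages across a modification network
#'
#' A gene may appear many times in a pair table, as target and as
#' modifier, and hand-curated tables occasionally list it with different
#' ages in different rows. Harmonization maps each gene to a single age:
#' the modal rank over all its appearances, with ties broken toward the
#' older (smaller) rank. All pair ranks are rewritten from that map and
#' each rewritten cell is logged.
#'
#' @param network a `ptm_network`.
#' @return the network with ranks rewritten, `harmonized = TRUE` and a
#'   `changes` data frame (`row`, `gene`, `role`, `old_rank`, `new_rank`).
#' @export
harmonize_ages <- function(network) {
  stopifnot(inherits(network, "ptm_network"))
  d <- network$pairs
  app <- rbind(data.frame(gene = d$target, rank = d$target_rank),
               data.frame(gene = d$modifier, rank = d$modifier_rank))
  modal <- vapply(split(app$rank, app$gene), function(v) {
    t <- table(v)
    min(as.integer(names(t)[t == max(t)]))
  }, integer(1))
  changes <- list()
  for (i in seq_len(nrow(d))) {
    nt <- modal[[d$target[i]]]
    if (nt != d$target_rank[i]) {
      changes[[length(changes) + 1L]] <- data.frame(
        row = i, gene = d$target[i], role = "target",
        old_rank = d$target_rank[i], new_rank = nt)
      d$target_rank[i] <- nt
    }
    nm <- modal[[d$modifier[i]]]
    if (nm != d$modifier_rank[i]) {
      changes[[length(changes) + 1L]] <- data.frame(
        row = i, gene = d$modifier[i], role = "modifier",
        old_rank = d$modifier_rank[i], new_rank = nm)
      d$modifier_rank[i] <- nm
    }
  }
  lbl <- network$scale$label
  d$target_age <- lbl[d$target_rank]
  d$modifier_age <- lbl[d$modifier_rank]
  network$pairs <- d
  network$harmonized <- TRUE
  network$changes <- if (length(changes)) do.call(rbind, changes)
                     else data.frame()
  network$age_map <- modal
  network
}

#' Classify pairs by relative age of target and modifier
#'
#' Non-self pairs fall in one of three categories: `same` (equal ranks),
#' `target_younger` (target in a more recent group than its modifier) and
#' `target_older`. `delta` is the absolute rank difference on the full
#' scale. Self-modifications are excluded from categories (category `NA`,
#' delta 0).
#'
#' @param network a harmonized `ptm_network`.
#' @return the `pairs` data frame with added `category` and `delta`.
#' @export
classify_pairs <- function(network) {
  stopifnot(inherits(network, "ptm_network"))
  d <- network$pairs
  cat <- ifelse(d$self, NA_character_,
                ifelse(d$target_rank == d$modifier_rank, "same",
                       ifelse(d$target_rank > d$modifier_rank,
                              "target_younger", "target_older")))
  delta <- ifelse(d$self, 0L, abs(d$target_rank - d$modifier_rank))
  d$category <- cat
  d$delta <- as.integer(delta)
  d
}

#' Summary counts of a modification network
#'
#' @param network a `ptm_network` (harmonize first for age-dependent
#'   fields).
#' @return list with `n_pairs_with_self`, `n_pairs`, `ptm_counts`
#'   (non-self, by type), `n_targets`, `n_modifiers`, `categories`
#'   (named counts same / target_younger / target_older),
#'   `modifier_subnetworks` (counts of non-self pairs by modifier
#'   subnetwork annotation).
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "ptm_network"))
  d <- classify_pairs(network)
  ns <- d[!d$self, , drop = FALSE]
  ptm_levels <- c("P", "U", "S", "A", "deA")
  ptm_counts <- vapply(ptm_levels, function(t) sum(ns$ptm == t), integer(1))
  cats <- c(same = sum(ns$category == "same"),
            target_younger = sum(ns$category == "target_younger"),
            target_older = sum(ns$category == "target_older"))
  list(n_pairs_with_self = nrow(d),
       n_pairs = nrow(ns),
       ptm_counts = ptm_counts,
       n_targets = length(unique(d$target)),
       n_modifiers = length(unique(d$modifier)),
       categories = cats,
       modifier_subnetworks = table(ns$modifier_net))
}

#' Evolutionary jump profile of a modification network
#'
#' Among non-self pairs whose members differ in age, a jump is the rank
#' distance between target and modifier; jumps below `threshold` groups
#' are "small", the rest "large".
#'
#' @param network a harmonized `ptm_network`.
#' @param threshold small/large boundary in age-group ranks (default 3:
#'   a difference of less than 3 groups is small).
#' @return named integer vector `c(small = ..., large = ...)`.
#' @export
jump_profile <- function(network, threshold = 3L) {
  if (threshold < 1L) stop("threshold must be >= 1")
  d <- classify_pairs(network)
  dd <- d$delta[!d$self & d$delta > 0L]
  c(small = sum(dd < threshold), large = sum(dd >= threshold))
}

# draw one permutation of modifiers avoiding self-pairs (whole-replicate
# rejection); returns indices into the modifier vector
.permute_no_self <- function(targets, modifiers, max_tries = 10000L) {
  n <- length(modifiers)
  for (t in seq_len(max_tries)) {
    perm <- sample.int(n)
    if (!any(targets == modifiers[perm])) return(perm)
  }
  stop("could not draw a self-pair-free permutation after ", max_tries,
       " tries")
}

#' Free permutation null for age coupling
#'
#' Each replicate permutes the modifier column against the fixed target
#' column uniformly at random; permutations creating any self-pair are
#' rejected and redrawn as a whole. Per replicate the same /
#' target-younger / target-older counts are recorded. Empirical p-values
#' use (r + 1)/(n + 1) smoothing and are two-sided (double the smaller
#' tail, capped at 1).
#'
#' @param network a harmonized `ptm_network`; self pairs are dropped
#'   before randomization.
#' @param n_reps number of replicates (the conventional choice is 1000).
#' @param seed integer RNG seed.
#' @return An object of class `null_distribution`: list with `scheme`,
#'   `n_reps`, `seed`, `observed` (category counts, plus
#'   `different` = younger + older), `replicates` (data frame of per-
#'   replicate counts), `summary` (mean/sd per statistic), `p_empirical`.
#' @export
randomize_free <- function(network, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(network, "ptm_network"), n_reps >= 1L)
  d <- classify_pairs(network)
  d <- d[!d$self, , drop = FALSE]
  obs <- c(same = sum(d$category == "same"),
           target_younger = sum(d$category == "target_younger"),
           target_older = sum(d$category == "target_older"))
  obs["different"] <- obs[["target_younger"]] + obs[["target_older"]]
  set.seed(seed)
  tr <- d$target_rank; mr <- d$modifier_rank
  reps <- matrix(0L, n_reps, 4L,
                 dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_reps)) {
    perm <- .permute_no_self(d$target, d$modifier)
    pm <- mr[perm]
    same <- sum(tr == pm)
    younger <- sum(tr > pm)
    older <- sum(tr < pm)
    reps[i, ] <- c(same, younger, older, younger + older)
  }
  .null_distribution("free", n_reps, seed, obs, as.data.frame(reps))
}

#' Stratified permutation null preserving the category triple
#'
#' Randomizes modifier-target pairings while holding the numbers of
#' same-age, target-younger and target-older pairs fixed at their
#' observed values, so every replicate reproduces the observed category
#' triple exactly and only the age *distances* within each category can
#' vary. Admissible pairings are sampled by a transposition Markov chain
#' (the standard edge-swap sampler for constrained network nulls):
#' starting from the observed assignment, random swaps of the modifiers
#' of two pairs are proposed and accepted when neither pair becomes a
#' self-pair and the two pairs' category changes cancel, leaving the
#' global triple untouched. The chain continues across replicates;
#' `swaps_per_pair` x (number of pairs) proposals separate consecutive
#' replicates (and precede the first one as burn-in). Per replicate the
#' small and large jump counts (see [jump_profile()]), the large-jump
#' count among pairs whose modifier is older than the target, and the
#' mean age distance of those pairs are recorded.
#'
#' @inheritParams randomize_free
#' @param threshold jump threshold passed through (default 3).
#' @param swaps_per_pair proposed transpositions per pair between
#'   consecutive replicates of the swap chain (default 20).
#' @return a `null_distribution` with per-replicate columns `small`,
#'   `large`, `modifier_older_large` (large jumps among pairs with an
#'   older modifier) and `mean_delta_modifier_older`.
#' @export
randomize_stratified <- function(network, n_reps = 1000L, seed = 1L,
                                 threshold = 3L, swaps_per_pair = 20L) {
  stopifnot(inherits(network, "ptm_network"), n_reps >= 1L)
  d <- classify_pairs(network)
  d <- d[!d$self, , drop = FALSE]
  obs_jump <- c(small = sum(d$delta > 0 & d$delta < threshold),
                large = sum(d$delta >= threshold))
  # "modifier-older" pairs are those whose target is the younger member
  obs <- c(obs_jump,
           modifier_older_large = sum(d$category == "target_younger" &
                                        d$delta >= threshold),
           mean_delta_modifier_older =
             mean(d$delta[d$category == "target_younger"]))
  set.seed(seed)
  n <- nrow(d)
  tr <- d$target_rank
  mr0 <- d$modifier_rank
  # self-pair lookup: self_ok[i, j] TRUE when target i may hold modifier j
  self_ok <- outer(d$target, d$modifier, "!=")
  src <- seq_len(n)  # src[i]: index of the pair whose modifier pair i holds
  cur <- sign(tr - mr0[src])  # 0 same, +1 target younger, -1 target older
  step <- max(1L, swaps_per_pair) * n
  reps <- matrix(0, n_reps, 4L, dimnames = list(NULL, names(obs)))
  advance <- function() {
    a_all <- sample.int(n, step, replace = TRUE)
    b_all <- sample.int(n, step, replace = TRUE)
    for (k in seq_len(step)) {
      a <- a_all[k]; b <- b_all[k]
      if (a == b) next
      ma <- src[b]; mb <- src[a]
      if (!self_ok[a, ma] || !self_ok[b, mb]) next
      na_ <- sign(tr[a] - mr0[ma]); nb_ <- sign(tr[b] - mr0[mb])
      # the multiset of two sign codes is determined by (sum, product)
      if (na_ + nb_ != cur[a] + cur[b] || na_ * nb_ != cur[a] * cur[b]) next
      src[a] <<- ma; src[b] <<- mb
      cur[a] <<- na_; cur[b] <<- nb_
    }
  }
  advance()  # burn-in
  for (i in seq_len(n_reps)) {
    if (i > 1L) advance()
    mr_new <- mr0[src]
    delta <- abs(tr - mr_new)
    mod_older <- cur > 0L  # target younger than its modifier
    reps[i, ] <- c(sum(delta > 0 & delta < threshold),
                   sum(delta >= threshold),
                   sum(mod_older & delta >= threshold),
                   mean(delta[mod_older]))
  }
  .null_distribution("stratified", n_reps, seed, obs, as.data.frame(reps))
}

.null_distribution <- function(scheme, n_reps, seed, observed, replicates) {
  summ <- data.frame(statistic = names(observed),
                     observed = as.numeric(observed),
                     null_mean = colMeans(replicates),
                     null_sd = apply(replicates, 2, stats::sd),
                     row.names = NULL, stringsAsFactors = FALSE)
  p <- vapply(names(observed), function(s) {
    r_hi <- sum(replicates[[s]] >= observed[[s]])
    r_lo <- sum(replicates[[s]] <= observed[[s]])
    min(1, 2 * min(r_hi + 1, r_lo + 1) / (n_reps + 1))
  }, numeric(1))
  summ$p_empirical <- p
  structure(list(scheme = scheme, n_reps = n_reps, seed = seed,
                 observed = observed, replicates = replicates,
                 summary = summ),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(x$scheme, "permutation null,", x$n_reps, "replicates (seed",
      paste0(x$seed, "):\n"))
  print.data.frame(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
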