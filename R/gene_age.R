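#' Assign a gene age by the oldest-hit rule
#'
#' A gene is assigned to the age group of the most distant (lowest-rank)
#' organism in which a homolog was found. With `discount_isolated = TRUE`,
#' if the oldest rank is supported only by isolated-flagged presences
#' (possible horizontal transfers or artifacts, see
#' [flag_isolated_hits()]), the rule skips to the next-oldest rank with a
#' non-isolated presence and records that it did so.
#'
#' @param profile a `phylo_profile`.
#' @param gene gene (row) name; or use [assign_ages()] for all rows.
#' @param discount_isolated logical (default FALSE).
#' @return list with `gene`, `method = "oldest_hit"`, `rank`, `group`,
#'   `flags` (character vector; may contain `"used_isolated_hit"` or
#'   `"discounted_isolated_hit"`).
#' @export
assign_age_oldest_hit <- function(profile, gene, discount_isolated = FALSE) {
  stopifnot(inherits(profile, "phylo_profile"))
  tree <- profile$tree
  row <- profile$matrix[gene, ]
  if (sum(row) == 0L) stop("no homologs found for gene ", gene)
  iso <- profile$isolated[gene, ]
  ranks <- tree$group_rank[colnames(profile$matrix)]
  pres_ranks <- ranks[row == 1L]
  solid_ranks <- ranks[row == 1L & !iso]
  oldest <- min(pres_ranks)
  flags <- character(0)
  rank <- oldest
  if (any(iso[row == 1L] & ranks[row == 1L] == oldest)) {
    if (oldest %in% solid_ranks) {
      # isolated and solid support coexist at the oldest rank: keep it
    } else if (discount_isolated) {
      if (!length(solid_ranks))
        stop("gene ", gene, " has only isolated presences")
      rank <- min(solid_ranks)
      flags <- "discounted_isolated_hit"
    } else {
      flags <- "used_isolated_hit"
    }
  }
  list(gene = gene, method = "oldest_hit", rank = unname(rank),
       group = tree$scale$name[rank], flags = flags)
}

#' Assign ages to all genes of a profile
#'
#' Applies the oldest-hit rule, Dollo parsimony or Wagner parsimony to
#' every row of a profile and returns a tidy table.
#'
#' @param profile a `phylo_profile`.
#' @param method one of `"oldest_hit"`, `"dollo"`, `"wagner"`.
#' @param discount_isolated passed to [assign_age_oldest_hit()].
#' @param gain_cost,loss_cost passed to [wagner_reconstruct()].
#' @param reference reference organism for multi-gain Wagner ages.
#' @return data frame with columns `gene`, `method`, `rank`, `group`,
#'   `flags` (comma-joined).
#' @export
assign_ages <- function(profile, method = c("oldest_hit", "dollo", "wagner"),
                        discount_isolated = FALSE, gain_cost = 1,
                        loss_cost = 1, reference = "Hsa") {
  method <- match.arg(method)
  tree <- profile$tree
  rows <- rownames(profile$matrix)
  res <- lapply(rows, function(g) {
    if (method == "oldest_hit") {
      a <- assign_age_oldest_hit(profile, g, discount_isolated)
    } else {
      rec <- if (method == "dollo")
        dollo_reconstruct(tree, profile$matrix[g, ], gene = g)
      else
        wagner_reconstruct(tree, profile$matrix[g, ], gain_cost, loss_cost,
                           gene = g)
      a <- age_from_reconstruction(rec, tree, reference)
      a$flags <- character(0)
    }
    data.frame(gene = g, method = method, rank = a$rank, group = a$group,
               flags = paste(a$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cumulative emergence curves over the age scale
#'
#' For each stratum (all genes, one curve per functional tier, or one per
#' subnetwork) the curve gives the cumulative fraction of the stratum's
#' genes whose age rank is at most r, for r = 1..G. A gene belonging to
#' several tiers or subnetworks counts once in each stratum it belongs to.
#' Curves are normalised within-stratum, so each reaches 1 at the youngest
#' rank.
#'
#' @param ages data frame from [assign_ages()] (columns `gene`, `rank`).
#' @param annotations optional data frame with columns `gene` and either
#'   `tier` or `subnetwork` (multi-membership as repeated rows or
#'   comma-separated values).
#' @param scale an [age_scale()].
#' @param stratify_by `"none"`, `"tier"` or `"subnetwork"`.
#' @return data frame with columns `stratum`, `rank`, `group`,
#'   `cumulative_fraction`; non-decreasing in `rank` within stratum.
#' @export
emergence_curves <- function(ages, annotations = NULL,
                             scale = default_age_scale(),
                             stratify_by = c("none", "tier", "subnetwork")) {
  stratify_by <- match.arg(stratify_by)
  G <- nrow(scale)
  curve_of <- function(ranks) {
    counts <- tabulate(ranks, nbins = G)
    cumsum(counts) / length(ranks)
  }
  strata <- list()
  if (stratify_by == "none") {
    strata[["all"]] <- ages$rank
  } else {
    col <- stratify_by
    stopifnot(!is.null(annotations), all(c("gene", col) %in% names(annotations)))
    ann <- annotations
    # expand comma-separated multi-membership
    ann <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
      vals <- trimws(strsplit(ann[[col]][i], ",")[[1]])
      data.frame(gene = ann$gene[i], stratum = vals, stringsAsFactors = FALSE)
    }))
    for (s in unique(ann$stratum)) {
      gs <- unique(ann$gene[ann$stratum == s])
      rk <- ages$rank[ages$gene %in% gs]
      if (!length(rk)) {
        warning("stratum ", s, " has no aged genes; curve omitted")
        next
      }
      strata[[s]] <- rk
    }
  }
  out <- lapply(names(strata), function(s) {
    data.frame(stratum = s, rank = seq_len(G), group = scale$name,
               cumulative_fraction = curve_of(strata[[s]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
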