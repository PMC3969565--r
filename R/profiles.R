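#' Build a phylogenetic profile from an ortholog hit table
#'
#' A phylogenetic profile is a binary gene-by-species matrix recording in
#' which species a homolog of each gene was found. Cells are set from
#' scored bidirectional (reciprocal best) hits; the seed organism's own
#' column is always 1 for its seed genes.
#'
#' The hit table is a flattened export of pairwise ortholog searches with
#' columns `seed_gene`, `seed_species`, `target_species`, `hit_id`,
#' `score` (in \[0,1\]) and `bidirectional` (logical).
#'
#' @param hits data frame of ortholog hits (see Details).
#' @param genes character vector of seed genes defining the rows.
#' @param tree a [parse_species_tree()] `species_tree`; its leaves define
#'   the columns, ordered by (group rank, species code).
#' @param min_score minimum hit score for a presence call (default 0.05,
#'   the conventional confidence floor of scored reciprocal-hit output).
#' @param seed_species code of the seed organism (default `"Hsa"`).
#' @return An object of class `phylo_profile`: list with `matrix` (0/1,
#'   genes x species), `provenance` (character matrix: "direct",
#'   "transitive" or "absent"), `isolated` (logical matrix), `tree`.
#' @export
build_profile <- function(hits, genes, tree, min_score = 0.05,
                          seed_species = "Hsa") {
  stopifnot(inherits(tree, "species_tree"), length(genes) >= 1L)
  species <- tree$species[order(tree$group_rank[tree$species], tree$species)]
  mat <- matrix(0L, nrow = length(genes), ncol = length(species),
                dimnames = list(genes, species))
  if (nrow(hits)) {
    need <- c("seed_gene", "target_species", "score", "bidirectional")
    stopifnot(all(need %in% names(hits)))
    bad_sp <- setdiff(unique(hits$target_species), species)
    if (length(bad_sp))
      stop("unknown species in hit table: ", paste(bad_sp, collapse = ", "))
    unknown <- !(hits$seed_gene %in% genes)
    if (any(unknown)) {
      warning("skipping ", sum(unknown), " hits for genes not in the gene ",
              "list: ", paste(unique(hits$seed_gene[unknown]), collapse = ", "))
      hits <- hits[!unknown, , drop = FALSE]
    }
    keep <- hits$bidirectional & hits$score >= min_score
    h <- hits[keep, , drop = FALSE]
    if (nrow(h)) mat[cbind(h$seed_gene, h$target_species)] <- 1L
  }
  if (seed_species %in% species) mat[, seed_species] <- 1L
  prov <- matrix(ifelse(mat == 1L, "direct", "absent"),
                 nrow = nrow(mat), dimnames = dimnames(mat))
  structure(list(matrix = mat, provenance = prov,
                 isolated = matrix(FALSE, nrow(mat), ncol(mat),
                                   dimnames = dimnames(mat)),
                 tree = tree),
            class = "phylo_profile")
}

#' Extend a profile with transitive hits through secondary seed organisms
#'
#' When a gene has no direct hit in a distant species, a homolog may still
#' be recoverable through a well-studied intermediate: if the gene has a
#' bidirectional hit in a secondary seed organism, and that seed gene in
#' turn has a bidirectional hit in the distant species, the cell is filled
#' with provenance `"transitive"`. Existing presences are never altered.
#'
#' @param profile a `phylo_profile`.
#' @param secondary_hits named list of hit tables, one per secondary seed
#'   organism (names are species codes; each table has the same columns as
#'   in [build_profile()], with `seed_gene` in that organism's gene space).
#' @param links data frame with columns `gene` (row of the profile),
#'   `seed_species` and `seed_gene` naming the intermediate. A link is only
#'   honoured if `gene` is itself present in `seed_species` in the profile
#'   (i.e. the claimed bidirectional match exists); otherwise it is dropped
#'   with a warning.
#' @param min_score score threshold applied to the secondary hits.
#' @return the extended `phylo_profile`.
#' @export
apply_transitive_extension <- function(profile, secondary_hits, links,
                                       min_score = 0.05) {
  stopifnot(inherits(profile, "phylo_profile"),
            all(c("gene", "seed_species", "seed_gene") %in% names(links)))
  mat <- profile$matrix
  prov <- profile$provenance
  for (i in seq_len(nrow(links))) {
    g <- links$gene[i]; sd <- links$seed_species[i]; sg <- links$seed_gene[i]
    if (!g %in% rownames(mat)) next
    if (!sd %in% names(secondary_hits))
      stop("no secondary hit table for seed organism ", sd)
    if (!(sd %in% colnames(mat)) || mat[g, sd] != 1L) {
      warning("link ignored: ", g, " has no bidirectional hit in ", sd)
      next
    }
    h <- secondary_hits[[sd]]
    h <- h[h$seed_gene == sg & h$bidirectional & h$score >= min_score, ,
           drop = FALSE]
    for (s in intersect(unique(h$target_species), colnames(mat))) {
      if (mat[g, s] == 0L) {
        mat[g, s] <- 1L
        prov[g, s] <- "transitive"
      }
    }
  }
  profile$matrix <- mat
  profile$provenance <- prov
  profile
}

#' Flag isolated hits (possible horizontal transfer or artifacts)
#'
#' A presence supported by only a few species of one age group, far (in
#' rank) from the gene's other presences, is suspicious: it may reflect
#' horizontal gene transfer or a spurious match rather than vertical
#' descent. Such cells are flagged; the matrix itself is not changed.
#' Flags are advisory and consumed by the oldest-hit age rule via
#' `discount_isolated`.
#'
#' @param profile a `phylo_profile`.
#' @param max_group_support flag only if the cell's age group holds at most
#'   this many presences for the gene (default 1).
#' @param min_gap minimum rank distance to the nearest other age group with
#'   any presence (default 2).
#' @return the profile with its `isolated` matrix updated.
#' @export
flag_isolated_hits <- function(profile, max_group_support = 1L,
                               min_gap = 2L) {
  stopifnot(inherits(profile, "phylo_profile"),
            max_group_support >= 1L, min_gap >= 1L)
  tree <- profile$tree
  mat <- profile$matrix
  ranks <- tree$group_rank[colnames(mat)]
  iso <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (g in rownames(mat)) {
    pres <- mat[g, ] == 1L
    if (!any(pres)) next
    by_group <- tapply(pres, ranks, sum)
    pres_ranks <- as.integer(names(by_group)[by_group > 0L])
    if (length(pres_ranks) < 2L) next
    for (r in pres_ranks) {
      support <- by_group[[as.character(r)]]
      if (support > max_group_support) next
      gap <- min(abs(setdiff(pres_ranks, r) - r))
      if (gap >= min_gap)
        iso[g, pres & ranks == r] <- TRUE
    }
  }
  profile$isolated <- iso
  profile
}

#' Detect gene losses in target (model) organisms
#'
#' An absence in a species is evidence of loss -- rather than the gene never
#' having been there -- when the gene is present in at least one species of
#' a strictly older age group. For each target species, every such absence
#' is reported.
#'
#' @param profile a `phylo_profile`.
#' @param targets character vector of species codes to screen.
#' @return data frame with columns `gene`, `species`, `species_rank`,
#'   `oldest_present_rank`, `complete_genome`, `note`.
#' @export
detect_model_organism_losses <- function(profile, targets) {
  stopifnot(inherits(profile, "phylo_profile"))
  tree <- profile$tree
  bad <- setdiff(targets, tree$species)
  if (length(bad)) stop("unknown target species: ", paste(bad, collapse = ", "))
  mat <- profile$matrix
  ranks <- tree$group_rank[colnames(mat)]
  out <- list()
  for (s in targets) {
    rs <- tree$group_rank[[s]]
    for (g in rownames(mat)) {
      if (mat[g, s] != 0L) next
      oldest <- suppressWarnings(min(ranks[mat[g, ] == 1L]))
      if (is.finite(oldest) && oldest < rs) {
        out[[length(out) + 1L]] <- data.frame(
          gene = g, species = s, species_rank = rs,
          oldest_present_rank = oldest,
          complete_genome = unname(tree$complete[[s]]),
          note = if (tree$complete[[s]]) "loss in complete genome"
                 else "absence in draft genome",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), species = character(),
                      species_rank = integer(), oldest_present_rank = integer(),
                      complete_genome = logical(), note = character()))
  do.call(rbind, out)
}

#' @export
print.phylo_profile <- function(x, ...) {
  cat("Phylogenetic profile:", nrow(x$matrix), "genes x",
      ncol(x$matrix), "species;",
      sum(x$provenance == "transitive"), "transitive cells;",
      sum(x$isolated), "isolated flags\n")
  invisible(x)
}

# ---- TSV I/O --------------------------------------------------------------

#' Read an ortholog hit table TSV
#'
#' Header: `seed_gene seed_species target_species hit_id score bidirectional`
#' (tab-separated; `bidirectional` is true/false).
#'
#' @param path file path.
#' @return data frame of hits.
#' @export
read_hits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seed_gene", "seed_species", "target_species", "hit_id",
            "score", "bidirectional")
  if (!all(need %in% names(h)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  h$bidirectional <- as.logical(h$bidirectional)
  if (any(h$score < 0 | h$score > 1)) stop("hit scores must lie in [0,1]")
  h
}

#' Write / read a profile as TSV
#'
#' The matrix TSV has a first column `gene` then one 0/1 column per species;
#' a companion flags TSV (`<path>.flags.tsv`) lists `gene species flag` rows
#' for transitive and isolated cells.
#'
#' @param profile a `phylo_profile`.
#' @param path output path for the matrix TSV.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(gene = rownames(profile$matrix), profile$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx_t <- which(profile$provenance == "transitive", arr.ind = TRUE)
  idx_i <- which(profile$isolated, arr.ind = TRUE)
  flags <- rbind(
    data.frame(gene = rownames(profile$matrix)[idx_t[, 1]],
               species = colnames(profile$matrix)[idx_t[, 2]],
               flag = rep("transitive", nrow(idx_t))),
    data.frame(gene = rownames(profile$matrix)[idx_i[, 1]],
               species = colnames(profile$matrix)[idx_i[, 2]],
               flag = rep("isolated", nrow(idx_i))))
  utils::write.table(flags, paste0(path, ".flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param tree the `species_tree` the profile is defined on.
#' @export
read_profile <- function(path, tree) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "gene")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$gene
  prof <- structure(list(matrix = mat,
                         provenance = matrix(ifelse(mat == 1L, "direct",
                                                    "absent"),
                                             nrow(mat), dimnames = dimnames(mat)),
                         isolated = matrix(FALSE, nrow(mat), ncol(mat),
                                           dimnames = dimnames(mat)),
                         tree = tree),
                    class = "phylo_profile")
  fp <- paste0(path, ".flags.tsv")
  if (file.exists(fp)) {
    fl <- utils::read.delim(fp, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(fl))) {
      if (fl$flag[i] == "transitive")
        prof$provenance[fl$gene[i], fl$species[i]] <- "transitive"
      if (fl$flag[i] == "isolated")
        prof$isolated[fl$gene[i], fl$species[i]] <- TRUE
    }
  }
  prof
}
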