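#' Species tree with age-group mapping
#'
#' A species tree couples a rooted phylogeny (an [ape::read.tree()] `phylo`
#' object, binary or multifurcating) with the assignment of every leaf
#' species to exactly one age group on an [age_scale()]. Leaves carry a
#' three-letter species code, optionally a full species name and a genome
#' completeness flag.
#'
#' @param newick_text a Newick string (branch lengths, if present, are
#'   ignored by all downstream operations).
#' @param group_map data frame with columns `species` and `age_group`
#'   (full names or short labels of the scale), and optionally `full_name`
#'   and `complete` (logical; genome completely sequenced).
#' @param scale an [age_scale()]; defaults to [default_age_scale()].
#' @return An object of class `species_tree`: a list with elements
#'   `phylo` (the rooted tree), `species` (leaf codes, tree order),
#'   `group` (named character: species -> group name),
#'   `group_rank` (named integer), `full_name`, `complete`, `scale`.
#' @examples
#' gm <- data.frame(species = c("Hsa", "Mmu", "Dme"),
#'                  age_group = c("Mammalia", "Mammalia", "Bilateria"))
#' tr <- parse_species_tree("((Hsa,Mmu),Dme);", gm)
#' tr$group_rank[["Dme"]]  # 8
#' @export
parse_species_tree <- function(newick_text, group_map,
                               scale = default_age_scale()) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L,
            is.data.frame(group_map),
            all(c("species", "age_group") %in% names(group_map)))
  phy <- ape::read.tree(text = newick_text)
  if (is.null(phy)) stop("invalid Newick string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  unmapped <- setdiff(phy$tip.label, group_map$species)
  if (length(unmapped))
    stop("unknown species: ", paste(unmapped, collapse = ", "))
  m <- group_map[match(phy$tip.label, group_map$species), , drop = FALSE]
  rank <- age_rank(scale, m$age_group)
  # store canonical full names so labels and names agree downstream
  grp <- scale$name[rank]
  names(grp) <- names(rank) <- phy$tip.label
  full <- if ("full_name" %in% names(m)) m$full_name else m$species
  comp <- if ("complete" %in% names(m)) as.logical(m$complete)
          else rep(TRUE, nrow(m))
  names(full) <- names(comp) <- phy$tip.label
  structure(list(phylo = phy, species = phy$tip.label, group = grp,
                 group_rank = rank, full_name = full, complete = comp,
                 scale = scale),
            class = "species_tree")
}

#' Serialize a species tree
#'
#' Writes the topology as Newick and the leaf-to-group map as a data frame,
#' so that `parse_species_tree(write_species_tree(x)$newick, ...)` round-trips
#' the topology and group assignments.
#'
#' @param tree a `species_tree`.
#' @return list with `newick` (character) and `group_map` (data frame).
#' @export
write_species_tree <- function(tree) {
  stopifnot(inherits(tree, "species_tree"))
  list(newick = ape::write.tree(tree$phylo),
       group_map = data.frame(species = tree$species,
                              age_group = unname(tree$group[tree$species]),
                              full_name = unname(tree$full_name[tree$species]),
                              complete = unname(tree$complete[tree$species]),
                              stringsAsFactors = FALSE))
}

#' Read a species-to-group map from TSV
#'
#' Expects a header line `species<TAB>age_group` with optional extra columns
#' `full_name` and `complete`.
#'
#' @param path file path.
#' @return data frame usable as `group_map` in [parse_species_tree()].
#' @export
read_group_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "age_group") %in% names(gm)))
    stop("group map must have columns 'species' and 'age_group'")
  gm
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", length(x$species), "leaves,",
      length(unique(x$group)), "age groups\n")
  invisible(x)
}

#' Bundled 12-species example tree
#'
#' A ladder-topology tree with one species per age group of the default
#' scale plus a second early eukaryote, nested so that every age group is
#' monophyletic. Useful for examples, simulations and tests.
#'
#' @return a `species_tree` with 12 leaves covering all 11 groups.
#' @examples
#' tr <- fixture_tree()
#' table(tr$group_rank)
#' @export
fixture_tree <- function() {
  nw <- paste0("(Eco,((Ngr,Tbr),(Ath,(Ddi,(Sce,(Tad,(Nve,(Dme,",
               "(Cin,(Dre,Hsa))))))))));")
  gm <- data.frame(
    species = c("Eco", "Ngr", "Tbr", "Ath", "Ddi", "Sce",
                "Tad", "Nve", "Dme", "Cin", "Dre", "Hsa"),
    age_group = c("Prokaryota", "early Eukaryota", "early Eukaryota",
                  "Viridiplantae", "Unikonta", "Opisthokonta", "Metazoa",
                  "Radiata", "Bilateria", "Chordata", "Vertebrata",
                  "Mammalia"),
    full_name = c("Escherichia coli", "Naegleria gruberi",
                  "Trypanosoma brucei", "Arabidopsis thaliana",
                  "Dictyostelium discoideum", "Saccharomyces cerevisiae",
                  "Trichoplax adhaerens", "Nematostella vectensis",
                  "Drosophila melanogaster", "Ciona intestinalis",
                  "Danio rerio", "Homo sapiens"),
    complete = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  parse_species_tree(nw, gm)
}

# Internal tree helpers shared by parsimony and simulation ------------------

# children of each node as a list indexed by node id (1..Ntip+Nnode)
.tree_children <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    ch[[phy$edge[i, 1L]]] <- c(ch[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  ch
}

.tree_root <- function(phy) {
  setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
}

# internal nodes in postorder (children before parents)
.postorder_nodes <- function(phy) {
  ord <- ape::reorder.phylo(phy, "postorder")
  unique(ord$edge[, 1L])
}

# leaf tip indices below each node (list indexed by node id)
.tips_below <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  below <- vector("list", n)
  ch <- .tree_children(phy)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (nd in .postorder_nodes(phy))
    below[[nd]] <- sort(unlist(below[ch[[nd]]]))
  below
}

# MRCA of a set of tip indices (handles single tips and the root)
.mrca_node <- function(phy, tips) {
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(phy, tips)
}
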