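#' Run the full profile-to-report pipeline
#'
#' Executes, in order: profile construction (or loading), isolated-hit
#' flagging, gene clustering, age assignment by all three methods,
#' emergence curves, optional age enrichment, model-organism loss
#' detection, and the modification-network analysis. One TSV/JSON is
#' written per stage plus a run manifest (parameter echo, seed, per-stage
#' row counts). Stages whose inputs are not configured are skipped and
#' noted in the manifest.
#'
#' @param config either a path to a YAML file or a named list with
#'   entries: `tree` (Newick path), `groups` (group-map TSV), one of
#'   `hits` + `genes` (paths) or `profile` (profile TSV); optionally
#'   `annotations` (TSV: gene, tier, subnetwork), `background` (TSV:
#'   gene, rank), `ptm_pairs` (TSV), `loss_targets` (character vector),
#'   and parameters `min_score`, `gain_cost`, `loss_cost`,
#'   `discount_isolated`, `reps`, `seed`, `jump_threshold`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  p <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- p("seed", 1L)
  manifest <- list(package = "netage",
                   version = as.character(utils::packageVersion("netage")),
                   seed = seed,
                   parameters = config[setdiff(names(config),
                                               c("tree", "groups", "hits",
                                                 "genes", "profile",
                                                 "annotations", "background",
                                                 "ptm_pairs"))],
                   stages = list())
  note <- function(stage, status, rows = NA) {
    manifest$stages[[stage]] <<- list(status = status, rows = rows)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
      .write_manifest(manifest, out_dir)
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  tree <- run_stage("tree", {
    stopifnot(!is.null(config$tree), !is.null(config$groups))
    parse_species_tree(paste(readLines(config$tree), collapse = ""),
                       read_group_map(config$groups))
  })
  note("tree", "ok", length(tree$species))

  profile <- run_stage("profile", {
    if (!is.null(config$profile)) {
      read_profile(config$profile, tree)
    } else {
      stopifnot(!is.null(config$hits), !is.null(config$genes))
      build_profile(read_hits(config$hits),
                    readLines(config$genes), tree,
                    min_score = p("min_score", 0.05))
    }
  })
  profile <- flag_isolated_hits(profile)
  write_profile(profile, file.path(out_dir, "profile.tsv"))
  note("profile", "ok", nrow(profile$matrix))

  if (nrow(profile$matrix) >= 2L) {
    cl <- run_stage("cluster", cluster_genes(profile))
    utils::write.table(data.frame(position = seq_along(cl$gene_order),
                                  gene = cl$gene_order),
                       file.path(out_dir, "cluster_order.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("cluster", "ok", length(cl$gene_order))
  } else note("cluster", "skipped")

  ages <- run_stage("ages", {
    do.call(rbind, lapply(c("oldest_hit", "dollo", "wagner"), function(m)
      assign_ages(profile, m,
                  discount_isolated = p("discount_isolated", FALSE),
                  gain_cost = p("gain_cost", 1),
                  loss_cost = p("loss_cost", 1))))
  })
  utils::write.table(ages, file.path(out_dir, "ages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("ages", "ok", nrow(ages))

  ann <- NULL
  if (!is.null(config$annotations))
    ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
  curves <- run_stage("curves", {
    oh <- ages[ages$method == "oldest_hit", ]
    rbind(emergence_curves(oh, scale = tree$scale),
          if (!is.null(ann) && "tier" %in% names(ann))
            emergence_curves(oh, ann, tree$scale, "tier"),
          if (!is.null(ann) && "subnetwork" %in% names(ann))
            emergence_curves(oh, ann, tree$scale, "subnetwork"))
  })
  utils::write.table(curves, file.path(out_dir, "curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("curves", "ok", nrow(curves))

  if (!is.null(config$background)) {
    rep_ <- run_stage("enrichment", {
      bg <- utils::read.delim(config$background, stringsAsFactors = FALSE)
      names(bg)[names(bg) == "age_rank"] <- "rank"
      age_enrichment_report(ages[ages$method == "oldest_hit",
                                 c("gene", "rank")], bg, tree$scale)
    })
    utils::write.table(rep_$per_group,
                       file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("enrichment", "ok", nrow(rep_$per_group))
  } else note("enrichment", "skipped")

  targets <- p("loss_targets", character(0))
  if (length(targets)) {
    losses <- run_stage("losses",
                        detect_model_organism_losses(profile, targets))
    utils::write.table(losses, file.path(out_dir, "losses.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("losses", "ok", nrow(losses))
  } else note("losses", "skipped")

  if (!is.null(config$ptm_pairs)) {
    ptm <- run_stage("ptm", {
      net <- harmonize_ages(load_ptm_pairs(config$ptm_pairs, tree$scale))
      reps <- p("reps", 1000L)
      list(summary = summarize_network(net),
           jumps = as.list(jump_profile(net, p("jump_threshold", 3L))),
           free_null = randomize_free(net, reps, seed)$summary,
           stratified_null = randomize_stratified(
             net, reps, seed, p("jump_threshold", 3L))$summary)
    })
    jsonlite::write_json(ptm, file.path(out_dir, "ptm_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    note("ptm", "ok", ptm$summary$n_pairs_with_self)
  } else note("ptm", "skipped")

  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
}
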