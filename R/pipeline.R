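## Orchestration of the three analysis tracks with manifests and
## reproducible seeds. Tracks:
##   A "supernet-markers": amplicon alignment + binary marker table ->
##     splits -> filtered supernetwork (default min_supporting = 31,
##     strict greater);
##   B "supernet-loci": per-locus alignments -> curation -> per-locus MP
##     trees -> filtered supernetwork (presets 8 or 6) + pairwise
##     hybridization report + incongruence ratio;
##   C "mosaic": the population-mixing simulation;
##   plus "mjnet" (median-joining network) and "hybrid" (pair report only).

#' Named parameter presets for published-style runs
#'
#' `"retro-supernet"` (markers + amplicon splits, min_supporting 31,
#' strict), `"loci-21"` (min_supporting 8), `"loci-15"` (min_supporting 6),
#' `"figD"` (two populations, 1% outcrossing, 200 generations).
#'
#' @param name preset name.
#' @return named list of parameters.
#' @export
pipeline_preset <- function(name = c("retro-supernet", "loci-21", "loci-15",
                                     "figD")) {
  switch(match.arg(name),
         "retro-supernet" = list(min_supporting = 31L, strict_greater = TRUE),
         "loci-21" = list(min_supporting = 8L, strict_greater = FALSE),
         "loci-15" = list(min_supporting = 6L, strict_greater = FALSE),
         "figD" = list(k = 2L, c = 0.01, scheme = "symmetric-pair",
                       generations = 200L, N = 1000L, L = 20L,
                       replicates = 20L))
}

#' Run one analysis track end to end
#'
#' Validates the configuration, executes the selected track and writes its
#' artifacts plus a `manifest.json` (inputs, parameters, seeds, package
#' version; no timestamps, so re-runs are byte-identical) into `out_dir`.
#'
#' @param config named list. Common fields: `track` (one of `"mjnet"`,
#'   `"supernet-markers"`, `"supernet-loci"`, `"hybrid"`, `"mosaic"`),
#'   `out_dir`, `seed`. Track fields: `alignment` (FASTA path),
#'   `markers` (TSV path), `trees` (Newick path), `locus_dir` (directory of
#'   FASTA files), `min_supporting`, `strict_greater`, `runs`,
#'   `n_jumbles`, `bootstrap`, plus [sim_config()] fields for `"mosaic"`.
#' @return invisible list of in-memory results per step.
#' @export
run_track <- function(config) {
  tracks <- c("mjnet", "supernet-markers", "supernet-loci", "hybrid", "mosaic")
  if (is.null(config$track) || !config$track %in% tracks)
    stop("config error: track must be one of ", paste(tracks, collapse = ", "))
  if (is.null(config$out_dir)) stop("config error: out_dir required")
  needed <- switch(config$track,
                   "mjnet" = "alignment",
                   "supernet-markers" = c("alignment", "markers"),
                   "supernet-loci" = "locus_dir",
                   "hybrid" = "trees",
                   "mosaic" = character())
  for (f in needed) {
    if (is.null(config[[f]])) stop("config error: field '", f, "' required")
    if (!file.exists(config[[f]]))
      stop("config error: missing input file: ", config[[f]])
  }
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(config$track,
                "mjnet" = track_mjnet(config),
                "supernet-markers" = track_supernet_markers(config),
                "supernet-loci" = track_supernet_loci(config),
                "hybrid" = track_hybrid(config),
                "mosaic" = track_mosaic(config))
  manifest <- list(track = config$track, seed = config$seed,
                   inputs = config[needed],
                   parameters = config[setdiff(names(config),
                                               c("track", "out_dir", "seed",
                                                 needed))],
                   package = "emmernet",
                   version = as.character(utils::packageVersion("emmernet")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

track_mjnet <- function(config) {
  groups <- if (!is.null(config$groups)) read_groups(config$groups) else NULL
  aln <- read_alignment(config$alignment, groups = groups)
  aln <- curate_alignment(aln)
  haps <- collapse_haplotypes(aln)
  net <- median_joining(haps, epsilon = config$epsilon %||% 0L)
  ed <- net$edges
  ed$from <- rownames(net$states)[ed$from]
  ed$to <- rownames(net$states)[ed$to]
  utils::write.table(ed, file.path(config$out_dir, "mjnet_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(node = rownames(net$states),
                      observed = net$observed,
                      multiplicity = net$multiplicity)
  utils::write.table(nodes, file.path(config$out_dir, "mjnet_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(alignment = aln, haplotypes = haps, network = net)
}

track_supernet_markers <- function(config) {
  aln <- read_alignment(config$alignment)
  aln <- curate_alignment(aln)
  col_splits <- unlist(lapply(seq_len(ncol(aln)), function(j)
    tryCatch(split_from_column(aln, j), error = function(e) NULL)),
    recursive = FALSE)
  mm <- read_marker_matrix(config$markers)
  mk_splits <- splits_from_markers(mm)
  inputs <- c(col_splits, mk_splits)
  zs <- zclosure(inputs, runs = config$runs %||% 5L, seed = config$seed)
  params <- filter_params(config$min_supporting %||% 31L,
                          config$strict_greater %||% TRUE)
  filtered <- filter_splits(zs, inputs, params)
  write_splits_nexus(filtered, file.path(config$out_dir, "supernet.nex"))
  graph <- build_splits_graph(filtered)
  write_graph_text(graph, file.path(config$out_dir, "supernet_graph.tsv"))
  list(splits = zs, filtered = filtered, graph = graph)
}

track_supernet_loci <- function(config) {
  files <- sort(list.files(config$locus_dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  if (!length(files)) stop("config error: no FASTA files in locus_dir")
  locus_scores <- integer(length(files))
  trees <- list()
  alns <- list()
  for (i in seq_along(files)) {
    aln <- curate_alignment(read_alignment(files[i],
                                           locus = basename(files[i])))
    alns[[i]] <- aln
    mp <- mp_search(aln, n_jumbles = config$n_jumbles %||% 10L,
                    seed = config$seed + i)
    locus_scores[i] <- mp$score
    trees[[i]] <- if (length(mp$trees) > 1L) strict_consensus(mp$trees)
                  else mp$trees[[1L]]
  }
  ## concatenated matrix over the union of taxa (missing rows padded '?')
  all_taxa <- sort(unique(unlist(lapply(alns, rownames))))
  concat <- do.call(cbind, lapply(alns, function(a) {
    m <- matrix("?", length(all_taxa), ncol(a),
                dimnames = list(all_taxa, NULL))
    m[rownames(a), ] <- unclass(a)
    m
  }))
  concat <- seq_alignment(concat)
  mp_c <- mp_search(concat, n_jumbles = config$n_jumbles %||% 10L,
                    seed = config$seed)
  ratio <- incongruence_ratio(mp_c$score, locus_scores)
  zs <- zclosure(trees, runs = config$runs %||% 5L, seed = config$seed)
  params <- filter_params(config$min_supporting %||% 8L,
                          config$strict_greater %||% FALSE)
  filtered <- filter_splits(zs, trees, params)
  write_splits_nexus(filtered, file.path(config$out_dir, "supernet.nex"))
  rooted <- lapply(trees, function(tr)
    if (ape::is.rooted(tr)) tr else
      ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE))
  report <- pairwise_report(rooted, cap = config$cap %||% 8L)
  score_tab <- data.frame(locus = basename(files), score = locus_scores)
  utils::write.table(score_tab, file.path(config$out_dir, "locus_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("concatenated_score\t%d\nsum_locus_scores\t%d\nincongruence_ratio\t%.4f",
                     mp_c$score, sum(locus_scores), ratio),
             file.path(config$out_dir, "incongruence.tsv"))
  utils::write.table(report$pairs, file.path(config$out_dir, "pair_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(locus_scores = locus_scores, concat_score = mp_c$score,
       ratio = ratio, filtered = filtered, report = report)
}

track_hybrid <- function(config) {
  trees <- read_trees(config$trees, rooted = TRUE)
  report <- pairwise_report(trees, cap = config$cap %||% 8L)
  utils::write.table(report$pairs, file.path(config$out_dir, "pair_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("n_pairs\t%d\nn_conflicting\t%d\nmean_hybridizations\t%s",
                     report$n_pairs, report$n_conflicting,
                     format(report$mean_hybridizations)),
             file.path(config$out_dir, "hybrid_summary.tsv"))
  list(report = report)
}

track_mosaic <- function(config) {
  fields <- intersect(names(config),
                      c("k", "proportions", "N", "L", "c", "scheme",
                        "generations", "replicates"))
  cfg <- do.call(sim_config, c(config[fields], list(seed = config$seed)))
  tr <- simulate_mixing(cfg)
  tab <- data.frame(generation = seq_along(tr$mean_freq) - 1L,
                    mean_freq = tr$mean_freq,
                    mean_n_genotypes = tr$n_genotypes)
  utils::write.table(format(tab, digits = 10),
                     file.path(config$out_dir, "trajectory.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("final_generation\t%d\nfinal_mean_freq\t%.6f",
                     cfg$generations, tr$mean_freq[cfg$generations + 1L]),
             file.path(config$out_dir, "mosaic_summary.tsv"))
  list(trajectory = tr)
}

write_graph_text <- function(graph, path) {
  ed <- graph$edges
  ed$split_key <- vapply(graph$splits[ed$split], split_key, "")
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
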