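default_parameters <- function() {
  list(max_mismatch = 1L, fdr_threshold = 0.001, log2_threshold = 1,
       extreme_threshold = 10, cluster_k = 4L, alpha = 0.05)
}

#' Validate a pipeline configuration
#'
#' A configuration holds a `design` block (fields of [synthetic_design()]),
#' a `parameters` block (max_mismatch, fdr_threshold, log2_threshold,
#' extreme_threshold, cluster_k, alpha), an optional `comparisons` list of
#' `case`/`control` pairs (defaulting to the staged six) and an optional
#' `annotation` block (`n_terms`).  Unspecified fields take their defaults.
#'
#' @param config A list, or a path to a YAML file.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) return(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  design_args <- config$design %||% list()
  if (!is.null(design_args$gene_length_range))
    design_args$gene_length_range <- unlist(design_args$gene_length_range)
  if (!is.null(design_args$fold_change_range))
    design_args$fold_change_range <- unlist(design_args$fold_change_range)
  design <- do.call(synthetic_design, design_args)
  pars <- utils::modifyList(default_parameters(), config$parameters %||% list())
  for (nm in c("fdr_threshold", "extreme_threshold", "alpha")) {
    if (!is.numeric(pars[[nm]]) || pars[[nm]] <= 0)
      stopf("parameter %s must be positive", nm)
  }
  if (!is.numeric(pars$log2_threshold) || pars$log2_threshold < 0)
    stopf("parameter log2_threshold must be non-negative")
  if (!pars$max_mismatch %in% 0:2) stopf("max_mismatch must be 0, 1 or 2")
  if (!is_count(pars$cluster_k) || pars$cluster_k < 1)
    stopf("cluster_k must be a positive integer")
  cmp <- config$comparisons
  if (is.null(cmp)) {
    design_cmp <- default_comparisons(design$library_names)
  } else {
    design_cmp <- comparison_design(
      case = vapply(cmp, function(p) p$case, character(1)),
      control = vapply(cmp, function(p) p$control, character(1)))
    bad <- setdiff(unique(c(design_cmp$case, design_cmp$control)),
                   design$library_names)
    if (length(bad))
      stopf("comparison references undeclared library label: %s", bad[1L])
  }
  ann <- utils::modifyList(list(n_terms = 30L), config$annotation %||% list())
  structure(list(design = design, parameters = pars,
                 comparisons = design_cmp, annotation = ann),
            class = "pipeline_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full tag-DGE pipeline
#'
#' Orchestrates simulate -> clean -> map -> differential expression ->
#' screens -> clustering -> enrichment and writes every stage product under
#' `out_dir`: per-library raw and clean files with ledgers, the mapping
#' ledgers and raw-component tables, coverage profiles, per-comparison DE
#' tables with up/down counts, the intersection and extreme-ratio lists,
#' cluster assignments, enrichment tables, and a JSON manifest echoing the
#' package version, seed and parameters.  All randomness flows from the
#' design seed, so a rerun with the same configuration reproduces every
#' output byte for byte.
#'
#' @param config A [pipeline_config()], a config list, or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory bundle: reference, clean tables,
#'   mappings, expression matrix, DE results, intersection, profiles,
#'   extremes, clusters, enrichment, manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[tagdge] stage %s", name))
    tryCatch(expr, error = function(e) {
      stopf("stage %s failed: %s", name, conditionMessage(e))
    })
  }
  design <- cfg$design
  pars <- cfg$parameters

  sim <- stage("simulate", {
    sim <- simulate_experiment(design)
    ann <- simulate_annotation(sim$reference, n_terms = cfg$annotation$n_terms)
    sim_dir <- file.path(out_dir, "simulated")
    write_simulation(sim, sim_dir, annotation = ann)
    write_tsv(ann, file.path(sim_dir, "annotation.tsv"))
    c(sim, list(annotation = ann))
  })

  ctts <- stage("clean", {
    dir.create(file.path(out_dir, "clean"), showWarnings = FALSE)
    ctts <- lapply(sim$libraries, filter_raw_tags)
    for (ct in ctts)
      write_clean_tags(ct, file.path(out_dir, "clean",
                                     paste0(ct$library, ".clean.tsv")))
    write_tsv(report_raw_components(ctts),
              file.path(out_dir, "clean", "raw_components.tsv"))
    ctts
  })

  maps <- stage("map", {
    dir.create(file.path(out_dir, "mapping"), showWarnings = FALSE)
    index <- build_tag_index(sim$reference)
    maps <- lapply(ctts, map_tags, index = index,
                   max_mismatch = pars$max_mismatch)
    for (m in maps) {
      base <- file.path(out_dir, "mapping", m$library)
      write_tsv(data.frame(gene = names(m$counts), count = m$counts),
                paste0(base, ".counts.tsv"))
      jsonlite::write_json(c(list(library = m$library), as.list(m$ledger)),
                           paste0(base, ".ledger.json"), auto_unbox = TRUE)
      cov <- coverage_profile(m)
      write_tsv(cov$genes, paste0(base, ".coverage.tsv"))
    }
    write_tsv(report_mapping(maps),
              file.path(out_dir, "mapping", "mapping_summary.tsv"))
    maps
  })

  expr <- stage("expression", expression_matrix(maps))

  de <- stage("diffexp", {
    dir.create(file.path(out_dir, "dge"), showWarnings = FALSE)
    de <- call_de(expr, cfg$comparisons,
                  fdr_threshold = pars$fdr_threshold,
                  log2_threshold = pars$log2_threshold)
    for (nm in names(de$results))
      write_tsv(de$results[[nm]], file.path(out_dir, "dge",
                                            paste0(nm, ".tsv")))
    write_tsv(de_summary(de), file.path(out_dir, "dge", "summary.tsv"))
    de
  })

  screens <- stage("screen", {
    inter <- intersect_comparisons(de)
    writeLines(inter, file.path(out_dir, "dge", "intersection.txt"))
    prof <- NULL; ext <- list(up = character(0), down = character(0))
    clusters <- NULL
    if (length(inter)) {
      prof <- trend_profiles(de, inter)
      write_tsv(data.frame(gene = rownames(prof), prof, check.names = FALSE),
                file.path(out_dir, "dge", "trend_profiles.tsv"))
      ext <- screen_extremes(prof, threshold = pars$extreme_threshold)
      if (length(inter) >= pars$cluster_k) {
        clusters <- cluster_trends(prof, k = pars$cluster_k)
        write_tsv(data.frame(gene = names(clusters$groups),
                             group = clusters$groups),
                  file.path(out_dir, "dge", "clusters.tsv"))
      }
    }
    writeLines(ext$up, file.path(out_dir, "dge", "extreme_up.txt"))
    writeLines(ext$down, file.path(out_dir, "dge", "extreme_down.txt"))
    list(intersection = inter, profiles = prof, extremes = ext,
         clusters = clusters)
  })

  enr <- stage("enrich", {
    dir.create(file.path(out_dir, "enrich"), showWarnings = FALSE)
    res <- withCallingHandlers(
      enrich_terms(screens$intersection, sim$annotation,
                   alpha = pars$alpha),
      warning = function(w) {
        message("[tagdge] enrich: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_tsv(res, file.path(out_dir, "enrich", "enrichment.tsv"))
    res
  })

  manifest <- stage("manifest", {
    files <- sort(list.files(out_dir, recursive = TRUE))
    files <- setdiff(files, "manifest.json")
    man <- list(package = "tagdge",
                version = as.character(packageVersion("tagdge")),
                seed = design$seed,
                parameters = pars,
                design = unclass(design),
                comparisons = cfg$comparisons$comparison,
                n_intersection = length(screens$intersection),
                files = files)
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })

  invisible(list(config = cfg, reference = sim$reference,
                 libraries = sim$libraries, annotation = sim$annotation,
                 clean = ctts, mappings = maps, expression = expr,
                 de = de, intersection = screens$intersection,
                 profiles = screens$profiles, extremes = screens$extremes,
                 clusters = screens$clusters, enrichment = enr,
                 manifest = manifest))
}
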