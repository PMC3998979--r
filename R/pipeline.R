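#' Default pipeline configuration
#'
#' Full-default configuration list whose analysis parameters are the
#' conventional tag-DGE thresholds: one allowed mismatch, singleton
#' removal, FDR ceiling 0.001 with |log2 ratio| >= 1, expressed-in->=3-
#' libraries stage filter, and six clusters. Either provide input paths
#' (`reference`, `libraries`, `annotation`) or keep the `simulate` block to
#' generate everything synthetically.
#'
#' @param ... named overrides of top-level fields.
#' @return a `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(
      n_genes = 300L,
      genotypes = c("TM1", "IL1"),
      stages = c("15DPA", "20DPA", "25DPA"),
      library_depth = 2e4,
      de_fraction = 0.1,
      de_log2_effect = 2,
      dispersion = 0,
      error_rate = 0.01,
      n_terms = 20L
    ),
    reference = NULL, libraries = NULL, metadata = NULL, annotation = NULL,
    strands = "sense",
    min_count = 2L,           # singleton filter
    max_mismatch = 1L,
    min_libraries = 3L,       # stage filter
    expression_threshold = 0,
    log_pseudo = 1,
    fdr_max = 0.001,
    min_abs_log2 = 1,
    pseudo_tpm = 0.5,
    clustering = list(method = "sota", k = 6L, distance = "pearson"),
    out_dir = "tagdge_out"
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; missing fields take the [default_config()] values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

#' Write the default configuration template as YAML
#' @param path output file.
#' @export
write_config_template <- function(path) {
  yaml::write_yaml(unclass(default_config()), path)
  invisible(path)
}

#' Run the full tag-DGE pipeline
#'
#' simulate (or load) -> index -> clean/map -> matrix -> DEG comparisons ->
#' clustering -> enrichment. Writes every artifact as plain text under
#' `out_dir` plus a JSON manifest of parameters, seeds and output file
#' hashes; identical config and seed yield byte-identical outputs.
#'
#' Comparisons are every non-reference genotype versus the first genotype
#' at the same stage (the recipient-line convention).
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[tagdge] ", ...)

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    s <- config$simulate
    design <- synth_design(
      n_genes = s$n_genes, genotype_ids = s$genotypes, stage_ids = s$stages,
      library_depth = s$library_depth, de_fraction = s$de_fraction,
      de_log2_effect = s$de_log2_effect, dispersion = s$dispersion,
      error_rate = s$error_rate, seed = config$seed)
    sim <- simulate_experiment(design)
    reference <- sim$reference
    raw_libs <- sim$libraries
    metadata <- sim$metadata
    annotation <- make_annotation(reference, s$n_terms,
                                  seed = derive_seed(config$seed, "annotation"))
    write_reference(reference, file.path(out_dir, "reference.fasta"))
    for (id in names(raw_libs))
      write_tag_file(raw_libs[[id]], file.path(out_dir, paste0("library_", id, ".tsv")))
    write_annotation(annotation, file.path(out_dir, "annotation.tsv"))
    write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
    msg("simulated ", length(raw_libs), " libraries over ",
        length(reference), " genes")
  } else {
    if (is.null(config$reference) || is.null(config$libraries))
      .stopf("config needs 'reference' and 'libraries' paths (or a 'simulate' block)")
    reference <- read_reference(config$reference)
    raw_libs <- lapply(config$libraries, read_tag_file)
    names(raw_libs) <- vapply(raw_libs, `[[`, character(1), "library_id")
    metadata <- if (!is.null(config$metadata)) read_tsv(config$metadata) else NULL
    annotation <- if (!is.null(config$annotation))
      read_annotation(config$annotation) else NULL
  }

  # --- index ------------------------------------------------------------
  index <- build_index(reference, strands = config$strands)
  write_index_tsv(index, file.path(out_dir, "tag_index.tsv"))
  msg("indexed ", length(index$keys), " distinct tags over ",
      length(index$genes_touched), " genes")

  # --- clean, map, QC ----------------------------------------------------
  cleans <- lapply(raw_libs, clean_tags, min_count = config$min_count)
  mappings <- lapply(cleans, map_library, index = index,
                     max_mismatch = config$max_mismatch)
  qcs <- lapply(names(cleans), function(id)
    library_qc(cleans[[id]], mappings[[id]], length(reference)))
  write_qc_table(qcs, file.path(out_dir, "library_qc.tsv"))
  for (id in names(mappings))
    write_mapping_tsv(mappings[[id]], file.path(out_dir, paste0("expression_", id, ".tsv")))
  msg("mapped libraries: ",
      paste(vapply(qcs, function(q)
        sprintf("%s %.2f%%", q$library_id, q$pct_clean_mapped), character(1)),
        collapse = ", "))

  # --- matrix -----------------------------------------------------------
  mat <- assemble(unname(mappings), metadata)
  write_matrix_tsv(mat, file.path(out_dir, "tpm_matrix.tsv"),
                   metadata_path = file.path(out_dir, "library_metadata.tsv"))

  # --- differential -----------------------------------------------------
  comparisons <- list()
  if (!is.null(metadata)) {
    ref_geno <- metadata$genotype[1]
    for (i in which(metadata$genotype != ref_geno)) {
      a <- metadata$library_id[metadata$genotype == ref_geno &
                                 metadata$stage == metadata$stage[i]]
      if (length(a) != 1) next
      b <- metadata$library_id[i]
      cmp <- compare_libraries(mat, a, b, fdr_max = config$fdr_max,
                               min_abs_log2 = config$min_abs_log2,
                               pseudo_tpm = config$pseudo_tpm)
      comparisons[[cmp$label]] <- cmp
      write_comparison_tsv(cmp, file.path(out_dir, paste0("dge_", cmp$label, ".tsv")))
    }
    msg(length(comparisons), " comparisons, DEG counts: ",
        paste(vapply(comparisons, function(cmp)
          sprintf("%s=%d", cmp$label, cmp$n_up + cmp$n_down), character(1)),
          collapse = ", "))
    if (length(comparisons) >= 2) {
      cd <- common_degs(comparisons)
      write_tsv(data.frame(region = names(cd$sizes), n = unname(cd$sizes),
                           genes = vapply(cd$regions, paste, character(1),
                                          collapse = ",")),
                file.path(out_dir, "common_degs.tsv"))
    }
  }

  # --- clustering -------------------------------------------------------
  fit <- NULL
  if (!is.null(metadata)) {
    # the expressed-in->=k-libraries filter cannot exceed the number of
    # libraries any stage actually has
    min_libs <- min(config$min_libraries, max(table(metadata$stage)))
    if (min_libs < config$min_libraries)
      msg("stage filter lowered to ", min_libs, " (libraries per stage)")
    filtered <- stage_filter(mat, min_libs, config$expression_threshold)
    logm <- log_transform(filtered, config$log_pseudo)
    kk <- min(config$clustering$k, nrow(logm))
    fit <- if (identical(config$clustering$method, "hierarchical"))
      hier_cluster(logm, distance = config$clustering$distance, k = kk)
    else sota_cluster(logm, distance = config$clustering$distance,
                      max_clusters = kk,
                      seed = derive_seed(config$seed, "sota"))
    write_assignment_tsv(fit$assignment, file.path(out_dir, "clusters.tsv"))
    writeLines(as_newick(fit), file.path(out_dir, "cluster_tree.nwk"))
    summ <- cluster_profile_summary(fit$assignment, logm)
    write_tsv(data.frame(cluster = rownames(summ$profiles),
                         size = summ$sizes, summ$profiles,
                         check.names = FALSE),
              file.path(out_dir, "cluster_profiles.tsv"))
    msg("clustered ", nrow(logm), " genes into ", fit$k, " groups")
  }

  # --- enrichment -------------------------------------------------------
  if (!is.null(annotation) && length(comparisons) > 0) {
    amap <- annotation_map(annotation)
    for (cmp in comparisons) {
      degs <- deg_set(cmp)
      degs <- degs[degs %in% amap$universe]
      if (length(degs) == 0) next
      write_enrichment_tsv(enrich(degs, amap),
                           file.path(out_dir, paste0("enrichment_", cmp$label, ".tsv")))
    }
    if (!is.null(fit)) {
      prof <- cluster_function_profile(fit$assignment[names(fit$assignment) %in%
                                                        amap$universe], amap)
      for (k in names(prof))
        write_enrichment_tsv(prof[[k]],
                             file.path(out_dir, paste0("enrichment_cluster_", k, ".tsv")))
    }
  }

  # --- manifest ---------------------------------------------------------
  outputs <- sort(list.files(out_dir, full.names = FALSE))
  outputs <- setdiff(outputs, "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(hashes) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("tagdge")),
    seed = config$seed,
    parameters = unclass(config)[c("strands", "min_count", "max_mismatch",
                                   "min_libraries", "expression_threshold",
                                   "log_pseudo", "fdr_max", "min_abs_log2",
                                   "pseudo_tpm", "clustering")],
    outputs = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(index = index, qc = qcs, matrix = mat,
                 comparisons = comparisons, clustering = fit,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommand dispatcher for scripted use:
#' `tagdge_cli(c("all", "--config", "cfg.yaml", "--out", "results"))`.
#' Subcommands `simulate`, `index`, `map`, `matrix`, `dge`, `cluster`,
#' `enrich` all run the pipeline through the stage they name (stages are
#' cheap and deterministic, so re-running earlier ones keeps the driver
#' simple); `all` and `template` (writes a config YAML) complete the set.
#'
#' @param args character vector of arguments (default: the real command
#'   line).
#' @return exit status 0 invisibly on success.
#' @export
tagdge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: tagdge <simulate|index|map|matrix|dge|cluster|enrich|all|template> [--config FILE] [--out DIR] [--seed N]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", "tagdge_out")
  if (cmd == "template") {
    write_config_template(opt("--config", "tagdge_config.yaml"))
    return(invisible(0L))
  }
  cfg <- if (!is.null(opt("--config"))) read_pipeline_config(opt("--config"))
         else default_config()
  seed <- opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!cmd %in% c("simulate", "index", "map", "matrix", "dge", "cluster",
                  "enrich", "all")) {
    message(usage); return(invisible(1L))
  }
  run_pipeline(cfg, out_dir = out)
  invisible(0L)
}
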