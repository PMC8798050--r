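# One-shot pipeline wiring the stages into the inventory workflow:
# simulate or load -> supermatrix + QC -> distances -> clustering + sweep ->
# representatives -> (optional) backbone compliance -> diversity reports.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a 'simulate' block or an 'inputs' block")
  if (is.null(config$seed)) stop("config needs a 'seed'")
  config
}

run_stage <- function(name, log, expr) {
  log(paste0("stage: ", name))
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full inventory pipeline
#'
#' Executes the stages in order — simulate (or load), concatenate,
#' partition QC, distance matrix on the required fragment, mOTU clustering
#' at every configured threshold plus a threshold sweep, representative
#' selection, optional backbone-compliance check, and the diversity,
#' endemism and turnover reports — writing TSV/newick outputs, a decision
#' log, and a manifest of output checksums to `out_dir`.
#'
#' @param config list or YAML path. Required: `seed`, and either a
#'   `simulate` block (arguments to [sim_config()]) or an `inputs` block
#'   with `fragments` (named FASTA paths), `metadata` and `barriers` paths.
#'   Optional keys (defaults in parentheses): `thresholds` (0.02, 0.05),
#'   `sweep_grid` (1\%–10\% by 1\%), `min_overlap` (100), `method`
#'   ("single_linkage"), `rcfv_cutoff` (0.1), `symmetry_alpha` (0.05),
#'   `require_fragment` ("cox1"), `backbone` (newick path), `described`
#'   (TSV path with columns unit, described).
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results (`partitions`,
#'   `sweep`, `region_table`, `endemism`, `turnover`, `qc`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  dataset <- run_stage("load", log, {
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config,
                     c(config$simulate, list(seed = config$seed)))
      emit_dataset(cfg, dir = file.path(out_dir, "synthetic"))
    } else {
      frags <- lapply(config$inputs$fragments, read_alignment)
      md <- read_metadata(config$inputs$metadata)
      bars <- read_barrier_map(config$inputs$barriers)
      list(fragments = frags, metadata = md,
           config = list(barriers = bars))
    }
  })
  metadata <- dataset$metadata
  barriers <- dataset$config$barriers

  thresholds <- config$thresholds %||% c(0.02, 0.05)
  min_overlap <- config$min_overlap %||% 100
  method <- config$method %||% "single_linkage"
  require_fragment <- config$require_fragment %||% "cox1"
  log(sprintf("thresholds: %s; min_overlap: %d; method: %s",
              paste(thresholds, collapse = ", "), min_overlap, method))

  concat <- run_stage("concatenate", log,
                      concatenate_fragments(dataset$fragments))
  write_alignment(concat$alignment, file.path(out_dir, "supermatrix.fasta"))
  write_partition_scheme(concat$scheme,
                         file.path(out_dir, "partitions.txt"))

  qc <- run_stage("qc", log, {
    rep <- qc_report(concat$alignment, concat$scheme,
                     max_pairs = config$qc_max_pairs %||% 500)
    filter_partitions(rep, config$rcfv_cutoff %||% 0.1,
                      config$symmetry_alpha %||% 0.05)
  })
  log(paste("qc kept:", paste(qc$kept, collapse = ", "),
            "| dropped:", paste(qc$dropped, collapse = ", ")))

  frag_aln <- run_stage("distances", log, {
    aln <- dataset$fragments[[require_fragment]]
    if (is.null(aln)) stop("required fragment '", require_fragment,
                           "' not among inputs")
    aln
  })
  D <- distance_matrix(frag_aln, min_overlap = min_overlap)

  partitions <- run_stage("cluster", log, {
    ps <- lapply(thresholds, function(t) {
      if (method == "greedy") cluster_greedy(frag_aln, D, t)
      else cluster_single_linkage(D, t, aln = frag_aln)
    })
    names(ps) <- paste0("t", sub("^0\\.", "", format(thresholds)))
    ps
  })
  for (nm in names(partitions))
    log(sprintf("%s: %d mOTUs (%d counting only %s-bearing clusters)", nm,
                n_motus(partitions[[nm]]),
                count_motus(partitions[[nm]], metadata, require_fragment),
                require_fragment))

  sweep_tab <- run_stage("sweep", log, {
    grid <- config$sweep_grid %||% seq(0.01, 0.10, by = 0.01)
    threshold_sweep(D, grid, method = method, aln = frag_aln)
  })

  reps <- run_stage("representatives", log,
                    lapply(partitions, select_representatives,
                           aln = frag_aln))
  for (nm in names(reps))
    writeLines(reps[[nm]], file.path(out_dir,
                                     paste0("representatives_", nm, ".txt")))

  compliance <- NULL
  if (!is.null(config$backbone)) {
    compliance <- run_stage("compliance", log, {
      bb <- read_tree(config$backbone)
      bc <- backbone_constraint(bb, rownames(frag_aln))
      write_constraint(bc, file.path(out_dir, "constraint.nwk"))
      full <- neighbor_joining(D)
      check_backbone_compliance(full, bc)
    })
    log(paste("backbone compliant:", compliance$compliant))
  }

  described <- run_stage("described", log, {
    if (!is.null(config$described)) {
      utils::read.delim(config$described, stringsAsFactors = FALSE)
    } else if (!is.null(dataset$truth)) {
      # synthetic runs: "described" = true species per region
      occ <- unique(dataset$truth[, c("species", "region")])
      stats::aggregate(list(described = occ$species),
                       by = list(unit = occ$region), FUN = length)
    } else NULL
  })

  inv <- run_stage("inventory", log, {
    region_tab <- if (!is.null(described))
      aggregate_regions(partitions, metadata, described) else NULL
    endem <- endemism_table(partitions[[length(partitions)]], metadata,
                            level = "landmass")
    turn <- turnover(partitions[[length(partitions)]], metadata, barriers)
    list(region_table = region_tab, endemism = endem, turnover = turn)
  })

  tables <- list(sweep = sweep_tab, qc = qc$report,
                 endemism = inv$endemism$by_unit,
                 turnover_per_motu = inv$turnover$per_motu,
                 turnover_counts = data.frame(
                   barrier = names(inv$turnover$counts),
                   motus = as.integer(inv$turnover$counts)))
  if (!is.null(inv$region_table)) tables$region_table <- inv$region_table
  render_report(tables, out_dir)

  writeLines(log_lines, log_path)
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(partitions = partitions, sweep = sweep_tab,
                 region_table = inv$region_table, endemism = inv$endemism,
                 turnover = inv$turnover, qc = qc, compliance = compliance,
                 manifest = manifest))
}
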