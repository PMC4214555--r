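#' Pipeline run configuration
#'
#' Collects every threshold and mode flag of the end-to-end pipeline,
#' validated up front and serialized verbatim into the output directory
#' so each run records the parameters it used.
#'
#' @param out_dir Output directory for inputs, intermediates and reports.
#' @param simulate A [sim_config()] to generate synthetic inputs, or
#'   `NULL` to consume an existing input directory.
#' @param inputs_dir Directory holding inputs laid out as
#'   [write_simulation()] emits them (per-strain GFF3 and bedGraph,
#'   `ssu_alignment.fasta`, `homology.tsv`, optional
#'   `structure_flags.tsv`); defaults to `<out_dir>/inputs`.
#' @param min_depth Expression threshold (reads per base).
#' @param min_len,max_len,max_gap RUF caller parameters, nt.
#' @param thresholds A [class_thresholds()].
#' @param zone A [goldilocks_zone()], or `"derived"` to derive bounds
#'   from the RNA conserved-fraction curve.
#' @param domains Named vector mapping strains to `"Bacteria"` /
#'   `"Archaea"`; strains not listed default to Bacteria.
#' @param pool Pool datasets (sum depths) before calling and ranking.
#' @param strand_aware Strand-aware masking in the RUF caller.
#' @param resume Reuse intermediates already present in `out_dir`.
#' @param seed Seed recorded and used for any simulation.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, inputs_dir = NULL,
                       min_depth = 10, min_len = 50, max_len = 400,
                       max_gap = 10, thresholds = class_thresholds(),
                       zone = goldilocks_zone(), domains = NULL,
                       pool = FALSE, strand_aware = TRUE,
                       resume = FALSE, seed = 1L) {
  stopifnot(is.null(simulate) || inherits(simulate, "sim_config"),
            inherits(thresholds, "class_thresholds"),
            identical(zone, "derived") || inherits(zone, "goldilocks_zone"))
  if (is.null(inputs_dir)) inputs_dir <- file.path(out_dir, "inputs")
  structure(list(out_dir = out_dir, simulate = simulate,
                 inputs_dir = inputs_dir, min_depth = min_depth,
                 min_len = min_len, max_len = max_len, max_gap = max_gap,
                 thresholds = thresholds, zone = zone, domains = domains,
                 pool = pool, strand_aware = strand_aware,
                 resume = resume, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_inputs <- function(cfg) {
  dir <- cfg$inputs_dir
  gff <- list.files(dir, pattern = "\\.gff3$", full.names = TRUE)
  if (!length(gff)) stop("stage load-inputs: no GFF3 files in ", dir)
  annotations <- lapply(gff, read_annotation)
  names(annotations) <- vapply(annotations, `[[`, character(1), "strain_id")
  tracks <- lapply(names(annotations), function(st) {
    fwd <- list.files(dir, pattern = sprintf("^%s_.*_fwd\\.bedgraph$", st),
                      full.names = TRUE)
    if (!length(fwd)) stop("stage load-inputs: no bedGraph files for ", st)
    tks <- lapply(fwd, function(p) {
      ds <- sub("_fwd\\.bedgraph$", "", sub(sprintf("^%s_", st), "", basename(p)))
      prev <- sub("_fwd\\.bedgraph$", "_rev.bedgraph", p)
      read_depth(p, if (file.exists(prev)) prev,
                 genome_length = annotations[[st]]$genome_length,
                 strain_id = st, dataset_id = ds)
    })
    names(tks) <- vapply(tks, `[[`, character(1), "dataset_id")
    tks
  })
  names(tracks) <- names(annotations)
  homology <- read_tsv_report(file.path(dir, "homology.tsv"))
  flags_path <- file.path(dir, "structure_flags.tsv")
  structure_flags <- if (file.exists(flags_path)) read_tsv_report(flags_path)
                     else data.frame(group_id = character(), structured = logical())
  list(annotations = annotations, tracks = tracks,
       alignment = read_alignment(file.path(dir, "ssu_alignment.fasta")),
       homology = homology, structure_flags = structure_flags)
}

#' Assign RUF calls to homology groups by interval overlap
#'
#' Matches each distinct call to the homology-map interval of the same
#' strain and strand with the largest reciprocal overlap (at least 50%
#' of the longer interval); unmatched calls become singleton groups
#' named after the call.
#'
#' @param calls [call_rufs()] output, possibly many strains/datasets.
#' @param ruf_map Data frame with `family_id`, `strain_id`, `start`,
#'   `end`, `strand` rows for known RUF homologs (may have zero rows).
#' @return `calls` with a `group_id` column added.
#' @export
assign_ruf_homology <- function(calls, ruf_map) {
  calls$group_id <- sprintf("%s_ruf_%05d_%05d", calls$strain_id,
                            calls$start, calls$end)
  for (i in seq_len(nrow(calls))) {
    cand <- ruf_map[ruf_map$strain_id == calls$strain_id[i] &
                    (ruf_map$strand == calls$strand[i] |
                     calls$strand[i] == "both"), , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, calls$end[i]) - pmax(cand$start, calls$start[i])
    span <- pmax(cand$end - cand$start, calls$end[i] - calls$start[i])
    j <- which.max(ov / span)
    if (ov[j] / span[j] >= 0.5) calls$group_id[i] <- cand$family_id[j]
  }
  calls
}

stage_file <- function(cfg, name) file.path(cfg$out_dir, name)

run_stage <- function(cfg, outputs, fun) {
  paths <- vapply(outputs, stage_file, character(1), cfg = cfg)
  if (cfg$resume && all(file.exists(paths))) return(invisible(FALSE))
  fun(paths)
  invisible(TRUE)
}

#' Run the full comparative RNA-seq pipeline
#'
#' Orchestrates simulate (optional) -> RUF calling -> joint ranking ->
#' min-rank aggregation -> F84 distances -> family conservation ->
#' conserved-fraction curves and zone classification -> evidence
#' integration -> QC, writing every intermediate as TSV/JSON/PHYLIP
#' under `out_dir` and a machine-readable `summary.json` of headline
#' numbers. Deterministic given the configuration and seed; with
#' `resume = TRUE`, stages whose outputs already exist are skipped and
#' deleted intermediates are recomputed identically from their inputs.
#'
#' @param cfg A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_echo <- cfg
  cfg_echo$thresholds <- unclass(cfg$thresholds)
  if (!identical(cfg$zone, "derived")) cfg_echo$zone <- unclass(cfg$zone)
  if (!is.null(cfg$simulate)) cfg_echo$simulate <- unclass(cfg$simulate)
  yaml::write_yaml(unclass(cfg_echo), stage_file(cfg, "run_config.yaml"))

  if (!is.null(cfg$simulate) &&
      !(cfg$resume && file.exists(file.path(cfg$inputs_dir, "homology.tsv")))) {
    message("stage simulate: generating synthetic inputs")
    sim <- simulate_dataset(cfg$simulate)
    write_simulation(sim, cfg$inputs_dir)
    write_tsv_report(sim$ruf_groups[c("group_id", "structured")],
                     file.path(cfg$inputs_dir, "structure_flags.tsv"))
  }
  inp <- pipeline_inputs(cfg)
  strains <- names(inp$annotations)

  message("stage call-rufs: min_depth=", cfg$min_depth, " len=[",
          cfg$min_len, ",", cfg$max_len, "] max_gap=", cfg$max_gap,
          " pool=", cfg$pool, " strand_aware=", cfg$strand_aware)
  run_stage(cfg, "rufs.tsv", function(p) {
    calls <- do.call(rbind, lapply(strains, function(st) {
      tks <- inp$tracks[[st]]
      if (cfg$pool) tks <- list(pooled = pool_tracks(tks))
      do.call(rbind, lapply(tks, call_rufs, ann = inp$annotations[[st]],
                            min_depth = cfg$min_depth, min_len = cfg$min_len,
                            max_len = cfg$max_len, max_gap = cfg$max_gap,
                            strand_aware = cfg$strand_aware))
    }))
    ruf_map <- inp$homology[inp$homology$kind == "ruf" &
                            !is.na(inp$homology$start), , drop = FALSE]
    write_tsv_report(assign_ruf_homology(calls, ruf_map), p)
  })
  calls <- read_tsv_report(stage_file(cfg, "rufs.tsv"))

  message("stage rank: threshold=", cfg$min_depth)
  run_stage(cfg, "expression.tsv", function(p) {
    expr <- do.call(rbind, lapply(strains, function(st) {
      ann <- inp$annotations[[st]]
      here <- calls[calls$strain_id == st, , drop = FALSE]
      feats <- rbind(ann$features,
                     if (nrow(here)) {
                       rf <- ruf_features(here)
                       rf$family_id <- here$group_id[!duplicated(
                         here[c("strain_id", "start", "end", "strand")])]
                       rf
                     })
      expression_table(annotation_set(st, ann$genome_length, feats),
                       inp$tracks[[st]], threshold = cfg$min_depth,
                       pool = cfg$pool)
    }))
    write_tsv_report(expr, p)
  })
  expr <- read_tsv_report(stage_file(cfg, "expression.tsv"))

  run_stage(cfg, "aggregate.tsv", function(p)
    write_tsv_report(aggregate_min_rank(expr, cfg$thresholds), p))

  message("stage distances: F84 on ", length(inp$alignment), " SSU sequences")
  run_stage(cfg, "distances.phylip", function(p)
    write_distance_matrix(f84_distance_matrix(inp$alignment), p))
  dmat <- read_distance_matrix(stage_file(cfg, "distances.phylip"))

  run_stage(cfg, "conservation.tsv", function(p) {
    hom <- inp$homology
    gene_map <- hom[hom$kind != "ruf" & hom$present, , drop = FALSE]
    presence <- split(gene_map$strain_id, gene_map$family_id)
    expressed_calls <- calls[calls$median_depth >= cfg$min_depth, , drop = FALSE]
    ruf_presence <- split(expressed_calls$strain_id, expressed_calls$group_id)
    ruf_presence <- lapply(ruf_presence, unique)
    fam <- family_conservation(c(presence, ruf_presence), dmat, cfg$thresholds)
    kind <- gene_map$kind[match(fam$family_id, gene_map$family_id)]
    fam$family_class <- ifelse(is.na(kind), "ruf", kind)
    write_tsv_report(fam, p)
  })
  fam <- read_tsv_report(stage_file(cfg, "conservation.tsv"))

  message("stage goldilocks: zone=",
          if (identical(cfg$zone, "derived")) "derived"
          else sprintf("[%g, %g]", cfg$zone$d_min, cfg$zone$d_max))
  run_stage(cfg, c("curves.tsv", "zone.json", "pairs.tsv"), function(p) {
    grid <- sort(unique(c(0, fam$max_distance[is.finite(fam$max_distance)],
                          max(dmat[is.finite(dmat)]))))
    grid <- grid[grid >= 0]
    if (length(grid) < 2L) grid <- c(0, 1)
    curves <- do.call(rbind, lapply(split(fam, fam$family_class),
      function(x) {
        cv <- conserved_fraction_curve(x, grid)
        cbind(family_class = x$family_class[1L], as.data.frame(cv))
      }))
    write_tsv_report(curves, p[1L])
    zone <- if (identical(cfg$zone, "derived")) {
      rna <- fam[fam$family_class == "rna", , drop = FALSE]
      derived_zone(conserved_fraction_curve(rna, grid))
    } else cfg$zone
    domains <- cfg$domains
    if (is.null(domains))
      domains <- stats::setNames(rep("Bacteria", nrow(dmat)), rownames(dmat))
    pairs <- classify_pairs(dmat, domains, zone)
    jsonlite::write_json(
      list(d_min = zone$d_min, d_max = zone$d_max,
           n_pairs = nrow(pairs),
           n_too_hot = sum(pairs$zone_label == "too_hot"),
           n_goldilocks = sum(pairs$zone_label == "goldilocks"),
           n_too_cold = sum(pairs$zone_label == "too_cold")),
      p[2L], auto_unbox = TRUE, digits = NA)
    write_tsv_report(pairs, p[3L])
  })

  run_stage(cfg, c("evidence.tsv", "venn.json"), function(p) {
    groups <- unique(calls$group_id)
    expressed_calls <- calls[calls$median_depth >= cfg$min_depth, , drop = FALSE]
    n_strains <- vapply(groups, function(g)
      length(unique(expressed_calls$strain_id[expressed_calls$group_id == g])),
      integer(1))
    structured <- groups %in%
      inp$structure_flags$group_id[inp$structure_flags$structured]
    ev <- evidence_integration(data.frame(
      group_id = groups, conserved = n_strains >= 2L,
      structured = structured, expressed_elsewhere = n_strains >= 2L,
      stringsAsFactors = FALSE))
    write_tsv_report(ev$records, p[1L])
    jsonlite::write_json(c(as.list(ev$venn),
                           list(n_high_confidence = ev$n_high_confidence,
                                n_total = ev$n_total)),
                         p[2L], auto_unbox = TRUE, digits = NA)
  })

  message("stage qc")
  run_stage(cfg, "qc.tsv", function(p) {
    hom <- inp$homology
    core_prot <- utils::head(sort(unique(
      hom$family_id[hom$kind == "protein"])), 40L)
    core_rna <- utils::head(sort(unique(hom$family_id[hom$kind == "rna"])), 16L)
    qc <- do.call(rbind, lapply(strains, function(st)
      qc_report(inp$tracks[[st]], inp$annotations[[st]],
                core_prot, core_rna, min_depth = cfg$min_depth)))
    write_tsv_report(qc, p)
  })

  agg <- read_tsv_report(stage_file(cfg, "aggregate.tsv"))
  venn <- jsonlite::read_json(stage_file(cfg, "venn.json"), simplifyVector = TRUE)
  zone_info <- jsonlite::read_json(stage_file(cfg, "zone.json"),
                                   simplifyVector = TRUE)
  qc <- read_tsv_report(stage_file(cfg, "qc.tsv"))
  summary <- list(
    n_strains = length(strains),
    n_ruf_calls = nrow(calls),
    n_ruf_groups = length(unique(calls$group_id)),
    n_high_confidence = venn$n_high_confidence,
    zone = zone_info,
    n_families_ranked = nrow(agg),
    median_concordance = stats::median(qc$concordance, na.rm = TRUE),
    thresholds = unclass(cfg$thresholds),
    min_depth = cfg$min_depth, seed = cfg$seed)
  jsonlite::write_json(summary, stage_file(cfg, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
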