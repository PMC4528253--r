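#' Build or read a pipeline run configuration
#'
#' A run configuration names every input file and every tunable constant
#' of an end-to-end run. It can be written as a flat YAML file and read
#' back losslessly; command-line flags override file values.
#'
#' @param ptm path to the PTM record TSV (required).
#' @param alignment path to the aligned FASTA (required).
#' @param structure path to the target PDB (required).
#' @param functions optional known-function TSV.
#' @param disorder optional disorder TSV.
#' @param target_member alignment member the structure chain represents
#'   (default: first chain mapped to first member on validation).
#' @param chain_id structure chain to project onto.
#' @param family_id family label.
#' @param weights list of [fp_weights()] arguments.
#' @param probe_radius,n_points SASA parameters (see [sasa_atoms()]).
#' @param contact_cutoff interface cutoff in Angstrom.
#' @param group_by `"family"` or `"pooled"` ranking medians.
#' @param assume_terminal_disorder treat short unresolved terminal runs
#'   as disordered (see [residue_structure_info()]).
#' @param out_dir output directory.
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(ptm, alignment, structure, functions = NULL,
                       disorder = NULL, target_member = NULL,
                       chain_id = NULL, family_id = "family",
                       weights = list(), probe_radius = 1.4,
                       n_points = 960, contact_cutoff = 5.0,
                       group_by = "family",
                       assume_terminal_disorder = FALSE,
                       out_dir = "ptmfp_out") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file holding `run_config` fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  out <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("ptm", "alignment", "structure")) {
    if (is.null(cfg[[f]])) {
      stop("config field '", f, "' is required", call. = FALSE)
    }
  }
  paths <- c(ptm = cfg$ptm, alignment = cfg$alignment,
             structure = cfg$structure, functions = cfg$functions,
             disorder = cfg$disorder)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ",
         paste(names(missing), missing, sep = " = ", collapse = ", "),
         call. = FALSE)
  }
  if (!cfg$group_by %in% c("family", "pooled")) {
    stop("group_by must be 'family' or 'pooled'", call. = FALSE)
  }
  invisible(paths)
}

#' Run the full hotspot -> projection -> scoring -> statistics pipeline
#'
#' Executes every stage against the files named in the configuration and
#' writes the complete artifact set into `out_dir`: the hotspot table,
#' the scored and ranked FP table, known-vs-unknown separation reports
#' (for FP, total PTMs, relative SASA and PRC), the known-fraction
#' threshold curve, the colored structural projection (PDB + viewer
#' script + unmapped sidecar), and a JSON manifest with input checksums
#' and the configuration echo. Reruns on identical inputs produce
#' identical tables (the pipeline is deterministic).
#'
#' @param cfg a [run_config()] (or path to a YAML config).
#' @return the manifest, invisibly (list; element `paths` names every
#'   artifact, `ranking` holds the in-memory `fp_ranking`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  inputs <- validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- read_ptm_table(cfg$ptm) |>
    filter_ptms() |>
    deduplicate_ptms()
  if (!is.null(cfg$functions)) {
    records <- annotate_known_function(
      records, readr::read_tsv(cfg$functions, col_types = readr::cols(),
                               progress = FALSE))
  }

  alignment <- read_alignment(cfg$alignment, family_id = cfg$family_id)
  hotspots <- build_hotspots(records, alignment)

  model <- read_structure(cfg$structure)
  chain_id <- cfg$chain_id %||% model$atoms$chain[1]
  target_member <- cfg$target_member %||% names(alignment$members)[1]
  tmap <- map_alignment_to_structure(alignment, target_member, model,
                                     chain_id = chain_id)
  sasa_tbl <- shrake_rupley_sasa(model, chain_id = chain_id,
                                 probe_radius = cfg$probe_radius,
                                 n_points = cfg$n_points)
  iface <- detect_interface_residues(model,
                                     contact_cutoff = cfg$contact_cutoff)
  disorder <- if (!is.null(cfg$disorder)) read_disorder_tsv(cfg$disorder)
  weights <- do.call(fp_weights, as.list(cfg$weights))
  info <- residue_structure_info(
    alignment, tmap, sasa_tbl, interface_tbl = iface, disorder = disorder,
    burial_threshold = weights$burial_threshold,
    assume_terminal_disorder = isTRUE(cfg$assume_terminal_disorder))

  scored <- score_hotspots(hotspots, info, weights = weights)
  ranking <- rank_hotspots(scored, group_by = cfg$group_by)

  paths <- list(
    hotspots = file.path(cfg$out_dir, "hotspots.tsv"),
    fp = file.path(cfg$out_dir, "fp_scores.tsv"),
    separation = file.path(cfg$out_dir, "separation.json"),
    thresholds = file.path(cfg$out_dir, "threshold_curve.tsv"),
    manifest = file.path(cfg$out_dir, "manifest.json")
  )
  write_hotspot_table(hotspots, paths$hotspots)
  write_fp_table(ranking, paths$fp)

  sep <- NULL
  if (any(ranking$known_function) && any(!ranking$known_function)) {
    factors <- c(fp = "fp", total_ptms = "total_ptms",
                 relative_sasa = "relative_sasa", ptm_res_con = "PRC")
    sep <- purrr::imap(factors, function(col, lab) {
      unclass(separation_report(ranking, value = col,
                                known = known_function,
                                factor_label = lab))
    })
    jsonlite::write_json(sep, paths$separation, auto_unbox = TRUE,
                         digits = NA)
    readr::write_tsv(known_fraction_vs_threshold(ranking),
                     paths$thresholds, progress = FALSE)
  } else {
    message("single-class labels: separation reports skipped")
  }

  proj <- write_projection(model, tmap, hotspots,
                           file.path(cfg$out_dir, "projection"))
  paths <- c(paths, as.list(proj))

  manifest <- list(
    package = "ptmfp",
    version = as.character(utils::packageVersion("ptmfp")),
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    input_md5 = as.list(tools::md5sum(inputs)),
    n_records = nrow(records), n_hotspots = nrow(hotspots),
    n_scored = nrow(ranking),
    outputs = paths[vapply(paths, is.character, logical(1))]
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  manifest$paths <- paths
  manifest$ranking <- ranking
  manifest$separation <- sep
  invisible(manifest)
}
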