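# Replica orchestration: run every analysis on one trajectory, aggregate
# across replicas, and write deterministic CSV/PDB/JSON outputs. No metric is
# computed here; every number comes from a module operation.

# small stable fingerprint of the configuration, embedded in output headers
config_hash <- function(config) {
  cfg <- unclass(config)
  # hash only the analysis-relevant content: output location and directory
  # prefixes of the inputs must not change the fingerprint
  cfg$outdir <- NULL
  if (!is.null(cfg$reference)) cfg$reference <- basename(cfg$reference)
  if (length(cfg$replicas) > 0)
    cfg$replicas <- lapply(cfg$replicas, basename)
  txt <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                       digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

default_config <- function() {
  list(
    reference = NULL,
    replicas = list(),
    outdir = "barrelgate_out",
    dt_ns = 2,
    protein_chain = "A",
    backbone_names = list("CA"),
    gate = list(pairs = list(c(437L, 668L), c(433L, 666L), c(427L, 663L)),
                flank_resids = NULL,
                closure_threshold = 6),
    axis_point = c(0, 0, 0),
    lipid = NULL,       # list(resname, pa_name, pb_name, tail_names)
    membrane = NULL,    # list(resname)
    cutoffs = list(contact_cutoff = 4.0,
                   exit_threshold = 0.9,
                   gate_region_radius = 8.0,
                   tilt_bin_width = 2.5),
    seed = 1
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read (or build) a run configuration
#'
#' Loads a YAML configuration, fills unset fields with defaults, and checks
#' that all input paths resolve. Paths are interpreted relative to the
#' config file's directory.
#'
#' @param path YAML file; NULL returns the pure defaults (paths unchecked).
#' @return a `RunConfig` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: '", path, "'")
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
    root <- dirname(normalizePath(path))
    fix <- function(p) if (!is.null(p) && !file.exists(p))
      file.path(root, p) else p
    cfg$reference <- fix(cfg$reference)
    cfg$replicas <- lapply(cfg$replicas, fix)
    if (length(cfg$replicas) < 1)
      stop("config must name at least one replica trajectory")
    missing <- c(Filter(function(p) !file.exists(p), cfg$replicas),
                 if (!is.null(cfg$reference) &&
                     !file.exists(cfg$reference)) cfg$reference)
    if (length(missing) > 0)
      stop("input file(s) not found: ",
           paste(unlist(missing), collapse = ", "))
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Print a default configuration file
#'
#' Writes the full default configuration as YAML, so every threshold and
#' selection is inspectable and overridable.
#'
#' @param path output path, or "" for stdout.
#' @return invisibly, the YAML text.
#' @export
write_default_config <- function(path = "") {
  txt <- yaml::as.yaml(default_config())
  if (nzchar(path)) writeLines(txt, path) else cat(txt)
  invisible(txt)
}

write_metric_csv <- function(df, path, config, extra = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# barrelgate config_hash=%s", config_hash(config)),
               sprintf("# contact_cutoff_A=%g exit_threshold=%g gate_region_radius_A=%g tilt_bin_width_deg=%g closure_threshold_A=%g",
                       config$cutoffs$contact_cutoff,
                       config$cutoffs$exit_threshold,
                       config$cutoffs$gate_region_radius,
                       config$cutoffs$tilt_bin_width,
                       config$gate$closure_threshold),
               extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a metric CSV written by the pipeline
#' @param path CSV path.
#' @return data.frame (header comments skipped).
#' @export
read_metric_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

resolve_gate <- function(config) {
  gate_definition(pairs = lapply(config$gate$pairs, as.integer),
                  flank_resids = config$gate$flank_resids,
                  closure_threshold = config$gate$closure_threshold)
}

resolve_selection <- function(structure, label, ...) {
  idx <- withCallingHandlers(select_atoms(structure, ...),
                             warning = function(w) invokeRestart("muffleWarning"))
  if (length(idx) == 0)
    stop("selection '", label, "' resolved to no atoms; aborting")
  idx
}

#' Analyse one replica trajectory
#'
#' Runs every analysis stage the configuration enables on one trajectory and
#' writes the per-replica tables (RMSD, RMSF, aperture + summary + closure,
#' flicker, tilt + histogram, insertion, contact frequencies) under
#' `<outdir>/replica_<id>/`. Without a `lipid` section the lipid and contact
#' stages are skipped with a notice (the uncomplexed mode); without a
#' `membrane` section the flicker stage is skipped. Every output embeds the
#' config hash and the cutoffs in `#` header comments.
#'
#' @param config a `RunConfig`.
#' @param replica_id index into `config$replicas`.
#' @return a `ReplicaResult` list with the in-memory results and file paths.
#' @export
run_replica <- function(config, replica_id) {
  stopifnot(inherits(config, "RunConfig"))
  path <- config$replicas[[replica_id]]
  if (is.null(path) || !file.exists(path))
    stop("trajectory for replica ", replica_id, " not found")
  traj <- read_pdb(path)
  traj$times <- (seq_len(n_frames(traj)) - 1) * config$dt_ns
  tmpl <- traj$template
  refstruct <- if (!is.null(config$reference))
    as_structure(read_pdb(config$reference), 1) else as_structure(traj, 1)

  outdir <- file.path(config$outdir, sprintf("replica_%d", replica_id))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(df, name, extra = character(0)) {
    p <- file.path(outdir, paste0(name, ".csv"))
    write_metric_csv(df, p, config, extra)
    paths[[name]] <<- p
    p
  }

  backbone <- resolve_selection(tmpl, "backbone",
                                chain = config$protein_chain,
                                name = unlist(config$backbone_names))
  gate <- resolve_gate(config)
  if (is.null(gate$flank_resids) || length(gate$flank_resids) == 0)
    gate <- gate_definition(gate$pairs,
                            closure_threshold = gate$closure_threshold)

  res <- list(replica_id = replica_id, n_frames = n_frames(traj),
              gate = gate, config_hash = config_hash(config))

  res$rmsd <- rmsd_series(traj, backbone)
  emit(res$rmsd, "rmsd")
  res$rmsf <- rmsf_profile(traj, backbone)
  emit(res$rmsf, "rmsf")

  res$aperture <- suppressMessages(aperture_series(traj, gate))
  ap_long <- data.frame(
    frame = rep(seq_len(nrow(res$aperture$distances)),
                times = ncol(res$aperture$distances)),
    time_ns = rep(res$aperture$times %||% NA_real_,
                  times = ncol(res$aperture$distances)),
    pair = rep(colnames(res$aperture$distances),
               each = nrow(res$aperture$distances)),
    distance_A = as.vector(res$aperture$distances))
  emit(ap_long, "aperture")
  emit(res$aperture$summary, "aperture_summary")
  res$closure <- closure_report(res$aperture)
  emit(cbind(res$closure$fractions,
             threshold_A = res$closure$threshold_A,
             stayed_open = res$closure$stayed_open), "closure")

  plane <- fit_gate_plane(refstruct, gate$flank_resids,
                          as.numeric(config$axis_point))
  res$plane <- plane

  if (!is.null(config$membrane)) {
    membrane <- resolve_selection(tmpl, "membrane",
                                  resname = config$membrane$resname)
    flank_atoms <- ca_index(tmpl, gate$flank_resids)
    res$flicker <- flicker_depth_series(
      traj, plane, membrane, flank_atoms,
      gate_region_radius = config$cutoffs$gate_region_radius)
    emit(res$flicker, "flicker")
  } else {
    message("no membrane selection configured; flicker stage skipped")
  }

  if (!is.null(config$lipid)) {
    lp <- config$lipid
    pa <- resolve_selection(tmpl, "lipid PA", resname = lp$resname,
                            name = lp$pa_name)
    pb <- resolve_selection(tmpl, "lipid PB", resname = lp$resname,
                            name = lp$pb_name)
    tails <- lapply(lp$tail_names, function(nms)
      resolve_selection(tmpl, "lipid tail", resname = lp$resname,
                        name = unlist(nms)))
    lipid <- lipid_definition(pa[1], pb[1], tails)
    res$lipid <- lipid

    res$tilt <- tilt_series(traj, lipid,
                            bin_width = config$cutoffs$tilt_bin_width)
    emit(data.frame(frame = seq_along(res$tilt$angles),
                    time_ns = res$tilt$times %||% NA_real_,
                    tilt_deg = res$tilt$angles), "tilt")
    emit(res$tilt$histogram, "tilt_hist")

    res$insertion <- insertion_series(traj, lipid, plane)
    ins_long <- data.frame(
      frame = rep(seq_along(res$insertion$overall),
                  times = 1 + ncol(res$insertion$per_tail)),
      tail = rep(c("overall", colnames(res$insertion$per_tail)),
                 each = length(res$insertion$overall)),
      fraction = c(res$insertion$overall,
                   as.vector(res$insertion$per_tail)))
    emit(ins_long, "insertion",
         extra = "# insertion is the heavy-atom-count fraction past the oriented gate plane (atom-fraction proxy)")
    res$egress <- egress_order(res$insertion,
                               exit_threshold = config$cutoffs$exit_threshold)
    emit(res$egress$table, "egress")

    lipid_atoms <- heavy_atoms(tmpl,
                               resolve_selection(tmpl, "lipid",
                                                 resname = lp$resname))
    prot_map <- residue_atom_map(
      tmpl, resolve_selection(tmpl, "protein",
                              chain = config$protein_chain))
    res$contact_freq <- contact_frequencies(
      traj, lipid_atoms, prot_map,
      cutoff = config$cutoffs$contact_cutoff)
    emit(data.frame(resid = as.integer(names(res$contact_freq)),
                    replica_id = replica_id,
                    frequency = as.numeric(res$contact_freq)),
         "contacts")
  } else {
    message("no lipid configured (uncomplexed mode); ",
            "lipid and contact stages skipped")
  }

  res$paths <- paths
  class(res) <- c("ReplicaResult", "list")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate replica results
#'
#' Cross-replica aggregation mirroring the figure-panel structure: per-pair
#' mean aperture curves across replicas (replicas of unequal length are
#' truncated to the shortest, with a warning), the cross-replica
#' geometric-mean contact score table, and the reference structure annotated
#' with the scores in the B-factor column. All replicas must share one gate
#' definition.
#'
#' @param results list of `ReplicaResult`s.
#' @param config the `RunConfig` used for the replicas.
#' @param reference a `Structure` to annotate (default: re-read from
#'   `config$reference` or the first replica).
#' @return an `AggregateResult` list: `aperture_mean` (frames x pairs),
#'   `contact_table` (or NULL in uncomplexed mode), `annotated_path`,
#'   `n_replicas`, written files under `<outdir>/aggregate/`.
#' @export
aggregate_replicas <- function(results, config, reference = NULL) {
  if (length(results) < 1) stop("at least one replica result required")
  gates <- lapply(results, function(r)
    lapply(r$gate$pairs, as.integer))
  if (length(unique(vapply(gates, function(g)
    paste(unlist(g), collapse = ","), character(1)))) != 1)
    stop("mixed gate definitions across replicas")
  nfs <- vapply(results, function(r) nrow(r$aperture$distances), integer(1))
  nf <- min(nfs)
  if (length(unique(nfs)) > 1)
    warning("replicas differ in frame count (",
            paste(nfs, collapse = ", "), "); truncating to ", nf)

  outdir <- file.path(config$outdir, "aggregate")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  ap <- Reduce(`+`, lapply(results, function(r)
    r$aperture$distances[seq_len(nf), , drop = FALSE])) / length(results)
  ap_df <- data.frame(frame = seq_len(nf), ap, check.names = FALSE)
  write_metric_csv(ap_df, file.path(outdir, "aperture_mean.csv"), config)

  contact_table <- NULL
  annotated_path <- NULL
  have_contacts <- !vapply(results, function(r)
    is.null(r$contact_freq), logical(1))
  if (all(have_contacts)) {
    contact_table <- contact_score_table(
      lapply(results, function(r) r$contact_freq))
    write_metric_csv(contact_table,
                     file.path(outdir, "contact_scores.csv"), config)
    if (is.null(reference)) {
      ref_path <- config$reference %||% config$replicas[[1]]
      reference <- as_structure(read_pdb(ref_path), 1)
    }
    annotated <- annotate_scores(reference, contact_table)
    annotated_path <- file.path(outdir, "annotated.pdb")
    write_annotated_pdb(annotated, annotated_path)
  }

  manifest <- list(config_hash = config_hash(config),
                   n_replicas = length(results),
                   n_frames_used = nf,
                   replica_frames = as.list(nfs),
                   cutoffs = config$cutoffs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(aperture_mean = ap, contact_table = contact_table,
                 annotated_path = annotated_path,
                 n_replicas = length(results), outdir = outdir),
            class = c("AggregateResult", "list"))
}

#' Run the full pipeline from a configuration
#'
#' Convenience wrapper: [run_replica()] for every configured trajectory,
#' then [aggregate_replicas()].
#'
#' @param config a `RunConfig` or path to a YAML config file.
#' @return list with `replicas` (list of `ReplicaResult`) and `aggregate`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  results <- lapply(seq_along(config$replicas),
                    function(i) run_replica(config, i))
  agg <- aggregate_replicas(results, config)
  list(replicas = results, aggregate = agg)
}

#' Write a synthetic fixture bundle
#'
#' Emits the default synthetic study bundle: one multi-model PDB trajectory
#' and ground-truth JSON per replica, a reference PDB, and a ready-to-run
#' YAML configuration wired to the bundle. This is the corpus the pipeline
#' tests and the worked examples run on.
#'
#' @param dir output directory (created if needed).
#' @param seed base seed.
#' @param n_frames frames per replica.
#' @param n_replicas number of replicas (1..3).
#' @return path to the written config file.
#' @export
write_fixture_bundle <- function(dir, seed = 1, n_frames = 200,
                                 n_replicas = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec1 <- NULL
  gen1 <- NULL
  traj_paths <- character(n_replicas)
  for (r in seq_len(n_replicas)) {
    spec <- default_study_spec(replica = r, seed = seed,
                               n_frames = n_frames)
    gen <- generate_trajectory(spec, replica = r)
    traj_paths[r] <- file.path(dir, sprintf("traj_rep%d.pdb", r))
    write_trajectory_pdb(gen$trajectory, traj_paths[r])
    truth <- gen$truth
    truth$spec <- NULL
    truth$lipid <- NULL
    truth$gate <- NULL
    truth <- rapply(truth, unclass, how = "replace")
    truth$plane <- lapply(unclass(gen$truth$plane), as.numeric)
    jsonlite::write_json(
      truth, file.path(dir, sprintf("truth_rep%d.json", r)),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (r == 1) {
      spec1 <- spec
      gen1 <- gen
      write_annotated_pdb(gen$structure, file.path(dir, "reference.pdb"))
    }
  }
  lipid_names <- lapply(gen1$truth$lipid$tails, function(ti)
    gen1$structure$atoms$name[ti])
  cfg <- default_config()
  cfg$reference <- "reference.pdb"
  cfg$replicas <- as.list(basename(traj_paths))
  cfg$outdir <- "results"
  cfg$dt_ns <- spec1$dt_ns
  cfg$gate$flank_resids <- spec1$gate$flank_resids
  cfg$axis_point <- c(0, 0, toy_z_mid(spec1))
  cfg$lipid <- list(resname = "LPA", pa_name = "PA", pb_name = "PB",
                    tail_names = lipid_names)
  cfg$membrane <- list(resname = "MEM")
  cfg$seed <- seed
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
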