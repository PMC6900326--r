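#' Analysis configuration
#'
#' Collects every numeric convention of the workflow in one auditable place.
#' Defaults: hydrogen-bond cutoff 3.5 A, salt bridge 4.0 A, metal
#' coordination 3.0 A, pi-T window 4-7 A / 60-120 deg, water-site pairing
#' cutoff 1.8 A, conservation thresholds 90/60 percent, graph edge occupancy
#' floor 50 percent, frame interval 2 ps. Round-trips losslessly through
#' YAML via [write_config()] / [read_config()].
#'
#' @param input path to a multi-model PDB (optional if an ensemble is passed
#'   to [run_full_analysis()] directly).
#' @param fit_selection selection string for superposition.
#' @param water_names water residue names.
#' @param hbond_cutoff,salt_bridge_cutoff,metal_cutoff Angstrom.
#' @param pi_d_window,pi_angle_window numeric length-2 windows.
#' @param link_cutoff,min_occupancy_report,conserved_threshold,semi_threshold
#'   water-site clustering parameters (see [cluster_params()]).
#' @param occ_min graph hbond-edge occupancy floor, percent.
#' @param ligand_res ligand residue name(s); NULL disables ligand stages.
#' @param charged_amine ligand atom flagged "+" in path strings.
#' @param site_region optional selection restricting water-site detection;
#'   `"ligand"` means waters within `site_region_radius` of the ligand.
#' @param site_region_radius Angstrom.
#' @param torsions list of [torsion_spec()]s to track.
#' @param tracked_pairs data.frame (`label`, `atom_a`, `atom_b`) for the
#'   snapshot report.
#' @param snapshot_times_ps numeric snapshot times (ps).
#' @param path_source,path_targets node ids for recognition-path search.
#' @param metal_selection selection string for coordination detection.
#' @param frame_interval_ps,t0_ps trajectory timing metadata.
#' @param seed integer seed recorded in outputs.
#' @param output_dir directory for report files.
#' @return object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(input = NULL,
                            fit_selection = "backbone",
                            water_names = DEFAULT_WATER_NAMES,
                            hbond_cutoff = 3.5,
                            salt_bridge_cutoff = 4.0,
                            metal_cutoff = 3.0,
                            pi_d_window = c(4, 7),
                            pi_angle_window = c(60, 120),
                            link_cutoff = 1.8,
                            min_occupancy_report = 10,
                            conserved_threshold = 90,
                            semi_threshold = 60,
                            occ_min = 50,
                            ligand_res = c("LIG", "SRO", "NOR", "EPI"),
                            charged_amine = "N1",
                            site_region = NULL,
                            site_region_radius = 6,
                            torsions = NULL,
                            tracked_pairs = NULL,
                            snapshot_times_ps = NULL,
                            path_source = NULL,
                            path_targets = NULL,
                            metal_selection = "elem CU",
                            frame_interval_ps = 2,
                            t0_ps = 0,
                            seed = 1,
                            output_dir = "results") {
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Write / read an analysis configuration
#'
#' @param config an [analysis_config()].
#' @param path YAML file path.
#' @return `read_config` returns the `analysis_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- unclass(config)
  x$torsions <- lapply(x$torsions, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$torsions <- lapply(x$torsions, function(t) torsion_spec(t$label, t$atoms))
  if (length(x$torsions) == 0) x$torsions <- NULL
  if (!is.null(x$tracked_pairs))
    x$tracked_pairs <- as.data.frame(x$tracked_pairs,
                                     stringsAsFactors = FALSE)
  cfg <- do.call(analysis_config, x)
  cfg
}

# hash of the scientific configuration; where the outputs land is not part
# of the analysis identity
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  x <- unclass(config)
  x$output_dir <- NULL
  x$torsions <- lapply(x$torsions, unclass)
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

write_report_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hydronet %s config %s",
                     as.character(utils::packageVersion("hydronet")), hash),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis workflow
#'
#' align -> detect interactions -> cluster water sites -> occupancy ->
#' interaction graph -> recognition paths -> reports. Deterministic given
#' the inputs and configuration; every stage logs one line with its counts,
#' and every output file embeds the configuration hash.
#'
#' @param config an [analysis_config()].
#' @param ensemble optional [md_ensemble()]; when NULL, `config$input` is
#'   read.
#' @param verbose print one log line per stage.
#' @return (invisibly) list with `ensemble` (aligned), `events`,
#'   `occupancy`, `sites`, `graph`, `paths`, `rmsd`, `rmsf`, `torsions`,
#'   `report`, `files`, `config_hash`.
#' @export
run_full_analysis <- function(config = analysis_config(), ensemble = NULL,
                              verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out_file <- function(name) {
    p <- file.path(config$output_dir, name)
    files <<- c(files, p)
    p
  }

  if (is.null(ensemble)) {
    if (is.null(config$input)) stop("stage input: no ensemble and no input path")
    ensemble <- read_structure(config$input, water_names = config$water_names,
                               frame_interval = config$frame_interval_ps,
                               t0 = config$t0_ps)
  }
  say("input: %d frames, %d atoms in frame 1", n_frames(ensemble),
      nrow(ensemble$frames[[1]]$atoms))

  aligned <- align_ensemble(ensemble, config$fit_selection)
  say("align: fit selection '%s', mean fit_rmsd %.3f A",
      if (is.character(config$fit_selection)) config$fit_selection else "<sel>",
      mean(attr(aligned, "fit_rmsd")))

  rmsd <- rmsd_series(aligned, config$fit_selection)
  rmsf <- rmsf_per_residue(aligned, config$fit_selection)
  write_report_csv(as.data.frame(rmsd), out_file("rmsd.csv"), hash)
  write_report_csv(as.data.frame(rmsf), out_file("rmsf.csv"), hash)

  ev_h <- detect_events(aligned, "hbond", d_max = config$hbond_cutoff)
  ev_s <- detect_events(aligned, "salt_bridge",
                        d_max = config$salt_bridge_cutoff)
  has_metal <- length(select_idx(aligned$frames[[1]],
                                 config$metal_selection)) > 0
  ev_m <- if (has_metal)
    detect_events(aligned, "metal_coord",
                  metal_selection = config$metal_selection,
                  d_max = config$metal_cutoff)
  else NULL
  events <- rbind(ev_h, ev_s, ev_m)
  say("detect: %d hbond, %d salt-bridge, %d metal events",
      nrow(ev_h), nrow(ev_s), if (is.null(ev_m)) 0L else nrow(ev_m))
  write_report_csv(events, out_file("events.csv"), hash)

  occ <- occupancy(events, frame_range = seq_len(n_frames(aligned)))
  write_report_csv(occ, out_file("occupancy.csv"), hash)

  params <- cluster_params(link_cutoff = config$link_cutoff,
                           min_occupancy_report = config$min_occupancy_report,
                           conserved_threshold = config$conserved_threshold,
                           semi_threshold = config$semi_threshold)
  region <- config$site_region
  have_ligand <- !is.null(config$ligand_res) &&
    any(aligned$frames[[1]]$atoms$res_name %in% config$ligand_res)
  if (identical(region, "ligand"))
    region <- if (have_ligand)
      selection(res_name = config$ligand_res, oxygen_only_water = FALSE)
    else NULL
  sites <- cluster_water_sites(aligned, params, region = region,
                               region_radius = config$site_region_radius)
  say("waters: %d site(s) detected", length(sites))
  write_report_csv(as.data.frame(sites), out_file("water_sites.csv"), hash)

  graph <- build_graph(aligned, events, sites, occ_min = config$occ_min,
                       ligand_res = if (is.null(config$ligand_res)) character()
                                    else config$ligand_res,
                       charged_amine = config$charged_amine)
  say("graph: %d nodes, %d edges", igraph::vcount(graph),
      igraph::ecount(graph))
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("node_a", "node_b")
  write_report_csv(el, out_file("graph_edges.csv"), hash)

  paths <- NULL
  if (!is.null(config$path_source) && !is.null(config$path_targets) &&
      have_ligand) {
    paths <- find_path(graph, config$path_source, config$path_targets)
    if (paths$found) {
      say("path: %d hops: %s", paths$hops, format_path(paths))
      writeLines(c(sprintf("# hydronet config %s", hash), format_path(paths)),
                 out_file("path.txt"))
      jsonlite::write_json(
        list(config_hash = hash, nodes = paths$nodes, kinds = paths$kinds,
             hops = paths$hops, min_of_percent = paths$min_of_percent,
             n_water_sites = paths$n_water_sites),
        out_file("path.json"), auto_unbox = TRUE, digits = NA)
    } else say("path: no path found")
  } else if (is.null(config$path_source) || !have_ligand) {
    say("path: stage skipped (no ligand or no source/targets configured)")
  }

  torsions <- NULL
  if (!is.null(config$torsions) && have_ligand) {
    torsions <- lapply(config$torsions, function(ts)
      torsion_series(aligned, ts))
    names(torsions) <- vapply(config$torsions, `[[`, "", "label")
    tdf <- do.call(rbind, lapply(names(torsions), function(nm)
      cbind(label = nm, as.data.frame(torsions[[nm]]))))
    write_report_csv(tdf, out_file("torsions.csv"), hash)
  }

  report <- NULL
  if (!is.null(config$tracked_pairs) && !is.null(config$snapshot_times_ps)) {
    report <- tracked_report(aligned, events, config$tracked_pairs,
                             config$snapshot_times_ps)
    write_report_csv(report, out_file("tracked_report.csv"), hash)
  }

  invisible(list(ensemble = aligned, events = events, occupancy = occ,
                 sites = sites, graph = graph, paths = paths, rmsd = rmsd,
                 rmsf = rmsf, torsions = torsions, report = report,
                 files = files, config_hash = hash))
}

#' Waters of a single structure as individual sites
#'
#' For crystal-structure graphs (one frame), each water oxygen becomes its
#' own fully-occupied site labeled `W<res_seq>`, so water-mediated bridges
#' can be traced through named crystal waters.
#'
#' @param model a [structure_model()].
#' @return a `water_sites` object.
#' @export
waters_as_sites <- function(model) {
  w <- model$atoms[model$atoms$is_water & model$atoms$element == "O", ,
                   drop = FALSE]
  sites <- lapply(seq_len(nrow(w)), function(i) {
    list(site_id = paste0("W", w$res_seq[i]),
         centroid = c(w$x[i], w$y[i], w$z[i]),
         members = data.frame(frame = 1L, water_id = w$res_seq[i], dist = 0),
         occupancy = list(n_present = 1L, n_total = 1L, of_percent = 100),
         conservation_class = "conserved")
  })
  structure(sites, class = "water_sites", n_total = 1L,
            params = cluster_params())
}
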