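#' @title Ligand-to-metal recognition paths
#' @description Builds a typed interaction graph whose nodes are ligand
#'   atoms, protein residues, conserved water sites and metal ions, and finds
#'   minimal-hop recognition paths from a ligand atom to metal centers,
#'   including water-mediated routes (paths through water-site nodes).
#' @name recognition
NULL

title_case <- function(x) paste0(toupper(substr(x, 1, 1)),
                                 tolower(substr(x, 2, nchar(x))))

# map atom keys to graph node ids + display labels
node_of_key <- function(keys, ligand_res, site_lookup, frames,
                        charged_amine = "N1") {
  parts <- strsplit(keys, ":", fixed = TRUE)
  id <- character(length(keys)); label <- id; type <- id
  for (i in seq_along(parts)) {
    p <- parts[[i]]   # chain, res_name, res_seq, name
    if (p[2] %in% DEFAULT_WATER_NAMES) {
      sid <- site_lookup[[paste(frames[i], p[3])]]
      if (is.null(sid)) { id[i] <- NA_character_; next }
      id[i] <- sid; label[i] <- sid; type[i] <- "water_site"
    } else if (p[2] %in% ligand_res) {
      id[i] <- paste0("LIG:", p[4]); type[i] <- "ligand_atom"
      label[i] <- if (p[4] == charged_amine) paste0(p[4], "(+)") else p[4]
    } else if (is_metal_element(guess_element(p[4], p[2]))) {
      id[i] <- paste0(title_case(p[2]), p[3]); label[i] <- id[i]
      type[i] <- "metal"
    } else {
      id[i] <- paste0(title_case(p[2]), p[3]); label[i] <- id[i]
      type[i] <- "residue"
    }
  }
  data.frame(id = id, label = label, type = type, stringsAsFactors = FALSE)
}

#' Build the interaction graph of an analysed ensemble
#'
#' Nodes: every protein residue (side-chain atoms collapsed onto one residue
#' node), every metal ion, every atom of the ligand residue(s), and every
#' detected water site (individual waters are replaced by their site).
#' Edges: `covalent_adjacent` between residues with consecutive `res_seq` on
#' one chain; `hbond` edges from hydrogen-bond and salt-bridge events where
#' the node-pair occupation frequency is at least `occ_min` percent
#' (occupancy counted site-wise for water sites); `metal_coord` edges from
#' the coordination detector. Each edge carries its representative (mean)
#' distance and its occupancy.
#'
#' @param ensemble the analysed [md_ensemble()].
#' @param events combined events data.frame over the ensemble
#'   ([detect_events()] output, possibly rbind-ed across detectors).
#' @param sites a `water_sites` object from [cluster_water_sites()].
#' @param occ_min minimum O.F. (percent) for an hbond edge (default 50).
#' @param ligand_res residue name(s) of the ligand.
#' @param charged_amine ligand atom name displayed with a "(+)" mark.
#' @return an [igraph::igraph] with vertex attributes `name`, `label`,
#'   `type` and edge attributes `kind`, `distance`, `of_percent`.
#' @export
build_graph <- function(ensemble, events, sites, occ_min = 50,
                        ligand_res = c("LIG", "SRO", "NOR", "EPI"),
                        charged_amine = "N1") {
  nf <- n_frames(ensemble)
  f1 <- ensemble$frames[[1]]
  a <- f1$atoms

  # --- nodes ---------------------------------------------------------------
  prot <- a[!a$is_water & a$res_name %in% PROTEIN_RES, , drop = FALSE]
  resid <- unique(prot[, c("chain", "res_name", "res_seq")])
  res_nodes <- data.frame(id = paste0(title_case(resid$res_name), resid$res_seq),
                          label = paste0(title_case(resid$res_name), resid$res_seq),
                          type = "residue", stringsAsFactors = FALSE)
  met <- a[is_metal_element(a$element) & !a$is_water, , drop = FALSE]
  met_nodes <- if (nrow(met))
    data.frame(id = paste0(title_case(met$res_name), met$res_seq),
               label = paste0(title_case(met$res_name), met$res_seq),
               type = "metal", stringsAsFactors = FALSE)
  else NULL
  lig <- a[a$res_name %in% ligand_res, , drop = FALSE]
  lig_nodes <- if (nrow(lig))
    data.frame(id = paste0("LIG:", lig$name),
               label = ifelse(lig$name == charged_amine,
                              paste0(lig$name, "(+)"), lig$name),
               type = "ligand_atom", stringsAsFactors = FALSE)
  else NULL
  site_nodes <- if (length(sites))
    data.frame(id = vapply(sites, `[[`, "", "site_id"),
               label = vapply(sites, `[[`, "", "site_id"),
               type = "water_site", stringsAsFactors = FALSE)
  else NULL
  nodes <- unique(rbind(res_nodes, met_nodes, lig_nodes, site_nodes))

  # (frame, water_id) -> site id
  site_lookup <- list()
  for (s in sites)
    for (j in seq_len(nrow(s$members)))
      site_lookup[[paste(s$members$frame[j], s$members$water_id[j])]] <-
        s$site_id

  # --- edges ---------------------------------------------------------------
  edges <- list(); k <- 0
  add_edges <- function(df) { k <<- k + 1; edges[[k]] <<- df }

  if (nrow(resid) > 1) {
    resid <- resid[order(resid$chain, resid$res_seq), , drop = FALSE]
    adj <- which(diff(resid$res_seq) == 1 &
                   resid$chain[-nrow(resid)] == resid$chain[-1])
    if (length(adj))
      add_edges(data.frame(
        a = paste0(title_case(resid$res_name[adj]), resid$res_seq[adj]),
        b = paste0(title_case(resid$res_name[adj + 1]), resid$res_seq[adj + 1]),
        kind = "covalent_adjacent", distance = NA_real_, of_percent = 100,
        stringsAsFactors = FALSE))
  }

  if (!is.null(events) && nrow(events)) {
    ok_keys <- unique(unlist(lapply(ensemble$frames, model_keys)))
    bad <- setdiff(unique(c(events$atom_a, events$atom_b)), ok_keys)
    if (length(bad))
      stop("graph-consistency error: event atom ", bad[1],
           " absent from ensemble")
    na <- node_of_key(events$atom_a, ligand_res, site_lookup, events$frame,
                      charged_amine)
    nb <- node_of_key(events$atom_b, ligand_res, site_lookup, events$frame,
                      charged_amine)
    keep <- !is.na(na$id) & !is.na(nb$id) & na$id != nb$id
    ev <- data.frame(a = pmin(na$id[keep], nb$id[keep]),
                     b = pmax(na$id[keep], nb$id[keep]),
                     kind = ifelse(events$kind[keep] == "metal_coord",
                                   "metal_coord", "hbond"),
                     distance = events$distance[keep],
                     frame = events$frame[keep], stringsAsFactors = FALSE)
    if (nrow(ev)) {
      grp <- split(ev, paste(ev$kind, ev$a, ev$b))
      agg <- do.call(rbind, lapply(grp, function(g) data.frame(
        a = g$a[1], b = g$b[1], kind = g$kind[1],
        distance = mean(g$distance),
        of_percent = 100 * length(unique(g$frame)) / nf,
        stringsAsFactors = FALSE)))
      agg <- agg[agg$kind != "hbond" | agg$of_percent >= occ_min, ,
                 drop = FALSE]
      if (nrow(agg)) add_edges(agg)
    }
  }

  ed <- if (k) do.call(rbind, c(edges, list(make.row.names = FALSE))) else NULL
  if (!is.null(ed) && nrow(ed)) {
    # one edge per node pair: covalent > metal_coord > hbond
    pri <- c(covalent_adjacent = 1, metal_coord = 2, hbond = 3)
    ed <- ed[order(paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b)), pri[ed$kind]), ,
             drop = FALSE]
    pair <- paste(pmin(ed$a, ed$b), pmax(ed$a, ed$b))
    ofmax <- tapply(ed$of_percent, pair, max)
    ed <- ed[!duplicated(pair), , drop = FALSE]
    ed$of_percent <- as.numeric(ofmax[paste(pmin(ed$a, ed$b),
                                            pmax(ed$a, ed$b))])
    extra <- setdiff(unique(c(ed$a, ed$b)), nodes$id)
    if (length(extra))
      stop("graph-consistency error: edge endpoint ", extra[1],
           " is not a node")
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(ed)) data.frame(a = character(), b = character(),
                                kind = character(), distance = numeric(),
                                of_percent = numeric())
    else ed,
    directed = FALSE, vertices = nodes)
  g
}

#' Find a minimal-hop recognition path
#'
#' Breadth-first minimal-hop path from `source` to the nearest node of
#' `targets`. Among equal-hop paths the one with maximal minimum-edge
#' occupancy wins; remaining ties fall to the lexicographically smallest
#' node-id sequence, so results are deterministic.
#'
#' @param graph graph from [build_graph()].
#' @param source,targets node ids (e.g. `"LIG:N1"`, `"Cu3048"`).
#' @param max_hops optional hop bound.
#' @param required_kinds optional edge kinds the search is restricted to.
#' @param forbidden_kinds optional edge kinds removed before the search.
#' @return object of class `path_result`: `found`, `nodes`, `labels`,
#'   `kinds` (edge kinds), `hops`, `min_of_percent`, `n_water_sites`.
#' @export
find_path <- function(graph, source, targets, max_hops = NULL,
                      required_kinds = NULL, forbidden_kinds = NULL) {
  vn <- igraph::V(graph)$name
  if (!source %in% vn) stop("argument error: source node not in graph: ", source)
  if (!length(targets)) stop("argument error: empty target set")
  missing_t <- setdiff(targets, vn)
  if (length(missing_t))
    stop("argument error: target node not in graph: ", missing_t[1])

  g <- graph
  drop <- logical(igraph::ecount(g))
  if (!is.null(forbidden_kinds))
    drop <- drop | igraph::E(g)$kind %in% forbidden_kinds
  if (!is.null(required_kinds))
    drop <- drop | !(igraph::E(g)$kind %in% required_kinds)
  if (any(drop)) g <- igraph::delete_edges(g, which(drop))

  no_path <- structure(list(found = FALSE, nodes = character(),
                            labels = character(), kinds = character(),
                            hops = NA_integer_, min_of_percent = NA_real_,
                            n_water_sites = NA_integer_),
                       class = "path_result")
  if (source %in% targets)
    return(path_result_from_nodes(g, source))

  d <- igraph::distances(g, v = source, to = targets)
  if (all(!is.finite(d))) return(no_path)
  best <- min(d)
  if (!is.null(max_hops) && best > max_hops) return(no_path)
  best_targets <- targets[d[1, ] == best]
  cand <- list()
  for (tg in best_targets) {
    ps <- igraph::all_shortest_paths(g, from = source, to = tg)$vpaths
    cand <- c(cand, lapply(ps, function(p) igraph::as_ids(p)))
  }
  score <- vapply(cand, function(nodes) min(path_edge_of(g, nodes)), numeric(1))
  cand <- cand[score == max(score)]
  seqs <- vapply(cand, function(nodes) paste(nodes, collapse = "\r"),
                 character(1))
  path_result_from_nodes(g, cand[[order(seqs)[1]]])
}

path_edge_of <- function(g, nodes) {
  if (length(nodes) < 2) return(100)
  vapply(seq_len(length(nodes) - 1), function(i) {
    e <- igraph::get_edge_ids(g, c(nodes[i], nodes[i + 1]))
    igraph::E(g)$of_percent[e]
  }, numeric(1))
}

path_result_from_nodes <- function(g, nodes) {
  kinds <- if (length(nodes) < 2) character() else
    vapply(seq_len(length(nodes) - 1), function(i) {
      e <- igraph::get_edge_ids(g, c(nodes[i], nodes[i + 1]))
      igraph::E(g)$kind[e]
    }, character(1))
  labs <- igraph::V(g)$label[match(nodes, igraph::V(g)$name)]
  types <- igraph::V(g)$type[match(nodes, igraph::V(g)$name)]
  structure(list(found = TRUE, nodes = nodes, labels = labs, kinds = kinds,
                 hops = length(kinds),
                 min_of_percent = min(path_edge_of(g, nodes)),
                 n_water_sites = sum(types == "water_site"),
                 types = types),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) cat("<path_result> no path\n")
  else cat(sprintf("<path_result> %d hop(s): %s\n", x$hops, format_path(x)))
  invisible(x)
}

#' Format a recognition path as a human-readable chain
#'
#' Non-covalent steps (hydrogen bonds, and any step through a water site)
#' are joined with an ellipsis, covalent adjacency and metal coordination
#' with a hyphen, mirroring the conventional
#' `N1(+)...Asp1025-His1026-Cu3052-...` notation.
#'
#' @param path a `path_result` with `found = TRUE`.
#' @return single string.
#' @export
format_path <- function(path) {
  stopifnot(inherits(path, "path_result"), isTRUE(path$found))
  if (!length(path$kinds)) return(path$labels[1])
  seps <- vapply(seq_along(path$kinds), function(i) {
    water_step <- path$types[i] == "water_site" ||
      path$types[i + 1] == "water_site"
    if (path$kinds[i] == "hbond" || water_step) "…" else "-"
  }, character(1))
  paste0(path$labels[1],
         paste0(seps, path$labels[-1], collapse = ""))
}
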