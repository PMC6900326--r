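# Independent oracles and fixture builders used across the suite. The
# oracles are deliberately naive (double loops, exhaustive enumeration) and
# share no code with the package implementation they check.

# plain double-loop hydrogen-bond scan
oracle_hbonds <- function(model, table = default_donor_acceptor_table(),
                          d_max = 3.5) {
  a <- model$atoms
  roles <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$is_water[i] && a$element[i] == "O") { roles[i] <- "both"; next }
    hit <- which(table$atom_name == a$name[i] &
                   (table$res_name == a$res_name[i] |
                      (table$res_name == "*" &
                         a$res_name[i] %in% hydronet:::PROTEIN_RES) |
                      (table$res_name == "*L" &
                         !(a$res_name[i] %in% hydronet:::PROTEIN_RES) &
                         !a$is_water[i] &
                         !hydronet:::is_metal_element(a$element[i]))))
    if (length(hit)) {
      specific <- hit[!(table$res_name[hit] %in% c("*", "*L"))]
      roles[i] <- table$role[if (length(specific)) specific[1] else hit[1]]
    }
  }
  keys <- hydronet:::model_keys(model)
  bb <- c("N", "CA", "C", "O")
  out <- list(); k <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (i >= j) next
    ri <- roles[i]; rj <- roles[j]
    ok <- (ri %in% c("donor", "both") && rj %in% c("acceptor", "both")) ||
      (rj %in% c("donor", "both") && ri %in% c("acceptor", "both"))
    if (!ok) next
    if (!a$is_water[i] && !a$is_water[j] &&
        a$chain[i] == a$chain[j] && a$res_seq[i] == a$res_seq[j]) next
    if (a$chain[i] == a$chain[j] && abs(a$res_seq[i] - a$res_seq[j]) == 1 &&
        a$name[i] %in% bb && a$name[j] %in% bb) next
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
    if (d <= d_max) {
      k <- k + 1
      pair <- sort(c(keys[i], keys[j]))
      out[[k]] <- data.frame(atom_a = pair[1], atom_b = pair[2], distance = d)
    }
  }
  if (!k) return(data.frame(atom_a = character(), atom_b = character(),
                            distance = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$atom_a, res$atom_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_salt_bridges <- function(model, d_max = 4.0) {
  a <- model$atoms
  keys <- hydronet:::model_keys(model)
  acid <- (a$res_name == "ASP" & a$name %in% c("OD1", "OD2")) |
    (a$res_name == "GLU" & a$name %in% c("OE1", "OE2"))
  base <- (a$res_name == "LYS" & a$name == "NZ") |
    (a$res_name == "ARG" & a$name %in% c("NE", "NH1", "NH2"))
  out <- list(); k <- 0
  for (i in which(acid)) for (j in which(base)) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
    if (d <= d_max) {
      k <- k + 1
      pair <- sort(c(keys[i], keys[j]))
      out[[k]] <- data.frame(atom_a = pair[1], atom_b = pair[2], distance = d)
    }
  }
  if (!k) return(data.frame(atom_a = character(), atom_b = character(),
                            distance = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$atom_a, res$atom_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_metal <- function(model, d_max = 3.0) {
  a <- model$atoms
  keys <- hydronet:::model_keys(model)
  met <- which(a$element == "CU")
  lig <- which(a$element %in% c("N", "O", "S"))
  out <- list(); k <- 0
  for (i in met) for (j in lig) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
    if (d <= d_max) {
      k <- k + 1
      pair <- sort(c(keys[i], keys[j]))
      out[[k]] <- data.frame(atom_a = pair[1], atom_b = pair[2], distance = d)
    }
  }
  if (!k) return(data.frame(atom_a = character(), atom_b = character(),
                            distance = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$atom_a, res$atom_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# reduce package events to the oracle's (atom_a, atom_b, distance) shape
event_pairs <- function(ev) {
  out <- ev[, c("atom_a", "atom_b", "distance")]
  out <- out[order(out$atom_a, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random small model mixing protein-like residues, waters and a copper
random_model <- function(n = 100, seed = 1, box = 12) {
  set.seed(seed)
  cast <- list(
    list(res = "ASP", atoms = c("N", "CA", "C", "O", "OD1", "OD2")),
    list(res = "GLU", atoms = c("N", "CA", "C", "O", "OE1", "OE2")),
    list(res = "LYS", atoms = c("N", "CA", "C", "O", "NZ")),
    list(res = "ARG", atoms = c("N", "CA", "C", "O", "NE", "NH1", "NH2")),
    list(res = "SER", atoms = c("N", "CA", "C", "O", "OG")),
    list(res = "ALA", atoms = c("N", "CA", "C", "O")))
  rows <- list(); k <- 0; res_seq <- 0
  while (k < n - 3) {
    res_seq <- res_seq + 1
    cc <- cast[[sample.int(length(cast), 1)]]
    for (nm in cc$atoms) {
      k <- k + 1
      rows[[k]] <- data.frame(name = nm, res_name = cc$res, res_seq = res_seq,
                              chain = "A", x = runif(1, 0, box),
                              y = runif(1, 0, box), z = runif(1, 0, box),
                              stringsAsFactors = FALSE)
    }
  }
  rows[[k + 1]] <- data.frame(name = "CU", res_name = "CU", res_seq = 9001,
                              chain = "M", x = runif(1, 0, box),
                              y = runif(1, 0, box), z = runif(1, 0, box))
  rows[[k + 2]] <- data.frame(name = "O", res_name = "HOH", res_seq = 9101,
                              chain = "W", x = runif(1, 0, box),
                              y = runif(1, 0, box), z = runif(1, 0, box))
  rows[[k + 3]] <- data.frame(name = "O", res_name = "HOH", res_seq = 9102,
                              chain = "W", x = runif(1, 0, box),
                              y = runif(1, 0, box), z = runif(1, 0, box))
  structure_model(do.call(rbind, rows))
}

# exhaustive BFS: minimal hop count from source to any target
oracle_bfs_hops <- function(edges, source, targets) {
  nodes <- unique(c(edges$a, edges$b, source, targets))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (r in seq_len(nrow(edges))) {
    adj[[edges$a[r]]] <- c(adj[[edges$a[r]]], edges$b[r])
    adj[[edges$b[r]]] <- c(adj[[edges$b[r]]], edges$a[r])
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!is.finite(dist[v])) {
      dist[v] <- dist[u] + 1
      queue <- c(queue, v)
    }
  }
  min(dist[targets])
}

# random connected-ish labeled graph as an igraph with occupancy attributes
random_test_graph <- function(n = 20, p = 0.12, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  ed <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                   kind = sample(c("hbond", "covalent_adjacent",
                                   "metal_coord"), sum(keep), replace = TRUE),
                   distance = stats::runif(sum(keep), 2, 4),
                   of_percent = stats::runif(sum(keep), 50, 100),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(id = nodes, label = nodes, type = "residue"))
  list(graph = g, edges = ed, nodes = nodes)
}

# tiny ensemble of explicit frames from one atoms table + coordinate sets
frames_from_coords <- function(atoms, coord_list, frame_interval = 2) {
  frames <- lapply(seq_along(coord_list), function(i) {
    a <- atoms
    a$x <- coord_list[[i]][, 1]
    a$y <- coord_list[[i]][, 2]
    a$z <- coord_list[[i]][, 3]
    structure_model(a, model_id = i)
  })
  md_ensemble(frames, frame_interval = frame_interval)
}

# rotation matrix about z by deg
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
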