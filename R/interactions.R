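#' @title Geometric interaction detection
#' @description Distance-based detection of hydrogen bonds, salt bridges,
#'   metal coordination and T-shaped pi-stacking, plus torsion measurement and
#'   occupation-frequency (O.F.) statistics over an ensemble. All criteria are
#'   heavy-atom only: hydrogens are ignored everywhere, so crystal structures
#'   and MD frames are treated uniformly.
#' @name interactions
NULL

#' Measure an interatomic distance
#' @param model a [structure_model()].
#' @param a,b atom keys (see [atom_key()]).
#' @return Euclidean distance in Angstrom.
#' @export
measure_distance <- function(model, a, b) {
  ia <- find_atom(model, a); ib <- find_atom(model, b)
  sqrt(sum((coords(model, ia) - coords(model, ib))^2))
}

#' Measure a signed dihedral angle
#'
#' Standard IUPAC convention: cis = 0, trans = +/-180, sign by right-hand
#' rule about the central bond.
#'
#' @param model a [structure_model()].
#' @param spec a [torsion_spec()] or character vector of four atom keys.
#' @return angle in degrees, in (-180, 180].
#' @export
measure_torsion <- function(model, spec) {
  keys <- if (inherits(spec, "torsion_spec")) spec$atoms else spec
  stopifnot(length(keys) == 4)
  p <- t(vapply(keys, function(k) coords(model, find_atom(model, k))[1, ],
                numeric(3)))
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate-torsion error: collinear atom triple")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

#' Define a named torsion
#' @param label torsion label, e.g. `"chi1"`.
#' @param atoms character vector of four distinct atom keys, in order.
#' @return object of class `torsion_spec`.
#' @export
torsion_spec <- function(label, atoms) {
  stopifnot(length(atoms) == 4, !anyDuplicated(atoms))
  structure(list(label = label, atoms = atoms), class = "torsion_spec")
}

# ---- donor/acceptor bookkeeping -------------------------------------------

#' Default hydrogen-bond donor/acceptor role table
#'
#' Heavy-atom roles per (res_name, atom_name); `res_name = "*"` is a wildcard
#' (protein backbone N/O). Water oxygens always act as both donor and
#' acceptor, whether or not listed. The `charged` column marks membership in
#' a charged group, used by the salt-bridge detector. Extend or override by
#' rbinding rows; rows for ligand atom names (N1, N6, O3, O7, O8, O10) cover
#' protonated-amine neurotransmitter-like ligands under res_name `"*L"`,
#' a wildcard matching any non-protein, non-water residue.
#'
#' @return data.frame with columns `res_name`, `atom_name`, `role`
#'   (`donor`/`acceptor`/`both`), `charged` (`""`, `"anion"` or `"cation"`).
#' @export
default_donor_acceptor_table <- function() {
  e <- function(res, atom, role, charged = "")
    data.frame(res_name = res, atom_name = atom, role = role,
               charged = charged, stringsAsFactors = FALSE)
  rbind(
    e("*", "N", "donor"), e("*", "O", "acceptor"), e("*", "OXT", "acceptor"),
    e("ASP", c("OD1", "OD2"), "acceptor", "anion"),
    e("GLU", c("OE1", "OE2"), "acceptor", "anion"),
    e("LYS", "NZ", "donor", "cation"),
    e("ARG", c("NE", "NH1", "NH2"), "donor", "cation"),
    e("HIS", c("ND1", "NE2"), "both"),
    e("SER", "OG", "both"), e("THR", "OG1", "both"), e("TYR", "OH", "both"),
    e("ASN", "OD1", "acceptor"), e("ASN", "ND2", "donor"),
    e("GLN", "OE1", "acceptor"), e("GLN", "NE2", "donor"),
    e("TRP", "NE1", "donor"), e("CYS", "SG", "both"),
    e("*L", "N1", "donor", "cation"), e("*L", "N6", "donor"),
    e("*L", c("O3", "O7", "O8", "O10"), "both"))
}

PROTEIN_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# per-atom role lookup: specific row wins over backbone/ligand wildcard
atom_roles <- function(atoms, table) {
  role <- rep("", nrow(atoms)); charged <- rep("", nrow(atoms))
  wildcard_l <- !(atoms$res_name %in% PROTEIN_RES) & !atoms$is_water &
    !is_metal_element(atoms$element)
  # residue-specific rows take precedence over "*"/"*L" wildcards
  table <- table[order(table$res_name %in% c("*", "*L")), , drop = FALSE]
  for (r in seq_len(nrow(table))) {
    rn <- table$res_name[r]
    hit <- if (rn == "*") atoms$res_name %in% PROTEIN_RES
           else if (rn == "*L") wildcard_l
           else atoms$res_name == rn
    hit <- hit & atoms$name == table$atom_name[r] & role == ""
    role[hit] <- table$role[r]; charged[hit] <- table$charged[r]
  }
  role[atoms$is_water & atoms$element == "O"] <- "both"
  list(role = role, charged = charged)
}

new_events <- function(kind = character(), atom_a = character(),
                       atom_b = character(), distance = numeric(),
                       frame = integer(), extra = numeric()) {
  data.frame(kind = kind, atom_a = atom_a, atom_b = atom_b,
             distance = distance, frame = frame,
             extra = if (length(extra)) extra else rep(NA_real_, length(kind)),
             stringsAsFactors = FALSE)
}

# order the two atom keys of each event lexicographically, dedup, sort
finalize_events <- function(ev) {
  if (!nrow(ev)) return(ev)
  swap <- ev$atom_b < ev$atom_a
  tmp <- ev$atom_a[swap]; ev$atom_a[swap] <- ev$atom_b[swap]; ev$atom_b[swap] <- tmp
  ev <- ev[!duplicated(paste(ev$kind, ev$atom_a, ev$atom_b, ev$frame)), ,
           drop = FALSE]
  ev <- ev[order(ev$atom_a, ev$atom_b), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

pair_events <- function(model, idx_a, idx_b, d_max, kind, frame,
                        exclude_fn = NULL) {
  if (!length(idx_a) || !length(idx_b)) return(new_events())
  xa <- coords(model, idx_a); xb <- coords(model, idx_b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= d_max^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(new_events())
  ia <- idx_a[hit[, 1]]; ib <- idx_b[hit[, 2]]
  keep <- ia != ib
  if (!is.null(exclude_fn)) keep <- keep & !exclude_fn(model$atoms, ia, ib)
  if (!any(keep)) return(new_events())
  ia <- ia[keep]; ib <- ib[keep]
  keys <- model_keys(model)
  new_events(kind = rep(kind, length(ia)), atom_a = keys[ia], atom_b = keys[ib],
             distance = sqrt(pmax(d2[hit][keep], 0)),
             frame = rep(as.integer(frame), length(ia)))
}

# same residue, or 1-2/1-3 backbone pairs of consecutive residues
hbond_excluded <- function(atoms, ia, ib) {
  same_res <- atoms$chain[ia] == atoms$chain[ib] &
    atoms$res_seq[ia] == atoms$res_seq[ib] & !atoms$is_water[ia] &
    !atoms$is_water[ib]
  bb <- c("N", "CA", "C", "O")
  peptide <- atoms$chain[ia] == atoms$chain[ib] &
    abs(atoms$res_seq[ia] - atoms$res_seq[ib]) == 1 &
    atoms$name[ia] %in% bb & atoms$name[ib] %in% bb
  same_res | peptide
}

#' Detect hydrogen bonds in one model
#'
#' Heavy-atom criterion: every donor-acceptor pair at distance `<= d_max`
#' (default 3.5 Angstrom), excluding intra-residue pairs and 1-2/1-3 backbone
#' pairs of consecutive residues. Water oxygens act as both donor and
#' acceptor. Events are deduplicated on unordered atom pairs and sorted by
#' (atom_a, atom_b).
#'
#' @param model a [structure_model()].
#' @param table donor/acceptor table, see [default_donor_acceptor_table()].
#' @param d_max heavy-atom distance cutoff, Angstrom.
#' @param frame frame index recorded in the events.
#' @return data.frame of events (kind `"hbond"`).
#' @export
detect_hbonds <- function(model, table = default_donor_acceptor_table(),
                          d_max = 3.5, frame = 1L) {
  if (!nrow(model$atoms)) stop("empty-structure error: model has no atoms")
  ar <- atom_roles(model$atoms, table)
  don <- which(ar$role %in% c("donor", "both"))
  acc <- which(ar$role %in% c("acceptor", "both"))
  finalize_events(pair_events(model, don, acc, d_max, "hbond", frame,
                              exclude_fn = hbond_excluded))
}

#' Detect salt bridges in one model
#'
#' Carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2) against basic nitrogens
#' (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2 when `include_his`), at heavy-atom
#' distance `<= d_max` (default 4.0 Angstrom); one event per atom pair.
#'
#' @inheritParams detect_hbonds
#' @param include_his treat histidine imidazole nitrogens as basic.
#' @return data.frame of events (kind `"salt_bridge"`).
#' @export
detect_salt_bridges <- function(model, d_max = 4.0, frame = 1L,
                                include_his = FALSE) {
  a <- model$atoms
  acid <- which((a$res_name == "ASP" & a$name %in% c("OD1", "OD2")) |
                  (a$res_name == "GLU" & a$name %in% c("OE1", "OE2")))
  base <- which((a$res_name == "LYS" & a$name == "NZ") |
                  (a$res_name == "ARG" & a$name %in% c("NE", "NH1", "NH2")) |
                  (include_his & a$res_name == "HIS" &
                     a$name %in% c("ND1", "NE2")))
  finalize_events(pair_events(model, acid, base, d_max, "salt_bridge", frame))
}

#' Detect metal coordination contacts in one model
#'
#' Every metal atom in `metal_selection` against all N/O/S atoms (water
#' oxygens included, supporting metal...water bridges) at distance `<= d_max`
#' (default 3.0 Angstrom).
#'
#' @inheritParams detect_hbonds
#' @param metal_selection selection matching at least one metal atom.
#' @return data.frame of events (kind `"metal_coord"`).
#' @export
detect_metal_coordination <- function(model, metal_selection = "elem CU",
                                      d_max = 3.0, frame = 1L) {
  met <- select_idx(model, metal_selection)
  if (!length(met)) stop("argument error: metal selection matches no atoms")
  lig <- which(model$atoms$element %in% c("N", "O", "S"))
  lig <- setdiff(lig, met)
  finalize_events(pair_events(model, met, lig, d_max, "metal_coord", frame))
}

#' Detect a T-shaped pi-stacking contact between two rings
#'
#' Fits a plane to each ring (SVD); reports an event iff the ring-centroid
#' distance lies in `d_window` (default 4.0-7.0 Angstrom) and the inter-plane
#' angle lies in `angle_window` (default 60-120 degrees, i.e. near
#' perpendicular; parallel stacking is excluded). The `extra` column carries
#' the inter-plane angle.
#'
#' @inheritParams detect_hbonds
#' @param ring_a,ring_b character vectors of >= 5 atom keys each.
#' @param d_window,angle_window length-2 numeric ranges.
#' @return data.frame with 0 or 1 event (kind `"pi_T"`).
#' @export
detect_pi_T <- function(model, ring_a, ring_b, d_window = c(4, 7),
                        angle_window = c(60, 120), frame = 1L) {
  ring_geom <- function(keys) {
    stopifnot(length(keys) >= 5)
    xyz <- coords(model, vapply(keys, function(k) find_atom(model, k), 1L))
    ctr <- colMeans(xyz)
    s <- svd(sweep(xyz, 2, ctr))
    if (s$d[2] < 1e-8) stop("degenerate-ring error: ring atoms are collinear")
    list(center = ctr, normal = s$v[, 3])
  }
  ga <- ring_geom(ring_a); gb <- ring_geom(ring_b)
  d <- sqrt(sum((ga$center - gb$center)^2))
  cosang <- abs(sum(ga$normal * gb$normal)) /
    sqrt(sum(ga$normal^2) * sum(gb$normal^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi   # folded to [0, 90]
  in_window <- (ang >= angle_window[1] & ang <= angle_window[2]) ||
    ((180 - ang) >= angle_window[1] & (180 - ang) <= angle_window[2])
  if (d >= d_window[1] && d <= d_window[2] && in_window)
    new_events("pi_T", ring_a[1], ring_b[1], d, as.integer(frame), extra = ang)
  else new_events()
}

# ---- ensemble-level detection and occupancy -------------------------------

#' Run a detector over every frame of an ensemble
#'
#' @param ensemble an [md_ensemble()].
#' @param detector one of `"hbond"`, `"salt_bridge"`, `"metal_coord"`, or a
#'   function `(model, frame) -> events`.
#' @param ... passed to the detector.
#' @return combined events data.frame over all frames.
#' @export
detect_events <- function(ensemble, detector = "hbond", ...) {
  fn <- if (is.function(detector)) detector else switch(
    detector,
    hbond = function(m, f, ...) detect_hbonds(m, frame = f, ...),
    salt_bridge = function(m, f, ...) detect_salt_bridges(m, frame = f, ...),
    metal_coord = function(m, f, ...) detect_metal_coordination(m, frame = f, ...),
    stop("argument error: unknown detector '", detector, "'"))
  out <- lapply(seq_len(n_frames(ensemble)), function(i)
    fn(ensemble$frames[[i]], i, ...))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group atom keys to residue level
#'
#' Maps `"A:ASP:1025:OD2"` to `"ASP1025"`; water atoms map to
#' `"W<res_seq>"`. Useful as part of a grouping rule for [occupancy()]
#' (e.g. counting Asp1025 OD1 *or* OD2 as one "Asp1025" interaction).
#'
#' @param keys character vector of atom keys.
#' @return character vector of residue-level labels.
#' @export
residue_label <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (p[2] %in% DEFAULT_WATER_NAMES) paste0("W", p[3])
    else paste0(p[2], p[3])
  }, character(1))
}

#' Occupation frequency of interaction keys
#'
#' For each grouping key, the O.F. is `100 * n_present / n_total`, where
#' `n_present` counts frames in `frame_range` with at least one event mapping
#' to that key. The grouping rule is an explicit input: the default keeps
#' atom-level keys (`kind atom_a|atom_b`); pass e.g.
#' `function(ev) paste(residue_label(ev$atom_a), residue_label(ev$atom_b))`
#' to group to residue level.
#'
#' @param events events data.frame (from [detect_events()] or a detector).
#' @param key_fn function mapping the events data.frame to a character key
#'   per event.
#' @param frame_range integer vector of frame indices analysed (non-empty);
#'   also fixes `n_total`.
#' @return data.frame with columns `key`, `n_present`, `n_total`,
#'   `of_percent`, sorted by decreasing O.F. then key.
#' @export
occupancy <- function(events,
                      key_fn = function(ev) paste(ev$kind, ev$atom_a, ev$atom_b),
                      frame_range) {
  stopifnot(length(frame_range) >= 1)
  n_total <- length(unique(frame_range))
  ev <- events[events$frame %in% frame_range, , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(key = character(), n_present = integer(),
                      n_total = integer(), of_percent = numeric()))
  key <- key_fn(ev)
  n_present <- vapply(split(ev$frame, key),
                      function(f) length(unique(f)), integer(1))
  out <- data.frame(key = names(n_present),
                    n_present = as.integer(n_present),
                    n_total = n_total,
                    of_percent = 100 * as.integer(n_present) / n_total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$of_percent, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
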