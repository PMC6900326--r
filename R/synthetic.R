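#' @title Synthetic ensembles with planted ground truth
#' @description A seeded generator that builds a rigid scaffold of
#'   residue-like groups, a monoamine-like ligand, copper centers and water
#'   sites, then simulates an ensemble around it: per-residue Gaussian noise,
#'   Bernoulli-toggled interactions placed inside/outside their detection
#'   cutoffs, water sites occupied with specified probabilities (with
#'   water-identity exchange), and a random global rigid motion per frame so
#'   that superposition is exercised. Every analysis stage can be validated
#'   against the planted truth without external data.
#' @name synthetic
NULL

#' Scaffold specification
#'
#' Parameters of the synthetic binding-site scaffold. The residue cast
#' mirrors a multicopper-oxidase amine-binding site: an acidic triad
#' (Asp1025, Glu935, Glu272), the catechol-binding acids (Asp230, Glu232),
#' supporting residues (Asp206, Phe209, Gln235, Arg239, Asn271, Lys938, a
#' 7-residue helix 931-937), the T1-copper ligands (Cys1021, His1022,
#' His1026, Met1031, Glu1032) and six integral copper ions (three mononuclear
#' T1 centers 18 Angstrom apart and a trinuclear cluster).
#'
#' @param triad pairwise distances (Angstrom) planted between the triad
#'   oxygens Asp1025 OD1, Glu935 OE1 and Glu272 OE1, in the order
#'   (1025-935, 1025-272, 935-272).
#' @param pairs optional extra placement requests: data.frame with columns
#'   `atom` (key of the atom to move), `anchor` (key), `distance` (Angstrom).
#' @param crystal_waters if TRUE, add crystal-like waters: one at each
#'   binding-site hydrophilic position, plus a linear three-water bridge
#'   between Glu1032 OE1 and the trinuclear Cu3047.
#' @param labile_cu if TRUE, add an extra labile copper ion (Cu3053) 9
#'   Angstrom from the T1 center Cu3052.
#' @param chi1,chi2 planted ligand side-chain torsions, degrees.
#' @return object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(triad = c(5.1, 4.7, 6.6), pairs = NULL,
                          crystal_waters = FALSE, labile_cu = FALSE,
                          chi1 = 90, chi2 = -150) {
  stopifnot(length(triad) == 3, all(triad > 0))
  structure(list(triad = triad, pairs = pairs,
                 crystal_waters = crystal_waters, labile_cu = labile_cu,
                 chi1 = chi1, chi2 = chi2),
            class = "scaffold_spec")
}

# place atom D given A, B, C with |CD| = bond, angle(B,C,D) = ang (deg) and
# dihedral(A,B,C,D) = dih (deg); standard internal-coordinate construction
place_dihedral <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180; dih <- -dih * pi / 180
  bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# local residue template around a center: backbone (N, CA, C, O) plus a
# stacked side-chain column; spacing everywhere >= 1.5 A
residue_template <- function(center, atom_names) {
  bb <- list(N = c(-0.7, -0.5, -0.4), CA = c(0.8, -0.5, -0.4),
             C = c(1.6, 0.8, -0.4), O = c(3.0, 1.5, 0))
  out <- matrix(NA_real_, length(atom_names), 3)
  k <- 0
  for (i in seq_along(atom_names)) {
    nm <- atom_names[i]
    if (nm %in% names(bb)) out[i, ] <- center + bb[[nm]]
    else {
      out[i, ] <- center + c(-0.2, 1.4 + 1.6 * k, 0.9 + 0.3 * k)
      k <- k + 1
    }
  }
  out
}

RES_ATOMS <- list(
  ASP = c("N", "CA", "C", "O", "CB", "OD1", "OD2"),
  GLU = c("N", "CA", "C", "O", "CB", "OE1", "OE2"),
  LYS = c("N", "CA", "C", "O", "CB", "NZ"),
  ARG = c("N", "CA", "C", "O", "CB", "NE", "NH1", "NH2"),
  HIS = c("N", "CA", "C", "O", "CB", "ND1", "NE2"),
  ASN = c("N", "CA", "C", "O", "CB", "OD1", "ND2"),
  GLN = c("N", "CA", "C", "O", "CB", "OE1", "NE2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  MET = c("N", "CA", "C", "O", "CB", "SD"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  ALA = c("N", "CA", "C", "O", "CB"),
  GLY = c("N", "CA", "C", "O"))

# residue roster: name, seq and hand-laid center of the local template
scaffold_roster <- function() {
  r <- function(res_name, res_seq, cx, cy, cz)
    data.frame(res_name = res_name, res_seq = res_seq,
               cx = cx, cy = cy, cz = cz, stringsAsFactors = FALSE)
  rbind(
    r("ASP",  206, -12.0,  -8.0,  4.0),
    r("PHE",  209,   0.0,   0.0,  0.0),   # ring placed explicitly (pi-T)
    r("ASP",  230,   6.0, -12.0, -6.0),
    r("GLU",  232,  -4.0, -12.0,  2.0),
    r("GLN",  235,   2.0, -15.0,  6.0),
    r("ARG",  239, -10.0, -15.0,  5.0),
    r("ASN",  271,   7.0,   6.0, -6.0),
    r("GLU",  272, -10.5,   4.5,  3.0),
    r("GLU",  931, -18.0,   4.0,  3.0),
    r("ALA",  932, -18.0,  10.0,  3.0),
    r("ALA",  933, -18.0,  16.0,  3.0),
    r("ALA",  934, -18.0,  22.0,  3.0),
    r("GLU",  935, -18.0,  28.0,  3.0),
    r("ALA",  936, -18.0,  34.0,  3.0),
    r("ASN",  937, -18.0,  40.0,  3.0),
    r("LYS",  938, -18.0,  46.0,  3.0),
    r("CYS", 1021,  14.0,   5.5, -2.5),
    r("HIS", 1022,  17.5,   5.5,  2.0),
    r("ASP", 1025,   2.0,  -4.5,  0.0),
    r("HIS", 1026,   7.0,  -3.5, -2.5),
    r("MET", 1031,  12.0,  -5.5,  1.0),
    r("GLU", 1032,  17.5,  -9.5,  2.0))
}

LIGAND_ATOMS <- c("N1", "C2", "C3", "C4", "C12", "N6", "O10", "O3",
                  "C13", "C14", "C15", "C16", "C17", "C18", "O7", "O8")

# deterministic ligand geometry: ethylamine chain with the requested chi1 /
# chi2 torsions, a hydroxyl-bearing head group and a six-membered ring for
# pi-stacking (ring plane z = const, so its normal is the z axis)
ligand_coords <- function(chi1, chi2) {
  p <- list()
  p$N1 <- c(0, 0, 0)
  p$C2 <- c(1.52, 0, 0)
  p$C3 <- p$C2 + 1.52 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  p$C4 <- place_dihedral(p$N1, p$C2, p$C3, 1.52, 111, chi2)
  p$C12 <- place_dihedral(p$C2, p$C3, p$C4, 1.52, 111, chi1)
  p$N6 <- place_dihedral(p$C3, p$C4, p$C12, 1.52, 115, 180)
  p$O10 <- place_dihedral(p$C4, p$C12, p$N6, 1.52, 112, 60)
  p$O3 <- p$C3 + c(0, 0, -1.52)
  rc <- p$C12 + c(3.2, 2.6, 1.2)            # ring center
  th <- (0:5) * pi / 3
  ring <- c("C13", "C14", "C15", "C16", "C17", "C18")
  for (i in 1:6) p[[ring[i]]] <- rc + 1.55 * c(cos(th[i]), sin(th[i]), 0)
  p$O7 <- rc + 3.15 * c(cos(th[2]), sin(th[2]), 0)   # para-OH analogue
  p$O8 <- rc + 3.15 * c(cos(th[4]), sin(th[4]), 0)   # meta-OH analogue
  p
}

#' Planted key-atom geometry of the default scaffold
#'
#' The explicit coordinates the generator plants for the functional atoms:
#' hydrogen-bonding partners of the ligand, the salt-bridge pairs, the
#' copper-coordinating side chains, the T1 and trinuclear coppers, and the
#' acidic-triad triangle. Returned as a named list of 3-vectors so tests can
#' reason about the geometry directly.
#' @keywords internal
planted_positions <- function(triad = c(5.1, 4.7, 6.6)) {
  pos <- list(
    "M:CU:3052:CU" = c(10.75, 0, 0),
    "M:CU:3046:CU" = c(10.75, 18, 0),
    "M:CU:3051:CU" = c(10.75, 9, 15.588457),
    "M:CU:3047:CU" = c(16, -2, 4),
    "M:CU:3048:CU" = c(16, 2.8, 4),
    "M:CU:3049:CU" = c(19.5, 0.4, 4),
    "A:HIS:1026:NE2" = c(8.65, 0, 0),
    "A:CYS:1021:SG" = c(12.306, 1.556, 0),
    "A:HIS:1022:NE2" = c(13.9, 2.8, 4),
    "A:MET:1031:SD" = c(10.75, -1.7, 1.7),
    "A:GLU:1032:OE2" = c(11.4, -2, 4),
    "A:ASP:1025:OD2" = c(-2.74, 0, 0))
  # acidic triad triangle in the plane z = 0.6 anchored at Asp1025 OD1
  d12 <- triad[1]; d13 <- triad[2]; d23 <- triad[3]
  a <- c(-3.5, 1.2, 0.6)
  yb <- (d12^2 + d13^2 - d23^2) / (2 * d12)   # projection of c on ab
  xb <- sqrt(max(d13^2 - yb^2, 0))
  pos[["A:ASP:1025:OD1"]] <- a
  pos[["A:GLU:935:OE1"]] <- a + c(0, d12, 0)
  pos[["A:GLU:272:OE1"]] <- a + c(-xb, yb, 0)   # -x: away from the ligand
  pos
}

#' Build the synthetic scaffold structure
#'
#' Deterministic given `seed`: lays out the residue roster, constructs the
#' ligand with the requested torsions, places the functional atoms at their
#' planted coordinates (triad triangle at the requested pairwise distances,
#' copper-coordinating atoms at coordination range, the Phe209 ring
#' T-stacked on the ligand ring), and applies any extra pair placements.
#' Fails with a placement error if any two atoms end up closer than 1.5
#' Angstrom.
#'
#' @param spec a [scaffold_spec()].
#' @param seed integer RNG seed (recorded in the provenance).
#' @return a [structure_model()].
#' @export
make_scaffold <- function(spec = scaffold_spec(), seed = 1) {
  stopifnot(inherits(spec, "scaffold_spec"))
  set.seed(seed)
  roster <- scaffold_roster()
  rows <- list(); k <- 0
  add <- function(chain, res_name, res_seq, name, xyz, element = NULL) {
    k <<- k + 1
    rows[[k]] <<- data.frame(
      name = name, res_name = res_name, res_seq = res_seq, chain = chain,
      x = xyz[1], y = xyz[2], z = xyz[3],
      element = if (is.null(element)) guess_element(name, res_name) else element,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(roster))) {
    nms <- RES_ATOMS[[roster$res_name[i]]]
    xyz <- residue_template(c(roster$cx[i], roster$cy[i], roster$cz[i]), nms)
    for (j in seq_along(nms))
      add("A", roster$res_name[i], roster$res_seq[i], nms[j], xyz[j, ])
  }
  lig <- ligand_coords(spec$chi1, spec$chi2)
  for (nm in LIGAND_ATOMS) add("L", "SRO", 2001L, nm, lig[[nm]])
  for (ms in c(3046, 3047, 3048, 3049, 3051, 3052))
    add("M", "CU", ms, "CU", c(0, 0, 0), element = "CU")  # placed below
  atoms <- do.call(rbind, rows)
  key <- atom_key(atoms$chain, atoms$res_name, atoms$res_seq, atoms$name)

  setp <- function(k2, xyz) {
    i <- match(k2, key); stopifnot(!is.na(i))
    atoms$x[i] <<- xyz[1]; atoms$y[i] <<- xyz[2]; atoms$z[i] <<- xyz[3]
  }
  pp <- planted_positions(spec$triad)
  for (nm in names(pp)) setp(nm, pp[[nm]])

  # Phe209 ring: T-stacked on the ligand ring -- centroid 5 A along the
  # ligand-ring normal (z), ring plane containing z so the planes are
  # perpendicular
  lig_rc <- colMeans(do.call(rbind, lig[c("C13", "C14", "C15", "C16",
                                          "C17", "C18")]))
  prc <- lig_rc + c(0, 0, 5)
  ph <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  th <- (0:5) * pi / 3
  for (i in 1:6)
    setp(paste0("A:PHE:209:", ph[i]),
         prc + 1.55 * c(cos(th[i]), 0, sin(th[i])))
  for (nm in c("N", "CA", "C", "O", "CB")) {
    i <- match(paste0("A:PHE:209:", nm), key)
    off <- residue_template(prc + c(4.0, 1.0, 1.5), nm)
    atoms$x[i] <- off[1]; atoms$y[i] <- off[2]; atoms$z[i] <- off[3]
  }

  if (spec$labile_cu) {
    atoms <- rbind(atoms, data.frame(
      name = "CU", res_name = "CU", res_seq = 3053L, chain = "M",
      x = 10.75, y = -9, z = 0, element = "CU"))  # 9 A from Cu3052
    key <- atom_key(atoms$chain, atoms$res_name, atoms$res_seq, atoms$name)
  }

  if (spec$crystal_waters) {
    # the bridge anchors on a relocated Glu1032 OE1 pointing at the cluster
    key <- atom_key(atoms$chain, atoms$res_name, atoms$res_seq, atoms$name)
    setp("A:GLU:1032:OE1", bridge_geometry()$oe1)
    ws <- crystal_water_positions(spec)
    atoms <- rbind(atoms, data.frame(
      name = "O", res_name = "HOH", res_seq = ws$res_seq, chain = "W",
      x = ws$x, y = ws$y, z = ws$z, element = "O"))
  }

  if (!is.null(spec$pairs)) {
    key <- atom_key(atoms$chain, atoms$res_name, atoms$res_seq, atoms$name)
    for (r in seq_len(nrow(spec$pairs))) {
      ia <- match(spec$pairs$atom[r], key)
      ib <- match(spec$pairs$anchor[r], key)
      if (is.na(ia) || is.na(ib))
        stop("placement error: unknown atom in pair request")
      u <- c(atoms$x[ia] - atoms$x[ib], atoms$y[ia] - atoms$y[ib],
             atoms$z[ia] - atoms$z[ib])
      nu <- sqrt(sum(u^2))
      u <- if (nu < 1e-9) c(1, 0, 0) else u / nu
      p <- c(atoms$x[ib], atoms$y[ib], atoms$z[ib]) + spec$pairs$distance[r] * u
      atoms$x[ia] <- p[1]; atoms$y[ia] <- p[2]; atoms$z[ia] <- p[3]
    }
  }

  check_clashes(atoms)
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, model_id = 1L,
                  provenance = sprintf("synthetic scaffold (seed %d)", seed))
}

# three binding-site hydrophilic positions plus the linear three-water
# bridge Glu1032 OE1 ... W2331 ... W2090 ... W2338 ... Cu3047
crystal_water_positions <- function(spec = scaffold_spec()) {
  s <- site_positions()
  bridge <- bridge_geometry()$waters
  data.frame(
    res_seq = c(2326L, 2309L, 2329L, 2331L, 2090L, 2338L),
    x = c(s$WS_A[1], s$WS_B[1], s$WS_C[1], bridge[, 1]),
    y = c(s$WS_A[2], s$WS_B[2], s$WS_C[2], bridge[, 2]),
    z = c(s$WS_A[3], s$WS_B[3], s$WS_C[3], bridge[, 3]))
}

# binding-site hydrophilic site centroids (near ligand N1, O10 and O7)
site_positions <- function() {
  list(WS_A = c(0, 2.8, 0),
       WS_B = c(-1.0, -2.4, -2.6),
       WS_C = c(3.2, 3.4, -3.4),
       W1 = c(14, -2, 4))   # 2.0 A from Cu3047, 2.6 A from Glu1032 OE2
}

# crystal bridge: Glu1032 OE1 relocated toward the cluster, three waters on
# the line to Cu3047 at 2.7 A spacing, last one 2.4 A from the copper
bridge_geometry <- function() {
  cu <- c(16, -2, 4)
  u <- c(0.8, 2.7, 1.6); u <- u / sqrt(sum(u^2))
  oe1 <- cu + (3 * 2.7 + 2.4) * u
  list(oe1 = oe1,
       waters = t(vapply(1:3, function(k) oe1 - 2.7 * k * u, numeric(3))))
}

check_clashes <- function(atoms, min_dist = 1.5) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  diag(d2) <- Inf
  worst <- which.min(d2)
  if (sqrt(max(min(d2), 0)) < min_dist - 1e-9) {
    ij <- arrayInd(worst, dim(d2))
    stop(sprintf(
      "placement error: atoms %s:%s%d:%s and %s:%s%d:%s clash at %.2f A",
      atoms$chain[ij[1]], atoms$res_name[ij[1]], atoms$res_seq[ij[1]],
      atoms$name[ij[1]], atoms$chain[ij[2]], atoms$res_name[ij[2]],
      atoms$res_seq[ij[2]], atoms$name[ij[2]], sqrt(max(min(d2), 0))))
  }
  invisible(TRUE)
}

#' Planted ground truth for a simulated ensemble
#'
#' @param sites data.frame with columns `x`, `y`, `z` (centroid), `p`
#'   (per-frame occupancy probability), `id_base` (first water residue id)
#'   and `n_ids` (size of the identity-exchange pool).
#' @param interactions data.frame with columns `atom` (key of the moved
#'   partner), `anchor` (key), `p` (per-frame Bernoulli probability), `d_on`
#'   (planted distance when present, Angstrom), `cutoff` (detection cutoff;
#'   when absent the partner sits at `cutoff + 0.5`).
#' @param exchange_period frames between water-identity exchanges.
#' @param noise_sigma default per-coordinate Gaussian sigma (Angstrom) for
#'   protein/ligand residues; metals stay fixed.
#' @param sigma_overrides optional data.frame (`res_seq`, `sigma`).
#' @param path_nodes planted direct recognition path (node ids).
#' @param water_path_nodes planted water-mediated path, with `"<site>"`
#'   placeholders for water-site nodes.
#' @param link_cutoff site pairing cutoff the water jitter respects (waters
#'   are placed within `0.5 * link_cutoff` of their centroid).
#' @param max_rot_deg,max_trans maximum per-frame global rigid jitter.
#' @return object of class `planted_truth`.
#' @export
planted_truth <- function(sites = NULL, interactions = NULL,
                          exchange_period = 10, noise_sigma = 0.1,
                          sigma_overrides = NULL, path_nodes = NULL,
                          water_path_nodes = NULL, link_cutoff = 1.8,
                          max_rot_deg = 15, max_trans = 3) {
  if (!is.null(sites)) stopifnot(all(sites$p >= 0 & sites$p <= 1))
  if (!is.null(interactions))
    stopifnot(all(interactions$p >= 0 & interactions$p <= 1))
  structure(list(sites = sites, interactions = interactions,
                 exchange_period = exchange_period,
                 noise_sigma = noise_sigma,
                 sigma_overrides = sigma_overrides,
                 path_nodes = path_nodes,
                 water_path_nodes = water_path_nodes,
                 link_cutoff = link_cutoff, max_rot_deg = max_rot_deg,
                 max_trans = max_trans, seed = NA_integer_),
            class = "planted_truth")
}

random_rotation <- function(max_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Simulate a noisy ensemble around a scaffold
#'
#' Per frame: per-residue Gaussian positional noise (metals fixed); each
#' planted interaction drawn Bernoulli(p) and its moved partner placed at
#' `d_on` (present) or `cutoff + 0.5` (absent) along its scaffold direction
#' from the anchor; each water site drawn Bernoulli(p) and, when occupied, a
#' water oxygen placed uniformly within `0.5 * link_cutoff` of the centroid,
#' with the water residue id rotating through the site's id pool every
#' `exchange_period` frames; finally a random global rigid transform
#' (rotation up to `max_rot_deg`, translation up to `max_trans`) applied to
#' all atoms. Fully deterministic given `seed`.
#'
#' @param model scaffold [structure_model()] from [make_scaffold()].
#' @param truth a [planted_truth()].
#' @param n_frames number of frames (>= 1).
#' @param frame_interval_ps sampling interval, ps.
#' @param seed integer RNG seed; recorded in the returned truth.
#' @return list with `ensemble` (an [md_ensemble()]) and `truth` (the input
#'   truth with `seed` filled in).
#' @export
simulate_trajectory <- function(model, truth, n_frames = 100,
                                frame_interval_ps = 2, seed = 1) {
  stopifnot(inherits(model, "structure_model"),
            inherits(truth, "planted_truth"), n_frames >= 1)
  set.seed(seed)
  base <- model$atoms
  nb <- nrow(base)
  res_id <- paste(base$chain, base$res_seq)
  sigma <- rep(truth$noise_sigma, nb)
  sigma[is_metal_element(base$element)] <- 0
  if (!is.null(truth$sigma_overrides))
    for (r in seq_len(nrow(truth$sigma_overrides)))
      sigma[base$res_seq == truth$sigma_overrides$res_seq[r]] <-
        truth$sigma_overrides$sigma[r]

  ints <- truth$interactions
  if (!is.null(ints)) {
    keys <- atom_key(base$chain, base$res_name, base$res_seq, base$name)
    ints$i_atom <- match(ints$atom, keys)
    ints$i_anchor <- match(ints$anchor, keys)
    if (anyNA(ints$i_atom) || anyNA(ints$i_anchor))
      stop("placement error: planted interaction names an unknown atom")
  }
  sites <- truth$sites

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    a <- base
    a$x <- a$x + stats::rnorm(nb, 0, sigma)
    a$y <- a$y + stats::rnorm(nb, 0, sigma)
    a$z <- a$z + stats::rnorm(nb, 0, sigma)
    if (!is.null(ints)) {
      on <- stats::runif(nrow(ints)) < ints$p
      for (r in seq_len(nrow(ints))) {
        ia <- ints$i_atom[r]; ib <- ints$i_anchor[r]
        u <- c(base$x[ia] - base$x[ib], base$y[ia] - base$y[ib],
               base$z[ia] - base$z[ib])
        u <- u / sqrt(sum(u^2))
        d <- if (on[r]) ints$d_on[r] else ints$cutoff[r] + 0.5
        p <- c(a$x[ib], a$y[ib], a$z[ib]) + d * u
        a$x[ia] <- p[1]; a$y[ia] <- p[2]; a$z[ia] <- p[3]
      }
    }
    if (!is.null(sites) && nrow(sites)) {
      occ <- stats::runif(nrow(sites)) < sites$p
      jit <- matrix(stats::rnorm(3 * nrow(sites)), ncol = 3)
      jit <- jit / sqrt(rowSums(jit^2)) *
        (stats::runif(nrow(sites))^(1 / 3) * 0.5 * truth$link_cutoff)
      if (any(occ)) {
        idx <- which(occ)
        wid <- sites$id_base[idx] +
          ((f - 1) %/% truth$exchange_period) %% sites$n_ids[idx]
        a <- rbind(a, data.frame(
          serial = max(base$serial) + seq_along(idx),
          name = "O", element = "O", res_name = "HOH",
          res_seq = as.integer(wid), chain = "W",
          x = sites$x[idx] + jit[idx, 1], y = sites$y[idx] + jit[idx, 2],
          z = sites$z[idx] + jit[idx, 3],
          occupancy = 1, b_factor = 0, is_water = TRUE))
      }
    }
    R <- random_rotation(truth$max_rot_deg)
    tr <- stats::rnorm(3); tr <- tr / sqrt(sum(tr^2)) *
      stats::runif(1, 0, truth$max_trans)
    xyz <- cbind(a$x, a$y, a$z) %*% t(R)
    a$x <- xyz[, 1] + tr[1]; a$y <- xyz[, 2] + tr[2]; a$z <- xyz[, 3] + tr[3]
    frames[[f]] <- structure_model(a, model_id = f,
                                   provenance = sprintf("synthetic (seed %d)",
                                                        seed))
  }
  truth$seed <- seed
  list(ensemble = md_ensemble(frames, frame_interval = frame_interval_ps),
       truth = truth)
}

#' The packaged benchmark system
#'
#' A complete study system with planted truth: the default scaffold; three
#' binding-site water sites with occupancy probabilities 1.0, 0.85 and 0.5
#' (centroids mutually >= 4.5 Angstrom apart, identity-exchanging ids); one
#' bridge water site (p = 1) between Glu1032 and the trinuclear Cu3047;
#' Bernoulli-toggled hydrogen bonds, salt bridges and copper coordination
#' supporting the direct and water-mediated recognition paths.
#'
#' @param seed integer seed driving all randomness.
#' @param n_frames frames to simulate.
#' @param frame_interval_ps sampling interval, ps.
#' @return list with `ensemble`, `truth`, `scaffold`.
#' @export
benchmark_system <- function(seed = 1, n_frames = 1000,
                             frame_interval_ps = 2) {
  scaffold <- make_scaffold(scaffold_spec(), seed = seed)
  s <- site_positions()
  sites <- data.frame(
    label = c("WS_A", "WS_B", "WS_C", "W1"),
    x = c(s$WS_A[1], s$WS_B[1], s$WS_C[1], s$W1[1]),
    y = c(s$WS_A[2], s$WS_B[2], s$WS_C[2], s$W1[2]),
    z = c(s$WS_A[3], s$WS_B[3], s$WS_C[3], s$W1[3]),
    p = c(1.0, 0.85, 0.5, 1.0),
    id_base = c(2326L, 2309L, 2329L, 2090L),
    n_ids = c(4L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  ints <- data.frame(
    atom = c("A:ASP:1025:OD2", "A:GLU:272:OE2", "A:LYS:938:NZ",
             "A:ARG:239:NH1", "A:ASN:271:ND2", "A:ASP:230:OD1",
             "A:HIS:1026:NE2", "A:CYS:1021:SG", "A:HIS:1022:NE2",
             "A:MET:1031:SD"),
    anchor = c("L:SRO:2001:N1", "L:SRO:2001:N1", "A:GLU:935:OE1",
               "A:GLU:232:OE1", "L:SRO:2001:O10", "L:SRO:2001:O7",
               "M:CU:3052:CU", "M:CU:3052:CU", "M:CU:3048:CU",
               "M:CU:3052:CU"),
    p = c(1.0, 0.5, 0.85, 1.0, 0.6, 1.0, 1.0, 1.0, 1.0, 1.0),
    d_on = c(2.74, 2.60, 2.70, 2.70, 3.10, 2.60, 2.10, 2.20, 2.10, 2.40),
    cutoff = c(3.5, 3.5, 4.0, 4.0, 3.5, 3.5, 3.0, 3.0, 3.0, 3.0),
    stringsAsFactors = FALSE)
  truth <- planted_truth(
    sites = sites, interactions = ints,
    path_nodes = c("LIG:N1", "Asp1025", "His1026", "Cu3052", "Cys1021",
                   "His1022", "Cu3048"),
    water_path_nodes = c("LIG:N1", "Asp1025", "His1026", "Cu3052", "Met1031",
                         "Glu1032", "<W1>", "Cu3047"))
  out <- simulate_trajectory(scaffold, truth, n_frames = n_frames,
                             frame_interval_ps = frame_interval_ps,
                             seed = seed)
  list(ensemble = out$ensemble, truth = out$truth, scaffold = scaffold)
}
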