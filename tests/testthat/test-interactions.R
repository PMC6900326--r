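mini_model <- function(df) structure_model(df)

two_atom_model <- function(p1, p2, res1 = "ASP", n1 = "OD2", res2 = "SRO",
                           n2 = "N1", seq1 = 1025, seq2 = 2001,
                           ch2 = "L") {
  mini_model(data.frame(
    name = c(n1, n2), res_name = c(res1, res2), res_seq = c(seq1, seq2),
    chain = c("A", ch2),
    x = c(p1[1], p2[1]), y = c(p1[2], p2[2]), z = c(p1[3], p2[3]),
    stringsAsFactors = FALSE))
}

test_that("distances follow the 3-4-5 triangle and self-distance is zero", {
  m <- two_atom_model(c(0, 0, 0), c(3, 4, 0))
  expect_equal(measure_distance(m, "A:ASP:1025:OD2", "L:SRO:2001:N1"), 5)
  expect_equal(measure_distance(m, "A:ASP:1025:OD2", "A:ASP:1025:OD2"), 0)
  expect_error(measure_distance(m, "A:ASP:1025:OD2", "A:GLY:1:CA"),
               "atom-not-found.*A:GLY:1:CA")
})

# independent dihedral fixture: rotate the fourth point about the central
# bond by an explicit axis-angle rotation
dihedral_points <- function(angle_deg) {
  a <- c(1.5, 1, 0); b <- c(0, 0, 0); c_ <- c(2, 0, 0)
  d0 <- c_ + c(0.5, 1, 0)              # angle 0 (cis, same side as a)
  axis <- c(1, 0, 0)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(-th) * K + (1 - cos(-th)) * (K %*% K)
  rel <- d0 - c_
  list(a = a, b = b, c = c_, d = c_ + as.vector(R %*% rel))
}

torsion_model <- function(p) {
  mini_model(data.frame(
    name = c("C1", "C2", "C3", "C4"), res_name = "LIG", res_seq = 1,
    chain = "L",
    x = c(p$a[1], p$b[1], p$c[1], p$d[1]),
    y = c(p$a[2], p$b[2], p$c[2], p$d[2]),
    z = c(p$a[3], p$b[3], p$c[3], p$d[3]), stringsAsFactors = FALSE))
}

tkeys <- paste0("L:LIG:1:C", 1:4)

test_that("dihedrals follow the IUPAC signed convention", {
  expect_equal(measure_torsion(torsion_model(dihedral_points(0)), tkeys), 0,
               tolerance = 1e-8)
  expect_equal(abs(measure_torsion(torsion_model(dihedral_points(180)),
                                   tkeys)), 180, tolerance = 1e-8)
  for (ang in c(70, -70, 113, -166, 25.5))
    expect_equal(measure_torsion(torsion_model(dihedral_points(ang)), tkeys),
                 ang, tolerance = 1e-6)
})

test_that("collinear torsion atoms are rejected", {
  p <- list(a = c(0, 0, 0), b = c(1, 0, 0), c = c(2, 0, 0), d = c(3, 1, 0))
  expect_error(measure_torsion(torsion_model(p), tkeys), "degenerate-torsion")
})

test_that("an Asp-carboxylate at 2.74 A from a ligand amine is one H-bond", {
  m <- two_atom_model(c(0, 0, 0), c(2.74, 0, 0))
  ev <- detect_hbonds(m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.74)
  expect_equal(ev$kind, "hbond")
  # same pair beyond the 3.5 A heavy-atom cutoff: nothing
  expect_equal(nrow(detect_hbonds(two_atom_model(c(0, 0, 0), c(3.6, 0, 0)))),
               0)
})

test_that("salt bridges respect the 4.0 A default cutoff", {
  glu_lys <- function(d) two_atom_model(c(0, 0, 0), c(d, 0, 0), res1 = "GLU",
                                        n1 = "OE1", res2 = "LYS", n2 = "NZ",
                                        seq1 = 935, seq2 = 938, ch2 = "A")
  ev <- detect_salt_bridges(glu_lys(2.70))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "salt_bridge")
  expect_equal(nrow(detect_salt_bridges(glu_lys(4.5))), 0)
})

test_that("metal coordination includes waters and needs a metal match", {
  m <- mini_model(data.frame(
    name = c("CU", "NE2", "O"), res_name = c("CU", "HIS", "HOH"),
    res_seq = c(3052, 1022, 2090), chain = c("M", "A", "W"),
    x = c(0, 2.1, 0), y = c(0, 0, 3.4), z = 0, stringsAsFactors = FALSE))
  ev <- detect_metal_coordination(m)
  expect_equal(nrow(ev), 1)           # His at 2.1 in, water at 3.4 out
  expect_equal(ev$distance, 2.1)
  m2 <- mini_model(data.frame(
    name = c("CU", "O"), res_name = c("CU", "HOH"), res_seq = c(1, 2),
    chain = "M", x = c(0, 2.5), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_equal(detect_metal_coordination(m2)$distance, 2.5)
  expect_error(detect_metal_coordination(m, metal_selection = "elem FE"),
               "argument")
})

hexagon <- function(center, u, v, r = 1.55) {
  th <- (0:5) * pi / 3
  t(vapply(th, function(t) center + r * (cos(t) * u + sin(t) * v),
           numeric(3)))
}

ring_model <- function(xa, xb) {
  mini_model(data.frame(
    name = c(paste0("C", 1:6), paste0("D", 1:6)),
    res_name = c(rep("LIG", 6), rep("PHE", 6)),
    res_seq = c(rep(1, 6), rep(209, 6)), chain = c(rep("L", 6), rep("A", 6)),
    x = c(xa[, 1], xb[, 1]), y = c(xa[, 2], xb[, 2]),
    z = c(xa[, 3], xb[, 3]), stringsAsFactors = FALSE))
}

ra_keys <- paste0("L:LIG:1:C", 1:6)
rb_keys <- paste0("A:PHE:209:D", 1:6)

test_that("perpendicular rings at 5 A are a T contact, parallel rings are not", {
  xa <- hexagon(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  xb <- hexagon(c(0, 0, 5), c(1, 0, 0), c(0, 0, 1))   # plane contains z
  ev <- detect_pi_T(ring_model(xa, xb), ra_keys, rb_keys)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$extra, 90, tolerance = 1e-6)
  expect_equal(ev$distance, 5, tolerance = 1e-8)
  xpar <- hexagon(c(0, 0, 4), c(1, 0, 0), c(0, 1, 0))  # coplanar stack
  expect_equal(nrow(detect_pi_T(ring_model(xa, xpar), ra_keys, rb_keys)), 0)
  xfar <- hexagon(c(0, 0, 8), c(1, 0, 0), c(0, 0, 1))  # T but too far
  expect_equal(nrow(detect_pi_T(ring_model(xa, xfar), ra_keys, rb_keys)), 0)
})

test_that("randomized ring placements match direct centroid/normal math", {
  set.seed(21)
  for (i in 1:25) {
    ctr <- runif(3, -3, 3)
    # random orthonormal pair
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    xa <- hexagon(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
    xb <- hexagon(ctr, q[, 1], q[, 2])
    ev <- detect_pi_T(ring_model(xa, xb), ra_keys, rb_keys)
    d <- sqrt(sum(ctr^2))
    ang <- acos(min(abs(q[, 3][3]), 1)) * 180 / pi   # vs z normal of ring a
    expected <- d >= 4 && d <= 7 && ang >= 60
    expect_equal(nrow(ev) == 1, expected)
    if (nrow(ev) == 1) expect_equal(ev$extra, ang, tolerance = 1e-6)
  }
})

test_that("degenerate rings are rejected", {
  line <- cbind(seq(0, 5, length.out = 6), 0, 0)
  xa <- hexagon(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(detect_pi_T(ring_model(xa, line), ra_keys, rb_keys),
               "degenerate-ring")
})

test_that("all detectors equal their brute-force oracles on random models", {
  for (s in 1:20) {
    m <- random_model(n = 80, seed = s)
    expect_equal(event_pairs(detect_hbonds(m)), oracle_hbonds(m),
                 tolerance = 1e-10)
    expect_equal(event_pairs(detect_salt_bridges(m)), oracle_salt_bridges(m),
                 tolerance = 1e-10)
    expect_equal(event_pairs(detect_metal_coordination(m)), oracle_metal(m),
                 tolerance = 1e-10)
  }
})

test_that("detector output is invariant under rigid motion of the model", {
  m <- random_model(n = 80, seed = 3)
  R <- rot_z(37)
  xyz <- sweep(cbind(m$atoms$x, m$atoms$y, m$atoms$z) %*% t(R), 2,
               c(4, -7, 11), "+")
  m2 <- m
  m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
  for (fn in list(detect_hbonds, detect_salt_bridges))
    expect_equal(event_pairs(fn(m)), event_pairs(fn(m2)), tolerance = 1e-8)
})

test_that("occupancy is exact snapshot arithmetic and respects grouping", {
  ev <- data.frame(kind = "hbond", atom_a = "A:GLU:272:OE1",
                   atom_b = "L:SRO:2001:N1", distance = 2.6,
                   frame = c(1, 2, 3), extra = NA_real_)
  of <- occupancy(ev, frame_range = 1:6)
  expect_equal(of$of_percent, 50)        # present in 3 of 6 frames
  expect_equal(of$n_present, 3)
  of_all <- occupancy(ev, frame_range = 1:3)
  expect_equal(of_all$of_percent, 100)
  # residue grouping: OD1-or-OD2 counts once per frame, O.F. >= atom-level
  ev2 <- data.frame(kind = "hbond",
                    atom_a = c("A:ASP:1025:OD1", "A:ASP:1025:OD2",
                               "A:ASP:1025:OD2"),
                    atom_b = "L:SRO:2001:N1", distance = 2.7,
                    frame = c(1, 2, 3), extra = NA_real_)
  atom_level <- occupancy(ev2, frame_range = 1:4)
  res_level <- occupancy(
    ev2, key_fn = function(e) paste(residue_label(e$atom_a),
                                    residue_label(e$atom_b)),
    frame_range = 1:4)
  expect_equal(res_level$of_percent, 75)
  expect_gte(res_level$of_percent, max(atom_level$of_percent))
  expect_equal(res_level$key, "ASP1025 SRO2001")
})

test_that("a planted Bernoulli(0.85) contact is recovered within 3 points", {
  set.seed(4242)
  present <- which(runif(1000) < 0.85)
  ev <- data.frame(kind = "hbond", atom_a = "A:GLU:935:OE1",
                   atom_b = "A:LYS:938:NZ", distance = 2.7, frame = present,
                   extra = NA_real_)
  of <- occupancy(ev, frame_range = 1:1000)
  expect_lt(abs(of$of_percent - 100 * length(present) / 1000), 1e-9)
  expect_lt(abs(of$of_percent - 85), 3)
})

test_that("enlarging the cutoff never lowers an occupation frequency", {
  m_list <- lapply(1:40, function(s) random_model(60, seed = 100 + s))
  cuts <- c(2.5, 3.0, 3.5, 4.0)
  prev <- NULL
  for (dm in cuts) {
    ev <- do.call(rbind, lapply(seq_along(m_list), function(i)
      detect_hbonds(m_list[[i]], d_max = dm, frame = i)))
    of <- occupancy(ev, frame_range = 1:40)
    cur <- stats::setNames(of$of_percent, of$key)
    if (!is.null(prev))
      for (k in names(prev))
        expect_gte(cur[[k]], prev[[k]])
    prev <- cur
  }
})
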