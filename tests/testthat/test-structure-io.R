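pdb_line <- function(serial, name, res, chain, seq, x, y, z, occ = 1,
                     alt = " ", rec = "ATOM  ") {
  nm <- if (nchar(name) >= 4) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%s%5d %4s%s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          rec, serial, nm, alt, res, chain, seq, x, y, z, occ, 0)
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

test_that("multi-MODEL files parse into one frame per model", {
  lines <- c("MODEL        1",
             pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
             pdb_line(3, "C", "ALA", "A", 1, 2, 1.3, 0),
             pdb_line(4, "O", "ALA", "A", 1, 3.2, 1.5, 0),
             pdb_line(5, "CB", "ALA", "A", 1, 1.5, -1.5, 0),
             "ENDMDL",
             "MODEL        2",
             pdb_line(1, "N", "ALA", "A", 1, 0.1, 0, 0),
             pdb_line(2, "CA", "ALA", "A", 1, 1.6, 0, 0),
             pdb_line(3, "C", "ALA", "A", 1, 2.1, 1.3, 0),
             pdb_line(4, "O", "ALA", "A", 1, 3.3, 1.5, 0),
             pdb_line(5, "CB", "ALA", "A", 1, 1.6, -1.5, 0),
             "ENDMDL", "END")
  e <- read_structure(write_tmp_pdb(lines))
  expect_equal(n_frames(e), 2)
  expect_equal(nrow(e$frames[[1]]$atoms), 5)
  expect_equal(nrow(e$frames[[2]]$atoms), 5)
  expect_equal(e$frames[[2]]$atoms$x[1], 0.1)
})

test_that("a non-water atom missing from one model is a consistency error", {
  lines <- c("MODEL        1",
             pdb_line(1, "N", "GLY", "A", 3, 0, 0, 0),
             pdb_line(2, "CA", "GLY", "A", 3, 1.5, 0, 0),
             "ENDMDL",
             "MODEL        2",
             pdb_line(1, "N", "GLY", "A", 3, 0, 0, 0),
             "ENDMDL", "END")
  expect_error(read_structure(write_tmp_pdb(lines)), "consistency")
})

test_that("missing files and atom-free files raise I/O errors", {
  expect_error(read_structure(tempfile()), "I/O")
  expect_error(read_structure(write_tmp_pdb(c("REMARK nothing", "END"))),
               "empty-structure")
})

test_that("highest-occupancy altloc wins, ties broken by letter", {
  lines <- c(pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
             pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
             pdb_line(3, "OG", "SER", "A", 1, 1, 1, 1, occ = 0.5, alt = "A"),
             pdb_line(4, "OG", "SER", "A", 1, 5, 5, 5, occ = 0.5, alt = "B"),
             "END")
  m <- read_structure(write_tmp_pdb(lines))$frames[[1]]
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 9)   # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$name == "OG"], 1)   # tie -> altloc A
})

test_that("frames follow MODEL numbers, not record order", {
  lines <- c("MODEL        2",
             pdb_line(1, "CA", "GLY", "A", 1, 5, 0, 0),
             pdb_line(2, "N", "GLY", "A", 1, 6, 0, 0),
             "ENDMDL",
             "MODEL        1",
             pdb_line(1, "CA", "GLY", "A", 1, 1, 0, 0),
             pdb_line(2, "N", "GLY", "A", 1, 2, 0, 0),
             "ENDMDL", "END")
  e <- read_structure(write_tmp_pdb(lines))
  expect_equal(e$frames[[1]]$atoms$x[1], 1)
  expect_equal(e$frames[[2]]$atoms$x[1], 5)
})

test_that("write then read is the identity to 0.001 A, waters included", {
  bs <- benchmark_system(seed = 11, n_frames = 20)
  f <- tempfile(fileext = ".pdb")
  write_structure(bs$ensemble, f)
  back <- read_structure(f)
  expect_equal(n_frames(back), 20)
  for (i in c(1, 7, 20)) {
    a0 <- bs$ensemble$frames[[i]]$atoms
    a1 <- back$frames[[i]]$atoms
    expect_equal(nrow(a1), nrow(a0))
    expect_equal(a1$name, a0$name)
    expect_equal(a1$res_seq, a0$res_seq)
    expect_equal(a1$res_name, a0$res_name)
    expect_lt(max(abs(a1$x - a0$x), abs(a1$y - a0$y), abs(a1$z - a0$z)),
              0.0011)
  }
})

test_that("single-frame output has no MODEL records and bio3d agrees", {
  skip_if_not_installed("bio3d")
  m <- make_scaffold(scaffold_spec(crystal_waters = TRUE), seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  expect_false(any(grepl("^MODEL", readLines(f))))
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ref$atom), nrow(m$atoms))
  expect_equal(ref$atom$x, round(m$atoms$x, 3))
  expect_equal(ref$atom$resno, m$atoms$res_seq)
  expect_equal(ref$atom$elety, m$atoms$name)
})

test_that("selection grammar picks the documented subsets", {
  m <- make_scaffold(scaffold_spec(crystal_waters = TRUE), seed = 1)
  w <- select_atoms(m, "resname HOH")
  expect_equal(nrow(w), 6)               # oxygen-only waters
  expect_true(all(w$element == "O"))
  od <- select_atoms(m, "res 1025 and name OD1,OD2")
  expect_equal(nrow(od), 2)
  expect_setequal(od$name, c("OD1", "OD2"))
  expect_equal(od$res_name, c("ASP", "ASP"))
  expect_equal(nrow(select_atoms(m, "resname XXX")), 0)   # empty, no error
  cu <- select_atoms(m, "elem CU")
  expect_equal(nrow(cu), 6)
  # helix 931-937: GLU(7) + 4xALA(5) + GLU(7) + ASN(7) atoms
  expect_equal(nrow(select_atoms(m, "chain A and res 931-937")), 41)
  expect_error(parse_selection("frobnicate 12"), "selection-syntax")
  expect_error(parse_selection("res twelve"), "selection-syntax")
})
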