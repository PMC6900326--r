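# ensemble of pure water frames at given positions (already "aligned")
water_frames <- function(pos_list, ids_list = NULL) {
  frames <- lapply(seq_along(pos_list), function(i) {
    p <- pos_list[[i]]
    if (is.null(p) || !nrow(p)) p <- matrix(numeric(0), ncol = 3)
    ids <- if (is.null(ids_list)) 9000 + seq_len(nrow(p)) else ids_list[[i]]
    base <- data.frame(name = "CA", res_name = "ALA",
                       res_seq = 1:3, chain = "A",
                       x = c(0, 5, 0), y = c(0, 0, 5), z = 0)
    w <- if (nrow(p))
      data.frame(name = "O", res_name = "HOH", res_seq = ids, chain = "W",
                 x = p[, 1], y = p[, 2], z = p[, 3])
    else NULL
    structure_model(rbind(base, w), model_id = i)
  })
  e <- md_ensemble(frames)
  e$aligned <- TRUE
  e
}

test_that("one jittered water gives one fully-occupied conserved site", {
  set.seed(10)
  pos <- lapply(1:100, function(i)
    matrix(c(3, 3, 3) + rnorm(3, sd = 0.1), ncol = 3))
  sites <- cluster_water_sites(water_frames(pos))
  expect_length(sites, 1)
  expect_equal(sites[[1]]$occupancy$of_percent, 100)
  expect_equal(sites[[1]]$conservation_class, "conserved")
  expect_equal(sites[[1]]$site_id, "WS1")
  expect_lt(max(sites[[1]]$members$dist), 1.8)
})

test_that("two well-separated persistent waters give two 100% sites", {
  pos <- lapply(1:50, function(i)
    rbind(c(0, 0, 0), c(10, 0, 0)))
  sites <- cluster_water_sites(water_frames(pos))
  expect_length(sites, 2)
  expect_equal(unname(vapply(sites, function(s) s$occupancy$of_percent, 1)),
               c(100, 100))
})

test_that("an intermittent site with identity exchange is recovered", {
  bs <- benchmark_system(seed = 31, n_frames = 1000)
  al <- align_ensemble(bs$ensemble)
  sites <- cluster_water_sites(
    al, region = selection(res_name = "SRO", oxygen_only_water = FALSE))
  expect_length(sites, 3)
  of <- vapply(sites, function(s) s$occupancy$of_percent, 1)
  expect_lt(abs(of[1] - 100), 3)
  expect_lt(abs(of[2] - 85), 3)
  expect_lt(abs(of[3] - 50), 3)
  # water-identity exchange at the top site: several distinct residue ids
  expect_gte(length(unique(sites[[1]]$members$water_id)), 2)
  cls <- unname(vapply(sites, function(s) s$conservation_class, ""))
  expect_equal(cls, c("conserved", "semi_conserved", "transient"))
})

test_that("conservation classes follow the 90/60 thresholds", {
  fake_site <- function(of) list(site_id = "WS1", centroid = c(0, 0, 0),
                                 members = NULL,
                                 occupancy = list(of_percent = of))
  cls <- function(of)
    classify_sites(list(fake_site(of)))[[1]]$conservation_class
  expect_equal(cls(100), "conserved")
  expect_equal(cls(90), "conserved")
  expect_equal(cls(85), "semi_conserved")
  expect_equal(cls(60), "semi_conserved")
  expect_equal(cls(59.9), "transient")
})

test_that("skipping superposition inflates the site count at least 3-fold", {
  bs <- benchmark_system(seed = 17, n_frames = 400)
  p0 <- cluster_params(min_occupancy_report = 0)
  aligned <- cluster_water_sites(align_ensemble(bs$ensemble), p0)
  raw <- suppressWarnings(cluster_water_sites(bs$ensemble, p0))
  expect_gte(length(raw), 3 * length(aligned))
})

test_that("an unaligned-looking ensemble triggers a warning", {
  bs <- benchmark_system(seed = 2, n_frames = 5)
  expect_warning(cluster_water_sites(bs$ensemble), "aligned")
})

test_that("clustering is deterministic and respects per-frame uniqueness", {
  bs <- benchmark_system(seed = 23, n_frames = 150)
  al <- align_ensemble(bs$ensemble)
  s1 <- cluster_water_sites(al)
  s2 <- cluster_water_sites(al)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # at most one member water per frame per site; assigned <= waters in frame
  per_frame_waters <- vapply(al$frames, function(f)
    sum(f$atoms$is_water), 1L)
  assigned <- table(factor(unlist(lapply(s1, function(s) s$members$frame)),
                           levels = seq_len(n_frames(al))))
  expect_true(all(assigned <= per_frame_waters))
  for (s in s1) expect_false(anyDuplicated(s$members$frame) > 0)
})

test_that("tightening the pairing cutoff never merges sites away", {
  set.seed(77)
  pos <- lapply(1:80, function(i) {
    n <- sample(1:4, 1)
    matrix(runif(3 * n, 0, 6), ncol = 3)
  })
  e <- water_frames(pos)
  p0 <- function(cut) cluster_params(link_cutoff = cut,
                                     min_occupancy_report = 0)
  n_sites <- vapply(c(2.4, 1.8, 1.2, 0.6), function(cut)
    length(cluster_water_sites(e, p0(cut))), 1L)
  expect_true(all(diff(n_sites) >= 0))
})

test_that("water matching between structures is a greedy nearest pairing", {
  m <- make_scaffold(scaffold_spec(crystal_waters = TRUE), seed = 1)
  self <- match_waters_between_structures(m, m)
  expect_equal(nrow(self), 6)
  expect_true(all(self$distance == 0))
  expect_equal(self$ref_water, self$other_water)
  # displace one water by 2.0 A: beyond the 1.8 A pairing cutoff
  m2 <- m
  i <- which(m2$atoms$res_seq == 2326 & m2$atoms$is_water)
  m2$atoms$x[i] <- m2$atoms$x[i] + 2.0
  moved <- match_waters_between_structures(m, m2)
  expect_equal(nrow(moved), 5)
  expect_true(2326 %in% attr(moved, "unmatched_ref"))
  expect_true(2326 %in% attr(moved, "unmatched_other"))
})

test_that("matching equals the exhaustive greedy oracle on random sets", {
  for (s in 1:10) {
    set.seed(s)
    nr <- sample(3:8, 1); no <- sample(3:8, 1)
    wr <- matrix(runif(3 * nr, 0, 6), ncol = 3)
    wo <- matrix(runif(3 * no, 0, 6), ncol = 3)
    mk <- function(w, ids) structure_model(data.frame(
      name = "O", res_name = "HOH", res_seq = ids, chain = "W",
      x = w[, 1], y = w[, 2], z = w[, 3]))
    got <- match_waters_between_structures(mk(wr, 100 + 1:nr),
                                           mk(wo, 200 + 1:no), cutoff = 1.8)
    # oracle: repeatedly take the globally nearest unmatched pair <= cutoff
    d <- as.matrix(stats::dist(rbind(wr, wo)))[1:nr, nr + 1:no, drop = FALSE]
    pairs <- list()
    repeat {
      if (all(!is.finite(d)) || min(d) > 1.8) break
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1]] <- c(100 + ij[1], 200 + ij[2], d[ij[1], ij[2]])
      d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
    }
    if (length(pairs)) {
      want <- do.call(rbind, pairs)
      got_o <- got[order(got$ref_water), ]
      want_o <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(got_o$ref_water, as.integer(want_o[, 1]))
      expect_equal(got_o$other_water, as.integer(want_o[, 2]))
      expect_equal(got_o$distance, unname(want_o[, 3]), tolerance = 1e-10)
    } else expect_equal(nrow(got), 0)
  }
})
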