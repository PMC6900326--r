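#' Clustering parameters for water-site detection
#'
#' `link_cutoff` is the pairing distance between superposed water positions
#' (1.8 Angstrom by default); `conserved_threshold` / `semi_threshold` are the
#' occupation-frequency boundaries of the conservation classes; sites below
#' `min_occupancy_report` percent are dropped from reports.
#'
#' @param link_cutoff Angstrom, > 0.
#' @param min_occupancy_report,conserved_threshold,semi_threshold percent.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(link_cutoff = 1.8, min_occupancy_report = 10,
                           conserved_threshold = 90, semi_threshold = 60) {
  stopifnot(link_cutoff > 0, semi_threshold >= 0,
            semi_threshold <= conserved_threshold, conserved_threshold <= 100)
  structure(list(link_cutoff = link_cutoff,
                 min_occupancy_report = min_occupancy_report,
                 conserved_threshold = conserved_threshold,
                 semi_threshold = semi_threshold),
            class = "cluster_params")
}

# per-frame water oxygen table: frame, water_id, x, y, z
water_table <- function(ensemble, region = NULL, region_radius = 6) {
  out <- vector("list", n_frames(ensemble))
  for (i in seq_len(n_frames(ensemble))) {
    a <- ensemble$frames[[i]]$atoms
    w <- a[a$is_water & a$element == "O", , drop = FALSE]
    if (!is.null(region) && nrow(w)) {
      ridx <- select_idx(ensemble$frames[[i]], region)
      if (length(ridx)) {
        rx <- coords(ensemble$frames[[i]], ridx)
        wx <- cbind(w$x, w$y, w$z)
        d2 <- outer(rowSums(wx^2), rowSums(rx^2), "+") - 2 * wx %*% t(rx)
        w <- w[sqrt(pmax(apply(d2, 1, min), 0)) <= region_radius, ,
               drop = FALSE]
      }
    }
    if (nrow(w))
      out[[i]] <- data.frame(frame = i, water_id = w$res_seq,
                             x = w$x, y = w$y, z = w$z)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect hydrophilic water sites across a superposed ensemble
#'
#' Greedy leader clustering of superposed water-oxygen positions, frame by
#' frame: each water joins the nearest existing site whose centroid lies
#' within `link_cutoff` (ties broken toward the lower site index), otherwise
#' seeds a new site; when two waters of one frame map to one site the nearer
#' wins and the other is re-queued. Site centroids are updated after each
#' frame. A single refinement pass then re-assigns every water against the
#' frozen centroids (minimum-distance greedy matching, at most one water per
#' site per frame). Sites are sorted by occupancy (descending) and labeled
#' WS1, WS2, ... deterministically.
#'
#' @param aligned an aligned [md_ensemble()] (a warning is issued when the
#'   ensemble does not carry the aligned flag).
#' @param params a [cluster_params()].
#' @param region optional selection; only waters within `region_radius`
#'   Angstrom of the selected atoms (per frame) are clustered.
#' @param region_radius Angstrom, used with `region`.
#' @return object of class `water_sites`: list of sites, each with
#'   `site_id`, `centroid`, `members` (frame, water_id, dist), `occupancy`
#'   (n_present, n_total, of_percent) and `conservation_class`.
#' @export
cluster_water_sites <- function(aligned, params = cluster_params(),
                                region = NULL, region_radius = 6) {
  stopifnot(inherits(aligned, "md_ensemble"))
  if (!isTRUE(aligned$aligned))
    warning("ensemble does not carry the aligned flag; ",
            "site detection assumes superposed frames")
  wt <- water_table(aligned, region, region_radius)
  nf <- n_frames(aligned)
  if (is.null(wt) || !nrow(wt))
    return(structure(list(), class = "water_sites",
                     n_total = nf, params = params))

  cutoff <- params$link_cutoff
  cent <- matrix(numeric(0), ncol = 3)     # running centroids
  sums <- matrix(numeric(0), ncol = 3); cnt <- integer(0)

  for (f in sort(unique(wt$frame))) {
    rows <- which(wt$frame == f)
    queue <- rows
    excluded <- lapply(rows, function(r) integer(0))
    names(excluded) <- as.character(rows)
    taken <- integer(0)      # site -> row taken this frame
    taken_d <- numeric(0)
    while (length(queue)) {
      r <- queue[1]; queue <- queue[-1]
      p <- c(wt$x[r], wt$y[r], wt$z[r])
      sid <- NA_integer_
      if (nrow(cent)) {
        d <- sqrt(rowSums(sweep(cent, 2, p)^2))
        d[excluded[[as.character(r)]]] <- Inf
        ok <- which(d <= cutoff)
        if (length(ok)) sid <- ok[which.min(d[ok])]   # ties -> lowest index
      }
      if (is.na(sid)) {                 # seed a new site at this water
        cent <- rbind(cent, p); sums <- rbind(sums, p); cnt <- c(cnt, 1L)
        sid <- nrow(cent)
        taken[as.character(sid)] <- r; taken_d[as.character(sid)] <- 0
        next
      }
      dr <- sqrt(sum((cent[sid, ] - p)^2))
      key <- as.character(sid)
      if (is.na(taken[key])) {
        taken[key] <- r; taken_d[key] <- dr
        sums[sid, ] <- sums[sid, ] + p; cnt[sid] <- cnt[sid] + 1L
      } else if (dr < taken_d[key]) {   # displace the farther water
        loser <- taken[key]
        lp <- c(wt$x[loser], wt$y[loser], wt$z[loser])
        sums[sid, ] <- sums[sid, ] - lp + p
        taken[key] <- r; taken_d[key] <- dr
        excluded[[as.character(loser)]] <-
          c(excluded[[as.character(loser)]], sid)
        queue <- c(queue, loser)
      } else {
        excluded[[as.character(r)]] <- c(excluded[[as.character(r)]], sid)
        queue <- c(queue, r)
      }
    }
    keep <- cnt > 0
    cent[keep, ] <- sums[keep, , drop = FALSE] / cnt[keep]
  }

  # refinement pass against frozen centroids
  members <- refine_assignments(wt, cent, cutoff)
  build_sites(members, wt, nf, params)
}

# minimum-distance greedy matching of waters to frozen centroids, per frame
refine_assignments <- function(wt, cent, cutoff) {
  out <- vector("list", length(unique(wt$frame)))
  k <- 0
  for (f in sort(unique(wt$frame))) {
    rows <- which(wt$frame == f)
    wx <- cbind(wt$x[rows], wt$y[rows], wt$z[rows])
    d2 <- outer(rowSums(wx^2), rowSums(cent^2), "+") - 2 * wx %*% t(cent)
    d <- sqrt(pmax(d2, 0))
    cand <- which(d <= cutoff, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(d[cand], cand[, 2], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
    used_w <- logical(length(rows)); used_s <- logical(nrow(cent))
    sel <- logical(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      wi <- cand[j, 1]; si <- cand[j, 2]
      if (!used_w[wi] && !used_s[si]) {
        used_w[wi] <- TRUE; used_s[si] <- TRUE; sel[j] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    if (!nrow(cand)) next
    k <- k + 1
    out[[k]] <- data.frame(site = cand[, 2], row = rows[cand[, 1]],
                           dist = d[cand])
  }
  do.call(rbind, out[seq_len(k)])
}

build_sites <- function(members, wt, n_total, params) {
  if (is.null(members) || !nrow(members))
    return(structure(list(), class = "water_sites",
                     n_total = n_total, params = params))
  sites <- lapply(split(members, members$site), function(g) {
    pos <- cbind(wt$x[g$row], wt$y[g$row], wt$z[g$row])
    ctr <- colMeans(pos)
    mem <- data.frame(frame = wt$frame[g$row], water_id = wt$water_id[g$row],
                      dist = sqrt(rowSums(sweep(pos, 2, ctr)^2)))
    mem <- mem[order(mem$frame), , drop = FALSE]
    rownames(mem) <- NULL
    np <- length(unique(mem$frame))
    list(site_id = NA_character_, centroid = ctr, members = mem,
         occupancy = list(n_present = np, n_total = n_total,
                          of_percent = 100 * np / n_total))
  })
  occ <- vapply(sites, function(s) s$occupancy$of_percent, numeric(1))
  sites <- sites[occ >= params$min_occupancy_report]
  occ <- occ[occ >= params$min_occupancy_report]
  cx <- vapply(sites, function(s) s$centroid[1], numeric(1))
  cy <- vapply(sites, function(s) s$centroid[2], numeric(1))
  cz <- vapply(sites, function(s) s$centroid[3], numeric(1))
  ord <- order(-occ, cx, cy, cz)
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$site_id <- paste0("WS", i)
  classify_sites(structure(sites, class = "water_sites",
                           n_total = n_total, params = params), params)
}

#' Assign conservation classes to water sites
#'
#' A site is `conserved` when its O.F. is at least `conserved_threshold`
#' percent (default 90), `semi_conserved` at `semi_threshold` (default 60),
#' otherwise `transient`.
#'
#' @param sites a `water_sites` object (or plain list of sites).
#' @param params a [cluster_params()].
#' @return `sites`, each with `conservation_class` filled in.
#' @export
classify_sites <- function(sites, params = cluster_params()) {
  for (i in seq_along(sites)) {
    of <- sites[[i]]$occupancy$of_percent
    sites[[i]]$conservation_class <-
      if (of >= params$conserved_threshold) "conserved"
      else if (of >= params$semi_threshold) "semi_conserved"
      else "transient"
  }
  sites
}

#' @export
print.water_sites <- function(x, ...) {
  cat(sprintf("<water_sites> %d site(s) over %d frames\n",
              length(x), attr(x, "n_total")))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' Tabulate water sites
#'
#' @param x a `water_sites` object.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame with one row per site: `site_id`, centroid `x/y/z`,
#'   `n_present`, `n_total`, `of_percent`, `class`, `n_water_ids` (distinct
#'   water residue ids observed at the site -- identity exchange shows as
#'   `n_water_ids > 1`).
#' @export
as.data.frame.water_sites <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  if (!length(x))
    return(data.frame(site_id = character(), x = numeric(), y = numeric(),
                      z = numeric(), n_present = integer(),
                      n_total = integer(), of_percent = numeric(),
                      class = character(), n_water_ids = integer()))
  do.call(rbind, lapply(x, function(s) data.frame(
    site_id = s$site_id, x = s$centroid[1], y = s$centroid[2],
    z = s$centroid[3], n_present = s$occupancy$n_present,
    n_total = s$occupancy$n_total,
    of_percent = s$occupancy$of_percent, class = s$conservation_class,
    n_water_ids = length(unique(s$members$water_id)),
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Match waters between two superposed structures
#'
#' One-to-one matching of water oxygens: candidate pairs are sorted by
#' distance (ascending) and accepted greedily when both waters are still
#' unmatched and the distance is at most `cutoff` (the 1.8 Angstrom pairing
#' convention by default).
#'
#' @param reference,other [structure_model()]s; `other` must already be
#'   superposed onto `reference`.
#' @param cutoff pairing distance, Angstrom.
#' @return data.frame with columns `ref_water`, `other_water` (residue ids)
#'   and `distance`; unmatched water ids are attached as attributes
#'   `unmatched_ref` and `unmatched_other`.
#' @export
match_waters_between_structures <- function(reference, other, cutoff = 1.8) {
  wr <- reference$atoms[reference$atoms$is_water &
                          reference$atoms$element == "O", , drop = FALSE]
  wo <- other$atoms[other$atoms$is_water & other$atoms$element == "O", ,
                    drop = FALSE]
  empty <- data.frame(ref_water = integer(), other_water = integer(),
                      distance = numeric())
  if (!nrow(wr) || !nrow(wo)) {
    attr(empty, "unmatched_ref") <- wr$res_seq
    attr(empty, "unmatched_other") <- wo$res_seq
    return(empty)
  }
  xr <- cbind(wr$x, wr$y, wr$z); xo <- cbind(wo$x, wo$y, wo$z)
  d <- sqrt(pmax(outer(rowSums(xr^2), rowSums(xo^2), "+") - 2 * xr %*% t(xo), 0))
  cand <- which(d <= cutoff, arr.ind = TRUE)
  out <- empty
  if (nrow(cand)) {
    cand <- cand[order(d[cand], cand[, 1], cand[, 2]), , drop = FALSE]
    used_r <- logical(nrow(wr)); used_o <- logical(nrow(wo))
    rows <- list(); k <- 0
    for (j in seq_len(nrow(cand))) {
      i <- cand[j, 1]; o <- cand[j, 2]
      if (!used_r[i] && !used_o[o]) {
        used_r[i] <- used_o[o] <- TRUE
        k <- k + 1
        rows[[k]] <- data.frame(ref_water = wr$res_seq[i],
                                other_water = wo$res_seq[o],
                                distance = d[i, o])
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "unmatched_ref") <- wr$res_seq[!used_r]
    attr(out, "unmatched_other") <- wo$res_seq[!used_o]
  } else {
    attr(out, "unmatched_ref") <- wr$res_seq
    attr(out, "unmatched_other") <- wo$res_seq
  }
  rownames(out) <- NULL
  out
}
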