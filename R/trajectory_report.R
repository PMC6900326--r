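#' RMSD time series of an aligned ensemble
#'
#' Per-frame root-mean-square deviation over the selected atoms against the
#' reference frame, after superposition (the fit is assumed already applied;
#' see [align_ensemble()]).
#'
#' @param aligned an aligned [md_ensemble()].
#' @param sel selection evaluated on every frame (default: backbone).
#' @param reference_frame index of the reference frame.
#' @return `metric_series` data.frame with columns `frame`, `time_ps`,
#'   `value` (Angstrom) and a `summary` attribute (min/max/mean/sd).
#' @export
rmsd_series <- function(aligned, sel = "backbone", reference_frame = 1) {
  stopifnot(inherits(aligned, "md_ensemble"))
  ref <- aligned$frames[[reference_frame]]
  idx <- select_idx(ref, sel)
  if (!length(idx)) stop("argument error: empty selection for RMSD")
  keys <- model_keys(ref)[idx]
  rx <- coords(ref, idx)
  vals <- vapply(seq_len(n_frames(aligned)), function(i) {
    f <- aligned$frames[[i]]
    m <- match(keys, model_keys(f))
    if (anyNA(m)) stop("argument error: selection absent from frame ", i)
    sqrt(mean(rowSums((coords(f, m) - rx)^2)))
  }, numeric(1))
  metric_series("rmsd", seq_len(n_frames(aligned)), frame_times(aligned), vals)
}

#' Per-residue RMSF of an aligned ensemble
#'
#' Root-mean-square fluctuation about the mean position over frames,
#' `sqrt(<|r - <r>|^2>)`, computed per selected atom and averaged over each
#' residue's selected atoms.
#'
#' @param aligned an aligned [md_ensemble()].
#' @param sel selection (default: backbone).
#' @return `metric_series` data.frame indexed by residue: columns `chain`,
#'   `res_seq`, `res_name`, `value` (Angstrom).
#' @export
rmsf_per_residue <- function(aligned, sel = "backbone") {
  stopifnot(inherits(aligned, "md_ensemble"))
  ref <- aligned$frames[[1]]
  idx <- select_idx(ref, sel)
  if (!length(idx)) stop("argument error: empty selection for RMSF")
  keys <- model_keys(ref)[idx]
  nf <- n_frames(aligned)
  # two-pass: mean position first, then squared deviations (numerically
  # stable for coordinates far from the origin)
  midx <- lapply(seq_len(nf), function(i) {
    m <- match(keys, model_keys(aligned$frames[[i]]))
    if (anyNA(m)) stop("argument error: selection absent from frame ", i)
    m
  })
  s1 <- matrix(0, length(idx), 3)
  for (i in seq_len(nf)) s1 <- s1 + coords(aligned$frames[[i]], midx[[i]])
  mean_xyz <- s1 / nf
  msf <- numeric(length(idx))
  for (i in seq_len(nf))
    msf <- msf + rowSums((coords(aligned$frames[[i]], midx[[i]]) -
                            mean_xyz)^2)
  atom_rmsf <- sqrt(msf / nf)
  a <- ref$atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$res_seq)
  agg <- tapply(atom_rmsf, key, mean)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], res_seq = a$res_seq[first],
                    res_name = a$res_name[first],
                    value = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$res_seq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- series_summary(out$value)
  class(out) <- c("metric_series", class(out))
  out
}

metric_series <- function(label, frames, times, values) {
  stopifnot(length(frames) == length(values), !is.unsorted(times, strictly = TRUE))
  out <- data.frame(frame = frames, time_ps = times, value = values)
  attr(out, "label") <- label
  attr(out, "summary") <- series_summary(values)
  class(out) <- c("metric_series", class(out))
  out
}

series_summary <- function(v)
  c(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))

#' Torsion time series
#'
#' @param ensemble an [md_ensemble()].
#' @param spec a [torsion_spec()].
#' @return `metric_series` data.frame (degrees).
#' @export
torsion_series <- function(ensemble, spec) {
  vals <- vapply(ensemble$frames, function(f) measure_torsion(f, spec),
                 numeric(1))
  metric_series(spec$label, seq_len(n_frames(ensemble)),
                frame_times(ensemble), vals)
}

#' Map snapshot times to frame indices
#'
#' Nearest frame by time; ties resolve toward the earlier frame.
#'
#' @param ensemble an [md_ensemble()].
#' @param times_ps numeric snapshot times (ps), all within the trajectory
#'   span.
#' @return integer frame indices.
#' @export
snapshot_frames <- function(ensemble, times_ps) {
  ft <- frame_times(ensemble)
  if (any(times_ps < min(ft) | times_ps > max(ft)))
    stop("argument error: snapshot outside trajectory span [",
         min(ft), ", ", max(ft), "] ps")
  vapply(times_ps, function(t) {
    d <- abs(ft - t)
    which(d == min(d))[1]    # ties -> earlier frame
  }, integer(1))
}

#' Consolidated tracked-interaction report
#'
#' One row per tracked atom pair: the interatomic distance at each snapshot
#' time (cell filled only when the pair is actually detected as interacting
#' in that snapshot's frame, mirroring snapshot tables of interaction
#' distances), plus the whole-trajectory occupation frequency of the pair.
#'
#' @param ensemble an [md_ensemble()].
#' @param events combined events data.frame over the ensemble.
#' @param pairs data.frame with columns `label`, `atom_a`, `atom_b` (atom
#'   keys). May be empty.
#' @param snapshot_times_ps numeric snapshot times, ps.
#' @param key_fn grouping rule for the occupancy column (default: the
#'   unordered atom pair).
#' @return data.frame: `label`, one `t<ns>` column per snapshot (distance in
#'   Angstrom or NA), `of_percent`.
#' @export
tracked_report <- function(ensemble, events, pairs, snapshot_times_ps,
                           key_fn = NULL) {
  snaps <- snapshot_frames(ensemble, snapshot_times_ps)
  cols <- paste0("t", snapshot_times_ps / 1000)
  if (is.null(pairs) || !nrow(pairs)) {
    out <- data.frame(label = character())
    for (cn in cols) out[[cn]] <- numeric()
    out$of_percent <- numeric()
    return(out)
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ev_key <- pair_key(events$atom_a, events$atom_b)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    k <- pair_key(pairs$atom_a[r], pairs$atom_b[r])
    d <- vapply(seq_along(snaps), function(j) {
      fr <- snaps[j]
      hit <- which(ev_key == k & events$frame == fr)
      if (!length(hit)) return(NA_real_)
      measure_distance(ensemble$frames[[fr]], pairs$atom_a[r], pairs$atom_b[r])
    }, numeric(1))
    present <- length(unique(events$frame[ev_key == k]))
    row <- data.frame(label = pairs$label[r], stringsAsFactors = FALSE)
    for (j in seq_along(cols)) row[[cols[j]]] <- d[j]
    row$of_percent <- 100 * present / n_frames(ensemble)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
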