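#' Rigid-body least-squares superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the weighted
#' RMSD of `mobile` onto `reference`; a reflection in the SVD solution is
#' corrected by a sign flip of the smallest singular vector, so `det(R) = +1`
#' always. The transform maps a mobile point `x` to `R x + t`.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, equal N.
#' @param weights optional non-negative N-vector (default uniform).
#' @return object of class `rigid_transform`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `fit_rmsd` (Angstrom, the minimized value).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("argument error: mobile and reference must be equal-size N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate-fit error: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("argument error: bad weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # rank check: collinear (or coincident) point sets have no unique rotation
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-8 || svd(B, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate-fit error: point set is collinear or coincident")
  H <- t(A * w) %*% B                       # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cr - R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = tr, fit_rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param xyz N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, -transform$translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> fit_rmsd = %.4f A\n", x$fit_rmsd))
  invisible(x)
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Each frame is fitted on `fit_selection` (default: protein backbone
#' N/CA/C/O, never waters, ligand or metals — the analytes must not bias the
#' fit) against the same selection in the reference frame, and the resulting
#' transform is applied to *all* atoms of the frame, waters included.
#' Idempotent: re-aligning an aligned ensemble is a no-op to numerical
#' precision.
#'
#' @param ensemble an [md_ensemble()].
#' @param fit_selection selection (string or [selection()]) used for fitting;
#'   must match at least 3 atoms present in every frame.
#' @param reference_frame index of the reference frame (default 1), or a
#'   [structure_model()] used as an external reference (e.g. a crystal
#'   structure) containing the fit selection.
#' @return the aligned `md_ensemble`, with a numeric `fit_rmsd` attribute
#'   (one value per frame, Angstrom).
#' @export
align_ensemble <- function(ensemble, fit_selection = "backbone",
                           reference_frame = 1) {
  stopifnot(inherits(ensemble, "md_ensemble"))
  sel <- parse_selection(fit_selection)
  if (inherits(reference_frame, "structure_model")) {
    ref_model <- reference_frame
  } else {
    stopifnot(reference_frame >= 1, reference_frame <= n_frames(ensemble))
    ref_model <- ensemble$frames[[reference_frame]]
  }
  ref_idx <- select_idx(ref_model, sel)
  if (length(ref_idx) < 3)
    stop("alignment-selection error: fit selection matches fewer than 3 atoms")
  ref_keys <- model_keys(ref_model)[ref_idx]
  ref_xyz <- coords(ref_model, ref_idx)

  rmsds <- numeric(n_frames(ensemble))
  for (i in seq_len(n_frames(ensemble))) {
    f <- ensemble$frames[[i]]
    idx <- match(ref_keys, model_keys(f))
    if (anyNA(idx))
      stop("alignment-selection error: fit atom ", ref_keys[which(is.na(idx))[1]],
           " absent from frame ", i)
    tr <- kabsch_fit(coords(f, idx), ref_xyz)
    ensemble$frames[[i]] <- set_coords(f, apply_transform(tr, coords(f)))
    rmsds[i] <- tr$fit_rmsd
  }
  ensemble$aligned <- TRUE
  attr(ensemble, "fit_rmsd") <- rmsds
  ensemble
}
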