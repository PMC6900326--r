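#' @title Structure models and ensembles
#' @description Core containers: a `structure_model` is one set of atomic
#'   coordinates (one MD frame or one crystal structure); an `md_ensemble` is
#'   an ordered list of frames sampled at a fixed time interval. All analysis
#'   functions in the package consume these two classes.
#' @name structure-containers
NULL

# Residue names recognized as water by default (TIP3P-converted MD frames and
# crystal conventions).
DEFAULT_WATER_NAMES <- c("HOH", "WAT", "TIP3", "SOL")

ATOM_COLS <- c("serial", "name", "element", "res_name", "res_seq", "chain",
               "x", "y", "z", "occupancy", "b_factor", "is_water")

#' Create a structure model
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain`, `x`, `y`, `z`, and optionally
#'   `occupancy`, `b_factor`, `is_water`. Coordinates are in Angstrom.
#' @param model_id integer model number (>= 1).
#' @param provenance free-text origin note.
#' @param water_names residue names treated as water when `is_water` is absent.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L, provenance = "",
                            water_names = DEFAULT_WATER_NAMES) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "res_name", "res_seq", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"element" %in% names(atoms))
    atoms$element <- guess_element(atoms$name, atoms$res_name)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  if (!"is_water" %in% names(atoms)) atoms$is_water <- atoms$res_name %in% water_names
  atoms$res_seq <- as.integer(atoms$res_seq)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atoms table")
  if (model_id < 1) stop("model_id must be >= 1")
  key <- paste(atoms$chain, atoms$res_seq, atoms$name)
  dup <- duplicated(key) & !atoms$is_water
  if (any(dup))
    stop("duplicate atom within model: ", key[which(dup)[1]])
  structure(list(atoms = atoms[, ATOM_COLS], model_id = as.integer(model_id),
                 provenance = provenance),
            class = "structure_model")
}

#' Create an ensemble of frames
#'
#' All frames must share the same non-water atom table (same
#' (chain, res_seq, name) set in the same order); the water complement may
#' differ frame to frame.
#'
#' @param frames list of `structure_model` objects in time order.
#' @param frame_interval time between consecutive frames, ps (> 0).
#' @param t0 time of the first frame, ps.
#' @return object of class `md_ensemble`.
#' @export
md_ensemble <- function(frames, frame_interval = 2, t0 = 0) {
  stopifnot(length(frames) >= 1, frame_interval > 0)
  lapply(frames, function(f) stopifnot(inherits(f, "structure_model")))
  ref <- atom_table_key(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    k <- atom_table_key(frames[[i]])
    if (length(k) != length(ref) || any(k != ref)) {
      bad <- if (length(k) < length(ref)) setdiff(ref, k) else
        c(setdiff(k, ref), setdiff(ref, k))
      if (!length(bad)) bad <- ref[which(k != ref)[1]]
      stop("ensemble-consistency error: frame ", i,
           " non-water atom table differs from frame 1 (first mismatch: ",
           bad[1], ")")
    }
  }
  structure(list(frames = frames, frame_interval = frame_interval, t0 = t0,
                 aligned = FALSE),
            class = "md_ensemble")
}

atom_table_key <- function(model) {
  a <- model$atoms[!model$atoms$is_water, ]
  paste(a$chain, a$res_seq, a$name, sep = ":")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> model %d: %d atoms (%d water O), %d residues\n",
              x$model_id, nrow(a), sum(a$is_water),
              length(unique(paste(a$chain, a$res_seq)[!a$is_water]))))
  invisible(x)
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat(sprintf("<md_ensemble> %d frames, dt = %g ps, t = %g..%g ps%s\n",
              n_frames(x), x$frame_interval, x$t0,
              x$t0 + (n_frames(x) - 1) * x$frame_interval,
              if (isTRUE(x$aligned)) " [aligned]" else ""))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `md_ensemble`.
#' @return integer.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Frame times in ps
#' @param ensemble an `md_ensemble`.
#' @return numeric vector, one entry per frame.
#' @export
frame_times <- function(ensemble)
  ensemble$t0 + (seq_len(n_frames(ensemble)) - 1) * ensemble$frame_interval

#' Coordinate matrix of a model
#' @param model a `structure_model`.
#' @param idx optional row indices.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  m <- cbind(a$x, a$y, a$z)
  rownames(m) <- NULL
  m
}

set_coords <- function(model, xyz, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(model$atoms))
  model$atoms$x[idx] <- xyz[, 1]
  model$atoms$y[idx] <- xyz[, 2]
  model$atoms$z[idx] <- xyz[, 3]
  model
}

# ---- atom keys ------------------------------------------------------------

#' Build atom keys
#'
#' An atom key is the string `"chain:res_name:res_seq:name"`, e.g.
#' `"A:ASP:1025:OD2"`; it identifies one atom in a model.
#'
#' @param chain,res_name,res_seq,name key components (vectorized).
#' @return character vector of keys.
#' @export
atom_key <- function(chain, res_name, res_seq, name)
  paste(chain, res_name, res_seq, name, sep = ":")

model_keys <- function(model)
  atom_key(model$atoms$chain, model$atoms$res_name,
           model$atoms$res_seq, model$atoms$name)

#' Locate an atom by key
#' @param model a `structure_model`.
#' @param key atom key string (see [atom_key()]).
#' @return row index in `model$atoms`.
#' @export
find_atom <- function(model, key) {
  i <- match(key, model_keys(model))
  if (is.na(i)) stop("atom-not-found error: ", key)
  i
}

guess_element <- function(name, res_name = "") {
  # Strip digits; take the leading alphabetic run. A two-letter symbol (CU,
  # FE, ZN ...) is accepted only when the residue name itself is that symbol
  # (metal-ion HET groups); "CA" in an amino acid stays carbon.
  two <- c("CU", "FE", "ZN", "MG", "MN", "NA", "CL", "CA", "BR", "SE", "NI", "CO")
  el <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  ifelse(el %in% two & toupper(res_name) == el, el, substr(el, 1, 1))
}

is_metal_element <- function(element)
  element %in% c("CU", "FE", "ZN", "MG", "MN", "NA", "CA", "NI", "CO", "K")
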