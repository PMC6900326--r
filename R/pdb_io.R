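#' Read a coordinate file into an ensemble
#'
#' Fixed-column PDB parsing. One frame is created per MODEL block (a single
#' frame if the file has no MODEL records). ATOM and HETATM records are both
#' accepted; a missing element column is inferred from the atom name. When a
#' residue carries alternate locations, the highest-occupancy altloc is kept
#' (ties broken by altloc letter, 'A' first). Frames are ordered by MODEL
#' number regardless of record order in the file. Author residue numbering is
#' preserved verbatim; nothing is ever renumbered.
#'
#' @param path PDB file path.
#' @param dialect currently only `"pdb"`.
#' @param water_names residue names flagged as water.
#' @param frame_interval,t0 time metadata attached to the ensemble (ps).
#' @return an [md_ensemble()].
#' @export
read_structure <- function(path, dialect = "pdb",
                           water_names = DEFAULT_WATER_NAMES,
                           frame_interval = 2, t0 = 0) {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("I/O error: cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty-structure error: no ATOM/HETATM records in ", path)

  # assign a model number to every line
  model_no <- rep(NA_integer_, length(lines))
  cur <- NA_integer_
  model_starts <- grepl("^MODEL", lines)
  for (i in which(model_starts))
    model_no[i] <- suppressWarnings(as.integer(substr(lines[i], 7, 14)))
  if (any(model_starts)) {
    cur <- NA_integer_
    for (i in seq_along(lines)) {
      if (model_starts[i]) cur <- model_no[i]
      else if (grepl("^ENDMDL", lines[i])) cur <- NA_integer_
      model_no[i] <- cur
    }
  } else model_no[] <- 1L

  al <- lines[is_atom]
  mn <- model_no[is_atom]
  if (anyNA(mn)) mn[is.na(mn)] <- 1L   # atoms outside MODEL blocks -> frame 1

  num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- data.frame(
    serial   = suppressWarnings(as.integer(substr(al, 7, 11))),
    name     = trimws(substr(al, 13, 16)),
    altloc   = substr(al, 17, 17),
    res_name = trimws(substr(al, 18, 21)),
    chain    = trimws(substr(al, 22, 22)),
    res_seq  = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode    = trimws(substr(al, 27, 27)),
    x        = num(substr(al, 31, 38)),
    y        = num(substr(al, 39, 46)),
    z        = num(substr(al, 47, 54)),
    occupancy = num(substr(al, 55, 60)),
    b_factor  = num(substr(al, 61, 66)),
    element   = trimws(substr(al, 77, 78)),
    model    = mn,
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$b_factor[is.na(atoms$b_factor)] <- 0
  blank <- atoms$element == ""
  atoms$element[blank] <- guess_element(atoms$name[blank], atoms$res_name[blank])
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("I/O error: unparseable coordinates in ", path)

  frames <- lapply(sort(unique(atoms$model)), function(m) {
    a <- atoms[atoms$model == m, , drop = FALSE]
    a <- resolve_altlocs(a)
    a$altloc <- a$icode <- a$model <- NULL
    structure_model(a, model_id = m, provenance = path,
                    water_names = water_names)
  })
  md_ensemble(frames, frame_interval = frame_interval, t0 = t0)
}

# keep the highest-occupancy altloc per (chain, res_seq, icode, name);
# ties broken by altloc letter ('A' beats 'B', blank beats lettered).
resolve_altlocs <- function(a) {
  if (all(a$altloc %in% c("", " "))) return(a)
  key <- paste(a$chain, a$res_seq, a$icode, a$name, sep = ":")
  ord <- order(key, -a$occupancy, a$altloc)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$res_seq, a$icode, a$name, sep = ":")), ,
         drop = FALSE]
  a[order(a$serial), , drop = FALSE]
}

#' Write an ensemble as a (multi-)MODEL PDB file
#'
#' Coordinates are written at 3 decimals in fixed PDB columns; a single-frame
#' ensemble is written without MODEL/ENDMDL records. The output is re-readable
#' by [read_structure()] with atom identities preserved exactly and
#' coordinates to +/- 0.001 Angstrom.
#'
#' @param ensemble an [md_ensemble()] or single [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ensemble, path) {
  if (inherits(ensemble, "structure_model"))
    ensemble <- md_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "md_ensemble"), n_frames(ensemble) >= 1)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot write ", path))
  on.exit(close(con))
  multi <- n_frames(ensemble) > 1
  for (i in seq_len(n_frames(ensemble))) {
    f <- ensemble$frames[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", f$model_id), con)
    writeLines(format_atom_lines(f$atoms), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_lines <- function(a) {
  rec <- ifelse(a$res_name %in% c("HOH", "WAT", "TIP3", "SOL") |
                  nchar(a$element) > 1, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(a$name) >= 4 | nchar(a$element) > 1,
               sprintf("%-4s", a$name), sprintf(" %-3s", a$name))
  sprintf("%s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm, a$res_name,
          substr(paste0(a$chain, " "), 1, 1), a$res_seq %% 10000L,
          a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
}
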