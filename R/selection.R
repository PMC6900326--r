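#' Atom selections
#'
#' A selection is a conjunction of simple filters over chain, residue name,
#' residue number (single values or ranges), atom name, element and the
#' water flag. Build one programmatically with `selection()` or parse the
#' compact string grammar with [parse_selection()]:
#'
#' ```
#' "resname HOH"                 # waters (oxygen-only by default)
#' "res 1025 and name OD1,OD2"   # the Asp1025 carboxylate oxygens
#' "chain A and res 200-240"     # residue range
#' "elem CU"                     # copper ions
#' "backbone"                    # names N, CA, C, O; never water
#' "water" / "not water"
#' ```
#'
#' Evaluating a selection on a model returns a deterministic, ordered (file
#' order) atom subset; an empty match is allowed and is not an error.
#'
#' @param chain,res_name,name,element character vectors (any match).
#' @param res_seq integer vector of residue numbers (after range expansion).
#' @param water TRUE (waters only), FALSE (exclude waters), NA (either).
#' @param backbone if TRUE restrict to backbone atom names N, CA, C, O.
#' @param oxygen_only_water if TRUE (default), water selections return only
#'   oxygen atoms, making hydrogen-less crystal and MD inputs uniform.
#' @return object of class `atom_selection`.
#' @export
selection <- function(chain = NULL, res_name = NULL, res_seq = NULL,
                      name = NULL, element = NULL, water = NA,
                      backbone = FALSE, oxygen_only_water = TRUE) {
  structure(list(chain = chain, res_name = res_name, res_seq = res_seq,
                 name = name, element = element, water = water,
                 backbone = backbone, oxygen_only_water = oxygen_only_water),
            class = "atom_selection")
}

#' Parse the selection string grammar
#'
#' @param expr selection string (see [selection()] for the grammar).
#' @return an `atom_selection`.
#' @export
parse_selection <- function(expr) {
  if (inherits(expr, "atom_selection")) return(expr)
  if (!is.character(expr) || length(expr) != 1)
    stop("selection-syntax error: expression must be a single string")
  sel <- selection()
  toks <- strsplit(trimws(expr), "\\s+and\\s+")[[1]]
  for (tok in toks) {
    parts <- strsplit(trimws(tok), "\\s+")[[1]]
    kw <- tolower(parts[1])
    arg <- if (length(parts) > 1) paste(parts[-1], collapse = "") else NULL
    vals <- if (!is.null(arg)) strsplit(arg, ",")[[1]] else NULL
    if (kw %in% c("res", "resi", "resid", "resseq")) {
      if (is.null(vals)) stop("selection-syntax error: '", tok, "'")
      sel$res_seq <- unlist(lapply(vals, function(v) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
          ab <- as.integer(strsplit(sub("(.)-", "\\1 ", v), " ")[[1]])
          seq(ab[1], ab[2])
        } else if (grepl("^-?[0-9]+$", v)) as.integer(v)
        else stop("selection-syntax error: bad residue token '", v, "'")
      }))
    } else if (kw == "resname") {
      if (is.null(vals)) stop("selection-syntax error: '", tok, "'")
      sel$res_name <- toupper(vals)
    } else if (kw == "name") {
      if (is.null(vals)) stop("selection-syntax error: '", tok, "'")
      sel$name <- toupper(vals)
    } else if (kw == "chain") {
      if (is.null(vals)) stop("selection-syntax error: '", tok, "'")
      sel$chain <- vals
    } else if (kw %in% c("elem", "element")) {
      if (is.null(vals)) stop("selection-syntax error: '", tok, "'")
      sel$element <- toupper(vals)
    } else if (kw == "water" && length(parts) == 1) {
      sel$water <- TRUE
    } else if (kw == "not" && length(parts) == 2 &&
               tolower(parts[2]) == "water") {
      sel$water <- FALSE
    } else if (kw == "backbone" && length(parts) == 1) {
      sel$backbone <- TRUE
      sel$water <- FALSE
    } else if (kw == "all" && length(parts) == 1) {
      # no-op
    } else stop("selection-syntax error: unknown clause '", tok, "'")
  }
  sel
}

#' Evaluate a selection on a model
#'
#' @param model a [structure_model()].
#' @param sel an `atom_selection` or selection string.
#' @return the matching rows of `model$atoms`, in file order (possibly empty).
#' @export
select_atoms <- function(model, sel) {
  a <- model$atoms
  out <- a[select_mask(model, sel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Row indices matched by a selection
#' @inheritParams select_atoms
#' @return integer vector of row indices into `model$atoms`.
#' @export
select_idx <- function(model, sel) which(select_mask(model, sel))

select_mask <- function(model, sel) {
  sel <- parse_selection(sel)
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$res_name)) keep <- keep & toupper(a$res_name) %in% sel$res_name
  if (!is.null(sel$res_seq)) keep <- keep & a$res_seq %in% sel$res_seq
  if (!is.null(sel$name)) keep <- keep & toupper(a$name) %in% sel$name
  if (!is.null(sel$element)) keep <- keep & toupper(a$element) %in% sel$element
  if (!is.na(sel$water)) keep <- keep & (a$is_water == sel$water)
  if (isTRUE(sel$backbone))
    keep <- keep & a$name %in% c("N", "CA", "C", "O") & !a$is_water
  if (isTRUE(sel$oxygen_only_water))
    keep <- keep & (!a$is_water | a$element == "O")
  keep
}
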