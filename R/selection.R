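#' Atom selections
#'
#' A selection is a predicate over (chain, residue range, residue names,
#' atom-name class). Atom-name classes follow trajectory-tool conventions:
#' \describe{
#'   \item{`all-heavy`}{every non-hydrogen atom (default)}
#'   \item{`backbone-no-O`}{N, CA, C (the clustering selection used for
#'     backbone RMSD without the carbonyl oxygen)}
#'   \item{`backbone`}{N, CA, C, O}
#'   \item{`calpha`}{CA only}
#'   \item{`sidechain-heavy`}{heavy atoms outside N/CA/C/O}
#'   \item{`named`}{an explicit atom-name list via `atom_names`}
#'   \item{`all`}{every atom including hydrogens}
#' }
#'
#' @param chain chain id(s) or `NULL` for any.
#' @param resno integer residue numbers (any when `NULL`).
#' @param resnames 3-letter residue names (any when `NULL`).
#' @param class one of the atom-name classes above.
#' @param atom_names character vector, required for `class = "named"`.
#' @return object of class `AtomSelection`.
#' @export
atom_select <- function(chain = NULL, resno = NULL, resnames = NULL,
                        class = c("all-heavy", "backbone-no-O", "backbone",
                                  "calpha", "sidechain-heavy", "named", "all"),
                        atom_names = NULL) {
  class <- match.arg(class)
  if (class == "named" && is.null(atom_names))
    stop("class 'named' requires atom_names")
  structure(list(chain = chain, resno = resno, resnames = resnames,
                 class = class, atom_names = atom_names),
            class = "AtomSelection")
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Apply a selection to a model
#'
#' For two models sharing topology the returned index lists have equal
#' length and identical atom identity.
#'
#' @param m `StructureModel`.
#' @param sel `AtomSelection` (or `NULL` for all heavy atoms).
#' @return integer vector of atom indices into `m$atoms`.
#' @export
select_atoms <- function(m, sel = NULL) {
  a <- m$atoms
  if (is.null(sel)) sel <- atom_select()
  if (!inherits(sel, "AtomSelection")) stop("sel must be an AtomSelection")
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  if (!is.null(sel$resnames)) keep <- keep & a$resname %in% sel$resnames
  heavy <- toupper(a$element) != "H"
  keep <- keep & switch(
    sel$class,
    "all" = TRUE,
    "all-heavy" = heavy,
    "backbone-no-O" = a$atom %in% c("N", "CA", "C"),
    "backbone" = a$atom %in% BACKBONE_ATOMS,
    "calpha" = a$atom == "CA",
    "sidechain-heavy" = heavy & !(a$atom %in% BACKBONE_ATOMS),
    "named" = a$atom %in% sel$atom_names
  )
  which(keep)
}

#' Parse a compact selection string
#'
#' Grammar: `"<chain>:<spec>"` where `<spec>` is an atom class
#' (`backbone`, `backbone-no-O`, `calpha`, `all-heavy`, `sidechain-heavy`,
#' `all`) or a residue range `"150-155"` (implying all heavy atoms), or the
#' two combined as `"150-155/backbone"`. A bare class (no colon) applies to
#' every chain.
#'
#' @param txt selection string, e.g. `"A:backbone"`, `"C:all-heavy"`,
#'   `"A:150-155"`.
#' @return an `AtomSelection`.
#' @export
parse_selection <- function(txt) {
  stopifnot(is.character(txt), length(txt) == 1L)
  chain <- NULL
  spec <- txt
  if (grepl(":", txt, fixed = TRUE)) {
    parts <- strsplit(txt, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("bad selection string: ", txt)
    chain <- parts[1L]
    spec <- parts[2L]
  }
  resno <- NULL
  cls <- spec
  if (grepl("/", spec, fixed = TRUE)) {
    sp <- strsplit(spec, "/", fixed = TRUE)[[1L]]
    spec_range <- sp[1L]
    cls <- sp[2L]
  } else if (grepl("^[0-9]+(-[0-9]+)?$", spec)) {
    spec_range <- spec
    cls <- "all-heavy"
  } else {
    spec_range <- NULL
  }
  if (!is.null(spec_range)) {
    bounds <- as.integer(strsplit(spec_range, "-", fixed = TRUE)[[1L]])
    resno <- if (length(bounds) == 2L) seq(bounds[1L], bounds[2L]) else bounds
  }
  atom_select(chain = chain, resno = resno, class = cls)
}
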