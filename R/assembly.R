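#' Construct an assembly from an atom table
#'
#' An assembly is the package's coordinate container: one row per heavy atom,
#' plus structure-level metadata held in attributes. It behaves as a tibble,
#' so the usual dplyr verbs work on it directly; functions that need the
#' metadata (symmetry detection, compaction, the pipeline) take the assembly
#' object itself.
#'
#' @param atoms A data frame with columns `serial` (integer), `chain`
#'   (character), `resno` (integer author numbering), `icode` (character,
#'   `""` if none), `resid` (3-letter residue code), `elety` (atom name),
#'   `element` (element symbol), `x`, `y`, `z` (Angstrom), `o` (occupancy in
#'   \[0, 1\]), `b` (B-factor), `altloc` (character, `""` if none), `het`
#'   (logical, `TRUE` for heteroatoms/ligands).
#' @param id Structure identifier (e.g. a PDB id).
#' @param state_label One of `"apo"`, `"product_bound"`, `"unknown"`.
#' @param unit_cell Optional [unit_cell()] object.
#' @param space_group Optional space-group symbol.
#'
#' @return A tibble of class `quat_assembly`.
#' @export
new_assembly <- function(atoms, id = "assembly",
                         state_label = c("unknown", "apo", "product_bound"),
                         unit_cell = NULL, space_group = NULL) {
  state_label <- match.arg(state_label)
  atoms <- as_tibble(atoms)
  needed <- c("serial", "chain", "resno", "icode", "resid", "elety",
              "element", "x", "y", "z", "o", "b", "altloc", "het")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("assembly must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("atom coordinates must be finite")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    abort("occupancies must lie in [0, 1]")
  }
  if (!is.null(unit_cell)) stopifnot(inherits(unit_cell, "quat_unit_cell"))
  structure(
    atoms[, needed],
    id = id,
    state_label = state_label,
    unit_cell = unit_cell,
    space_group = space_group,
    class = c("quat_assembly", class(tibble()))
  )
}

#' @export
print.quat_assembly <- function(x, ...) {
  prot <- x[!x$het, ]
  cat(sprintf(
    "<quat_assembly> %s (%s): %d chains [%s], %d residues, %d atoms (%d het)\n",
    attr(x, "id"), attr(x, "state_label"),
    length(unique(prot$chain)), paste(unique(prot$chain), collapse = ","),
    nrow(dplyr::distinct(prot, .data$chain, .data$resno, .data$icode)),
    nrow(x), sum(x$het)
  ))
  if (!is.null(attr(x, "unit_cell"))) {
    uc <- attr(x, "unit_cell")
    cat(sprintf("  cell: %.2f %.2f %.2f; %.1f %.1f %.1f  %s\n",
                uc$a, uc$b, uc$c, uc$alpha, uc$beta, uc$gamma,
                attr(x, "space_group") %||% ""))
  }
  NextMethod()
}

# Keep class/attributes through dplyr verbs that return a compatible table.
#' @export
`[.quat_assembly` <- function(x, ...) {
  out <- NextMethod()
  restore_assembly(out, x)
}

restore_assembly <- function(out, template) {
  if (is.data.frame(out) &&
      all(c("chain", "resno", "elety", "x", "y", "z") %in% names(out))) {
    attr(out, "id") <- attr(template, "id")
    attr(out, "state_label") <- attr(template, "state_label")
    attr(out, "unit_cell") <- attr(template, "unit_cell")
    attr(out, "space_group") <- attr(template, "space_group")
    class(out) <- unique(c("quat_assembly", class(tibble())))
  }
  out
}

#' Assembly metadata accessors
#'
#' @param x An assembly.
#' @return `assembly_id()` the identifier; `state_label()` the apo /
#'   product-bound label; `chain_ids()` the protein chain identifiers in
#'   order of appearance.
#' @export
assembly_id <- function(x) attr(x, "id")

#' @rdname assembly_id
#' @export
state_label <- function(x) attr(x, "state_label")

#' @rdname assembly_id
#' @export
chain_ids <- function(x) unique(x$chain[!x$het])

#' Coordinate matrix of an atom table
#'
#' @param atoms An assembly or plain atom tibble.
#' @return An n x 3 matrix of coordinates (Angstrom).
#' @export
atom_coords <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace the coordinates of an atom table
#'
#' @param atoms An assembly or atom tibble.
#' @param m An n x 3 coordinate matrix.
#' @return The input with coordinates replaced.
#' @export
set_atom_coords <- function(atoms, m) {
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

#' Select protein atoms, C-alpha atoms or one chain
#'
#' `protein_atoms()` drops heteroatoms (ligands, waters); `ca_atoms()`
#' additionally keeps only C-alpha rows; `chain_atoms()` subsets one chain.
#'
#' @param x An assembly or atom tibble.
#' @param chain A chain identifier.
#' @return An atom tibble (assembly attributes preserved).
#' @export
protein_atoms <- function(x) x[!x$het, ]

#' @rdname protein_atoms
#' @export
ca_atoms <- function(x) x[!x$het & x$elety == "CA", ]

#' @rdname protein_atoms
#' @export
chain_atoms <- function(x, chain) x[x$chain == chain, ]

#' Apply a rigid transform to an assembly or atom table
#'
#' @param atoms An assembly or atom tibble.
#' @param transform A [rigid_transform()] (rotation + translation).
#' @return The input with transformed coordinates.
#' @export
transform_atoms <- function(atoms, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- atom_coords(atoms) %*% t(transform$rotation)
  m <- sweep(m, 2, transform$translation, "+")
  set_atom_coords(atoms, m)
}

centroid <- function(atoms) colMeans(atom_coords(atoms))
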