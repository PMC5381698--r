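#' Read a macromolecular structure into an assembly
#'
#' Reads a PDB or mmCIF file (via bio3d) into the package's atom-level
#' tibble container. Only the first model of multi-model files is kept, and
#' alternate locations are reduced to a single conformer per atom: the
#' highest-occupancy altloc wins, ties broken by altloc letter order, so
#' downstream geometry is deterministic. Heteroatoms (ligands such as
#' UDP-glucose, waters) are retained but flagged `het = TRUE`; protein-only
#' selections exclude them by default.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param id Structure identifier; defaults to the file base name.
#' @param state_label `"apo"`, `"product_bound"` or `"unknown"`.
#' @return A [new_assembly()] object. For PDB input the `CRYST1` record, when
#'   present, populates the unit cell and space group.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL,
                           state_label = c("unknown", "apo", "product_bound")) {
  format <- match.arg(format)
  state_label <- match.arg(state_label)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      # read.cif emits advisory warnings (beta status, secondary-structure
      # records) that carry no information about the atom records we use
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) abort(paste0("cannot parse ", format, " file '",
                                     path, "': ", conditionMessage(e)))
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) abort("structure contains no atoms")
  atoms <- tibble(
    serial = as.integer(at$eleno),
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = ifelse(is.na(at$elesy), guess_element(at$elety),
                     as.character(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, pmin(pmax(at$o, 0), 1)),
    b = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    het = at$type == "HETATM"
  )
  atoms <- apply_altloc_policy(atoms)

  cell <- NULL; sg <- NULL
  if (format == "pdb") {
    cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
    if (length(cryst) >= 1) {
      v <- suppressWarnings(as.numeric(c(
        substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
        substr(cryst[1], 25, 33), substr(cryst[1], 34, 40),
        substr(cryst[1], 41, 47), substr(cryst[1], 48, 54)
      )))
      if (all(is.finite(v)) && all(v > 0)) {
        cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
        sg <- trimws(substr(cryst[1], 56, 66))
      }
    }
  }
  new_assembly(atoms, id = id %||% tools::file_path_sans_ext(basename(path)),
               state_label = state_label, unit_cell = cell, space_group = sg)
}

# keep one conformer per (chain, resno, icode, elety): highest occupancy,
# ties by altloc letter
apply_altloc_policy <- function(atoms) {
  atoms |>
    arrange(.data$chain, .data$resno, .data$icode, .data$elety,
            dplyr::desc(.data$o), .data$altloc) |>
    distinct(.data$chain, .data$resno, .data$icode, .data$elety,
             .keep_all = TRUE) |>
    arrange(.data$serial)
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA"),
         two, substr(e, 1, 1))
}

#' Write an assembly as a PDB file
#'
#' Fixed-width PDB output via bio3d. Round-tripping preserves chain ids,
#' residue numbering and coordinates to 3 decimals (the PDB field
#' precision).
#'
#' @param assembly An assembly.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(assembly, path) {
  if (nrow(assembly) == 0) abort("refusing to write an empty assembly")
  m <- atom_coords(assembly)
  if (any(abs(m) > 9999.999)) {
    abort("coordinates exceed the PDB fixed-width field (|x| > 9999.999)")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(m)),
    type = ifelse(assembly$het, "HETATM", "ATOM"),
    resno = assembly$resno,
    resid = assembly$resid,
    eleno = assembly$serial,
    elety = assembly$elety,
    chain = assembly$chain,
    insert = ifelse(assembly$icode == "", NA, assembly$icode),
    o = assembly$o,
    b = assembly$b,
    elesy = assembly$element
  )
  invisible(path)
}

#' Define a named residue region
#'
#' A region is a chain-agnostic set of inclusive residue-number ranges in a
#' named numbering scheme (e.g. the sugar-binding loop T286-G293 of human
#' UDP-glucose pyrophosphorylase isoform 1).
#'
#' @param name Region name.
#' @param ranges A list of `c(start, end)` pairs (inclusive), or a two-column
#'   matrix/data frame.
#' @param numbering_scheme Label of the numbering the ranges are expressed in.
#' @return A `region_definition` object.
#' @export
region_definition <- function(name, ranges, numbering_scheme = "author") {
  if (is.data.frame(ranges) || is.matrix(ranges)) {
    ranges <- lapply(seq_len(nrow(ranges)),
                     function(i) as.integer(ranges[i, 1:2]))
  }
  if (is.numeric(ranges)) ranges <- list(as.integer(ranges))
  ranges <- lapply(ranges, function(r) as.integer(r[1:2]))
  for (r in ranges) {
    if (anyNA(r) || r[1] > r[2]) abort("region ranges need start <= end")
  }
  all_res <- unlist(lapply(ranges, function(r) r[1]:r[2]))
  if (anyDuplicated(all_res)) abort("region ranges must not overlap")
  structure(list(name = name, ranges = ranges,
                 numbering_scheme = numbering_scheme),
            class = "region_definition")
}

#' @export
print.region_definition <- function(x, ...) {
  cat(sprintf("<region> %s [%s]: %s\n", x$name, x$numbering_scheme,
              paste(vapply(x$ranges, function(r)
                paste0(r[1], "-", r[2]), ""), collapse = ", ")))
  invisible(x)
}

# residue numbers covered by a region, expressed in a chain's numbering
# (offset added to the region bounds)
region_resno <- function(region, offset = 0L) {
  sort(unlist(lapply(region$ranges,
                     function(r) (r[1] + offset):(r[2] + offset))))
}

#' Resolve a region on one chain of an assembly
#'
#' Selects the atoms of the residues a region covers on a given chain. The
#' `offset` expresses the region's numbering in the chain's numbering: a
#' residue is selected iff its number equals a region position plus
#' `offset`. This is how a region defined in hUGP1 (isoform 1) numbering is
#' applied to an isoform 2 chain, whose numbering runs 11 lower (offset
#' -11); the reverse mapping, isoform 2 regions onto an isoform 1 chain,
#' uses +11.
#'
#' @param assembly An assembly.
#' @param region A [region_definition()].
#' @param chain Chain identifier.
#' @param offset Integer numbering offset (default 0).
#' @param include_het Keep heteroatom residues falling in the range
#'   (default `FALSE`).
#' @return An atom tibble of the selected residues, with attributes
#'   `region_name` and `missing_resno` (residue numbers expected in the
#'   chain numbering but absent, e.g. disordered loops). An empty selection
#'   is returned with a warning, not an error.
#' @export
resolve_region <- function(assembly, region, chain, offset = 0L,
                           include_het = FALSE) {
  stopifnot(inherits(region, "region_definition"))
  if (!chain %in% unique(assembly$chain)) {
    abort(paste0("chain '", chain, "' not present in assembly"))
  }
  wanted <- region_resno(region, as.integer(offset))
  sel <- assembly[assembly$chain == chain & assembly$resno %in% wanted, ]
  if (!include_het) sel <- sel[!sel$het, ]
  present <- unique(sel$resno)
  missing_resno <- setdiff(wanted, present)
  if (length(present) == 0) {
    warn(paste0("region '", region$name, "' resolves to no residues on chain ",
                chain))
  }
  attr(sel, "region_name") <- region$name
  attr(sel, "missing_resno") <- missing_resno
  sel
}

#' Read region definitions from a YAML config file
#'
#' The file maps region names to `ranges` (list of `[start, end]` pairs) and
#' an optional `numbering_scheme`. A ready-made config for human UDP-glucose
#' pyrophosphorylase ships with the package
#' (`system.file("extdata", "hugp_regions.yaml", package = "quatstruct")`).
#'
#' @param path Path to the YAML file.
#' @return A named list of [region_definition()] objects.
#' @export
read_regions <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    region_definition(nm, entry$ranges,
                      entry$numbering_scheme %||% "author")
  })
  setNames(out, names(raw))
}
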