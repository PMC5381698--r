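#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3x3 proper orthonormal matrix (det = +1).
#' @param translation length-3 vector, Angstrom.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be proper orthonormal (det = +1)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_angle_axis(x$rotation)
  cat(sprintf("<rigid_transform> angle %.3f deg about [%.3f %.3f %.3f], t = [%.3f %.3f %.3f]\n",
              aa$angle, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(f, g)` returns the transform applying `g` first, then
#' `f`; `invert_transform(f)` the inverse.
#'
#' @param f,g `rigid_transform` objects.
#' @export
compose_transform <- function(f, g) {
  rigid_transform(f$rotation %*% g$rotation,
                  as.vector(f$rotation %*% g$translation) + f$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(f) {
  rigid_transform(t(f$rotation), -as.vector(t(f$rotation) %*% f$translation))
}

#' Rotation angle and axis of a rotation matrix
#'
#' @param rotation 3x3 proper rotation matrix.
#' @return List with `angle` (degrees, in \[0, 180\]) and `axis` (unit
#'   vector; arbitrary for angle 0, sign fixed toward the +z hemisphere).
#' @export
rotation_angle_axis <- function(rotation) {
  tr <- sum(diag(rotation))
  angle <- acos(pmin(pmax((tr - 1) / 2, -1), 1))
  if (angle < 1e-12) {
    return(list(angle = 0, axis = c(0, 0, 1)))
  }
  if (abs(angle - pi) < 1e-6) {
    # near 180 deg: axis from the symmetric part, largest diagonal of R + I
    m <- (rotation + diag(3)) / 2
    axis <- sqrt(pmax(diag(m), 0))
    k <- which.max(axis)
    sgn <- sign(m[k, ]); sgn[sgn == 0] <- 1
    axis <- axis * sgn / sgn[k]
  } else {
    axis <- c(rotation[3, 2] - rotation[2, 3],
              rotation[1, 3] - rotation[3, 1],
              rotation[2, 1] - rotation[1, 2]) / (2 * sin(angle))
  }
  axis <- axis / sqrt(sum(axis^2))
  axis <- orient_axis(axis)
  list(angle = angle * 180 / pi, axis = axis)
}

# deterministic hemisphere convention: z > 0, ties toward +x then +y
orient_axis <- function(axis) {
  if (axis[3] < -1e-12 ||
      (abs(axis[3]) <= 1e-12 && (axis[1] < -1e-12 ||
        (abs(axis[1]) <= 1e-12 && axis[2] < 0)))) -axis else axis
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' point sets in one-to-one correspondence, by singular value decomposition
#' of the cross-covariance matrix with the usual sign correction that
#' excludes reflections.
#'
#' @param ref_coords,mov_coords N x 3 coordinate matrices (N >= 3), row i of
#'   `mov_coords` corresponding to row i of `ref_coords`.
#' @return A `superposition` object: `transform` (the [rigid_transform()]
#'   taking the moving set onto the reference), `rmsd` (Angstrom),
#'   `n_atoms_fit`, and `degenerate` (`TRUE` when the point set is
#'   rank-deficient, e.g. collinear; a minimising transform is still
#'   returned).
#' @export
kabsch_fit <- function(ref_coords, mov_coords) {
  ref_coords <- as.matrix(ref_coords); mov_coords <- as.matrix(mov_coords)
  stopifnot(ncol(ref_coords) == 3, ncol(mov_coords) == 3)
  n <- nrow(ref_coords)
  if (n != nrow(mov_coords)) abort("point sets must have equal size")
  if (n < 3) abort("superposition needs at least 3 points")
  cr <- colMeans(ref_coords); cm <- colMeans(mov_coords)
  p <- sweep(ref_coords, 2, cr); q <- sweep(mov_coords, 2, cm)
  h <- crossprod(q, p)  # 3x3 cross-covariance (moving -> reference)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  degenerate <- s$d[2] < 1e-8 * max(s$d[1], 1e-12)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- sweep(q %*% t(rot), 2, cr - cr, "+")  # centred fit
  rmsd <- sqrt(mean(rowSums((fitted - p)^2)))
  structure(list(transform = rigid_transform(rot, trans),
                 rmsd = rmsd, n_atoms_fit = n, degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms%s\n", x$rmsd,
              x$n_atoms_fit, if (x$degenerate) " (degenerate set)" else ""))
  invisible(x)
}

#' @export
glance.superposition <- function(x, ...) {
  aa <- rotation_angle_axis(x$transform$rotation)
  tibble(rmsd = x$rmsd, n_atoms_fit = x$n_atoms_fit,
         rotation_angle = aa$angle, degenerate = x$degenerate)
}

# shared-residue CA coordinate pairing between two atom tables
paired_ca <- function(ref_atoms, mov_atoms, ref_offset = 0L, mov_offset = 0L) {
  rca <- ca_atoms(ref_atoms); mca <- ca_atoms(mov_atoms)
  rkey <- rca$resno - ref_offset; mkey <- mca$resno - mov_offset
  shared <- intersect(rkey, mkey)
  list(ref = atom_coords(rca[match(shared, rkey), ]),
       mov = atom_coords(mca[match(shared, mkey), ]),
       key = shared)
}

#' Per-residue displacement profile between two conformational states
#'
#' Superposes the moving chain onto the reference chain on the C-alpha atoms
#' of a stable fit region, then reports, for each residue of a report
#' region present in both states, the C-alpha displacement and the maximum
#' side-chain heavy-atom displacement. This is the quantitative form of
#' apo-versus-product-bound loop comparisons: the fit region anchors the
#' frame, the report region is the functional element whose movement is
#' measured.
#'
#' Correspondence is by residue number (after offsets) and atom name. Glycine
#' and residues whose side-chain atoms are absent from either state get
#' `NA` side-chain displacement. Residues missing from either state are
#' excluded and listed in the `missing_resno` attribute.
#'
#' @param ref_atoms,mov_atoms Atom tibbles (typically one chain each) for the
#'   reference and moving state.
#' @param fit_region [region_definition()] used for the superposition
#'   (C-alpha only; must resolve to >= 3 shared residues).
#' @param report_region [region_definition()] whose residues are profiled.
#' @param ref_offset,mov_offset Numbering offsets taking each chain's
#'   numbering to the regions' numbering scheme (chain numbering minus region
#'   numbering; see [resolve_region()]).
#' @return A tibble (`displacement_profile` class) with columns `seq_num`
#'   (region numbering), `res_name`, `ca_disp`, `sc_disp` (Angstrom), plus
#'   attributes `superposition` (the fit) and `missing_resno`.
#' @export
displacement_profile <- function(ref_atoms, mov_atoms, fit_region,
                                 report_region,
                                 ref_offset = 0L, mov_offset = 0L) {
  fit_ref <- region_subset(ref_atoms, fit_region, ref_offset)
  fit_mov <- region_subset(mov_atoms, fit_region, mov_offset)
  pair <- paired_ca_tables(fit_ref, fit_mov, ref_offset, mov_offset)
  if (nrow(pair) < 3) abort("fit region must share >= 3 C-alpha atoms")
  fit <- kabsch_fit(pair[, c("x_ref", "y_ref", "z_ref")],
                    pair[, c("x_mov", "y_mov", "z_mov")])

  rep_ref <- region_subset(ref_atoms, report_region, ref_offset)
  rep_mov <- region_subset(mov_atoms, report_region, mov_offset)
  rep_mov <- transform_atoms(rep_mov, fit$transform)

  ref_key <- dplyr::mutate(as_tibble(rep_ref), seq_num = .data$resno - ref_offset)
  mov_key <- dplyr::mutate(as_tibble(rep_mov), seq_num = .data$resno - mov_offset)
  joined <- dplyr::inner_join(
    dplyr::select(ref_key, "seq_num", "resid", "elety", "x", "y", "z"),
    dplyr::select(mov_key, "seq_num", "elety", "x", "y", "z"),
    by = c("seq_num", "elety"), suffix = c("_ref", "_mov")
  )
  if (nrow(joined) == 0) {
    warn("report region shares no residues between the two states")
    out <- tibble(seq_num = integer(), res_name = character(),
                  ca_disp = double(), sc_disp = double())
  } else {
    joined$disp <- sqrt((joined$x_ref - joined$x_mov)^2 +
                        (joined$y_ref - joined$y_mov)^2 +
                        (joined$z_ref - joined$z_mov)^2)
    out <- joined |>
      group_by(.data$seq_num, res_name = .data$resid) |>
      summarise(
        ca_disp = if (any(.data$elety == "CA"))
          .data$disp[.data$elety == "CA"][1] else NA_real_,
        sc_disp = {
          sc <- .data$disp[!(.data$elety %in% BACKBONE_ATOMS)]
          if (length(sc)) max(sc) else NA_real_
        },
        .groups = "drop"
      ) |>
      arrange(.data$seq_num)
  }
  wanted <- region_resno(report_region, 0L)
  attr(out, "missing_resno") <- setdiff(wanted, out$seq_num)
  attr(out, "superposition") <- fit
  class(out) <- c("displacement_profile", class(out))
  out
}

region_subset <- function(atoms, region, offset) {
  wanted <- region_resno(region, as.integer(offset))
  atoms[!atoms$het & atoms$resno %in% wanted, ]
}

paired_ca_tables <- function(ref_atoms, mov_atoms, ref_offset, mov_offset) {
  rca <- as_tibble(ca_atoms(ref_atoms))
  mca <- as_tibble(ca_atoms(mov_atoms))
  rca$seq_num <- rca$resno - ref_offset
  mca$seq_num <- mca$resno - mov_offset
  dplyr::inner_join(
    dplyr::select(rca, "seq_num", x_ref = "x", y_ref = "y", z_ref = "z"),
    dplyr::select(mca, "seq_num", x_mov = "x", y_mov = "y", z_mov = "z"),
    by = "seq_num"
  )
}

#' Maximum displacement of a profile
#'
#' @param profile A [displacement_profile()].
#' @param atom_class `"ca"` or `"sidechain"`.
#' @return One-row tibble: `atom_class`, `max_disp` (Angstrom), `seq_num`
#'   and `res_name` of the residue attaining it.
#' @export
max_displacement <- function(profile, atom_class = c("ca", "sidechain")) {
  atom_class <- match.arg(atom_class)
  if (nrow(profile) == 0) abort("displacement profile is empty")
  v <- if (atom_class == "ca") profile$ca_disp else profile$sc_disp
  if (all(is.na(v))) abort(paste0("no defined ", atom_class, " displacements"))
  k <- which.max(v)
  tibble(atom_class = atom_class, max_disp = v[k],
         seq_num = profile$seq_num[k], res_name = profile$res_name[k])
}

#' @export
tidy.displacement_profile <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.displacement_profile <- function(x, ...) {
  fit <- attr(x, "superposition")
  dplyr::bind_cols(
    tibble(n_residues = nrow(x),
           max_ca_disp = if (all(is.na(x$ca_disp))) NA_real_
                         else max(x$ca_disp, na.rm = TRUE),
           max_sc_disp = if (all(is.na(x$sc_disp))) NA_real_
                         else max(x$sc_disp, na.rm = TRUE),
           n_missing = length(attr(x, "missing_resno"))),
    if (!is.null(fit)) tibble(fit_rmsd = fit$rmsd, n_atoms_fit = fit$n_atoms_fit)
  )
}
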