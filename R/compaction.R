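#' Orthonormal frame of a symmetry model
#'
#' Builds the analysis frame used for compaction metrics: z is the principal
#' symmetry axis, x the projection of the first secondary 2-fold axis onto
#' the plane perpendicular to z (or a deterministic perpendicular vector for
#' cyclic groups), y completes the right-handed set. Measuring extents in
#' this frame makes per-axis deltas comparable between apo and
#' product-bound states.
#'
#' @param symmetry A `symmetry_model` from [detect_point_group()].
#' @return A 3x3 matrix whose columns are the x, y, z unit axes.
#' @export
symmetry_frame <- function(symmetry) {
  z <- symmetry$principal_axis
  z <- z / sqrt(sum(z^2))
  x0 <- if (length(symmetry$secondary_axes) > 0) {
    symmetry$secondary_axes[[1]]
  } else {
    # deterministic perpendicular: project the coordinate axis least
    # aligned with z
    cand <- diag(3)[, which.min(abs(z))]
    cand
  }
  x <- x0 - sum(x0 * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  m <- cbind(x = x, y = y / sqrt(sum(y^2)), z = z)
  rownames(m) <- c("x", "y", "z")
  m
}

#' Extents of a selection along a frame
#'
#' Projects heavy-atom coordinates onto each axis of an orthonormal frame
#' and returns max minus min per axis; optionally the 1st-99th percentile
#' span for robustness against stray atoms.
#'
#' @param atoms An assembly or atom tibble (>= 4 atoms).
#' @param frame 3x3 matrix with unit axes in columns (default identity).
#' @param robust Use the 1st-99th percentile span instead of min/max
#'   (default `FALSE`: raw extents).
#' @return Named numeric vector `c(x=, y=, z=)`, Angstrom.
#' @export
aligned_extents <- function(atoms, frame = diag(3), robust = FALSE) {
  if (nrow(atoms) == 0) abort("empty selection has no extents")
  if (nrow(atoms) < 4) abort("extents need at least 4 atoms")
  frame <- as.matrix(frame)
  if (max(abs(crossprod(frame) - diag(3))) > 1e-6) {
    abort("frame must be orthonormal")
  }
  p <- atom_coords(atoms) %*% frame
  span <- function(v) {
    if (robust) diff(stats::quantile(v, c(0.01, 0.99), names = FALSE))
    else max(v) - min(v)
  }
  setNames(apply(p, 2, span), c("x", "y", "z"))
}

#' Substrate-induced compaction between apo and product-bound assemblies
#'
#' Measures per-axis extents and bounding-box volume of a selection in the
#' symmetry-aligned frame of the product-bound (holo) assembly, after
#' superposing the apo assembly onto it, and reports the holo-minus-apo
#' deltas and the percent volume change (negative = compaction). The volume
#' proxy is the frame-aligned bounding box; the robust percentile extents
#' are available for sensitivity analysis.
#'
#' @param apo,holo Assemblies of the two states with matching chain sets and
#'   residue numbering (apply any isoform offset upstream by renumbering).
#' @param chains Optional chain subset defining the selection (e.g. a
#'   side-by-side dimer); default all shared chains.
#' @param symmetry Optional `symmetry_model`; computed on the holo assembly
#'   when omitted.
#' @param robust Passed to [aligned_extents()].
#' @return A `compaction_report`: `frame`, `extents_apo`, `extents_holo`,
#'   `deltas`, `volume_apo`, `volume_holo`, `percent_volume_change`.
#' @export
compaction_report <- function(apo, holo, chains = NULL, symmetry = NULL,
                              robust = FALSE) {
  ch_apo <- chain_ids(apo); ch_holo <- chain_ids(holo)
  if (is.null(chains)) {
    if (!setequal(ch_apo, ch_holo)) {
      abort(paste0("chain sets differ: apo-only {",
                   paste(setdiff(ch_apo, ch_holo), collapse = ","),
                   "}, holo-only {",
                   paste(setdiff(ch_holo, ch_apo), collapse = ","), "}"))
    }
    chains <- ch_holo
  } else {
    missing_ch <- setdiff(chains, intersect(ch_apo, ch_holo))
    if (length(missing_ch) > 0) {
      abort(paste0("chains absent from one state: ",
                   paste(missing_ch, collapse = ",")))
    }
  }
  apo_sel <- protein_atoms(apo)[protein_atoms(apo)$chain %in% chains, ]
  holo_sel <- protein_atoms(holo)[protein_atoms(holo)$chain %in% chains, ]

  if (is.null(symmetry)) symmetry <- detect_point_group(holo)
  frame <- symmetry_frame(symmetry)

  # superpose apo onto holo on shared CA (chain + residue number)
  key <- function(a) paste(a$chain, a$resno)
  aca <- ca_atoms(apo_sel); hca <- ca_atoms(holo_sel)
  shared <- intersect(key(aca), key(hca))
  if (length(shared) < 3) abort("states share fewer than 3 C-alpha atoms")
  fit <- kabsch_fit(atom_coords(hca[match(shared, key(hca)), ]),
                    atom_coords(aca[match(shared, key(aca)), ]))
  apo_sel <- transform_atoms(apo_sel, fit$transform)

  e_apo <- aligned_extents(apo_sel, frame, robust)
  e_holo <- aligned_extents(holo_sel, frame, robust)
  v_apo <- prod(e_apo); v_holo <- prod(e_holo)
  structure(list(
    frame = frame, chains = chains,
    extents_apo = e_apo, extents_holo = e_holo,
    deltas = e_holo - e_apo,
    volume_apo = v_apo, volume_holo = v_holo,
    percent_volume_change = (v_holo / v_apo - 1) * 100,
    superposition_rmsd = fit$rmsd, robust = robust),
    class = "compaction_report")
}

#' @export
print.compaction_report <- function(x, ...) {
  cat(sprintf("<compaction_report> chains %s\n",
              paste(x$chains, collapse = ",")))
  cat(sprintf("  extents apo  : %7.2f %7.2f %7.2f A\n",
              x$extents_apo[1], x$extents_apo[2], x$extents_apo[3]))
  cat(sprintf("  extents holo : %7.2f %7.2f %7.2f A\n",
              x$extents_holo[1], x$extents_holo[2], x$extents_holo[3]))
  cat(sprintf("  deltas       : %+7.2f %+7.2f %+7.2f A\n",
              x$deltas[1], x$deltas[2], x$deltas[3]))
  cat(sprintf("  volume change: %+.1f %%\n", x$percent_volume_change))
  invisible(x)
}

#' @export
tidy.compaction_report <- function(x, ...) {
  tibble(axis = c("x", "y", "z"),
         extent_apo = unname(x$extents_apo),
         extent_holo = unname(x$extents_holo),
         delta = unname(x$deltas))
}

#' @export
glance.compaction_report <- function(x, ...) {
  tibble(volume_apo = x$volume_apo, volume_holo = x$volume_holo,
         percent_volume_change = x$percent_volume_change,
         superposition_rmsd = x$superposition_rmsd, robust = x$robust)
}
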