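# Internal-coordinate (NeRF) atom placement: position d at distance `bond`
# from c, with angle(b,c,d) and torsion(a,b,c,d) as given.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(ang),
               bond * cos(tor) * sin(ang),
               bond * sin(tor) * sin(ang))
  c + cbind(bc, m, n) %*% d_local
}

#' Generate a toy subunit chain
#'
#' Builds a poly-alanine helix (N, CA, C, O, CB per residue, 5 atoms) from
#' ideal internal coordinates (phi = -57, psi = -47 degrees), so bond
#' lengths are ideal and consecutive C-alpha atoms sit ~3.8 Angstrom apart.
#' The subunit is purely geometric — enough residue chemistry for the
#' contact-typing tables, no sterics — and is centred at the origin. With
#' `noise_sd > 0`, seeded Gaussian jitter is added to every coordinate.
#'
#' @param seed Integer seed (controls the optional jitter; the ideal
#'   geometry is deterministic).
#' @param n_residues Number of residues (>= 10).
#' @param noise_sd Coordinate noise, Angstrom (default 0).
#' @return An atom tibble (chain `"A"`, residues 1..n, resid `"ALA"`).
#' @export
make_subunit <- function(seed = 1, n_residues = 30, noise_sd = 0) {
  if (n_residues < 10) abort("subunit needs at least 10 residues")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  phi <- -57; psi <- -47; omega <- 180
  coords <- matrix(0, nrow = n_residues * 5, ncol = 3)
  names_v <- character(n_residues * 5)
  resno_v <- integer(n_residues * 5)
  n_prev <- ca_prev <- c_prev <- NULL
  row <- 0
  for (i in seq_len(n_residues)) {
    if (i == 1) {
      n_i <- c(0, 0, 0)
      ca_i <- c(1.458, 0, 0)
      a <- (180 - 111.2) * pi / 180
      c_i <- ca_i + 1.525 * c(cos(a), sin(a), 0)
    } else {
      n_i <- as.vector(place_atom(n_prev, ca_prev, c_prev, 1.329, 116.2, psi))
      ca_i <- as.vector(place_atom(ca_prev, c_prev, n_i, 1.458, 121.7, omega))
      c_i <- as.vector(place_atom(c_prev, n_i, ca_i, 1.525, 111.2, phi))
    }
    o_i <- as.vector(place_atom(n_i, ca_i, c_i, 1.231, 120.8, psi + 180))
    cb_i <- as.vector(place_atom(n_i, c_i, ca_i, 1.521, 110.1, 122.6))
    for (at in list(c("N", list(n_i)), c("CA", list(ca_i)),
                    c("C", list(c_i)), c("O", list(o_i)),
                    c("CB", list(cb_i)))) {
      row <- row + 1
      names_v[row] <- at[[1]]; resno_v[row] <- i
      coords[row, ] <- at[[2]]
    }
    n_prev <- n_i; ca_prev <- ca_i; c_prev <- c_i
  }
  coords <- sweep(coords, 2, colMeans(coords))
  if (noise_sd > 0) {
    set.seed(seed)
    coords <- coords + matrix(rnorm(length(coords), sd = noise_sd),
                              ncol = 3)
  }
  tibble(
    serial = seq_len(row), chain = "A", resno = resno_v, icode = "",
    resid = "ALA", elety = names_v,
    element = substr(names_v, 1, 1),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = 1, b = 0, altloc = "", het = FALSE
  )
}

rot_z <- function(deg) rotation_about(c(0, 0, 1), deg)
rot_x180 <- function() rotation_about(c(1, 0, 0), 180)

#' Assemble a Cn or Dn oligomer from a subunit
#'
#' Places `n` copies of the subunit around the z axis at 360/n degree steps
#' and a radial offset large enough to avoid clashes; for a dihedral `Dn`
#' assembly a second ring, related to the first by a 2-fold rotation about
#' the x axis, is stacked underneath (two cyclic rings back to back, the
#' architecture of the D4 UDP-glucose pyrophosphorylase octamer). Chains
#' are lettered `A`, `B`, ... around the first ring then the second. The
#' planted ground truth (point group, axes, generator permutation, the
#' exact placement operators) is attached as the `ground_truth` attribute.
#'
#' @param subunit An atom tibble from [make_subunit()] (single chain).
#' @param point_group `"C"` or `"D"`.
#' @param n Ring order (>= 2).
#' @param radius Ring radius, Angstrom; default auto-chosen for >= 4
#'   Angstrom clearance between neighbouring subunits.
#' @param state_label Passed to the assembly.
#' @return A [new_assembly()] with `ground_truth` attribute. Errors if any
#'   inter-chain atom pair ends up closer than 2.5 Angstrom (radius too
#'   small).
#' @export
make_assembly <- function(subunit, point_group = c("C", "D"), n = 4,
                          radius = NULL, state_label = "unknown") {
  point_group <- match.arg(point_group)
  if (n < 2) abort("ring order n must be >= 2")
  sub <- as_tibble(subunit)
  m <- atom_coords(sub)
  m <- sweep(m, 2, colMeans(m))
  r_sph <- sqrt(max(rowSums(m^2)))
  if (is.null(radius)) radius <- (2 * r_sph + 4) / (2 * sin(pi / n))
  z_off <- if (point_group == "D") max(abs(m[, 3])) + 2 else 0
  base <- sweep(m, 2, c(radius, 0, z_off), "+")

  n_chain <- if (point_group == "D") 2L * n else n
  ids <- LETTERS[seq_len(n_chain)]
  if (n_chain > 26) abort("more than 26 chains not supported")
  ops <- vector("list", n_chain)
  chains <- vector("list", n_chain)
  for (k in seq_len(n)) {
    r <- rot_z(360 * (k - 1) / n)
    ops[[k]] <- r
    ck <- sub
    ck$chain <- ids[k]
    chains[[k]] <- set_atom_coords(ck, base %*% t(r))
  }
  if (point_group == "D") {
    x2 <- rot_x180()
    for (k in seq_len(n)) {
      r <- x2 %*% ops[[k]]
      ops[[n + k]] <- r
      ck <- sub
      ck$chain <- ids[n + k]
      chains[[n + k]] <- set_atom_coords(ck, base %*% t(r))
    }
  }
  atoms <- bind_rows(chains)
  atoms$serial <- seq_len(nrow(atoms))
  asm <- new_assembly(atoms, id = paste0("synthetic_",
                                         point_group, n),
                      state_label = state_label)
  # clash check over all chain pairs
  combos <- utils::combn(ids, 2)
  for (j in seq_len(ncol(combos))) {
    hits <- close_pairs(
      atom_coords(chain_atoms(asm, combos[1, j])),
      atom_coords(chain_atoms(asm, combos[2, j])), 2.5)
    if (nrow(hits) > 0) {
      abort(sprintf("chains %s and %s clash (< 2.5 A): radius too small",
                    combos[1, j], combos[2, j]))
    }
  }
  cyc <- if (point_group == "C") {
    setNames(ids[c(2:n, 1)], ids)
  } else {
    setNames(c(ids[c(2:n, 1)], ids[n + c(n, 1:(n - 1))]), ids)
  }
  rings <- if (point_group == "C") list(ids) else
    list(ids[seq_len(n)], ids[n + seq_len(n)])
  # orbit of an ordered neighbour pair runs forward around every ring
  nbr <- unlist(lapply(rings, function(r) setNames(r[c(2:n, 1)], r)))
  attr(asm, "ground_truth") <- list(
    point_group = paste0(point_group, n), n_fold = as.integer(n),
    dihedral = point_group == "D",
    principal_axis = c(0, 0, 1),
    secondary_axis = if (point_group == "D") c(1, 0, 0),
    chain_cycle = cyc,
    neighbor_map = nbr,
    rings = rings,
    generator_angle = 360 / n,
    ops = setNames(ops, ids),
    radius = radius
  )
  asm
}

# straight-side-chain coordinates for the toy ARG / ASP residues used in
# contact planting; u = CA->CB direction, w = a deterministic perpendicular
toy_sidechain <- function(resid, ca, cb) {
  u <- cb - ca; u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- c(u[2] * ref[3] - u[3] * ref[2],
         u[3] * ref[1] - u[1] * ref[3],
         u[1] * ref[2] - u[2] * ref[1])
  w <- w / sqrt(sum(w^2))
  if (resid == "ARG") {
    list(CG = cb + 1.53 * u, CD = cb + 3.06 * u, NE = cb + 4.53 * u,
         CZ = cb + 5.86 * u, NH1 = cb + 7.19 * u,
         NH2 = cb + 5.86 * u + 1.33 * w)
  } else if (resid == "ASP") {
    list(CG = cb + 1.53 * u, OD1 = cb + 2.77 * u,
         OD2 = cb + 1.53 * u + 1.24 * (cos(2 * pi / 3) * u +
                                         sin(2 * pi / 3) * w))
  } else {
    abort(paste0("no toy side chain for ", resid))
  }
}

mutate_toy_residue <- function(asm, chain, resno, new_resid) {
  sel <- asm$chain == chain & asm$resno == resno & !asm$het
  if (!any(sel)) abort(paste0("residue ", resno, " absent in chain ", chain))
  ca <- atom_coords(asm[sel & asm$elety == "CA", ])[1, ]
  cb <- atom_coords(asm[sel & asm$elety == "CB", ])[1, ]
  asm$resid[sel] <- new_resid
  extra <- toy_sidechain(new_resid, ca, cb)
  add <- tibble(
    serial = max(asm$serial) + seq_along(extra), chain = chain,
    resno = resno, icode = "", resid = new_resid, elety = names(extra),
    element = substr(names(extra), 1, 1),
    x = vapply(extra, `[`, 0, 1), y = vapply(extra, `[`, 0, 2),
    z = vapply(extra, `[`, 0, 3),
    o = 1, b = 0, altloc = "", het = FALSE
  )
  out <- bind_rows(as_tibble(asm), add) |>
    arrange(.data$chain, .data$resno, .data$serial)
  out$serial <- seq_len(nrow(out))
  restore_assembly(out, asm)
}

#' Plant a symmetric inter-subunit contact
#'
#' Turns the designated region residue of every chain into a toy arginine
#' and the designated partner residue into a toy aspartate, then translates
#' each chain's aspartate minimally so that the NH1 atom of one chain's
#' arginine and the OD1 atom of the next chain's aspartate (next along the
#' planted cyclic permutation) sit exactly at the target distance. The same
#' edit is applied in every chain through the assembly's symmetry
#' operators, so the point group is preserved exactly. This emulates the
#' mutual R287-D456 interlock geometry of neighbouring subunits.
#'
#' @param assembly An assembly from [make_assembly()] (needs its
#'   `ground_truth` attribute).
#' @param region_resno Residue number to become the arginine (the
#'   binding-region residue).
#' @param partner_resno Residue number to become the aspartate (on the
#'   neighbouring chain side).
#' @param distance Target NH1-OD1 distance, Angstrom (>= 2.5).
#' @return The edited assembly; `ground_truth$planted_contacts` lists one
#'   row per chain pair with the achieved distance (within 0.01 Angstrom of
#'   target, verified).
#' @export
plant_contact <- function(assembly, region_resno, partner_resno,
                          distance = 2.9) {
  if (distance < 2.5) abort("planted distance must be >= 2.5 A")
  gt <- attr(assembly, "ground_truth")
  if (is.null(gt)) abort("assembly carries no ground_truth (use make_assembly)")
  if (region_resno == partner_resno) {
    abort("region and partner residues must differ")
  }
  asm <- assembly
  for (ch in chain_ids(asm)) {
    asm <- mutate_toy_residue(asm, ch, region_resno, "ARG")
    asm <- mutate_toy_residue(asm, ch, partner_resno, "ASP")
  }
  attr(asm, "ground_truth") <- gt
  cyc <- gt$neighbor_map %||% gt$chain_cycle
  planted <- vector("list", length(cyc))
  for (i in seq_along(cyc)) {
    ch <- names(cyc)[i]; nb <- unname(cyc[i])
    nh1 <- atom_coords(asm[asm$chain == ch & asm$resno == region_resno &
                             asm$elety == "NH1", ])[1, ]
    od1 <- atom_coords(asm[asm$chain == nb & asm$resno == partner_resno &
                             asm$elety == "OD1", ])[1, ]
    v <- nh1 - od1; d0 <- sqrt(sum(v^2))
    if (d0 < 1e-9) abort("degenerate geometry: planted atoms coincide")
    shift <- (1 - distance / d0) * v
    sel <- asm$chain == nb & asm$resno == partner_resno
    mcur <- atom_coords(asm[sel, ])
    asm[sel, c("x", "y", "z")] <- as.data.frame(sweep(mcur, 2, shift, "+"))
    planted[[i]] <- tibble(region_chain = ch, region_resno = region_resno,
                           partner_chain = nb, partner_resno = partner_resno,
                           target = distance)
  }
  planted <- bind_rows(planted)
  planted$achieved <- vapply(seq_len(nrow(planted)), function(i) {
    nh1 <- atom_coords(asm[asm$chain == planted$region_chain[i] &
                             asm$resno == region_resno &
                             asm$elety == "NH1", ])[1, ]
    od1 <- atom_coords(asm[asm$chain == planted$partner_chain[i] &
                             asm$resno == partner_resno &
                             asm$elety == "OD1", ])[1, ]
    sqrt(sum((nh1 - od1)^2))
  }, 0)
  if (any(abs(planted$achieved - distance) > 0.01)) {
    abort("planted contact construction failed to reach the target distance")
  }
  gt$planted_contacts <- planted
  attr(asm, "ground_truth") <- gt
  asm
}

#' Construct an apo/product-bound pair with known deformation
#'
#' The apo state is the input assembly; the holo state rotates the atoms of
#' a region rigidly about a hinge axis (through the C-alpha of the region's
#' first residue, mapped into each chain's local frame so symmetry is
#' preserved) by `angle` degrees, optionally followed by an isotropic
#' compaction of the whole assembly about its centroid. The expected
#' C-alpha and side-chain displacements follow the chord formula
#' `2 r sin(angle/2)` with `r` the atom's distance from the hinge axis,
#' and are returned alongside (valid as displacements when
#' `compaction_factor = 1`).
#'
#' @param assembly An assembly (synthetic or read from file).
#' @param region A [region_definition()] or integer residue numbers.
#' @param hinge_axis Direction of the hinge in the first chain's frame
#'   (default x axis).
#' @param angle Rotation angle, degrees (<= 30).
#' @param compaction_factor Isotropic scale factor applied to the holo
#'   state (default 1 = none; 0.95 shrinks volume by ~14.26 per cent).
#' @return List: `apo`, `holo` (state labels set), `expected` (tibble
#'   `seq_num`, `ca_disp`, `sc_disp` — the analytic chord displacements for
#'   the first chain).
#' @export
make_apo_holo_pair <- function(assembly, region, hinge_axis = c(1, 0, 0),
                               angle = 10, compaction_factor = 1) {
  if (abs(angle) > 30) abort("hinge angle must be <= 30 degrees")
  resnos <- if (inherits(region, "region_definition")) {
    region_resno(region)
  } else as.integer(region)
  chains <- chain_ids(assembly)
  first_ch <- chains[1]
  apo <- assembly
  attr(apo, "state_label") <- "apo"
  holo <- assembly

  ref_ca <- ca_atoms(chain_atoms(protein_atoms(assembly), first_ch))
  expected <- NULL
  for (ch in chains) {
    # map the hinge into this chain's frame via the chain-to-chain rotation
    rot_ch <- if (ch == first_ch) diag(3) else
      chain_pair_transform(assembly, first_ch, ch)$transform$rotation
    u <- as.vector(rot_ch %*% (hinge_axis / sqrt(sum(hinge_axis^2))))
    ca_sel <- holo$chain == ch & holo$resno == min(resnos) &
      holo$elety == "CA" & !holo$het
    pivot <- atom_coords(holo[ca_sel, ])[1, ]
    sel <- holo$chain == ch & holo$resno %in% resnos & !holo$het
    m <- atom_coords(holo[sel, ])
    rot <- rotation_about(u, angle)
    moved <- sweep(sweep(m, 2, pivot) %*% t(rot), 2, pivot, "+")
    if (ch == first_ch) {
      # analytic chord displacements from the distance to the hinge line
      rel <- sweep(m, 2, pivot)
      r_axis <- sqrt(rowSums((rel - (rel %*% u) %*% t(u))^2))
      disp <- 2 * r_axis * abs(sin(angle * pi / 360))
      sub <- holo[sel, ]
      expected <- tibble(seq_num = sub$resno, elety = sub$elety,
                         disp = disp) |>
        group_by(.data$seq_num) |>
        summarise(
          ca_disp = .data$disp[.data$elety == "CA"][1],
          sc_disp = {
            sc <- .data$disp[!(.data$elety %in% BACKBONE_ATOMS)]
            if (length(sc)) max(sc) else NA_real_
          }, .groups = "drop")
    }
    holo[sel, c("x", "y", "z")] <- as.data.frame(moved)
  }
  if (compaction_factor != 1) {
    prot_m <- atom_coords(holo)
    ctr <- colMeans(prot_m)
    holo[, c("x", "y", "z")] <- as.data.frame(
      sweep(sweep(prot_m, 2, ctr) * compaction_factor, 2, ctr, "+"))
  }
  attr(holo, "state_label") <- "product_bound"
  list(apo = apo, holo = holo, expected = expected)
}

#' Simulate kinetics and melting-curve datasets
#'
#' `simulate_kinetics()` draws velocities from the Michaelis-Menten or Hill
#' model with additive Gaussian noise; `simulate_melt()` draws a Boltzmann
#' sigmoid melting curve between raw fluorescence baselines. Both are
#' deterministic given the seed.
#'
#' @param model `"MM"` or `"Hill"`.
#' @param v_max,k Model parameters (`k` is Km or K0.5).
#' @param h Hill coefficient (Hill model only).
#' @param conc Substrate concentration grid.
#' @param noise_sd Gaussian noise SD (same units as velocity /
#'   fluorescence).
#' @param seed Integer seed.
#' @return A tibble `conc`/`velocity`.
#' @export
simulate_kinetics <- function(model = c("MM", "Hill"), v_max = 10, k = 2,
                              h = 1, conc = c(0.25, 0.5, 1, 2, 4, 8, 16),
                              noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (model == "MM") h <- 1
  mu <- hill_fn(conc, v_max, k, h)
  set.seed(seed)
  tibble(conc = conc, velocity = mu + rnorm(length(conc), sd = noise_sd))
}

#' @rdname simulate_kinetics
#' @param t_m,slope Boltzmann parameters, degrees C.
#' @param temperature Temperature grid, degrees C.
#' @param baseline Low/high raw fluorescence plateaus, length 2.
#' @return For `simulate_melt()`, a tibble `temperature`/`fluorescence`.
#' @export
simulate_melt <- function(t_m = 55, slope = 2,
                          temperature = seq(20, 90, by = 1),
                          noise_sd = 0, baseline = c(0.1, 1.1), seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  mu <- baseline[1] + diff(baseline) /
    (1 + exp((t_m - temperature) / slope))
  set.seed(seed)
  tibble(temperature = temperature,
         fluorescence = mu + rnorm(length(temperature), sd = noise_sd))
}
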