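#' Rigid transform relating two chains of an assembly
#'
#' Superposes chain `chain_a` onto `chain_b` on their shared C-alpha atoms
#' (matched by residue number) and extracts the rotation angle and axis.
#' In a cyclic Cn oligomer, neighbouring chains are related by 360/n degrees
#' about the symmetry axis; across the two rings of a Dn assembly the angle
#' is 180 degrees about an axis perpendicular to the principal one.
#'
#' @param assembly An assembly.
#' @param chain_a,chain_b Chain identifiers.
#' @return List: `transform` ([rigid_transform()] taking a onto b), `angle`
#'   (degrees, \[0, 180\]), `axis` (unit vector), `rmsd`, `n_atoms_fit`.
#' @export
chain_pair_transform <- function(assembly, chain_a, chain_b) {
  pa <- paired_ca(chain_atoms(protein_atoms(assembly), chain_a),
                  chain_atoms(protein_atoms(assembly), chain_b))
  if (length(pa$key) < 3) {
    abort(paste0("chains ", chain_a, " and ", chain_b,
                 " share fewer than 3 C-alpha residues"))
  }
  fit <- kabsch_fit(pa$mov, pa$ref)  # transform taking chain_a onto chain_b
  aa <- rotation_angle_axis(fit$transform$rotation)
  list(transform = fit$transform, angle = aa$angle, axis = aa$axis,
       rmsd = fit$rmsd, n_atoms_fit = fit$n_atoms_fit)
}

# per-chain CA coordinate list keyed by residue number
chain_ca_list <- function(assembly) {
  prot <- protein_atoms(assembly)
  out <- lapply(chain_ids(assembly), function(ch) {
    ca <- ca_atoms(chain_atoms(prot, ch))
    m <- atom_coords(ca); rownames(m) <- ca$resno
    m
  })
  setNames(out, chain_ids(assembly))
}

rmsd_keyed <- function(a, b) {
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3) return(Inf)
  sqrt(mean(rowSums((a[shared, , drop = FALSE] -
                     b[shared, , drop = FALSE])^2)))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues construction of the proper rotation by `angle_deg` degrees
#' about `axis` (normalised internally).
#'
#' @param axis Length-3 direction vector.
#' @param angle_deg Rotation angle, degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2)); th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# apply rotation about an axis through a point to every chain, map each onto
# its nearest chain; NULL unless the result is a bijection within tolerance
validate_operation <- function(cas, rot, center, residual_tol) {
  chains <- names(cas)
  perm <- character(length(chains)); res <- numeric(length(chains))
  for (i in seq_along(chains)) {
    moved <- sweep(sweep(cas[[i]], 2, center) %*% t(rot), 2, center, "+")
    rownames(moved) <- rownames(cas[[i]])
    d <- vapply(cas, function(b) rmsd_keyed(moved, b), 0)
    k <- which.min(d)
    if (!is.finite(d[k]) || d[k] > residual_tol) return(NULL)
    perm[i] <- chains[k]; res[i] <- d[k]
  }
  if (anyDuplicated(perm)) return(NULL)
  list(perm = setNames(perm, chains), residual = mean(res))
}

perm_cycle_lengths <- function(perm) {
  chains <- names(perm); seen <- character(); lens <- integer()
  for (ch in chains) {
    if (ch %in% seen) next
    cur <- ch; len <- 0L
    repeat {
      seen <- c(seen, cur); len <- len + 1L; cur <- unname(perm[cur])
      if (cur == ch) break
    }
    lens <- c(lens, len)
  }
  lens
}

#' Detect the point group of a homo-oligomeric assembly
#'
#' Identifies the highest-order cyclic (Cn) or dihedral (Dn) point group
#' whose rotation operations map every chain onto another chain within a
#' C-alpha RMSD tolerance. The principal axis is estimated from the skew
#' parts of the pairwise chain-to-chain rotations (the "summed generator"
#' vectors sin(theta) u, which cancel for the perpendicular 2-folds of a
#' dihedral group and accumulate along the ring axis); candidate group
#' operations are then validated explicitly: a rotation by 360/n about the
#' principal axis through the assembly centroid must permute the chains, and
#' for Dn an additional 2-fold about a perpendicular axis must exchange the
#' two rings. If the full assembly supports no group beyond C1 but a subset
#' of chains is mutually symmetric, the label is downgraded and the best
#' group over that consistent subset is reported alongside.
#'
#' @param assembly An assembly with >= 2 chains sharing one residue
#'   numbering.
#' @param angle_tol Angle tolerance in degrees (default 5).
#' @param residual_tol C-alpha RMSD tolerance in Angstrom for a chain to
#'   count as symmetry-mapped (default 1.5).
#' @return A `symmetry_model` object: `point_group` (e.g. `"C4"`, `"D4"`,
#'   `"C1"`), `n_fold`, `dihedral`, `principal_axis`, `secondary_axes`
#'   (2-fold axes, Dn only), `chain_cycle` (permutation realised by the
#'   cyclic generator), `face_to_back` (cyclic permutation is a single
#'   n-cycle), `fit_residual` (mean mapped C-alpha RMSD), `pairs` (tibble of
#'   pairwise angles/residuals), and for downgraded assemblies
#'   `subset_chains`/`subset_group`.
#' @export
detect_point_group <- function(assembly, angle_tol = 5, residual_tol = 1.5) {
  cas <- chain_ca_list(assembly)
  n_chain <- length(cas)
  if (n_chain < 2) return(c1_model(assembly, cas))

  chains <- names(cas)
  pairs <- tidyr::expand_grid(chain_a = chains, chain_b = chains) |>
    filter(.data$chain_a < .data$chain_b)
  pinfo <- purrr::pmap(pairs, function(chain_a, chain_b) {
    tr <- tryCatch(chain_pair_transform(assembly, chain_a, chain_b),
                   error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    tibble(chain_a = chain_a, chain_b = chain_b, angle = tr$angle,
           ax = tr$axis[1], ay = tr$axis[2], az = tr$axis[3],
           residual = tr$rmsd)
  })
  pair_tbl <- bind_rows(pinfo)
  sym_pairs <- filter(pair_tbl, .data$residual <= residual_tol)

  model <- NULL
  if (nrow(sym_pairs) > 0) {
    axis <- principal_axis_estimate(sym_pairs, angle_tol)
    center <- colMeans(do.call(rbind, cas))
    model <- best_group(cas, axis, center, sym_pairs, angle_tol, residual_tol)
  }
  if (is.null(model)) {
    out <- c1_model(assembly, cas)
    out$pairs <- pair_tbl
    # downgrade path: shrink to a mutually consistent subset until some
    # group validates (e.g. one displaced chain leaves an intact C4 ring)
    sub_chains <- unique(c(sym_pairs$chain_a, sym_pairs$chain_b))
    while (length(sub_chains) >= 2) {
      sub_cas <- cas[sub_chains]
      sub_pairs <- filter(sym_pairs, .data$chain_a %in% sub_chains,
                          .data$chain_b %in% sub_chains)
      sub_model <- NULL
      if (nrow(sub_pairs) > 0) {
        sub_axis <- principal_axis_estimate(sub_pairs, angle_tol)
        sub_center <- colMeans(do.call(rbind, sub_cas))
        sub_model <- best_group(sub_cas, sub_axis, sub_center, sub_pairs,
                                angle_tol, residual_tol)
      }
      if (!is.null(sub_model)) {
        out$subset_chains <- sub_chains
        out$subset_group <- sub_model$point_group
        break
      }
      # drop the least-connected chain (ties: last id)
      counts <- vapply(sub_chains, function(ch) {
        sum(sub_pairs$chain_a == ch | sub_pairs$chain_b == ch)
      }, 0L)
      drop <- sub_chains[counts == min(counts)]
      sub_chains <- setdiff(sub_chains, drop[length(drop)])
    }
    return(out)
  }
  model$pairs <- pair_tbl
  model$assembly_id <- assembly_id(assembly)
  model
}

c1_model <- function(assembly, cas) {
  structure(list(point_group = "C1", n_fold = 1L, dihedral = FALSE,
                 principal_axis = c(0, 0, 1), secondary_axes = list(),
                 chain_cycle = setNames(names(cas), names(cas)),
                 face_to_back = FALSE, fit_residual = 0,
                 pairs = tibble(), assembly_id = assembly_id(assembly)),
            class = "symmetry_model")
}

principal_axis_estimate <- function(sym_pairs, angle_tol) {
  rotational <- filter(sym_pairs, .data$angle > angle_tol,
                       .data$angle < 180 - angle_tol)
  if (nrow(rotational) > 0) {
    vs <- as.matrix(rotational[, c("ax", "ay", "az")]) *
      sin(rotational$angle * pi / 180)
    ref <- vs[1, ]
    signs <- ifelse(as.vector(vs %*% ref) >= 0, 1, -1)
    v <- unname(colSums(vs * signs))
  } else {
    # all observed rotations are 2-folds (C2/D2): take the axis closest to +z
    axes <- as.matrix(sym_pairs[, c("ax", "ay", "az")])
    v <- unname(axes[which.max(abs(axes[, 3])), ])
  }
  orient_axis(v / sqrt(sum(v^2)))
}

best_group <- function(cas, axis, center, sym_pairs, angle_tol, residual_tol) {
  n_chain <- length(cas)
  candidates <- list()
  if (n_chain %% 2 == 0 && n_chain / 2 >= 2) {
    candidates <- c(candidates, list(list(type = "D", n = n_chain / 2)))
  }
  for (d in sort(divisors(n_chain), decreasing = TRUE)) {
    if (d >= 2) candidates <- c(candidates, list(list(type = "C", n = d)))
  }
  for (cand in candidates) {
    m <- try_group(cas, axis, center, cand, sym_pairs, angle_tol, residual_tol)
    if (!is.null(m)) return(m)
  }
  NULL
}

divisors <- function(n) which(n %% seq_len(n) == 0)

try_group <- function(cas, axis, center, cand, sym_pairs, angle_tol,
                      residual_tol) {
  n <- cand$n
  gen <- validate_operation(cas, rotation_about(axis, 360 / n), center,
                            residual_tol)
  if (is.null(gen)) return(NULL)
  lens <- perm_cycle_lengths(gen$perm)
  if (!all(lens == n)) return(NULL)

  if (cand$type == "C") {
    return(structure(list(
      point_group = paste0("C", n), n_fold = as.integer(n), dihedral = FALSE,
      principal_axis = axis, secondary_axes = list(),
      chain_cycle = gen$perm,
      face_to_back = length(lens) == 1,
      fit_residual = gen$residual), class = "symmetry_model"))
  }
  # dihedral: need a validated 2-fold perpendicular to the principal axis
  twofolds <- filter(sym_pairs, abs(.data$angle - 180) <= angle_tol)
  sec <- list(); sec_perm <- NULL; sec_res <- NULL
  if (nrow(twofolds) > 0) {
    for (i in seq_len(nrow(twofolds))) {
      a2 <- c(twofolds$ax[i], twofolds$ay[i], twofolds$az[i])
      if (abs(sum(a2 * axis)) > sin(angle_tol * pi / 180)) next
      a2 <- a2 - sum(a2 * axis) * axis
      a2 <- orient_axis(a2 / sqrt(sum(a2^2)))
      v2 <- validate_operation(cas, rotation_about(a2, 180), center,
                               residual_tol)
      if (is.null(v2)) next
      if (!any(vapply(sec, function(s) abs(sum(s * a2)) >
                        cos(angle_tol * pi / 180), TRUE))) {
        sec <- c(sec, list(a2))
      }
      if (is.null(sec_perm)) { sec_perm <- v2$perm; sec_res <- v2$residual }
    }
  }
  if (is.null(sec_perm)) return(NULL)
  structure(list(
    point_group = paste0("D", n), n_fold = as.integer(n), dihedral = TRUE,
    principal_axis = axis, secondary_axes = sec,
    chain_cycle = gen$perm, twofold_cycle = sec_perm,
    face_to_back = all(perm_cycle_lengths(gen$perm) == n) &&
      length(perm_cycle_lengths(gen$perm)) == 2,
    fit_residual = mean(c(gen$residual, sec_res))),
    class = "symmetry_model")
}

#' @export
print.symmetry_model <- function(x, ...) {
  cat(sprintf("<symmetry_model> %s  (residual %.3f A)\n", x$point_group,
              x$fit_residual))
  cat(sprintf("  principal axis: [%.3f %.3f %.3f]\n",
              x$principal_axis[1], x$principal_axis[2], x$principal_axis[3]))
  if (length(x$secondary_axes)) {
    cat(sprintf("  %d secondary 2-fold axes\n", length(x$secondary_axes)))
  }
  cyc <- paste(names(x$chain_cycle), unname(x$chain_cycle), sep = "->")
  cat("  cycle:", paste(cyc, collapse = " "), "\n")
  if (!is.null(x$subset_group)) {
    cat(sprintf("  downgraded; consistent subset {%s} forms %s\n",
                paste(x$subset_chains, collapse = ","), x$subset_group))
  }
  invisible(x)
}

#' @export
glance.symmetry_model <- function(x, ...) {
  tibble(point_group = x$point_group, n_fold = x$n_fold,
         dihedral = x$dihedral, fit_residual = x$fit_residual,
         face_to_back = x$face_to_back,
         n_secondary_axes = length(x$secondary_axes))
}

#' @export
tidy.symmetry_model <- function(x, ...) x$pairs

#' Classify pairwise subunit interfaces
#'
#' Counts inter-chain heavy-atom pairs closer than a cutoff for every chain
#' pair and labels contacting pairs. Pairs whose contacts are dominated
#' (more than half of the atom pairs, on both sides) by user-named terminal
#' strand regions are `end_to_end`; other contacting pairs are
#' `side_by_side`; pairs below the contact threshold are `none`. In a D4
#' UDP-glucose pyrophosphorylase octamer this separates the C-terminal
#' beta-strand dimer contacts from the lateral ring contacts.
#'
#' @param assembly An assembly.
#' @param terminal_regions A [region_definition()] (or list of them) naming
#'   the terminal strand(s).
#' @param contact_cutoff Heavy-atom distance cutoff, Angstrom (default 4.5).
#' @param min_pairs Minimum atom-pair count to call an interface
#'   (default 30).
#' @param offset Numbering offset applied to all chains (see
#'   [resolve_region()]).
#' @return Tibble: `chain_a`, `chain_b`, `n_contact_pairs`,
#'   `frac_terminal`, `label`.
#' @export
classify_interfaces <- function(assembly, terminal_regions,
                                contact_cutoff = 4.5, min_pairs = 30,
                                offset = 0L) {
  if (inherits(terminal_regions, "region_definition")) {
    terminal_regions <- list(terminal_regions)
  }
  prot <- protein_atoms(assembly)
  chains <- chain_ids(assembly)
  if (length(chains) < 2) abort("interface classification needs >= 2 chains")
  term_resno <- unique(unlist(lapply(terminal_regions, region_resno,
                                     offset = as.integer(offset))))
  combos <- utils::combn(chains, 2)
  out <- purrr::map(seq_len(ncol(combos)), function(k) {
    ca <- combos[1, k]; cb <- combos[2, k]
    a <- chain_atoms(prot, ca); b <- chain_atoms(prot, cb)
    hits <- close_pairs(atom_coords(a), atom_coords(b), contact_cutoff)
    n_pairs <- nrow(hits)
    if (n_pairs < min_pairs) {
      return(tibble(chain_a = ca, chain_b = cb, n_contact_pairs = n_pairs,
                    frac_terminal = NA_real_, label = "none"))
    }
    in_term <- a$resno[hits[, 1]] %in% term_resno &
               b$resno[hits[, 2]] %in% term_resno
    frac <- mean(in_term)
    tibble(chain_a = ca, chain_b = cb, n_contact_pairs = n_pairs,
           frac_terminal = frac,
           label = if (frac > 0.5) "end_to_end" else "side_by_side")
  })
  bind_rows(out)
}
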