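# Cell-grid neighbour search: all pairs (i in a, j in b) with
# distance <= cutoff. Bins the second set into cubic cells of edge `cutoff`
# and, per occupied cell of the first set, tests only the 27 surrounding
# cells — O(n) for bounded density instead of the O(n^2) all-pairs scan
# (which serves as the test oracle).
close_pairs <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  empty <- cbind(ia = integer(), ib = integer(), dist = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  ka <- floor(a / cutoff); kb <- floor(b / cutoff)
  keyb <- paste(kb[, 1], kb[, 2], kb[, 3])
  bins <- split(seq_len(nrow(b)), keyb)
  keya <- paste(ka[, 1], ka[, 2], ka[, 3])
  a_cells <- split(seq_len(nrow(a)), keya)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res <- vector("list", length(a_cells))
  for (ci in seq_along(a_cells)) {
    ia <- a_cells[[ci]]
    cell <- ka[ia[1], ]
    nb_keys <- paste(cell[1] + shifts[, 1], cell[2] + shifts[, 2],
                     cell[3] + shifts[, 3])
    ib <- unlist(bins[nb_keys], use.names = FALSE)
    if (is.null(ib) || length(ib) == 0) next
    d2 <- outer(rowSums(a[ia, , drop = FALSE]^2),
                rowSums(b[ib, , drop = FALSE]^2), "+") -
      2 * a[ia, , drop = FALSE] %*% t(b[ib, , drop = FALSE])
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    res[[ci]] <- cbind(ia = ia[hit[, 1]], ib = ib[hit[, 2]],
                       dist = sqrt(pmax(d2[hit], 0)))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) empty else out
}

#' Distance criteria for typed contact detection
#'
#' Heavy-atom criteria (the structures carry no hydrogens, so no angular
#' terms): hydrogen bond between donor-capable and acceptor-capable N/O
#' atoms; salt bridge between basic side-chain N (Arg/Lys/His) and acidic
#' side-chain O (Asp/Glu); hydrophobic carbon-carbon contact between apolar
#' side chains.
#'
#' @param hbond,salt_bridge,hydrophobic Distance cutoffs in Angstrom.
#' @export
contact_criteria <- function(hbond = 3.5, salt_bridge = 4.0,
                             hydrophobic = 4.5) {
  stopifnot(hbond > 0, salt_bridge > 0, hydrophobic > 0)
  structure(list(hbond = hbond, salt_bridge = salt_bridge,
                 hydrophobic = hydrophobic), class = "contact_criteria")
}

atom_chemistry <- function(atoms) {
  res <- atoms$resid; ety <- atoms$elety
  flag_in <- function(tbl) {
    mapply(function(r, e) e %in% (tbl[[r]] %||% character()), res, ety,
           USE.NAMES = FALSE)
  }
  out <- as_tibble(atoms)
  out$.donor <- (ety == "N" & res != "PRO") | flag_in(SIDECHAIN_DONORS)
  out$.acceptor <- ety %in% c("O", "OXT") | flag_in(SIDECHAIN_ACCEPTORS)
  out$.basic <- flag_in(SALT_BASIC)
  out$.acidic <- flag_in(SALT_ACIDIC)
  out$.apolar_c <- out$element == "C" & res %in% APOLAR_RESIDUES &
    !(ety %in% BACKBONE_ATOMS)
  out
}

#' Detect typed atomic contacts in an assembly
#'
#' Scans all heavy-atom pairs (grid-accelerated) and emits one record per
#' qualifying (atom pair, contact type): `hbond`, `salt_bridge`,
#' `hydrophobic`. A pair can satisfy several criteria at once — an Arg
#' guanidinium N 2.9 Angstrom from an Asp carboxylate O is both an H-bond
#' and a salt bridge. Atom pairs within one residue are not contacts.
#' Each unordered pair appears once, the lower (chain, residue number, atom
#' name) first, and records are ordered by chain then residue number.
#'
#' @param assembly An assembly (heteroatoms are ignored; the chemistry
#'   tables cover the 20 standard residues).
#' @param criteria A [contact_criteria()] object.
#' @return Tibble of class `contact_records`: `chain_a`, `resno_a`,
#'   `resid_a`, `atom_a`, `chain_b`, `resno_b`, `resid_b`, `atom_b`,
#'   `distance`, `contact_type`, `scope` (`intra_chain`/`inter_chain`).
#' @export
detect_contacts <- function(assembly, criteria = contact_criteria()) {
  atoms <- atom_chemistry(protein_atoms(assembly))
  cand <- atoms[atoms$.donor | atoms$.acceptor | atoms$.basic |
                  atoms$.acidic | atoms$.apolar_c, ]
  max_cut <- max(criteria$hbond, criteria$salt_bridge, criteria$hydrophobic)
  hits <- close_pairs(atom_coords(cand), atom_coords(cand), max_cut)
  hits <- hits[hits[, "ia"] < hits[, "ib"], , drop = FALSE]
  if (nrow(hits) == 0) return(empty_contacts())
  ia <- hits[, "ia"]; ib <- hits[, "ib"]; d <- hits[, "dist"]
  same_res <- cand$chain[ia] == cand$chain[ib] &
    cand$resno[ia] == cand$resno[ib] & cand$icode[ia] == cand$icode[ib]
  keep <- !same_res & d > 0
  ia <- ia[keep]; ib <- ib[keep]; d <- d[keep]

  rec <- function(sel, type, cutoff) {
    s <- sel & d <= cutoff
    if (!any(s)) return(NULL)
    tibble(ia = ia[s], ib = ib[s], distance = d[s], contact_type = type)
  }
  is_no <- cand$element %in% c("N", "O")
  hb <- (cand$.donor[ia] & cand$.acceptor[ib]) |
        (cand$.donor[ib] & cand$.acceptor[ia])
  hb <- hb & is_no[ia] & is_no[ib]
  sb <- (cand$.basic[ia] & cand$.acidic[ib]) |
        (cand$.basic[ib] & cand$.acidic[ia])
  hp <- cand$.apolar_c[ia] & cand$.apolar_c[ib]
  typed <- bind_rows(rec(hb, "hbond", criteria$hbond),
                     rec(sb, "salt_bridge", criteria$salt_bridge),
                     rec(hp, "hydrophobic", criteria$hydrophobic))
  if (is.null(typed) || nrow(typed) == 0) return(empty_contacts())

  lab <- function(i, suffix) {
    setNames(tibble(cand$chain[i], cand$resno[i], cand$resid[i],
                    cand$elety[i]),
             paste0(c("chain_", "resno_", "resid_", "atom_"), suffix))
  }
  # canonical pair order: lower (chain, resno, atom name) first
  flip <- with(typed, {
    ka <- paste(cand$chain[ia], sprintf("%08d", cand$resno[ia]),
                cand$elety[ia])
    kb <- paste(cand$chain[ib], sprintf("%08d", cand$resno[ib]),
                cand$elety[ib])
    ka > kb
  })
  a_idx <- ifelse(flip, typed$ib, typed$ia)
  b_idx <- ifelse(flip, typed$ia, typed$ib)
  out <- dplyr::bind_cols(
    lab(a_idx, "a"), lab(b_idx, "b"),
    tibble(distance = typed$distance, contact_type = typed$contact_type)
  )
  out$scope <- ifelse(out$chain_a == out$chain_b, "intra_chain", "inter_chain")
  out <- distinct(arrange(out, .data$chain_a, .data$resno_a, .data$atom_a,
                          .data$chain_b, .data$resno_b, .data$atom_b,
                          .data$contact_type))
  class(out) <- c("contact_records", class(out))
  out
}

empty_contacts <- function() {
  out <- tibble(chain_a = character(), resno_a = integer(),
                resid_a = character(), atom_a = character(),
                chain_b = character(), resno_b = integer(),
                resid_b = character(), atom_b = character(),
                distance = double(), contact_type = character(),
                scope = character())
  class(out) <- c("contact_records", class(out))
  out
}

#' Classify binding-region stabilisation as lock or interlock
#'
#' Restricts detected contacts to those touching a binding region (e.g. the
#' sugar-binding loop) and classifies its stabilisation: `interlock` when at
#' least one stabilising contact is intermolecular (the region of one
#' subunit is held by a neighbouring subunit, as R287-D456 in the
#' UDP-glucose pyrophosphorylase octamer), `lock` when an intramolecular
#' contact with sequence separation at least `min_seq_separation` stabilises
#' it (tertiary stabilisation within one chain, as in monomeric enzymes),
#' `both` or `none` otherwise. For symmetric oligomers the same partner
#' pairs should recur in every chain; chains deviating from the recurring
#' pattern are listed.
#'
#' @param assembly An assembly.
#' @param binding_region A [region_definition()]; must resolve on at least
#'   one chain (an error is raised if it resolves nowhere).
#' @param min_seq_separation Minimum |residue number difference| for an
#'   intramolecular contact to count as a lock (default 20).
#' @param offset Numbering offset for the region on all chains.
#' @param criteria A [contact_criteria()] object.
#' @param contacts Optional precomputed [detect_contacts()] table.
#' @return An `interlock_report`: `classification`, `stabilizing_contacts`
#'   (contact records touching the region), `partner_pairs` (tibble of
#'   region residue, partner residue, partner chain, scope),
#'   `recurring_pairs`, `deviating_chains`.
#' @export
detect_interlock <- function(assembly, binding_region,
                             min_seq_separation = 20, offset = 0L,
                             criteria = contact_criteria(),
                             contacts = NULL) {
  chains <- chain_ids(assembly)
  resolved <- vapply(chains, function(ch) {
    nrow(suppressWarnings(
      resolve_region(assembly, binding_region, ch, offset))) > 0
  }, TRUE)
  if (!any(resolved)) {
    abort(paste0("region '", binding_region$name,
                 "' resolves in no chain of the assembly"))
  }
  if (is.null(contacts)) contacts <- detect_contacts(assembly, criteria)
  reg <- region_resno(binding_region, as.integer(offset))
  a_in <- contacts$resno_a %in% reg
  b_in <- contacts$resno_b %in% reg
  stab <- contacts[a_in | b_in, ]
  a_first <- stab$resno_a %in% reg
  partner_pairs <- tibble(
    region_chain = ifelse(a_first, stab$chain_a, stab$chain_b),
    region_resno = ifelse(a_first, stab$resno_a, stab$resno_b),
    region_resid = ifelse(a_first, stab$resid_a, stab$resid_b),
    partner_chain = ifelse(a_first, stab$chain_b, stab$chain_a),
    partner_resno = ifelse(a_first, stab$resno_b, stab$resno_a),
    partner_resid = ifelse(a_first, stab$resid_b, stab$resid_a),
    scope = stab$scope
  ) |> distinct()

  inter <- stab$scope == "inter_chain"
  intra_sep <- stab$scope == "intra_chain" &
    abs(stab$resno_a - stab$resno_b) >= min_seq_separation
  classification <- if (any(inter) && any(intra_sep)) "both"
    else if (any(inter)) "interlock"
    else if (any(intra_sep)) "lock"
    else "none"

  # symmetry recurrence: partner patterns (region res, partner res) per chain
  pat <- partner_pairs |>
    filter(.data$scope == "inter_chain") |>
    mutate(pattern = paste(.data$region_resno, .data$partner_resno))
  chains_res <- chains[resolved]
  recurring <- pat |>
    group_by(.data$pattern) |>
    summarise(n_chains = dplyr::n_distinct(.data$region_chain),
              .groups = "drop") |>
    filter(.data$n_chains == length(chains_res))
  deviating <- if (nrow(recurring) > 0) {
    miss <- vapply(chains_res, function(ch) {
      !all(recurring$pattern %in% pat$pattern[pat$region_chain == ch])
    }, TRUE)
    chains_res[miss]
  } else chains_res[!chains_res %in% unique(pat$region_chain)]

  structure(list(binding_region = binding_region,
                 classification = classification,
                 stabilizing_contacts = stab,
                 partner_pairs = partner_pairs,
                 recurring_pairs = recurring$pattern,
                 deviating_chains = deviating,
                 min_seq_separation = min_seq_separation),
            class = "interlock_report")
}

#' @export
print.interlock_report <- function(x, ...) {
  cat(sprintf("<interlock_report> region %s: %s (%d stabilizing contacts)\n",
              x$binding_region$name, x$classification,
              nrow(x$stabilizing_contacts)))
  if (nrow(x$partner_pairs)) {
    print(utils::head(x$partner_pairs, 10))
  }
  invisible(x)
}

#' @export
glance.interlock_report <- function(x, ...) {
  tibble(region = x$binding_region$name,
         classification = x$classification,
         n_stabilizing = nrow(x$stabilizing_contacts),
         n_inter_chain = sum(x$stabilizing_contacts$scope == "inter_chain"),
         n_recurring_pairs = length(x$recurring_pairs),
         n_deviating_chains = length(x$deviating_chains))
}

#' @export
tidy.interlock_report <- function(x, ...) x$partner_pairs

#' Contacts abolished by in-silico side-chain truncation
#'
#' Geometric plausibility check for point mutants (e.g. R287L, D456K): each
#' substituted side chain is truncated to the atoms shared between the old
#' and new residue type (no rotamer building), and every detected contact
#' involving a removed atom is reported as abolished. The delta of a double
#' mutant is the union of the single-mutant deltas.
#'
#' @param assembly An assembly.
#' @param substitutions Data frame with columns `chain`, `resno`,
#'   `new_resid` (3-letter code).
#' @param criteria A [contact_criteria()] object.
#' @param contacts Optional precomputed contact table.
#' @return The abolished contact records, with `sub_chain`, `sub_resno`,
#'   `sub_new_resid` columns identifying the causing substitution.
#' @export
mutate_in_silico_contact_check <- function(assembly, substitutions,
                                           criteria = contact_criteria(),
                                           contacts = NULL) {
  substitutions <- as_tibble(substitutions)
  stopifnot(all(c("chain", "resno", "new_resid") %in% names(substitutions)))
  if (is.null(contacts)) contacts <- detect_contacts(assembly, criteria)
  prot <- protein_atoms(assembly)
  out <- purrr::pmap(substitutions, function(chain, resno, new_resid, ...) {
    res_atoms <- prot[prot$chain == chain & prot$resno == resno, ]
    if (nrow(res_atoms) == 0) {
      abort(paste0("no residue ", resno, " in chain ", chain))
    }
    if (!new_resid %in% names(SIDECHAIN_ATOMS)) {
      abort(paste0("unknown residue name: ", new_resid))
    }
    old_resid <- res_atoms$resid[1]
    removed <- setdiff(sidechain_atoms_of(old_resid),
                       sidechain_atoms_of(new_resid))
    hit_a <- contacts$chain_a == chain & contacts$resno_a == resno &
      contacts$atom_a %in% removed
    hit_b <- contacts$chain_b == chain & contacts$resno_b == resno &
      contacts$atom_b %in% removed
    delta <- contacts[hit_a | hit_b, ]
    if (nrow(delta) == 0) return(NULL)
    dplyr::mutate(as_tibble(delta), sub_chain = chain, sub_resno = resno,
                  sub_new_resid = new_resid)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- dplyr::mutate(as_tibble(empty_contacts()),
                         sub_chain = character(), sub_resno = integer(),
                         sub_new_resid = character())
  }
  res
}
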