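# Shared fixture builders (everything generated in code; no stored binaries).

toy_c4 <- function(n_res = 30, seed = 1) {
  make_assembly(make_subunit(seed, n_res), "C", 4)
}

toy_d4 <- function(n_res = 30, seed = 1) {
  make_assembly(make_subunit(seed, n_res), "D", 4)
}

# a free-standing atom tibble row
atom_row <- function(serial, chain, resno, resid, elety, xyz,
                     element = substr(elety, 1, 1)) {
  tibble::tibble(serial = serial, chain = chain, resno = resno, icode = "",
                 resid = resid, elety = elety, element = element,
                 x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 0,
                 altloc = "", het = FALSE)
}

# random toy assembly over the residue-chemistry tables, for oracle tests
random_toy_assembly <- function(n_atoms = 50, seed = 42, box = 15) {
  set.seed(seed)
  pool <- list(
    ARG = c("N", "CA", "C", "O", "CB", "NE", "NH1", "NH2"),
    ASP = c("N", "CA", "C", "O", "CB", "OD1", "OD2"),
    LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1"),
    SER = c("N", "CA", "C", "O", "CB", "OG"),
    ALA = c("N", "CA", "C", "O", "CB")
  )
  rows <- lapply(seq_len(n_atoms), function(i) {
    resid <- sample(names(pool), 1)
    elety <- sample(pool[[resid]], 1)
    atom_row(i, sample(c("A", "B"), 1), sample(1:12, 1), resid, elety,
             runif(3, 0, box))
  })
  at <- dplyr::bind_rows(rows)
  # one atom name per residue per altloc: drop duplicates
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$elety,
                        .keep_all = TRUE)
  new_assembly(at, id = "random_toy")
}

# apply a fixed non-trivial global rigid motion to an assembly
shift_rotate <- function(assembly, angle = 37, axis = c(1, 2, 3),
                         shift = c(5, -3, 8)) {
  tr <- rigid_transform(rotation_about(axis / sqrt(sum(axis^2)), angle),
                        shift)
  transform_atoms(assembly, tr)
}
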