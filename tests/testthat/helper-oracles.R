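# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: rotations are parameterised by Euler angles and
# scanned/refined numerically, neighbour searches are plain O(n^2) loops.

euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# brute-force minimum RMSD over proper rotations: coarse Euler grid followed
# by Nelder-Mead refinement; translation handled by centring both sets
oracle_min_rmsd <- function(ref, mov) {
  p <- sweep(as.matrix(ref), 2, colMeans(ref))
  q <- sweep(as.matrix(mov), 2, colMeans(mov))
  f <- function(ang) {
    r <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((q %*% t(r) - p)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  bgrid <- seq(0, pi, length.out = 7)
  best <- NULL; best_val <- Inf
  for (a in grid) for (b in bgrid) for (c in grid) {
    v <- f(c(a, b, c))
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  opt$value
}

# exhaustive all-pairs contact detection applying the package's distance
# criteria tables directly
oracle_contacts <- function(assembly, criteria = contact_criteria()) {
  at <- as.data.frame(assembly[!assembly$het, ])
  n <- nrow(at)
  sc_of <- function(tbl, r) if (r %in% names(tbl)) tbl[[r]] else character()
  donors <- list(
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
    HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
    TRP = "NE1", TYR = "OH")
  acceptors <- list(ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
                    GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
                    SER = "OG", THR = "OG1", TYR = "OH")
  basic <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HIS = c("ND1", "NE2"))
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  apolar <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
  bb <- c("N", "CA", "C", "O", "OXT")
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
    d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) -
                     c(at$x[j], at$y[j], at$z[j]))^2))
    if (d > max(criteria$hbond, criteria$salt_bridge, criteria$hydrophobic)) {
      next
    }
    don <- function(k) (at$elety[k] == "N" && at$resid[k] != "PRO") ||
      at$elety[k] %in% sc_of(donors, at$resid[k])
    acc <- function(k) at$elety[k] %in% c("O", "OXT") ||
      at$elety[k] %in% sc_of(acceptors, at$resid[k])
    is_no <- function(k) at$element[k] %in% c("N", "O")
    types <- character()
    if (d <= criteria$hbond && is_no(i) && is_no(j) &&
        ((don(i) && acc(j)) || (don(j) && acc(i)))) {
      types <- c(types, "hbond")
    }
    if (d <= criteria$salt_bridge &&
        ((at$elety[i] %in% sc_of(basic, at$resid[i]) &&
            at$elety[j] %in% sc_of(acidic, at$resid[j])) ||
           (at$elety[j] %in% sc_of(basic, at$resid[j]) &&
              at$elety[i] %in% sc_of(acidic, at$resid[i])))) {
      types <- c(types, "salt_bridge")
    }
    if (d <= criteria$hydrophobic &&
        at$element[i] == "C" && at$element[j] == "C" &&
        at$resid[i] %in% apolar && at$resid[j] %in% apolar &&
        !(at$elety[i] %in% bb) && !(at$elety[j] %in% bb)) {
      types <- c(types, "hydrophobic")
    }
    for (tp in types) {
      ki <- paste(at$chain[i], sprintf("%08d", at$resno[i]), at$elety[i])
      kj <- paste(at$chain[j], sprintf("%08d", at$resno[j]), at$elety[j])
      a <- if (ki <= kj) i else j; b <- if (ki <= kj) j else i
      rows[[length(rows) + 1]] <- data.frame(
        chain_a = at$chain[a], resno_a = at$resno[a],
        resid_a = at$resid[a], atom_a = at$elety[a],
        chain_b = at$chain[b], resno_b = at$resno[b],
        resid_b = at$resid[b], atom_b = at$elety[b],
        distance = d, contact_type = tp,
        scope = if (at$chain[a] == at$chain[b]) "intra_chain"
                else "inter_chain",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$chain_a, out$resno_a, out$atom_a, out$chain_b, out$resno_b,
            out$atom_b, out$contact_type), ]
}

contact_key <- function(ct) {
  if (is.null(ct) || nrow(ct) == 0) return(character())
  sort(paste(ct$chain_a, ct$resno_a, ct$atom_a, ct$chain_b, ct$resno_b,
             ct$atom_b, ct$contact_type))
}
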