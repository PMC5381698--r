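#' Crystallographic unit cell
#'
#' @param a,b,c Cell edges, Angstrom.
#' @param alpha,beta,gamma Cell angles, degrees (each in (0, 180)).
#' @return A `quat_unit_cell` object.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) abort("cell edges must be positive")
  if (any(c(alpha, beta, gamma) <= 0 | c(alpha, beta, gamma) >= 180)) {
    abort("cell angles must lie in (0, 180) degrees")
  }
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "quat_unit_cell")
}

#' Unit-cell volume
#'
#' Triclinic formula
#' `V = abc sqrt(1 - cos^2(a) - cos^2(b) - cos^2(g) + 2 cos(a)cos(b)cos(g))`,
#' which reduces to `abc` for orthorhombic and `a^2 c sin(gamma)` for
#' trigonal/hexagonal cells.
#'
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "quat_unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  rad <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (rad <= 0) abort("invalid angle combination: cell volume not real")
  cell$a * cell$b * cell$c * sqrt(rad)
}

# reciprocal of 0.813e-3 with partial specific volume 0.74 cm^3/g: solvent
# fraction = 1 - 1.230 / V_M
MATTHEWS_SOLVENT_CONST <- 1.230

#' Matthews coefficient and solvent content
#'
#' `V_M = V_cell / (Z * M)` (cubic Angstrom per Dalton), with Z the number
#' of protein molecules per unit cell and M the molar mass of one molecule.
#' The solvent fraction follows as `(1 - 1.230 / V_M) * 100` per cent,
#' using a protein partial specific volume of 0.74 cm^3/g; it is undefined
#' (flagged `NA`) for V_M at or below 1.230.
#'
#' @param cell A [unit_cell()].
#' @param z_molecules Protein molecules per unit cell (>= 1).
#' @param molar_mass Molar mass of one molecule, Da.
#' @return One-row tibble: `cell_volume`, `n_molecules_per_cell`,
#'   `molar_mass`, `matthews_vm`, `solvent_fraction` (per cent; `NA` when
#'   undefined). Nothing is rounded.
#' @export
matthews <- function(cell, z_molecules, molar_mass) {
  if (z_molecules < 1) abort("z_molecules must be >= 1")
  if (molar_mass <= 0) abort("molar_mass must be positive")
  v <- cell_volume(cell)
  vm <- v / (z_molecules * molar_mass)
  solvent <- if (vm > MATTHEWS_SOLVENT_CONST) {
    (1 - MATTHEWS_SOLVENT_CONST / vm) * 100
  } else {
    warn("Matthews coefficient <= 1.230: solvent content undefined")
    NA_real_
  }
  tibble(cell_volume = v, n_molecules_per_cell = as.integer(z_molecules),
         molar_mass = molar_mass, matthews_vm = vm,
         solvent_fraction = solvent)
}

#' Molar mass of a protein chain from its sequence
#'
#' Average-isotope residue masses summed over the one-letter sequence, plus
#' one water per chain.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet
#'   (whitespace ignored).
#' @return Mass in Dalton.
#' @export
molar_mass_from_sequence <- function(sequence) {
  letters1 <- strsplit(gsub("\\s", "", toupper(sequence)), "")[[1]]
  if (length(letters1) == 0) abort("empty sequence")
  unknown <- setdiff(letters1, names(AA_RESIDUE_MASS))
  if (length(unknown) > 0) {
    abort(paste0("unknown amino-acid letter(s): ",
                 paste(unique(unknown), collapse = ", ")))
  }
  sum(AA_RESIDUE_MASS[letters1]) + WATER_MASS
}

hill_fn <- function(x, v_max, k, h) v_max * x^h / (k^h + x^h)

#' Fit Michaelis-Menten or Hill kinetics
#'
#' Least-squares fit of `y = Vmax x / (Km + x)` (model `"MM"`) or
#' `y = Vmax x^H / (K^H + x^H)` (model `"Hill"`; `K` is the
#' half-saturation constant K0.5, and H = 1 recovers Michaelis-Menten
#' exactly). Hill fits are initialisation-sensitive, so a small multi-start
#' is used: Vmax from 1.2 max(y), K from the interpolated half-max
#' concentration, H in {0.5, 1, 2, 4}; the converged start with the lowest
#' residual sum of squares wins.
#'
#' @param data Data frame with columns `conc` (substrate concentration,
#'   >= 0) and `velocity`; at least 5 points and 2 distinct concentrations.
#' @param model `"MM"` or `"Hill"`.
#' @return A `kinetics_fit` object: `model`, `parameters` (tibble of
#'   estimate and standard error), `rss`, `n`, `converged`, `fitted`.
#' @export
fit_kinetics <- function(data, model = c("MM", "Hill")) {
  model <- match.arg(model)
  data <- as_tibble(data)
  stopifnot(all(c("conc", "velocity") %in% names(data)))
  x <- data$conc; y <- data$velocity
  if (length(x) < 5) abort("kinetics fitting needs at least 5 points")
  if (any(x < 0)) abort("concentrations must be non-negative")
  if (length(unique(x)) < 2) abort("need at least 2 distinct concentrations")

  v0 <- max(y) * 1.2
  k0 <- half_max_conc(x, y)
  starts <- if (model == "MM") {
    list(c(v_max = v0, k = k0))
  } else {
    lapply(c(0.5, 1, 2, 4), function(h) c(v_max = v0, k = k0, h = h))
  }
  fits <- lapply(starts, function(st) {
    tryCatch({
      if (model == "MM") {
        minpack.lm::nlsLM(velocity ~ v_max * conc / (k + conc), data = data,
                          start = as.list(st),
                          lower = c(1e-12, 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(velocity ~ v_max * conc^h / (k^h + conc^h),
                          data = data, start = as.list(st),
                          lower = c(1e-12, 1e-12, 1e-3),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (length(fits) == 0) {
    abort(paste0("kinetics fit failed to converge from any start (model ",
                 model, ", n = ", length(x), ")"))
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  best <- fits[[which.min(rss)]]
  sm <- summary(best)
  par_names <- if (model == "MM") c("v_max", "k_m") else
    c("v_max", "k_half", "hill_h")
  params <- tibble(term = par_names,
                   estimate = unname(coef(best)),
                   std_error = unname(sm$coefficients[, "Std. Error"]))
  structure(list(model = model, parameters = params,
                 rss = min(rss), n = length(x), converged = TRUE,
                 fitted = stats::fitted(best), data = data,
                 fit = best),
            class = "kinetics_fit")
}

half_max_conc <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  half <- max(y) / 2
  above <- which(y >= half)
  if (length(above) == 0 || above[1] == 1) return(max(stats::median(x), 1e-6))
  i <- above[1]
  x0 <- x[i - 1]; x1 <- x[i]; y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(x1)
  max(x0 + (half - y0) * (x1 - x0) / (y1 - y0), 1e-6)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s, n = %d, RSS = %.4g\n", x$model, x$n, x$rss))
  print(x$parameters)
  invisible(x)
}

#' @export
tidy.kinetics_fit <- function(x, ...) x$parameters

#' @export
glance.kinetics_fit <- function(x, ...) {
  est <- setNames(x$parameters$estimate, x$parameters$term)
  tibble(model = x$model, v_max = est[["v_max"]],
         k = est[[if (x$model == "MM") "k_m" else "k_half"]],
         hill_h = if (x$model == "Hill") est[["hill_h"]] else 1,
         rss = x$rss, n = x$n, converged = x$converged)
}

#' Extra-sum-of-squares comparison of Hill versus Michaelis-Menten
#'
#' Michaelis-Menten (2 parameters) is nested in Hill (3 parameters) at
#' H = 1, so the models are compared with an F-test on the residual sums of
#' squares: `F = (RSS_MM - RSS_Hill) / (RSS_Hill / (n - 3))`. Hill is
#' preferred when p < `alpha` — the formal version of calling a
#' substrate-velocity curve sigmoidal rather than hyperbolic.
#'
#' @param data Data frame with `conc` and `velocity` columns.
#' @param alpha Preference threshold (default 0.05).
#' @return One-row tibble: `preferred`, `f_statistic`, `p_value`,
#'   `rss_mm`, `rss_hill`, `hill_h`.
#' @export
compare_kinetic_models <- function(data, alpha = 0.05) {
  fit_mm <- fit_kinetics(data, "MM")
  fit_hill <- fit_kinetics(data, "Hill")
  n <- fit_mm$n
  df2 <- n - 3
  if (df2 <= 0) abort("too few points for model comparison")
  num <- max(fit_mm$rss - fit_hill$rss, 0)
  f <- (num / 1) / (fit_hill$rss / df2)
  p <- pf(f, 1, df2, lower.tail = FALSE)
  h <- fit_hill$parameters$estimate[fit_hill$parameters$term == "hill_h"]
  tibble(preferred = if (p < alpha) "Hill" else "MM",
         f_statistic = f, p_value = p,
         rss_mm = fit_mm$rss, rss_hill = fit_hill$rss, hill_h = h)
}

#' Fit a Boltzmann sigmoid to a thermofluor melting curve
#'
#' Normalises the fluorescence to \[0, 1\] and fits
#' `F(T) = 1 / (1 + exp((Tm - T) / slope))`; the inflection point Tm is the
#' melting temperature. Two normalisation modes: `"plateau"` (default) uses
#' the means of the first and last `n_plateau` points as the pre- and
#' post-transition baselines, which resists spikes; `"minmax"` uses the
#' global minimum and maximum.
#'
#' @param data Data frame with columns `temperature` (strictly increasing,
#'   degrees C) and `fluorescence`; at least 10 points.
#' @param normalize `"plateau"` or `"minmax"`.
#' @param n_plateau Points per plateau for `"plateau"` normalisation
#'   (default 5).
#' @return A `melt_fit` object: `t_m` (degrees C), `slope`, `rss`, `n`,
#'   `normalized` data.
#' @export
fit_melt <- function(data, normalize = c("plateau", "minmax"),
                     n_plateau = 5) {
  normalize <- match.arg(normalize)
  data <- as_tibble(data)
  stopifnot(all(c("temperature", "fluorescence") %in% names(data)))
  tt <- data$temperature; ff <- data$fluorescence
  if (length(tt) < 10) abort("melt fitting needs at least 10 points")
  if (any(diff(tt) <= 0)) abort("temperatures must be strictly increasing")
  if (normalize == "plateau") {
    lo <- mean(head(ff, n_plateau)); hi <- mean(tail(ff, n_plateau))
  } else {
    lo <- min(ff); hi <- max(ff)
  }
  if (hi - lo <= .Machine$double.eps * max(abs(c(lo, hi)), 1) ||
      hi <= lo) {
    abort("no fluorescence rise: data are not sigmoidal")
  }
  fn <- (ff - lo) / (hi - lo)
  nd <- tibble(temperature = tt, f_norm = fn)
  t0 <- tt[which.min(abs(fn - 0.5))]
  slope0 <- max(diff(range(tt)) / 20, 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(f_norm ~ 1 / (1 + exp((t_m - temperature) / slope)),
                      data = nd, start = list(t_m = t0, slope = slope0),
                      lower = c(min(tt), 1e-6), upper = c(max(tt), Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("melt fit failed: ",
                                     conditionMessage(e)))
  )
  est <- coef(fit)
  structure(list(t_m = unname(est["t_m"]), slope = unname(est["slope"]),
                 rss = sum(stats::resid(fit)^2), n = length(tt),
                 normalize = normalize, normalized = nd,
                 fitted = stats::fitted(fit), fit = fit),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f C, slope = %.2f C (n = %d, RSS = %.4g)\n",
              x$t_m, x$slope, x$n, x$rss))
  invisible(x)
}

#' @export
tidy.melt_fit <- function(x, ...) {
  tibble(term = c("t_m", "slope"), estimate = c(x$t_m, x$slope))
}

#' @export
glance.melt_fit <- function(x, ...) {
  tibble(t_m = x$t_m, slope = x$slope, rss = x$rss, n = x$n,
         normalize = x$normalize)
}
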