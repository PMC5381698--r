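#' Configuration for the quaternary-mechanism report
#'
#' Collects the inputs and tunable cutoffs of the end-to-end analysis. All
#' defaults equal the documented module defaults; the full configuration is
#' serialised into the report for provenance.
#'
#' @param apo_path,holo_path Structure files for the two states.
#' @param regions A named list of [region_definition()]s or a path to a
#'   YAML region config. Must contain the binding region named in
#'   `binding_region`; a region named in `terminal_region` enables
#'   interface classification.
#' @param binding_region Name of the binding region (e.g. `"SB_loop"`).
#' @param terminal_region Name of the terminal-strand region, or `NULL`.
#' @param fit_region Name of the stable region used as superposition frame;
#'   `NULL` (default) fits on all non-binding-region C-alpha atoms — the
#'   choice of fit frame is the main sensitivity of displacement maxima,
#'   so it is an explicit parameter.
#' @param apo_offset,holo_offset Numbering offsets of each structure
#'   relative to the regions' numbering scheme (e.g. -11 for an isoform 2
#'   structure against isoform 1 regions).
#' @param angle_tol,residual_tol Symmetry detection tolerances.
#' @param criteria [contact_criteria()].
#' @param min_seq_separation Lock threshold, residues.
#' @param contact_cutoff,min_pairs Interface classification parameters.
#' @param output_dir Optional directory for the JSON report.
#' @return A `quat_config` object.
#' @export
quat_config <- function(apo_path, holo_path, regions, binding_region,
                        terminal_region = NULL, fit_region = NULL,
                        apo_offset = 0L, holo_offset = 0L,
                        angle_tol = 5, residual_tol = 1.5,
                        criteria = contact_criteria(),
                        min_seq_separation = 20,
                        contact_cutoff = 4.5, min_pairs = 30,
                        output_dir = NULL) {
  for (p in c(apo_path, holo_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  if (is.character(regions) && length(regions) == 1) {
    if (!file.exists(regions)) abort(paste0("region file not found: ", regions))
    regions <- read_regions(regions)
  }
  stopifnot(is.list(regions),
            all(vapply(regions, inherits, TRUE, "region_definition")))
  if (!binding_region %in% names(regions)) {
    abort(paste0("binding region '", binding_region,
                 "' missing from region definitions"))
  }
  if (!is.null(terminal_region) && !terminal_region %in% names(regions)) {
    abort(paste0("terminal region '", terminal_region, "' missing"))
  }
  if (!is.null(fit_region) && !fit_region %in% names(regions)) {
    abort(paste0("fit region '", fit_region, "' missing"))
  }
  structure(list(apo_path = apo_path, holo_path = holo_path,
                 regions = regions, binding_region = binding_region,
                 terminal_region = terminal_region, fit_region = fit_region,
                 apo_offset = as.integer(apo_offset),
                 holo_offset = as.integer(holo_offset),
                 angle_tol = angle_tol, residual_tol = residual_tol,
                 criteria = criteria,
                 min_seq_separation = min_seq_separation,
                 contact_cutoff = contact_cutoff, min_pairs = min_pairs,
                 output_dir = output_dir),
            class = "quat_config")
}

round_num <- function(x, digits) {
  if (is.numeric(x)) round(x, digits) else x
}

#' Run the end-to-end quaternary-mechanism report
#'
#' Orchestrates the full analysis of an apo / product-bound structure pair:
#' point-group symmetry per state, interface classification, per-region
#' displacement maxima, lock/interlock classification of the binding
#' region, and the compaction report. Each stage is run in sequence; a
#' failing stage is recorded with its error while later independent stages
#' still run. When `config$output_dir` is set, the report is written as
#' JSON (`quaternary_report.json`, schema version 1; Angstrom values at 3
#' decimals, percentages at 1; the timestamp lives in a separate field so
#' reports from identical inputs are byte-identical apart from it).
#'
#' @param config A [quat_config()].
#' @return A `quaternary_report` list: `config`, `symmetry` (per state),
#'   `interfaces`, `displacement` (per-region maxima), `interlock`,
#'   `compaction`, `errors` (named list of stage failures, empty on full
#'   success).
#' @export
run_quaternary_report <- function(config) {
  stopifnot(inherits(config, "quat_config"))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  apo <- stage("read_apo",
               read_structure(config$apo_path, state_label = "apo"))
  holo <- stage("read_holo",
                read_structure(config$holo_path,
                               state_label = "product_bound"))
  sym_apo <- if (!is.null(apo)) {
    stage("symmetry_apo",
          detect_point_group(apo, config$angle_tol, config$residual_tol))
  }
  sym_holo <- if (!is.null(holo)) {
    stage("symmetry_holo",
          detect_point_group(holo, config$angle_tol, config$residual_tol))
  }
  interfaces <- if (!is.null(holo) && !is.null(config$terminal_region)) {
    stage("interfaces",
          classify_interfaces(holo, config$regions[[config$terminal_region]],
                              config$contact_cutoff, config$min_pairs,
                              offset = config$holo_offset))
  }
  displacement <- if (!is.null(apo) && !is.null(holo)) {
    stage("displacement",
          pipeline_displacement(apo, holo, config))
  }
  interlock <- if (!is.null(holo)) {
    stage("interlock",
          detect_interlock(holo, config$regions[[config$binding_region]],
                           config$min_seq_separation,
                           offset = config$holo_offset,
                           criteria = config$criteria))
  }
  compaction <- if (!is.null(apo) && !is.null(holo) &&
                    !is.null(sym_holo)) {
    stage("compaction",
          compaction_report(apo, holo, symmetry = sym_holo))
  }
  report <- structure(list(config = config,
                           symmetry = list(apo = sym_apo, holo = sym_holo),
                           interfaces = interfaces,
                           displacement = displacement,
                           interlock = interlock,
                           compaction = compaction,
                           errors = errors),
                      class = "quaternary_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report_to_json(report),
      file.path(config$output_dir, "quaternary_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  }
  report
}

# displacement maxima for every region against the fit frame
pipeline_displacement <- function(apo, holo, config) {
  fit_region <- if (!is.null(config$fit_region)) {
    config$regions[[config$fit_region]]
  } else {
    # default frame: everything outside the binding region
    binding <- config$regions[[config$binding_region]]
    covered <- region_resno(binding)
    all_res <- sort(unique(protein_atoms(holo)$resno)) - config$holo_offset
    keep <- setdiff(all_res, covered)
    region_definition("fit_frame", runs_to_ranges(keep),
                      binding$numbering_scheme)
  }
  apo_chain <- chain_atoms(protein_atoms(apo), chain_ids(apo)[1])
  holo_chain <- chain_atoms(protein_atoms(holo), chain_ids(holo)[1])
  purrr::imap(config$regions, function(reg, nm) {
    prof <- displacement_profile(apo_chain, holo_chain, fit_region, reg,
                                 ref_offset = config$apo_offset,
                                 mov_offset = config$holo_offset)
    if (nrow(prof) == 0) return(NULL)
    list(profile = prof,
         max_ca = max_displacement(prof, "ca"),
         max_sc = tryCatch(max_displacement(prof, "sidechain"),
                           error = function(e) NULL))
  })
}

runs_to_ranges <- function(v) {
  v <- sort(unique(v))
  if (length(v) == 0) abort("empty residue set")
  breaks <- c(0, which(diff(v) > 1), length(v))
  lapply(seq_len(length(breaks) - 1), function(i) {
    c(v[breaks[i] + 1], v[breaks[i + 1]])
  })
}

report_to_json <- function(report) {
  cfg <- report$config
  sym_json <- function(s) {
    if (is.null(s)) return(NULL)
    list(point_group = s$point_group,
         principal_axis = round_num(s$principal_axis, 3),
         fit_residual = round_num(s$fit_residual, 3),
         chain_cycle = as.list(s$chain_cycle),
         face_to_back = s$face_to_back)
  }
  disp_json <- if (!is.null(report$displacement)) {
    purrr::map(purrr::compact(report$displacement), function(d) {
      list(max_ca = round_num(d$max_ca$max_disp, 3),
           max_ca_residue = d$max_ca$seq_num,
           max_sidechain = if (!is.null(d$max_sc))
             round_num(d$max_sc$max_disp, 3),
           n_residues = nrow(d$profile))
    })
  }
  comp_json <- if (!is.null(report$compaction)) {
    cr <- report$compaction
    list(extents_apo = round_num(unname(cr$extents_apo), 3),
         extents_holo = round_num(unname(cr$extents_holo), 3),
         deltas = round_num(unname(cr$deltas), 3),
         percent_volume_change = round_num(cr$percent_volume_change, 1))
  }
  il_json <- if (!is.null(report$interlock)) {
    il <- report$interlock
    list(classification = il$classification,
         n_stabilizing_contacts = nrow(il$stabilizing_contacts),
         partner_pairs = il$partner_pairs,
         deviating_chains = il$deviating_chains)
  }
  list(schema_version = 1L,
       generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = list(apo_path = cfg$apo_path, holo_path = cfg$holo_path,
                     binding_region = cfg$binding_region,
                     terminal_region = cfg$terminal_region,
                     fit_region = cfg$fit_region,
                     apo_offset = cfg$apo_offset,
                     holo_offset = cfg$holo_offset,
                     angle_tol = cfg$angle_tol,
                     residual_tol = cfg$residual_tol,
                     hbond_cutoff = cfg$criteria$hbond,
                     salt_bridge_cutoff = cfg$criteria$salt_bridge,
                     hydrophobic_cutoff = cfg$criteria$hydrophobic,
                     min_seq_separation = cfg$min_seq_separation,
                     contact_cutoff = cfg$contact_cutoff,
                     min_pairs = cfg$min_pairs),
       symmetry = list(apo = sym_json(report$symmetry$apo),
                       holo = sym_json(report$symmetry$holo)),
       interfaces = report$interfaces,
       displacement = disp_json,
       interlock = il_json,
       compaction = comp_json,
       errors = report$errors)
}

#' @export
print.quaternary_report <- function(x, ...) {
  cat("<quaternary_report>\n")
  if (!is.null(x$symmetry$holo)) {
    cat("  holo symmetry:", x$symmetry$holo$point_group, "\n")
  }
  if (!is.null(x$symmetry$apo)) {
    cat("  apo symmetry :", x$symmetry$apo$point_group, "\n")
  }
  if (!is.null(x$interlock)) {
    cat("  binding region:", x$interlock$classification, "\n")
  }
  if (!is.null(x$compaction)) {
    cat(sprintf("  volume change: %+.1f %%\n",
                x$compaction$percent_volume_change))
  }
  if (length(x$errors)) {
    cat("  FAILED stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
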