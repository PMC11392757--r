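# Orchestration of the three analysis arcs (flexibility, interface
# stability, bridge geometry) plus the SAXS stack. Each runner takes a
# validated config list, writes tidy CSV tables and a JSON summary under
# the output directory, and returns the report invisibly-friendly as a
# list. Defaults mirror the analysis conventions used throughout the
# package: 2 A contact cutoff, 1 ns windows, 0.5 occupancy, LIE (0.5,
# 0.18), q*Rg <= 1.3, 20-100 ns summary window, 1.8 A graft-RMSD warning.

validate_config <- function(config, required, optional = character(0)) {
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  }
  config
}

write_report <- function(report, output_dir, stem) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(output_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

manifest <- function(config, output_dir, stem) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config[!vapply(config, is.function, logical(1))]
  cfg <- cfg[!vapply(cfg, function(x) is.list(x) && !is.null(attr(x, "class")),
                     logical(1))]
  info <- list(
    package_version = as.character(utils::packageVersion("fabflex")),
    config = cfg,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(info, file.path(output_dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' Run the Fab-Fab flexibility analysis
#'
#' Computes per-frame Fab-Fab angles for one or more trajectories, their
#' windowed summaries (mean, SD, range over the summary window), and
#' optionally a two-group t-test on the per-model SDs.
#'
#' @param config list with keys: `trajectories` (named list of
#'   [md_trajectory()] objects or multi-model PDB paths), `fab1`, `fab2`
#'   (domain-definition lists as for [fab_fab_angle()]), optional
#'   `window_ns` (default c(20, 100)), `dt_ns` (for paths), `groups` (named
#'   list of two character vectors of trajectory names to compare),
#'   `output_dir`.
#' @return list with `per_frame` (long data.frame), `summaries` (one row per
#'   trajectory), optional `t_test`.
#' @export
run_flexibility <- function(config) {
  config <- validate_config(config, c("trajectories", "fab1", "fab2"),
                            c("window_ns", "dt_ns", "groups", "output_dir"))
  window_ns <- config$window_ns %||% c(20, 100)
  trajs <- config$trajectories
  if (is.null(names(trajs))) names(trajs) <- paste0("model_", seq_along(trajs))
  per_frame <- list()
  summaries <- list()
  for (nm in names(trajs)) {
    tr <- trajs[[nm]]
    if (is.character(tr)) tr <- read_trajectory(tr, dt_ns = config$dt_ns %||% 1)
    asr <- angle_series(tr, config$fab1, config$fab2, window_ns = window_ns)
    per_frame[[nm]] <- data.frame(model = nm, asr)
    s <- summary(asr)
    summaries[[nm]] <- data.frame(model = nm, mean_deg = s$mean, sd_deg = s$sd,
                                  range_deg = s$range, n_frames = s$n)
  }
  report <- list(per_frame = do.call(rbind, per_frame),
                 summaries = do.call(rbind, summaries))
  rownames(report$summaries) <- NULL
  if (!is.null(config$groups)) {
    g <- config$groups
    if (length(g) != 2) stop("groups must name exactly two groups")
    sd_of <- function(members) {
      report$summaries$sd_deg[match(members, report$summaries$model)]
    }
    tt <- compare_angle_sd(sd_of(g[[1]]), sd_of(g[[2]]))
    report$t_test <- c(list(group_a = names(g)[1], group_b = names(g)[2]), tt)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$per_frame,
                     file.path(config$output_dir, "angles_per_frame.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summaries,
                     file.path(config$output_dir, "angle_summaries.csv"),
                     row.names = FALSE)
    write_report(report[setdiff(names(report), "per_frame")],
                 config$output_dir, "flexibility")
    manifest(list(window_ns = window_ns, models = names(trajs)),
             config$output_dir, "flexibility")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the interface contact/energy analysis
#'
#' Computes the per-window contact-persistence table and the top pairs by
#' persistent time for a trajectory, and/or the LIE series and stability
#' verdict for an energy table.
#'
#' @param config list with optional keys `trajectory` (an [md_trajectory()]
#'   or path), `group_a`, `group_b` (selections or chain-id vectors),
#'   `contact_params` (a [contact_params()]), `energies` (an
#'   [energy_series()] or path), `lie_coeffs`, `tail_fraction`, `top_k`
#'   (default 8), `dt_ns`, `output_dir`. At least one of `trajectory` or
#'   `energies` is required.
#' @return list with any of `contacts` (contact table), `top_pairs`,
#'   `energies` (series with e_lie), `verdict`, `tail_mean`.
#' @export
run_interface <- function(config) {
  config <- validate_config(config, character(0),
                            c("trajectory", "group_a", "group_b",
                              "contact_params", "energies", "lie_coeffs",
                              "tail_fraction", "top_k", "dt_ns", "output_dir"))
  if (is.null(config$trajectory) && is.null(config$energies)) {
    stop("config needs 'trajectory' and/or 'energies'")
  }
  report <- list()
  if (!is.null(config$trajectory)) {
    tr <- config$trajectory
    if (is.character(tr)) tr <- read_trajectory(tr, dt_ns = config$dt_ns %||% 1)
    as_sel <- function(x, label) {
      if (inherits(x, "atom_selection")) x
      else select_atoms(tr$structure, chain = x, label = label)
    }
    ga <- as_sel(config$group_a, "group_a")
    gb <- as_sel(config$group_b, "group_b")
    ct <- contact_persistence(tr, ga, gb,
                              config$contact_params %||% contact_params())
    top_k <- config$top_k %||% 8
    pp <- attr(ct, "pair_persistence")
    report$contacts <- ct
    report$top_pairs <- utils::head(pp, top_k)
  }
  if (!is.null(config$energies)) {
    es <- config$energies
    coeffs <- config$lie_coeffs %||% c(elec = 0.5, vdw = 0.18)
    if (is.character(es)) es <- read_energy_table(es, coeffs = coeffs)
    verdict <- classify_association(es, config$tail_fraction %||% 0.2)
    report$energies <- es
    report$verdict <- as.character(verdict)
    report$tail_mean <- attr(verdict, "tail_mean")
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$contacts)) {
      utils::write.csv(report$contacts,
                       file.path(config$output_dir, "contact_persistence.csv"),
                       row.names = FALSE)
      utils::write.csv(report$top_pairs,
                       file.path(config$output_dir, "top_pairs.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$energies)) {
      utils::write.csv(report$energies,
                       file.path(config$output_dir, "lie_series.csv"),
                       row.names = FALSE)
    }
    write_report(report[intersect(names(report),
                                  c("top_pairs", "verdict", "tail_mean"))],
                 config$output_dir, "interface")
  }
  report
}

#' Run the receptor-bridge geometry analysis
#'
#' Optionally grafts a ligand onto a target via shared atoms (with the 1.8
#' Angstrom RMSD warning), then measures the two receptors' transmembrane
#' vectors and the inter-membrane angle.
#'
#' @param config list with keys `structure` (assembled `structure_model`) or
#'   `target` + `ligand` + `shared_target` + `shared_ligand` (for
#'   [graft_structure()]), plus `helices1`, `helices2` (helix definition
#'   data.frames); optional `rmsd_warn` (default 1.8), `output_dir`.
#' @return list with `structure`, optional `fit`, `tm1`, `tm2`,
#'   `tm_angle_deg`.
#' @export
run_bridge_model <- function(config) {
  config <- validate_config(config, c("helices1", "helices2"),
                            c("structure", "target", "ligand", "shared_target",
                              "shared_ligand", "rmsd_warn", "output_dir"))
  report <- list()
  if (!is.null(config$structure)) {
    st <- config$structure
  } else {
    g <- graft_structure(config$target, config$ligand, config$shared_target,
                         config$shared_ligand,
                         rmsd_warn = config$rmsd_warn %||% 1.8)
    st <- g$structure
    report$fit <- list(rmsd = g$fit$rmsd, n_atoms = g$fit$n_atoms)
  }
  v1 <- tm_vector(st, config$helices1)
  v2 <- tm_vector(st, config$helices2)
  report$structure <- st
  report$tm1 <- v1$vector
  report$tm2 <- v2$vector
  report$tm_angle_deg <- tm_angle(v1, v2)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(st, file.path(config$output_dir, "assembly.pdb"))
    write_report(report[setdiff(names(report), "structure")],
                 config$output_dir, "bridge_model")
  }
  report
}

#' Run the SAXS analysis stack on one profile
#'
#' Guinier fit, dimensionless Kratky transform, and Porod volume/mass for an
#' experimental or synthetic profile; optionally a chi-square fit against a
#' model structure's Debye curve, and P(r)/Dmax for a model structure.
#'
#' @param config list with key `profile` (a [saxs_profile()] or path);
#'   optional `model` (a `structure_model` for chi2 + P(r)), `qrg_max`
#'   (default 1.3), `bin_width` (P(r), default 2), `granularity`,
#'   `output_dir`.
#' @return list with `guinier`, `kratky_peak`, `porod`; optional `chi2`,
#'   `pddf`.
#' @export
run_saxs <- function(config) {
  config <- validate_config(config, "profile",
                            c("model", "qrg_max", "bin_width", "granularity",
                              "output_dir"))
  prof <- config$profile
  if (is.character(prof)) prof <- read_saxs_profile(prof)
  gu <- guinier_fit(prof, qrg_max = config$qrg_max %||% 1.3)
  kr <- kratky_dimensionless(prof, gu)
  po <- porod_volume(prof, gu)
  report <- list(
    guinier = list(rg = gu$rg, i0 = gu$i0, n_points = gu$n_points,
                   q_min = gu$fit_range[1], q_max = gu$fit_range[2],
                   r_squared = gu$r_squared),
    kratky_peak = list(qrg = attr(kr, "peak_qrg"),
                       value = attr(kr, "peak_value")),
    porod = list(invariant = po$porod_invariant, vp_a3 = po$vp,
                 mm_kda = po$mm_kda)
  )
  if (!is.null(config$model)) {
    gran <- config$granularity %||% "residue"
    calc <- debye_profile(config$model, prof$q, granularity = gran)
    if (!is.null(prof$sigma)) {
      cs <- chi_square_fit(calc, prof)
      report$chi2 <- list(chi2 = cs$chi2, scale_c = cs$scale_c,
                          n_points = cs$n_points)
    }
    pd <- pddf_from_structure(config$model, bin_width = config$bin_width %||% 2,
                              granularity = gran)
    report$pddf <- list(dmax = pd$dmax, bin_width = pd$bin_width)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(kr),
                     file.path(config$output_dir, "kratky_dimensionless.csv"),
                     row.names = FALSE)
    write_report(report, config$output_dir, "saxs")
  }
  report
}
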