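#' Default threshold grid around the mean-field critical point
#'
#' 30 linearly spaced thresholds on `[0.2, 3] * Tc_mf`, where `Tc_mf` is the
#' mean-field estimate from [mean_field_tc()]; wide enough to cover the
#' transition on arbitrary synthetic networks.
#'
#' @param net a `weighted_network`.
#' @param r2 refractory release probability used in the mean-field formula.
#' @param n_points number of grid points (default 30).
#' @return numeric grid.
#' @export
default_threshold_grid <- function(net, r2, n_points = 30L) {
  tc <- mean_field_tc(net, r2)
  if (tc <= 0) stop("mean-field threshold is not positive")
  seq(0.2 * tc, 3 * tc, length.out = n_points)
}

log_info <- function(...) message("[criticonn] ", ...)

#' Contrast of critical vs non-critical small-world dynamics
#'
#' Runs the excitable automaton on two Watts-Strogatz networks of `n` nodes
#' (rewiring 0.5, exponential weights, rate 12.5): total degree `k = 10`
#' (critical: interior S2 peak) and `k = 2` (non-critical: no interior
#' peak), with `r1 = 0.001`, `r2 = 0.3` on the unnormalized symmetric
#' weights. Both sweeps share the grid derived from the k=10 network.
#'
#' @param n nodes per network (default 2000).
#' @param t_max,t_init simulation length (defaults 10000 / 200).
#' @param n_thresholds grid size (default 30).
#' @param seed master seed.
#' @return bundle list with sweeps `critical` and `noncritical`.
#' @export
experiment_ws_contrast <- function(n = 2000L, t_max = 10000L, t_init = 200L,
                                   n_thresholds = 30L, seed = 1L) {
  log_info("ws_contrast: generating WS networks (n=", n, ")")
  net_c <- generate_ws_network(n, k = 10L, pi = 0.5, lam = 12.5,
                               seed = derive_subseed(seed, 1L))
  net_n <- generate_ws_network(n, k = 2L, pi = 0.5, lam = 12.5,
                               seed = derive_subseed(seed, 2L))
  grid <- default_threshold_grid(net_c, r2 = 0.3, n_points = n_thresholds)
  base <- gh_params(threshold = grid[1L], r1 = 0.001, r2 = 0.3,
                    t_max = t_max, t_init = t_init, seed = seed)
  log_info("ws_contrast: sweeping k=10 network")
  sw_c <- threshold_sweep(net_c, grid, base)
  log_info("ws_contrast: sweeping k=2 network")
  sw_n <- threshold_sweep(net_n, grid, base)
  list(experiment = "ws_contrast", seed = seed,
       tables = list(critical = as.data.frame(sw_c),
                     noncritical = as.data.frame(sw_n)),
       summary = list(
         peak_critical = peak_location(get_curve(sw_c, "S2")),
         peak_noncritical = peak_location(get_curve(sw_n, "S2"))),
       sweeps = list(critical = sw_c, noncritical = sw_n))
}

#' S2 comb across artificial-stroke severities
#'
#' Generates a modular synthetic connectome, normalizes it to unit
#' in-strength, and sweeps the excitable automaton for node-severity lesions
#' of the target RSN across `severities`, averaging the S2 curve over
#' `n_realizations` seeded lesion draws per severity.
#'
#' @param connectome optional list `(network, parcellation)`; generated with
#'   [generate_modular_connectome()] defaults when `NULL`.
#' @param target RSN label (default `"auditory"`).
#' @param severities numeric vector of node fractions (default
#'   `seq(0.75, 1, by = 0.05)`, the severe regime in which the peak is
#'   progressively lost).
#' @param variant lesion variant, `"node_severity"` (default) or
#'   `"edge_fraction"`.
#' @param n_realizations lesion draws per severity (default 20).
#' @param t_max,t_init,n_thresholds simulation protocol.
#' @param seed master seed.
#' @return bundle list; `tables$s2_family` has one row per
#'   (severity, threshold).
#' @export
experiment_stroke_sweep <- function(connectome = NULL, target = "auditory",
                                    severities = seq(0.75, 1, by = 0.05),
                                    variant = "node_severity",
                                    n_realizations = 20L,
                                    t_max = 10000L, t_init = 200L,
                                    n_thresholds = 30L, seed = 1L) {
  if (is.null(connectome)) {
    log_info("stroke_sweep: generating synthetic connectome")
    connectome <- generate_modular_connectome(seed = derive_subseed(seed, 1L))
  }
  net <- normalize_in_strength(connectome$network)
  parc <- connectome$parcellation
  rates <- default_rates(net$n_nodes)
  grid <- default_threshold_grid(net, rates$r2, n_points = n_thresholds)
  base <- gh_params(threshold = grid[1L], r1 = rates$r1, r2 = rates$r2,
                    t_max = t_max, t_init = t_init, seed = seed)
  fam <- lapply(seq_along(severities), function(si) {
    sev <- severities[si]
    log_info("stroke_sweep: severity ", sev, " (", variant, ")")
    spec <- lesion_spec(target, sev, variant,
                        n_realizations = n_realizations,
                        seed = derive_subseed(seed, 100L + si))
    ens <- lesion_ensemble(net, parc, spec, function(lnet, sub_seed) {
      p <- base; p$seed <- sub_seed
      sw <- threshold_sweep(lnet, grid, p)
      get_curve(sw, "S2")$values
    })
    data.frame(severity = sev, threshold = grid, S2 = ens$mean)
  })
  tab <- do.call(rbind, fam)
  peaks <- lapply(split(tab, tab$severity), function(d) {
    peak_location(indicator_curve(d$threshold, d$S2, "S2"))
  })
  list(experiment = "stroke_sweep", seed = seed,
       tables = list(s2_family = tab),
       summary = list(peaks = peaks))
}

#' Structural-integrity analysis of artificial strokes
#'
#' For each target RSN and severity, draws `n_realizations` node-severity
#' lesions and measures: area under the S2 threshold curve (`I2`),
#' normalized modularity `Q/Qmax` of a seeded Louvain partition, and the
#' conductance `h_G` of the target RSN. Ensemble means are converted to
#' relative changes `(A - A0)/A0` against the unlesioned network, and the
#' Pearson correlations of `I2(norm)` with `Q(norm)` and with `-h_G(norm)`
#' are reported.
#'
#' @inheritParams experiment_stroke_sweep
#' @param targets RSN labels to lesion (default: all modules except the
#'   largest complement, i.e. six of the eight default RSNs).
#' @param severities node fractions 0 to 1 (default `seq(0, 1, by = 0.2)`).
#' @return bundle list with `tables$measures` and correlation summaries.
#' @export
experiment_structural <- function(connectome = NULL,
                                  targets = NULL,
                                  severities = seq(0, 1, by = 0.2),
                                  n_realizations = 20L,
                                  t_max = 10000L, t_init = 200L,
                                  n_thresholds = 30L, seed = 1L) {
  if (is.null(connectome)) {
    log_info("structural: generating synthetic connectome")
    connectome <- generate_modular_connectome(seed = derive_subseed(seed, 1L))
  }
  net <- normalize_in_strength(connectome$network)
  parc <- connectome$parcellation
  if (is.null(targets)) targets <- utils::head(attr(parc, "levels"), 6L)
  rates <- default_rates(net$n_nodes)
  grid <- default_threshold_grid(net, rates$r2, n_points = n_thresholds)
  base <- gh_params(threshold = grid[1L], r1 = rates$r1, r2 = rates$r2,
                    t_max = t_max, t_init = t_init, seed = seed)

  measure_net <- function(mnet, target, sub_seed) {
    p <- base; p$seed <- sub_seed
    sw <- threshold_sweep(mnet, grid, p)
    part <- louvain_partition(mnet, seed = sub_seed)
    c(I2 = area_under_s2(get_curve(sw, "S2")),
      Q_norm = q_normalized(mnet, part),
      h_G = conductance(mnet, parcellation_nodes(parc, target)))
  }

  rows <- list()
  for (target in targets) {
    base_vals <- measure_net(net, target, derive_subseed(seed, 7L))
    for (sev in severities) {
      log_info("structural: target ", target, ", severity ", sev)
      spec <- lesion_spec(target, sev, "node_severity",
                          n_realizations = n_realizations,
                          seed = derive_subseed(seed, 1000L +
                                                  length(rows)))
      ens <- lesion_ensemble(net, parc, spec, function(lnet, sub_seed) {
        measure_net(lnet, target, sub_seed)
      })
      m <- ens$mean
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, severity = sev,
        I2 = m[["I2"]], Q_norm = m[["Q_norm"]], h_G = m[["h_G"]],
        I2_norm = normalized_change(m[["I2"]], base_vals[["I2"]]),
        Q_norm_norm = normalized_change(m[["Q_norm"]], base_vals[["Q_norm"]]),
        h_G_norm = if (base_vals[["h_G"]] != 0) {
          normalized_change(m[["h_G"]], base_vals[["h_G"]])
        } else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  cor_q <- pearson_ci(tab$I2_norm, tab$Q_norm_norm)
  cor_h <- pearson_ci(tab$I2_norm, -tab$h_G_norm)
  list(experiment = "structural", seed = seed,
       tables = list(measures = tab),
       summary = list(cor_I2_Qnorm = cor_q, cor_I2_neg_hG = cor_h))
}

#' Divided-lattice Ising experiment
#'
#' Temperature sweeps of the Ising model on the undivided lattice, the
#' equal-halves division, and the central-patch division, with per-subsystem
#' cluster series. Reproduces the qualitative structure in which the
#' whole-system S2 of a divided lattice has no interior peak while the
#' subsystem S2 curves do.
#'
#' @param rows,cols lattice size (default 100 x 100).
#' @param patch_side side of the central patch (default 50).
#' @param temperatures grid (default [default_temperature_grid()]).
#' @param t_max,t_init sweeps (defaults 5000 / 200).
#' @param seed master seed.
#' @return bundle list with one table per division.
#' @export
experiment_ising_divided <- function(rows = 100L, cols = 100L,
                                     patch_side = 50L,
                                     temperatures = default_temperature_grid(),
                                     t_max = 5000L, t_init = 200L,
                                     seed = 1L) {
  base <- ising_params(temperature = temperatures[1L], t_max = t_max,
                       t_init = t_init, seed = seed)
  run_one <- function(division, ps = NULL) {
    log_info("ising_divided: division=", division)
    lat <- build_lattice(lattice_spec(rows, cols, division, patch_side = ps))
    parc <- if (division == "none") NULL else lat$parcellation
    temperature_sweep(lat$network, temperatures, base, parc = parc)
  }
  sw0 <- run_one("none")
  swh <- run_one("equal_halves")
  swp <- run_one("central_patch", patch_side)
  list(experiment = "ising_divided", seed = seed,
       tables = list(undivided = as.data.frame(sw0),
                     equal_halves = as.data.frame(swh),
                     central_patch = as.data.frame(swp)),
       summary = list(
         peak_undivided = peak_location(get_curve(sw0, "S2")),
         peak_halves_whole = peak_location(get_curve(swh, "S2")),
         peak_halves_A = peak_location(get_curve(swh, "S2:A")),
         peak_patch_whole = peak_location(get_curve(swp, "S2")),
         peak_patch_A = peak_location(get_curve(swp, "S2:A"))),
       sweeps = list(undivided = sw0, equal_halves = swh,
                     central_patch = swp))
}

#' Comb families: progressive loss of the S2 peak
#'
#' (a) Ising: S2 temperature curves for central patches of increasing side
#' (subsystem sizes 400 to 3600 by default); (b) excitable automaton on a
#' modular connectome: S2 threshold curves for edge-fraction lesions of the
#' target RSN at severities 0.75 to 1. Above a size/severity threshold the
#' interior S2 maximum is lost.
#'
#' @param patch_sides Ising patch sides (default `c(20, 30, 40, 50, 60)`).
#' @param severities edge-removal fractions (default `seq(0.75, 1, 0.05)`).
#' @inheritParams experiment_ising_divided
#' @inheritParams experiment_stroke_sweep
#' @param ising_t_max,gh_t_max per-model simulation lengths.
#' @return bundle list with `tables$ising_family` and `tables$gh_family`.
#' @export
experiment_comb <- function(rows = 100L, cols = 100L,
                            patch_sides = c(20L, 30L, 40L, 50L, 60L),
                            temperatures = default_temperature_grid(),
                            ising_t_max = 5000L,
                            connectome = NULL, target = "auditory",
                            severities = seq(0.75, 1, by = 0.05),
                            n_realizations = 20L,
                            gh_t_max = 10000L,
                            t_init = 200L, n_thresholds = 30L, seed = 1L) {
  base_i <- ising_params(temperature = temperatures[1L], t_max = ising_t_max,
                         t_init = t_init, seed = seed)
  ising_fam <- lapply(patch_sides, function(ps) {
    log_info("comb: Ising patch side ", ps)
    lat <- build_lattice(lattice_spec(rows, cols, "central_patch",
                                      patch_side = ps))
    sw <- temperature_sweep(lat$network, temperatures, base_i)
    data.frame(patch_side = ps, n_b = ps^2, temperature = temperatures,
               S2 = get_curve(sw, "S2")$values)
  })
  # the lesion comb varies RSN connectivity: edge-fraction removals
  gh <- experiment_stroke_sweep(connectome = connectome, target = target,
                                severities = severities,
                                variant = "edge_fraction",
                                n_realizations = n_realizations,
                                t_max = gh_t_max, t_init = t_init,
                                n_thresholds = n_thresholds,
                                seed = derive_subseed(seed, 2L))
  list(experiment = "comb", seed = seed,
       tables = list(ising_family = do.call(rbind, ising_fam),
                     gh_family = gh$tables$s2_family),
       summary = list(gh_peaks = gh$summary$peaks))
}

#' Run an experiment from a configuration
#'
#' `config` is a YAML file or a named list with at least `experiment` (one of
#' `"ws_contrast"`, `"stroke_sweep"`, `"structural"`, `"ising_divided"`,
#' `"comb"`) and optionally `out_dir`, `seed`, plus any arguments of the
#' corresponding `experiment_*()` function. Results are returned and, when
#' `out_dir` is set, written to disk as one TSV per table plus a
#' `summary.json` carrying the master seed and peak/correlation summaries.
#' Runs are deterministic given the config.
#'
#' @param config path to a YAML file or a named list.
#' @return the experiment bundle, invisibly if written to disk.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$experiment)) {
    stop("config must name an experiment")
  }
  fn <- switch(config$experiment,
               ws_contrast = experiment_ws_contrast,
               stroke_sweep = experiment_stroke_sweep,
               structural = experiment_structural,
               ising_divided = experiment_ising_divided,
               comb = experiment_comb,
               stop("unknown experiment: ", config$experiment))
  out_dir <- config$out_dir
  args <- config[setdiff(names(config), c("experiment", "out_dir"))]
  bad <- setdiff(names(args), names(formals(fn)))
  if (length(bad) > 0L) {
    stop("unknown config key(s) for ", config$experiment, ": ",
         paste(bad, collapse = ", "))
  }
  bundle <- do.call(fn, args)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle$tables)) {
      utils::write.table(bundle$tables[[nm]],
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      c(list(experiment = bundle$experiment, seed = bundle$seed),
        bundle$summary),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_info("wrote ", length(bundle$tables), " table(s) to ", out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Plot the curves and scatter summaries of an experiment bundle
#'
#' Produces line plots of the S2 curves per condition and, for the
#' structural experiment, scatter plots of `I2(norm)` against `Q(norm)` and
#' `-h_G(norm)` with the correlation annotated. Requires ggplot2 (Suggests);
#' plots are written as PNG when `out_dir` is given, otherwise returned.
#' Regeneration from a saved bundle is simulation-free.
#'
#' @param bundle an experiment bundle from [run_experiment()].
#' @param out_dir optional output directory for PNG files.
#' @return named list of ggplot objects, invisibly when written.
#' @export
make_report <- function(bundle, out_dir = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("make_report requires the ggplot2 package")
  }
  if (is.null(bundle$tables) || length(bundle$tables) == 0L) {
    stop("bundle has no tables")
  }
  curve_plot <- function(tab, xcol, grp, title) {
    d <- data.frame(x = tab[[xcol]], S2 = tab$S2)
    p <- if (!is.null(grp)) {
      d$grp <- factor(tab[[grp]])
      ggplot2::ggplot(d, ggplot2::aes(x, S2, color = grp, group = grp)) +
        ggplot2::geom_line() + ggplot2::labs(color = grp)
    } else {
      ggplot2::ggplot(d, ggplot2::aes(x, S2)) + ggplot2::geom_line()
    }
    p + ggplot2::xlab(xcol) + ggplot2::theme_minimal() +
      ggplot2::ggtitle(title)
  }
  plots <- list()
  for (nm in names(bundle$tables)) {
    tab <- bundle$tables[[nm]]
    xcol <- intersect(c("threshold", "temperature"), names(tab))
    if (length(xcol) == 1L && "S2" %in% names(tab)) {
      grp <- intersect(c("severity", "patch_side"), names(tab))
      plots[[nm]] <- curve_plot(tab, xcol,
                                if (length(grp) == 1L) grp else NULL, nm)
    }
  }
  if (identical(bundle$experiment, "structural")) {
    tab <- bundle$tables$measures
    scat <- function(x, y, title) {
      d <- data.frame(x = x, y = y)
      ggplot2::ggplot(d, ggplot2::aes(x, y)) + ggplot2::geom_point() +
        ggplot2::theme_minimal() + ggplot2::ylab("I2 (norm.)") +
        ggplot2::ggtitle(title)
    }
    lab_q <- sprintf("rho = %.2f [%.2f, %.2f]",
                     bundle$summary$cor_I2_Qnorm$rho,
                     bundle$summary$cor_I2_Qnorm$ci_low,
                     bundle$summary$cor_I2_Qnorm$ci_high)
    plots$scatter_q <- scat(tab$Q_norm_norm, tab$I2_norm,
                            paste("I2(norm) vs Q(norm):", lab_q)) +
      ggplot2::xlab("Q (norm.)")
    lab_h <- sprintf("rho = %.2f [%.2f, %.2f]",
                     bundle$summary$cor_I2_neg_hG$rho,
                     bundle$summary$cor_I2_neg_hG$ci_low,
                     bundle$summary$cor_I2_neg_hG$ci_high)
    plots$scatter_h <- scat(-tab$h_G_norm, tab$I2_norm,
                            paste("I2(norm) vs -h_G(norm):", lab_h)) +
      ggplot2::xlab("-h_G (norm.)")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), plots[[nm]],
                      width = 7, height = 5, dpi = 150)
    }
    return(invisible(plots))
  }
  plots
}
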