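#' Registry of named experiments
#'
#' Each named experiment carries the exact parameterization of the
#' corresponding published analysis: the certainty/gamble surfaces
#' (`fig2`), the normal-form equilibrium sweeps (`fig3`), the level-k
#' tower values and policies (`fig6`), the sophistication-level stationary
#' grid (`fig7`), the reference-point sweep (`fig8`), and the
#' supplementary comparisons (`s1` tower values for expected-utility vs
#' CPT agents, `s2` their stationary distributions, `s3` discount factors
#' 0.85/0.95, `s4` the all-expected-utility level grid, `s5` the mixed
#' expected-utility/CPT pair, `s6`/`s7` utility concavity 0.99/0.95).
#'
#' @return A named list of experiment descriptions (parameters plus a
#'   short note on grid choices that the source analyses leave open).
#' @export
experiment_registry <- function() {
  markov <- list(spec = canyon_spec(), config = planning_config(0.9),
                 params = markov_cpt_params(), k_max = 4L)
  list(
    fig2 = list(
      kind = "surfaces",
      scenarios = list(
        a = list(r_certain = 900, r_plus = 1000, r_minus = 0, p = 0.95),
        b = list(r_certain = -900, r_plus = 0, r_minus = -1000, p = 0.05),
        c = list(r_certain = 55, r_plus = 1000, r_minus = 0, p = 0.05),
        d = list(r_certain = -55, r_plus = 0, r_minus = -1000, p = 0.95)),
      utility = utility_spec("power", gamma = 0.85, lambda = 2),
      delta = 0.75,
      b_grid = seq(-100, 100, length.out = 81),
      alpha_grid = seq(0.1, 3, length.out = 81),
      note = "axis ranges are not printed in the source; defaults span the decision boundary"),
    fig3 = list(
      kind = "normal_form_sweeps",
      game = stag_hunt(),
      delta = 0.75,
      panels = list(
        list(axis1 = list(param = "reference_point",
                          values = seq(-3, 3, length.out = 61)),
             axis2 = list(param = "alpha",
                          values = seq(0.1, 3, length.out = 61))),
        list(axis1 = list(param = "lambda",
                          values = seq(0.5, 3, length.out = 61)),
             axis2 = list(param = "alpha",
                          values = seq(0.1, 3, length.out = 61))),
        list(axis1 = list(param = "gamma",
                          values = seq(0.5, 1.5, length.out = 61)),
             axis2 = list(param = "alpha",
                          values = seq(0.1, 3, length.out = 61))),
        list(axis1 = list(param = "reference_point",
                          values = seq(-3, 3, length.out = 61)),
             axis2 = list(param = "lambda",
                          values = seq(0.5, 3, length.out = 61))),
        list(axis1 = list(param = "reference_point",
                          values = seq(-3, 3, length.out = 61)),
             axis2 = list(param = "gamma",
                          values = seq(0.5, 1.5, length.out = 61)))),
      note = "grid ranges/resolutions are not printed in the source"),
    fig6 = c(markov, list(kind = "tower")),
    fig7 = c(markov, list(kind = "levels_grid")),
    fig8 = c(markov, list(kind = "reference_points",
                          b_values = c(-1, 0, 1, 2))),
    s1 = c(markov, list(kind = "tower_pair",
                        params_eut = eut_params())),
    s2 = c(markov, list(kind = "agent_mix",
                        mixes = list(
                          eut = list(eut_params(), eut_params()),
                          cpt = list(markov_cpt_params(),
                                     markov_cpt_params())))),
    s3 = c(markov, list(kind = "discounts", beta_values = c(0.85, 0.95))),
    s4 = c(markov, list(kind = "levels_grid", params = eut_params())),
    s5 = c(markov, list(kind = "agent_mix",
                        mixes = list(
                          eut_cpt = list(eut_params(),
                                         markov_cpt_params())))),
    s6 = c(markov, list(kind = "concavity", gamma_values = 0.99)),
    s7 = c(markov, list(kind = "concavity", gamma_values = 0.95))
  )
}

#' Run a named experiment and write its outputs
#'
#' Executes one registry entry (or a custom modification of one) and
#' writes deterministic tab-separated numeric tables plus a manifest
#' recording every parameter and residual. Rerunning a spec produces
#' byte-identical tables.
#'
#' @param name Registry name (see [experiment_registry()]).
#' @param out_dir Output directory (created if missing).
#' @param overrides Named list of fields to replace in the registry entry.
#' @return Character vector of the files written, invisibly.
#' @export
run_experiment <- function(name, out_dir, overrides = list()) {
  reg <- experiment_registry()
  if (!name %in% names(reg)) {
    stop("unknown experiment: ", name, "; known: ",
         paste(names(reg), collapse = ", "))
  }
  ex <- utils::modifyList(reg[[name]], overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  manifest <- list(experiment = name, package = "cptcoord",
                   overrides = names(overrides))
  if (ex$kind == "surfaces") {
    for (nm in names(ex$scenarios)) {
      sc <- ex$scenarios[[nm]]
      surf <- decision_surface(sc$r_certain, sc$r_plus, sc$r_minus, sc$p,
                               ex$b_grid, ex$alpha_grid, ex$utility,
                               ex$delta)
      emit(surf[, c("b", "alpha", "difference")],
           paste0("surface_", nm, ".tsv"))
    }
    manifest$scenarios <- ex$scenarios
  } else if (ex$kind == "normal_form_sweeps") {
    defaults <- cpt_params(
      utility_spec("power", gamma = 1, lambda = 1),
      weighting_spec("prelec", alpha = 1, delta = ex$delta), 0)
    for (i in seq_along(ex$panels)) {
      pn <- ex$panels[[i]]
      sw <- equilibrium_sweep(ex$game, pn$axis1, pn$axis2, defaults)
      emit(sw, sprintf("sweep_%s_x_%s.tsv", pn$axis1$param, pn$axis2$param))
    }
  } else if (ex$kind == "tower") {
    tower <- level_k_tower(ex$k_max, ex$spec, ex$params, ex$params,
                           ex$config)
    emit(tidy(tower), "tower.tsv")
    emit(glance(tower), "tower_summary.tsv")
  } else if (ex$kind == "tower_pair") {
    for (lab in c("cpt", "eut")) {
      p <- if (lab == "cpt") ex$params else ex$params_eut
      tower <- level_k_tower(ex$k_max, ex$spec, p, p, ex$config)
      emit(tidy(tower), paste0("tower_", lab, ".tsv"))
      emit(glance(tower), paste0("tower_", lab, "_summary.tsv"))
    }
  } else {
    args <- list(kind = ex$kind, spec = ex$spec, params = ex$params,
                 config = ex$config, k_max = ex$k_max)
    for (fld in c("b_values", "beta_values", "gamma_values", "mixes")) {
      if (!is.null(ex[[fld]])) args[[fld]] <- ex[[fld]]
    }
    sw <- do.call(run_sweep, args)
    emit(dplyr::select(sw, -"rho"), "sweep_summary.tsv")
    st <- joint_states(ex$spec$n_positions)
    flat <- dplyr::bind_rows(purrr::map(seq_len(nrow(sw)), function(i) {
      setting <- dplyr::select(sw[i, ], -"rho", -"stag_mass", -"hare_mass",
                               -"residual")
      dplyr::bind_cols(setting[rep(1L, nrow(st)), , drop = FALSE],
                       st, tibble::tibble(probability = sw$rho[[i]]))
    }))
    emit(flat, "stationary_distributions.tsv")
    manifest$residual_max <- max(sw$residual)
  }
  manifest$files <- basename(files)
  man_path <- file.path(out_dir, "manifest.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(manifest_serializable(manifest), man_path)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)), man_path)
  }
  invisible(c(files, man_path))
}

# drop closures/classed objects yaml cannot encode
manifest_serializable <- function(x) {
  rapply(x, function(v) {
    if (is.atomic(v)) v else utils::capture.output(utils::str(v))
  }, how = "replace")
}
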