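#' Read an area table from CSV
#'
#' Expects columns `id,x,y,cases` and either `pop` or the census pair
#' `pop2006,pop2011` (averaged into the population at risk). Validation and
#' the averaging rule live in [area_table()].
#'
#' @param path CSV file path.
#' @return an [area_table()].
#' @export
read_area_table <- function(path) {
  area_table(utils::read.csv(path))
}

#' Write an area (or result) table to CSV
#'
#' @param tab data frame; list-columns (cluster memberships) are flattened
#'   to semicolon-separated strings.
#' @param path output CSV path.
#' @export
write_table_csv <- function(tab, path) {
  tab <- as.data.frame(tab)
  for (j in seq_along(tab))
    if (is.list(tab[[j]]))
      tab[[j]] <- vapply(tab[[j]], paste, character(1), collapse = ";")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    areas = NULL, edges = NULL,           # CSV paths; NULL -> simulate
    sim = NULL,                           # simulation_spec overrides (list)
    out_dir = "sirscan-out",
    seed = 1L,
    moran = list(n_perm = 999L, input = "cases"),
    seb = list(order = 2L, include_lower = TRUE),
    bym = list(n_iter = 5000L, n_burn = 1000L, n_chains = 2L, thin = 1L,
               a_v = 0.5, b_v = 0.005, a_u = 0.5, b_u = 0.5),
    scan = list(gini = TRUE, max_frac = 0.5, reps = 999L, alpha = 0.05,
                years = 3),
    skip_bym = FALSE, skip_scan = FALSE, skip_seb = FALSE,
    verbose = TRUE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full small-area analysis pipeline
#'
#' Stages: load (or simulate) the area table and adjacency, expected counts
#' and raw SIRs, Moran's I, spatial empirical Bayes smoothing, the BYM
#' model, and the spatial scan (Gini-selected maximum size by default).
#' Every stage writes its table under `out_dir`; the resolved configuration
#' and a log are echoed there for provenance. Stages already written are
#' kept if a later stage fails.
#'
#' @param config named list overriding the defaults (see
#'   `sirscan:::default_pipeline_config()`), or a path to a YAML file with
#'   the same structure. Key entries: `areas`/`edges` (CSV paths; when
#'   `NULL` a synthetic study from [simulation_spec()] modified by `sim` is
#'   generated), `seed`, `skip_bym`, `skip_scan`, `skip_seb`, and the
#'   per-stage blocks `moran`, `seb`, `bym`, `scan`.
#' @return invisibly, a list with the per-stage results (`areas`, `sir`,
#'   `moran`, `seb`, `bym`, `scan`) and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "pipeline.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (isTRUE(cfg$verbose)) message(msg)
  }
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  # -- inputs ---------------------------------------------------------------
  if (is.null(cfg$areas)) {
    say("simulating synthetic study (no input areas given)")
    spec <- do.call(simulation_spec,
                    c(cfg$sim, if (is.null(cfg$sim$seed)) list(seed = cfg$seed)))
    study <- simulate_study(spec)
    areas <- study$areas; edges <- study$edges
    write_table_csv(areas, file.path(cfg$out_dir, "areas.csv"))
    write_edge_list(edges, file.path(cfg$out_dir, "edges.csv"))
    if (!is.null(study$truth))
      jsonlite::write_json(study$truth, file.path(cfg$out_dir, "truth.json"))
  } else {
    say("reading areas from ", cfg$areas)
    areas <- read_area_table(cfg$areas)
    if (is.null(cfg$edges)) stop("edges CSV required when areas are supplied")
    edges <- read_edge_list(cfg$edges)
  }
  res <- list(areas = areas, out_dir = cfg$out_dir)

  # -- SIR ------------------------------------------------------------------
  sir <- compute_raw_sir(compute_expected(areas))
  write_table_csv(sir, file.path(cfg$out_dir, "sir.csv"))
  say("sir.csv written (", nrow(sir), " areas, ", sum(sir$cases), " cases)")
  res$sir <- sir

  w1 <- build_weights(edges, areas$id, order = 1L)

  # -- Moran's I ------------------------------------------------------------
  x <- switch(cfg$moran$input,
              cases = sir$cases, sir = sir$sir, rate = sir$cases / sir$n,
              stop("moran$input must be cases, sir or rate"))
  mor <- morans_i(x, w1, n_perm = cfg$moran$n_perm, seed = cfg$seed)
  jsonlite::write_json(list(I = mor$I, E_I = mor$E_I, p_perm = mor$p_perm,
                            n_perm = mor$n_perm, input = cfg$moran$input),
                       file.path(cfg$out_dir, "moran.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("Moran's I = %.4f (p = %.4g)", mor$I, mor$p_perm))
  res$moran <- mor

  # -- SEB smoothing --------------------------------------------------------
  if (!isTRUE(cfg$skip_seb)) {
    w2 <- build_weights(edges, areas$id, order = cfg$seb$order,
                        include_lower = cfg$seb$include_lower)
    seb <- seb_smooth(sir, w2)
    write_table_csv(seb, file.path(cfg$out_dir, "sir_seb.csv"))
    say("sir_seb.csv written (zero SIRs: raw ", sum(seb$sir == 0),
        " -> smoothed ", sum(seb$sir_seb == 0), ")")
    res$seb <- seb
  }

  # -- BYM model ------------------------------------------------------------
  if (!isTRUE(cfg$skip_bym)) {
    fit <- fit_bym(sir, w1,
                   priors = bym_priors(cfg$bym$a_v, cfg$bym$b_v,
                                       cfg$bym$a_u, cfg$bym$b_u),
                   config = mcmc_config(cfg$bym$n_iter, cfg$bym$n_burn,
                                        cfg$bym$n_chains, seed = cfg$seed,
                                        thin = cfg$bym$thin))
    bym <- summarize_posterior(fit)
    write_table_csv(bym, file.path(cfg$out_dir, "sir_bym.csv"))
    diag <- list(rhat = as.list(fit$rhat),
                 accept = lapply(fit$accept, as.list))
    jsonlite::write_json(diag, file.path(cfg$out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    say(sprintf("sir_bym.csv written (rhat alpha = %.3f)",
                unname(fit$rhat["alpha"])))
    res$bym <- fit
    res$bym_summary <- bym
  }

  # -- spatial scan ---------------------------------------------------------
  if (!isTRUE(cfg$skip_scan)) {
    D <- pairwise_distances(areas)
    if (isTRUE(cfg$scan$gini)) {
      sc <- gini_select(sir, D, R = cfg$scan$reps, seed = cfg$seed,
                        alpha = cfg$scan$alpha, years = cfg$scan$years)
      write_table_csv(sc$profile, file.path(cfg$out_dir, "gini_profile.csv"))
      say(sprintf("gini profile written (optimal frac %s, Gini %s)",
                  format(sc$optimal_frac), format(sc$optimal_gini)))
      clusters <- sc$clusters
    } else {
      sc <- scan_poisson(sir, D, max_frac = cfg$scan$max_frac,
                         R = cfg$scan$reps, seed = cfg$seed,
                         alpha = cfg$scan$alpha, years = cfg$scan$years)
      clusters <- sc$clusters
    }
    write_table_csv(clusters, file.path(cfg$out_dir, "clusters.csv"))
    say("clusters.csv written (", nrow(clusters), " clusters)")
    res$scan <- sc
  }

  say("pipeline complete")
  invisible(res)
}
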