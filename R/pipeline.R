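pipeline_defaults <- function() {
  list(
    mode = "full",
    temperatures = c(300, 323, 345),
    pmf = list(kind = "acid_acid"),
    schedule = list(r_start = 15, r_end = 3.5, spacing = 0.5, spring = 6),
    sampler = list(n_samples = 20000, n_equilibration = 1000,
                   proposal_step = 0.5, thin = 20),
    wham = list(bin_width = 0.05, tolerance = 1e-7, max_iterations = 1e5,
                bootstrap_replicates = 0),
    thermo = list(r0 = 3.9, r1 = 5.3, standard_state = "molar_1M"),
    vanthoff = list(T0 = 298),
    speciation = NULL,
    input_table = NULL,
    seed = 1)
}

#' Build and validate a pipeline configuration
#'
#' Merges the supplied settings into the documented defaults. Unknown keys
#' (top-level or within a stage block) are rejected with an error naming
#' the offending key, so typos cannot silently fall back to defaults. The
#' result round-trips losslessly through JSON serialization.
#'
#' Two modes exist: `"full"` runs simulate -> WHAM -> well integration at
#' each temperature -> Van't Hoff fit (-> optional speciation);
#' `"thermo"` skips sampling and takes `input_table`, a data.frame with a
#' `temperature` column (K) plus either `dG` (kJ/mol) or `K_d` (mM), so
#' published free-energy tables can be processed directly.
#'
#' @param ... named settings overriding the defaults; stage blocks
#'   (`schedule`, `sampler`, `wham`, `thermo`, `vanthoff`) are lists merged
#'   key by key.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- pipeline_defaults()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && !is.data.frame(user[[key]]) &&
        is.list(user[[key]])) {
      bad <- setdiff(names(user[[key]]), names(cfg[[key]]))
      if (length(bad) > 0L)
        stop("unknown key(s) in '", key, "': ", paste(bad, collapse = ", "))
      cfg[[key]][names(user[[key]])] <- user[[key]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  if (!cfg$mode %in% c("full", "thermo"))
    stop("mode must be 'full' or 'thermo'")
  if (cfg$mode == "thermo" && is.null(cfg$input_table))
    stop("thermo mode requires input_table")
  structure(cfg, class = "pipeline_config")
}

model_for <- function(kind) {
  switch(kind,
         acid_acid = make_default_pmf(),
         water_COH = make_water_pmf("COH"),
         water_CO = make_water_pmf("CO"),
         stop("unknown pmf kind: ", kind))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes all artifacts under `out_dir`:
#' one PMF table per temperature (full mode), an association-results table
#' `association.csv` (temperature, dG_dissociation, K_d), a Van't Hoff
#' summary `vanthoff.json`, an optional speciation curve
#' `speciation.csv`, and a `manifest.json` listing every output file with
#' its MD5 hash together with the seed, package version and configuration.
#' Identical configuration and seed reproduce byte-identical tables and
#' hence identical manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param verbose print stage progress.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- character(0)

  if (config$mode == "thermo") {
    tab <- config$input_table
    if (!"temperature" %in% names(tab))
      stop("input_table needs a 'temperature' column")
    if ("dG" %in% names(tab)) {
      assoc <- data.frame(temperature = tab$temperature,
                          dG_dissociation = tab$dG,
                          K_d = kd_from_dG(tab$dG, tab$temperature))
    } else if ("K_d" %in% names(tab)) {
      assoc <- data.frame(temperature = tab$temperature,
                          dG_dissociation = dG_from_kd(tab$K_d,
                                                       tab$temperature),
                          K_d = tab$K_d)
    } else stop("input_table needs a 'dG' or 'K_d' column")
  } else {
    model <- model_for(config$pmf$kind)
    assoc_rows <- list()
    for (ti in seq_along(config$temperatures)) {
      Tk <- config$temperatures[ti]
      say("simulate + wham at ", Tk, " K")
      scfg <- sampler_config(n_samples = config$sampler$n_samples,
                             n_equilibration = config$sampler$n_equilibration,
                             proposal_step = config$sampler$proposal_step,
                             thin = config$sampler$thin,
                             seed = config$seed + 1000L * (ti - 1L))
      ds <- run_schedule(model, config$schedule$r_start,
                         config$schedule$r_end, config$schedule$spacing,
                         config$schedule$spring, Tk, scfg)
      wcfg <- wham_config(bin_width = config$wham$bin_width,
                          tolerance = config$wham$tolerance,
                          max_iterations = config$wham$max_iterations,
                          bootstrap_replicates = config$wham$bootstrap_replicates,
                          seed = config$seed + 1000L * (ti - 1L))
      prof <- if (wcfg$bootstrap_replicates >= 2L) {
        bootstrap_error(ds, wcfg)
      } else {
        solve_wham(ds, wcfg)
      }
      pmf_file <- file.path(out_dir, sprintf("pmf_%gK.dat", Tk))
      write_pmf_table(prof, pmf_file)
      files <- c(files, pmf_file)
      res <- integrate_association(prof, config$thermo$r0, config$thermo$r1,
                                   Tk, config$thermo$standard_state)
      assoc_rows[[ti]] <- data.frame(temperature = Tk,
                                     dG_dissociation = res$dG_dissociation,
                                     K_d = res$K_d)
    }
    assoc <- do.call(rbind, assoc_rows)
  }

  assoc_file <- file.path(out_dir, "association.csv")
  write_table(assoc, assoc_file)
  files <- c(files, assoc_file)

  fit <- NULL
  if (nrow(assoc) >= 2L) {
    say("vanthoff fit")
    fit <- vant_hoff_fit(assoc$temperature, assoc$K_d,
                         T0 = config$vanthoff$T0)
    vh_file <- file.path(out_dir, "vanthoff.json")
    jsonlite::write_json(
      list(K_d0_mM = fit$K_d0, T0_K = fit$T0, dH_kJ_per_mol = fit$dH,
           fit_method = fit$fit_method, K_d0_method = fit$K_d0_method,
           residuals_ln = fit$residuals),
      vh_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, vh_file)
  }

  if (!is.null(config$speciation) && !is.null(fit)) {
    say("speciation")
    sp <- config$speciation
    K_h <- if (is.null(sp$K_h)) Inf else sp$K_h
    Tsp <- if (is.null(sp$temperature)) config$vanthoff$T0 else sp$temperature
    Ksp <- predict(fit, Tsp)
    curve <- speciation_curve(sp$C_total,
                              if (is.null(sp$W_total)) 0 else sp$W_total,
                              equilibrium_constants(Ksp, K_h, Tsp))
    sp_file <- file.path(out_dir, "speciation.csv")
    write_table(curve, sp_file)
    files <- c(files, sp_file)
  }

  manifest <- list(
    package = "pmfassoc",
    version = as.character(utils::packageVersion("pmfassoc")),
    seed = config$seed,
    mode = config$mode,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
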