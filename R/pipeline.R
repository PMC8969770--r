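#' Run configuration
#'
#' @param mode `"simulate"` (generate a synthetic dataset, then analyze it)
#'   or `"analyze"` (read a dataset directory).
#' @param input_dir Dataset directory (required for `"analyze"`).
#' @param truth Optional `experiment_truth` for `"simulate"`; defaults to
#'   [default_truth()] seeded by `seed`.
#' @param seed Integer seed (noise stream, bootstrap, restarts).
#' @param T Absolute temperature (K) for the free-energy derivation.
#' @param center,half_window Spectral integration window (nm).
#' @param weighting Transport-fit weighting, `"uniform"` or `"poisson"`.
#' @param hrs_mode HRS term in the isotherm model, `"free"` or `"total"`.
#' @param n_boot Bootstrap replicates for isotherm uncertainties (0 = off).
#' @param out_dir Optional output directory: the dataset (simulate mode),
#'   report JSON, transport table and Table-1-style CSV are persisted there.
#' @param max_bg_iter,bg_tol Background fixed-point iteration controls (see
#'   [run_pipeline()]).
#' @return List of class `shg_run_config`.
#' @export
shg_run_config <- function(mode = c("simulate", "analyze"), input_dir = NULL,
                           truth = NULL, seed = 1,
                           T = shg_constants$default_T,
                           center = 400, half_window = 10,
                           weighting = "uniform", hrs_mode = "free",
                           n_boot = 0, out_dir = NULL,
                           max_bg_iter = 15, bg_tol = 1e-8) {
  mode <- match.arg(mode)
  check_pos(T, "T")
  if (mode == "analyze" && is.null(input_dir))
    stop("invalid config: analyze mode requires input_dir", call. = FALSE)
  structure(list(mode = mode, input_dir = input_dir, truth = truth,
                 seed = as.integer(seed), T = T, center = center,
                 half_window = half_window, weighting = weighting,
                 hrs_mode = hrs_mode, n_boot = n_boot, out_dir = out_dir,
                 max_bg_iter = max_bg_iter, bg_tol = bg_tol),
            class = "shg_run_config")
}

stage_error <- function(stage, parent) {
  stop(structure(class = c("shg_stage_error", "error", "condition"),
                 list(message = sprintf("pipeline stage '%s' failed: %s",
                                        stage, conditionMessage(parent)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "shg_stage_error")) stop(e) else stage_error(stage, e)
  })
}

#' Run the full SHG analysis pipeline
#'
#' Stages, in order: (1) simulate or ingest the dataset; (2) calibrate the
#' HRS slope `alpha` from the dye-only series and the baseline `B` from the
#' dye-free spectra; (3) fit the transport model to every trace and the
#' modified Langmuir model to each sample's isotherm. Because the
#' incoherent background of a trace (`alpha * M_free + B`) depends on the
#' free-dye concentration, which is only known once the isotherm is fitted,
#' stage 3 iterates kinetics -> isotherm -> background update to a fixed
#' point (`bg_tol` relative change, at most `max_bg_iter` sweeps; the first
#' sweep uses `B` alone). At zero noise the fixed point is the generating
#' truth. (4) Optional residual bootstrap; (5) derived thermodynamic
#' report per sample. Intermediates and reports are persisted under
#' `out_dir` when given. Deterministic under identical config + seed.
#'
#' @param config An [shg_run_config()].
#' @return Object of class `shg_run_report`: `samples` (per label: `fit`,
#'   `derived`), `transport` (transport_table), `calibration` (`alpha`,
#'   `B`, `r_squared`), `config`, `provenance`, `bg_iterations`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "shg_run_config"))

  ds <- run_stage("input", {
    if (config$mode == "simulate") {
      truth <- config$truth
      if (is.null(truth)) truth <- default_truth(config$seed)
      ds <- simulate_experiment(truth)
      if (!is.null(config$out_dir))
        write_dataset(ds, file.path(config$out_dir, "dataset"))
      ds
    } else read_dataset(config$input_dir)
  })

  cal <- run_stage("calibration", {
    if (length(ds$dye_only$spectra) == 0 || length(ds$dye_free) == 0)
      stop("missing calibration series (dye_only and/or dye_free)", call. = FALSE)
    hrs <- hrs_calibration(ds$dye_only$conc_uM, ds$dye_only$spectra,
                           center = config$center,
                           half_window = config$half_window)
    B <- baseline_offset(ds$dye_free, center = config$center,
                         half_window = config$half_window)
    list(alpha = max(hrs$alpha, 0), B = B, r_squared = hrs$r_squared)
  })

  # group traces by sample label
  labels <- vapply(ds$traces, function(tr) tr$sample$label, character(1))
  groups <- split(seq_along(ds$traces), labels)

  kin_iso <- run_stage("kinetics_isotherm", {
    bg <- rep(cal$B, length(ds$traces))
    fits <- NULL; lang <- list(); n_iter <- 0L
    for (it in seq_len(max(1L, config$max_bg_iter))) {
      n_iter <- it
      fits <- lapply(seq_along(ds$traces), function(i)
        fit_transport(ds$traces[[i]], weighting = config$weighting,
                      background = bg[i]))
      lang <- lapply(groups, function(idx) {
        iso <- assemble_isotherm(fits[idx],
                                 sample = ds$traces[[idx[1]]]$sample,
                                 alpha = cal$alpha, B = cal$B)
        fit_modified_langmuir(iso, hrs_mode = config$hrs_mode,
                              restart_seed = config$seed)
      })
      bg_new <- bg
      for (lab in names(groups)) {
        p <- lang[[lab]]$params
        for (i in groups[[lab]]) {
          M <- langmuir_coverage(ds$traces[[i]]$C_total, p$Nmax, p$K)$M_free
          bg_new[i] <- cal$alpha * M + cal$B
        }
      }
      delta <- max(abs(bg_new - bg)) / max(max(abs(bg_new)), 1e-12)
      bg <- bg_new
      if (delta < config$bg_tol) break
    }
    list(fits = fits, lang = lang, bg = bg, n_iter = n_iter)
  })

  lang <- kin_iso$lang
  if (config$n_boot > 0) {
    lang <- run_stage("bootstrap", lapply(lang, bootstrap_uncertainties,
                                          n_boot = config$n_boot,
                                          seed = config$seed))
  }

  transport <- run_stage("transport_table", {
    rows <- lapply(kin_iso$fits, function(f)
      data.frame(sample = f$sample$label, C_total = f$C_total,
                 tau = f$tau, tau_stderr = f$stderr[3], n = 1L))
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$sample, tab$C_total), ]
    rownames(tab) <- NULL
    structure(tab, class = c("transport_table", "data.frame"))
  })

  samples <- run_stage("report", {
    out <- lapply(names(lang), function(lab)
      list(fit = lang[[lab]], derived = derived_report(lang[[lab]], T = config$T)))
    names(out) <- names(lang)
    out
  })

  report <- structure(list(
    samples = samples, transport = transport, calibration = cal,
    config = config,
    bg_iterations = kin_iso$n_iter,
    provenance = list(package = "liposhg",
                      version = as.character(utils::packageVersion("liposhg")),
                      seed = config$seed,
                      mode = config$mode)),
    class = "shg_run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, config$out_dir)
  }
  report
}

#' @export
print.shg_run_report <- function(x, ...) {
  cat(sprintf("SHG pipeline report (%s mode, seed %d): alpha = %.4g counts/uM, B = %.4g counts\n",
              x$config$mode, x$provenance$seed, x$calibration$alpha,
              x$calibration$B))
  for (lab in names(x$samples)) print(x$samples[[lab]]$derived)
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (parameters, uncertainties, derived quantities,
#' transport table, calibration, provenance; no timestamps, so identical
#' runs give byte-identical files), `transport_table.csv`, and
#' `table1.csv` with one row per sample in the columns
#' sample, A, A_err, K, K_err, Nmax_uM, Nmax_err, lipid_per_site,
#' lipid_per_site_err, deltaG_kcal_mol, deltaG_err, T_K.
#'
#' @param report An `shg_run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(report$samples), function(lab) {
    s <- report$samples[[lab]]
    p <- s$fit$params; d <- s$derived
    data.frame(sample = lab, A = p$A, A_err = s$fit$stderr["A"],
               K = p$K, K_err = s$fit$stderr["K"],
               Nmax_uM = p$Nmax, Nmax_err = s$fit$stderr["Nmax"],
               lipid_per_site = d$lipids_per_site,
               lipid_per_site_err = d$lipids_per_site_sigma,
               deltaG_kcal_mol = d$delta_g, deltaG_err = d$delta_g_sigma,
               T_K = d$T)
  })
  tab1 <- do.call(rbind, rows)
  rownames(tab1) <- NULL
  utils::write.csv(tab1, file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$transport),
                   file.path(dir, "transport_table.csv"), row.names = FALSE)

  json <- list(
    calibration = report$calibration,
    samples = lapply(report$samples, function(s) list(
      params = unclass(s$fit$params),
      stderr = as.list(s$fit$stderr),
      cov = s$fit$cov,
      derived = list(delta_g = s$derived$delta_g,
                     delta_g_sigma = s$derived$delta_g_sigma,
                     lipids_per_site = s$derived$lipids_per_site,
                     lipids_per_site_sigma = s$derived$lipids_per_site_sigma,
                     signal_per_coverage = s$derived$signal_per_coverage,
                     signal_per_coverage_sigma = s$derived$signal_per_coverage_sigma,
                     T = s$derived$T))),
    transport = as.data.frame(report$transport),
    bg_iterations = report$bg_iterations,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare samples within a pipeline report
#'
#' Pairwise differences (second sample minus first) of K, Nmax and deltaG
#' with uncertainties combined in quadrature, and the per-concentration
#' transport-time differences; each difference is flagged when it exceeds
#' one combined standard deviation.
#'
#' @param report An `shg_run_report` containing >= 2 samples.
#' @return List of class `sample_comparison`: `params` (data.frame of
#'   quantity, diff, sigma, exceeds_1sigma per sample pair), `tau`
#'   (data.frame by concentration), `pair`.
#' @export
compare_samples <- function(report) {
  stopifnot(inherits(report, "shg_run_report"))
  labs <- names(report$samples)
  if (length(labs) < 2)
    stop("insufficient samples: need >= 2 samples to compare", call. = FALSE)
  a <- report$samples[[labs[1]]]; b <- report$samples[[labs[2]]]
  # differences below numerical resolution (1e-6 of the quantity's scale)
  # are never flagged, so exact-arithmetic ties do not trip the 1-sigma test
  one <- function(q, va, vb, sa, sb) {
    d <- vb - va; s <- sqrt(sa^2 + sb^2)
    thr <- max(s, 1e-6 * max(abs(va), abs(vb)), na.rm = TRUE)
    data.frame(quantity = q, diff = d, sigma = s,
               exceeds_1sigma = is.finite(thr) && abs(d) > thr)
  }
  params <- rbind(
    one("K", a$fit$params$K, b$fit$params$K,
        a$fit$stderr["K"], b$fit$stderr["K"]),
    one("Nmax", a$fit$params$Nmax, b$fit$params$Nmax,
        a$fit$stderr["Nmax"], b$fit$stderr["Nmax"]),
    one("delta_g", a$derived$delta_g, b$derived$delta_g,
        a$derived$delta_g_sigma, b$derived$delta_g_sigma))
  rownames(params) <- NULL

  tt <- as.data.frame(report$transport)
  ta <- tt[tt$sample == labs[1], ]; tb <- tt[tt$sample == labs[2], ]
  common <- intersect(ta$C_total, tb$C_total)
  tau <- do.call(rbind, lapply(common, function(C) {
    ra <- ta[ta$C_total == C, ][1, ]; rb <- tb[tb$C_total == C, ][1, ]
    d <- rb$tau - ra$tau; s <- sqrt(ra$tau_stderr^2 + rb$tau_stderr^2)
    thr <- max(s, 1e-6 * max(abs(ra$tau), abs(rb$tau)), na.rm = TRUE)
    data.frame(C_total = C, tau_diff = d, sigma = s,
               exceeds_1sigma = is.finite(thr) && abs(d) > thr)
  }))
  structure(list(pair = labs[1:2], params = params, tau = tau),
            class = "sample_comparison")
}

#' @export
print.sample_comparison <- function(x, ...) {
  cat(sprintf("Sample comparison: '%s' -> '%s'\n", x$pair[1], x$pair[2]))
  print(x$params)
  invisible(x)
}
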