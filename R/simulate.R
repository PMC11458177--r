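#' Substrate construct definition
#'
#' @param name construct identifier.
#' @param L total length in amino acids (> 0).
#' @param labeling_efficiency fraction of molecules carrying the fluorophore,
#'   in (0, 1]. Peak amplitudes scale with it because unlabeled substrate
#'   competes for motor binding without contributing signal.
#' @return an object of class `substrate_spec`.
#' @export
substrate_spec <- function(name, L, labeling_efficiency = 1) {
  check_scalar(L, "L", lower = 0, strict_lower = TRUE)
  check_scalar(labeling_efficiency, "labeling_efficiency",
               lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(name = as.character(name), L = L,
                 labeling_efficiency = labeling_efficiency),
            class = "substrate_spec")
}

#' Built-in RepA-Titin substrate registry
#'
#' The three RepA-Titin constructs: 70 unstructured RepA residues (the motor
#' binding site) followed by 1-3 tandem Titin I27 domains and a C-terminal
#' fluorophore, with total lengths 168, 265, and 362 aa. Labeling
#' efficiencies are representative of maleimide labeling (65-100%), with the
#' two-domain construct labeled best so that it shows the largest peak.
#'
#' @return named list of [substrate_spec] objects.
#' @export
repa_titin_registry <- function() {
  list(
    `RepA-Titin_1` = substrate_spec("RepA-Titin_1", 168, 0.70),
    `RepA-Titin_2` = substrate_spec("RepA-Titin_2", 265, 0.95),
    `RepA-Titin_3` = substrate_spec("RepA-Titin_3", 362, 0.80))
}

#' Reference kinetic conditions for ClpB on RepA-Titin substrates
#'
#' Default generating parameter sets for the three nucleotide regimes studied
#' with this assay, used as the "true" parameters of synthetic datasets:
#'
#' * `"atp_atpgs_1to1"` - 500 uM ATP : 500 uM ATPgS; k_U = 0.017 /s,
#'   m = 56.5 aa; terminal dissociation varies per substrate within
#'   0.01-0.15 /s; ATPgS pre-translocation 0.09 aa/s from a 48 aa excluded
#'   length.
#' * `"atp_atpgs_3to1"` - 500 uM ATP : 150 uM ATPgS; k_U = 0.055 /s,
#'   m = 58 aa; pre-translocation 0.05 aa/s from a 67 aa excluded length.
#' * `"atpgs_only"` - ATPgS as sole energy source; k_U = 0.0042 /s,
#'   m = 26 aa; slow terminal dissociation (0.002-0.01 /s); the fixed 71 aa
#'   offset reflects the pre-incubation before standard mixing.
#'
#' Each set also carries `k_end_kinematic`, a single terminal dissociation
#' rate constant (equal to the condition's `k_U`) used for multi-delay-time
#' kinematic designs: with a common `k_end = k_U` and a small product
#' amplitude, the peak time is exactly proportional to the number of steps,
#' so the length-vs-peak-time intercept reads off the pre-translocated
#' distance without bias (see the methods vignette). The per-substrate
#' `k_end` values span the observed dissociation range and are the defaults
#' for closure (parameter-recovery) datasets; they are assigned so that
#' every trace keeps the assay's lag/rise/decay shape and, together with the
#' labeling efficiencies, the two-domain construct shows the tallest peak,
#' as in the real assay.
#'
#' @param condition one of the names above.
#' @return list with `k_U`, `m`, per-substrate `k_end`, `k_end_kinematic`,
#'   amplitudes `F1`, `F2`, and the linear pre-translocation model
#'   (`excluded_length`, `v_gammaS`).
#' @export
clpb_conditions <- function(condition = c("atp_atpgs_1to1", "atp_atpgs_3to1",
                                          "atpgs_only")) {
  condition <- match.arg(condition)
  base <- list(F1 = 1, F2 = 0.05)
  cond <- switch(condition,
    atp_atpgs_1to1 = list(k_U = 0.017, m = 56.5,
                          k_end = c(`RepA-Titin_1` = 0.08,
                                    `RepA-Titin_2` = 0.01,
                                    `RepA-Titin_3` = 0.05),
                          k_end_kinematic = 0.017,
                          excluded_length = 48, v_gammaS = 0.09),
    atp_atpgs_3to1 = list(k_U = 0.055, m = 58,
                          k_end = c(`RepA-Titin_1` = 0.08,
                                    `RepA-Titin_2` = 0.01,
                                    `RepA-Titin_3` = 0.05),
                          k_end_kinematic = 0.055,
                          excluded_length = 67, v_gammaS = 0.05),
    atpgs_only = list(k_U = 0.0042, m = 26,
                      k_end = c(`RepA-Titin_1` = 0.008,
                                `RepA-Titin_2` = 0.005,
                                `RepA-Titin_3` = 0.002),
                      k_end_kinematic = 0.0042,
                      excluded_length = 71, v_gammaS = 0))
  c(cond, base, list(condition = condition))
}

#' Synthetic experiment design
#'
#' Everything needed to generate a deterministic synthetic single-turnover
#' dataset: substrates, delay times, the linear ATPgS pre-translocation model
#' `C(dt1) = excluded_length + v_gammaS * dt1`, the generating kinetic
#' parameters, and the noise model.
#'
#' @param substrates list of [substrate_spec]; default [repa_titin_registry()].
#' @param dt1 vector of delay times between the two mixing events (s).
#' @param condition optional name passed to [clpb_conditions()]; supplies
#'   defaults for every kinetic argument left `NULL`.
#' @param k_U,m global generating unfolding rate constant (1/s) and kinetic
#'   step-size (aa).
#' @param k_end terminal dissociation rate constant(s) (1/s); scalar or named
#'   per substrate.
#' @param F1,F2 generating fluorescence amplitudes.
#' @param excluded_length amino acids never translocated (aa).
#' @param v_gammaS ATPgS-driven pre-translocation rate (aa/s).
#' @param extent_of_binding fraction of substrate with motor bound (scales
#'   amplitudes; see [extent_of_binding()]).
#' @param F0 baseline raw fluorescence offset (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   noiseless peak amplitude of each trace.
#' @param drift optional slow linear baseline drift (units per s, default 0).
#' @param n_replicates replicates per (substrate, dt1).
#' @param seed integer seed; required whenever `noise_sd > 0`.
#' @param t_grid sampling grid (s).
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(substrates = repa_titin_registry(),
                              dt1 = 600,
                              condition = "atp_atpgs_1to1",
                              k_U = NULL, m = NULL, k_end = NULL,
                              F1 = NULL, F2 = NULL,
                              excluded_length = NULL, v_gammaS = NULL,
                              extent_of_binding = 1, F0 = 5,
                              noise_sd = 0.02, drift = 0,
                              n_replicates = 3L, seed = NULL,
                              t_grid = default_time_grid()) {
  cond <- clpb_conditions(condition)
  if (is.null(k_U)) k_U <- cond$k_U
  if (is.null(m)) m <- cond$m
  if (is.null(k_end)) k_end <- cond$k_end
  if (is.null(F1)) F1 <- cond$F1
  if (is.null(F2)) F2 <- cond$F2
  if (is.null(excluded_length)) excluded_length <- cond$excluded_length
  if (is.null(v_gammaS)) v_gammaS <- cond$v_gammaS
  check_scalar(k_U, "k_U", lower = 0, strict_lower = TRUE)
  check_scalar(m, "m", lower = 0, strict_lower = TRUE)
  check_scalar(excluded_length, "excluded_length", lower = 0)
  check_scalar(v_gammaS, "v_gammaS", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(extent_of_binding, "extent_of_binding", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (any(dt1 < 0)) stop_usage("dt1 must be nonnegative")
  if (!length(substrates) || !all(vapply(substrates, inherits, logical(1),
                                         "substrate_spec")))
    stop_usage("`substrates` must be a list of substrate_spec objects")
  names(substrates) <- vapply(substrates, `[[`, character(1), "name")
  if (length(k_end) == 1L && is.null(names(k_end)))
    k_end <- stats::setNames(rep(k_end, length(substrates)), names(substrates))
  if (!all(names(substrates) %in% names(k_end)))
    stop_usage("`k_end` must be named for every substrate")
  check_time_grid(t_grid)
  if (noise_sd > 0 && is.null(seed))
    stop_usage("a `seed` is required when noise_sd > 0 (reproducibility contract)")
  design <- structure(
    list(substrates = substrates, dt1 = as.numeric(dt1),
         k_U = k_U, m = m, k_end = k_end[names(substrates)],
         F1 = F1, F2 = F2,
         excluded_length = excluded_length, v_gammaS = v_gammaS,
         extent_of_binding = extent_of_binding, F0 = F0,
         noise_sd = noise_sd, drift = drift,
         n_replicates = as.integer(n_replicates),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         t_grid = t_grid, condition = condition),
    class = "experiment_design")
  # every delay time must leave translocatable length on every substrate
  Ls <- vapply(substrates, `[[`, numeric(1), "L")
  for (d in design$dt1) {
    C <- pretranslocation_distance(design, d)
    if (C >= min(Ls))
      stop_usage("C(dt1 = %g s) = %g aa reaches the shortest substrate (%g aa)",
                 d, C, min(Ls))
  }
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d substrate(s) x %d dt1 x %d replicate(s)\n",
              length(x$substrates), length(x$dt1), x$n_replicates))
  cat(sprintf("  k_U = %g /s, m = %g aa, C(dt1) = %g + %g * dt1 aa\n",
              x$k_U, x$m, x$excluded_length, x$v_gammaS))
  cat(sprintf("  noise_sd = %g, seed = %s\n", x$noise_sd, format(x$seed)))
  invisible(x)
}

#' Pre-translocated distance at a given delay time
#'
#' Linear model of slow ATPgS-driven pre-unfolding during the ageing period:
#' `C = excluded_length + v_gammaS * dt1` (aa).
#'
#' @param design an [experiment_design].
#' @param dt1 delay time (s); defaults to the design's first delay time.
#' @return C in amino acids.
#' @export
pretranslocation_distance <- function(design, dt1 = design$dt1[1]) {
  stopifnot(inherits(design, "experiment_design"))
  check_scalar(dt1, "dt1", lower = 0)
  design$excluded_length + design$v_gammaS * dt1
}

# deterministic per-trace RNG stream
trace_seed <- function(seed, substrate_idx, dt1_idx, replicate_index) {
  if (is.na(seed)) seed <- 0L
  as.integer((as.double(seed) + 97003 * replicate_index +
                641 * substrate_idx + 7919 * dt1_idx) %% 2147483647)
}

#' Simulate one raw stopped-flow trace
#'
#' Computes `n = (L - C(dt1)) / m`, evaluates the sequential-mechanism signal,
#' scales it by labeling efficiency and extent of binding, adds the baseline
#' offset `F0` (plus optional drift) and Gaussian noise with standard
#' deviation `noise_sd` times the noiseless peak amplitude. Deterministic
#' given `(seed, substrate, dt1, replicate_index)`.
#'
#' @param substrate a [substrate_spec] belonging to the design (matched by
#'   name for the per-substrate `k_end` and the noise stream).
#' @param design an [experiment_design].
#' @param replicate_index replicate number (1-based).
#' @param dt1 delay time (s); defaults to the design's first.
#' @return a raw [timecourse].
#' @export
simulate_timecourse <- function(substrate, design, replicate_index = 1L,
                                dt1 = design$dt1[1]) {
  stopifnot(inherits(substrate, "substrate_spec"),
            inherits(design, "experiment_design"))
  sub_idx <- match(substrate$name, names(design$substrates))
  if (is.na(sub_idx))
    stop_usage("substrate '%s' is not part of the design", substrate$name)
  dt1_idx <- match(dt1, design$dt1)
  if (is.na(dt1_idx)) dt1_idx <- 0L
  C <- pretranslocation_distance(design, dt1)
  n <- steps_from_length(substrate$L, C = C, m = design$m)
  pars <- scheme_params(design$k_U, design$k_end[[substrate$name]], n,
                        F1 = design$F1, F2 = design$F2)
  clean <- signal_model(pars, design$t_grid)$y
  amp <- substrate$labeling_efficiency * design$extent_of_binding
  y <- design$F0 + amp * clean + design$drift * design$t_grid
  if (design$noise_sd > 0) {
    peak_amp <- amp * max(clean)
    y <- y + with_preserved_rng({
      set.seed(trace_seed(design$seed, sub_idx, dt1_idx, replicate_index))
      stats::rnorm(length(y), sd = design$noise_sd * peak_amp)
    })
  }
  timecourse(design$t_grid, y, substrate = substrate$name, L = substrate$L,
             dt1 = dt1, replicate = as.integer(replicate_index),
             normalization = "raw")
}

#' Simulate a full synthetic dataset
#'
#' One raw trace per (substrate, dt1, replicate), plus a manifest recording
#' the complete generating truth for parameter-recovery studies. When `dir`
#' is given the traces are written as CSV files and the manifest as JSON, and
#' the manifest records the file names.
#'
#' @param design an [experiment_design].
#' @param dir optional output directory.
#' @return an object of class `st_dataset`: list with `traces` (list of
#'   [timecourse]) and `manifest`.
#' @export
simulate_dataset <- function(design, dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  traces <- list()
  files <- character()
  for (d_i in seq_along(design$dt1)) {
    for (s in design$substrates) {
      for (r in seq_len(design$n_replicates)) {
        tc <- simulate_timecourse(s, design, replicate_index = r,
                                  dt1 = design$dt1[d_i])
        key <- sprintf("%s_dt1-%g_rep%d", s$name, design$dt1[d_i], r)
        traces[[key]] <- tc
        if (!is.null(dir)) {
          if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
          f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "-", key), ".csv"))
          write_timecourse(tc, f)
          files[key] <- basename(f)
        }
      }
    }
  }
  manifest <- list(
    substrates = data.frame(
      name = names(design$substrates),
      L = vapply(design$substrates, `[[`, numeric(1), "L"),
      labeling_efficiency = vapply(design$substrates, `[[`, numeric(1),
                                   "labeling_efficiency"),
      row.names = NULL),
    dt1 = design$dt1,
    n_replicates = design$n_replicates,
    seed = design$seed,
    true_params = list(
      k_U = design$k_U, m = design$m,
      k_end = as.list(design$k_end),
      F1 = design$F1, F2 = design$F2,
      excluded_length = design$excluded_length, v_gammaS = design$v_gammaS,
      extent_of_binding = design$extent_of_binding, F0 = design$F0,
      noise_sd = design$noise_sd, drift = design$drift,
      condition = design$condition),
    files = if (length(files)) as.list(files) else NULL)
  ds <- structure(list(traces = traces, manifest = manifest),
                  class = "st_dataset")
  if (!is.null(dir))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ds
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("<st_dataset> %d trace(s); dt1 = {%s} s; seed = %s\n",
              length(x$traces), paste(x$manifest$dt1, collapse = ", "),
              format(x$manifest$seed)))
  invisible(x)
}

#' Read a synthetic dataset back from disk
#'
#' @param dir directory containing `manifest.json` and the trace CSVs.
#' @return an `st_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_usage("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(manifest$files)) stop_usage("manifest in %s lists no files", dir)
  traces <- lapply(manifest$files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop_usage("manifest names missing file: %s", path)
    read_timecourse(path)
  })
  names(traces) <- names(manifest$files)
  structure(list(traces = traces, manifest = manifest), class = "st_dataset")
}
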