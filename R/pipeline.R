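#' Signed percent deviation between a simulated and a reference value
#'
#' `deviation = (simulated - reference) / reference * 100`, with the
#' magnitude rounded to the nearest integer and an over/under label, the
#' format in which simulation-versus-experiment comparisons are usually
#' quoted.
#'
#' @param simulated,reference Scalars; `reference` must be nonzero.
#' @return A list of class `"crowd_deviation"`: `simulated`, `reference`,
#'   `signed_percent`, `magnitude` (nearest integer of the absolute
#'   deviation), `label` (`"overestimation"`, `"underestimation"`, or
#'   `"exact"`).
#' @examples
#' percent_deviation(0.31, 0.89)  # underestimation by 65%
#' @export
percent_deviation <- function(simulated, reference) {
  if (reference == 0) stop("reference must be nonzero")
  signed <- (simulated - reference) / reference * 100
  label <- if (signed > 0) "overestimation" else if (signed < 0)
    "underestimation" else "exact"
  structure(list(simulated = simulated, reference = reference,
                 signed_percent = signed,
                 magnitude = round(abs(signed)), label = label),
            class = "crowd_deviation")
}

#' @export
print.crowd_deviation <- function(x, ...) {
  cat(sprintf("%s by %d%% (simulated %.6g vs reference %.6g)\n",
              x$label, x$magnitude, x$simulated, x$reference))
  invisible(x)
}

#' Assemble a long-format concentration sweep table
#'
#' Combines per-concentration observable values into one long table with
#' one row per (concentration, observable): value, uncertainty, the
#' value normalized to the reference concentration, and the Enskog
#' hard-sphere reference ratio at the crowder volume fraction of each
#' concentration.
#'
#' @param runs A list; each element is a list with `concentration`
#'   (% w/v), `observables` (named numeric), `errors` (named numeric,
#'   same names), and optionally `phi` (volume fraction; derived from
#'   the concentration via [solvent_counts()] + [volume_fraction()] in
#'   the default box when absent).
#' @param reference Reference concentration for normalization; default
#'   the smallest concentration present.
#' @param box Box used when deriving `phi`, default 4 nm cubic.
#' @return A data.frame with columns `concentration`, `observable`,
#'   `value`, `error`, `normalized`, `enskog_ref`.
#' @export
concentration_sweep <- function(runs, reference = NULL,
                                box = crowdsolv::box(4)) {
  if (length(runs) == 0L) stop("empty run list")
  obs_names <- lapply(runs, function(r) sort(names(r$observables)))
  if (length(unique(obs_names)) != 1L) {
    all_names <- sort(unique(unlist(obs_names)))
    missing_by_run <- vapply(obs_names, function(nm) {
      paste(setdiff(all_names, nm), collapse = ",")
    }, character(1))
    stop("inconsistent observable sets across runs; missing per run: ",
         paste(sprintf("[%s]", missing_by_run), collapse = " "))
  }
  conc <- vapply(runs, function(r) r$concentration, numeric(1))
  if (is.null(reference)) reference <- min(conc)
  phi <- vapply(runs, function(r) {
    if (!is.null(r$phi)) r$phi else {
      volume_fraction(solvent_counts(r$concentration, box)$n_peg, box)
    }
  }, numeric(1))
  ens <- enskog_ratio(phi)
  rows <- list()
  for (nm in obs_names[[1]]) {
    vals <- vapply(runs, function(r) r$observables[[nm]], numeric(1))
    errs <- vapply(runs, function(r) {
      if (!is.null(r$errors) && nm %in% names(r$errors))
        r$errors[[nm]] else NA_real_
    }, numeric(1))
    norm <- normalize_series(conc, vals, reference)
    rows[[nm]] <- data.frame(concentration = conc, observable = nm,
                             value = vals, error = errs,
                             normalized = norm, enskog_ref = ens)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$concentration, out$observable), , drop = FALSE]
}

#' End-to-end synthetic diffusion sweep
#'
#' Generates Brownian trajectories whose target diffusion constants
#' follow the Enskog hard-sphere decline of the crowder volume fraction
#' at each concentration, estimates the diffusion constant of each from
#' its MSD, attaches five-block errors, and assembles the long-format
#' sweep table. The synthetic ground truth thus reproduces a purely
#' excluded-volume crowding scenario against which the analysis chain is
#' validated end to end.
#'
#' @param concentrations Concentration grid (% w/v).
#' @param D0 Dilute-limit diffusion constant (1e-5 cm^2/s), default 2.3.
#' @param n_particles,n_steps Trajectory size per concentration.
#' @param seed Base RNG seed; concentration `i` uses `seed + i`.
#' @param box Composition box for the volume fraction, default 4 nm
#'   cubic.
#' @param n_blocks Blocks for the per-concentration error, default 5.
#' @return The [concentration_sweep()] table, with attribute `targets`
#'   (the generator ground truth).
#' @export
run_diffusion_sweep <- function(concentrations, D0 = 2.3,
                                n_particles = 200L, n_steps = 400L,
                                seed = 1L, box = crowdsolv::box(4),
                                n_blocks = 5L) {
  runs <- list()
  targets <- numeric(length(concentrations))
  for (i in seq_along(concentrations)) {
    cc <- concentrations[i]
    phi <- volume_fraction(solvent_counts(cc, box)$n_peg, box)
    D_true <- D0 * enskog_ratio(phi)
    targets[i] <- D_true
    gen <- brownian_trajectory(n_particles, n_steps, D_true,
                               box = crowdsolv::box(50), seed = seed + i)
    ms <- msd(gen$unwrapped)
    est <- diffusion_pbc(ms)
    # block error: independent D estimates from contiguous time blocks
    nf <- n_frames(gen$unwrapped)
    bs <- floor(nf / n_blocks)
    # short blocks keep few integer lags: widen the fit window so at
    # least 5 lag points remain (the Brownian generator has no ballistic
    # short-time regime, so including short lags is unbiased)
    block_D <- vapply(seq_len(n_blocks), function(b) {
      idx <- ((b - 1L) * bs + 1L):(b * bs)
      sub <- trajectory(gen$unwrapped$coords[idx, , , drop = FALSE],
                        gen$unwrapped$times[idx],
                        gen$unwrapped$boxes[idx, , drop = FALSE])
      diffusion_pbc(msd(sub), fit_window = c(0, 0.6))$D_pbc
    }, numeric(1))
    runs[[i]] <- list(concentration = cc, phi = phi,
                      observables = c(D_pbc = est$D_pbc),
                      errors = c(D_pbc = stats::sd(block_D)))
  }
  out <- concentration_sweep(runs, reference = min(concentrations), box = box)
  attr(out, "targets") <- targets
  out
}

#' Write a data frame as a byte-reproducible CSV
#'
#' Numeric columns are formatted to 6 significant digits so repeated runs
#' with the same seed emit byte-identical files.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_csv_reproducible <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], digits = 6, format = "g"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Machine-readable run report
#'
#' Collects analysis outputs into a versioned JSON-compatible list and
#' optionally writes it to disk.
#'
#' @param results Named list of analysis outputs (coerced with
#'   `unclass`).
#' @param seed RNG seed echoed into the report.
#' @param path Optional output path for the JSON file.
#' @return The report list, invisibly when written.
#' @export
report <- function(results, seed = NA_integer_, path = NULL) {
  if (length(results) == 0L) stop("at least one completed analysis required")
  rep_ <- list(schema_version = "1.0",
               package_version = as.character(utils::packageVersion("crowdsolv")),
               seed = seed,
               results = lapply(results, function(x) {
                 if (is.data.frame(x)) x else unclass(x)
               }))
  if (!is.null(path)) {
    jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(rep_))
  }
  rep_
}
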