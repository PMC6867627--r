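#' Write a motility fingerprint to JSON
#'
#' Serializes the population estimates as
#' `{parameter: {value, error_low, error_high, n}}` with 9 significant
#' digits, so repeated runs on identical input produce byte-identical
#' files. For `v_run`, `p_run` and `q` the error bounds are value +/- one
#' standard error; for the lifetimes they are the 99% confidence interval.
#'
#' @param fp A [fingerprint()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_json <- function(fp, path) {
  stopifnot(inherits(fp, "motility_fingerprint"))
  e <- fp$estimates
  entry_se <- function(x) list(value = x$value,
                               error_low = x$value - x$se,
                               error_high = x$value + x$se, n = x$n)
  entry_ci <- function(x) list(value = x$value,
                               error_low = unname(x$ci[1L]),
                               error_high = unname(x$ci[2L]),
                               n = if (is.null(x$n)) NA else x$n)
  out <- list(v_run = entry_se(e$v_run),
              tau_run = entry_ci(e$tau_run),
              tau_rest = entry_ci(e$tau_rest),
              p_run = entry_se(e$p_run),
              q = entry_se(e$q),
              immobile_fraction = list(value = e$immobile_fraction$value,
                                       n = e$immobile_fraction$n),
              n_cells = fp$n_cells)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(9),
                       na = "null")
  invisible(path)
}

#' Spider-plot table: fingerprints normalized to a reference condition
#'
#' Divides every condition's five parameters by the reference condition's
#' values, the normalization used to overlay conditions on one radar
#' chart.
#'
#' @param fingerprints Named list of [fingerprint()] objects.
#' @param reference Name of the reference condition (default: first).
#' @return Data frame with one row per condition x parameter: `condition`,
#'   `parameter`, `value`, `relative` (value / reference value).
#' @export
spider_data <- function(fingerprints, reference = names(fingerprints)[1L]) {
  stopifnot(length(fingerprints) >= 1L, !is.null(names(fingerprints)),
            reference %in% names(fingerprints))
  params <- c("v_run", "tau_run", "tau_rest", "p_run", "q")
  val <- function(fp, p) fp$estimates[[p]]$value
  ref <- fingerprints[[reference]]
  rows <- lapply(names(fingerprints), function(cond) {
    fp <- fingerprints[[cond]]
    data.frame(condition = cond, parameter = params,
               value = vapply(params, val, numeric(1), fp = fp),
               relative = vapply(params, val, numeric(1), fp = fp) /
                 vapply(params, val, numeric(1), fp = ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an analysis configuration from YAML
#'
#' Recognized top-level blocks: `geometry` (center_x, center_y, radius),
#' `segmentation` (arguments of [segmentation_params()]), `simulation`
#' (arguments of [simulation_params()]), `fit` (`fit_range`,
#' `censor_horizon`, `conf_level`). Missing blocks fall back to package
#' defaults.
#'
#' @param path YAML file path.
#' @return List with `geometry`, `segmentation`, `simulation` (or `NULL`),
#'   `fit`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geometry <- do.call(ring_geometry, as.list(cfg$geometry))
  segmentation <- do.call(segmentation_params, as.list(cfg$segmentation))
  simulation <- if (is.null(cfg$simulation)) NULL else
    do.call(simulation_params, as.list(cfg$simulation))
  fit <- list(fit_range = c(2, 16), censor_horizon = 16, conf_level = 0.99)
  fit[names(cfg$fit)] <- cfg$fit
  if (!is.null(cfg$fit$fit_range)) fit$fit_range <- unlist(cfg$fit$fit_range)
  if (fit$fit_range[1L] < 0 || fit$fit_range[2L] > fit$censor_horizon) {
    stop("fit_range must lie within [0, censor_horizon]")
  }
  list(geometry = geometry, segmentation = segmentation,
       simulation = simulation, fit = fit)
}
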