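## File formats: ATSAS-style SAXS .dat, ITC CSV with metadata block,
## JSON fit reports, and the run configuration container.

#' Read a SAXS curve from a .dat file
#'
#' Whitespace-separated `q I [sigma]` columns with `#` comment lines
#' (ATSAS-compatible), q in A^-1. A missing sigma column is synthesized as
#' 1% of I with a warning.
#'
#' @param path input file.
#' @return A [scattering_profile()]; `#` comments are kept in attribute
#'   `comments`.
#' @export
read_saxs_dat <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(trimws(lines), "#")]
  data_lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rows <- strsplit(trimws(data_lines), "\\s+")
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L)))
    stop_domain("expected 2 or 3 whitespace-separated columns in ", path)
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncol)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2L, any))[1L]
    stop_domain("non-numeric row at data line ", bad, " of ", path)
  }
  vals <- t(vals)
  if (any(diff(vals[, 1L]) <= 0))
    stop_domain("q must be strictly increasing in ", path)
  sigma <- if (ncol == 3L) vals[, 3L] else {
    warning("no sigma column in ", path, "; synthesizing 1% of I",
            call. = FALSE)
    NULL
  }
  prof <- scattering_profile(vals[, 1L], vals[, 2L], sigma)
  attr(prof, "comments") <- comments
  prof
}

#' Write a SAXS curve to a .dat file
#'
#' @param profile a [scattering_profile()].
#' @param path output file.
#' @param header optional comment text (written as `#` lines).
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(profile, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  lines <- c(lines, sprintf("%.17g %.17g %.17g",
                            profile$q, profile$I, profile$sigma))
  writeLines(lines, path)
  invisible(path)
}

.ITC_META_REQUIRED <- c("cell_volume_uL", "cell_conc_M", "syringe_conc_M",
                        "temperature_C")

#' Read an ITC CSV file
#'
#' Format: `#key=value` metadata lines (requiring `cell_volume_uL`,
#' `cell_conc_M`, `syringe_conc_M`, `temperature_C`) followed by a header
#' row `injection,volume_uL,ndh_kcal_per_mol[,sigma]` and one row per
#' injection.
#'
#' @param path input file.
#' @return A `titration_experiment`.
#' @export
read_itc_csv <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  kv <- kv[lengths(kv) == 2L]
  meta <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                          vapply(kv, function(x) trimws(x[[1L]]), character(1)))
  missing <- setdiff(.ITC_META_REQUIRED, names(meta))
  if (length(missing) > 0L)
    stop_domain("missing metadata key(s): ", paste(missing, collapse = ", "))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("injection", "volume_uL", "ndh_kcal_per_mol")
  if (!all(need %in% names(df)))
    stop_domain("ITC CSV must have columns ", paste(need, collapse = ", "))
  protocol <- titration_protocol(
    cell_volume = as.numeric(meta[["cell_volume_uL"]]),
    cell_conc = as.numeric(meta[["cell_conc_M"]]),
    syringe_conc = as.numeric(meta[["syringe_conc_M"]]),
    injection_volumes = df$volume_uL)
  ## rebuild the deterministic molar-ratio axis from the protocol
  m <- itc_model_ndh(binding_parameters(0, 0, 0), protocol)
  sigma <- if ("sigma" %in% names(df)) df$sigma else
    rep(NA_real_, nrow(df))
  structure(list(protocol = protocol,
                 ndh = df$ndh_kcal_per_mol,
                 sigma = sigma,
                 molar_ratio = m$molar_ratio,
                 complex = NULL,
                 seed = if ("seed" %in% names(meta))
                   as.integer(meta[["seed"]]) else NA_integer_,
                 perfusion = "simple",
                 temperature_C = as.numeric(meta[["temperature_C"]]),
                 meta = as.list(meta)),
            class = "titration_experiment")
}

#' Write a titration experiment to ITC CSV
#'
#' @param exp a `titration_experiment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(exp, path) {
  p <- exp$protocol
  meta <- c(sprintf("#cell_volume_uL=%.17g", p$cell_volume),
            sprintf("#cell_conc_M=%.17g", p$cell_conc),
            sprintf("#syringe_conc_M=%.17g", p$syringe_conc),
            "#temperature_C=25",
            sprintf("#seed=%d", as.integer(exp$seed %||% NA_integer_)),
            sprintf("#generator=tabiophys %s", package_version_string()))
  has_sigma <- !is.null(exp$sigma) && !anyNA(exp$sigma)
  hdr <- paste0("injection,volume_uL,ndh_kcal_per_mol",
                if (has_sigma) ",sigma" else "")
  rows <- sprintf("%d,%.17g,%.17g%s", seq_along(exp$ndh),
                  p$injection_volumes, exp$ndh,
                  if (has_sigma) sprintf(",%.17g", exp$sigma) else "")
  writeLines(c(meta, hdr, rows), path)
  invisible(path)
}

#' Write an ITC fit report as JSON
#'
#' @param fit an `itc_fit`.
#' @param path output JSON path.
#' @param extra optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, extra = NULL) {
  report <- list(
    K_A = fit$K_A, log10_K_A = fit$log10_K_A,
    dG_kcal_mol = fit$dG_kcal_mol,
    dH = fit$dH, offset = fit$offset,
    se_log10_K_A = fit$se_log10_K_A, se_dH = fit$se_dH,
    se_offset = fit$se_offset,
    converged = fit$converged, k_lower_bound = fit$k_lower_bound,
    n_injections = fit$n_injections,
    residual_rms = fit$residual_rms,
    tool_version = package_version_string())
  if (!is.null(extra)) report <- c(report, extra)
  report$config_hash <- config_hash(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.RUN_CONFIG_KEYS <- c("seed", "root_tol", "optimizer_tol", "chi2_bound",
                      "qrg_limit", "smooth_window", "max_states",
                      "enumeration_bound", "beam_width", "log_level")

#' Run configuration
#'
#' Validated key-value configuration shared by the command-line tools.
#' Unknown keys are rejected with an error naming the key; the config (and
#' its hash) is echoed into output metadata so any result can be traced to
#' its inputs.
#'
#' @param ... named configuration values; see
#'   `tabiophys:::.RUN_CONFIG_KEYS` for the accepted names.
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  vals <- list(...)
  if (length(vals) > 0L && (is.null(names(vals)) || any(names(vals) == "")))
    stop_domain("all configuration values must be named")
  unknown <- setdiff(names(vals), .RUN_CONFIG_KEYS)
  if (length(unknown) > 0L)
    stop_domain("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, root_tol = 1e-12, optimizer_tol = 1e-12,
                   chi2_bound = NA_real_, qrg_limit = 1.3,
                   smooth_window = 7L, max_states = 4L,
                   enumeration_bound = 25000, beam_width = 100L,
                   log_level = "info")
  cfg <- utils::modifyList(defaults, vals)
  cfg$hash <- config_hash(cfg[.RUN_CONFIG_KEYS[.RUN_CONFIG_KEYS %in% names(cfg)]])
  structure(cfg, class = "run_config")
}
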