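# Shared configuration parsing, provenance-stamped writers and the command
# line entry point (a thin layer over the package functions; see
# inst/exec/whiskerbeam).

.config_keys <- list(
  geometry = c("L", "R", "trunc", "rho", "E", "alpha",
               "length_unit", "radius_unit"),
  contact = c("c_frac", "c_pos"),
  force = c("kind", "F_max", "t_f", "tau", "C", "s"),
  solver = c("n_modes", "n_free", "dt", "t_max", "seed"),
  output = c("dir", "formats"))

.len_units <- c(m = 1, mm = 1e-3, um = 1e-6)

#' Read and validate a run configuration
#'
#' YAML file with blocks \code{geometry}, \code{contact}, \code{force},
#' \code{solver}, \code{output}. Unknown blocks or keys are rejected.
#' Geometry lengths may be given in \code{m}, \code{mm} or \code{um} via
#' \code{length_unit} (applies to \code{L}, \code{trunc}) and
#' \code{radius_unit} (applies to \code{R}); all values are converted to SI
#' on load. Defaults are recorded so they can be emitted in provenance
#' headers.
#'
#' @param path YAML file path.
#' @return list with \code{geom} (a [whisker_geometry()]), \code{c_frac},
#'   \code{profile} (a [force_profile()]), \code{solver}, \code{output} and
#'   \code{raw} (the resolved key-value list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(.config_keys))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(cfg)) {
    extra <- setdiff(names(cfg[[blk]]), .config_keys[[blk]])
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s': %s", blk,
                   paste(extra, collapse = ", ")))
  }
  g <- cfg$geometry
  if (is.null(g)) stop("config requires a 'geometry' block")
  lu <- .len_units[[g$length_unit %||% "m"]]
  ru <- .len_units[[g$radius_unit %||% "m"]]
  if (is.null(lu) || is.null(ru)) stop("units must be one of m, mm, um")
  # YAML 1.1 reads exponent forms like 3.0e9 as strings; coerce numerics
  num <- function(x, default = NULL) {
    if (is.null(x)) return(default)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("non-numeric config value: ", x)
    v
  }
  geom <- whisker_geometry(L = num(g$L) * lu, R = num(g$R) * ru,
                           trunc = num(g$trunc, 0) * lu,
                           rho = num(g$rho, 1000), E = num(g$E),
                           alpha = num(g$alpha, 0))
  cf <- NULL
  if (!is.null(cfg$contact)) {
    cf <- if (!is.null(cfg$contact$c_frac)) num(cfg$contact$c_frac)
          else num(cfg$contact$c_pos) * lu / geom$L
    contact_position(geom, c_frac = cf)
  }
  f <- cfg$force %||% list()
  profile <- if (identical(f$kind, "ramp")) {
    force_profile("ramp", s = num(f$s, 1e-4))
  } else {
    force_profile("gaussian_smooth", F_max = num(f$F_max, 1e-6),
                  t_f = num(f$t_f, 10e-3), tau = num(f$tau, 0.1e-3),
                  C = num(f$C, 0.5))
  }
  sv <- cfg$solver %||% list()
  solver <- list(n_modes = as.integer(num(sv$n_modes, 60)),
                 n_free = if (!is.null(sv$n_free))
                   as.integer(num(sv$n_free)),
                 dt = num(sv$dt, 1e-5), t_max = num(sv$t_max, NA),
                 seed = as.integer(num(sv$seed, 1)))
  if (is.na(solver$t_max)) solver$t_max <- NULL
  output <- utils::modifyList(list(dir = ".", formats = "csv"),
                              cfg$output %||% list())
  list(geom = geom, c_frac = cf, profile = profile, solver = solver,
       output = output,
       raw = list(geometry = g, contact = cfg$contact, force = f,
                  solver = solver, output = output))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic provenance header lines ('#'-prefixed); no timestamps so
# identical configs give byte-identical outputs
provenance_header <- function(info) {
  ver <- as.character(utils::packageVersion("whiskerbeam"))
  lines <- c(sprintf("# whiskerbeam %s", ver))
  flat <- unlist(info, use.names = TRUE)
  if (length(flat))
    lines <- c(lines, sprintf("# %s: %s", names(flat), as.character(flat)))
  lines
}

# hash of the resolved configuration (md5 of its canonical JSON)
config_hash <- function(raw) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(raw, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a data frame as CSV with a provenance header
#'
#' Comma separated, '.' decimal, preceded by '#'-prefixed comment lines
#' recording the package version and the run metadata (config hash, seed,
#' tolerances) — deterministic, so identical runs give identical bytes.
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list folded into the header.
#' @return the path, invisibly.
#' @export
write_series_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(meta), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' Export an eigenmode spectrum
#'
#' JSON records \code{{case, l_frac, c_frac, j, beta, omega}} or the same as
#' CSV, consumed by downstream dynamics/cue tooling.
#'
#' @param basis a [eigenmode_basis()] result.
#' @param path output path; format from extension (.json or .csv).
#' @param meta extra provenance fields (CSV only).
#' @return the path, invisibly.
#' @export
export_spectrum <- function(basis, path, meta = list()) {
  stopifnot(inherits(basis, "whisker_modes"))
  df <- data.frame(case = basis$case,
                   l_frac = basis$shape$l_frac,
                   c_frac = basis$shape$c_frac %||% NA_real_,
                   j = seq_along(basis$beta),
                   beta = basis$beta, omega = basis$omega)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_series_csv(df, path, meta)
  }
  invisible(path)
}

cli_args <- function(argv) {
  # --key value pairs after the subcommand
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    k <- argv[i]
    if (!startsWith(k, "--")) stop("unexpected argument: ", k)
    out[[substring(k, 3)]] <- if (i < length(argv) &&
                                  !startsWith(argv[i + 1L], "--")) {
      i <- i + 1L
      argv[i]
    } else TRUE
    i <- i + 1L
  }
  out
}

#' Command line entry point
#'
#' Subcommands: \code{eigen} (dimensionless spectrum for a boundary case),
#' \code{simulate} (touch simulation from a YAML config; writes follicle and
#' displacement CSVs), \code{sweep} (frequency / truncation / excitation /
#' ratio / rate sweeps), \code{fit} (damped-oscillation fit of a trace CSV,
#' written as JSON) and \code{fixtures} (synthetic trace generation). Every
#' output carries a provenance header with the config hash and seed. Invoked
#' by the \code{inst/exec/whiskerbeam} script; returns an exit status rather
#' than quitting, so it can be driven programmatically.
#'
#' @param argv character vector of command line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @examples
#' \donttest{
#' out <- tempfile(fileext = ".csv")
#' run_cli(c("eigen", "--case", "free-full", "--modes", "3", "--out", out))
#' }
#' @export
run_cli <- function(argv) {
  usage <- "usage: whiskerbeam <eigen|simulate|sweep|fit|fixtures> [--options]"
  status <- tryCatch({
    if (!length(argv)) stop(usage)
    cmd <- argv[1]
    a <- cli_args(argv[-1])
    switch(cmd,
      eigen = cli_eigen(a),
      simulate = cli_simulate(a),
      sweep = cli_sweep(a),
      fit = cli_fit(a),
      fixtures = cli_fixtures(a),
      stop(usage))
    0L
  }, error = function(e) {
    message("whiskerbeam error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_eigen <- function(a) {
  case <- gsub("-", "_", a$case %||% "free_full")
  n <- as.integer(a$modes %||% 10)
  shape <- list(l_frac = as.numeric(a$`l-frac` %||% 0),
                c_frac = if (!is.null(a$`c-frac`)) as.numeric(a$`c-frac`))
  betas <- find_eigenvalues(case, shape, n)
  df <- data.frame(case = case, l_frac = shape$l_frac,
                   c_frac = shape$c_frac %||% NA_real_,
                   j = seq_along(betas), beta = betas)
  out <- a$out %||% ""
  if (nzchar(out)) {
    if (grepl("\\.json$", out))
      jsonlite::write_json(df, out, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    else write_series_csv(df, out, list(command = "eigen", modes = n))
    message("wrote ", out)
  } else {
    print(df)
  }
}

cli_simulate <- function(a) {
  cfg <- read_run_config(a$config %||% stop("simulate requires --config"))
  if (is.null(cfg$c_frac)) stop("config needs a contact block")
  sv <- cfg$solver
  sim <- simulate_touch(cfg$geom, c_frac = cfg$c_frac, profile = cfg$profile,
                        n_modes = sv$n_modes,
                        n_free = sv$n_free %||% sv$n_modes,
                        dt = sv$dt, t_max = sv$t_max)
  meta <- list(command = "simulate", config_hash = config_hash(cfg$raw),
               seed = sv$seed, detach_residual = sim$detach$residual)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  write_series_csv(follicle_signal(sim),
                   file.path(cfg$output$dir, "follicle_signal.csv"), meta)
  write_series_csv(as.data.frame(displacement_field(sim)),
                   file.path(cfg$output$dir, "displacement_field.csv"), meta)
  message("wrote follicle_signal.csv and displacement_field.csv in ",
          cfg$output$dir)
}

cli_sweep <- function(a) {
  cfg <- read_run_config(a$config %||% stop("sweep requires --config"))
  type <- a$type %||% "frequency"
  grid <- if (!is.null(a$grid))
    as.numeric(strsplit(a$grid, ",")[[1]]) else NULL
  res <- switch(type,
    frequency = frequency_sweep(cfg$geom,
      grid %||% seq(cfg$geom$trunc / cfg$geom$L + 0.05, 0.95, by = 0.05),
      n_modes = as.integer(a$modes %||% 5)),
    truncation = truncation_sweep(grid %||% seq(0, 0.25, by = 0.05),
      c_frac = cfg$c_frac %||% 0.6, n_modes = as.integer(a$modes %||% 5)),
    excitation = excitation_spectrum(cfg$geom, c_frac = cfg$c_frac %||% 0.6,
      profile = cfg$profile, n_modes = as.integer(a$modes %||% 16)),
    ratio = ratio_analysis(cfg$geom, cfg$profile,
      grid %||% c(0.1, 0.3, 0.5, 0.7, 0.9),
      n_modes = as.integer(a$modes %||% cfg$solver$n_modes)),
    rate = rate_of_change_comparison(cfg$geom,
      grid %||% seq(cfg$geom$trunc / cfg$geom$L + 0.05, 0.95, by = 0.02)),
    stop("unknown sweep type: ", type))
  out <- a$out %||% paste0("sweep_", type, ".csv")
  write_series_csv(res, out,
                   list(command = "sweep", type = type,
                        config_hash = config_hash(cfg$raw)))
  message("wrote ", out)
}

cli_fit <- function(a) {
  tr <- read_vibration_trace(a$trace %||% stop("fit requires --trace"))
  f <- fit_damped_oscillation(tr)
  out <- a$out %||% "fit.json"
  jsonlite::write_json(
    list(coefficients = as.list(coef(f)),
         ci = list(lower = as.list(f$ci[, "lower"]),
                   upper = as.list(f$ci[, "upper"])),
         rss = f$rss, f_hz = coef(f)[["omega"]] / (2 * pi)),
    out, auto_unbox = TRUE, digits = NA)
  message("wrote ", out)
}

cli_fixtures <- function(a) {
  seed <- as.integer(a$seed %||% 1)
  tr <- synth_vibration_trace(noise_sd = as.numeric(a$`noise-sd` %||% 0.05),
                              seed = seed)
  out <- a$out %||% sprintf("trace_seed%d.csv", seed)
  write_vibration_trace(tr, out)
  message("wrote ", out)
}
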