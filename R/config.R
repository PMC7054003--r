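# Configuration, output and manifest glue for the command-line interface.
#
# Configs are YAML with a flat block structure; angles are degrees in the
# file and converted at the motor_params/load_force boundary. All defaults
# equal the wild-type parameter set used throughout the package.

#' Default configuration
#'
#' @return nested list with blocks \code{motor}, \code{rates},
#'   \code{force}, \code{lattice} and per-command blocks.
#' @export
default_config <- function() {
  list(
    # L and dV are NA by default, meaning "use the mutant preset"
    motor = list(mutant = "6IQ", L = NA, lp = 350, theta_c = 65,
                 nu_c = 261, theta_p = 83, mu_c = 5, a = 0.4, b = 0.045,
                 dphi_ac = 55.6, Dh = 5.7e4, dV = NA, kBT = 4.1),
    rates = list(td1 = 1000 / 12, td2 = 1000 / 1.5, th = 1000 / 750),
    force = list(F = 0, theta_F = 0, phi_F = 0),
    lattice = list(R = 5.5, dz = 72 / 13, n_max = 39),
    steps = list(mode = "forward-only", sigma = 1, bin_width = 5),
    contours = list(spacing = 2, plane = "z-x"),
    force_scan = list(from = 0, to = 2.5, by = 0.1),
    offaxis = list(F = 1, theta_from = 0, theta_to = 40, theta_by = 5,
                   phi_from = -90, phi_to = 90, phi_by = 30),
    constraint_scan = list(mu_from = 0, mu_to = 10, mu_by = 1,
                           theta_p = 83),
    runs = list(n_runs = 100, seed = 1, force_rule = "constant",
                trap_stiffness = 0.02, trap_offaxis_y = 50),
    bd = list(n_traj = 50, seed = 1, dt = 0.1, max_time = 2,
              detached = "trailing", coverslip = FALSE),
    fit = list(free_params = c("theta_c", "dphi_ac", "theta_p"),
               datasets = list(), n_restarts = 5, seed = 1)
  )
}

check_config_block <- function(user, def, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(def))
      stop(sprintf("unknown configuration key: %s%s", path, nm))
    if (is.list(def[[nm]]) && !is.null(user[[nm]]) && is.list(user[[nm]]) &&
        nm != "datasets")
      check_config_block(user[[nm]], def[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

merge_config <- function(user, def) {
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && is.list(user[[nm]]) && nm != "datasets")
      def[[nm]] <- merge_config(user[[nm]], def[[nm]])
    else def[[nm]] <- user[[nm]]
  }
  def
}

validate_config <- function(cfg) {
  m <- cfg$motor
  if (!is.null(m$lp) && m$lp <= 0) stop("invalid config: lp must be positive")
  if (!is.null(m$b) && (m$b <= 0 || m$b > 1))
    stop("invalid config: binding penalty b must be in (0, 1]")
  if (!is.null(m$dphi_ac) && (m$dphi_ac < 0 || m$dphi_ac > 180))
    stop("invalid config: dphi_ac must be in [0, 180] degrees")
  if (cfg$force$F < 0) stop("invalid config: force magnitude must be >= 0")
  if (cfg$lattice$n_max < 26) stop("invalid config: n_max must be >= 26")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, fills all unset values
#' with the wild-type defaults, and validates ranges. An empty file yields
#' the full default configuration.
#'
#' @param path YAML file path.
#' @return validated config list (class \code{myov_config}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  def <- default_config()
  check_config_block(user, def)
  cfg <- merge_config(user, def)
  validate_config(cfg)
  structure(cfg, class = c("myov_config", "list"))
}

#' @rdname load_config
#' @param cfg config list.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

config_objects <- function(cfg) {
  m <- cfg$motor
  unset <- function(x) if (is.null(x) || length(x) != 1 || is.na(x)) NULL else x
  params <- motor_params(L = unset(m$L), lp = m$lp, theta_c = m$theta_c,
                         nu_c = m$nu_c, theta_p = m$theta_p, mu_c = m$mu_c,
                         a = m$a, b = m$b, dphi_ac = m$dphi_ac, Dh = m$Dh,
                         dV = unset(m$dV), kBT = m$kBT, mutant = m$mutant)
  list(params = params,
       rates = kinetic_rates(cfg$rates$td1, cfg$rates$td2, cfg$rates$th),
       force = load_force(cfg$force$F, cfg$force$theta_F, cfg$force$phi_F),
       lattice = actin_lattice(cfg$lattice$R, cfg$lattice$dz,
                               cfg$lattice$n_max))
}

write_csv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

write_matrix_text <- function(mat, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")), con)
  utils::write.table(as.data.frame(mat), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Run a named analysis command from a configuration
#'
#' Executes one of the packaged analyses and writes its tabular outputs
#' plus a JSON manifest (effective configuration, derived quantities, seed,
#' package version, output checksums). Rerunning with the configuration
#' stored in a manifest reproduces stochastic outputs exactly.
#'
#' @param subcommand one of \code{"steps"}, \code{"contours"},
#'   \code{"force-scan"}, \code{"offaxis"}, \code{"constraint-scan"},
#'   \code{"runs"}, \code{"bd"}.
#' @param cfg configuration (see \code{\link{load_config}}).
#' @param out_dir output directory.
#' @param overwrite allow writing into existing output files.
#' @return invisible list of written file paths.
#' @export
run_command <- function(subcommand, cfg = default_config(),
                        out_dir = ".", overwrite = FALSE) {
  ob <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, gsub("-", "_", subcommand))
  files <- character(0)
  ensure <- function(path) {
    if (file.exists(path) && !overwrite)
      stop("output exists (use overwrite = TRUE): ", path)
    path
  }
  ec <- effective_constraint(ob$params, ob$force)
  meta <- list(command = subcommand, mutant = ob$params$mutant,
               F_pN = ob$force$F, theta_F = ob$force$theta_F,
               phi_F = ob$force$phi_F,
               T_eff = sprintf("%.4f", ec$T_eff),
               bFL = sprintf("%.4f", ec$bFL),
               g = sprintf("%.4f", ob$rates$g))

  if (subcommand == "steps") {
    kin <- myov_kinetics(ob$params, ob$force, ob$rates, ob$lattice)
    dist <- step_distribution(kin$pp, ob$lattice, cfg$steps$mode)
    hb <- measurement_convolve(dist, cfg$steps$sigma, cfg$steps$bin_width)
    f <- ensure(paste0(stem, ".csv"))
    write_csv_with_header(hb, f, meta)
    files <- f
  } else if (subcommand == "contours") {
    g <- free_head_density(ob$params, ob$force,
                           spacing = cfg$contours$spacing)
    pr <- project_density(g, cfg$contours$plane)
    f <- ensure(paste0(stem, ".txt"))
    write_matrix_text(pr$values, f,
                      c(meta, list(plane = cfg$contours$plane,
                                   u_axis = range(pr$u), v_axis = range(pr$v),
                                   spacing = cfg$contours$spacing)))
    files <- f
  } else if (subcommand == "force-scan") {
    fs <- seq(cfg$force_scan$from, cfg$force_scan$to, by = cfg$force_scan$by)
    rows <- lapply(fs, function(F) {
      r <- run_at_force(ob$params, load_force(F), ob$rates, ob$lattice)
      data.frame(F = F, z_run = r$rs$z_run, t_run = r$rs$t_run,
                 v_run = r$rs$v_run, step_ratio = r$rs$step_ratio,
                 Pt = r$rs$Pt, tT = r$kin$bt$tT, tL = r$kin$bt$tL,
                 tdiff = r$kin$bt$tdiff)
    })
    f <- ensure(paste0(stem, ".csv"))
    write_csv_with_header(do.call(rbind, rows), f, meta)
    files <- f
  } else if (subcommand == "offaxis") {
    oc <- cfg$offaxis
    oa <- offaxis_scan(ob$params, ob$rates, F = oc$F,
                       theta_F = seq(oc$theta_from, oc$theta_to, oc$theta_by),
                       phi_F = seq(oc$phi_from, oc$phi_to, oc$phi_by),
                       lattice = ob$lattice)
    f <- ensure(paste0(stem, ".txt"))
    write_matrix_text(oa$percent, f,
                      c(meta, list(theta_F = oa$theta_F, phi_F = oa$phi_F)))
    files <- f
  } else if (subcommand == "constraint-scan") {
    cc <- cfg$constraint_scan
    cs <- constraint_scan(ob$params, ob$rates,
                          mu_c = seq(cc$mu_from, cc$mu_to, cc$mu_by),
                          theta_p = cc$theta_p, lattice = ob$lattice)
    f <- ensure(paste0(stem, ".csv"))
    write_csv_with_header(cs, f, meta)
    files <- f
  } else if (subcommand == "runs") {
    rc <- cfg$runs
    mc <- run_monte_carlo(ob$params, ob$rates, n_runs = rc$n_runs,
                          seed = rc$seed, force_rule = rc$force_rule,
                          force = ob$force,
                          trap = list(stiffness = rc$trap_stiffness,
                                      offaxis_y = rc$trap_offaxis_y),
                          lattice = ob$lattice)
    f <- ensure(paste0(stem, ".csv"))
    write_csv_with_header(mc$runs, f, c(meta, list(seed = rc$seed)))
    files <- f
  } else if (subcommand == "bd") {
    bc <- cfg$bd
    st <- bd_settings(dt = bc$dt, max_time = bc$max_time, seed = bc$seed,
                      coverslip = bc$coverslip)
    res <- simulate_step(ob$params, ob$rates, ob$lattice, ob$force, st,
                         detached = bc$detached, n_traj = bc$n_traj)
    f <- ensure(paste0(stem, ".csv"))
    write_csv_with_header(res, f, c(meta, list(seed = bc$seed)))
    files <- f
  } else {
    stop("unknown subcommand: ", subcommand)
  }

  manifest <- list(subcommand = subcommand, config = unclass(cfg),
                   derived = list(T_eff = ec$T_eff, bFL = ec$bFL,
                                  theta_c_prime = ec$theta_c_prime,
                                  g = ob$rates$g),
                   package_version = as.character(utils::packageVersion("myovstep")),
                   files = as.list(setNames(as.character(tools::md5sum(files)),
                                            basename(files))))
  mf <- ensure(paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = I(17))
  invisible(c(files, mf))
}

#' Rebuild the configuration stored in a run manifest
#'
#' Reads the JSON manifest written by \code{\link{run_command}} and merges
#' its configuration echo onto the defaults, so the run can be reproduced
#' exactly.
#'
#' @param path manifest file path.
#' @return validated configuration list.
#' @export
config_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- merge_config(man$config, default_config())
  validate_config(cfg)
  structure(cfg, class = c("myov_config", "list"))
}
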