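#' Default run configuration
#'
#' Nested configuration with the standard parameter set: thermostat
#' `gamma = 4.5`, time step `dt = 0.02 tau`, density `rho = 3`, like-species
#' repulsion 25, mesh size `a_x = 3.35 r_c`, monodisperse network, rod
#' `d/a_x = 1.4`. Every stochastic component consumes an explicit seed from
#' the `seeds` section.
#'
#' @return nested named list (sections `system`, `engine`, `analysis`,
#'   `theory`, `ctrw`, `seeds`).
#' @export
default_config <- function() {
  list(
    system = list(cells_per_side = 4L, a_x = 3.35, cv = 0,
                  beads_per_strand = 7L, d_over_ax = 1.4, L_over_ax = 2.1,
                  a_rp = 25, bead_spacing = 0.5),
    engine = list(gamma = 4.5, sigma = NULL, dt = 0.02, rho = 3, a_ii = 25,
                  kT = 1, lambda_vv = 0.65, bond_k = 100, bond_r0 = 0.7,
                  n_equil = 5000L, n_prod = 20000L, record_every = 5L),
    analysis = list(n_lags = 40L, bin_width = 0.335,
                    fickian_band = c(0.9, 1.1), plateau_exponent = 0.25,
                    trapped_exponent = 0.1, alpha1_threshold = 0.3),
    theory = list(N = 16L, n_samples = 2000L, z_points = 13L, shell = 3,
                  crosslink_smear = 0.25),
    ctrw = list(tau_hop = 150, tau_0 = 50, U0 = 1, n_steps = 8192L),
    seeds = list(build = 1L, run = 2L, theory = 3L, ctrw = 4L))
}

merge_validate <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.null(user[[nm]])) next # explicit YAML null keeps the default
    if (is.list(base[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a section")
      base[[nm]] <- merge_validate(base[[nm]], user[[nm]], here)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load, validate and save run configurations
#'
#' `load_config()` reads a YAML file (an empty file yields the full default
#' configuration), recursively merges it over [default_config()], rejects
#' unknown keys with their key path, and validates ranges -- including the
#' fluctuation-dissipation constraint when an explicit `sigma` is given.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(default_config(), user)
  eng <- cfg$engine
  if (eng$gamma <= 0 || eng$dt <= 0 || eng$rho <= 0 || eng$kT <= 0)
    stop("engine.gamma/dt/rho/kT must be positive")
  if (!is.null(eng$sigma) &&
      abs(eng$sigma^2 - 2 * eng$gamma * eng$kT) > 1e-8)
    stop("engine.sigma violates sigma^2 = 2 gamma kT")
  if (cfg$system$cv < 0) stop("system.cv must be non-negative")
  if (cfg$system$cells_per_side < 2) stop("system.cells_per_side must be >= 2")
  if (cfg$theory$N < 1) stop("theory.N must be >= 1")
  cfg
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in output files so any
#' result can be traced to the exact configuration that produced it.
#'
#' @param config configuration list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Parameters and specs from a configuration
#'
#' @param config a configuration list.
#' @return `config_params()` gives the [dpd_params()]; `config_network()`
#'   the [network_spec()]; `config_rod()` the [build_rod()] spec.
#' @export
config_params <- function(config) {
  e <- config$engine
  dpd_params(a_ii = e$a_ii, a_rp = config$system$a_rp, gamma_dpd = e$gamma,
             sigma = e$sigma, kT = e$kT, dt = e$dt, lambda_vv = e$lambda_vv,
             rho = e$rho, bond_k = e$bond_k, bond_r0 = e$bond_r0)
}

#' @rdname config_params
#' @export
config_network <- function(config) {
  s <- config$system
  network_spec(s$cells_per_side, a_x = s$a_x,
               beads_per_strand = s$beads_per_strand, cv = s$cv,
               seed = config$seeds$build)
}

#' @rdname config_params
#' @export
config_rod <- function(config) {
  s <- config$system
  build_rod(s$L_over_ax * s$a_x, s$d_over_ax * s$a_x,
            bead_spacing = s$bead_spacing)
}
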