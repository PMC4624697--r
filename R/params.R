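#' Default model parameters
#'
#' Builds the full parameter set of the congression/bi-orientation model.
#' Units are pN, micrometres and seconds throughout; velocities are given in
#' um/min (the conventional experimental unit) and converted internally; the
#' chromosome drag coefficient `eta` is in pN s/um (1 kg/s = 1e6 pN s/um).
#'
#' Dynamic-instability parameters (`v_g`, `v_s`, `F_g`, `F_s`, `p_cat0`,
#' `p_res0`, `F_cat`, `F_res`), attachment parameters (`r_k`, `N_k`, `k_k`,
#' detachment rates/sensitivities), motor forces (`F_PEF` per crossing MT,
#' `F_CENPE` and `F_DYN` total per motor group) and the population parameters
#' (`N_MT`, `p_sc`, `k_nucl`, `n_C`) default to the wild-type values used for
#' human cells (46 chromosomes, cell major semi-axis 15 um).
#'
#' @param ... named overrides of any default listed below. Unknown names are
#'   an error.
#'
#' @return A named list of class `spindle_params`.
#'
#' @details Defaults:
#' \describe{
#'   \item{a}{cell major semi-axis, um (minor semi-axes are fixed at
#'     `b = 0.9 a`, `c = 0.7 a`)}
#'   \item{r_k}{kinetochore interaction radius, um}
#'   \item{r_C}{chromosome-arm disk radius, um}
#'   \item{N_k}{end-on slots per kinetochore}
#'   \item{k_k}{kinetochore-MT spring constant, pN/um}
#'   \item{p_detach_u0, F_detach_u}{unloaded detachment rate (1/s) and force
#'     sensitivity (pN) of unstable (slip-bond) attachments}
#'   \item{p_detach_s0, F_detach_s}{same for stable (catch-bond) attachments}
#'   \item{F_PEF}{polar ejection force per crossing MT, pN}
#'   \item{F_CENPE, F_DYN}{total lateral motor-group forces, pN}
#'   \item{v_g, v_s}{unloaded MT growth/shrinkage velocities, um/min}
#'   \item{F_g, F_s}{velocity force sensitivities, pN}
#'   \item{p_cat0, p_res0}{unloaded catastrophe/rescue rates, 1/s}
#'   \item{F_cat, F_res}{catastrophe/rescue force sensitivities, pN}
#'   \item{N_MT}{total MT number (fixed-N mode)}
#'   \item{p_sc}{fraction of MTs forming the stable interpolar scaffold}
#'   \item{k_nucl}{nucleation rate per pole, 1/s (nucleation mode)}
#'   \item{tau_MT}{minimum MT age for CENP-E lateral attachment, s}
#'   \item{delta_pole}{pole-arrival radius triggering the dynein-to-CENP-E
#'     switch, um}
#'   \item{tau_refract}{refractory period after a stochastic detachment
#'     during which the detached MT cannot re-bind the same kinetochore, s}
#'   \item{eta}{chromosome drag coefficient, pN s/um}
#'   \item{n_C}{number of chromosomes}
#'   \item{dt}{integration time step, s}
#'   \item{deadline_congression, deadline_biorientation}{first-passage
#'     deadlines, s}
#'   \item{eps_congression}{congression slab half-width as a fraction of `a`}
#'   \item{mode}{`"fixed_n"` (constant MT number) or `"nucleation"`
#'     (birth-death population)}
#'   \item{arm_geometry}{`"disk"` (arm disk normal to the pole-pole axis) or
#'     `"sphere"` (orientation-free spherical cross-section)}
#'   \item{interpolar_start}{logical; start all chromosomes inside the
#'     CENP-E shell of radius `0.45 a`}
#'   \item{cenpe_present}{logical; FALSE suppresses the dynein-to-CENP-E
#'     switch at the pole (CENP-E deletion leaves dynein active)}
#' }
#' @export
#' @examples
#' p <- spindle_params(N_MT = 2000, n_C = 10)
#' p$v_g
spindle_params <- function(...) {
  p <- list(
    # geometry
    a = 15,
    # kinetochore / attachment
    r_k = 0.3, r_C = 1.2, N_k = 25, k_k = 100,
    p_detach_u0 = 0.1, F_detach_u = 4,
    p_detach_s0 = 0.001, F_detach_s = 4,
    # motors
    F_PEF = 0.5, F_CENPE = 50, F_DYN = 50,
    # dynamic instability
    v_g = 12, F_g = 6, v_s = 14, F_s = 4,
    p_cat0 = 0.058, F_cat = 2.4, p_res0 = 0.045, F_res = 2.3,
    # population
    N_MT = 10000, p_sc = 0.1, k_nucl = 9, tau_MT = 60,
    # transport program
    delta_pole = 2.5, tau_refract = 5,
    # mechanics / integration
    eta = 200, n_C = 46, dt = 0.1,
    deadline_congression = 1000, deadline_biorientation = 1e5,
    eps_congression = 0.1,
    mode = "fixed_n", arm_geometry = "disk",
    interpolar_start = FALSE, cenpe_present = TRUE
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(p)
}

validate_params <- function(p) {
  pos <- c("a", "r_k", "r_C", "N_k", "k_k", "F_detach_u", "F_detach_s",
           "F_g", "F_s", "F_cat", "F_res", "v_g", "v_s", "eta", "dt",
           "tau_MT", "delta_pole", "deadline_congression",
           "deadline_biorientation", "eps_congression")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive scalar")
  nonneg <- c("p_cat0", "p_res0", "p_detach_u0", "p_detach_s0", "F_PEF",
              "F_CENPE", "F_DYN", "k_nucl", "tau_refract")
  for (nm in nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("parameter '", nm, "' must be a non-negative scalar")
  if (p$p_sc < 0 || p$p_sc > 1) stop("p_sc must lie in [0, 1]")
  if (!p$mode %in% c("fixed_n", "nucleation"))
    stop("mode must be 'fixed_n' or 'nucleation'")
  if (!p$arm_geometry %in% c("disk", "sphere"))
    stop("arm_geometry must be 'disk' or 'sphere'")
  if (p$n_C < 0 || p$n_C != round(p$n_C)) stop("n_C must be a count")
  if (p$N_MT < 1 || p$N_MT != round(p$N_MT)) stop("N_MT must be a count >= 1")
  if (p$N_k < 1 || p$N_k != round(p$N_k)) stop("N_k must be a count >= 1")
  structure(p, class = "spindle_params")
}

#' Check that the integration step resolves all model time scales
#'
#' The explicit Euler update requires the step to be small against the
#' end-on spring relaxation time `eta / k_k` and against every stochastic
#' waiting time, so that per-step event probabilities stay well below one.
#' Called by the run drivers before stepping; fails with a message rather
#' than integrating an unstable system.
#'
#' @param p a [spindle_params()] object.
#' @param max_rate_dt largest admissible rate times `dt` product.
#' @return `p`, invisibly, if the step passes.
#' @export
check_timestep <- function(p, max_rate_dt = 0.5) {
  relax <- p$eta / p$k_k
  if (p$dt > 0.2 * relax)
    stop(sprintf(
      "dt = %g s does not resolve the end-on spring relaxation time %g s",
      p$dt, relax))
  fast <- max(p$p_cat0, p$p_res0, p$p_detach_u0, p$p_detach_s0)
  if (fast * p$dt > max_rate_dt)
    stop(sprintf("dt = %g s is too large for the fastest rate %g /s",
                 p$dt, fast))
  # chromosomes should not cross their own interaction radius in one step
  f_max <- p$F_CENPE + p$F_DYN + p$k_k * p$r_k
  if (f_max * p$dt / p$eta > p$r_k)
    stop("dt too large: chromosome displacement per step exceeds r_k")
  invisible(p)
}

#' @export
print.spindle_params <- function(x, ...) {
  cat("<spindle_params>\n")
  cat(sprintf("  mode: %s   N_MT: %d (p_sc = %g)   k_nucl: %g /s/pole\n",
              x$mode, as.integer(x$N_MT), x$p_sc, x$k_nucl))
  cat(sprintf("  cell: a = %g um, n_C = %d chromosomes\n", x$a,
              as.integer(x$n_C)))
  cat(sprintf("  instability: v_g = %g, v_s = %g um/min; p_cat0 = %g, p_res0 = %g /s\n",
              x$v_g, x$v_s, x$p_cat0, x$p_res0))
  cat(sprintf("  motors: F_PEF = %g pN/MT, F_CENPE = %g pN, F_DYN = %g pN\n",
              x$F_PEF, x$F_CENPE, x$F_DYN))
  cat(sprintf("  integration: dt = %g s, eta = %g pN s/um\n", x$dt, x$eta))
  invisible(x)
}

#' Scenario presets
#'
#' Returns a parameter set patched for one of the named experimental
#' scenarios. Knockouts only zero the corresponding motor force; the
#' CENP-E knockout additionally leaves kinetochore dynein active at the
#' pole (there is no motor to replace it). The nucleation scenario switches
#' the population mode on, removes chromosomes, and uses the catastrophe
#' rate for which the per-MT turnover matches the fitted population
#' relaxation (see the package vignette).
#'
#' @param name one of `"wt_scattered"`, `"wt_interpolar"`, `"ko_dynein"`,
#'   `"ko_cenpe"`, `"ko_pef"`, `"nucleation_mode"`.
#' @param params base parameter set to patch.
#' @return a `spindle_params` object with attribute `"scenario"`.
#' @export
#' @examples
#' scenario_params("ko_dynein", spindle_params(n_C = 10, N_MT = 2000))
scenario_params <- function(name = c("wt_scattered", "wt_interpolar",
                                     "ko_dynein", "ko_cenpe", "ko_pef",
                                     "nucleation_mode"),
                            params = spindle_params()) {
  name <- match.arg(name)
  p <- switch(name,
    wt_scattered  = params,
    wt_interpolar = { params$interpolar_start <- TRUE; params },
    ko_dynein     = { params$F_DYN <- 0; params },
    ko_cenpe      = { params$F_CENPE <- 0; params$cenpe_present <- FALSE; params },
    ko_pef        = { params$F_PEF <- 0; params },
    nucleation_mode = {
      params$mode <- "nucleation"
      params$n_C <- 0L
      params$p_cat0 <- 0.205
      params
    })
  p <- validate_params(p)
  attr(p, "scenario") <- name
  p
}

#' Write / read a run configuration as JSON
#'
#' A configuration is a flat JSON object holding every model parameter plus
#' the scenario name and seed; a run is reproducible from the file alone.
#' Unknown keys in a file are an error, not a warning.
#'
#' @param params a [spindle_params()] object.
#' @param path file path.
#' @param scenario scenario name stored with the parameters.
#' @param seed integer seed stored with the parameters.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   list with elements `params`, `scenario`, `seed`.
#' @export
write_config <- function(params, path, scenario = "wt_scattered", seed = 1L) {
  stopifnot(inherits(params, "spindle_params"))
  obj <- c(unclass(params), list(scenario = scenario, seed = as.integer(seed)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- obj$scenario %||% "wt_scattered"
  seed <- as.integer(obj$seed %||% 1L)
  obj$scenario <- NULL
  obj$seed <- NULL
  defaults <- spindle_params()
  unknown <- setdiff(names(obj), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  p <- unclass(defaults)
  p[names(obj)] <- obj
  list(params = validate_params(p), scenario = scenario, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
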