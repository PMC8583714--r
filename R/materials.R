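#' Tissue composition of a callus element
#'
#' A callus element is modelled as a mixture of four tissue phases --
#' connective tissue, cartilage, woven bone and cortical bone -- plus a blood
#' perfusion level. Concentrations are volume percentages and must sum to 100.
#'
#' @param conn,cart,bone,cort Phase concentrations in percent.
#' @param perfusion Blood perfusion in percent (0 = avascular, 100 = fully
#'   vascularised).
#' @return An object of class `tissue_state`.
#' @examples
#' tissue_state(conn = 90, bone = 10, perfusion = 25)
#' @export
tissue_state <- function(conn = 100, cart = 0, bone = 0, cort = 0,
                         perfusion = 0) {
  x <- c(conn = conn, cart = cart, bone = bone, cort = cort)
  if (any(x < -1e-9))
    stop("tissue concentrations must be non-negative")
  if (abs(sum(x) - 100) > 1e-6)
    stop("tissue concentrations must sum to 100 % (got ", sum(x), ")")
  if (perfusion < -1e-9 || perfusion > 100 + 1e-9)
    stop("perfusion must lie in [0, 100] %")
  structure(list(conn = conn, cart = cart, bone = bone, cort = cort,
                 perfusion = min(max(perfusion, 0), 100)),
            class = "tissue_state")
}

#' Prony-series shear relaxation model
#'
#' Normalised relaxation function `g(t) = 1 - sum_i g_i (1 - exp(-t/tau_i))`,
#' together with the instantaneous elastic constants it modulates. The
#' long-time fraction `g_inf = 1 - sum(g)` must be strictly positive: the
#' material keeps a finite equilibrium stiffness.
#'
#' @param g Numeric vector of dimensionless branch weights, each in (0, 1).
#' @param tau Numeric vector of branch time constants in seconds.
#' @param E_inst Instantaneous Young's modulus in MPa.
#' @param nu Poisson ratio.
#' @return An object of class `prony_model`.
#' @examples
#' prony_model(g = c(0.396, 0.542), tau = c(10.775, 977.88))
#' @export
prony_model <- function(g, tau, E_inst = NA_real_, nu = NA_real_) {
  if (length(g) != length(tau))
    stop("g and tau must have the same length")
  if (length(g) && (any(g <= 0) || sum(g) >= 1))
    stop("branch weights must be positive with sum(g) < 1")
  if (any(tau <= 0)) stop("time constants must be positive")
  o <- order(tau)
  structure(list(g = as.numeric(g[o]), tau = as.numeric(tau[o]),
                 E_inst = E_inst, nu = nu),
            class = "prony_model")
}

#' @export
print.prony_model <- function(x, ...) {
  cat("Prony relaxation model (", length(x$g), " branch",
      if (length(x$g) != 1) "es", ")\n", sep = "")
  for (i in seq_along(x$g))
    cat(sprintf("  g_%d = %.4f   tau_%d = %.4g s\n", i, x$g[i], i, x$tau[i]))
  cat(sprintf("  g_inf = %.4f\n", 1 - sum(x$g)))
  if (!is.na(x$E_inst)) cat(sprintf("  E_inst = %.4g MPa\n", x$E_inst))
  invisible(x)
}

#' Evaluate the normalised relaxation function of a Prony model
#'
#' @param model A [prony_model()].
#' @param t Times in seconds.
#' @return `g(t)`, dimensionless, decreasing from 1 at `t = 0` to
#'   `1 - sum(g)` as `t -> Inf`.
#' @export
prony_g <- function(model, t) {
  stopifnot(inherits(model, "prony_model"))
  out <- rep(1 - sum(model$g), length(t))
  for (i in seq_along(model$g))
    out <- out + model$g[i] * exp(-t / model$tau[i])
  out
}

#' Per-tissue material library
#'
#' Linear-elastic constants for the four tissue phases (plus bone marrow,
#' which appears in the mesh but is never regenerated), and the Prony
#' relaxation model of immature callus tissue. Defaults follow the standard
#' fracture-healing literature values for the elastic constants and the
#' two-term Prony coefficients fitted to in vivo distraction relaxation
#' curves (g = 0.396, 0.542; tau = 10.775 s, 977.88 s).
#'
#' @param connective,cartilage,woven,cortical,marrow Each a numeric vector
#'   `c(E, nu)` with `E` in MPa.
#' @param callus_prony A [prony_model()] describing stress relaxation of the
#'   (unmineralised) callus.
#' @return An object of class `material_library`.
#' @examples
#' lib <- material_library()
#' lib$woven["E"]
#' @export
material_library <- function(connective = c(E = 3, nu = 0.3),
                             cartilage  = c(E = 10, nu = 0.45),
                             woven      = c(E = 4000, nu = 0.36),
                             cortical   = c(E = 20000, nu = 0.3),
                             marrow     = c(E = 2, nu = 0.17),
                             callus_prony = prony_model(
                               g = c(0.396, 0.542),
                               tau = c(10.775, 977.88))) {
  tis <- list(connective = connective, cartilage = cartilage,
              woven = woven, cortical = cortical, marrow = marrow)
  for (nm in names(tis)) {
    v <- tis[[nm]]
    if (!all(c("E", "nu") %in% names(v)) || v["E"] <= 0)
      stop("tissue '", nm, "' needs positive E and a nu value")
  }
  E <- vapply(tis[c("connective", "cartilage", "woven", "cortical")],
              function(v) v[["E"]], 0)
  if (any(diff(E) <= 0))
    stop("stiffness ordering E_conn < E_cart < E_woven < E_cort violated")
  structure(c(tis, list(callus_prony = callus_prony)),
            class = "material_library")
}

#' Daily stress-relaxation force of the distracted callus
#'
#' Empirical traction-force relaxation following one distraction increment on
#' day `j`: a sum of three Maxwell branches (time constants 3690 s, 469.3 s
#' and a day-dependent `9.95 exp(0.09 j)` s) plus an equilibrium term, each
#' amplitude growing exponentially with the distraction day as the callus
#' stiffens, all proportional to the applied displacement increment.
#'
#' @param j Distraction day (0 = initial state).
#' @param u Displacement increment in mm.
#' @param t Time after the increment, in seconds.
#' @return Traction force in N.
#' @examples
#' relaxation_force(0, 1, 0)       # peak force on day 0: 18.47 N per mm
#' relaxation_force(0, 1, 43200)   # nearly fully relaxed after 12 h
#' @export
relaxation_force <- function(j, u, t) {
  if (any(t < 0)) stop("negative relaxation time")
  if (any(u < 0)) stop("negative displacement increment")
  if (any(j < 0)) stop("negative distraction day")
  u * (3.57 * exp(0.17 * j) * exp(-t / 3690) +
       6.79 * exp(0.11 * j) * exp(-t / 469.3) +
       6.89 * exp(0.08 * j) * exp(-t / (9.95 * exp(0.09 * j))) +
       1.22 * exp(0.13 * j))
}

#' Residual force after a distraction increment
#'
#' The force retained in the callus once relaxation is complete, expressed as
#' a fixed 6.23 % fraction of the peak traction force of that day.
#'
#' @param j Distraction day (unused by the fraction itself; kept for symmetry
#'   with [relaxation_force()]).
#' @param peak Peak traction force in N.
#' @return Residual force in N.
#' @export
residual_force <- function(j, peak) {
  if (any(peak < 0)) stop("negative peak force")
  0.0623 * peak
}

#' A sampled stress-relaxation curve
#'
#' @param t Sample times in seconds (non-negative, increasing).
#' @param force Sampled traction forces in N (positive).
#' @param day Distraction day the curve belongs to.
#' @param u Displacement increment that produced the curve, in mm.
#' @return An object of class `relaxation_curve`.
#' @seealso [read_relaxation_curve()] to import a two-column CSV.
#' @export
relaxation_curve <- function(t, force, day = 0, u = 1) {
  if (length(t) != length(force)) stop("t and force lengths differ")
  if (any(t < 0)) stop("negative sample times")
  o <- order(t)
  t <- t[o]; force <- force[o]
  if (any(diff(force) > 1e-9 * force[1]))
    warning("relaxation force is not non-increasing in t")
  structure(list(t = t, force = force, day = day, u = u),
            class = "relaxation_curve")
}

#' @rdname relaxation_curve
#' @param path CSV file with columns `t_seconds, force_newtons`.
#' @export
read_relaxation_curve <- function(path, day = 0, u = 1) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected two columns: t_seconds, force_newtons")
  relaxation_curve(d[[1]], d[[2]], day = day, u = u)
}

#' @rdname relaxation_curve
#' @param curve A `relaxation_curve`.
#' @export
write_relaxation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  utils::write.csv(data.frame(t_seconds = curve$t,
                              force_newtons = curve$force),
                   path, row.names = FALSE)
  invisible(path)
}

#' Sample the empirical daily relaxation curve
#'
#' Convenience generator: evaluates [relaxation_force()] on `n` log-spaced
#' times spanning the 12-hour hold (plus the `t = 0` peak).
#'
#' @inheritParams relaxation_force
#' @param n Number of samples.
#' @param t_max End of the sampling window in seconds (12 h by default).
#' @return A [relaxation_curve()].
#' @export
sample_relaxation_curve <- function(j = 0, u = 1, n = 200, t_max = 43200) {
  t <- c(0, 10^seq(log10(0.1), log10(t_max), length.out = n - 1))
  relaxation_curve(t, relaxation_force(j, u, t), day = j, u = u)
}

#' Fit a Prony series to a relaxation curve
#'
#' Least-squares fit of the normalised relaxation function
#' `g(t) = 1 - sum_i g_i (1 - exp(-t/tau_i))` to `F(t)/F(0)`. By default the
#' equilibrium fraction `g_inf` is pinned to the fully relaxed tail of the
#' curve (the last sample), which is the conventional treatment when the
#' measured curve reaches its plateau within the sampling window; set
#' `equilibrium = "free"` for a fully unconstrained fit.
#'
#' @param curve A [relaxation_curve()].
#' @param n_terms Number of Maxwell branches.
#' @param equilibrium `"pin"` (default) or `"free"`.
#' @return A [prony_model()] with attributes `rms` (residual root mean
#'   square of the normalised fit) and `g_inf`.
#' @examples
#' crv <- sample_relaxation_curve(j = 0)
#' fit_prony(crv, 2)
#' @export
fit_prony <- function(curve, n_terms = 2,
                      equilibrium = c("pin", "free")) {
  stopifnot(inherits(curve, "relaxation_curve"))
  equilibrium <- match.arg(equilibrium)
  t <- curve$t
  if (length(t) < 2 * n_terms + 1)
    stop("need at least ", 2 * n_terms + 1, " samples for a ",
         n_terms, "-term fit")
  if (any(curve$force <= 0)) stop("forces must be positive")
  y <- curve$force / curve$force[t == min(t)][1]

  tpos <- t[t > 0]
  lt0 <- log(exp(seq(log(min(tpos)), log(max(tpos)),
                     length.out = n_terms + 2)))[2:(n_terms + 1)]
  gtail <- y[length(y)]

  if (equilibrium == "pin") {
    g0 <- rep((1 - gtail) / n_terms, n_terms)
    # parameterise the branch weights through softmax-free positive shares of
    # the relaxing fraction so the pinned g_inf is honoured exactly
    make_pred <- function(par) {
      g <- exp(par[1:n_terms])
      g <- g / sum(g) * (1 - gtail)
      tau <- exp(par[(n_terms + 1):(2 * n_terms)])
      pred <- rep(gtail, length(t))
      for (i in seq_len(n_terms)) pred <- pred + g[i] * exp(-t / tau[i])
      pred
    }
    par0 <- c(log(g0), lt0)
    res <- minpack.lm::nls.lm(par = par0,
                              fn = function(p) make_pred(p) - y,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500))
    if (res$info %in% c(0, 9))
      stop("Prony fit did not converge (info = ", res$info,
           ", residual norm = ", sqrt(res$deviance), ")")
    g <- exp(res$par[1:n_terms])
    g <- g / sum(g) * (1 - gtail)
    tau <- exp(res$par[(n_terms + 1):(2 * n_terms)])
    rms <- sqrt(mean(res$fvec^2))
  } else {
    make_pred <- function(par) {
      g <- par[1:n_terms]
      tau <- exp(par[(n_terms + 1):(2 * n_terms)])
      pred <- rep(1 - sum(g), length(t))
      for (i in seq_len(n_terms)) pred <- pred + g[i] * exp(-t / tau[i])
      pred
    }
    par0 <- c(rep((1 - gtail) / n_terms, n_terms), lt0)
    res <- minpack.lm::nls.lm(par = par0,
                              fn = function(p) make_pred(p) - y,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500))
    if (res$info %in% c(0, 9))
      stop("Prony fit did not converge (info = ", res$info,
           ", residual norm = ", sqrt(res$deviance), ")")
    g <- res$par[1:n_terms]
    tau <- exp(res$par[(n_terms + 1):(2 * n_terms)])
    rms <- sqrt(mean(res$fvec^2))
  }
  out <- prony_model(g = g, tau = tau)
  attr(out, "rms") <- rms
  attr(out, "g_inf") <- 1 - sum(g)
  out
}

#' Element-level material properties from a tissue mixture
#'
#' Converts a [tissue_state()] into effective constitutive parameters:
#' Young's modulus by the cube-root mixture rule
#' `E = (sum_i c_i E_i^(1/3))^3`, Poisson ratio by linear mixture, and the
#' callus Prony weights scaled linearly towards a purely elastic response as
#' the mineralised fraction (woven + cortical bone) approaches 100 %.
#'
#' @param state A [tissue_state()].
#' @param lib A [material_library()].
#' @return A list with components `E` (MPa), `nu`, and `prony` (a
#'   [prony_model()]; zero-branch, i.e. purely elastic, when fully
#'   mineralised).
#' @examples
#' lib <- material_library()
#' mixture_properties(tissue_state(), lib)                     # soft callus
#' mixture_properties(tissue_state(conn = 0, bone = 100), lib) # woven bone
#' @export
mixture_properties <- function(state, lib) {
  stopifnot(inherits(state, "tissue_state"), inherits(lib, "material_library"))
  c_i <- c(state$conn, state$cart, state$bone, state$cort) / 100
  E_i <- c(lib$connective["E"], lib$cartilage["E"],
           lib$woven["E"], lib$cortical["E"])
  nu_i <- c(lib$connective["nu"], lib$cartilage["nu"],
            lib$woven["nu"], lib$cortical["nu"])
  E <- sum(c_i * E_i^(1/3))^3
  nu <- sum(c_i * nu_i)
  scale <- 1 - (state$bone + state$cort) / 100
  pr <- lib$callus_prony
  prony <- if (scale <= 1e-12) {
    structure(list(g = numeric(0), tau = numeric(0),
                   E_inst = E, nu = nu), class = "prony_model")
  } else {
    prony_model(g = pr$g * scale, tau = pr$tau, E_inst = E, nu = nu)
  }
  list(E = unname(E), nu = unname(nu), prony = prony)
}

#' Instantaneous callus modulus implied by the day-0 relaxation curve
#'
#' Calibration helper: the modulus for which a uniform bar of the gap tissue,
#' with the cross-section of the cortical annulus, reproduces the measured
#' peak stiffness `F_j(0)/u` of the daily relaxation curve.
#'
#' @param geometry A [do_geometry()]; supplies the annulus area and gap
#'   length.
#' @param j Distraction day.
#' @return Instantaneous Young's modulus in MPa.
#' @export
calibrate_instantaneous_modulus <- function(geometry, j = 0) {
  stopifnot(inherits(geometry, "do_geometry"))
  A <- pi / 4 * (geometry$periosteal_diameter^2 - geometry$endosteal_diameter^2)
  k <- relaxation_force(j, 1, 0)  # N per mm
  k * geometry$current_gap / A
}
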