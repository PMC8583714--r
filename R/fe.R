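#' External fixator model
#'
#' Axial force-displacement law of the fixator: fixed at the bottom surface
#' and rigidly linked to the top of the upper fragment, so it acts in
#' parallel with the bone column. Either a linear stiffness or a monotone
#' piecewise-linear table through the origin.
#'
#' @param stiffness Linear spring stiffness in N/mm.
#' @param table Two-column matrix/data.frame (displacement mm, force N)
#'   defining a piecewise-linear law; must pass through the origin and be
#'   strictly monotone.
#' @return An object of class `fixator_model` with a `force(d)` function.
#' @export
fixator_model <- function(stiffness = NULL, table = NULL) {
  if (is.null(stiffness) == is.null(table))
    stop("give exactly one of stiffness or table")
  if (!is.null(stiffness)) {
    if (stiffness < 0) stop("stiffness must be non-negative")
    f <- function(d) stiffness * d
    k0 <- stiffness
  } else {
    table <- as.matrix(table)
    if (!any(apply(table, 1, function(r) all(abs(r) < 1e-12))))
      table <- rbind(c(0, 0), table)
    table <- table[order(table[, 1]), , drop = FALSE]
    if (any(diff(table[, 2]) <= 0) || any(diff(table[, 1]) <= 0))
      stop("fixator table must be strictly monotone")
    lo <- table[1, ]; hi <- table[nrow(table), ]
    f <- function(d) {
      y <- approx(table[, 1], table[, 2], d, rule = 2)$y
      # linear extrapolation beyond the table
      y[d < lo[1]] <- lo[2] + (d[d < lo[1]] - lo[1]) *
        diff(table[1:2, 2]) / diff(table[1:2, 1])
      n <- nrow(table)
      y[d > hi[1]] <- hi[2] + (d[d > hi[1]] - hi[1]) *
        diff(table[(n - 1):n, 2]) / diff(table[(n - 1):n, 1])
      y
    }
    k0 <- diff(table[1:2, 2]) / diff(table[1:2, 1])
  }
  structure(list(force = f, k0 = k0, stiffness = stiffness, table = table),
            class = "fixator_model")
}

#' Loading event definition
#'
#' Either a distraction increment (prescribed axial displacement of the top
#' fragment, ramped over `ramp_time` and held for `hold_time` while stresses
#' relax) or a consolidation load (axial compressive force through the
#' fixator-stabilised construct).
#'
#' @param kind `"distraction_increment"` or `"consolidation_load"`.
#' @param u Displacement increment in mm (distraction).
#' @param force Axial compressive force in N (consolidation).
#' @param ramp_time Load ramp duration in s.
#' @param hold_time Relaxation hold after the ramp in s (0 = no hold).
#' @param ramp_steps,hold_steps Time discretisation: uniform sub-steps over
#'   the ramp, log-spaced steps over the hold.
#' @return An object of class `load_case`.
#' @export
load_case <- function(kind = c("distraction_increment", "consolidation_load"),
                      u = NULL, force = NULL, ramp_time = 1,
                      hold_time = if (kind == "distraction_increment") 43200 else 0,
                      ramp_steps = 10, hold_steps = 20) {
  kind <- match.arg(kind)
  if (ramp_time <= 0) stop("ramp_time must be positive")
  if (kind == "distraction_increment") {
    if (is.null(u) || !is.null(force))
      stop("distraction_increment takes u, not force")
    if (u < 0) stop("negative displacement increment")
  } else {
    if (is.null(force) || !is.null(u))
      stop("consolidation_load takes force, not u")
  }
  structure(list(kind = kind, u = u, force = force, ramp_time = ramp_time,
                 hold_time = hold_time, ramp_steps = ramp_steps,
                 hold_steps = hold_steps),
            class = "load_case")
}

#' Fresh viscoelastic state for a mesh
#'
#' Zero residual stress and zero branch stresses; the starting condition of
#' the first loading event.
#'
#' @param mesh A `do_mesh`.
#' @param n_branches Number of Prony branches tracked.
#' @return A list with `sigma_perm` (n x 4 residual stress, MPa, Voigt order
#'   rr, zz, tt, rz) and `q` (n x 4 x n_branches branch stresses).
#' @export
initial_fe_state <- function(mesh, n_branches = 2) {
  n <- nrow(mesh$elem)
  list(sigma_perm = matrix(0, n, 4),
       q = array(0, dim = c(n, 4, n_branches)))
}

#' Per-element material table for the FE solver
#'
#' @param E,nu Numeric vectors, one entry per element (MPa / dimensionless).
#' @param gmat Matrix of Prony branch weights, one row per element (zero
#'   rows = purely elastic elements).
#' @param tau Branch time constants in s, shared across elements.
#' @param bulk_relax Apply the Prony relaxation to the volumetric response
#'   as well as the deviatoric one (default: deviatoric only).
#' @return An object of class `element_materials`.
#' @export
element_materials <- function(E, nu, gmat = NULL, tau = numeric(0),
                              bulk_relax = FALSE) {
  n <- length(E)
  if (length(nu) != n) stop("E and nu lengths differ")
  if (is.null(gmat)) gmat <- matrix(0, n, length(tau))
  if (length(tau) == 0) gmat <- matrix(0, n, 0)
  if (nrow(gmat) != n || ncol(gmat) != length(tau))
    stop("gmat must be n_elements x length(tau)")
  if (any(E <= 0)) stop("zero-stiffness element (non-positive E)")
  if (any(rowSums(gmat) >= 1)) stop("branch weights must sum below 1")
  structure(list(E = E, nu = nu, gmat = gmat, tau = tau,
                 bulk_relax = bulk_relax),
            class = "element_materials")
}

# ---------------------------------------------------------------------------
# internals: element kernels -------------------------------------------------

# Deviatoric unit kernel in Voigt (rr, zz, tt, engineering rz): sigma_dev =
# G * .DEV %*% eps. Volumetric projector row is m = (1,1,1,0).
.DEV <- matrix(c(4/3, -2/3, -2/3, 0,
                 -2/3, 4/3, -2/3, 0,
                 -2/3, -2/3, 4/3, 0,
                 0, 0, 0, 1), 4, 4, byrow = TRUE)

# Precompute, per mesh: integration kernels so that
#   K_e = K_el * PVOL + G_el * PDEV   (arrays n x 8 x 8)
#   f_e = BTW %*% sigma_e             (BTW: n x 8 x 4)
# plus the centroid strain-displacement operator Bc (n x 4 x 8).
.fe_setup <- function(mesh) {
  el <- mesh$elem
  n <- nrow(el)
  xr <- matrix(mesh$nodes[el, 1], n, 4)
  xz <- matrix(mesh$nodes[el, 2], n, 4)
  gp <- 1 / sqrt(3)
  pts <- rbind(c(-gp, -gp), c(gp, -gp), c(gp, gp), c(-gp, gp), c(0, 0))
  PVOL <- array(0, c(n, 8, 8)); PDEV <- array(0, c(n, 8, 8))
  BTW <- array(0, c(n, 8, 4)); Bc <- NULL
  for (k in 1:5) {
    xi <- pts[k, 1]; eta <- pts[k, 2]
    dNdxi <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
    dNdeta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
    N <- 0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
                  (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
    J11 <- xr %*% dNdxi; J12 <- xz %*% dNdxi
    J21 <- xr %*% dNdeta; J22 <- xz %*% dNdeta
    detJ <- as.vector(J11 * J22 - J12 * J21)
    if (any(detJ <= 0)) stop("non-positive element Jacobian in element ",
                             which(detJ <= 0)[1])
    rgp <- as.vector(xr %*% N)
    dNdr <- matrix(0, n, 4); dNdz <- matrix(0, n, 4)
    for (a in 1:4) {
      dNdr[, a] <- (as.vector(J22) * dNdxi[a] - as.vector(J12) * dNdeta[a]) / detJ
      dNdz[, a] <- (-as.vector(J21) * dNdxi[a] + as.vector(J11) * dNdeta[a]) / detJ
    }
    # B rows: 1 e_rr, 2 e_zz, 3 e_tt, 4 gamma_rz; dofs (ur1, uz1, ...)
    B <- array(0, c(n, 4, 8))
    for (a in 1:4) {
      cr <- 2 * a - 1; cz <- 2 * a
      B[, 1, cr] <- dNdr[, a]
      B[, 2, cz] <- dNdz[, a]
      B[, 3, cr] <- N[a] / rgp
      B[, 4, cr] <- dNdz[, a]
      B[, 4, cz] <- dNdr[, a]
    }
    if (k == 5) { Bc <- B; break }
    w <- detJ * 2 * pi * rgp
    bm <- matrix(B[, 1, ] + B[, 2, ] + B[, 3, ], nrow = n)  # volumetric row
    for (i in 1:8) {
      BTW[, i, ] <- BTW[, i, ] + w * B[, , i]
      for (j in i:8) {
        pv <- w * bm[, i] * bm[, j]
        pd <- numeric(n)
        for (a in 1:4) for (b in 1:4) if (.DEV[a, b] != 0)
          pd <- pd + B[, a, i] * .DEV[a, b] * B[, b, j]
        pd <- w * pd
        PVOL[, i, j] <- PVOL[, i, j] + pv
        PDEV[, i, j] <- PDEV[, i, j] + pd
        if (j > i) { PVOL[, j, i] <- PVOL[, i, j]; PDEV[, j, i] <- PDEV[, i, j] }
      }
    }
  }
  dof <- matrix(0L, n, 8)
  dof[, seq(1, 8, 2)] <- 2L * el - 1L
  dof[, seq(2, 8, 2)] <- 2L * el
  ii <- array(0L, c(n, 8, 8)); jj <- array(0L, c(n, 8, 8))
  for (i in 1:8) for (j in 1:8) { ii[, i, j] <- dof[, i]; jj[, i, j] <- dof[, j] }
  list(PVOL = PVOL, PDEV = PDEV, BTW = BTW, Bc = Bc,
       dof = dof, ii = as.vector(ii), jj = as.vector(jj), n = n)
}

# assemble global sparse stiffness for per-element bulk/shear moduli
.assemble_K <- function(setup, Kel, Gel, ndof, mapdof) {
  Ke <- Kel * setup$PVOL + Gel * setup$PDEV
  Matrix::sparseMatrix(i = mapdof[setup$ii], j = mapdof[setup$jj],
                       x = as.vector(Ke), dims = c(ndof, ndof))
}

# assemble global internal-force vector from per-element stress (n x 4)
.assemble_f <- function(setup, sigma, ndof, mapdof) {
  fe <- matrix(0, setup$n, 8)
  for (i in 1:8) fe[, i] <- rowSums(setup$BTW[, i, ] * sigma)
  as.vector(Matrix::sparseMatrix(i = mapdof[as.vector(setup$dof)], j = rep(1L, 8 * setup$n),
                                 x = as.vector(fe), dims = c(ndof, 1)))
}

#' Solve one loading event
#'
#' Assembles and integrates the axisymmetric small-strain viscoelastic
#' problem for a distraction increment (displacement-controlled ramp plus
#' relaxation hold) or a consolidation load (force through a rigid top
#' plate, with the fixator spring in parallel). Viscous branch stresses are
#' integrated with the recursive exponential update, exact for stress
#' relaxation under constant strain.
#'
#' @param mesh A `do_mesh`.
#' @param materials An [element_materials()] table.
#' @param fixator A [fixator_model()] or `NULL`. Required (and only allowed)
#'   for consolidation loads.
#' @param load A [load_case()].
#' @param state An [initial_fe_state()] or the `state` of a previous
#'   solution (residual-stress carryover).
#' @return An object of class `fe_solution`: nodal displacements at peak
#'   (end of ramp) and end of hold, per-element event strains (Voigt,
#'   centroid), updated viscoelastic `state`, and the reaction force on the
#'   loaded boundary at peak and end.
#' @export
solve_event <- function(mesh, materials, fixator = NULL, load, state = NULL) {
  stopifnot(inherits(mesh, "do_mesh"), inherits(materials, "element_materials"),
            inherits(load, "load_case"))
  consol <- load$kind == "consolidation_load"
  if (consol && is.null(fixator))
    stop("consolidation load requires a fixator model")
  if (!consol && !is.null(fixator))
    stop("the fixator acts only during consolidation events")
  nb <- ncol(materials$gmat)
  if (is.null(state)) state <- initial_fe_state(mesh, nb)
  setup <- .fe_setup(mesh)
  n <- setup$n
  nnode <- nrow(mesh$nodes)

  E <- materials$E; nu <- materials$nu
  G0 <- E / (2 * (1 + nu)); K0 <- E / (3 * (1 - 2 * nu))
  ginf <- 1 - rowSums(materials$gmat)
  m_vol <- c(1, 1, 1, 0)

  # dof bookkeeping -------------------------------------------------------
  top <- which(mesh$tag == "top_loaded")
  bottom <- which(mesh$tag == "bottom_fixed")
  axis <- which(mesh$tag == "axis")
  mapdof <- seq_len(2L * nnode)
  if (consol) {
    master <- 2L * nnode + 1L
    mapdof[2L * top] <- master
    ndof <- master
  } else ndof <- 2L * nnode
  fixed <- unique(c(2L * bottom, 2L * axis - 1L))
  presc <- if (consol) integer(0) else sort(unique(2L * top))
  known <- unique(c(fixed, presc))
  vacated <- if (consol) 2L * top else integer(0)  # remapped onto the master
  free <- setdiff(seq_len(ndof), c(known, vacated))

  # time marching ---------------------------------------------------------
  tr <- load$ramp_time
  times <- seq(tr / load$ramp_steps, tr, length.out = load$ramp_steps)
  if (load$hold_time > 0) {
    h0 <- min(1, load$hold_time / 100)
    times <- c(times, tr + 10^seq(log10(h0), log10(load$hold_time),
                                  length.out = load$hold_steps))
  }
  amp <- pmin(times / tr, 1)

  q <- state$q
  if (nb && (length(dim(q)) != 3 || dim(q)[3] != nb))
    stop("state carries a different number of Prony branches than materials")
  sigma_perm <- state$sigma_perm
  e_prev <- matrix(0, n, 4)       # event strain at previous step (Voigt)
  u_full <- numeric(ndof)
  t_prev <- 0
  peak <- NULL; final <- NULL

  for (m in seq_along(times)) {
    dt <- times[m] - t_prev
    t_prev <- times[m]
    if (nb) {
      a_i <- exp(-dt / materials$tau)
      c_i <- materials$tau / dt * (1 - a_i)
      gc <- as.vector(materials$gmat %*% c_i)
    } else { a_i <- numeric(0); c_i <- numeric(0); gc <- 0 }

    if (materials$bulk_relax) {
      fac <- ginf + gc
      Gel <- G0 * fac; Kel <- K0 * fac
    } else {
      Gel <- G0 * (ginf + gc)
      Kel <- K0
    }
    Kmat <- .assemble_K(setup, Kel, Gel, ndof, mapdof)
    if (consol) Kmat[ndof, ndof] <- Kmat[ndof, ndof] + fixator$k0

    # history stress known before the new increment
    sigma_hist <- sigma_perm - (G0 * gc) * (e_prev %*% .DEV)
    if (materials$bulk_relax) {
      tr_e <- e_prev[, 1] + e_prev[, 2] + e_prev[, 3]
      sigma_hist <- sigma_hist - (K0 * gc * tr_e) %*% t(m_vol)
    }
    if (nb) for (i in seq_len(nb)) sigma_hist <- sigma_hist + a_i[i] * q[, , i]

    f_hist <- .assemble_f(setup, sigma_hist, ndof, mapdof)
    f <- -f_hist
    u_new <- numeric(ndof)
    if (consol) {
      f[ndof] <- f[ndof] - load$force * amp[m]   # compressive: downward
      u_new <- u_full
      fact <- Matrix::Cholesky(Matrix::forceSymmetric(
        Kmat[free, free, drop = FALSE]), LDL = FALSE, perm = TRUE)
      for (it in 1:30) {
        Fs <- fixator$force(u_new[ndof])
        resid <- f - as.vector(Kmat %*% u_new)
        resid[ndof] <- resid[ndof] - (Fs - fixator$k0 * u_new[ndof])
        resid[known] <- 0
        du <- numeric(ndof)
        du[free] <- as.vector(Matrix::solve(fact, resid[free]))
        u_new <- u_new + du
        if (sqrt(sum(resid[free]^2)) <= 1e-6 * abs(load$force)) break
        if (it == 30) stop("Newton iteration for the fixator spring ",
                           "did not converge; |R| = ",
                           signif(sqrt(sum(resid[free]^2)), 4))
      }
    } else {
      u_new[presc] <- load$u * amp[m]
      rhs <- f[free] - as.vector(Kmat[free, known, drop = FALSE] %*% u_new[known])
      u_new[free] <- as.vector(Matrix::solve(Kmat[free, free, drop = FALSE], rhs))
    }

    # centroid event strain and branch-stress update
    ue <- matrix(u_new[mapdof[as.vector(setup$dof)]], n, 8)
    eps <- matrix(0, n, 4)
    for (cmp in 1:4) eps[, cmp] <- rowSums(setup$Bc[, cmp, ] * ue)
    de <- eps - e_prev
    if (nb) {
      dev_s <- de %*% .DEV
      tr_de <- de[, 1] + de[, 2] + de[, 3]
      for (i in seq_len(nb)) {
        add <- (G0 * materials$gmat[, i] * c_i[i]) * dev_s
        if (materials$bulk_relax)
          add <- add + (K0 * materials$gmat[, i] * c_i[i] * tr_de) %*% t(m_vol)
        q[, , i] <- a_i[i] * q[, , i] + add
      }
    }
    e_prev <- eps
    u_full <- u_new

    react <- if (consol) {
      -(as.vector(Kmat %*% u_full) + f_hist)[ndof]
    } else {
      sum((as.vector(Kmat %*% u_full) + f_hist)[presc])
    }
    snap <- list(u = u_full, eps = eps, reaction = react)
    if (is.null(peak) && times[m] >= tr - 1e-12) peak <- snap
    if (m == length(times)) final <- snap
  }
  if (is.null(peak)) peak <- final

  # fold the event's permanent stress into the carried residual stress
  tr_e <- e_prev[, 1] + e_prev[, 2] + e_prev[, 3]
  if (materials$bulk_relax) {
    sigma_perm <- sigma_perm + (G0 * ginf) * (e_prev %*% .DEV) +
      (K0 * ginf * tr_e) %*% t(m_vol)
  } else {
    sigma_perm <- sigma_perm + (G0 * ginf) * (e_prev %*% .DEV) +
      (K0 * tr_e) %*% t(m_vol)
  }

  unpack <- function(sol) {
    U <- cbind(sol$u[mapdof[seq(1, 2 * nnode, 2)]],
               sol$u[mapdof[seq(2, 2 * nnode, 2)]])
    colnames(U) <- c("u_r", "u_z")
    U
  }
  structure(list(mesh = mesh, load = load,
                 U_peak = unpack(peak), U_end = unpack(final),
                 strains_peak = peak$eps, strains_end = final$eps,
                 reaction_peak = peak$reaction, reaction_end = final$reaction,
                 state = list(sigma_perm = sigma_perm, q = q),
                 master_u = if (consol) final$u[ndof] else NA_real_),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution (%s): peak reaction %.4g N, end reaction %.4g N\n",
              x$load$kind, x$reaction_peak, x$reaction_end))
  invisible(x)
}

#' Dilatational and distortional strain invariants
#'
#' Per-element strain invariants of a solved loading event, the mechanical
#' inputs of the tissue-differentiation rules: the dilatational strain
#' `eps_dil = (e_rr + e_zz + e_tt) * 100` (volumetric, %, tension positive)
#' and the distortional strain `gamma_dist`, the octahedral shear strain
#' `(2/3) sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2) * 100` (%).
#'
#' @param sol An `fe_solution`.
#' @param which `"peak"` (end of ramp; the distraction stimulus) or
#'   `"end"` (after the relaxation hold).
#' @return A data.frame with columns `eps_dil` and `gamma_dist` (percent),
#'   one row per element.
#' @export
strain_invariants <- function(sol, which = c("peak", "end")) {
  stopifnot(inherits(sol, "fe_solution"))
  which <- match.arg(which)
  eps <- if (which == "peak") sol$strains_peak else sol$strains_end
  e_rr <- eps[, 1]; e_zz <- eps[, 2]; e_tt <- eps[, 3]; g_rz <- eps[, 4]
  # principal strains: in-plane eigenvalues plus the hoop strain
  cc <- (e_rr + e_zz) / 2
  rr <- sqrt(((e_rr - e_zz) / 2)^2 + (g_rz / 2)^2)
  e1 <- cc + rr; e2 <- cc - rr; e3 <- e_tt
  gamma <- (2 / 3) * sqrt((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)
  data.frame(eps_dil = (e_rr + e_zz + e_tt) * 100,
             gamma_dist = gamma * 100)
}

#' Interfragmentary movement
#'
#' Relative axial displacement between the two cortical fragment faces
#' bounding the distraction gap, averaged over the face nodes. Reported as a
#' magnitude (non-negative under compressive consolidation loads).
#'
#' @param sol An `fe_solution` (peak displacements are used: the IFM is read
#'   at load application, before stress relaxation).
#' @param mesh The mesh the event was solved on (defaults to the solution's
#'   own mesh).
#' @return IFM in mm.
#' @export
interfragmentary_movement <- function(sol, mesh = sol$mesh) {
  stopifnot(inherits(sol, "fe_solution"))
  uz <- sol$U_peak[, "u_z"]
  abs(mean(uz[mesh$gap_face_top]) - mean(uz[mesh$gap_face_bottom]))
}

#' Calibrate the fixator spring to a target initial IFM
#'
#' Finds the linear spring stiffness for which the end-of-distraction,
#' all-connective-tissue construct moves by `target_ifm` under the
#' consolidation load -- the dynamic-fixation condition used to anchor the
#' model before protocol comparisons.
#'
#' @param mesh Mesh of the end-of-distraction configuration.
#' @param lib A [material_library()].
#' @param target_ifm Target interfragmentary movement in mm.
#' @param load Axial compressive load in N.
#' @param tol Relative IFM tolerance of the calibration.
#' @return A [fixator_model()] with attribute `achieved_ifm`.
#' @export
calibrate_fixator <- function(mesh, lib, target_ifm = 0.5, load = 500,
                              tol = 0.01) {
  stopifnot(inherits(mesh, "do_mesh"), inherits(lib, "material_library"))
  if (target_ifm <= 0) stop("target_ifm must be positive")
  mats <- .region_materials(mesh, lib,
                            state_df = .uniform_callus_state(mesh))
  lc <- load_case("consolidation_load", force = load, ramp_time = 1,
                  ramp_steps = 2, hold_time = 0)
  ifm_for <- function(k) {
    sol <- solve_event(mesh, mats, fixator_model(stiffness = k), lc)
    interfragmentary_movement(sol, mesh)
  }
  ifm0 <- ifm_for(0)
  if (ifm0 < target_ifm)
    stop("unreachable target: tissue alone is stiffer than the target IFM (",
         signif(ifm0, 4), " mm < ", target_ifm, " mm)")
  S <- load / ifm0
  k <- max(load / target_ifm - S, 0)
  for (it in 1:20) {
    ifm <- ifm_for(k)
    if (abs(ifm - target_ifm) <= tol * target_ifm) break
    S <- load / ifm - k
    k <- max(load / target_ifm - S, 0)
    if (it == 20) stop("fixator calibration did not converge")
  }
  fx <- fixator_model(stiffness = k)
  attr(fx, "achieved_ifm") <- ifm
  fx
}

# all-connective callus state table used for calibration
.uniform_callus_state <- function(mesh) {
  n <- nrow(mesh$elem)
  data.frame(conn = rep(100, n), cart = 0, bone = 0, cort = 0, perfusion = 0)
}

# per-element materials from a state table + library; cortex/marrow fixed.
# Vectorised version of mixture_properties() for whole-mesh updates.
.region_materials <- function(mesh, lib, state_df) {
  n <- nrow(mesh$elem)
  pr <- lib$callus_prony
  E_i <- c(lib$connective["E"], lib$cartilage["E"],
           lib$woven["E"], lib$cortical["E"])
  nu_i <- c(lib$connective["nu"], lib$cartilage["nu"],
            lib$woven["nu"], lib$cortical["nu"])
  cm <- cbind(state_df$conn, state_df$cart, state_df$bone, state_df$cort) / 100
  E <- as.vector(cm %*% E_i^(1/3))^3
  nu <- as.vector(cm %*% nu_i)
  scale <- pmax(1 - (state_df$bone + state_df$cort) / 100, 0)
  gmat <- outer(scale, pr$g)
  cortex <- mesh$region == "cortex"; marrow <- mesh$region == "marrow"
  E[cortex] <- lib$cortical["E"]; nu[cortex] <- lib$cortical["nu"]
  E[marrow] <- lib$marrow["E"]; nu[marrow] <- lib$marrow["nu"]
  gmat[cortex | marrow, ] <- 0
  element_materials(E = E, nu = nu, gmat = gmat, tau = pr$tau)
}
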