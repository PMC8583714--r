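#' Simulation configuration
#'
#' Bundles everything a distraction-osteogenesis run needs: geometry,
#' material library, fuzzy rule base, protocol, fixator calibration target,
#' consolidation load, discretisation and termination settings.
#'
#' @param geometry A [do_geometry()].
#' @param lib A [material_library()].
#' @param rules A [rule_base()].
#' @param protocol Protocol label (see [parse_protocol()]) or a
#'   `do_protocol`.
#' @param fixator A pre-calibrated [fixator_model()], or `NULL` to calibrate
#'   at run time against `fixator_target_ifm`.
#' @param fixator_target_ifm Initial IFM (mm) of the all-connective,
#'   fully distracted construct under the consolidation load; the fixator
#'   spring is calibrated to reproduce it.
#' @param consolidation_load Daily axial compressive load in N.
#' @param callus_size,bone_size Element sizes in mm.
#' @param sigma Gaussian kernel width (mm) of the biological neighbourhood
#'   (growth propagation range); defaults to one callus element size.
#' @param transfer_sigma Kernel width (mm) of the numerical field-transfer
#'   map between meshes (the biological propagation range is `sigma`).
#' @param end_day Hard stop (days since surgery).
#' @param bridging_threshold IFM below which the gap counts as bridged, mm.
#' @param ramp_steps,hold_steps Time discretisation of distraction events.
#' @param consolidation_ramp_steps Sub-steps of the daily consolidation
#'   load ramp.
#' @param distraction_material Constitutive model of the callus during
#'   distraction events: `"empirical"` (default) assigns the whole callus
#'   the day-dependent viscoelastic law measured in vivo (stiffness from the
#'   daily peak relaxation force over the gap, Prony branches from the
#'   library), reproducing the near-uniform `r / l` strain state of the
#'   distracted interzone; `"mixture"` uses the tissue-composition mixture
#'   properties instead (strain then localises into the softest layers).
#'   Consolidation events always use mixture properties.
#' @param new_volume Accounting of freshly distracted volume during field
#'   transfer; see [transfer_fields()].
#' @param snapshot_every Record a full tissue-field snapshot every this many
#'   days (0 = none).
#' @param checkpoint_dir Directory for weekly state checkpoints (`NULL` =
#'   no checkpointing).
#' @return An object of class `do_config`.
#' @export
do_config <- function(geometry = do_geometry(), lib = material_library(),
                      rules = rule_base(), protocol = "control",
                      fixator = NULL, fixator_target_ifm = 0.5,
                      consolidation_load = 500,
                      callus_size = 0.25, bone_size = 2 * callus_size,
                      sigma = callus_size,
                      transfer_sigma = callus_size, end_day = 120,
                      bridging_threshold = 0.05,
                      ramp_steps = 10, hold_steps = 20,
                      consolidation_ramp_steps = 4,
                      distraction_material = c("empirical", "mixture"),
                      new_volume = c("center", "stretch", "slab"),
                      snapshot_every = 7, checkpoint_dir = NULL) {
  distraction_material <- match.arg(distraction_material)
  new_volume <- match.arg(new_volume)
  if (!inherits(protocol, "do_protocol")) protocol <- parse_protocol(protocol)
  stopifnot(inherits(geometry, "do_geometry"),
            inherits(lib, "material_library"), inherits(rules, "rule_base"))
  problems <- character(0)
  dist_end <- protocol$latency_days + protocol$distraction_days
  if (end_day < dist_end)
    problems <- c(problems, "end_day precedes the end of distraction")
  if (fixator_target_ifm <= 0)
    problems <- c(problems, "fixator_target_ifm must be positive")
  if (callus_size > geometry$initial_gap)
    problems <- c(problems, "callus_size exceeds the initial gap")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  structure(list(geometry = geometry, lib = lib, rules = rules,
                 protocol = protocol, fixator = fixator,
                 fixator_target_ifm = fixator_target_ifm,
                 consolidation_load = consolidation_load,
                 callus_size = callus_size, bone_size = bone_size,
                 sigma = sigma, transfer_sigma = transfer_sigma,
                 end_day = end_day,
                 bridging_threshold = bridging_threshold,
                 ramp_steps = ramp_steps, hold_steps = hold_steps,
                 consolidation_ramp_steps = consolidation_ramp_steps,
                 distraction_material = distraction_material,
                 new_volume = new_volume,
                 snapshot_every = snapshot_every,
                 checkpoint_dir = checkpoint_dir),
            class = "do_config")
}

#' Initialise the simulation state
#'
#' Builds the mesh at the initial osteotomy gap and assigns the
#' post-latency initial conditions: the callus is entirely connective
#' tissue with no perfusion; cortical fragments and marrow are fully
#' perfused. The day counter starts at the end of latency.
#'
#' @param config A [do_config()].
#' @return A list with `mesh`, `states` (per-element tissue table),
#'   `fe_state`, `gap` and `day`.
#' @export
initialize_state <- function(config) {
  stopifnot(inherits(config, "do_config"))
  mesh <- build_mesh(config$geometry, config$callus_size, config$bone_size)
  n <- nrow(mesh$elem)
  states <- data.frame(conn = rep(0, n), cart = 0, bone = 0, cort = 0,
                       perfusion = 0, damage = 0)
  callus <- mesh$region == "callus"
  cortex <- mesh$region == "cortex"
  marrow <- mesh$region == "marrow"
  states$conn[callus | marrow] <- 100
  states$cort[cortex] <- 100
  states$perfusion[cortex | marrow] <- 100
  nb <- length(config$lib$callus_prony$g)
  list(mesh = mesh, states = states,
       fe_state = initial_fe_state(mesh, nb),
       gap = config$geometry$initial_gap,
       day = config$protocol$latency_days)
}

# Gaussian neighbourhood aggregation restricted to elements near the gap
# (everything further than 3 sigma from the callus band cannot contribute).
.gap_neighborhood <- function(mesh, sigma) {
  z <- mesh$centroids[, "z"]
  margin <- 3 * sigma + 1e-9
  idx <- which(z > -margin & z < mesh$geometry$current_gap + margin)
  ctr <- mesh$centroids[idx, , drop = FALSE]
  d2 <- outer(ctr[, 1], ctr[, 1], "-")^2 + outer(ctr[, 2], ctr[, 2], "-")^2
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > (3 * sigma)^2] <- 0
  diag(w) <- 0
  rs <- rowSums(w); rs[rs == 0] <- 1
  list(idx = idx, W = w / rs)
}

.aggregate_sub <- function(nbh, field) {
  out <- numeric(length(field))
  out[nbh$idx] <- as.vector(nbh$W %*% field[nbh$idx])
  out
}

# one regulation step on the callus elements; returns updated states
.regulation_step <- function(mesh, states, invariants, rules, nbh,
                             step_days) {
  callus <- which(mesh$region == "callus")
  bone_field <- states$bone + states$cort
  n_perf <- .aggregate_sub(nbh, states$perfusion)
  n_bone <- .aggregate_sub(nbh, bone_field)
  inp <- data.frame(eps_dil = invariants$eps_dil[callus],
                    gamma_dist = invariants$gamma_dist[callus],
                    perfusion = states$perfusion[callus],
                    c_cart = states$cart[callus],
                    c_bone = states$bone[callus],
                    neighbor_perfusion = n_perf[callus],
                    neighbor_bone = n_bone[callus])
  out <- evaluate_rules(inp, rules, step_days = step_days)
  # necrotic-fraction debt: the damaged fraction of an element cannot
  # regenerate, so positive differentiation outputs scale with the intact
  # fraction; necrosis is resorbed slowly and diluted by later distraction
  damage <- states$damage[callus]
  intact <- ifelse(damage > rules$damage_gate, 0, 1 - damage)
  out$d_perfusion <- ifelse(out$d_perfusion > 0,
                            out$d_perfusion * intact, out$d_perfusion)
  out$d_cart <- ifelse(out$d_cart > 0, out$d_cart * intact, out$d_cart)
  out$d_bone <- ifelse(out$d_bone > 0, out$d_bone * intact, out$d_bone)
  heal <- rules$damage_heal_rate *
    (1 + rules$vascular_heal_gain * n_perf[callus] / 100)
  damage <- pmax(damage - heal * step_days, 0)
  damage[out$destroyed] <- 1
  upd <- apply_regulation(states[callus, c("conn", "cart", "bone", "cort",
                                           "perfusion"), drop = FALSE], out)
  states[callus, c("conn", "cart", "bone", "cort", "perfusion")] <- upd
  states$damage[callus] <- damage
  attr(states, "n_destroyed") <- sum(out$destroyed)
  states
}

# Uniform day-j empirical callus material for distraction events: the whole
# regenerate follows the measured daily relaxation law; stiffness from the
# day's peak force per unit increment acting over the gap column.
.empirical_materials <- function(mesh, lib, j) {
  n <- nrow(mesh$elem)
  g <- mesh$geometry
  A <- pi / 4 * (g$periosteal_diameter^2 - g$endosteal_diameter^2)
  E_cal <- relaxation_force(j, 1, 0) * g$current_gap / A
  pr <- lib$callus_prony
  E <- numeric(n); nu <- numeric(n)
  gmat <- matrix(0, n, length(pr$g))
  callus <- mesh$region == "callus"
  cortex <- mesh$region == "cortex"
  marrow <- mesh$region == "marrow"
  E[callus] <- E_cal; nu[callus] <- lib$connective["nu"]
  gmat[callus, ] <- matrix(pr$g, sum(callus), length(pr$g), byrow = TRUE)
  E[cortex] <- lib$cortical["E"]; nu[cortex] <- lib$cortical["nu"]
  E[marrow] <- lib$marrow["E"]; nu[marrow] <- lib$marrow["nu"]
  element_materials(E = E, nu = nu, gmat = gmat, tau = pr$tau)
}

# flatten / restore the viscoelastic state for field transfer
.fe_state_to_fields <- function(fe_state) {
  nb <- dim(fe_state$q)[3]
  f <- as.data.frame(fe_state$sigma_perm)
  names(f) <- paste0("sp", 1:4)
  for (i in seq_len(nb)) for (cmp in 1:4)
    f[[paste0("q", i, "_", cmp)]] <- fe_state$q[, cmp, i]
  f
}

.fields_to_fe_state <- function(f, nb) {
  n <- nrow(f)
  q <- array(0, c(n, 4, nb))
  for (i in seq_len(nb)) for (cmp in 1:4)
    q[, cmp, i] <- f[[paste0("q", i, "_", cmp)]]
  list(sigma_perm = as.matrix(f[, paste0("sp", 1:4)]), q = q)
}

#' Regenerated bone area
#'
#' Bone formed in the callus, measured in the r-z plane: the sum over callus
#' elements of the bone volume fraction times the element area.
#'
#' @param states Per-element tissue table (as in [initialize_state()]).
#' @param mesh The matching `do_mesh`.
#' @return Area in mm^2.
#' @export
bone_area <- function(states, mesh) {
  callus <- mesh$region == "callus"
  sum(states$bone[callus] / 100 * mesh$areas[callus])
}

#' Detect bony bridging in an IFM series
#'
#' @param ifm_series Data.frame with columns `day` and `ifm` (mm),
#'   time-ordered.
#' @param threshold Bridging threshold in mm.
#' @return The first day with IFM below the threshold, or `NA` if never
#'   reached.
#' @export
detect_bridging <- function(ifm_series, threshold = 0.05) {
  if (!nrow(ifm_series)) return(NA_real_)
  if (is.unsorted(ifm_series$day)) stop("IFM series must be time-ordered")
  hit <- which(ifm_series$ifm < threshold)
  if (!length(hit)) NA_real_ else ifm_series$day[hit[1]]
}

#' Run a distraction-osteogenesis simulation
#'
#' The full latency / distraction / consolidation loop. Per distraction
#' action: viscoelastic FE solve of the increment (1 s ramp, 12 h
#' relaxation hold, residual-stress carryover), peak strain invariants,
#' Gaussian neighbourhood aggregation, fuzzy regulation step, material
#' update, then remeshing of the widened gap and field transfer. Per
#' consolidation day: FE solve of the axial load through the calibrated
#' fixator, IFM recording, and one regulation step. Fully deterministic.
#'
#' @param config A [do_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `do_result`: `ifm_series` (consolidation
#'   days), `bone_area_series`, `concentration_series` (callus means),
#'   `bridging_day`, `snapshots`, the per-event `log`, the final `mesh`,
#'   `states` and `config`.
#' @export
run_do <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "do_config"))
  st <- initialize_state(config)
  proto <- config$protocol
  nb <- length(config$lib$callus_prony$g)
  tspec <- field_transfer_spec(sigma = config$transfer_sigma)

  log <- list(); snaps <- list()
  area_series <- list(); conc_series <- list()
  record_day <- function(day, mesh, states) {
    callus <- mesh$region == "callus"
    area_series[[length(area_series) + 1]] <<-
      data.frame(day = day, bone_area = bone_area(states, mesh))
    conc_series[[length(conc_series) + 1]] <<-
      data.frame(day = day,
                 bone = mean(states$bone[callus]),
                 cartilage = mean(states$cart[callus]),
                 perfusion = mean(states$perfusion[callus]))
    if (config$snapshot_every > 0 &&
        (day - proto$latency_days) %% config$snapshot_every == 0)
      snaps[[as.character(day)]] <<- list(day = day, mesh = mesh,
                                          states = states)
  }
  checkpoint <- function(day) {
    if (!is.null(config$checkpoint_dir) && day %% 7 == 0) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(st, file.path(config$checkpoint_dir,
                            sprintf("day%03d.rds", day)))
    }
  }

  record_day(st$day, st$mesh, st$states)
  nbh <- .gap_neighborhood(st$mesh, config$sigma)

  # distraction phase -----------------------------------------------------
  for (d in seq_len(nrow(proto$schedule))) {
    day <- proto$schedule$day[d]
    inc <- proto$schedule$increment[d]
    for (action in 1:2) {
      mats <- if (config$distraction_material == "empirical")
        .empirical_materials(st$mesh, config$lib, j = d - 1)
      else .region_materials(st$mesh, config$lib, st$states)
      lc <- load_case("distraction_increment", u = inc,
                      ramp_time = 1, hold_time = 43200,
                      ramp_steps = config$ramp_steps,
                      hold_steps = config$hold_steps)
      sol <- tryCatch(
        solve_event(st$mesh, mats, NULL, lc, st$fe_state),
        error = function(e) {
          checkpoint(day)
          stop("FE failure on day ", day, " action ", action, ": ",
               conditionMessage(e))
        })
      inv <- strain_invariants(sol, "peak")
      st$states <- .regulation_step(st$mesh, st$states, inv, config$rules,
                                    nbh, step_days = 0.5)
      callus <- st$mesh$region == "callus"
      log[[length(log) + 1]] <- data.frame(
        day = day + (action - 1) * 0.5, phase = "distraction",
        eps_med = stats::median(inv$eps_dil[callus]),
        gamma_med = stats::median(inv$gamma_dist[callus]),
        perfusion = mean(st$states$perfusion[callus]),
        bone = mean(st$states$bone[callus]),
        destroyed = attr(st$states, "n_destroyed"),
        n_callus = sum(callus),
        damage = mean(st$states$damage[callus]),
        ifm = NA_real_)

      # widen the gap: remesh and map all fields onto the new mesh
      new_gap <- st$gap + inc
      new_mesh <- remesh(st$mesh, new_gap)
      fields <- cbind(st$states, .fe_state_to_fields(sol$state))
      fields <- transfer_fields(st$mesh, fields, new_mesh, tspec,
                                new_volume = config$new_volume)
      st$states <- fields[, c("conn", "cart", "bone", "cort", "perfusion",
                              "damage")]
      tot <- st$states$conn + st$states$cart + st$states$bone + st$states$cort
      for (cmp in c("conn", "cart", "bone", "cort"))
        st$states[[cmp]] <- st$states[[cmp]] / tot * 100
      st$fe_state <- .fields_to_fe_state(fields, nb)
      st$mesh <- new_mesh
      st$gap <- new_gap
      nbh <- .gap_neighborhood(st$mesh, config$sigma)
    }
    st$day <- day
    record_day(day, st$mesh, st$states)
    checkpoint(day)
    if (!quiet) message("day ", day, " (distraction), gap ", st$gap, " mm")
  }

  # fixator calibration (shared boundary condition for all protocols) -----
  fixator <- config$fixator
  if (is.null(fixator)) {
    cal_geom <- config$geometry
    cal_geom$current_gap <- 15
    cal_mesh <- build_mesh(cal_geom, config$callus_size, config$bone_size)
    fixator <- calibrate_fixator(cal_mesh, config$lib,
                                 target_ifm = config$fixator_target_ifm,
                                 load = config$consolidation_load)
  }

  # consolidation phase ---------------------------------------------------
  ifm_series <- list()
  dist_end <- proto$latency_days + proto$distraction_days
  bridging_day <- NA_real_
  plateau <- 0
  last_ifm <- NA_real_
  consol_days <- if (config$end_day > dist_end)
    seq(dist_end + 1, config$end_day) else integer(0)
  for (day in consol_days) {
    mats <- .region_materials(st$mesh, config$lib, st$states)
    lc <- load_case("consolidation_load", force = config$consolidation_load,
                    ramp_time = 1, hold_time = 0,
                    ramp_steps = config$consolidation_ramp_steps)
    sol <- tryCatch(
      solve_event(st$mesh, mats, fixator, lc),
      error = function(e) {
        checkpoint(day)
        stop("FE failure on consolidation day ", day, ": ",
             conditionMessage(e))
      })
    ifm <- interfragmentary_movement(sol, st$mesh)
    ifm_series[[length(ifm_series) + 1]] <- data.frame(day = day, ifm = ifm)

    inv <- strain_invariants(sol, "peak")
    st$states <- .regulation_step(st$mesh, st$states, inv, config$rules,
                                  nbh, step_days = 1)
    callus <- st$mesh$region == "callus"
    log[[length(log) + 1]] <- data.frame(
      day = day, phase = "consolidation",
      eps_med = stats::median(inv$eps_dil[callus]),
      gamma_med = stats::median(inv$gamma_dist[callus]),
      perfusion = mean(st$states$perfusion[callus]),
      bone = mean(st$states$bone[callus]),
      destroyed = attr(st$states, "n_destroyed"),
      n_callus = sum(callus),
      damage = mean(st$states$damage[callus]),
      ifm = ifm)
    st$day <- day
    record_day(day, st$mesh, st$states)
    checkpoint(day)
    if (!quiet) message("day ", day, " (consolidation), IFM ",
                        signif(ifm, 3), " mm")

    if (is.na(bridging_day) && ifm < config$bridging_threshold)
      bridging_day <- day
    if (!is.na(bridging_day)) {
      plateau <- if (!is.na(last_ifm) && abs(ifm - last_ifm) < 1e-3)
        plateau + 1 else 0
      if (plateau >= 7) break
    }
    last_ifm <- ifm
  }

  structure(list(
    ifm_series = do.call(rbind, ifm_series),
    bone_area_series = do.call(rbind, area_series),
    concentration_series = do.call(rbind, conc_series),
    bridging_day = bridging_day,
    snapshots = snaps,
    log = do.call(rbind, log),
    mesh = st$mesh, states = st$states,
    fixator = fixator, config = config),
    class = "do_result")
}

#' @export
print.do_result <- function(x, ...) {
  p <- x$config$protocol
  cat(sprintf("Distraction osteogenesis run: protocol %s\n", p$label))
  cat(sprintf("  distraction days %d, simulated through day %g\n",
              p$distraction_days, max(x$bone_area_series$day)))
  if (!is.na(x$bridging_day))
    cat(sprintf("  bony bridging on day %g (IFM < %g mm)\n",
                x$bridging_day, x$config$bridging_threshold))
  else cat("  no bony bridging within the simulated window\n")
  cat(sprintf("  final bone area %.4g mm^2, final mean bone %.3g %%\n",
              utils::tail(x$bone_area_series$bone_area, 1),
              utils::tail(x$concentration_series$bone, 1)))
  invisible(x)
}

#' @export
summary.do_result <- function(object, ...) {
  out <- list(
    protocol = object$config$protocol$label,
    bridging_day = object$bridging_day,
    final_bone_area = utils::tail(object$bone_area_series$bone_area, 1),
    final_ifm = if (!is.null(object$ifm_series))
      utils::tail(object$ifm_series$ifm, 1) else NA_real_,
    weeks = stats::setNames(
      vapply(c(21, 42, 63), function(d) {
        s <- object$bone_area_series
        if (max(s$day) < d) NA_real_ else s$bone_area[which.min(abs(s$day - d))]
      }, 0), c("week3", "week6", "week9")))
  class(out) <- "summary.do_result"
  out
}

#' @export
print.summary.do_result <- function(x, ...) {
  cat("Protocol", x$protocol, "- bridging day:",
      ifelse(is.na(x$bridging_day), "none", x$bridging_day), "\n")
  cat(sprintf("  bone area (mm^2) wk3/wk6/wk9: %.3g / %.3g / %.3g; final %.4g\n",
              x$weeks["week3"], x$weeks["week6"], x$weeks["week9"],
              x$final_bone_area))
  cat(sprintf("  final IFM %.4g mm\n", x$final_ifm))
  invisible(x)
}

#' @export
plot.do_result <- function(x, which = c("ifm", "bone"), ...) {
  which <- match.arg(which)
  if (which == "ifm") {
    if (is.null(x$ifm_series)) stop("no consolidation days recorded")
    graphics::plot(x$ifm_series$day, x$ifm_series$ifm, type = "b", pch = 16,
                   cex = 0.6, xlab = "day", ylab = "IFM (mm)",
                   main = paste("Interfragmentary movement -",
                                x$config$protocol$label), ...)
    graphics::abline(h = x$config$bridging_threshold, lty = 2)
  } else {
    graphics::plot(x$bone_area_series$day, x$bone_area_series$bone_area,
                   type = "l", xlab = "day", ylab = "bone area (mm^2)",
                   main = paste("Regenerated bone -",
                                x$config$protocol$label), ...)
  }
  invisible(x)
}

#' Run and rank several distraction protocols
#'
#' Runs each protocol under a shared configuration (the fixator is
#' calibrated once and reused, as the common boundary condition) and
#' tabulates bridging day, bone area at weeks 3/6/9, and the ordering
#' relative to the control protocol.
#'
#' @param labels Character vector of protocol labels (>= 2).
#' @param config A [do_config()]; its `protocol` field is overridden.
#' @param quiet Suppress progress messages.
#' @return An object of class `do_comparison`: a data.frame `table` plus
#'   the list of full results.
#' @export
compare_protocols <- function(labels, config = do_config(), quiet = TRUE) {
  if (length(labels) < 2) stop("need at least two protocols to compare")
  if (is.null(config$fixator)) {
    cal_geom <- config$geometry
    cal_geom$current_gap <- 15
    cal_mesh <- build_mesh(cal_geom, config$callus_size, config$bone_size)
    config$fixator <- calibrate_fixator(
      cal_mesh, config$lib, target_ifm = config$fixator_target_ifm,
      load = config$consolidation_load)
  }
  runs <- list(); rows <- list()
  for (lab in labels) {
    cfg <- config
    cfg$protocol <- parse_protocol(lab)
    res <- tryCatch(run_do(cfg, quiet = quiet), error = function(e) e)
    if (inherits(res, "error")) {
      warning("protocol ", lab, " failed: ", conditionMessage(res))
      rows[[lab]] <- data.frame(protocol = lab, bridging_day = NA_real_,
                                week3 = NA_real_, week6 = NA_real_,
                                week9 = NA_real_, final_bone_area = NA_real_)
      next
    }
    runs[[lab]] <- res
    s <- summary(res)
    rows[[lab]] <- data.frame(protocol = lab, bridging_day = s$bridging_day,
                              week3 = s$weeks["week3"],
                              week6 = s$weeks["week6"],
                              week9 = s$weeks["week9"],
                              final_bone_area = s$final_bone_area)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if ("control" %in% tab$protocol) {
    ctrl <- tab$bridging_day[tab$protocol == "control"]
    tab$vs_control <- ifelse(is.na(tab$bridging_day) | is.na(ctrl), NA,
                             ifelse(tab$bridging_day < ctrl, "earlier",
                                    ifelse(tab$bridging_day > ctrl,
                                           "later", "equal")))
  }
  structure(list(table = tab, runs = runs, config = config),
            class = "do_comparison")
}

#' @export
print.do_comparison <- function(x, ...) {
  cat("Protocol comparison (bridging day; bone area mm^2 at wk 3/6/9):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
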