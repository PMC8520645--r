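#' Lumen blood-flow treatment
#'
#' The lumen blood can be treated three ways: \code{"advective"} (plug flow
#' at \code{velocity} along the artery axis, implicit upwind, inflow at
#' arterial temperature), \code{"clamped"} (blood held at the arterial
#' temperature, the infinite-convection limit) or \code{"static"} (pure
#' conduction, no flow).
#'
#' @param velocity plug-flow speed, m/s.
#' @param enabled logical; \code{FALSE} forces static blood.
#' @param blood_mode one of \code{"advective"}, \code{"clamped"},
#'   \code{"static"}.
#' @param direction +1 for flow toward +x (negative electrode upstream,
#'   positive electrode downstream), -1 for the reverse.
#' @export
flow_params <- function(velocity = 0.7, enabled = TRUE,
                        blood_mode = c("advective", "clamped", "static"),
                        direction = 1L) {
  blood_mode <- match.arg(blood_mode)
  if (velocity < 0) stop("flow velocity must be nonnegative")
  if (!enabled) blood_mode <- "static"
  structure(list(velocity = velocity, enabled = enabled,
                 blood_mode = blood_mode, direction = as.integer(sign(direction))),
            class = "flow_params")
}

#' Initial thermal state
#'
#' @param model a \code{voxel_model}.
#' @param T0 initial temperature, C (scalar or array).
#' @return a \code{thermal_state}: temperature field \code{T}, elapsed time
#'   \code{t}, cumulative per-voxel seconds at or above the damage
#'   temperature \code{time_above}, and the running maximum \code{Tmax}.
#' @export
thermal_state <- function(model, T0 = model$initial_temperature) {
  n <- model$grid$n
  T <- if (length(T0) == 1L) array(T0, n) else array(as.numeric(T0), n)
  structure(list(T = T, t = 0, time_above = array(0, n), Tmax = T),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("<thermal_state> t = %.3g s, T in [%.2f, %.2f] C, %d voxels with dwell > 0\n",
              x$t, min(x$T), max(x$T), sum(x$time_above > 0)))
  invisible(x)
}

# precomputed thermal coefficient arrays for a model (labels are static)
thermal_coeffs <- function(model, perfusion = perfusion_params(),
                           flow = flow_params(enabled = FALSE),
                           table = material_table()) {
  n <- model$grid$n
  h <- model$grid$spacing
  mv <- material_vectors(table)
  lab <- as.vector(model$labels)
  kth <- mv$k_thermal[lab]
  cvol <- mv$density[lab] * mv$heat_capacity[lab]
  nofalse <- logical(length(lab))
  g <- face_conductance_cpp(n, kth, nofalse, nofalse, h)
  # Dirichlet boundary at the initial/body temperature through half cells
  kb <- numeric(length(lab))
  if (identical(model$thermal_boundary, "dirichlet")) {
    kbarr <- array(0, n)
    karr <- kth; dim(karr) <- n
    ix <- lapply(n, seq_len)
    for (axis in 1:3) for (side in c(1L, n[axis])) {
      idx <- ix; idx[[axis]] <- side
      sl <- do.call(`[`, c(list(karr), idx))
      cur <- do.call(`[`, c(list(kbarr), idx))
      kbarr <- do.call(`[<-`, c(list(kbarr), idx, list(cur + 2 * sl * h)))
    }
    if (identical(flow$blood_mode, "advective")) {
      # outflow face of the lumen is zero-gradient, handled by the sweep
      out_i <- if (flow$direction >= 0) n[1] else 1L
      idx <- ix; idx[[1]] <- out_i
      bl <- do.call(`[`, c(list(model$labels), idx)) == MAT[["blood"]]
      cur <- do.call(`[`, c(list(kbarr), idx))
      cur[bl] <- 0
      kbarr <- do.call(`[<-`, c(list(kbarr), idx, list(cur)))
    }
    kb <- as.vector(kbarr)
  }
  perf <- numeric(length(lab))
  if (perfusion$perfusion_rate > 0) {
    sel <- lab %in% c(MAT[["artery_wall"]], MAT[["connective_tissue"]])
    perf[sel] <- perfusion$perfusion_rate * perfusion$blood_density *
      perfusion$blood_heat_capacity
  }
  soft <- lab %in% c(MAT[["blood"]], MAT[["artery_wall"]],
                     MAT[["connective_tissue"]], MAT[["gel"]])
  blood <- lab == MAT[["blood"]]
  clamp <- if (identical(flow$blood_mode, "clamped")) blood
           else logical(length(blood))
  list(kx = g$gx, ky = g$gy, kz = g$gz, kb = kb, cvol = cvol, perf = perf,
       soft = soft, blood = blood, clamp = clamp, h = h, n = n)
}

#' Largest stable explicit time step
#'
#' Stability bound of the explicit conduction update over the tissue, blood
#' and gel cells (stiff electrode-metal and insulator cells are advanced
#' point-implicitly and do not constrain the step).
#'
#' @param model a \code{voxel_model}.
#' @param perfusion,flow solver context (the perfusion sink tightens the
#'   bound slightly).
#' @return time step in seconds.
#' @export
stable_time_step <- function(model, perfusion = perfusion_params(),
                             flow = flow_params(enabled = FALSE)) {
  cf <- thermal_coeffs(model, perfusion, flow)
  stability_dt_cpp(cf$n, cf$kx, cf$ky, cf$kz, cf$kb, cf$cvol, cf$perf,
                   cf$h, cf$soft)
}

# one step on preallocated buffers; used by step_thermal and run_coupled.
# `qv` must be a plain numeric vector (no per-step copies).
.thermal_advance <- function(buf, cf, model, qv, perfusion, flow, dt, damage,
                             t_bound, Tref) {
  st <- thermal_step_cpp(cf$n, buf$Ta, buf$Tb, cf$kx, cf$ky, cf$kz, cf$kb,
                         t_bound, cf$cvol, qv, cf$perf,
                         perfusion$arterial_temperature, dt, cf$h,
                         cf$clamp, perfusion$arterial_temperature,
                         buf$time_above, damage$damage_temperature,
                         buf$Tmax, Tref)
  if (identical(flow$blood_mode, "advective") && flow$velocity > 0)
    advect_x_cpp(cf$n, buf$Tb, cf$blood, flow$velocity * dt / cf$h,
                 perfusion$arterial_temperature, flow$direction)
  tmp <- buf$Ta; buf$Ta <- buf$Tb; buf$Tb <- tmp
  list(buf = buf, max_temperature = st$max_temperature,
       max_drift = st$max_drift)
}

#' Advance the bioheat equation one time step
#'
#' Explicit finite-volume update of the Pennes equation
#' rho Cp dT/dt = div(k grad T) + q + rho_b Cp_b omega_b (T_b - T)
#' with harmonic-mean face conductivities across material interfaces,
#' Dirichlet boundary at the initial/body temperature, and the selected
#' blood treatment.  Cells whose local diffusion number exceeds the
#' explicit stability limit because of their material stiffness (the metal
#' shell) are advanced point-implicitly, which is unconditionally bounded.
#' The cumulative time at or above the damage temperature and the running
#' maximum temperature are updated.
#'
#' @param state a \code{thermal_state}.
#' @param model a \code{voxel_model}.
#' @param q Joule source field, W/m^3 (array or scalar).
#' @param perfusion a \code{\link{perfusion_params}}.
#' @param flow a \code{\link{flow_params}}.
#' @param dt time step, s; must not exceed \code{\link{stable_time_step}}.
#' @param damage a \code{\link{damage_params}} (for the dwell tracker).
#' @return the advanced \code{thermal_state}.
#' @export
step_thermal <- function(state, model, q = 0,
                         perfusion = perfusion_params(),
                         flow = flow_params(enabled = FALSE), dt,
                         damage = damage_params()) {
  cf <- thermal_coeffs(model, perfusion, flow)
  dt_max <- stability_dt_cpp(cf$n, cf$kx, cf$ky, cf$kz, cf$kb, cf$cvol,
                             cf$perf, cf$h, cf$soft)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("dt = %.4g s exceeds the explicit stability bound %.4g s",
                 dt, dt_max))
  qv <- if (length(q) == 1L) rep(as.numeric(q), prod(cf$n)) else as.vector(q)
  buf <- list(Ta = as.vector(state$T) + 0,  # force copies
              Tb = numeric(prod(cf$n)),
              time_above = as.vector(state$time_above) + 0,
              Tmax = as.vector(state$Tmax) + 0)
  adv <- .thermal_advance(buf, cf, model, qv, perfusion, flow, dt, damage,
                          model$initial_temperature, buf$Ta)
  if (!is.finite(adv$max_temperature))
    stop("bioheat step produced a non-finite temperature")
  out <- state
  out$T <- array(adv$buf$Ta, cf$n)
  out$time_above <- array(adv$buf$time_above, cf$n)
  out$Tmax <- array(adv$buf$Tmax, cf$n)
  out$t <- state$t + dt
  out
}

#' Coupled solver controls
#'
#' @param dt thermal step, s; \code{NA} picks half the explicit stability
#'   bound.
#' @param resolve_dT temperature drift (C) since the last electric solve
#'   that triggers a re-solve.
#' @param resolve_interval maximum simulated time (s) between electric
#'   solves.
#' @param resolve_min minimum simulated time (s) between drift-triggered
#'   solves, so that the sharp early transient cannot force a re-solve on
#'   every thermal step; a cadence-halving test bounds the effect.
#' @param tol CG relative tolerance for the coupling-loop solves; each solve
#'   is warm-started from the previous potential, and the terminal current
#'   and heat source are integrals that are insensitive at this level.
#'   (Stand-alone \code{\link{solve_potential}} defaults to 1e-8.)
#' @param maxit CG iteration budget.
#' @param max_temperature abort threshold, C (beyond model validity).
#' @param snapshot_interval simulated seconds between stored temperature
#'   snapshots (\code{NA}: store none; the final state is always returned).
#' @param verbose print per-solve progress.
#' @export
solver_controls <- function(dt = NA, resolve_dT = 1, resolve_interval = 1,
                            resolve_min = 0.25, tol = 1e-6, maxit = 50000L,
                            max_temperature = 150, snapshot_interval = NA,
                            verbose = FALSE) {
  structure(list(dt = dt, resolve_dT = resolve_dT,
                 resolve_interval = resolve_interval,
                 resolve_min = resolve_min, tol = tol,
                 maxit = as.integer(maxit), max_temperature = max_temperature,
                 snapshot_interval = snapshot_interval,
                 verbose = isTRUE(verbose)),
            class = "solver_controls")
}

#' Run the coupled electro-thermal simulation
#'
#' Alternates quasi-static electric solves and transient bioheat stepping.
#' The conductivity field is refreshed from the current temperature at
#' every electric re-solve; a re-solve is triggered when the temperature
#' anywhere has drifted more than \code{resolve_dT} since the last solve,
#' or after \code{resolve_interval} seconds of simulated time, whichever
#' comes first.  Each solve is warm-started from the previous potential.
#' Returns the final thermal state, the last potential solution, the
#' ablation-zone report (peak power over the run) and a per-solve log.
#'
#' @param model a \code{voxel_model}.
#' @param drive a \code{\link{drive_signal}}.
#' @param perfusion a \code{\link{perfusion_params}}.
#' @param flow a \code{\link{flow_params}}.
#' @param damage a \code{\link{damage_params}}.
#' @param t_end total simulated time, s.
#' @param controls a \code{\link{solver_controls}}.
#' @return a \code{coupled_result} list: \code{state}, \code{solution},
#'   \code{report}, \code{log} (data.frame of time, current, power, peak
#'   temperature), \code{model}.
#' @export
run_coupled <- function(model, drive = drive_signal(),
                        perfusion = perfusion_params(),
                        flow = flow_params(enabled = FALSE),
                        damage = damage_params(),
                        t_end = drive$duration,
                        controls = solver_controls(),
                        table = material_table()) {
  stopifnot(t_end > 0)
  cf <- thermal_coeffs(model, perfusion, flow, table)
  dt_max <- stability_dt_cpp(cf$n, cf$kx, cf$ky, cf$kz, cf$kb, cf$cvol,
                             cf$perf, cf$h, cf$soft)
  dt <- if (is.na(controls$dt)) 0.5 * dt_max else controls$dt
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("dt = %.4g s exceeds the explicit stability bound %.4g s",
                 dt, dt_max))
  npts <- prod(cf$n)
  buf <- list(Ta = rep(model$initial_temperature, npts),
              Tb = numeric(npts),
              time_above = numeric(npts),
              Tmax = rep(model$initial_temperature, npts))
  if (length(model$initial_temperature) > 1L)
    buf$Ta <- as.vector(model$initial_temperature)
  Tref <- buf$Ta + 0
  Vprev <- NULL
  t <- 0
  log_rows <- list()
  peak <- list(I = 0, P = 0, t = 0)
  sol <- NULL
  Tarr <- array(buf$Ta, cf$n)
  # boundary conductances depend on the boundary-cell conductivities, which
  # sit at the fixed boundary temperature: compute once
  gb0 <- boundary_conductance(model, sigma_field(model, Tarr, table = table))
  snapshots <- list()
  next_snap <- if (is.na(controls$snapshot_interval)) Inf
               else controls$snapshot_interval
  repeat {
    sig <- sigma_field(model, Tarr, table = table)
    sol <- solve_potential(model, sig, drive, tol = controls$tol,
                           maxit = controls$maxit, v0 = Vprev, gb = gb0)
    Vprev <- sol$V
    Tref <- buf$Ta + 0
    P <- drive$v_rms * sol$I_terminal
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(t = t, current_mA = 1e3 * sol$I_terminal, power_W = P,
                 max_T = max(buf$Ta), cg_iterations = sol$iterations)
    if (P > peak$P) peak <- list(I = sol$I_terminal, P = P, t = t)
    if (controls$verbose)
      message(sprintf("t = %6.2f s  I = %7.2f mA  P = %6.3f W  maxT = %6.2f C",
                      t, 1e3 * sol$I_terminal, P, max(buf$Ta)))
    if (t >= t_end - 1e-12) break
    t_solve <- t
    t_next <- min(t + controls$resolve_interval, t_end)
    qv <- as.vector(sol$q)
    repeat {
      step <- min(dt, t_next - t)
      adv <- .thermal_advance(buf, cf, model, qv, perfusion, flow, step,
                              damage, model$initial_temperature, Tref)
      buf <- adv$buf
      t <- t + step
      if (!is.finite(adv$max_temperature) ||
          adv$max_temperature > controls$max_temperature)
        stop(sprintf("temperature reached %.1f C at t = %.2f s: parameters are outside model validity",
                     adv$max_temperature, t))
      if (t >= next_snap - 1e-12) {
        snapshots[[length(snapshots) + 1L]] <-
          list(t = t, T = array(buf$Ta, cf$n))
        next_snap <- next_snap + controls$snapshot_interval
      }
      if (t >= t_next - 1e-12 ||
          (adv$max_drift > controls$resolve_dT &&
             t - t_solve >= controls$resolve_min - 1e-12)) break
    }
    Tarr <- array(buf$Ta, cf$n)
  }
  state <- structure(list(T = array(buf$Ta, cf$n), t = t,
                          time_above = array(buf$time_above, cf$n),
                          Tmax = array(buf$Tmax, cf$n)),
                     class = "thermal_state")
  lg <- do.call(rbind, log_rows)
  report <- ablation_report(state, model, damage,
                            power_report(peak$I, drive))
  structure(list(state = state, solution = sol, report = report, log = lg,
                 snapshots = snapshots, model = model, drive = drive,
                 perfusion = perfusion, flow = flow, damage = damage),
            class = "coupled_result")
}

#' @export
print.coupled_result <- function(x, ...) {
  cat(sprintf("<coupled_result> %s scenario, %.4g s simulated, %d electric solves\n",
              x$model$scenario, x$state$t, nrow(x$log)))
  print(x$report)
  invisible(x)
}

#' Volume-averaged bulk lumen blood temperature
#'
#' Mean temperature of the lumen blood voxels excluding a margin next to
#' the artery wall (the thin heated boundary layer).
#'
#' @param result a \code{coupled_result} from the artery scenario.
#' @param margin wall-exclusion distance, m.
#' @return temperature in degrees C.
#' @export
lumen_bulk_temperature <- function(result, margin = 0.5e-3) {
  model <- result$model
  if (!identical(model$scenario, "artery"))
    stop("lumen temperature is defined for the artery scenario")
  co <- coordinate_fields(model$grid)
  r <- sqrt(co$y^2 + co$z^2)
  lumen_r <- model$artery$lumen_diameter / 2
  sel <- as.vector(model$labels) == MAT[["blood"]] & r < lumen_r - margin
  mean(as.vector(result$state$T)[sel])
}

#' Peak downstream inner-wall temperature outside the ablation footprint
#'
#' Maximum temperature over the inner artery-wall surface voxels downstream
#' of the downstream electrode, excluding the damage footprint dilated by
#' \code{border} voxels: the warmed plume carried along the wall by the
#' blood flow.
#'
#' @param result a \code{coupled_result} from an advective-blood artery run.
#' @param border dilation of the excluded damage footprint, voxels.
#' @return temperature in degrees C.
#' @export
downstream_wall_peak <- function(result, border = 2L) {
  model <- result$model
  if (!identical(model$scenario, "artery"))
    stop("wall plume is defined for the artery scenario")
  lab <- model$labels
  blood <- lab == MAT[["blood"]]
  wall <- lab == MAT[["artery_wall"]]
  inner <- wall & dilate_mask(blood, 1L)
  dirn <- result$flow$direction %||% 1L
  co <- coordinate_fields(model$grid)
  xarr <- array(co$x, model$grid$n)
  emask <- model$eid == (if (dirn >= 0) 2L else 1L)
  edge <- if (dirn >= 0) max(xarr[emask]) else min(xarr[emask])
  downstream <- if (dirn >= 0) xarr > edge else xarr < edge
  excl <- dilate_mask(result$report$mask, as.integer(border))
  sel <- inner & downstream & !excl
  if (!any(sel)) return(NA_real_)
  max(result$state$T[sel])
}

# binary dilation by n steps of the 6-neighbourhood
dilate_mask <- function(mask, steps = 1L) {
  n <- dim(mask)
  for (s in seq_len(steps)) {
    out <- mask
    for (axis in 1:3) for (by in c(-1L, 1L)) {
      src <- dst <- lapply(n, seq_len)
      if (by == 1L) {
        dst[[axis]] <- seq_len(n[axis] - 1L) + 1L
        src[[axis]] <- seq_len(n[axis] - 1L)
      } else {
        dst[[axis]] <- seq_len(n[axis] - 1L)
        src[[axis]] <- seq_len(n[axis] - 1L) + 1L
      }
      shifted <- do.call(`[`, c(list(mask), src))
      cur <- do.call(`[`, c(list(out), dst))
      out <- do.call(`[<-`, c(list(out), dst, list(cur | shifted)))
    }
    mask <- out
  }
  mask
}
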