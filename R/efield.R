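#' Sinusoidal drive signal
#'
#' The quasi-static solve is performed once per coupling step at the RMS
#' differential voltage, so that the Joule source sigma * |E_rms|^2 equals
#' the cycle-averaged resistive dissipation and the reported power is
#' exactly V_RMS * I.
#'
#' @param v_pp peak-to-peak differential voltage, V.
#' @param frequency Hz.
#' @param duration application time, s.
#' @export
drive_signal <- function(v_pp = 60, frequency = 5e5, duration = 60) {
  if (v_pp < 0) stop("v_pp must be nonnegative")
  structure(list(v_pp = v_pp, frequency = frequency, duration = duration,
                 v_rms = v_pp / (2 * sqrt(2))),
            class = "drive_signal")
}

#' @export
print.drive_signal <- function(x, ...) {
  cat(sprintf("<drive_signal> %.4g Vp-p (%.4g V RMS) at %.4g kHz for %.4g s\n",
              x$v_pp, x$v_rms, x$frequency / 1e3, x$duration))
  invisible(x)
}

# half-cell conductance to the grounded outer boundary, per voxel
boundary_conductance <- function(model, sigma) {
  n <- model$grid$n
  h <- model$grid$spacing
  gb <- array(0, n)
  if (identical(model$electric_boundary, "grounded")) {
    add <- function(idx) {
      sl <- do.call(`[`, c(list(sigma), idx))
      cur <- do.call(`[`, c(list(gb), idx))
      do.call(`[<-`, c(list(gb), idx, list(cur + 2 * sl * h)))
    }
    ix <- lapply(n, seq_len)
    for (axis in 1:3) for (side in c(1L, n[axis])) {
      idx <- ix
      idx[[axis]] <- side
      gb <- add(idx)
    }
    # metal cells are Dirichlet already; no boundary face there
    gb[model$eid > 0L] <- 0
  }
  gb
}

#' Solve the quasi-static potential
#'
#' Finite-volume solve of div(sigma grad V) = 0 with the positive terminal
#' at +v_rms/2, the negative terminal at -v_rms/2 (the electrode metal is
#' treated as an equipotential Dirichlet region), and, in the artery
#' scenario, the far outer boundary grounded at 0 V through half-cell
#' conductances.  Face conductances are harmonic means of the two cell
#' conductivities; insulation-coated metal faces carry no current.  The
#' sparse system is solved by Jacobi-preconditioned conjugate gradients
#' (deterministic), optionally warm-started from a previous solution.
#'
#' @param model a \code{voxel_model}.
#' @param sigma per-voxel conductivity array (S/m); defaults to the field
#'   at the model's initial temperature.
#' @param drive a \code{\link{drive_signal}}.
#' @param tol relative residual tolerance.
#' @param maxit iteration budget.
#' @param v0 optional warm-start potential field.
#' @return a \code{potential_solution}: the potential field \code{V} (RMS
#'   convention), the Joule source field \code{q} (W/m^3), the terminal
#'   current \code{I_terminal} (A, out of the positive terminal),
#'   \code{I_neg}, boundary leakage current, residual and iteration count.
#' @export
solve_potential <- function(model, sigma = sigma_field(model),
                            drive = drive_signal(), tol = 1e-8,
                            maxit = 50000L, v0 = NULL, gb = NULL) {
  n <- model$grid$n
  h <- model$grid$spacing
  stopifnot(all(dim(sigma) == n))
  if (any(sigma < 0)) stop("sigma_field must be nonnegative")
  sigv <- as.vector(sigma)
  # bulk faces, then embedded-boundary window faces with conductance
  # sigma_t h^2 / d to the analytic tube surface.  Models without a contact
  # structure (e.g. hand-built test fixtures) conduct through the faces of
  # voxels marked exposed instead.
  exposed <- if (is.null(model$contacts)) as.vector(model$exposed)
             else logical(prod(n))
  g <- face_conductance_cpp(n, sigv, as.vector(model$eid > 0L), exposed, h)
  if (!is.null(model$contacts)) {
    nm <- c("gx", "gy", "gz")
    for (ax in 1:3) {
      ct <- model$contacts[[ax]]
      if (length(ct$index))
        g[[nm[ax]]][ct$index] <- sigv[ct$tissue] * h^2 / ct$d
    }
  }
  unknown <- as.vector(sigma > 0 & model$eid == 0L)
  vfix <- numeric(prod(n))
  vfix[as.vector(model$eid) == 2L] <- +drive$v_rms / 2
  vfix[as.vector(model$eid) == 1L] <- -drive$v_rms / 2
  if (is.null(gb)) gb <- boundary_conductance(model, sigma)
  x0 <- if (is.null(v0)) numeric(prod(n)) else as.vector(v0)
  sol <- cg_potential_cpp(n, g$gx, g$gy, g$gz, as.vector(gb), unknown, vfix,
                          x0, tol, as.integer(maxit))
  if (drive$v_rms > 0 && sol$bnorm == 0)
    stop("terminal is disconnected: no conducting path leaves the electrodes")
  if (sol$relres > tol)
    stop(sprintf("potential solve did not converge (relative residual %.3g after %d iterations)",
                 sol$relres, sol$iterations))
  cur <- terminal_current_cpp(n, g$gx, g$gy, g$gz, as.vector(gb), sol$V,
                              as.vector(model$eid), unknown)
  q <- joule_field_cpp(n, g$gx, g$gy, g$gz, as.vector(gb), sol$V, unknown, h)
  V <- sol$V; dim(V) <- n
  dim(q) <- n
  structure(list(V = V, q = q,
                 I_terminal = cur$I[2], I_neg = cur$I[1],
                 I_leak = cur$leak,
                 residual = sol$relres, iterations = sol$iterations,
                 drive = drive, spacing = h),
            class = "potential_solution")
}

#' @export
print.potential_solution <- function(x, ...) {
  cat(sprintf("<potential_solution> I = %.3f mA (residual %.2g, %d CG iterations)\n",
              1e3 * x$I_terminal, x$residual, x$iterations))
  cat(sprintf("  total dissipated power %.4g W\n",
              sum(x$q) * x$spacing^3))
  invisible(x)
}

#' Joule heat source field
#'
#' Volumetric resistive dissipation sigma |E_rms|^2 per voxel, computed
#' from the face currents of the converged solve so that its volume
#' integral balances V_RMS * I to solver accuracy.
#'
#' @param sol a \code{potential_solution}.
#' @return array of W/m^3.
#' @export
joule_heat <- function(sol) sol$q

#' Electric field magnitude
#'
#' Central-difference |grad V| on the voxel grid, for inspection/export.
#'
#' @param sol a \code{potential_solution}.
#' @return array of V/m.
#' @export
efield_magnitude <- function(sol) {
  V <- sol$V
  h <- sol$spacing
  n <- dim(V)
  grad1 <- function(axis) {
    ip <- im <- lapply(n, seq_len)
    ip[[axis]] <- pmin(ip[[axis]] + 1L, n[axis])
    im[[axis]] <- pmax(im[[axis]] - 1L, 1L)
    d <- do.call(`[`, c(list(V), ip)) - do.call(`[`, c(list(V), im))
    denom <- (ip[[axis]] - im[[axis]])[slice.index(V, axis)] * h
    d / denom
  }
  sqrt(grad1(1)^2 + grad1(2)^2 + grad1(3)^2)
}

#' Terminal power report
#'
#' Mirrors the drive/current/power row schema of a bipolar RF ablation
#' bench log: peak-to-peak and RMS voltage, terminal current in mA, and
#' power computed as V_RMS * I.
#'
#' @param sol a \code{potential_solution} (or a current in amperes).
#' @param drive a \code{\link{drive_signal}}.
#' @return a \code{power_report} list.
#' @export
power_report <- function(sol, drive = NULL) {
  I <- if (inherits(sol, "potential_solution")) sol$I_terminal else sol
  if (is.null(drive)) drive <- sol$drive
  structure(list(v_pp = drive$v_pp, v_rms = drive$v_rms,
                 current_mA = 1e3 * I, power_W = drive$v_rms * I),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("%8s %8s %12s %10s\n", "Vp-p", "V_RMS", "current (mA)", "power (W)"))
  cat(sprintf("%8.4g %8.4g %12.0f %10.2f\n", x$v_pp, x$v_rms, x$current_mA,
              x$power_W))
  invisible(x)
}

#' @export
format.power_report <- function(x, ...) {
  sprintf("Vpp=%g V, Vrms=%.2f V, I=%.0f mA, P=%.2f W",
          x$v_pp, x$v_rms, x$current_mA, x$power_W)
}
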