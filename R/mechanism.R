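#' Spherically symmetric electrolyte system
#'
#' Describes a charged sphere (a proteinoid microsphere decorated with CS
#' clusters) of radius `a` in an electrolyte, for the radial
#' Poisson-Boltzmann problem solved by [solve_pb_radial()]. The published
#' mechanism supplies no geometry or parameter values, so the defaults
#' (1 um sphere, 0.1 M 1:1 electrolyte, 298 K) are configuration, not
#' claims.
#'
#' @param a inner (sphere) radius, m.
#' @param R outer boundary radius, m (`R > a`); default `a` plus 30 Debye
#'   lengths, far enough that the screened potential has decayed.
#' @param sigma surface charge density at `r = a`, C/m^2.
#' @param ions data.frame with columns `z` (valence) and `c0` (bulk
#'   concentration, mol/m^3); must be bulk-electroneutral. Default 0.1 M
#'   1:1 (100 mol/m^3 of +1 and -1).
#' @param eps_r relative permittivity (default 78.5, water at 298 K).
#' @param temperature_K temperature, K.
#' @param rho_f fixed charge density in the electrolyte, C/m^3: a
#'   constant or a function of r (default 0; CS fixed charge can be
#'   supplied here).
#' @return object of class `electrolyte_system`.
#' @export
electrolyte_system <- function(a = 1e-6, R = NULL, sigma = 1e-4,
                               ions = data.frame(z = c(1, -1),
                                                 c0 = c(100, 100)),
                               eps_r = 78.5, temperature_K = 298,
                               rho_f = 0) {
  stopifnot(a > 0, temperature_K > 0, eps_r > 0,
            all(c("z", "c0") %in% names(ions)), all(ions$c0 > 0))
  if (abs(sum(ions$z * ions$c0)) > 1e-9 * sum(abs(ions$z) * ions$c0)) {
    stop("bulk electrolyte must be electroneutral", call. = FALSE)
  }
  eps <- .eps0 * eps_r
  kT <- .kB * temperature_K
  # Debye screening parameter kappa^2 = e^2 NA sum(z^2 c0) / (eps kT)
  kappa2 <- .qe^2 * .NA_const * sum(ions$z^2 * ions$c0) / (eps * kT)
  if (is.null(R)) R <- a + 30 / sqrt(kappa2)
  stopifnot(R > a)
  structure(list(a = a, R = R, sigma = sigma, ions = ions, eps_r = eps_r,
                 temperature_K = temperature_K, rho_f = rho_f,
                 kappa = sqrt(kappa2), lambda_D = 1 / sqrt(kappa2)),
            class = "electrolyte_system")
}

#' Solve the radial Poisson-Boltzmann equation
#'
#' Finite-difference solution of the spherically symmetric
#' Poisson-Boltzmann problem
#' \deqn{\frac{1}{r^2}\frac{d}{dr}\Big(\epsilon r^2
#'   \frac{d\psi}{dr}\Big) = -\rho_f(r) -
#'   \sum_i z_i F c_i^0 e^{-z_i e \psi / k_B T}}
#' with a Neumann inner boundary (`-eps dpsi/dr|_a = sigma`) and a
#' Dirichlet outer boundary (`psi(R) = 0`), by damped Newton iteration on
#' the dimensionless potential `u = e psi / kB T` until the residual
#' max-norm falls below `tol` relative to the source scale.
#'
#' In the small-charge limit the solution reproduces the linearized
#' Debye-Huckel profile
#' `psi(r) = sigma a^2 / (eps (1 + kappa a)) * exp(-kappa (r - a)) / r`.
#'
#' @param system an [electrolyte_system()].
#' @param n_grid number of radial grid points.
#' @param tol relative residual tolerance for the Newton iteration.
#' @param max_iter maximum Newton iterations.
#' @return list with `r` (m), `psi` (V), `u` (dimensionless),
#'   `iterations`, `residual`.
#' @examples
#' sys <- electrolyte_system(sigma = 1e-5)
#' sol <- solve_pb_radial(sys)
#' sol$psi[1]  # surface potential, V
#' @export
solve_pb_radial <- function(system, n_grid = 400L, tol = 1e-10,
                            max_iter = 200L) {
  stopifnot(inherits(system, "electrolyte_system"), n_grid >= 10L)
  eps <- .eps0 * system$eps_r
  kT <- .kB * system$temperature_K
  beta_e <- .qe / kT              # converts V to dimensionless u
  lD <- system$lambda_D
  # dimensionless radius x = r / lambda_D, potential u = e psi / kB T;
  # in these variables the source term is O(1) and for a symmetric
  # electrolyte linearizes to exactly u.
  r <- seq(system$a, system$R, length.out = n_grid)
  x <- r / lD
  h <- x[2L] - x[1L]
  rho_f <- if (is.function(system$rho_f)) {
    vapply(r, system$rho_f, numeric(1))
  } else rep(system$rho_f, n_grid)
  zs <- system$ions$z
  cs <- system$ions$c0
  scl <- beta_e * lD^2 / eps      # converts C/m^3 to the scaled source
  src_f <- scl * rho_f
  src_m <- function(u) {          # scaled mobile-charge source
    vapply(u, function(ui)
      scl * sum(zs * .qe * .NA_const * cs * exp(-zs * ui)), numeric(1))
  }
  dsrc_m <- function(u) {
    vapply(u, function(ui)
      -scl * sum(zs^2 * .qe * .NA_const * cs * exp(-zs * ui)), numeric(1))
  }
  bc <- system$sigma * beta_e * lD / eps   # scaled Neumann flux
  conv_scale <- max(1, abs(bc), max(abs(src_f)))
  residual <- function(u) {
    res <- numeric(n_grid)
    i <- 2:(n_grid - 1L)
    xp <- x[i] + h / 2
    xm <- x[i] - h / 2
    lap <- (xp^2 * (u[i + 1L] - u[i]) - xm^2 * (u[i] - u[i - 1L])) /
      (h^2 * x[i]^2)
    res[i] <- lap + src_f[i] + src_m(u[i])
    # Neumann at x_a (second-order one-sided): du/dx = -bc
    res[1L] <- (-3 * u[1L] + 4 * u[2L] - u[3L]) / (2 * h) + bc
    res[n_grid] <- u[n_grid]  # Dirichlet psi(R) = 0
    res
  }
  jacobian <- function(u) {
    J <- matrix(0, n_grid, n_grid)
    i <- 2:(n_grid - 1L)
    xp <- x[i] + h / 2
    xm <- x[i] - h / 2
    J[cbind(i, i - 1L)] <- xm^2 / (h^2 * x[i]^2)
    J[cbind(i, i + 1L)] <- xp^2 / (h^2 * x[i]^2)
    J[cbind(i, i)] <- -(xp^2 + xm^2) / (h^2 * x[i]^2) + dsrc_m(u[i])
    J[1L, 1:3] <- c(-3, 4, -1) / (2 * h)
    J[n_grid, n_grid] <- 1
    J
  }
  u <- numeric(n_grid)
  res <- residual(u)
  iter <- 0L
  converged <- max(abs(res)) <= tol * conv_scale
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    step <- solve(jacobian(u), -res)
    lambda <- 1
    repeat {   # damping: halve the step until the residual norm decreases
      u_new <- u + lambda * step
      res_new <- residual(u_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    u <- u_new
    res <- res_new
    # converged when the residual meets tolerance or the Newton update
    # is negligible (residual at its round-off floor)
    converged <- max(abs(res)) <= tol * conv_scale ||
      max(abs(lambda * step)) <= 1e-12 * max(1, max(abs(u)))
  }
  if (!converged) {
    stop(sprintf("PB solver did not converge in %d iterations", max_iter),
         call. = FALSE)
  }
  list(r = r, psi = u / beta_e, u = u, iterations = iter,
       residual = max(abs(res)))
}

#' Boltzmann open probability of an ion channel
#'
#' `P_open = 1 / (1 + exp(dG / (kB T)))`, the two-state Boltzmann gating
#' model; `dG` is the open-minus-closed Gibbs free energy difference,
#' which the CS-proteinoid surface interaction is proposed to shift.
#'
#' @param dG free-energy difference, J (vectorized).
#' @param temperature_K temperature, K.
#' @return open probability in (0, 1); strictly decreasing in `dG`.
#' @examples
#' channel_open_probability(0, 298)  # 0.5
#' @export
channel_open_probability <- function(dG, temperature_K = 298) {
  stopifnot(temperature_K > 0)
  stats::plogis(-dG / (.kB * temperature_K))
}

#' Multi-conductance membrane model
#'
#' Conductance-based membrane: `Cm dV/dt = -sum_i g_i (V - E_i) + I_ext`
#' with effective conductances `g_i = gbar_i * P_open(dG_i, T)`.
#' Consistent unit set: `Cm` in uF/cm^2, conductances in mS/cm^2, `E` in
#' mV, `I_ext` in uA/cm^2, time in ms.
#'
#' @param Cm membrane capacitance per area, uF/cm^2.
#' @param channels data.frame with columns `gbar` (mS/cm^2), `E` (mV) and
#'   optionally `dG` (J; default 0, i.e. `P_open = 0.5`).
#' @param I_ext external current, uA/cm^2.
#' @param temperature_K temperature for the gating factor, K.
#' @return object of class `membrane_model` with the effective
#'   conductances in `$g`.
#' @export
membrane_model <- function(Cm = 1,
                           channels = data.frame(gbar = 0.3, E = -65),
                           I_ext = 0, temperature_K = 298) {
  stopifnot(Cm > 0, all(c("gbar", "E") %in% names(channels)),
            all(channels$gbar >= 0))
  dG <- if ("dG" %in% names(channels)) channels$dG else
    rep(0, nrow(channels))
  g <- channels$gbar * channel_open_probability(dG, temperature_K)
  structure(list(Cm = Cm, channels = channels, g = g, E = channels$E,
                 I_ext = I_ext, temperature_K = temperature_K),
            class = "membrane_model")
}

#' Steady-state potential of a membrane model
#'
#' The algebraic fixed point `V* = (sum_i g_i E_i + I_ext) / sum_i g_i`
#' (undefined when the total conductance is zero).
#'
#' @param model a [membrane_model()].
#' @return steady-state potential, mV (`NA` for a pure capacitor).
#' @export
membrane_steady_state <- function(model) {
  stopifnot(inherits(model, "membrane_model"))
  g_tot <- sum(model$g)
  if (g_tot == 0) return(NA_real_)
  (sum(model$g * model$E) + model$I_ext) / g_tot
}

#' Integrate the membrane equation
#'
#' With constant effective conductances the equation is linear, so the
#' exponential-Euler update is exact per step:
#' `V <- V* + (V - V*) exp(-dt g_tot / Cm)`; a pure capacitor
#' (`g_tot = 0`) integrates to a linear ramp `I_ext / Cm`.
#'
#' @param model a [membrane_model()].
#' @param V0 initial potential, mV.
#' @param duration integration time, ms.
#' @param dt step, ms.
#' @return list with `times` (ms) and `V` (mV).
#' @export
simulate_membrane <- function(model, V0, duration, dt = 0.01) {
  stopifnot(inherits(model, "membrane_model"), dt > 0, duration >= dt)
  n <- floor(duration / dt) + 1L
  times <- (seq_len(n) - 1) * dt
  g_tot <- sum(model$g)
  if (g_tot == 0) {
    V <- V0 + model$I_ext / model$Cm * times
  } else {
    V_inf <- membrane_steady_state(model)
    decay <- exp(-g_tot / model$Cm * times)
    V <- V_inf + (V0 - V_inf) * decay
  }
  stop_if_not_finite(V, "membrane potential")
  list(times = times, V = V)
}

#' Plastic network of microspheres with CS-dependent Hebbian learning
#'
#' Connection weights between microspheres evolve as
#' `dw_ij/dt = eta(CS_ij) * x_i * y_j`, where the learning rate depends
#' on the local CS concentration. The default rate function is a
#' saturating Michaelis form `eta0 * CS / (K + CS)`, bounded so that high
#' CS concentrations stabilize rather than runaway-potentiate.
#'
#' @param weights numeric matrix of connection weights w_ij.
#' @param cs_field matrix of local CS concentrations (mg/ml), same shape.
#' @param x,y activity vectors of the pre- (length nrow) and post-
#'   (length ncol) populations.
#' @param eta learning-rate function of CS concentration; must be
#'   nonnegative.
#' @param eta0,K parameters of the default saturating rate (1/s and
#'   mg/ml).
#' @param clip optional c(lo, hi) weight clipping bounds.
#' @return object of class `plastic_network`.
#' @export
plastic_network <- function(weights, cs_field, x, y,
                            eta = function(cs) eta0 * cs / (K + cs),
                            eta0 = 0.1, K = 2, clip = NULL) {
  weights <- as.matrix(weights)
  cs_field <- as.matrix(cs_field)
  stopifnot(all(dim(weights) == dim(cs_field)),
            length(x) == nrow(weights), length(y) == ncol(weights),
            all(is.finite(weights)), all(cs_field >= 0))
  force(eta0); force(K)
  structure(list(weights = weights, cs_field = cs_field,
                 x = as.numeric(x), y = as.numeric(y), eta = eta,
                 clip = clip),
            class = "plastic_network")
}

#' One Euler step of the CS-dependent Hebbian rule
#'
#' `w_ij <- w_ij + dt * eta(CS_ij) * x_i * y_j`, with optional clipping.
#'
#' @param network a [plastic_network()].
#' @param dt time step, s.
#' @return the network with updated weights.
#' @examples
#' net <- plastic_network(matrix(0, 2, 2), matrix(2, 2, 2),
#'                        x = c(1, 1), y = c(1, 1))
#' hebbian_step(net, dt = 1)$weights
#' @export
hebbian_step <- function(network, dt) {
  stopifnot(inherits(network, "plastic_network"), dt > 0)
  if (!all(is.finite(network$x)) || !all(is.finite(network$y))) {
    stop("non-finite activities", call. = FALSE)
  }
  rate <- network$eta(network$cs_field)
  if (any(rate < 0)) stop("learning rate must be nonnegative",
                          call. = FALSE)
  w <- network$weights + dt * rate * outer(network$x, network$y)
  if (!is.null(network$clip)) {
    w <- pmin(pmax(w, network$clip[1L]), network$clip[2L])
  }
  network$weights <- w
  network
}
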