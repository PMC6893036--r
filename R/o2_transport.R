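# Axisymmetric model of oxygen advection, hemoglobin buffering, diffusion
# and consumption around a dilating cortical arteriole.
#
# Geometry: a blood cylinder (radius R1) inside a tissue annulus (outer
# radius R2), length L_a, on a structured finite-volume (r, z) grid. Blood
# carries total oxygen c_T = alpha*P + 4*C_Hb*S(P) by Poiseuille advection
# (z-upwinded) while free oxygen alpha*P diffuses in r and z; tissue has
# diffusion and a uniform zero-order consumption CMRO2. The inlet oxygen
# tension is fixed; all other open tissue boundaries are no-flux. The
# nonlinear (Hb-buffered) steady and transient systems are solved by Newton
# iteration with a sparse Jacobian.

#' Parameters of the arteriole oxygen-transport model
#'
#' Lengths in micrometers, times in seconds, concentrations in uM, oxygen
#' tensions in mmHg. `cmro2_rest` is accepted in the conventional
#' umol cm^-3 min^-1 and converted internally to uM/s (1 umol cm^-3 min^-1 =
#' 1000/60 uM/s). Solubility, hemoglobin content and the saturation-curve
#' constants are preparation-dependent configuration with literature
#' defaults.
#'
#' @param L_a Axial length, um.
#' @param R1 Resting vessel radius, um.
#' @param R2 Tissue outer radius, um.
#' @param D_O2 Oxygen diffusivity, um^2/s.
#' @param alpha Oxygen solubility, uM/mmHg.
#' @param C_Hb Hemoglobin (tetramer) concentration in blood, uM.
#' @param p50,hill_n Hill saturation-curve parameters (mmHg, unitless).
#' @param mu Blood dynamic viscosity, Pa s.
#' @param v_center_rest Resting centerline velocity, um/s; sets the axial
#'   pressure difference `p1` which is then held fixed, so dilation raises
#'   flow as radius^4.
#' @param cmro2_rest Resting oxygen consumption, umol cm^-3 min^-1.
#' @param pao2_inlet_rest Resting inlet oxygen tension, mmHg.
#' @param poisson_ratio,mu_s,lambda_s Tissue elasticity constants (the
#'   near-incompressible tissue response enters the transport solution only
#'   through the volume-preserving wall remap; kept for reporting).
#' @param nr_blood,nr_tissue,nz Radial cells in blood/tissue and axial cells.
#' @param probe_r,probe_z Probe location for reported tissue oxygen; default
#'   mid-annulus, mid-length.
#' @return Object of class `o2_params`.
#' @export
o2_params <- function(L_a = 100, R1 = 9, R2 = 50, D_O2 = 2800,
                      alpha = 1.3, C_Hb = 2300,
                      p50 = 40, hill_n = 2.6,
                      mu = 3e-3, v_center_rest = 2000,
                      cmro2_rest = 3, pao2_inlet_rest = 35,
                      poisson_ratio = 0.45, mu_s = 2000, lambda_s = 18000,
                      nr_blood = 10, nr_tissue = 30, nz = 50,
                      probe_r = NULL, probe_z = NULL) {
  if (!(R2 > R1 && R1 > 0)) stop("need R2 > R1 > 0", call. = FALSE)
  if (any(c(L_a, D_O2, alpha, C_Hb, mu, cmro2_rest) <= 0)) {
    stop("transport coefficients must be positive", call. = FALSE)
  }
  if (hill_n < 1) stop("hill_n must be >= 1", call. = FALSE)
  p <- list(
    L_a = L_a, R1 = R1, R2 = R2, D_O2 = D_O2, alpha = alpha, C_Hb = C_Hb,
    p50 = p50, hill_n = hill_n, mu = mu, v_center_rest = v_center_rest,
    cmro2_rest = cmro2_rest, cmro2_um_s = cmro2_rest * 1000 / 60,
    pao2_inlet_rest = pao2_inlet_rest,
    poisson_ratio = poisson_ratio, mu_s = mu_s, lambda_s = lambda_s,
    nr_blood = nr_blood, nr_tissue = nr_tissue, nz = nz,
    probe_r = probe_r %||% (R1 + R2) / 2,
    probe_z = probe_z %||% L_a / 2
  )
  # pressure difference (Pa) giving the requested resting centerline velocity
  p$delta_p <- 4 * mu * L_a * v_center_rest / R1^2
  p$p1_mmHg <- p$delta_p / 133.322
  structure(p, class = "o2_params")
}

#' Hill oxygen saturation curve
#'
#' `S(P) = P^n / (P^n + p50^n)`: the equilibrium hemoglobin saturation at
#' free oxygen tension `P`. Strictly increasing with `S(p50) = 1/2`.
#'
#' @param po2 Oxygen tension(s), mmHg (>= 0).
#' @param params An [o2_params()] object (only `p50`, `hill_n` used).
#' @return Saturation in `[0, 1]`.
#' @export
hill_saturation <- function(po2, params = o2_params()) {
  if (any(po2 < 0)) stop("oxygen tension must be non-negative", call. = FALSE)
  pn <- po2^params$hill_n
  pn / (pn + params$p50^params$hill_n)
}

hill_slope <- function(po2, params) {
  # dS/dP, guarded at P = 0
  n <- params$hill_n
  p50n <- params$p50^n
  po2 <- pmax(po2, 1e-9)
  n * po2^(n - 1) * p50n / (po2^n + p50n)^2
}

#' Poiseuille axial velocity profile
#'
#' Parabolic Stokes-flow profile `v(r) = dp/(4 mu L) (radius^2 - r^2)` for a
#' cylinder of the given radius under the axial pressure difference
#' `delta_p` (Pa). With `delta_p` held at its resting calibration, the
#' centerline velocity scales as radius^2 and volumetric flow as radius^4.
#'
#' @param params An [o2_params()].
#' @param radius Current vessel radius, um.
#' @param delta_p Axial pressure difference, Pa; defaults to the resting
#'   calibration in `params`.
#' @param r Radial positions at which to evaluate, um.
#' @return Tibble with `r` and `v` (um/s); attributes `v_center` and `flow`
#'   (um^3/s).
#' @export
poiseuille_velocity <- function(params, radius = params$R1, delta_p = NULL,
                                r = seq(0, radius, length.out = 50)) {
  stopifnot(radius > 0)
  dp <- delta_p %||% params$delta_p
  coef <- dp / (4 * params$mu * params$L_a)
  v <- coef * (radius^2 - r^2)
  out <- tibble::tibble(r = r, v = v)
  attr(out, "v_center") <- coef * radius^2
  attr(out, "flow") <- pi * coef * radius^4 / 2
  out
}

# ---- grid and operator assembly ------------------------------------------

# Build the finite-volume geometry for a given current vessel radius.
# Tissue radii follow the volume-preserving quadratic remap of the resting
# annulus, so the outer boundary stays at R2; local CMRO2 is rescaled to
# keep its volume integral fixed.
o2_grid <- function(params, radius = params$R1, refine = 1) {
  nrb <- params$nr_blood * refine
  nrt <- params$nr_tissue * refine
  nz <- params$nz * refine
  rf_b <- seq(0, radius, length.out = nrb + 1)
  rf_t0 <- seq(params$R1, params$R2, length.out = nrt + 1) # resting faces
  # volume-preserving map of the resting annulus onto [radius, R2]
  rf_t <- sqrt(radius^2 + (rf_t0^2 - params$R1^2) *
    (params$R2^2 - radius^2) / (params$R2^2 - params$R1^2))
  rf <- c(rf_b, rf_t[-1])
  nr <- nrb + nrt
  rc <- (rf[-1] + rf[-(nr + 1)]) / 2
  zf <- seq(0, params$L_a, length.out = nz + 1)
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2
  dz <- diff(zf)[1]
  ring_area <- pi * (rf[-1]^2 - rf[-(nr + 1)]^2) # cross-section per ring
  vol <- ring_area * dz
  blood <- seq_len(nr) <= nrb
  list(
    nr = nr, nz = nz, nrb = nrb, rf = rf, rc = rc, zc = zc, dz = dz,
    ring_area = ring_area, vol = rep(vol, nz), blood = rep(blood, nz),
    blood_ring = blood, radius = radius
  )
}

# Sparse operators for a given grid: diffusion matrix `Ld` (acts on P,
# units uM um^3/s per mmHg, positive-definite sign convention
# F_diff = -Ld P + b_dir * P_in), advection matrix `Adv` (acts on c_T) and
# inlet vectors.
o2_operators <- function(params, grid, advection = TRUE) {
  nr <- grid$nr
  nz <- grid$nz
  idx <- function(i, j) (j - 1L) * nr + i
  dal <- params$D_O2 * params$alpha
  ii <- jj <- xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i
    jj[[k]] <<- j
    xx[[k]] <<- x
  }
  # radial conductances between ring i and i+1 (same for every j)
  gr <- dal * 2 * pi * grid$rf[2:nr] * grid$dz /
    (grid$rc[2:nr] - grid$rc[1:(nr - 1)])
  for (j in seq_len(nz)) {
    a <- idx(1:(nr - 1), j)
    b <- idx(2:nr, j)
    add(a, b, -gr)
    add(b, a, -gr)
    add(a, a, gr)
    add(b, b, gr)
  }
  # axial conductances between j and j+1 per ring
  gz <- dal * grid$ring_area / grid$dz
  for (j in seq_len(nz - 1L)) {
    a <- idx(1:nr, j)
    b <- idx(1:nr, j + 1L)
    add(a, b, -gz)
    add(b, a, -gz)
    add(a, a, gz)
    add(b, b, gz)
  }
  nun <- nr * nz
  b_dir <- numeric(nun) # inlet Dirichlet diffusive conductance (blood only)
  g_in <- dal * grid$ring_area / (grid$dz / 2)
  rows_in <- idx(seq_len(grid$nrb), 1L)
  add(rows_in, rows_in, g_in[seq_len(grid$nrb)])
  b_dir[rows_in] <- g_in[seq_len(grid$nrb)]
  Ld <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(nun, nun)
  )
  # advection: flow per blood ring through its cross-section, upwinded in z
  vprof <- poiseuille_velocity(params, radius = grid$radius,
    r = grid$rc[seq_len(grid$nrb)]
  )
  fflow <- vprof$v * grid$ring_area[seq_len(grid$nrb)] # um^3/s per ring
  ai <- aj <- ax <- list()
  aadd <- function(i, j, x) {
    k <- length(ai) + 1L
    ai[[k]] <<- i
    aj[[k]] <<- j
    ax[[k]] <<- x
  }
  b_adv <- numeric(nun)
  if (advection) {
    for (i in seq_len(grid$nrb)) {
      rows <- idx(i, seq_len(nz))
      aadd(rows, rows, rep(fflow[i], nz)) # outflow
      aadd(rows[-1L], rows[-nz], rep(-fflow[i], nz - 1L)) # inflow from j-1
      b_adv[rows[1L]] <- fflow[i] # inlet inflow carries c_T(P_in)
    }
  }
  Adv <- if (length(ai) > 0) {
    Matrix::sparseMatrix(
      i = unlist(ai), j = unlist(aj), x = unlist(ax),
      dims = c(nun, nun)
    )
  } else {
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(nun, nun))
  }
  list(Ld = Ld, Adv = Adv, b_dir = b_dir, b_adv = b_adv, flow = sum(fflow))
}

# Total oxygen concentration and its derivative w.r.t. P, per cell.
o2_ctotal <- function(P, blood, params) {
  blood <- rep_len(blood, length(P))
  S <- hill_saturation(pmax(P, 0), params)
  hb <- 4 * params$C_Hb
  ct <- params$alpha * P + hb * S * blood
  ctp <- params$alpha + hb * hill_slope(P, params) * blood
  list(ct = ct, ctp = ctp)
}

# Newton solve of  M (ct(P) - ct_old)/dt + Adv ct(P) - (-Ld P + b_dir P_in
#  + b_adv ct_in) + sink = 0.  Steady state: dt = Inf.
o2_newton <- function(P0, params, grid, ops, p_in, sink, dt = Inf,
                      ct_old = NULL, tol = 1e-8, max_iter = 60) {
  P <- P0
  ct_in <- o2_ctotal(p_in, TRUE, params)$ct
  bvec <- ops$b_dir * p_in + ops$b_adv * ct_in
  scale <- sum(abs(bvec)) + sum(abs(sink)) + 1e-300
  trans <- is.finite(dt)
  for (it in seq_len(max_iter)) {
    cc <- o2_ctotal(P, grid$blood, params)
    f <- as.numeric(ops$Adv %*% cc$ct) + as.numeric(ops$Ld %*% P) - bvec + sink
    if (trans) f <- f + grid$vol * (cc$ct - ct_old) / dt
    res <- sqrt(sum(f^2)) / scale
    if (res < tol) {
      return(list(P = P, residual = res, iterations = it - 1L, converged = TRUE))
    }
    J <- ops$Adv %*% Matrix::Diagonal(x = cc$ctp) + ops$Ld
    if (trans) J <- J + Matrix::Diagonal(x = grid$vol * cc$ctp / dt)
    dP <- as.numeric(Matrix::solve(J, -f))
    # damped update with simple backtracking
    step <- 1
    repeat {
      Pn <- P + step * dP
      ccn <- o2_ctotal(Pn, grid$blood, params)
      fn <- as.numeric(ops$Adv %*% ccn$ct) + as.numeric(ops$Ld %*% Pn) - bvec + sink
      if (trans) fn <- fn + grid$vol * (ccn$ct - ct_old) / dt
      if (sqrt(sum(fn^2)) <= sqrt(sum(f^2)) * (1 - 1e-4 * step) || step < 1 / 64) break
      step <- step / 2
    }
    P <- P + step * dP
  }
  list(P = P, residual = res, iterations = max_iter, converged = FALSE)
}

#' Steady-state oxygen field around a resting arteriole
#'
#' Solves the coupled blood advection-diffusion (with hemoglobin buffering)
#' and tissue diffusion-consumption equations to steady state on the
#' finite-volume grid. With `advection = FALSE` and a fixed `wall_po2` the
#' solver reduces to the classical annular diffusion-consumption problem,
#' for which [krogh_annulus_profile()] gives the closed form.
#'
#' @param params An [o2_params()].
#' @param radius_factor Fractional vessel radius relative to rest (1 = rest).
#' @param cmro2_factor CMRO2 relative to rest.
#' @param pao2_inlet Inlet oxygen tension, mmHg.
#' @param refine Integer grid refinement factor.
#' @param advection Include blood flow; `FALSE` solves pure diffusion.
#' @param wall_po2 If non-`NULL`, replaces the blood domain by a Dirichlet
#'   condition at the vessel wall (tissue-only solve).
#' @param tol Relative residual tolerance.
#' @return Object of class `o2_state` with the tension field `P`
#'   (matrix, radial x axial), the grid, probe values and balance terms.
#' @export
o2_steady_state <- function(params = o2_params(), radius_factor = 1,
                            cmro2_factor = 1, pao2_inlet = NULL,
                            refine = 1, advection = TRUE, wall_po2 = NULL,
                            tol = 1e-8) {
  p_in <- pao2_inlet %||% params$pao2_inlet_rest
  radius <- params$R1 * radius_factor
  grid <- o2_grid(params, radius, refine)
  cm <- params$cmro2_um_s * cmro2_factor *
    (params$R2^2 - params$R1^2) / (params$R2^2 - radius^2)
  if (!is.null(wall_po2)) {
    return(o2_steady_tissue_only(params, grid, cm, wall_po2, tol))
  }
  ops <- o2_operators(params, grid, advection = advection)
  sink <- ifelse(grid$blood, 0, cm) * grid$vol
  sol <- o2_newton(rep(p_in, grid$nr * grid$nz), params, grid, ops, p_in,
    sink,
    tol = tol
  )
  if (!sol$converged) {
    stop(sprintf(
      "steady state failed to converge (relative residual %.3g)",
      sol$residual
    ), call. = FALSE)
  }
  new_o2_state(params, grid, ops, sol, p_in, cm, sink)
}

new_o2_state <- function(params, grid, ops, sol, p_in, cm, sink) {
  P <- matrix(sol$P, grid$nr, grid$nz)
  st <- structure(
    list(
      params = params, grid = grid, ops = ops,
      P = P, p_in = p_in, cmro2_um_s = cm, sink = sink,
      residual = sol$residual, radius = grid$radius
    ),
    class = "o2_state"
  )
  st$probe <- o2_probe(st)
  st
}

# Tissue-only annulus with Dirichlet wall tension (Krogh configuration).
o2_steady_tissue_only <- function(params, grid, cm, wall_po2, tol) {
  sel <- !grid$blood_ring
  nrt <- sum(sel)
  nz <- grid$nz
  rf <- grid$rf[(grid$nrb + 1L):(grid$nr + 1L)]
  rc <- grid$rc[sel]
  dal <- params$D_O2 * params$alpha
  gr <- dal * 2 * pi * rf[2:nrt] * grid$dz / diff(rc)
  g_wall <- dal * 2 * pi * rf[1] * grid$dz / (rc[1] - rf[1])
  # one axial slice suffices (z-invariant problem); solve tridiagonal system
  main <- numeric(nrt)
  lower <- -gr
  upper <- -gr
  main[1] <- g_wall + gr[1]
  if (nrt > 2) main[2:(nrt - 1)] <- gr[1:(nrt - 2)] + gr[2:(nrt - 1)]
  main[nrt] <- gr[nrt - 1]
  vol_r <- pi * (rf[-1]^2 - rf[-(nrt + 1)]^2) * grid$dz
  rhs <- -cm * vol_r
  rhs[1] <- rhs[1] + g_wall * wall_po2
  A <- Matrix::bandSparse(nrt, nrt,
    k = c(-1, 0, 1),
    diagonals = list(lower, main, upper)
  )
  Pr <- as.numeric(Matrix::solve(A, rhs))
  P <- matrix(rep(c(rep(NA_real_, grid$nrb), Pr), nz), grid$nr, nz)
  st <- structure(
    list(
      params = params, grid = grid, ops = NULL, P = P, p_in = NA_real_,
      cmro2_um_s = cm, sink = NULL, residual = 0, radius = grid$radius,
      wall_po2 = wall_po2, tissue_profile = tibble::tibble(r = rc, po2 = Pr)
    ),
    class = "o2_state"
  )
  st$probe <- o2_probe(st)
  st
}

o2_probe <- function(state) {
  g <- state$grid
  ir <- which.min(abs(g$rc - state$params$probe_r))
  iz <- which.min(abs(g$zc - state$params$probe_z))
  tis <- !g$blood_ring
  w <- g$vol[rep(tis, g$nz)]
  pt_mean <- sum(state$P[tis, ] * matrix(w, sum(tis), g$nz), na.rm = TRUE) / sum(w)
  list(
    pto2_probe = state$P[ir, iz],
    pto2_mean = pt_mean,
    pao2_probe = if (g$nrb >= 1 && !is.na(state$P[1, iz])) state$P[1, iz] else NA_real_
  )
}

#' Closed-form Krogh annulus oxygen profile
#'
#' Radial oxygen tension in an annulus `R1 <= r <= R2` with uniform
#' consumption `M`, fixed wall tension at `R1` and zero flux at `R2`:
#' `P(r) = P_w + (M/(D alpha)) ((r^2 - R1^2)/4 - (R2^2/2) ln(r/R1))`.
#'
#' @param params An [o2_params()].
#' @param wall_po2 Wall oxygen tension, mmHg.
#' @param r Radial positions, um.
#' @param cmro2_factor Consumption relative to rest.
#' @return Tibble with `r` and `po2`.
#' @export
krogh_annulus_profile <- function(params, wall_po2, r, cmro2_factor = 1) {
  m <- params$cmro2_um_s * cmro2_factor
  coef <- m / (params$D_O2 * params$alpha)
  po2 <- wall_po2 + coef *
    ((r^2 - params$R1^2) / 4 - (params$R2^2 / 2) * log(r / params$R1))
  tibble::tibble(r = r, po2 = po2)
}

#' Oxygen balance audit of a steady state
#'
#' Compares net convective + diffusive oxygen influx at the vessel inlet and
#' outlet against the volume-integrated consumption. At a converged steady
#' state these agree to the solver tolerance; the relative error is reported
#' against the consumption.
#'
#' @param state An `o2_state` from [o2_steady_state()].
#' @return One-row tibble: `inflow`, `outflow`, `consumption` (uM um^3/s)
#'   and `rel_error`.
#' @export
o2_balance <- function(state) {
  g <- state$grid
  params <- state$params
  nrb <- g$nrb
  vprof <- poiseuille_velocity(params, radius = g$radius, r = g$rc[seq_len(nrb)])
  fflow <- vprof$v * g$ring_area[seq_len(nrb)]
  ct_in <- o2_ctotal(state$p_in, TRUE, params)$ct
  ct_out <- o2_ctotal(state$P[seq_len(nrb), g$nz], TRUE, params)$ct
  dal <- params$D_O2 * params$alpha
  g_in <- dal * g$ring_area[seq_len(nrb)] / (g$dz / 2)
  inflow <- sum(fflow * ct_in) + sum(g_in * (state$p_in - state$P[seq_len(nrb), 1]))
  outflow <- sum(fflow * ct_out)
  consumption <- sum(state$sink)
  tibble::tibble(
    inflow = inflow, outflow = outflow, consumption = consumption,
    rel_error = (inflow - outflow - consumption) / consumption
  )
}

#' @export
print.o2_state <- function(x, ...) {
  cat(sprintf(
    "<o2_state> %d x %d cells | radius %.3g um | probe PtO2 %.4g mmHg, mean tissue %.4g mmHg\n",
    x$grid$nr, x$grid$nz, x$radius, x$probe$pto2_probe, x$probe$pto2_mean
  ))
  invisible(x)
}

#' @export
tidy.o2_state <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    r = rep(g$rc, g$nz),
    z = rep(g$zc, each = g$nr),
    domain = rep(ifelse(g$blood_ring, "blood", "tissue"), g$nz),
    po2 = as.vector(x$P)
  )
}

#' @export
autoplot.o2_state <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$r, fill = .data$po2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(pO[2] ~ (mmHg))) +
    ggplot2::geom_hline(yintercept = object$radius, colour = "white", linewidth = 0.3) +
    ggplot2::labs(x = "axial position (um)", y = "radius (um)") +
    ggplot2::theme_minimal()
}

# ---- scenarios ------------------------------------------------------------

smooth_trapezoid <- function(t, t_on, t_off, ramp_up, ramp_down) {
  out <- numeric(length(t))
  up <- t >= t_on & t < t_on + ramp_up
  out[up] <- (1 - cos(pi * (t[up] - t_on) / ramp_up)) / 2
  out[t >= t_on + ramp_up & t <= t_off] <- 1
  dn <- t > t_off & t < t_off + ramp_down
  out[dn] <- (1 + cos(pi * (t[dn] - t_off) / ramp_down)) / 2
  out
}

#' Locomotion scenario for the transport model
#'
#' Bundles the three time-varying drivers: fractional vessel-radius change,
#' CMRO2 scaling, and inlet oxygen-tension offset. The built-in profiles are
#' smoothed trapezoids spanning a locomotion bout from `t_on` to `t_off`.
#'
#' @param name Scenario label.
#' @param dilation Plateau fractional radius change (0.10 = 10% dilation,
#'   negative for constriction).
#' @param cmro2_rise Plateau fractional CMRO2 increase.
#' @param pao2_rise Plateau inlet oxygen-tension increase, mmHg.
#' @param t_on,t_off Bout onset/offset, s.
#' @param ramp_up,ramp_down Ramp durations, s.
#' @return Object of class `o2_scenario` with functions `dilation(t)`,
#'   `cmro2_factor(t)`, `pao2_inlet_offset(t)`.
#' @export
o2_scenario <- function(name = "custom", dilation = 0, cmro2_rise = 0,
                        pao2_rise = 0, t_on = 5, t_off = 20,
                        ramp_up = 2, ramp_down = 4) {
  env <- function(t) smooth_trapezoid(t, t_on, t_off, ramp_up, ramp_down)
  structure(
    list(
      name = name,
      dilation = function(t) dilation * env(t),
      cmro2_factor = function(t) 1 + cmro2_rise * env(t),
      pao2_inlet_offset = function(t) pao2_rise * env(t),
      plateau = list(
        dilation = dilation, cmro2_rise = cmro2_rise,
        pao2_rise = pao2_rise
      ),
      t_on = t_on, t_off = t_off
    ),
    class = "o2_scenario"
  )
}

#' Forelimb/hindlimb cortex locomotion scenario
#'
#' 10% arteriolar dilation and a 15% CMRO2 increase during the bout, with a
#' systemic arterial oxygenation rise shared by all regions.
#'
#' @param pao2_rise Plateau inlet oxygenation increase, mmHg.
#' @param ... Passed to [o2_scenario()].
#' @return An `o2_scenario`.
#' @export
scenario_flhl <- function(pao2_rise = 3, ...) {
  o2_scenario("FLHL", dilation = 0.10, cmro2_rise = 0.15, pao2_rise = pao2_rise, ...)
}

#' Frontal cortex locomotion scenario
#'
#' 5% vessel constriction and a 4% CMRO2 increase during the bout; the same
#' systemic arterial oxygenation rise as [scenario_flhl()]. Set
#' `pao2_rise = 0` to isolate the local drivers.
#'
#' @inheritParams scenario_flhl
#' @return An `o2_scenario`.
#' @export
scenario_fc <- function(pao2_rise = 3, ...) {
  o2_scenario("FC", dilation = -0.05, cmro2_rise = 0.04, pao2_rise = pao2_rise, ...)
}

#' Neural-activity blockade scenario
#'
#' Pharmacological silencing removes the activity-dependent share of oxygen
#' consumption: `CMRO2 = CMRO2_rest (1 - activity_fraction x suppression)`,
#' with vessel dilation clamped to zero. With the default 75%
#' activity-dependent fraction suppressed by 82%, resting consumption of
#' 3 umol cm^-3 min^-1 falls to 1.2 (one decimal).
#'
#' @param params An [o2_params()].
#' @param activity_fraction Activity-dependent fraction of resting CMRO2.
#' @param suppression Fraction of the activity-dependent part removed.
#' @return An `o2_scenario` with a constant reduced CMRO2; its
#'   `cmro2_blockade` field gives the value in umol cm^-3 min^-1.
#' @export
blockade_scenario <- function(params = o2_params(), activity_fraction = 0.75,
                              suppression = 0.82) {
  if (activity_fraction < 0 || activity_fraction > 1 ||
    suppression < 0 || suppression > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  fac <- 1 - activity_fraction * suppression
  sc <- o2_scenario("blockade")
  sc$cmro2_factor <- function(t) rep(fac, length(t))
  sc$dilation <- function(t) rep(0, length(t))
  sc$plateau$cmro2_rise <- fac - 1
  sc$cmro2_blockade <- params$cmro2_rest * fac
  sc
}

# ---- time-dependent simulation -------------------------------------------

#' Simulate the transport model through a locomotion scenario
#'
#' Implicit-Euler time stepping from the resting steady state. Each step
#' rebuilds the grid for the current vessel radius (blood nodes move with
#' the wall; tissue nodes follow the volume-preserving remap, with the CMRO2
#' density rescaled so its volume integral tracks only the scenario's CMRO2
#' factor), then solves the Hb-buffered nonlinear system by Newton
#' iteration.
#'
#' @param params An [o2_params()].
#' @param scenario An [o2_scenario()].
#' @param t_end Simulation end time, s.
#' @param dt Time step, s.
#' @param refine Grid refinement factor.
#' @return An `o2_timecourse` tibble: `time`, `radius`, `v_center`,
#'   `pao2_in`, `pao2_probe`, `pto2_probe`, `pto2_mean`; attribute `state0`
#'   holds the resting steady state.
#' @export
o2_simulate <- function(params = o2_params(), scenario = o2_scenario(),
                        t_end = 40, dt = 0.1, refine = 1) {
  st0 <- o2_steady_state(params, refine = refine)
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  P <- as.vector(st0$P)
  grid <- st0$grid
  out <- tibble::tibble(
    time = times, radius = NA_real_, v_center = NA_real_, pao2_in = NA_real_,
    pao2_probe = NA_real_, pto2_probe = NA_real_, pto2_mean = NA_real_
  )
  fill_row <- function(k, state, p_in) {
    out$radius[k] <<- state$radius
    out$v_center[k] <<- attr(
      poiseuille_velocity(state$params, radius = state$radius, r = 0), "v_center"
    )
    out$pao2_in[k] <<- p_in
    out$pao2_probe[k] <<- state$probe$pao2_probe
    out$pto2_probe[k] <<- state$probe$pto2_probe
    out$pto2_mean[k] <<- state$probe$pto2_mean
  }
  fill_row(1L, st0, st0$p_in)
  state <- st0
  for (k in 2:n) {
    t_k <- times[k]
    radius <- params$R1 * (1 + scenario$dilation(t_k))
    if (radius <= 0) stop("scenario drives the vessel radius non-positive", call. = FALSE)
    p_in <- params$pao2_inlet_rest + scenario$pao2_inlet_offset(t_k)
    cmf <- scenario$cmro2_factor(t_k)
    grid_k <- o2_grid(params, radius, refine)
    ops_k <- o2_operators(params, grid_k)
    cm_k <- params$cmro2_um_s * cmf *
      (params$R2^2 - params$R1^2) / (params$R2^2 - radius^2)
    sink_k <- ifelse(grid_k$blood, 0, cm_k) * grid_k$vol
    ct_old <- o2_ctotal(P, grid_k$blood, params)$ct # carried on moving mesh
    sol <- o2_newton(P, params, grid_k, ops_k, p_in, sink_k,
      dt = dt,
      ct_old = ct_old, tol = 1e-8
    )
    if (!sol$converged) {
      stop(sprintf(
        "time step at t = %.3g s failed to converge (residual %.3g); reduce dt",
        t_k, sol$residual
      ), call. = FALSE)
    }
    P <- sol$P
    state <- new_o2_state(params, grid_k, ops_k, sol, p_in, cm_k, sink_k)
    fill_row(k, state, p_in)
  }
  attr(out, "state0") <- st0
  attr(out, "scenario") <- scenario$name
  class(out) <- c("o2_timecourse", class(out))
  out
}

#' @export
glance.o2_timecourse <- function(x, ...) {
  st0 <- attr(x, "state0")
  tibble::tibble(
    scenario = attr(x, "scenario"),
    pto2_rest = st0$probe$pto2_probe,
    dpto2_peak = max(x$pto2_probe) - st0$probe$pto2_probe,
    dpto2_trough = min(x$pto2_probe) - st0$probe$pto2_probe,
    t_end = max(x$time)
  )
}

#' @export
autoplot.o2_timecourse <- function(object, ...) {
  st0 <- attr(object, "state0")
  df <- tidyr::pivot_longer(
    dplyr::mutate(
      tibble::as_tibble(object),
      dPtO2 = .data$pto2_probe - st0$probe$pto2_probe,
      dPaO2 = .data$pao2_in - st0$p_in,
      radius_pct = 100 * (.data$radius / st0$radius - 1)
    )[c("time", "dPtO2", "dPaO2", "radius_pct")],
    -"time",
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Decompose a scenario's tissue-oxygen response into its drivers
#'
#' Runs the full scenario plus the three single-driver scenarios
#' (dilation-only, CMRO2-only, inlet-oxygenation-only) and reports each
#' tissue-oxygen change relative to rest, along with the additivity defect
#' (full response minus the sum of single-driver responses).
#'
#' @inheritParams o2_simulate
#' @return Tibble with `time`, `driver` and `dpto2`; attribute
#'   `additivity_defect` (max |defect| / max |full response|).
#' @export
o2_decompose <- function(params = o2_params(), scenario = scenario_flhl(),
                         t_end = 40, dt = 0.1, refine = 1) {
  base <- scenario$plateau
  single <- function(keep) {
    o2_scenario(
      name = keep,
      dilation = if (keep == "dilation") base$dilation else 0,
      cmro2_rise = if (keep == "cmro2") base$cmro2_rise else 0,
      pao2_rise = if (keep == "pao2_inlet") base$pao2_rise else 0,
      t_on = scenario$t_on, t_off = scenario$t_off
    )
  }
  runs <- list(
    full = o2_simulate(params, scenario, t_end, dt, refine),
    dilation = o2_simulate(params, single("dilation"), t_end, dt, refine),
    cmro2 = o2_simulate(params, single("cmro2"), t_end, dt, refine),
    pao2_inlet = o2_simulate(params, single("pao2_inlet"), t_end, dt, refine)
  )
  rest <- attr(runs$full, "state0")$probe$pto2_probe
  out <- purrr::imap_dfr(runs, function(r, nm) {
    tibble::tibble(time = r$time, driver = nm, dpto2 = r$pto2_probe - rest)
  })
  wide <- tidyr::pivot_wider(out, names_from = "driver", values_from = "dpto2")
  defect <- wide$full - (wide$dilation + wide$cmro2 + wide$pao2_inlet)
  attr(out, "additivity_defect") <- max(abs(defect)) / max(abs(wide$full))
  class(out) <- c("o2_decomposition", class(out))
  out
}

#' @export
autoplot.o2_decomposition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time, y = .data$dpto2,
    colour = .data$driver
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = expression(Delta * PtO[2] ~ (mmHg)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
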