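# 2-D finite-volume drift-diffusion solver for the Schottky-barrier RFET.
#
# Discretization: box method on the tensor mesh built by build_device().
# Node index k = i + (j-1)*nx, i along the channel, j through the film
# (j = 1 is the gated surface). Poisson has Dirichlet columns at the two
# Schottky contacts (barrier-pinned potential) and a mixed oxide-capacitance
# boundary on gated top-surface cells; carriers obey Scharfetter-Gummel
# edge fluxes with Robin (injection-velocity) conditions at the contacts,
# the Boltzmann linearization of the Tsu-Esaki flux whose tunneling
# enhancement is recomputed from the evolving band profile by WKB.

# Bernoulli function B(u) = u / (exp(u) - 1), overflow-safe, vectorized.
.bernoulli <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-10
  out[small] <- 1 - u[small] / 2
  big <- !small & u > 709          # e^u overflows; B(u) ~ u e^-u
  out[big] <- u[big] * exp(-u[big])
  mid <- !small & !big
  out[mid] <- u[mid] / expm1(u[mid])
  out
}

# Residual rhs - A x from triplet form with compensated arithmetic
# (Dekker two-product + Neumaier row sums). The continuity matrices carry
# edge fluxes many orders of magnitude above the net terminal currents, so
# a double-precision residual would be pure rounding noise and iterative
# refinement could not reach terminal-current conservation at the 1e-3
# level on femtoampere OFF currents.
.compensated_residual <- function(ti, tj, tv, x, rhs) {
  nn <- length(rhs)
  p <- tv * x[tj]
  splt <- function(a) {
    c <- 134217729 * a  # 2^27 + 1 Dekker split
    hi <- c - (c - a)
    list(hi = hi, lo = a - hi)
  }
  sa <- splt(tv); sb <- splt(x[tj])
  perr <- ((sa$hi * sb$hi - p) + sa$hi * sb$lo + sa$lo * sb$hi) +
    sa$lo * sb$lo
  ord <- order(ti)
  tab <- tabulate(ti[ord], nn)
  pos <- cbind(ti[ord], sequence(tab))
  P <- matrix(0, nn, max(tab))
  P[pos] <- p[ord]
  s <- numeric(nn); comp <- numeric(nn)
  for (k in seq_len(ncol(P))) {
    v <- P[, k]
    t <- s + v
    comp <- comp + ifelse(abs(s) >= abs(v), (s - t) + v, (v - t) + s)
    s <- t
  }
  err <- numeric(nn)
  esum <- rowsum(perr, ti, reorder = FALSE)
  err[as.integer(rownames(esum))] <- esum
  (rhs - s) - (comp + err)
}

# Bias-independent structure of the Poisson system on free nodes
# (columns 2..nx-1; contact columns are Dirichlet). Called by build_device.
.poisson_structure <- function(dev) {
  nx <- dev$nx; ny <- dev$ny
  nxf <- nx - 2L
  nfree <- nxf * ny
  kf <- function(i, j) (i - 1L) + (j - 1L) * nxf  # i in 2..nx-1
  dxc <- diff(dev$xs); dyc <- diff(dev$ys)
  eps <- dev$eps_si

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  add <- function(a, b, v) {
    ti <<- c(ti, a); tj <<- c(tj, b); tv <<- c(tv, v)
  }
  # x-edges among free columns: i = 2..nx-2 connects (i, i+1)
  jj <- rep(seq_len(ny), each = nx - 3L)
  ii <- rep(2:(nx - 2L), times = ny)
  g <- eps * dev$wy[jj] / dxc[ii]
  a <- kf(ii, jj); b <- kf(ii + 1L, jj)
  add(a, a, g); add(b, b, g); add(a, b, -g); add(b, a, -g)
  # x-edges to the Dirichlet contact columns
  jv <- seq_len(ny)
  g_src <- eps * dev$wy / dxc[1]          # edge (1,j)-(2,j)
  g_drn <- eps * dev$wy / dxc[nx - 1L]    # edge (nx-1,j)-(nx,j)
  add(kf(rep(2L, ny), jv), kf(rep(2L, ny), jv), g_src)
  add(kf(rep(nx - 1L, ny), jv), kf(rep(nx - 1L, ny), jv), g_drn)
  b_src <- numeric(nfree); b_drn <- numeric(nfree)
  b_src[kf(rep(2L, ny), jv)] <- g_src
  b_drn[kf(rep(nx - 1L, ny), jv)] <- g_drn
  # y-edges
  jj <- rep(seq_len(ny - 1L), each = nxf)
  ii <- rep(2:(nx - 1L), times = ny - 1L)
  g <- eps * dev$wx[ii] / dyc[jj]
  a <- kf(ii, jj); b <- kf(ii, jj + 1L)
  add(a, a, g); add(b, b, g); add(a, b, -g); add(b, a, -g)
  # oxide-capacitance (Robin) term on gated top-surface cells
  b_cg <- numeric(nfree); b_pg <- numeric(nfree); b_sig <- numeric(nfree)
  for (i in 2:(nx - 1L)) {
    gid <- dev$gate_id[i]
    if (gid == 0L) next
    k <- kf(i, 1L)
    add(k, k, dev$c_ox * dev$wx[i])
    if (gid == 1L) b_cg[k] <- dev$c_ox * dev$wx[i]
    if (gid == 2L) {
      b_pg[k] <- dev$c_ox * dev$wx[i]
      b_sig[k] <- dev$wx[i]
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nfree, nfree))
  A <- Matrix::forceSymmetric(A)
  ii_all <- rep(2:(nx - 1L), times = ny)
  jj_all <- rep(seq_len(ny), each = nxf)
  area <- dev$wx[ii_all] * dev$wy[jj_all]
  free_nodes <- ii_all + (jj_all - 1L) * nx
  list(A_geom = A, nfree = nfree, free_nodes = free_nodes,
       area_free = area, b_src = b_src, b_drn = b_drn,
       b_cg = b_cg, b_pg = b_pg, b_sig = b_sig)
}

# Contact potentials under bias (source grounded).
.contact_psi <- function(dev, bias) {
  c(src = dev$psi_contact0, drn = dev$psi_contact0 + bias$v_ds)
}

# Nonlinear Poisson solve with frozen quasi-Fermi potentials.
# psi: full-node vector (modified and returned); chol_env caches the
# factorization pattern across Newton steps.
.solve_poisson <- function(dev, psi, phi_n, phi_p, bias,
                           tol = 1e-8, maxit = 100, clamp = 0.5,
                           chol_env = NULL) {
  nx <- dev$nx; ny <- dev$ny
  pc <- .contact_psi(dev, bias)
  src_idx <- 1L + (seq_len(ny) - 1L) * nx
  drn_idx <- nx + (seq_len(ny) - 1L) * nx
  psi[src_idx] <- pc["src"]; psi[drn_idx] <- pc["drn"]
  fr <- dev$free_nodes
  sigma_si <- bias$sigma_pg * 1e4  # C/cm^2 -> C/m^2
  b_fix <- dev$b_src * pc["src"] + dev$b_drn * pc["drn"] +
    dev$b_cg * bias$v_cg + dev$b_pg * bias$v_pg + dev$b_sig * sigma_si
  q <- .const$q
  for (it in seq_len(maxit)) {
    pf <- psi[fr]
    ex_n <- pmin((pf - phi_n[fr]) / dev$vt, 120)
    ex_p <- pmin((phi_p[fr] - pf) / dev$vt, 120)
    n <- dev$ni * exp(ex_n)
    p <- dev$ni * exp(ex_p)
    rho <- q * (p - n + dev$doping) * dev$area_free
    Fres <- as.numeric(dev$A_geom %*% pf) - b_fix - rho
    ddiag <- q * (n + p) / dev$vt * dev$area_free
    A <- dev$A_geom + Matrix::Diagonal(dev$nfree, ddiag)
    if (is.null(chol_env)) {
      dpsi <- as.numeric(Matrix::solve(A, -Fres))
    } else {
      if (is.null(chol_env$ch)) {
        chol_env$ch <- Matrix::Cholesky(A, LDL = FALSE)
      } else {
        chol_env$ch <- Matrix::update(chol_env$ch, A)
      }
      dpsi <- as.numeric(Matrix::solve(chol_env$ch, -Fres,
                                       system = "A"))
    }
    dpsi <- pmax(pmin(dpsi, clamp), -clamp)
    psi[fr] <- pf + dpsi
    if (max(abs(dpsi)) < tol) {
      return(list(psi = psi, iterations = it, converged = TRUE,
                  residual = max(abs(Fres))))
    }
  }
  list(psi = psi, iterations = maxit, converged = FALSE,
       residual = max(abs(Fres)))
}

# Conduction/valence band edges (eV, relative to the grounded Fermi level)
# from the node potential.
.band_edges <- function(dev, psi) {
  ec <- dev$vt * log(dev$nc / dev$ni) - psi
  list(ec = ec, ev = ec - dev$materials$bandgap)
}

# Tunneling enhancement factors gamma (>= 1) per film row for one contact
# and carrier, from WKB through the mesh-sampled barrier in a window next
# to the contact. Returns a vector of length ny.
.contact_gamma <- function(dev, psi, contact = c("src", "drn"),
                           carrier = c("e", "h"), bias,
                           window_nm = 150, n_energy = 80) {
  contact <- match.arg(contact); carrier <- match.arg(carrier)
  nx <- dev$nx; ny <- dev$ny
  v_c <- if (contact == "src") 0 else bias$v_ds
  m_kg <- switch(carrier, e = dev$materials$tunneling_mass_e,
                 h = dev$materials$tunneling_mass_h) * .const$m0
  if (contact == "src") {
    sel <- which(dev$xs <= window_nm * 1e-9)
    xw <- dev$xs[sel]
  } else {
    sel <- rev(which(dev$xs >= dev$xs[nx] - window_nm * 1e-9))
    xw <- dev$xs[nx] - dev$xs[sel]
  }
  pref <- 2 * sqrt(2 * m_kg * .const$q) / .const$hbar
  d <- diff(xw)
  w <- c(d[1] / 2, if (length(d) > 1) (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  gam <- numeric(ny)
  offset <- dev$vt * log(dev$nc / dev$ni)
  for (j in seq_len(ny)) {
    prow <- psi[sel + (j - 1L) * nx]
    barrier <- if (carrier == "e") {
      offset - prow + v_c
    } else {
      dev$materials$bandgap - offset + prow - v_c
    }
    e_max <- max(barrier)
    e_lo <- max(0, min(barrier))
    if (e_max - e_lo < 1e-6) { gam[j] <- 1; next }
    energies <- seq(e_lo, e_max, length.out = n_energy)
    dE <- outer(barrier, energies, "-")
    dE[dE < 0] <- 0
    wkb <- pref * as.numeric(crossprod(sqrt(dE), w))
    eta <- (e_max - energies) / dev$vt - wkb
    integrand <- exp(pmin(eta, 600))
    gam[j] <- 1 + sum((energies[-1] - energies[-n_energy]) *
                        (integrand[-1] + integrand[-n_energy]) / 2) / dev$vt
  }
  gam
}

# Linear continuity solve for one carrier with SG fluxes and Robin contact
# conditions. Returns density (full vector) and the two terminal currents
# (A, conventional current into the terminal, this carrier's contribution).
.solve_continuity <- function(dev, psi, carrier = c("e", "h"),
                              gam_src, gam_drn, band_shift = NULL) {
  carrier <- match.arg(carrier)
  nx <- dev$nx; ny <- dev$ny; nn <- nx * ny
  q <- .const$q
  mu <- if (carrier == "e") dev$mu_n else dev$mu_p
  v_r <- if (carrier == "e") dev$v_rich_e else dev$v_rich_h
  dens_b <- if (carrier == "e") dev$n_b else dev$p_b
  psi_eff <- if (is.null(band_shift)) psi else {
    if (carrier == "e") psi + band_shift else psi - band_shift
  }
  dxc <- diff(dev$xs); dyc <- diff(dev$ys)
  # x-edges
  jj <- rep(seq_len(ny), each = nx - 1L)
  ii <- rep(seq_len(nx - 1L), times = ny)
  a_x <- ii + (jj - 1L) * nx; b_x <- a_x + 1L
  c_x <- q * mu * dev$vt * dev$wy[jj] / dxc[ii]
  # y-edges
  jj <- rep(seq_len(ny - 1L), each = nx)
  ii <- rep(seq_len(nx), times = ny - 1L)
  a_y <- ii + (jj - 1L) * nx; b_y <- a_y + nx
  c_y <- q * mu * dev$vt * dev$wx[ii] / dyc[jj]
  av <- c(a_x, a_y); bv <- c(b_x, b_y); cv <- c(c_x, c_y)
  u <- (psi_eff[bv] - psi_eff[av]) / dev$vt
  if (carrier == "e") {
    ca_diag <- cv * .bernoulli(-u)   # coefficient of n_a in node-a equation
    cb_off  <- cv * .bernoulli(u)    # coefficient of n_b
  } else {
    ca_diag <- cv * .bernoulli(u)
    cb_off  <- cv * .bernoulli(-u)
  }
  ti <- c(av, av, bv, bv)
  tj <- c(av, bv, bv, av)
  tv <- c(ca_diag, -cb_off, cb_off, -ca_diag)
  # Robin contact terms
  src_idx <- 1L + (seq_len(ny) - 1L) * nx
  drn_idx <- nx + (seq_len(ny) - 1L) * nx
  r_src <- q * gam_src * v_r * dev$wy
  r_drn <- q * gam_drn * v_r * dev$wy
  ti <- c(ti, src_idx, drn_idx)
  tj <- c(tj, src_idx, drn_idx)
  tv <- c(tv, r_src, r_drn)
  rhs <- numeric(nn)
  rhs[src_idx] <- r_src * dens_b
  rhs[drn_idx] <- r_drn * dens_b
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nn, nn))
  fac <- Matrix::lu(A)
  dens <- as.numeric(Matrix::solve(fac, rhs))
  # two rounds of iterative refinement with a compensated residual: the
  # boundary densities must be accurate enough that the sub-fA imbalance
  # of the terminal fluxes stays below 1e-3 of the OFF-state current
  for (r in 1:2) {
    resid <- .compensated_residual(ti, tj, tv, dens, rhs)
    dens <- dens + as.numeric(Matrix::solve(fac, resid))
  }
  dens <- pmax(dens, 1e-30 * dev$ni)
  # terminal currents: carriers absorbed by the metal (dens > dens_b) carry
  # conventional current into the terminal for electrons, out for holes
  sgn <- if (carrier == "e") 1 else -1
  i_src <- sgn * dev$width * sum(r_src * (dens[src_idx] - dens_b))
  i_drn <- sgn * dev$width * sum(r_drn * (dens[drn_idx] - dens_b))
  list(dens = dens, i_src = i_src, i_drn = i_drn)
}

#' Solver control settings
#'
#' @param tol_potential Gummel convergence threshold on the max potential
#'   update, V.
#' @param tol_current Relative drain-current stagnation threshold.
#' @param max_iter Maximum Gummel iterations per bias point.
#' @param poisson_tol,poisson_max Inner nonlinear-Poisson Newton tolerance
#'   (V) and iteration cap.
#' @param clamp Per-node Newton update clamp, V.
#' @param ramp_step Maximum bias change per continuation step, V.
#' @param current_floor Floor used in relative current comparisons, A.
#' @return A list of settings.
#' @export
solver_control <- function(tol_potential = 1e-5, tol_current = 1e-4,
                           max_iter = 200, poisson_tol = 1e-8,
                           poisson_max = 30, clamp = 0.5,
                           ramp_step = 0.5, current_floor = 1e-15) {
  as.list(environment())
}

# One Gummel solve at a fixed bias from a given initial state.
.gummel <- function(dev, bias, state, control, chol_env,
                    band_shift = NULL) {
  psi <- state$psi; phi_n <- state$phi_n; phi_p <- state$phi_p
  i_d_prev <- Inf
  for (it in seq_len(control$max_iter)) {
    psi_prev <- psi
    ps <- .solve_poisson(dev, psi, phi_n, phi_p, bias,
                         tol = control$poisson_tol,
                         maxit = control$poisson_max,
                         clamp = control$clamp, chol_env = chol_env)
    psi <- ps$psi
    g_se <- .contact_gamma(dev, psi, "src", "e", bias)
    g_de <- .contact_gamma(dev, psi, "drn", "e", bias)
    g_sh <- .contact_gamma(dev, psi, "src", "h", bias)
    g_dh <- .contact_gamma(dev, psi, "drn", "h", bias)
    el <- .solve_continuity(dev, psi, "e", g_se, g_de, band_shift)
    ho <- .solve_continuity(dev, psi, "h", g_sh, g_dh, band_shift)
    phi_n <- psi - dev$vt * log(pmax(el$dens, 1e-30 * dev$ni) / dev$ni)
    phi_p <- psi + dev$vt * log(pmax(ho$dens, 1e-30 * dev$ni) / dev$ni)
    i_d <- el$i_drn + ho$i_drn
    dpsi <- max(abs(psi - psi_prev))
    dabs <- abs(i_d - i_d_prev)
    dcur <- dabs / max(abs(i_d), control$current_floor)
    i_d_prev <- i_d
    if (dpsi < control$tol_potential &&
        (dcur < control$tol_current || dabs < control$current_floor)) {
      return(list(psi = psi, phi_n = phi_n, phi_p = phi_p,
                  n = el$dens, p = ho$dens,
                  current_drain = i_d,
                  current_source = el$i_src + ho$i_src,
                  converged = TRUE, iterations = it))
    }
  }
  list(psi = psi, phi_n = phi_n, phi_p = phi_p,
       n = el$dens, p = ho$dens, current_drain = i_d,
       current_source = el$i_src + ho$i_src,
       converged = FALSE, iterations = control$max_iter)
}

.state_template <- function(dev) {
  nn <- dev$nx * dev$ny
  neutral <- dev$vt * asinh(dev$doping / (2 * dev$ni))
  list(psi = rep(neutral, nn), phi_n = rep(0, nn), phi_p = rep(0, nn))
}

.as_device_state <- function(dev, sol, bias) {
  shape <- function(v) matrix(v, nrow = dev$nx, ncol = dev$ny)
  structure(list(
    potential = shape(sol$psi), n = shape(sol$n * 1e-6),  # cm^-3
    p = shape(sol$p * 1e-6),
    phi_n = shape(sol$phi_n), phi_p = shape(sol$phi_p),
    current_drain = sol$current_drain,
    current_source = sol$current_source,
    converged = sol$converged, iterations = sol$iterations,
    bias = bias,
    x_nm = dev$xs * 1e9, y_nm = dev$ys * 1e9),
    class = "device_state")
}

#' @export
print.device_state <- function(x, ...) {
  cat(sprintf(
    "<device_state> v_pg = %g V, v_cg = %g V, v_ds = %g V, sigma = %.3g C/cm^2\n",
    x$bias$v_pg, x$bias$v_cg, x$bias$v_ds, x$bias$sigma_pg))
  cat(sprintf("  I_D = %.4g nA, I_S = %.4g nA, %s after %d Gummel iterations\n",
              x$current_drain * 1e9, x$current_source * 1e9,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Equilibrium Poisson solution
#'
#' Self-consistent solution of the nonlinear Poisson equation with
#' equilibrium carrier statistics (flat quasi-Fermi levels at the grounded
#' contact level). Requires `v_ds = 0`; gate voltages and sheet charge may
#' be nonzero. Detailed balance makes all terminal currents vanish.
#'
#' @param device An `rfet_device` from [build_device()].
#' @param bias A [bias_point()] with `v_ds = 0`.
#' @param control A [solver_control()].
#' @return A `device_state` (currents identically 0).
#' @export
solve_poisson_equilibrium <- function(device, bias = bias_point(),
                                      control = solver_control()) {
  stopifnot(inherits(device, "rfet_device"))
  if (bias$v_ds != 0)
    .fail("equilibrium solve requires v_ds = 0")
  st <- .state_template(device)
  chol_env <- new.env()
  ps <- .solve_poisson(device, st$psi, st$phi_n, st$phi_p, bias,
                       tol = control$poisson_tol, maxit = 400,
                       clamp = control$clamp, chol_env = chol_env)
  if (!ps$converged)
    .fail("equilibrium Poisson failed to converge (residual ",
          format(ps$residual), ")")
  psi <- ps$psi
  n <- device$ni * exp(pmin(psi / device$vt, 120))
  p <- device$ni * exp(pmin(-psi / device$vt, 120))
  .as_device_state(device,
                   list(psi = psi, phi_n = st$phi_n, phi_p = st$phi_p,
                        n = n, p = p, current_drain = 0, current_source = 0,
                        converged = TRUE, iterations = ps$iterations),
                   bias)
}

# First-order density-gradient quantum potential, -hbar^2/(6 m q) *
# laplacian(sqrt(n))/sqrt(n), computed by finite differences with Neumann
# edges; zeroed on the contact columns.
.quantum_potential <- function(dev, dens, m_rel) {
  nx <- dev$nx; ny <- dev$ny
  s <- matrix(sqrt(pmax(dens, 1e-30 * dev$ni)), nx, ny)
  lap <- matrix(0, nx, ny)
  xs <- dev$xs; ys <- dev$ys
  for (j in seq_len(ny)) {
    sp <- stats::splinefun(xs, s[, j])
    lap[, j] <- lap[, j] + sp(xs, deriv = 2)
  }
  if (ny >= 3) {
    dy <- ys[2] - ys[1]
    for (i in seq_len(nx)) {
      v <- s[i, ]
      l <- c(0, diff(v, differences = 2), 0) / dy^2
      l[1] <- l[2]; l[ny] <- l[ny - 1]
      lap[i, ] <- lap[i, ] + l
    }
  }
  qp <- -(.const$hbar^2 / (6 * m_rel * .const$m0 * .const$q)) *
    as.numeric(lap) / as.numeric(s)
  qp[rep(c(TRUE, rep(FALSE, nx - 2L), TRUE), ny)] <- 0
  # first-order correction only: bound the quantum potential so contact
  # gradients cannot destabilize the corrective pass
  pmax(pmin(qp, 0.2), -0.2)
}

#' Solve one bias point of the drift-diffusion system
#'
#' Gummel iteration (nonlinear Poisson with damped Newton, then
#' Scharfetter-Gummel electron and hole continuity with Tsu-Esaki-derived
#' Schottky injection) with bias continuation: the target bias is
#' approached in ramp steps from equilibrium, or from a supplied warm-start
#' state. Convergence requires the max potential update below
#' `tol_potential` and relative drain-current stagnation below
#' `tol_current`.
#'
#' @param device An `rfet_device`.
#' @param bias A [bias_point()].
#' @param control A [solver_control()].
#' @param init Optional warm start: a previous return value of this
#'   function at a nearby bias (its internal fields are reused).
#' @return A `device_state` with mesh fields (`potential` in V, `n`, `p` in
#'   cm^-3) and terminal currents in A.
#' @export
solve_bias_point <- function(device, bias, control = solver_control(),
                             init = NULL) {
  stopifnot(inherits(device, "rfet_device"), inherits(bias, "bias_point"))
  chol_env <- new.env()
  if (is.null(init)) {
    st <- .state_template(device)
    b0 <- bias_point(0, 0, 0, 0)
    ps <- .solve_poisson(device, st$psi, st$phi_n, st$phi_p, b0,
                         tol = control$poisson_tol, maxit = 400,
                         clamp = control$clamp, chol_env = chol_env)
    st$psi <- ps$psi
    from <- c(0, 0, 0, 0)
  } else {
    stopifnot(inherits(init, "device_state"))
    st <- list(psi = as.numeric(init$potential),
               phi_n = as.numeric(init$phi_n),
               phi_p = as.numeric(init$phi_p))
    from <- c(init$bias$v_pg, init$bias$v_cg, init$bias$v_ds,
              sigma_to_voltage_shift(init$bias$sigma_pg, device))
  }
  to <- c(bias$v_pg, bias$v_cg, bias$v_ds,
          sigma_to_voltage_shift(bias$sigma_pg, device))
  n_steps <- max(1L, ceiling(max(abs(to - from)) / control$ramp_step))
  sol <- NULL
  for (s in seq_len(n_steps)) {
    frac <- s / n_steps
    bi <- bias_point(
      v_pg = from[1] + frac * (bias$v_pg - from[1]),
      v_cg = from[2] + frac * (bias$v_cg - from[2]),
      v_ds = from[3] + frac * (bias$v_ds - from[3]),
      sigma_pg = (if (is.null(init)) 0 else init$bias$sigma_pg) +
        frac * (bias$sigma_pg -
                  (if (is.null(init)) 0 else init$bias$sigma_pg)))
    sol <- .gummel(device, bi, st, control, chol_env)
    if (!sol$converged && s < n_steps)
      .fail("drift-diffusion solve failed to converge at continuation ",
            "step ", s, "/", n_steps, " (v_pg = ", signif(bi$v_pg, 3),
            ", v_cg = ", signif(bi$v_cg, 3), ", v_ds = ",
            signif(bi$v_ds, 3), ")")
    st <- list(psi = sol$psi, phi_n = sol$phi_n, phi_p = sol$phi_p)
  }
  if (!sol$converged)
    .fail("drift-diffusion solve failed to converge at the target bias ",
          "(last Gummel iteration count ", sol$iterations, ")")
  if (isTRUE(device$spec$density_gradient)) {
    bs <- .quantum_potential(device, sol$n, device$materials$effective_mass_e)
    sol2 <- .gummel(device, bias, st, control, chol_env, band_shift = bs)
    if (sol2$converged) sol <- sol2
  }
  .as_device_state(device, sol, bias)
}

#' Transfer characteristic (I_D vs V_CG)
#'
#' Sweeps the control gate at fixed program-gate bias, drain bias, and
#' molecular sheet charge, using each converged point as the warm start of
#' the next (continuation).
#'
#' @param device An `rfet_device`.
#' @param v_cg_values Sorted control-gate voltages, V.
#' @param v_pg Program-gate voltage, V.
#' @param v_ds Drain-source voltage, V.
#' @param sigma_pg Molecular sheet charge, C/cm^2.
#' @param control A [solver_control()].
#' @return A `response_curve` with `x = v_cg_values` (kind `"v_cg"`) and
#'   drain current in A.
#' @export
transfer_curve <- function(device, v_cg_values, v_pg, v_ds, sigma_pg = 0,
                           control = solver_control()) {
  stopifnot(inherits(device, "rfet_device"))
  if (length(v_cg_values) == 0) .fail("empty v_cg sweep")
  if (is.unsorted(v_cg_values)) .fail("v_cg_values must be sorted")
  # sweep from the strongest |v_cg| toward 0 so the ON state (closest to
  # the programming condition) is reached first with a short ramp
  order_idx <- order(abs(v_cg_values), decreasing = TRUE)
  currents <- numeric(length(v_cg_values))
  state <- NULL
  for (ix in order_idx) {
    b <- bias_point(v_pg = v_pg, v_cg = v_cg_values[ix], v_ds = v_ds,
                    sigma_pg = sigma_pg)
    state <- tryCatch(
      solve_bias_point(device, b, control, init = state),
      error = function(e) .fail("transfer_curve failed at v_cg = ",
                                v_cg_values[ix], " V: ", conditionMessage(e)))
    currents[ix] <- state$current_drain
  }
  response_curve(x = v_cg_values, x_kind = "v_cg", current = currents,
                 metadata = list(v_pg = v_pg, v_ds = v_ds,
                                 sigma_pg = sigma_pg,
                                 mesh = c(device$nx, device$ny)))
}
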