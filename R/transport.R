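## 1-D diffusion across the channel half-height: supplies the
## near-electrode concentration n(0, t) that feeds the surface kinetics.

#' Characteristic diffusion time across the half channel
#'
#' `t_D = L^2 / (4 D)`: beyond this time the near-electrode
#' concentration has essentially equilibrated with the bulk and the
#' quasi-steady approximation n(0, t) ~ n_o holds.
#'
#' @param L half channel height, m.
#' @param D diffusivity, m^2/s.
#' @return diffusion time, s.
#' @examples
#' diffusion_time(15e-6, 1e-10) # 0.5625 s
#' @export
diffusion_time <- function(L, D) {
  stopifnot(L > 0, D > 0)
  L^2 / (4 * D)
}

#' Quasi-steady near-electrode concentration
#'
#' Fast path standing in for the full PDE solution. For a channel
#' prefilled with analyte (`initial = "prefilled"`, the default
#' protocol) the near-electrode concentration is simply the bulk value.
#' For a switched inlet (`initial = "empty"`) the concentration ramps
#' up as the diffusion front arrives; the ramp is the exact
#' eigenfunction solution of the slab 0..L with a reflecting wall at
#' x = 0, n(L, t) = n_o and n(x, 0) = 0:
#' `n(0,t)/n_o = 1 - sum_k 2 (-1)^k / lambda_k exp(-lambda_k^2 D t / L^2)`
#' with `lambda_k = (k + 1/2) pi`. It starts at 0 and saturates at
#' `n_o` for t >> t_D.
#'
#' @param n_o bulk concentration (any unit; result is proportional).
#' @param t times, s (>= 0).
#' @param t_D diffusion time from [diffusion_time()].
#' @param initial `"prefilled"` (constant `n_o`) or `"empty"`
#'   (front-arrival ramp).
#' @param n_terms number of series terms.
#' @return n(0, t), same unit as `n_o`.
#' @export
surface_concentration_quasisteady <- function(n_o, t, t_D,
                                              initial = c("prefilled", "empty"),
                                              n_terms = 64) {
  initial <- match.arg(initial)
  stopifnot(all(t >= 0), t_D > 0)
  if (initial == "prefilled") return(rep(n_o, length(t)))
  # D t / L^2 = (t / t_D) / 4 under t_D = L^2 / (4 D)
  tt <- (t / t_D) / 4
  k <- seq_len(n_terms) - 1
  lam <- (k + 0.5) * pi
  s <- 1 - colSums(2 * (-1)^k / lam * exp(-outer(lam^2, tt)))
  s[t == 0] <- 0
  pmin(pmax(s, 0), 1) * n_o
}

# Geometrically stretched grid on [0, L], refined near x = 0.
stretched_grid <- function(L, n_nodes, stretch = 1.05) {
  h <- stretch^(0:(n_nodes - 2))
  x <- c(0, cumsum(h))
  x / x[length(x)] * L
}

#' Solve the 1-D diffusion problem with a reactive electrode boundary
#'
#' Finite-volume Crank-Nicolson solution of `dn/dt = D d2n/dx2` on
#' `x in [0, L]` with Dirichlet `n(L, t) = n_o` at the channel centre
#' and, at the electrode (`x = 0`), either a prescribed-flux (Robin)
#' condition `D dn/dx|_0 = J(n(0,t), theta(t))` coupled to the surface
#' coverage ODE `N_s dtheta/dt = J` by per-step operator splitting, or
#' an absorbing boundary `n(0, t) = 0`. The grid is geometrically
#' stretched towards the electrode; time stepping is implicit
#' (unconditionally stable), with the flux linearised in `n(0)` within
#' each step.
#'
#' @param D diffusivity, m^2/s.
#' @param L half channel height, m.
#' @param n_o bulk concentration (any amount unit U/m^3).
#' @param t_grid uniform time grid, s, starting at 0.
#' @param flux_law `function(n0, theta)` returning the net adsorption
#'   flux in U/(m^2 s) (positive = into the surface), or `NULL` for
#'   zero flux.
#' @param N_s monolayer site density in U/m^2 used to advance
#'   `theta`; `Inf` (default) freezes `theta` at `theta0`.
#' @param theta0 initial coverage.
#' @param x_nodes number of spatial nodes (>= 50).
#' @param stretch geometric stretching factor of the grid.
#' @param initial `"prefilled"` (`n(x,0) = n_o`) or `"empty"`
#'   (`n(x,0) = 0`, switched-inlet front arrival).
#' @param boundary `"flux"` (default) or `"absorbing"` (`n(0,t) = 0`).
#' @return Object of class `concentration_field`: list with `x`, `t`,
#'   `n` (time x space matrix), `n0` (= `n[, 1]`), `theta`, `adsorbed`
#'   (cumulative adsorbed amount per area, U/m^2), `n_o`.
#' @export
solve_diffusion <- function(D, L, n_o, t_grid, flux_law = NULL,
                            N_s = Inf, theta0 = 0,
                            x_nodes = 120, stretch = 1.05,
                            initial = c("prefilled", "empty"),
                            boundary = c("flux", "absorbing")) {
  initial <- match.arg(initial)
  boundary <- match.arg(boundary)
  stopifnot(D > 0, L > 0, n_o >= 0, x_nodes >= 50)
  nt <- length(t_grid)
  dtv <- diff(t_grid)
  if (any(abs(dtv - dtv[1]) > 1e-9 * dtv[1])) stop("t_grid must be uniform")
  dt <- dtv[1]
  x <- stretched_grid(L, x_nodes, stretch)
  h <- diff(x)
  nx <- x_nodes
  if (is.null(flux_law)) flux_law <- function(n0, theta) 0

  # finite-volume coefficients: cv_i dn_i/dt = D (n_{i+1}-n_i)/h_i
  #                                          - D (n_i-n_{i-1})/h_{i-1} (- J at i=1)
  cv <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)

  n <- matrix(NA_real_, nt, nx)
  n[1, ] <- if (initial == "prefilled") n_o else 0
  n[1, nx] <- n_o
  if (boundary == "absorbing") n[1, 1] <- 0
  theta <- numeric(nt); theta[1] <- theta0
  adsorbed <- numeric(nt)

  west <- D / h[pmax(1, seq_len(nx) - 1)]  # conductance to left neighbour
  east <- D / h[pmin(length(h), seq_len(nx))]

  idx_int <- 2:(nx - 1)

  # one implicit step of length dtl; wimp = 1 gives backward Euler,
  # 0.5 Crank-Nicolson
  advance <- function(cur, th, ads, dtl, wimp) {
    wexp <- 1 - wimp
    lap_old <- numeric(nx)
    lap_old[idx_int] <- east[idx_int] * (cur[idx_int + 1] - cur[idx_int]) -
      west[idx_int] * (cur[idx_int] - cur[idx_int - 1])

    # linearise the surface flux about the old surface state:
    # J ~ a * n0_new - b0
    n0_old <- cur[1]
    J_old <- flux_law(n0_old, th)
    eps <- max(abs(n0_old), n_o, 1) * 1e-6
    a <- (flux_law(n0_old + eps, th) - J_old) / eps
    b0 <- a * n0_old - J_old

    lower <- numeric(nx); diagc <- numeric(nx); upper <- numeric(nx)
    rhs <- numeric(nx)
    lower[idx_int] <- -wimp * dtl * west[idx_int]
    upper[idx_int] <- -wimp * dtl * east[idx_int]
    diagc[idx_int] <- cv[idx_int] + wimp * dtl * (west[idx_int] + east[idx_int])
    rhs[idx_int] <- cv[idx_int] * cur[idx_int] + wexp * dtl * lap_old[idx_int]
    if (boundary == "absorbing") {
      diagc[1] <- 1; upper[1] <- 0; rhs[1] <- 0
    } else {
      # the boundary control volume is tiny on the stretched grid, so
      # its storage term is negligible: impose the quasi-static flux
      # balance D(n2 - n1)/h1 = a n1 - b0 (exact as cv -> 0; avoids
      # the stiff boundary mode entirely)
      diagc[1] <- east[1] + a
      upper[1] <- -east[1]
      rhs[1] <- b0
    }
    diagc[nx] <- 1; lower[nx] <- 0; rhs[nx] <- n_o

    new <- thomas_solve(lower, diagc, upper, rhs)
    if (any(new < -1e-9 * max(n_o, 1)))
      stop("solve_diffusion: negative concentration (step-size instability)")
    new[new < 0] <- 0

    # operator splitting: advance coverage with the step-average flux
    J_avg <- 0.5 * (J_old + flux_law(new[1], th))
    if (is.finite(N_s)) th <- min(max(th + dtl * J_avg / N_s, 0), 1)
    list(cur = new, th = th, ads = ads + dtl * J_avg)
  }

  cur <- n[1, ]; th <- theta[1]; ads <- 0
  for (k in 2:nt) {
    # sub-step the early output intervals: the post-switch-on boundary
    # layer grows like sqrt(D t) and needs resolved time steps; later
    # intervals take a single Crank-Nicolson step (backward Euler on
    # the first interval smooths the initial discontinuity)
    m <- max(1L, min(32L, ceiling(10 * dt / t_grid[k])))
    for (s in seq_len(m)) {
      st <- advance(cur, th, ads, dt / m, if (k == 2) 1 else 0.5)
      cur <- st$cur; th <- st$th; ads <- st$ads
    }
    n[k, ] <- cur; theta[k] <- th; adsorbed[k] <- ads
  }
  structure(list(x = x, t = t_grid, n = n, n0 = n[, 1], theta = theta,
                 adsorbed = adsorbed, n_o = n_o),
            class = "concentration_field")
}

# Thomas algorithm for tridiagonal systems.
thomas_solve <- function(lower, diagc, upper, rhs) {
  n <- length(diagc)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diagc[1]
  dp[1] <- rhs[1] / diagc[1]
  for (i in 2:n) {
    m <- diagc[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Eigenfunction-series solution for the absorbing slab
#'
#' Independent closed form used to cross-check the PDE solver: slab
#' 0..L, `n(0,t) = 0` (absorbing face), `n(L,t) = n_o`, `n(x,0) = n_o`.
#' `n(x,t) = n_o [ x/L + sum_k (2/(k pi)) sin(k pi x / L) exp(-D (k pi / L)^2 t) ]`.
#'
#' @param x positions, m.
#' @param t time, s (scalar).
#' @inheritParams solve_diffusion
#' @param n_terms series terms.
#' @return n(x, t), same unit as `n_o`.
#' @export
absorbing_slab_series <- function(x, t, D, L, n_o, n_terms = 200) {
  k <- seq_len(n_terms)
  decay <- exp(-D * (k * pi / L)^2 * t)
  s <- vapply(x, function(xi)
    sum(2 / (k * pi) * sin(k * pi * xi / L) * decay), numeric(1))
  n_o * (x / L + s)
}
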