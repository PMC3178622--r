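#' Specification of a synthetic turbulence spectrum
#'
#' Describes the statistical properties of the kinematic (synthetic)
#' turbulent carrier flow: which Fourier modes are retained, the target
#' mean absolute flow speed, and how fast modes of different wavelength
#' decorrelate. The flow itself is generated by [init_flow()] and evolved
#' by [step_flow()].
#'
#' The energy spectrum family is the Karman-Obukhov form
#' \deqn{E(k) \propto k^{4} / (k^2 + k_0^2)^{17/6}}
#' with \eqn{k_0 = 1/L_{max}} in units of integer torus wavenumbers, so the
#' most energetic mode sits at the system scale. The exponent pair (4, 17/6)
#' is configurable through `spectrum_exponents`.
#'
#' @param k_max retain all integer wavevectors with `1 <= |k| <= k_max`.
#' @param U_target desired mean absolute flow speed (dimensionless); the
#'   realized field is rescaled so a dense-grid mean of `|u|` matches this.
#' @param L_max length of the largest energy mode; the domain size (1.0).
#' @param n_modes optional cap: keep only the `n_modes` lowest-`|k|`
#'   wavevectors (half-plane representatives). `NULL` keeps all with
#'   `|k| <= k_max`.
#' @param decorrelation_exponent exponent `q` of the per-mode relaxation
#'   rate `gamma_k = decorrelation_rate * |k|^q`; the default 2/3 gives
#'   Kolmogorov-like faster decorrelation of smaller eddies.
#' @param decorrelation_rate base relaxation rate of the largest mode
#'   (1/time); defaults to `U_target / L_max`, the large-eddy turnover rate.
#' @param spectrum_exponents numeric pair `(p1, p2)` in
#'   `E(k) = k^p1 / (k^2 + k0^2)^p2`.
#' @param family spectrum identifier; only `"karman-obukhov"` is built in.
#' @return an object of class `"spectrum_spec"`.
#' @seealso [init_flow()], [energy_spectrum()]
#' @export
spectrum_spec <- function(k_max = 8, U_target = 0.5, L_max = 1,
                          n_modes = NULL,
                          decorrelation_exponent = 2 / 3,
                          decorrelation_rate = NULL,
                          spectrum_exponents = c(4, 17 / 6),
                          family = "karman-obukhov") {
  if (L_max <= 0) stop("L_max must be positive")
  if (U_target < 0) stop("U_target must be nonnegative")
  if (k_max < 1) stop("k_max must be at least 1: no modes would be retained")
  if (!is.null(n_modes) && n_modes < 1) {
    stop("n_modes must be at least 1: no modes would be retained")
  }
  if (family != "karman-obukhov") {
    stop("unknown spectrum family: ", family)
  }
  structure(list(
    family = family,
    k_max = k_max,
    U_target = U_target,
    L_max = L_max,
    n_modes = n_modes,
    decorrelation_exponent = decorrelation_exponent,
    decorrelation_rate = if (is.null(decorrelation_rate)) {
      U_target / L_max
    } else {
      decorrelation_rate
    },
    spectrum_exponents = spectrum_exponents
  ), class = "spectrum_spec")
}

#' Karman-Obukhov spectral shape
#'
#' @param k wavenumber (integer torus units; vectorized).
#' @param k0 energy-containing wavenumber, `1/L_max`.
#' @param exponents numeric pair `(p1, p2)`.
#' @return unnormalized spectral energy density `E(k)`.
#' @keywords internal
karman_obukhov <- function(k, k0 = 1, exponents = c(4, 17 / 6)) {
  k^exponents[1] / (k^2 + k0^2)^exponents[2]
}

# Half-plane representative wavevectors with 1 <= |k| <= k_max, sorted by |k|.
# One representative per +/-k pair (ky > 0, or ky == 0 and kx > 0); the
# conjugate partner is implied by taking the real part of the mode sum.
mode_lattice <- function(k_max) {
  r <- ceiling(k_max)
  kx <- rep(-r:r, times = 2 * r + 1)
  ky <- rep(-r:r, each = 2 * r + 1)
  keep <- (ky > 0 | (ky == 0 & kx > 0)) & (kx^2 + ky^2) <= k_max^2
  k <- cbind(kx = kx[keep], ky = ky[keep])
  k[order(sqrt(k[, 1]^2 + k[, 2]^2), k[, 1], k[, 2]), , drop = FALSE]
}

#' Initialize a divergence-free synthetic turbulent flow
#'
#' Builds a [spectrum_spec()]-conforming set of Fourier modes on the unit
#' torus. Each mode's velocity direction is perpendicular to its wavevector,
#' so the evaluated field is divergence-free by construction. Mode complex
#' amplitudes are drawn from their stationary (Gaussian) distribution and
#' then rescaled, jointly with their stationary targets, so that the mean
#' absolute velocity over a dense evaluation grid equals `U_target` exactly.
#'
#' @param spec a [spectrum_spec()].
#' @param seed integer seed; identical seeds give identical flows.
#' @param calibration_n grid used to realize the `U_target` rescaling.
#' @return an object of class `"flow_modes"`: wavevectors, unit velocity
#'   directions, complex amplitudes `z`, stationary amplitude targets,
#'   per-mode relaxation rates, a uniform `mean_flow` component (zero by
#'   default; used for controlled advection in tests), and the current time.
#' @export
init_flow <- function(spec, seed = 1L, calibration_n = 256L) {
  stopifnot(inherits(spec, "spectrum_spec"))
  k <- mode_lattice(spec$k_max)
  if (!is.null(spec$n_modes)) {
    if (spec$n_modes > nrow(k)) {
      stop("n_modes exceeds the ", nrow(k), " lattice modes with |k| <= k_max")
    }
    k <- k[seq_len(spec$n_modes), , drop = FALSE]
  }
  m <- nrow(k)
  if (m == 0L) stop("no Fourier modes retained; increase k_max")
  kabs <- sqrt(k[, 1]^2 + k[, 2]^2)
  # unit vectors perpendicular to k: incompressibility by construction
  ex <- -k[, 2] / kabs
  ey <- k[, 1] / kabs
  k0 <- 1 / spec$L_max
  # Per-mode stationary energy ~ E(|k|)/|k|: the 1/|k| converts the shell
  # density of lattice modes (~ pi*|k| d k) into a per-mode share so the
  # shell-summed energy follows E(k).
  e_mode <- karman_obukhov(kabs, k0, spec$spectrum_exponents) / kabs
  gamma <- spec$decorrelation_rate * kabs^spec$decorrelation_exponent

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  abar <- sqrt(e_mode)
  z <- complex(
    real = stats::rnorm(m, 0, abar / sqrt(2)),
    imaginary = stats::rnorm(m, 0, abar / sqrt(2))
  )
  modes <- structure(list(
    k = k, kabs = kabs, ex = ex, ey = ey,
    z = z, abar = abar, gamma = gamma,
    mean_flow = c(0, 0), t = 0, spec = spec, seed = as.integer(seed)
  ), class = "flow_modes")

  if (spec$U_target == 0) {
    modes$z <- complex(real = rep(0, m), imaginary = rep(0, m))
    modes$abar <- rep(0, m)
    return(modes)
  }
  u <- velocity_grid(modes, calibration_n)
  realized <- mean(sqrt(u$ux^2 + u$uy^2))
  if (realized == 0) stop("degenerate flow realization: |u| identically zero")
  scale <- spec$U_target / realized
  modes$z <- modes$z * scale
  modes$abar <- modes$abar * scale
  modes
}

# set.seed inside package functions must not clobber the caller's RNG state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.flow_modes <- function(x, ...) {
  cat("<flow_modes> ", nrow(x$k), " modes, |k| in [",
    min(x$kabs), ", ", max(x$kabs), "], t = ", signif(x$t, 4),
    ", U_target = ", x$spec$U_target, "\n",
    sep = ""
  )
  invisible(x)
}

#' Advance the flow in time
#'
#' Each mode's complex amplitude follows an exact Ornstein-Uhlenbeck update
#' \deqn{z' = z e^{-\gamma_k dt} + \bar A_k \sqrt{(1 - e^{-2\gamma_k dt})/2}\,(\xi_1 + i \xi_2)}
#' which is mean-reverting with stationary `E|z|^2` equal to the prescribed
#' spectral share, and whose relaxation rate `gamma_k` grows with wavenumber
#' (smaller eddies decorrelate faster). Phases and amplitudes therefore
#' evolve randomly while the spectrum shape is preserved in expectation.
#'
#' @param modes a `"flow_modes"` object.
#' @param dt time step (> 0).
#' @return the updated `"flow_modes"` object.
#' @export
step_flow <- function(modes, dt) {
  stopifnot(inherits(modes, "flow_modes"), dt > 0)
  m <- length(modes$z)
  if (m > 0) {
    decay <- exp(-modes$gamma * dt)
    s <- modes$abar * sqrt((1 - decay^2) / 2)
    modes$z <- modes$z * decay +
      complex(real = stats::rnorm(m, 0, 1), imaginary = stats::rnorm(m, 0, 1)) * s
  }
  modes$t <- modes$t + dt
  modes
}

#' Evaluate the flow velocity at arbitrary points
#'
#' Exact trigonometric evaluation of the mode sum
#' \eqn{u(x) = \bar u + \sum_m Re(z_m e^{2\pi i k_m \cdot x}) \hat e_m},
#' periodic in both coordinates.
#'
#' @param modes a `"flow_modes"` object.
#' @param points an `p x 2` matrix of torus coordinates (wrapped internally).
#' @return a `p x 2` matrix of velocity vectors.
#' @export
velocity_at <- function(modes, points) {
  points <- matrix(points, ncol = 2)
  p <- nrow(points)
  m <- length(modes$z)
  if (m == 0L) {
    return(cbind(
      rep(modes$mean_flow[1], p),
      rep(modes$mean_flow[2], p)
    ))
  }
  theta <- 2 * pi * (points %*% t(modes$k))
  ct <- cos(theta)
  st <- sin(theta)
  re <- Re(modes$z)
  im <- Im(modes$z)
  ux <- ct %*% (re * modes$ex) - st %*% (im * modes$ex) + modes$mean_flow[1]
  uy <- ct %*% (re * modes$ey) - st %*% (im * modes$ey) + modes$mean_flow[2]
  cbind(as.vector(ux), as.vector(uy))
}

#' Evaluate the flow velocity on a regular n x n grid
#'
#' FFT synthesis of the mode sum; grid node `[i, j]` corresponds to
#' `x = (i-1)/n, y = (j-1)/n`. Identical (to round-off) to [velocity_at()]
#' on the same nodes, but much faster for full-grid evaluation.
#'
#' @param modes a `"flow_modes"` object.
#' @param n grid resolution (must exceed `2*k_max` to hold all modes).
#' @return list with `n x n` matrices `ux`, `uy`.
#' @export
velocity_grid <- function(modes, n) {
  n <- as.integer(n)
  if (length(modes$z) > 0 && n <= 2 * max(modes$kabs)) {
    stop("grid too coarse for the retained modes: need n > 2*k_max")
  }
  fx <- matrix(0 + 0i, n, n)
  fy <- matrix(0 + 0i, n, n)
  if (length(modes$z) > 0) {
    ix <- (modes$k[, 1] %% n) + 1L
    iy <- (modes$k[, 2] %% n) + 1L
    idx <- cbind(ix, iy)
    fx[idx] <- modes$z * modes$ex
    fy[idx] <- modes$z * modes$ey
  }
  ux <- Re(stats::fft(fx, inverse = TRUE)) + modes$mean_flow[1]
  uy <- Re(stats::fft(fy, inverse = TRUE)) + modes$mean_flow[2]
  list(ux = ux, uy = uy, n = n)
}

#' Shell-averaged kinetic energy spectrum of the evaluated flow
#'
#' Evaluates the velocity on a `grid_n` x `grid_n` grid, Fourier-transforms
#' it, and sums the kinetic energy of each Fourier coefficient into integer
#' wavenumber shells (`shell = round(|k|)`). The shell energies sum to the
#' grid-mean kinetic energy (Parseval).
#'
#' @param modes a `"flow_modes"` object.
#' @param grid_n evaluation grid resolution (a power of two is fastest).
#' @return a data.frame with columns `shell` and `energy`.
#' @export
energy_spectrum <- function(modes, grid_n = 128L) {
  u <- velocity_grid(modes, grid_n)
  n <- u$n
  hx <- stats::fft(u$ux)
  hy <- stats::fft(u$uy)
  # grid-mean 1/2 |u|^2 = sum_k (|hx|^2 + |hy|^2) / (2 n^4)
  e_coef <- (Mod(hx)^2 + Mod(hy)^2) / (2 * n^4)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fxg <- matrix(f, n, n)
  fyg <- matrix(f, n, n, byrow = TRUE)
  shell <- round(sqrt(fxg^2 + fyg^2))
  agg <- tapply(as.vector(e_coef), as.vector(shell), sum)
  data.frame(
    shell = as.integer(names(agg)),
    energy = as.numeric(agg)
  )
}

#' Model-expected shell energies for a flow
#'
#' The lattice-aware prescribed spectrum: sums each retained mode's
#' stationary energy `E|z|^2 / 4` into integer shells. This is the curve the
#' measured [energy_spectrum()] should follow in (time) expectation.
#'
#' @param modes a `"flow_modes"` object.
#' @return a data.frame with columns `shell` and `energy`.
#' @export
expected_spectrum <- function(modes) {
  shell <- round(modes$kabs)
  agg <- tapply(modes$abar^2 / 4, shell, sum)
  # +/- k conjugate pair: the representative carries the full pair energy
  # already because Re(z e^{i theta}) has grid-mean square |z|^2/2, i.e.
  # energy |z|^2/4 per representative mode.
  data.frame(shell = as.integer(names(agg)), energy = as.numeric(agg))
}

#' Goodness of fit of a measured spectrum to the prescribed curve
#'
#' Log-log regression of measured shell energies against the model-expected
#' shell energies; returns the R-squared together with the merged table.
#'
#' @param observed data.frame from [energy_spectrum()] (possibly averaged
#'   over snapshots).
#' @param expected data.frame from [expected_spectrum()].
#' @return list with `r_squared`, `slope`, and the merged `table`.
#' @export
spectrum_fit <- function(observed, expected) {
  tab <- merge(observed, expected, by = "shell", suffixes = c("_obs", "_exp"))
  tab <- tab[tab$shell > 0 & tab$energy_obs > 0 & tab$energy_exp > 0, ]
  fit <- stats::lm(log(energy_obs) ~ log(energy_exp), data = tab)
  list(
    r_squared = summary(fit)$r.squared,
    slope = unname(stats::coef(fit)[2]),
    table = tab
  )
}

#' Divergence diagnostic for the evaluated flow
#'
#' The velocity field is a finite sum of trigonometric modes, each with
#' velocity perpendicular to its wavevector, so its true divergence is
#' identically zero. `method = "spectral"` differentiates the evaluated grid
#' exactly (the field is band-limited), confirming zero divergence to
#' round-off; `method = "central"` uses second-order central differences,
#' whose truncation error is `O(h^2)` and therefore nonzero for oblique
#' high-k modes -- it is provided for comparison, not as the contract.
#'
#' @param modes a `"flow_modes"` object.
#' @param n evaluation grid resolution.
#' @param method `"spectral"` or `"central"`.
#' @return list with `max_divergence`, `max_speed`, and their ratio.
#' @export
flow_divergence <- function(modes, n = 256L, method = c("spectral", "central")) {
  method <- match.arg(method)
  u <- velocity_grid(modes, n)
  if (method == "spectral") {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    # zero the Nyquist derivative row/col for odd-derivative symmetry
    if (n %% 2 == 0) f[n %/% 2 + 1] <- 0
    fxg <- matrix(f, n, n)
    fyg <- matrix(f, n, n, byrow = TRUE)
    dux <- Re(stats::fft(2i * pi * fxg * stats::fft(u$ux), inverse = TRUE)) / n^2
    duy <- Re(stats::fft(2i * pi * fyg * stats::fft(u$uy), inverse = TRUE)) / n^2
    div <- dux + duy
  } else {
    h <- 1 / n
    right <- function(m) m[c(2:nrow(m), 1), ]
    left <- function(m) m[c(nrow(m), 1:(nrow(m) - 1)), ]
    up <- function(m) m[, c(2:ncol(m), 1)]
    down <- function(m) m[, c(ncol(m), 1:(ncol(m) - 1))]
    div <- (right(u$ux) - left(u$ux)) / (2 * h) +
      (up(u$uy) - down(u$uy)) / (2 * h)
  }
  speed <- sqrt(u$ux^2 + u$uy^2)
  list(
    max_divergence = max(abs(div)),
    max_speed = max(speed),
    ratio = if (max(speed) > 0) max(abs(div)) / max(speed) else 0
  )
}
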