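#' Assemble small-area model inputs for one cause and sex
#'
#' Builds the strata grid, aligned death and population vectors, the
#' centred-and-scaled covariate design, the ICAR and RW1 structure
#' matrices, and the dense design mapping the unconstrained parameter
#' vector to the log-rate linear predictor. Sum-to-zero constraints on
#' all random effects are enforced by working in an orthonormal basis of
#' the constraint subspace (per connected component for the spatial
#' effect, per race for the county-by-race effect), so the curvature of
#' the log-posterior is positive definite at the mode.
#'
#' The model is
#' `log m = beta0_race + X gamma + u_county + v_age + w_year + z_county:race`
#' with `u ~ ICAR(tau_u)`, `v ~ RW1(tau_v)`, `w ~ RW1(tau_w)`,
#' `z ~ iid Normal(0, 1/tau_z)` (dropped for single-race fits), and
#' `log tau_k ~ Normal(0, hyper_sd^2)` hyperpriors.
#'
#' @param deaths Deaths `count_table` (may be real-valued after garbage
#'   redistribution; must include rows for `cause`).
#' @param population Population `count_table`.
#' @param covariates Optional county covariate table (column `county`
#'   plus numeric columns). Covariates are centred and scaled to unit
#'   variance; zero-variance covariates are dropped with a warning.
#' @param graph A [county_graph()] covering all schema counties.
#' @param schema A [strata_schema()].
#' @param cause Cause to model (a schema cause, or `"all_cause"` if the
#'   deaths table carries derived all-cause rows).
#' @param sex Sex to model.
#' @param races Races to model jointly (default all schema races), or
#'   `"Total"` to fit the aggregated total population.
#' @param hyper_sd Standard deviation of the log-precision hyperprior.
#' @return A `model_inputs` list: `strata`, `D`, `P`, `MB` (design),
#'   `blocks` (random-effect blocks with structure matrices in basis
#'   coordinates and ranks), parameter layout, and bases for mapping
#'   back to natural effects.
#' @export
build_inputs <- function(deaths, population, covariates = NULL, graph,
                         schema, cause, sex, races = schema$races,
                         hyper_sd = 3) {
  stopifnot(setequal(graph$counties, schema$counties))
  cz <- cause; sx <- sex
  dd <- as.data.table(deaths)[cause == cz & sex == sx]
  if (!nrow(dd)) stop("no death rows for cause ", cz, ", sex ", sx)
  pp <- as.data.table(population)[sex == sx]
  total <- identical(races, RACE_TOTAL)
  if (total) {
    dd <- dd[, .(value = sum(value)), by = .(county, sex, age, year, cause)]
    dd[, race := RACE_TOTAL]
    pp <- pp[, .(value = sum(value)), by = .(county, sex, age, year)]
    pp[, race := RACE_TOTAL]
    fit_races <- RACE_TOTAL
  } else {
    dd <- dd[race %in% races]
    pp <- pp[race %in% races]
    fit_races <- races
  }

  grid <- CJ(county = schema$counties, race = fit_races, sex = sx,
             age = schema$ages, year = schema$years, cause = cz,
             sorted = TRUE)
  idx <- setdiff(IDX_COLS, "cause")
  D <- dd[grid, on = c(idx, "cause")]$value
  D[is.na(D)] <- 0
  P <- pp[grid, on = idx]$value
  if (anyNA(P)) stop("population missing for modelled strata")
  if (any(P == 0 & D > 0))
    stop("deaths observed in a stratum with zero population")

  nj <- length(schema$counties); nr <- length(fit_races)
  na <- length(schema$ages); nt <- length(schema$years)
  jj <- match(grid$county, schema$counties)
  rr <- match(grid$race, fit_races)
  aa <- match(grid$age, schema$ages)
  tt <- match(grid$year, schema$years)

  # fixed effects: race intercepts + covariates
  M_beta <- matrix(0, nrow(grid), nr)
  M_beta[cbind(seq_len(nrow(grid)), rr)] <- 1
  colnames(M_beta) <- paste0("beta0_", fit_races)
  Xs <- NULL; x_scale <- NULL
  if (!is.null(covariates)) {
    cv <- as.data.table(covariates)
    num_cols <- setdiff(names(cv), "county")
    X <- as.matrix(cv[match(schema$counties, county), num_cols,
                      with = FALSE])
    keep_cov <- apply(X, 2L, function(x) stats::var(x) > 0)
    if (any(!keep_cov))
      warning("dropping zero-variance covariate(s): ",
              paste(num_cols[!keep_cov], collapse = ", "))
    X <- X[, keep_cov, drop = FALSE]
    if (ncol(X)) {
      X <- scale(X)
      x_scale <- list(center = attr(X, "scaled:center"),
                      scale = attr(X, "scaled:scale"))
      Xs <- X[jj, , drop = FALSE]
      colnames(Xs) <- paste0("gamma_", num_cols[keep_cov])
    }
  }

  membership <- graph_components(graph)[schema$counties]
  Q_u <- icar_structure(graph)
  A_u <- component_basis(membership)
  A_v <- sum_to_zero_basis(na)
  A_w <- sum_to_zero_basis(nt)
  A_jz <- sum_to_zero_basis(nj)

  blocks <- list()
  design <- list(M_beta, Xs)
  if (ncol(A_u)) {
    blocks <- c(blocks, list(list(
      name = "u", Qt = as.matrix(Matrix::crossprod(A_u, Q_u %*% A_u)),
      rank = ncol(A_u), A = A_u)))
    design <- c(design, list(A_u[jj, , drop = FALSE]))
  }
  if (na >= 2L) {
    Q_a <- rw1_structure(na)
    blocks <- c(blocks, list(list(
      name = "v", Qt = as.matrix(Matrix::crossprod(A_v, Q_a %*% A_v)),
      rank = ncol(A_v), A = A_v)))
    design <- c(design, list(A_v[aa, , drop = FALSE]))
  }
  if (nt >= 2L) {
    Q_t <- rw1_structure(nt)
    blocks <- c(blocks, list(list(
      name = "w", Qt = as.matrix(Matrix::crossprod(A_w, Q_t %*% A_w)),
      rank = ncol(A_w), A = A_w)))
    design <- c(design, list(A_w[tt, , drop = FALSE]))
  }
  if (nr >= 2L && ncol(A_jz)) {
    A_z <- kronecker(diag(nr), A_jz)  # race-major rows (r-1)*nj + j
    blocks <- c(blocks, list(list(
      name = "z", Qt = diag(nr * ncol(A_jz)),
      rank = nr * ncol(A_jz), A = A_z)))
    design <- c(design, list(A_z[(rr - 1L) * nj + jj, , drop = FALSE]))
  }

  MB <- do.call(cbind, Filter(Negate(is.null), design))
  K_fix <- nr + if (is.null(Xs)) 0L else ncol(Xs)
  at <- K_fix
  for (b in seq_along(blocks)) {
    blocks[[b]]$idx <- at + seq_len(blocks[[b]]$rank)
    at <- at + blocks[[b]]$rank
  }
  K_eff <- at
  theta_idx <- K_eff + seq_along(blocks)

  structure(list(
    strata = grid, D = as.numeric(D), P = as.numeric(P), MB = MB,
    blocks = blocks, K_fix = K_fix, K_eff = K_eff,
    theta_idx = theta_idx, n_par = K_eff + length(blocks),
    beta_idx = seq_len(nr), races = fit_races,
    gamma_idx = if (K_fix > nr) (nr + 1L):K_fix else integer(),
    hyper_sd = hyper_sd, x_scale = x_scale, schema = schema,
    cause = cz, sex = sx, components = membership
  ), class = "model_inputs")
}

#' Negative log-posterior of the small-area model
#'
#' Poisson likelihood `sum(P * m - D * log(P * m))` over strata (terms
#' with `P = 0` contribute 0), plus the Gaussian random-effect penalties
#' `0.5 * tau_k * x_k' Q_k x_k` with rank-aware normalisers
#' `-0.5 * rank_k * log(tau_k)`, plus the log-precision hyperprior.
#' Constant terms that do not involve parameters (e.g. `log(D!)`) are
#' omitted.
#'
#' @param par Numeric parameter vector (fixed effects, random-effect
#'   basis coordinates, log-precisions), length `inputs$n_par`.
#' @param inputs A `model_inputs` object from [build_inputs()].
#' @return Scalar value of the negative log-posterior.
#' @export
neg_log_posterior <- function(par, inputs) {
  if (length(par) != inputs$n_par)
    stop("parameter vector has wrong length")
  if (any(!is.finite(par))) stop("non-finite parameter")
  eta <- drop(inputs$MB %*% par[seq_len(inputs$K_eff)])
  mu <- inputs$P * exp(eta)
  pos <- inputs$D > 0
  out <- sum(mu) - sum(inputs$D[pos] * (log(inputs$P[pos]) + eta[pos]))
  for (b in seq_along(inputs$blocks)) {
    bl <- inputs$blocks[[b]]
    x <- par[bl$idx]
    th <- par[inputs$theta_idx[b]]
    q <- drop(crossprod(x, bl$Qt %*% x))
    out <- out + 0.5 * exp(th) * q - 0.5 * bl$rank * th +
      th^2 / (2 * inputs$hyper_sd^2)
  }
  out
}

#' Gradient of [neg_log_posterior()]
#'
#' @inheritParams neg_log_posterior
#' @return Numeric gradient vector of length `inputs$n_par`.
#' @export
neg_log_posterior_grad <- function(par, inputs) {
  if (any(!is.finite(par))) stop("non-finite parameter")
  eta <- drop(inputs$MB %*% par[seq_len(inputs$K_eff)])
  mu <- inputs$P * exp(eta)
  g <- numeric(length(par))
  g[seq_len(inputs$K_eff)] <- drop(crossprod(inputs$MB, mu - inputs$D))
  for (b in seq_along(inputs$blocks)) {
    bl <- inputs$blocks[[b]]
    x <- par[bl$idx]
    th <- par[inputs$theta_idx[b]]
    Qx <- drop(bl$Qt %*% x)
    g[bl$idx] <- g[bl$idx] + exp(th) * Qx
    g[inputs$theta_idx[b]] <- 0.5 * exp(th) * sum(x * Qx) -
      0.5 * bl$rank + th / inputs$hyper_sd^2
  }
  g
}

default_init <- function(inputs) {
  par <- numeric(inputs$n_par)
  for (r in seq_along(inputs$races)) {
    sel <- inputs$strata$race == inputs$races[r]
    par[r] <- log((sum(inputs$D[sel]) + 0.5) / (sum(inputs$P[sel]) + 1))
  }
  par[inputs$theta_idx] <- log(10)
  par
}

# analytic Hessian of the negative log-posterior in the effect
# coordinates, at effects x_eff with log-precisions theta
effect_hessian <- function(x_eff, theta, inputs) {
  eta <- drop(inputs$MB %*% x_eff)
  mu <- inputs$P * exp(eta)
  H <- crossprod(inputs$MB * mu, inputs$MB)
  for (b in seq_along(inputs$blocks)) {
    bl <- inputs$blocks[[b]]
    H[bl$idx, bl$idx] <- H[bl$idx, bl$idx] + exp(theta[b]) * bl$Qt
  }
  (H + t(H)) / 2
}

# Newton minimisation of the negative log-posterior over the effect
# coordinates at fixed theta; returns the conditional mode and its
# Hessian (and the chol factor for the log-determinant)
inner_mode <- function(theta, inputs, x0, tol = 1e-9, max_iter = 50L) {
  x <- x0
  full <- function(x) c(x, theta)
  f0 <- neg_log_posterior(full(x), inputs)
  for (it in seq_len(max_iter)) {
    g <- neg_log_posterior_grad(full(x), inputs)[seq_len(inputs$K_eff)]
    if (max(abs(g)) < tol) break
    H <- effect_hessian(x, theta, inputs)
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R)) {
      H <- H + diag(1e-8 * max(1, abs(diag(H))), nrow(H))
      R <- chol(H)
    }
    step <- backsolve(R, forwardsolve(t(R), g))
    alpha <- 1
    repeat {
      cand <- x - alpha * step
      fc <- tryCatch(neg_log_posterior(full(cand), inputs),
                     error = function(e) Inf)
      if (is.finite(fc) && fc <= f0 + 1e-12 * abs(f0)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { cand <- x; fc <- f0; break }
    }
    x <- cand; f0 <- fc
  }
  H <- effect_hessian(x, theta, inputs)
  R <- tryCatch(chol(H), error = function(e) NULL)
  g <- neg_log_posterior_grad(full(x), inputs)[seq_len(inputs$K_eff)]
  list(x = x, H = H, R = R, f = f0, grad_norm = max(abs(g)), iter = it)
}

#' Fit the small-area model: MAP effects, empirical-Bayes precisions
#'
#' The log-precisions maximise the Laplace-approximate marginal
#' posterior: for each candidate `theta`, the effects (fixed effects and
#' random-effect basis coordinates) are profiled out by Newton
#' iteration with the analytic Hessian, and the objective is
#' `neg_log_posterior` at the conditional mode plus half the
#' log-determinant of the effect Hessian (the Laplace correction; a
#' joint mode without it is degenerate, collapsing weakly identified
#' random effects). The returned curvature `H` is the analytic effect
#' Hessian at the mode with the precisions plugged in -- the precision
#' of the Laplace approximation on the constraint-respecting subspace.
#'
#' @param inputs A `model_inputs` object.
#' @param tol Convergence tolerance on the effect-gradient max-norm.
#' @param max_iter Maximum outer (precision) iterations.
#' @param init Optional full initial parameter vector (effects then
#'   log-precisions).
#' @return A `fitted_sae` object: `par` (effects and log-precisions at
#'   the fitted mode), `H` (effect curvature), `grad_norm`,
#'   `converged`, `iterations`, and the `inputs` used. Non-convergence
#'   yields a warning, not an error.
#' @export
fit_map <- function(inputs, tol = 1e-6, max_iter = 200L, init = NULL) {
  par0 <- init %||% default_init(inputs)
  nb <- length(inputs$blocks)
  x0 <- par0[seq_len(inputs$K_eff)]
  theta0 <- if (nb) par0[inputs$theta_idx] else numeric()
  warm <- new.env()
  warm$x <- x0
  n_eval <- 0L
  outer_obj <- function(theta) {
    n_eval <<- n_eval + 1L
    m <- inner_mode(theta, inputs, warm$x, tol = tol * 1e-2)
    if (is.null(m$R)) return(1e12)  # indefinite: reject this theta
    warm$x <- m$x
    m$f + sum(log(diag(m$R)))
  }
  outer_conv <- 0L
  if (nb) {
    opt <- optim(theta0, outer_obj, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-10))
    theta <- opt$par
    outer_conv <- opt$convergence
  } else theta <- numeric()
  m <- inner_mode(theta, inputs, warm$x, tol = tol * 1e-2)
  par <- c(m$x, theta)
  converged <- m$grad_norm < tol && outer_conv == 0L
  if (!converged)
    warning("fit_map did not converge (effect gradient max-norm ",
            format(m$grad_norm, digits = 3), ", outer code ",
            outer_conv, ")")
  structure(list(par = par, H = m$H, grad_norm = m$grad_norm,
                 converged = converged, iterations = n_eval,
                 value = m$f, inputs = inputs),
            class = "fitted_sae")
}

#' @export
print.fitted_sae <- function(x, ...) {
  cat("fitted_sae:", x$inputs$cause, "/", x$inputs$sex, "/",
      paste(x$inputs$races, collapse = "+"), "-",
      length(x$par), "parameters, |grad| =",
      format(x$grad_norm, digits = 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  taus <- exp(x$par[x$inputs$theta_idx])
  names(taus) <- vapply(x$inputs$blocks, `[[`, "", "name")
  cat("  precisions:", paste(sprintf("tau_%s=%.3g", names(taus), taus),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Simulate rate draws from the Laplace-approximated posterior
#'
#' Parameter draws are multivariate normal, centred at the posterior
#' mode with covariance equal to the inverse curvature (restricted to
#' the constraint subspace by construction of the basis); each draw is
#' mapped through the linear predictor and exponentiated to a rate
#' surface.
#'
#' @param fitted A `fitted_sae` from [fit_map()].
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed; draws are a pure function of
#'   `(fitted, n_draws, seed)`.
#' @return A [draw_cube()] over the fitted strata grid.
#' @export
draw_posterior <- function(fitted, n_draws = 1000L, seed = 1L) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (!fitted$converged)
    warning("drawing from a fit that did not converge")
  inputs <- fitted$inputs
  R <- tryCatch(chol(fitted$H), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(fitted$H, symmetric = TRUE, only.values = TRUE)$values
    stop("curvature is not positive definite on the constraint subspace ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
  }
  set.seed(seed)
  K <- inputs$K_eff
  Z <- matrix(rnorm(K * n_draws), K, n_draws)
  X <- fitted$par[seq_len(K)] + backsolve(R, Z)
  eta <- inputs$MB %*% X
  draw_cube(inputs$strata, exp(eta))
}
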