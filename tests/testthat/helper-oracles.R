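# independent brute-force negative log-posterior: reconstructs natural
# effects from the basis coordinates, then sums the Poisson and penalty
# terms stratum by stratum with the full (unreduced) structure matrices
brute_nlp <- function(par, inputs, graph, schema) {
  x <- par[seq_len(inputs$K_eff)]
  eff <- list()
  beta0 <- x[inputs$beta_idx]
  for (b in seq_along(inputs$blocks)) {
    bl <- inputs$blocks[[b]]
    eff[[bl$name]] <- as.vector(bl$A %*% x[bl$idx])
  }
  out <- 0
  st <- inputs$strata
  for (i in seq_len(nrow(st))) {
    j <- match(st$county[i], schema$counties)
    r <- match(st$race[i], inputs$races)
    a <- match(st$age[i], schema$ages)
    t <- match(st$year[i], schema$years)
    eta <- beta0[r]
    if (!is.null(eff$u)) eta <- eta + eff$u[j]
    if (!is.null(eff$v)) eta <- eta + eff$v[a]
    if (!is.null(eff$w)) eta <- eta + eff$w[t]
    if (!is.null(eff$z))
      eta <- eta + eff$z[(r - 1L) * length(schema$counties) + j]
    P <- inputs$P[i]; D <- inputs$D[i]
    if (P > 0) {
      out <- out + P * exp(eta)
      if (D > 0) out <- out - D * log(P * exp(eta))
    }
  }
  Qs <- list(u = as.matrix(icar_structure(graph)),
             v = as.matrix(rw1_structure(length(schema$ages))),
             w = as.matrix(rw1_structure(length(schema$years))))
  if (!is.null(eff$z)) Qs$z <- diag(length(eff$z))
  for (b in seq_along(inputs$blocks)) {
    bl <- inputs$blocks[[b]]
    th <- par[inputs$theta_idx[b]]
    e <- eff[[bl$name]]
    out <- out + 0.5 * exp(th) * drop(t(e) %*% Qs[[bl$name]] %*% e) -
      0.5 * bl$rank * th + th^2 / (2 * inputs$hyper_sd^2)
  }
  out
}

# independent brute-force IPF: plain alternating scaler on one matrix
brute_ipf <- function(M, rowm, colm, iters = 2000L) {
  for (i in seq_len(iters)) {
    rs <- rowSums(M)
    M <- M * ifelse(rs == 0, 1, rowm / rs)
    cs <- colSums(M)
    M <- sweep(M, 2L, ifelse(cs == 0, 1, colm / cs), "*")
  }
  M
}

# one county, P = 1e5 per race; M rows = sorted races, cols = sorted causes
ipf_fixture <- function(M, rowm, colm) {
  races <- sort(c("AIAN", "Black", "White")[seq_len(nrow(M))])
  causes <- sort(paste0("cause_", letters[seq_len(ncol(M))]))
  sch <- strata_schema("k1", races, "both", "a1", 2000L, causes)
  pop <- CJ(county = "k1", race = races, sex = "both", age = "a1",
            year = 2000L)[, value := 1e5L]
  pop <- count_table(pop, sch, kind = "population")
  strata <- CJ(county = "k1", race = races, sex = "both", age = "a1",
               year = 2000L, cause = causes, sorted = TRUE)
  # CJ order: race-major, cause fastest -> matches as.vector(t(M))
  cube <- constant_cube(strata, as.vector(t(M)) / 1e5)
  rmc <- constant_cube(
    data.table(county = "k1", race = races, sex = "both", age = "a1",
               year = 2000L, cause = "all_cause"), rowm / 1e5)
  cmc <- constant_cube(
    data.table(county = "k1", race = "Total", sex = "both", age = "a1",
               year = 2000L, cause = causes), colm / (nrow(M) * 1e5))
  list(cube = cube, rm = rmc, cm = cmc, pop = pop,
       unpack = function(out) {
     ord <- order(out$strata$race, out$strata$cause)
     matrix(out$draws[ord, 1] * 1e5, nrow(M), ncol(M), byrow = TRUE)
   })
}
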