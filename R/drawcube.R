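#' Posterior draw cube
#'
#' The pipeline's currency after model fitting: a matrix of simulated
#' mortality-rate surfaces (rows = strata, columns = draws; rates per
#' person-year).
#'
#' @param strata A data.frame of stratum index columns (subset of
#'   `county`, `race`, `sex`, `age`, `year`, `cause`), one row per
#'   stratum, no duplicates.
#' @param draws Numeric matrix, `nrow(strata)` x `n_draws`, finite and
#'   non-negative (model output is strictly positive; calibrated cubes
#'   may contain structural zeros).
#' @return An object of class `draw_cube` with elements `strata`
#'   (keyed `data.table`) and `draws`.
#' @export
draw_cube <- function(strata, draws) {
  strata <- as.data.table(strata)
  idx <- idx_of(strata)
  if (!length(idx)) stop("strata must contain index columns")
  draws <- as.matrix(draws)
  if (nrow(draws) != nrow(strata))
    stop("draws must have one row per stratum")
  if (ncol(draws) < 1L) stop("at least one draw required")
  if (anyNA(draws) || any(!is.finite(draws)))
    stop("draws must be finite")
  if (any(draws < 0)) stop("draws must be non-negative")
  if (anyDuplicated(strata, by = idx)) stop("duplicated strata")
  ord <- do.call(order, strata[, idx, with = FALSE])
  strata <- strata[ord]
  draws <- draws[ord, , drop = FALSE]
  dimnames(draws) <- NULL
  structure(list(strata = strata, draws = draws, n_draws = ncol(draws)),
            class = "draw_cube")
}

#' @export
print.draw_cube <- function(x, ...) {
  cat("draw_cube:", nrow(x$strata), "strata x", x$n_draws, "draws;",
      "dimensions:", paste(idx_of(x$strata), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a draw cube by stratum values
#'
#' @param cube A [draw_cube()].
#' @param ... Named filters, e.g. `race = "White"`, `year = 2019`.
#' @return A [draw_cube()] restricted to matching strata.
#' @export
cube_subset <- function(cube, ...) {
  flt <- list(...)
  keep <- rep(TRUE, nrow(cube$strata))
  for (nm in names(flt))
    keep <- keep & cube$strata[[nm]] %in% flt[[nm]]
  draw_cube(cube$strata[keep], cube$draws[keep, , drop = FALSE])
}

# align cube2's rows to cube1's strata on the shared columns `by`;
# returns the row permutation of cube2 (errors if not a bijection)
cube_align <- function(cube1, cube2, by) {
  k1 <- do.call(paste, c(cube1$strata[, by, with = FALSE], sep = "\r"))
  k2 <- do.call(paste, c(cube2$strata[, by, with = FALSE], sep = "\r"))
  m <- match(k1, k2)
  if (anyNA(m) || anyDuplicated(m))
    stop("cubes do not share a common strata grid on: ",
         paste(by, collapse = ", "))
  m
}

#' Write a draw cube as long-format delimited text
#'
#' One row per stratum and draw: the stratum index columns, a `draw`
#' integer and the `rate` (per person-year). The matching reader
#' reconstructs the cube exactly.
#'
#' @param cube A [draw_cube()].
#' @param path Output file path.
#' @export
write_draw_cube <- function(cube, path) {
  idx <- idx_of(cube$strata)
  long <- cube$strata[rep(seq_len(nrow(cube$strata)), cube$n_draws)]
  long[, draw := rep(seq_len(cube$n_draws), each = nrow(cube$strata))]
  long[, rate := as.vector(cube$draws)]
  fwrite(long, path, sep = ",")
  invisible(path)
}

#' Read a draw cube written by [write_draw_cube()]
#'
#' @param path File path.
#' @return A [draw_cube()].
#' @export
read_draw_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  long <- fread(path, sep = ",")
  idx <- intersect(IDX_COLS, names(long))
  setorderv(long, c("draw", idx))
  strata <- unique(long[draw == 1L, idx, with = FALSE])
  n_draws <- max(long$draw)
  draw_cube(strata, matrix(long$rate, nrow = nrow(strata), ncol = n_draws))
}

# vector of populations aligned to the cube's strata; race = "Total"
# rows get the all-races population
pop_for_cube <- function(cube, population) {
  idx <- intersect(idx_of(cube$strata), setdiff(IDX_COLS, "cause"))
  pop <- as.data.table(population)
  p <- pop[, .(pop = sum(value)), by = idx]
  if ("race" %in% idx) {
    ptot <- pop[, .(pop = sum(value)), by = setdiff(idx, "race")]
    ptot[, race := RACE_TOTAL]
    p <- rbind(p, ptot[, names(p), with = FALSE])
  }
  m <- p[cube$strata, on = idx]
  if (anyNA(m$pop))
    stop("population missing for cube strata")
  m$pop
}
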