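# Internal helpers shared across modules.

# Standard atomic weights (isotope-averaged, amu) for the elements that
# occur in oral drugs; used for inertia tensors and mass oracles.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453,
  Se = 78.971, Br = 79.904, I = 126.904
)

#' Atomic masses for a vector of element symbols
#' @param elements character vector of element symbols (e.g. "C", "Cl")
#' @return numeric vector of isotope-averaged masses in amu
#' @keywords internal
atomicMasses <- function(elements) {
  m <- .ATOMIC_MASS[elements]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Least-squares (Kabsch) superposition RMSD between two coordinate
# matrices (n x 3, same atom order). Optionally restricted to heavy atoms
# by the caller. No symmetry correction is applied.
kabschRMSD <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)), ncol(a) == 3L)
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- a - b %*% t(rot)
  sqrt(sum(diff^2) / nrow(a))
}

# Stable non-cryptographic string hash (for per-molecule seed offsets).
stableStringHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

.checkTool <- function(tool) {
  if (Sys.which(tool) == "") {
    stop("required command-line tool '", tool, "' not found on PATH")
  }
  invisible(TRUE)
}

# Classed error for molecules that cannot produce calculated data
# (unparseable structure, failed 3D embedding, missing force-field
# parameters) -- these are flagged rather than crashing a pipeline run.
descriptorFailure <- function(msg, id = NA_character_) {
  structure(
    class = c("drugspace_descriptor_failure", "error", "condition"),
    list(message = msg, call = sys.call(-1), id = id)
  )
}
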