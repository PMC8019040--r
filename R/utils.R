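#' @useDynLib alphamorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm optimize pchisq pt pf sd var cor prcomp
#'   complete.cases setNames model.matrix cov2cor
#' @importFrom utils read.csv write.csv read.table head tail
NULL

.alphamorph_state <- new.env(parent = emptyenv())

#' Default refinement-coefficient grid
#'
#' 200 values of the dimensionless refinement coefficient k, evenly spaced
#' on a logarithmic scale between 0.1 and 10,000. Small k gives tight
#' "shrink-wrap" alpha shapes, large k approaches the convex hull.
#'
#' @param k_min,k_max grid endpoints (dimensionless, positive).
#' @param n number of grid values.
#' @return strictly increasing numeric vector of length `n`.
#' @export
k_grid_default <- function(k_min = 0.1, k_max = 10000, n = 200) {
  stopifnot(is.numeric(k_min), is.numeric(k_max), k_min > 0, k_max > k_min,
            n >= 2)
  10^seq(log10(k_min), log10(k_max), length.out = n)
}

#' Derive a per-stage random seed from a master seed
#'
#' Stages and specimens get reproducible, well-separated seeds derived from
#' a single master seed and a string tag. The result always fits in a
#' 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param tag character tag naming the stage or specimen.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1, is.finite(master), is.character(tag))
  h <- 0
  for (cc in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 131 + cc) %% 2147480009
  }
  as.integer((abs(as.numeric(master)) %% 2147480009 * 7919 + h) %% 2147480009 + 1)
}

# Run code with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Encode sorted vertex-index triples as exact doubles (valid for < 2^17 verts).
encode_faces <- function(faces) {
  stopifnot(max(faces) < 131072L)
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c_ <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c_
  (as.numeric(a) * 131072 + b) * 131072 + c_
}

# Grouped maximum: for each index in 1..n, max of vals at that index.
group_max <- function(idx, vals, n, init = -Inf) {
  out <- rep(init, n)
  o <- order(vals)          # ascending, so the last write per index wins
  out[idx[o]] <- vals[o]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
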