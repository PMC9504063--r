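# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded internals do not
#' perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Round half away from zero (spreadsheet convention). base::round() uses
# banker's rounding, which would turn 264.5 into 264.
round_half_up <- function(x) floor(x + 0.5)

# Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_param <- function(...) {
  stop(structure(class = c("mgmorph_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' to score recovery of planted shape classes by the clustering.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A number, 1 for identical partitions, about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_param("partitions differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Signed polygon area with x = col, y = row (shoelace). Positive sign is the
# package's counter-clockwise convention in array coordinates.
polygon_signed_area <- function(pts) {
  x <- pts[, 2L]; y <- pts[, 1L]
  n <- nrow(pts)
  i2 <- c(2:n, 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Is each query point inside (or on) the convex polygon `hull` (rows of
# (row, col) vertices in consistent orientation)?
points_in_convex <- function(pts, hull, tol = 1e-9) {
  if (polygon_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  inside <- rep(TRUE, nrow(pts))
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    # cross product sign: positive = left of edge a->b in (col, row) plane
    cr <- (b[2L] - a[2L]) * (pts[, 1L] - a[1L]) - (b[1L] - a[1L]) * (pts[, 2L] - a[2L])
    inside <- inside & (cr >= -tol)
  }
  inside
}
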