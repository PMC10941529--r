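# Internal helpers shared across modules.

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "contourfit_error_degenerate", ...)
}

abort_contract <- function(msg, ...) {
  rlang::abort(msg, class = "contourfit_error_contract", ...)
}

#' @keywords internal
#' @noRd
as_xyz_matrix <- function(points, arg = "points") {
  if (is.matrix(points)) {
    if (ncol(points) != 3) {
      abort_contract(sprintf("`%s` must have three columns (x, y, z).", arg))
    }
    m <- points
    colnames(m) <- c("x", "y", "z")
  } else if (is.data.frame(points)) {
    missing <- setdiff(c("x", "y", "z"), names(points))
    if (length(missing) > 0) {
      abort_contract(sprintf(
        "`%s` is missing column(s): %s.", arg, paste(missing, collapse = ", ")
      ))
    }
    m <- cbind(x = points$x, y = points$y, z = points$z)
  } else {
    abort_contract(sprintf("`%s` must be a data frame or matrix.", arg))
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    abort_contract(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  m
}

as_uv_matrix <- function(points, arg = "points") {
  if (is.matrix(points)) {
    if (ncol(points) != 2) {
      abort_contract(sprintf("`%s` must have two columns (u, v).", arg))
    }
    m <- points
  } else if (is.data.frame(points)) {
    nm <- names(points)
    if (all(c("u", "v") %in% nm)) {
      m <- cbind(points$u, points$v)
    } else if (all(c("x", "y") %in% nm)) {
      m <- cbind(points$x, points$y)
    } else {
      abort_contract(sprintf("`%s` needs columns u,v (or x,y).", arg))
    }
  } else {
    abort_contract(sprintf("`%s` must be a data frame or matrix.", arg))
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("u", "v")
  if (anyNA(m) || any(!is.finite(m))) {
    abort_contract(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  m
}

xyz_tibble <- function(m) {
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort_degenerate("Cannot normalise a near-zero vector.")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Map an angle in degrees to (-180, 180].
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  ifelse(w <= -180, w + 360, w)
}

# Temporarily seed the RNG, restoring the previous state on exit.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
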