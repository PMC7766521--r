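## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## element symbol from a PDB-style atom name; covers H, C, N, O, S, P and the
## common halogens/ions seen in small-molecule work.  No metals (out of scope).
element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1L, 2L)
  one <- substr(nm, 1L, 1L)
  out <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA2"), two, one)
  ## atom names like "CA" (alpha carbon) must stay carbon: only treat a
  ## two-letter symbol as such when the one-letter reading is impossible
  out <- ifelse(one %in% c("H", "C", "N", "O", "S", "P", "F"), one, out)
  bad <- !(out %in% c("H", "C", "N", "O", "S", "P", "F",
                      "CL", "BR", "NA", "MG", "ZN", "FE"))
  if (any(bad))
    stop("unknown element for atom name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  out
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector has no direction")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## rotation matrix for angle theta (radians) about unit axis u (Rodrigues)
rotation_matrix <- function(u, theta) {
  u <- unitv(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

## rotate points (n x 3) about an axis through `origin`
rotate_about_axis <- function(xyz, origin, axis, theta) {
  R <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, "+")
}
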