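# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  stop_if(n < .Machine$double.eps^0.5, "cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrices about coordinate axes (right-hand rule, radians).
rot_y <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, 0, st, 0, 1, 0, -st, 0, ct), 3, 3, byrow = TRUE)
}

rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  # QR-based uniform random rotation, det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Permutation p-value with the observed statistic counted once
#'
#' The observed statistic is treated as one member of the permutation
#' distribution, so the smallest attainable p-value is `1/n_perm` where
#' `n_perm` is `length(perms) + 1`. Ties count against the null
#' (`>=`/`<=` comparison).
#'
#' @param obs observed statistic.
#' @param perms vector of statistics from random permutations (the observed
#'   value is *not* among them).
#' @param tail `"upper"` (reject for large values) or `"lower"`.
#' @return p-value in `(0, 1]`.
#' @keywords internal
perm_pvalue <- function(obs, perms, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  n <- length(perms) + 1L
  hits <- if (tail == "upper") sum(perms >= obs) else sum(perms <= obs)
  (1 + hits) / n
}

# Deterministic child seeds derived from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
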