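# Diffusion gradient tables: b-values plus unit direction cosines, in the
# FSL bval/bvec dialect when on disk.

#' Construct a gradient table
#'
#' @param bvals Numeric vector of b-values (s/mm^2).
#' @param bvecs Numeric matrix (length(bvals) x 3) of direction cosines;
#'   rows with b > 0 must be unit vectors (tolerance 1e-6), b = 0 rows may
#'   be zero.
#' @return An object of class `gradient_table`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals and bvecs must have equal length", call. = FALSE)
  }
  if (!any(bvals == 0)) {
    stop("gradient table must contain at least one b = 0 entry", call. = FALSE)
  }
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("all nonzero-b directions must have unit norm (within 1e-6)",
         call. = FALSE)
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(round(x$bvals)))
  cat("<gradient_table> ", length(x$bvals), " entries; shells: ",
      paste(shells, collapse = ", "), " s/mm^2 (",
      sum(x$bvals == 0), " b0)\n", sep = "")
  invisible(x)
}

#' Generate a single-shell acquisition scheme
#'
#' Directions are an approximately uniform Fibonacci-spiral hemisphere set,
#' rotated by a random rotation drawn from the seed, so repeated calls with
#' the same seed are bit-identical.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6).
#' @param b Shell b-value in s/mm^2 (> 0).
#' @param n_b0 Number of b = 0 entries, placed first.
#' @param seed Integer seed for the orienting rotation.
#' @return A [gradient_table()].
#' @export
make_gradient_table <- function(n_directions, b = 1000, n_b0 = 1, seed = 1) {
  if (n_directions < 6) {
    stop("at least 6 diffusion directions are required (tensor underdetermined)",
         call. = FALSE)
  }
  if (b <= 0) stop("b must be positive", call. = FALSE)
  if (n_b0 < 1) stop("at least one b = 0 entry is required", call. = FALSE)
  d <- fibonacci_hemisphere(n_directions)
  Q <- withr::with_seed(as.integer(seed), {
    M <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
  d <- d %*% Q
  d <- d / sqrt(rowSums(d^2))
  gradient_table(c(rep(0, n_b0), rep(b, n_directions)),
                 rbind(matrix(0, n_b0, 3), d))
}

#' Read / write FSL-dialect bval and bvec files
#'
#' `bvec` files hold three whitespace-separated rows (x, y, z components),
#' `bval` files one row of b-values.
#'
#' @param prefix Path prefix; `<prefix>.bval` and `<prefix>.bvec` are used.
#' @return `read_bval_bvec()` returns a [gradient_table()];
#'   `write_bval_bvec()` returns `prefix` invisibly.
#' @export
read_bval_bvec <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bv <- scan(paste0(prefix, ".bvec"), quiet = TRUE)
  bv <- matrix(bv, nrow = 3, byrow = TRUE)
  gradient_table(bvals, t(bv))
}

#' @param gtab A [gradient_table()].
#' @rdname read_bval_bvec
#' @export
write_bval_bvec <- function(gtab, prefix) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  rows <- apply(t(gtab$bvecs), 1, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")
  })
  writeLines(rows, paste0(prefix, ".bvec"))
  invisible(prefix)
}
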