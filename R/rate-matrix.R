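#' Build the BLOSUM62-equivalent substitution rate matrix
#'
#' Constructs the generator \code{Q} of a reversible continuous-time Markov
#' substitution model whose one-step conditional probabilities match the
#' BLOSUM62 target frequencies. The recipe: form the conditional matrix
#' \code{M[a, b] = joint(a, b) / background(a)} from
#' \code{\link{blosum62_frequencies}}, take its principal matrix logarithm,
#' clamp the (numerically small) negative off-diagonal rates to zero, reset
#' the diagonal so rows sum to zero, and rescale so the expected rate is one
#' substitution per site per unit time. Branch lengths fed to
#' \code{\link{transition_matrix}} are therefore expected substitutions per
#' site.
#'
#' Because the joint table is symmetric, the model is reversible: its
#' stationary distribution equals the BLOSUM62 background frequencies and
#' detailed balance holds exactly (clamping removes rate pairs jointly, so it
#' cannot break reversibility). The eigendecomposition is computed through
#' the similarity transform \code{diag(sqrt(pi)) Q diag(1/sqrt(pi))}, which
#' is symmetric by detailed balance, guaranteeing real eigenvalues.
#'
#' @param clamp_threshold Maximum magnitude of a negative off-diagonal rate
#'   (before rescaling) that clamping is allowed to remove; a larger value
#'   signals a corrupted frequency table and is an error.
#' @param imag_tol Maximum tolerated imaginary part in the matrix logarithm
#'   (the symmetrized problem is real; this guards the eigenvalue sign).
#' @return An object of class \code{rate_matrix}: a list with the generator
#'   \code{q} (20 x 20, rows sum to 0), stationary distribution \code{pi},
#'   eigenvectors \code{u}, eigenvalues \code{lam}, inverse eigenvectors
#'   \code{u_inv}, and \code{alphabet}.
#' @seealso \code{\link{transition_matrix}}, \code{\link{aa_alphabet}}
#' @export
#' @examples
#' m <- blosum62_rate_matrix()
#' range(rowSums(m$q))            # ~0
#' -sum(m$pi * diag(m$q))         # 1: unit expected rate
blosum62_rate_matrix <- function(clamp_threshold = 0.01, imag_tol = 1e-8) {
  f <- blosum62_frequencies()
  p <- f$background
  sq <- sqrt(p)
  # D^{1/2} M D^{-1/2} = D^{-1/2} J D^{-1/2} is symmetric positive definite,
  # so the principal log of the conditional matrix M is real.
  sym <- f$joint / outer(sq, sq)
  e <- eigen(sym, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("conditional BLOSUM62 matrix is not positive definite; its principal matrix logarithm is not real",
         call. = FALSE)
  if (imag_tol <= 0) stop("'imag_tol' must be positive")
  logm_sym <- e$vectors %*% (log(e$values) * t(e$vectors))
  q <- sweep(sweep(logm_sym, 1, sq, "/"), 2, sq, "*")

  off <- q; diag(off) <- 0
  worst <- min(off)
  if (worst < -clamp_threshold)
    stop(sprintf("matrix logarithm produced an off-diagonal rate of %.4g; clamping would exceed the threshold %.4g (corrupted frequency table?)",
                 worst, clamp_threshold), call. = FALSE)
  off[off < 0] <- 0
  q <- off
  diag(q) <- -rowSums(q)

  rate <- -sum(p * diag(q))
  q <- q / rate
  dimnames(q) <- list(.AA, .AA)

  # spectral decomposition of the final generator via the same symmetrization
  symq <- sweep(sweep(q, 1, sq, "*"), 2, sq, "/")
  eq <- eigen((symq + t(symq)) / 2, symmetric = TRUE)
  u <- sweep(eq$vectors, 1, sq, "/")
  u_inv <- t(sweep(eq$vectors, 1, sq, "*"))

  structure(list(q = q, pi = p, u = u, lam = eq$values, u_inv = u_inv,
                 alphabet = .AA),
            class = "rate_matrix")
}

#' Transition probabilities after evolutionary time t
#'
#' Computes \code{P(t) = exp(Q t)} through the stored eigendecomposition,
#' \code{u diag(exp(lam t)) u_inv}. \code{P(t)[a, b]} is the probability
#' that a site occupied by residue \code{a} is occupied by residue \code{b}
#' after evolutionary time \code{t} (expected substitutions per site); rows
#' are therefore conditional distributions over the descendant residue.
#' Entries that come out numerically negative (rounding at large \code{t})
#' are clamped to zero and the row renormalized; the renormalization is
#' required to be a no-op to within \code{1e-8}.
#'
#' @param m A \code{rate_matrix} from \code{\link{blosum62_rate_matrix}}.
#' @param t Evolutionary time, a single non-negative number.
#' @return An object of class \code{transition_matrix}: list with the
#'   row-stochastic matrix \code{p} and the time \code{t}.
#' @export
#' @examples
#' m <- blosum62_rate_matrix()
#' p <- transition_matrix(m, 0.2)
#' rowSums(p$p)      # all 1
#' p$p["H", "D"]     # P(His -> Asp | t = 0.2)
transition_matrix <- function(m, t) {
  stopifnot(inherits(m, "rate_matrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single non-negative number", call. = FALSE)
  p <- m$u %*% (exp(m$lam * t) * m$u_inv)
  p[p < 0] <- 0
  rs <- rowSums(p)
  if (max(abs(rs - 1)) > 1e-8)
    stop(sprintf("row sums of P(t) deviate from 1 by %.3g before renormalization; the decomposition is numerically unsound at t = %g",
                 max(abs(rs - 1)), t), call. = FALSE)
  p <- p / rs
  dimnames(p) <- list(m$alphabet, m$alphabet)
  structure(list(p = p, t = t), class = "transition_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("BLOSUM62-equivalent substitution rate matrix (20 states)\n")
  cat(sprintf("  expected rate: %.6f substitutions/site/unit time\n",
              -sum(x$pi * diag(x$q))))
  cat("  stationary distribution (top 5):\n")
  top <- sort(x$pi, decreasing = TRUE)[1:5]
  cat(sprintf("    %s", paste(sprintf("%s=%.3f", names(top), top), collapse = " ")), "\n")
  invisible(x)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition probability matrix at t = %g (rows: ancestral residue)\n", x$t))
  print(round(x$p[1:5, 1:5], 4))
  cat("  ... (20 x 20)\n")
  invisible(x)
}

#' Export a model matrix as TSV
#'
#' Writes the generator \code{q}, the stationary vector \code{pi}, or a
#' transition matrix as tab-separated text with one-letter amino-acid row
#' and column headers.
#'
#' @param x A \code{rate_matrix}, \code{transition_matrix}, matrix or named
#'   vector.
#' @param path Output file path.
#' @param what For a \code{rate_matrix}: \code{"q"} or \code{"pi"}.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(x, path, what = c("q", "pi")) {
  if (inherits(x, "rate_matrix")) x <- x[[match.arg(what)]]
  if (inherits(x, "transition_matrix")) x <- x$p
  if (is.matrix(x)) {
    utils::write.table(data.frame(aa = rownames(x), x, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(data.frame(aa = names(x), value = unname(x)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
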