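# GTR+I+G substitution model: reversible rate matrix Q with q_ij = s_ij pi_j,
# normalised to one expected substitution per site per unit branch length,
# discrete-gamma rate heterogeneity (category means over equal-probability
# bins) and a proportion of invariant sites.

#' GTR+I+G model parameters
#'
#' @param rates six exchangeabilities in order AC, AG, AT, CG, CT, GT. GT is
#'   the reference and is rescaled to 1, leaving 5 free.
#' @param freqs equilibrium base frequencies (A, C, G, T), strictly positive,
#'   normalised to sum to 1.
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param alpha gamma shape (> 0). `Inf` disables rate heterogeneity.
#' @param ncat number of discrete gamma categories (default 4).
#' @return An object of class `gtr_params`.
#' @export
gtr_params <- function(rates = rep(1, 6), freqs = rep(0.25, 4),
                       p_inv = 0, alpha = Inf, ncat = 4L) {
  rates <- as.numeric(rates)
  freqs <- as.numeric(freqs)
  if (length(rates) != 6L || any(rates <= 0))
    stop("need 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  if (length(freqs) != 4L || any(freqs <= 0))
    stop("base frequencies must be 4 positive values")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(rates = rates / rates[6L],
                 freqs = freqs / sum(freqs),
                 p_inv = p_inv, alpha = alpha, ncat = as.integer(ncat)),
            class = "gtr_params")
}

#' @export
print.gtr_params <- function(x, ...) {
  cat("GTR+I+G parameters\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(x$rates, 4), collapse = " "), "\n")
  cat("  base frequencies (A C G T):",
      paste(signif(x$freqs, 4), collapse = " "), "\n")
  cat("  p_inv:", signif(x$p_inv, 4), "  alpha:", signif(x$alpha, 4),
      "  gamma categories:", x$ncat, "\n")
  invisible(x)
}

#' Build the normalised GTR rate matrix
#'
#' @param params a [gtr_params()] object.
#' @return 4x4 rate matrix `Q` with `q_ij = s_ij * pi_j` off-diagonal, rows
#'   summing to zero, scaled so the mean rate `-sum(pi_i q_ii)` is 1.
#' @export
gtr_rate_matrix <- function(params) {
  s <- params$rates
  pi <- params$freqs
  S <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  S[1,2] <- S[2,1] <- s[1]  # AC
  S[1,3] <- S[3,1] <- s[2]  # AG
  S[1,4] <- S[4,1] <- s[3]  # AT
  S[2,3] <- S[3,2] <- s[4]  # CG
  S[2,4] <- S[4,2] <- s[5]  # CT
  S[3,4] <- S[4,3] <- s[6]  # GT
  Q <- S * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# eigen decomposition of the reversible Q via the symmetrised form
# B = D^{1/2} Q D^{-1/2}; returns vectors/values so P(t) = V exp(L t) Vinv.
gtr_eigen <- function(params) {
  Q <- gtr_rate_matrix(params)
  pi <- params$freqs
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       vectors = diag(1 / d) %*% e$vectors,
       inv = t(e$vectors) %*% diag(d))
}

#' Transition probability matrix
#'
#' @param params a [gtr_params()] object (or a precomputed decomposition from
#'   the internal eigen helper, for repeated calls).
#' @param t branch length in expected substitutions/site (>= 0).
#' @param r rate multiplier (> 0), e.g. a gamma category rate.
#' @return 4x4 stochastic matrix `P = exp(Q r t)`.
#' @export
transition_prob <- function(params, t, r = 1) {
  if (t < 0) stop("branch length must be >= 0")
  if (r <= 0) stop("rate multiplier must be > 0")
  e <- if (inherits(params, "gtr_params")) gtr_eigen(params) else params
  P <- e$vectors %*% (exp(e$values * r * t) * e$inv)
  dimnames(P) <- list(c("A","C","G","T"), c("A","C","G","T"))
  # clip tiny negative round-off
  P[P < 0] <- 0
  P
}

#' Discrete gamma rate categories
#'
#' Mean rates of `ncat` equal-probability bins of a Gamma(alpha, alpha)
#' density, so the category mean is 1.
#'
#' @param alpha gamma shape (> 0); `Inf` gives all-ones.
#' @param ncat number of categories (>= 1).
#' @return Increasing numeric vector of length `ncat` with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("need >= 1 category")
  if (ncat == 1L || !is.finite(alpha)) return(rep(1, ncat))
  qb <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha,
                      rate = alpha)
  # E[X | bin] via the Gamma(alpha+1, alpha) cdf identity
  p <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  ncat * diff(p)
}
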