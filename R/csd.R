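#' Current source density parameters
#'
#' Parameters of the spherical-spline surface Laplacian: spline order `m`
#' (smoothness of the interpolating spline), the number of Legendre terms in
#' the series expansions, the Tikhonov regularisation added to the spline
#' system, and the head radius used to scale the Laplacian to uV/m^2. The
#' defaults (m = 4, 50 terms, lambda = 1e-5, 0.09 m) are the common
#' literature defaults; all are configurable and recorded with the output.
#'
#' @param m Spline order, integer >= 2.
#' @param legendre_terms Number of Legendre polynomial terms, >= 20.
#' @param lambda Nonnegative regularisation added to the diagonal.
#' @param head_radius Head radius in metres.
#' @return A list of class `csd_params`.
#' @export
csd_params <- function(m = 4, legendre_terms = 50, lambda = 1e-5,
                       head_radius = 0.09) {
  assert_that(is_count(m) && m >= 2, "spline order m must be an integer >= 2")
  assert_that(is_count(legendre_terms) && legendre_terms >= 20,
              "legendre_terms must be an integer >= 20")
  assert_that(lambda >= 0, "lambda must be nonnegative")
  structure(list(m = m, legendre_terms = legendre_terms, lambda = lambda,
                 head_radius = head_radius),
            class = "csd_params")
}

# Legendre polynomials P_1..P_L evaluated at x (vectorised), by recurrence.
legendre_upto <- function(x, L) {
  out <- matrix(0, nrow = length(x), ncol = L)
  p_prev <- rep(1, length(x))  # P_0
  p <- x                       # P_1
  out[, 1] <- p
  for (l in 2:L) {
    p_next <- ((2 * l - 1) * x * p - (l - 1) * p_prev) / l
    out[, l] <- p_next
    p_prev <- p
    p <- p_next
  }
  out
}

# The spline kernels of the spherical-spline interpolation. g() interpolates
# potentials; h() carries the (negative) surface Laplacian of g().
csd_gh <- function(cosmat, m, L) {
  l <- seq_len(L)
  P <- legendre_upto(as.vector(cosmat), L)
  gcoef <- (2 * l + 1) / (l * (l + 1))^m / (4 * pi)
  hcoef <- (2 * l + 1) / (l * (l + 1))^(m - 1) / (4 * pi)
  G <- matrix(P %*% gcoef, nrow = nrow(cosmat))
  H <- matrix(P %*% hcoef, nrow = nrow(cosmat))
  list(G = G, H = H)
}

# Precompute the linear map from potentials to CSD values at the electrodes.
# The spline v(E) = c0 + sum_i c_i g(cos(E, E_i)) is fit with sum(c) = 0 via
# the bordered system; the output is H %*% c / r^2 (negative surface
# Laplacian, uV/m^2).
csd_matrix <- function(mont, labels, params) {
  cosmat <- montage_cosines(mont, labels)
  gh <- csd_gh(cosmat, params$m, params$legendre_terms)
  n <- length(labels)
  A <- rbind(cbind(gh$G + diag(params$lambda, n), rep(1, n)),
             c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e) {
    abort(paste0("singular spherical-spline system (duplicate electrode ",
                 "positions?): ", conditionMessage(e)))
  })
  # rows 1..n of Ainv map [v; 0] to the spline coefficients c
  (gh$H %*% Ainv[seq_len(n), seq_len(n)]) / params$head_radius^2
}

#' Spherical-spline current source density (surface Laplacian) transform
#'
#' Fits, for every epoch and time sample, a regularised spherical-spline
#' interpolation of the scalp potentials on the unit sphere and returns the
#' negative surface Laplacian scaled by `head_radius^-2`, in uV/m^2. The
#' transform is linear, reference-free (adding any per-sample constant across
#' channels leaves the output unchanged), and maps spatially constant input
#' to zero.
#'
#' @param ep An [epoch_set] in microvolts, after [reject_artifacts()].
#' @param mont A [montage()] covering all scalp channels of `ep`.
#' @param params A [csd_params()].
#' @return The transformed epoch set (units `"uV/m^2"`, `csd_applied` set).
#' @export
csd_transform <- function(ep, mont, params = csd_params()) {
  if (ep$csd_applied) abort("epochs are already CSD-transformed")
  if (!ep$artifact_checked) {
    abort("pipeline order: run reject_artifacts() before csd_transform()")
  }
  labels <- ep$channels$label
  missing <- setdiff(labels, mont$label)
  assert_that(length(missing) == 0,
              paste0("montage does not cover scalp channel(s): ",
                     paste(missing, collapse = ", ")))
  M <- csd_matrix(mont, labels, params)
  for (i in seq_len(dim(ep$data)[1])) {
    ep$data[i, , ] <- M %*% ep$data[i, , ]
  }
  ep$units <- "uV/m^2"
  ep$csd_applied <- TRUE
  ep$csd_params <- params
  ep
}
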