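## Unseen-molecule estimators. All three operate on a single CU histogram and
## answer: how many distinct molecules would be seen if the total read count
## were multiplied by (t + 1)?

degenerateHistogram <- function(msg) {
  stop(structure(class = c("umisat_degenerate_histogram", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

estimatorUnstable <- function(msg) {
  stop(structure(class = c("umisat_estimator_unstable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Good-Toulmin estimator of new molecules
#'
#' Estimates the number of new molecules U discovered when the total read
#' count is multiplied by t + 1, via the alternating sum
#' \deqn{U = -\sum_{i \ge 1} (-t)^i h(i),}
#' where h(i) is the number of molecules seen with exactly i copies. The
#' estimator is distribution-free but the series is only stable for t <= 1;
#' larger t requires an explicit override.
#'
#' @param h a [CUHistogram-class].
#' @param t extrapolation factor, in [0, 1] unless
#'   \code{allowExtrapolation = TRUE}.
#' @param allowExtrapolation permit t > 1 despite the known instability.
#' @return A [PredictionResult-class]; a negative sum is floored so that
#'   predicted distinct molecules are >= 0, with the \code{clamped} flag set.
#' @examples
#' goodToulmin(CUHistogram(c(`1` = 5, `2` = 3)), t = 1)
#' @export
goodToulmin <- function(h, t, allowExtrapolation = FALSE) {
  stopifnot(is(h, "CUHistogram"))
  if (t < 0) stop("extrapolation factor t must be >= 0")
  if (t > 1 && !allowExtrapolation)
    stop("the Good-Toulmin series is unstable for t > 1; ",
         "set allowExtrapolation = TRUE to override")
  N <- nMolecules(h)
  U <- -sum((-t)^as.numeric(h@copies) * h@molecules)
  clamped <- (N + U) < 0
  distinct <- max(N + U, 0)
  new("PredictionResult", method = "good_toulmin", t = t,
      distinct = distinct, newMolecules = distinct - N, N = N,
      mt = NA_integer_, clamped = clamped)
}

## log NB density at 0 in the mean/size parameterization:
## pdf(0; mu, s) = (s/(s+mu))^s
logNB0 <- function(mu, size) size * (log(size) - log(size + mu))

#' Fit a zero-truncated negative binomial to a CU histogram by EM
#'
#' Models per-molecule read counts as NB(mu, size); molecules drawing zero
#' reads are unobserved, so the observed histogram is zero-truncated. The EM
#' iteration alternates an E step that imputes the unseen molecules
#' (L = N / (1 - pdf(0; mu, size)), z = L * pdf(0)) and updates the mean
#' (mu = sum i h(i) / L), with an M step that maximizes the complete-data
#' log-likelihood over the size parameter by L-BFGS-B, using the analytic
#' digamma gradient. Starting values are mu = 0.5, size = 1.
#'
#' @param h a [CUHistogram-class] with at least two distinct copy levels and
#'   at least \code{minMolecules} molecules; degenerate histograms raise an
#'   error of class \code{umisat_degenerate_histogram} (callers typically
#'   fall back to no correction).
#' @param tol relative change in the complete-data log-likelihood below which
#'   the iteration stops (default 1e-8). The likelihood surface has a long
#'   ridge at low saturation (the size parameter drifts toward a
#'   quasi-Poisson fit before the iteration turns toward the optimum), and a
#'   looser tolerance can stop the EM on that ridge, badly underestimating
#'   the library size; 1e-8 escapes it at negligible cost since each
#'   iteration only touches the distinct copy levels.
#' @param maxIter iteration cap (default 10000; low-saturation histograms
#'   legitimately take several thousand cheap iterations).
#' @param minMolecules minimum N for a fit to be attempted (default 20).
#' @param startSizes initial size values for the EM (the mean always starts
#'   at 0.5). The truncated likelihood has a spurious boundary attractor at
#'   size -> Inf (a zero-truncated Poisson limit) that can capture the EM
#'   when saturation is low; running the EM from an additional
#'   highly-dispersed start and keeping the candidate with the better
#'   observed-data (zero-truncated) log-likelihood makes the fit robust.
#' @return A [ZTNBFit-class].
#' @seealso [ztnbPredict()]
#' @export
ztnbFit <- function(h, tol = 1e-8, maxIter = 10000L, minMolecules = 20,
                    startSizes = c(1, 0.1)) {
  stopifnot(is(h, "CUHistogram"))
  N <- nMolecules(h)
  if (length(h@copies) < 2L)
    degenerateHistogram(sprintf(
      "gene '%s': ZTNB needs >= 2 distinct copy levels", h@gene))
  if (N < minMolecules)
    degenerateHistogram(sprintf(
      "gene '%s': ZTNB needs >= %g molecules, got %g", h@gene,
      minMolecules, N))
  i <- as.numeric(h@copies)
  hi <- h@molecules
  truncll <- function(mu, s) {
    p0 <- exp(logNB0(mu, s))
    sum(hi * (stats::dnbinom(i, size = s, mu = mu, log = TRUE) -
                log1p(-p0)))
  }
  fits <- lapply(startSizes, function(s0)
    ztnbEM(h, s0, tol = tol, maxIter = maxIter))
  obs <- vapply(fits, function(f) truncll(f@mu, f@size), numeric(1))
  fits[[which.max(obs)]]
}

## one EM run from a fixed starting size
ztnbEM <- function(h, startSize, tol, maxIter) {
  N <- nMolecules(h)
  S <- nReads(h)
  i <- as.numeric(h@copies)
  hi <- h@molecules
  mu <- 0.5
  size <- startSize
  llPrev <- NA_real_
  ll <- NA_real_
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    ## E step: impute the zero-copy mass, then update the mean
    p0 <- exp(logNB0(mu, size))
    L <- N / (1 - p0)
    z <- L * p0
    mu <- S / L
    ## M step: maximize complete-data log-likelihood over size.
    ## Gradient is L * pd(size) with
    ## pd(s) = sum digamma(i+s) h(i) / L - digamma(s) + log s - log(s + mu)
    ## (the zero bin contributes z * digamma(s); with mu = S/L the remaining
    ## terms of d/ds log-lik cancel exactly).
    negll <- function(s)
      -(z * logNB0(mu, s) +
          sum(hi * stats::dnbinom(i, size = s, mu = mu, log = TRUE)))
    neggr <- function(s)
      -(z * digamma(s) + sum(hi * digamma(i + s)) - L * digamma(s) +
          L * (log(s) - log(s + mu)))
    opt <- stats::optim(size, fn = negll, gr = neggr, method = "L-BFGS-B",
                        lower = 1e-6, upper = 1e8)
    size <- opt$par
    ll <- -opt$value
    if (!is.na(llPrev) && abs(ll - llPrev) / abs(ll) < tol) {
      converged <- TRUE
      break
    }
    llPrev <- ll
  }
  ## closing E step so the L = N / (1 - pdf(0)) invariant holds exactly for
  ## the reported (mu, size)
  p0 <- exp(logNB0(mu, size))
  L <- N / (1 - p0)
  z <- L * p0
  new("ZTNBFit", mu = mu, size = size, L = L, z = z, N = N, logLik = ll,
      converged = converged, nIter = iter)
}

#' Predict distinct molecules at higher depth from a ZTNB fit
#'
#' Assumes the NB size parameter is invariant as reads accumulate while the
#' mean scales proportionally with the read total, so at extrapolation factor
#' t the expected distinct molecules are
#' \deqn{L (1 - pdf(0; \mu (t+1), s)).}
#' At t = 0 this returns exactly the observed N; as t grows it saturates at
#' the estimated library size L.
#'
#' @param fit a [ZTNBFit-class].
#' @param t extrapolation factor >= 0.
#' @return A [PredictionResult-class].
#' @export
ztnbPredict <- function(fit, t) {
  stopifnot(is(fit, "ZTNBFit"))
  if (t < 0) stop("extrapolation factor t must be >= 0")
  distinct <- fit@L * (1 - exp(logNB0(fit@mu * (t + 1), fit@size)))
  new("PredictionResult", method = "ztnb", t = t, distinct = distinct,
      newMolecules = distinct - fit@N, N = fit@N, mt = NA_integer_,
      clamped = FALSE)
}

#' Daley-Smith rational-function estimator
#'
#' Stabilizes the Good-Toulmin alternating power series by a Pade rational
#' approximant so that extrapolation far beyond t = 1 stays bounded. The CU
#' histogram is first truncated to copy levels <= \code{mt} (default 2, which
#' needs only the single-copy and two-copy fractions and is therefore robust
#' to sparse histograms and usable with pooled 3-bin histograms); the series
#' coefficients \eqn{(-1)^{i+1} h(i)} then define a degree-[p/q] rational
#' function with p + q + 1 equal to the number of coefficients. A defective
#' approximant (denominator pole inside (0, t]) triggers a degree back-off;
#' if no stable approximant exists an error of class
#' \code{umisat_estimator_unstable} is raised. For even coefficient counts
#' the approximant has a finite saturation asymptote, returned analytically
#' for very large t (evaluation is performed in powers of 1/t, so t as large
#' as 1e20 is exact).
#'
#' @param h a [CUHistogram-class].
#' @param t extrapolation factor >= 0.
#' @param mt histogram truncation level (default 2).
#' @return A [PredictionResult-class].
#' @examples
#' ## with mt = 2 the t -> Inf asymptote is N + h(1)^2 / h(2)
#' dsPredict(CUHistogram(c(`1` = 100, `2` = 50)), t = 1e20)
#' @export
dsPredict <- function(h, t, mt = 2L) {
  stopifnot(is(h, "CUHistogram"))
  if (t < 0) stop("extrapolation factor t must be >= 0")
  if (mt < 1) stop("mt must be >= 1")
  N <- nMolecules(h)
  keep <- h@copies <= mt
  if (!any(keep))
    degenerateHistogram(sprintf(
      "gene '%s': no copy levels <= mt = %d", h@gene, mt))
  ## dense series coefficients a_i = (-1)^(i+1) h(i), i = 1..mt
  a <- numeric(max(h@copies[keep]))
  a[h@copies[keep]] <- h@molecules[keep]
  a <- a * (-1)^(seq_along(a) + 1)
  while (length(a) && a[length(a)] == 0) a <- a[-length(a)]
  if (sum(a != 0) < 2L)
    estimatorUnstable(sprintf(
      "gene '%s': fewer than two usable series coefficients after truncation",
      h@gene))
  fval <- NULL
  for (m in rev(seq(2L, length(a)))) {
    pade <- tryCatch(padeFromSeries(a[seq_len(m)]), error = function(e) NULL)
    if (is.null(pade)) next
    if (hasPoleIn(pade$den, t)) next
    fval <- evalPadeTimesT(pade$num, pade$den, t)
    if (is.finite(fval)) break
    fval <- NULL
  }
  if (is.null(fval))
    estimatorUnstable(sprintf(
      "gene '%s': no stable rational approximant on (0, %g]", h@gene, t))
  distinct <- max(N + fval, 0)
  new("PredictionResult", method = "ds", t = t, distinct = distinct,
      newMolecules = distinct - N, N = N, mt = as.integer(mt),
      clamped = FALSE)
}

## Pade approximant of g(u) = sum_{k>=0} b_k u^k from the series
## f(t) = t * g(t) with b_k = a_{k+1}. Returns numerator coefficients
## c_0..c_p and denominator coefficients d_0 = 1, d_1..d_q with
## q = floor(m/2), p = m - 1 - q, matching the series through order m - 1.
padeFromSeries <- function(a) {
  b <- a
  m <- length(b)
  q <- m %/% 2L
  p <- m - 1L - q
  bAt <- function(k) ifelse(k >= 0 & k < m, b[k + 1L], 0)
  if (q > 0L) {
    A <- outer(p + seq_len(q), seq_len(q), function(k, j) bAt(k - j))
    rhs <- -vapply(p + seq_len(q), bAt, numeric(1))
    d <- solve(A, rhs)
    if (any(!is.finite(d))) stop("singular Pade system")
  } else d <- numeric(0)
  dFull <- c(1, d)
  cc <- vapply(0:p, function(k) {
    j <- 0:min(k, q)
    sum(dFull[j + 1L] * vapply(k - j, bAt, numeric(1)))
  }, numeric(1))
  list(num = cc, den = dFull)
}

## does the denominator polynomial (coefficients in increasing order of u)
## have a real root in (0, t]?
hasPoleIn <- function(den, t) {
  if (length(den) < 2L) return(FALSE)
  r <- polyroot(den)
  real <- abs(Im(r)) < 1e-8 * (abs(r) + 1e-12)
  any(real & Re(r) > 0 & Re(r) <= t + 1e-12)
}

## evaluate f(t) = t * num(t) / den(t); for |t| > 1 use Horner in u = 1/t so
## astronomically large t (the saturation regime) evaluates without overflow.
evalPadeTimesT <- function(num, den, t) {
  p <- length(num) - 1L
  q <- length(den) - 1L
  horner <- function(coef, x) {
    acc <- 0
    for (k in rev(seq_along(coef))) acc <- acc * x + coef[k]
    acc
  }
  if (t <= 1) return(t * horner(num, t) / horner(den, t))
  u <- 1 / t
  numU <- horner(rev(num), u)   # num(t) = t^p * numU(u)
  denU <- horner(rev(den), u)   # den(t) = t^q * denU(u)
  expo <- 1L + p - q
  t^expo * numU / denU
}
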