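# Candidate distribution families for per-site background AF modelling.
#
# Each family is registered with density, CDF, quantile and random
# generators plus moment-based starting values for maximum-likelihood
# fitting. Parameter vectors are named numeric vectors; positivity
# constraints are handled by fitting on a log scale internally.

skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# ---- double Weibull: shape c, loc, scale ------------------------------------
ddweibull <- function(x, shape, loc = 0, scale = 1, log = FALSE) {
  z <- abs((x - loc) / scale)
  lf <- log(shape / 2) - log(scale) + (shape - 1) * log(pmax(z, 1e-300)) - z^shape
  if (log) lf else exp(lf)
}
pdweibull <- function(q, shape, loc = 0, scale = 1) {
  z <- (q - loc) / scale
  ifelse(z < 0, 0.5 * exp(-abs(z)^shape), 1 - 0.5 * exp(-z^shape))
}
qdweibull <- function(p, shape, loc = 0, scale = 1) {
  ifelse(p < 0.5,
         loc - scale * (-log(2 * p))^(1 / shape),
         loc + scale * (-log(2 * (1 - p)))^(1 / shape))
}

# ---- alpha: shape a, scale ---------------------------------------------------
dalpha <- function(x, a, scale = 1, log = FALSE) {
  z <- x / scale
  lf <- ifelse(z > 0,
               -log(scale) - 2 * log(z) - 0.5 * (a - 1 / z)^2 -
                 stats::pnorm(a, log.p = TRUE) - 0.5 * log(2 * pi),
               -Inf)
  if (log) lf else exp(lf)
}
palpha <- function(q, a, scale = 1) {
  z <- q / scale
  ifelse(z > 0, stats::pnorm(a - 1 / z) / stats::pnorm(a), 0)
}
qalpha <- function(p, a, scale = 1) {
  scale / (a - stats::qnorm(p * stats::pnorm(a)))
}

# ---- exponentially-modified normal: K, mu, sigma ----------------------------
dexponnorm <- function(x, K, mu = 0, sigma = 1, log = FALSE) {
  u <- (x - mu) / sigma
  lf <- -log(K * sigma) + 1 / (2 * K^2) - u / K +
    stats::pnorm(u - 1 / K, log.p = TRUE)
  if (log) lf else exp(lf)
}
pexponnorm <- function(q, K, mu = 0, sigma = 1) {
  u <- (q - mu) / sigma
  lt <- 1 / (2 * K^2) - u / K + stats::pnorm(u - 1 / K, log.p = TRUE)
  pmin(pmax(stats::pnorm(u) - exp(lt), 0), 1)
}
qexponnorm <- function(p, K, mu = 0, sigma = 1) {
  vapply(p, function(pp) {
    lo <- mu - 10 * sigma
    hi <- mu + sigma * (10 + 20 * K)
    stats::uniroot(function(x) pexponnorm(x, K, mu, sigma) - pp,
                   c(lo, hi), extendInt = "upX", tol = 1e-10)$root
  }, 0)
}
rexponnorm <- function(n, K, mu = 0, sigma = 1) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / (K * sigma))
}

# ---- noncentral t with location/scale: df, ncp, loc, scale ------------------
# R's pnt/qnt emit benign "full precision may not have been achieved"
# warnings in the far tails; precision there is ample for fitting/cutoffs.
dnctls <- function(x, df, ncp, loc = 0, scale = 1, log = FALSE) {
  lf <- suppressWarnings(
    stats::dt((x - loc) / scale, df = df, ncp = ncp, log = TRUE)) - log(scale)
  if (log) lf else exp(lf)
}
pnctls <- function(q, df, ncp, loc = 0, scale = 1) {
  suppressWarnings(stats::pt((q - loc) / scale, df = df, ncp = ncp))
}
qnctls <- function(p, df, ncp, loc = 0, scale = 1) {
  loc + scale * suppressWarnings(stats::qt(p, df = df, ncp = ncp))
}

# ---- Johnson SU: gamma, delta, xi, lambda -----------------------------------
djohnsonsu <- function(x, gamma, delta, xi = 0, lambda = 1, log = FALSE) {
  z <- (x - xi) / lambda
  lf <- log(delta) - log(lambda) - 0.5 * log(2 * pi) - 0.5 * log1p(z^2) -
    0.5 * (gamma + delta * asinh(z))^2
  if (log) lf else exp(lf)
}
pjohnsonsu <- function(q, gamma, delta, xi = 0, lambda = 1) {
  stats::pnorm(gamma + delta * asinh((q - xi) / lambda))
}
qjohnsonsu <- function(p, gamma, delta, xi = 0, lambda = 1) {
  xi + lambda * sinh((stats::qnorm(p) - gamma) / delta)
}

# ---- registry ---------------------------------------------------------------

# each entry: d(x, par, log), p(q, par), q(p, par), r(n, par),
# start(x) -> list of candidate named parameter vectors,
# unpack/pack handle the log-transform of positive parameters
vb_dist_registry <- function() {
  list(
    dweibull = list(
      par = c("shape", "loc", "scale"), positive = c(TRUE, FALSE, TRUE),
      d = function(x, p, log = FALSE) ddweibull(x, p["shape"], p["loc"], p["scale"], log),
      p = function(q, p) pdweibull(q, p["shape"], p["loc"], p["scale"]),
      q = function(pr, p) qdweibull(pr, p["shape"], p["loc"], p["scale"]),
      r = function(n, p) qdweibull(stats::runif(n), p["shape"], p["loc"], p["scale"]),
      start = function(x) list(c(shape = 1.5, loc = stats::median(x),
                                 scale = max(stats::sd(x), 1e-8)))
    ),
    lognorm = list(
      par = c("meanlog", "sdlog"), positive = c(FALSE, TRUE),
      d = function(x, p, log = FALSE) stats::dlnorm(x, p["meanlog"], p["sdlog"], log = log),
      p = function(q, p) stats::plnorm(q, p["meanlog"], p["sdlog"]),
      q = function(pr, p) stats::qlnorm(pr, p["meanlog"], p["sdlog"]),
      r = function(n, p) stats::rlnorm(n, p["meanlog"], p["sdlog"]),
      start = function(x) {
        lx <- log(x)
        list(c(meanlog = mean(lx), sdlog = max(stats::sd(lx), 1e-8)))
      },
      closed_form = function(x) {
        lx <- log(x)
        c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
      }
    ),
    alpha = list(
      par = c("a", "scale"), positive = c(TRUE, TRUE),
      d = function(x, p, log = FALSE) dalpha(x, p["a"], p["scale"], log),
      p = function(q, p) palpha(q, p["a"], p["scale"]),
      q = function(pr, p) qalpha(pr, p["a"], p["scale"]),
      r = function(n, p) qalpha(stats::runif(n), p["a"], p["scale"]),
      start = function(x) {
        a0 <- max(mean(x) / max(stats::sd(x), 1e-12), 0.5)
        list(c(a = a0, scale = mean(x) * a0))
      }
    ),
    exponnorm = list(
      par = c("K", "mu", "sigma"), positive = c(TRUE, FALSE, TRUE),
      d = function(x, p, log = FALSE) dexponnorm(x, p["K"], p["mu"], p["sigma"], log),
      p = function(q, p) pexponnorm(q, p["K"], p["mu"], p["sigma"]),
      q = function(pr, p) qexponnorm(pr, p["K"], p["mu"], p["sigma"]),
      r = function(n, p) rexponnorm(n, p["K"], p["mu"], p["sigma"]),
      start = function(x) {
        s <- stats::sd(x)
        lapply(c(0.5, 2), function(K0) {
          sig0 <- s / sqrt(1 + K0^2)
          c(K = K0, mu = mean(x) - K0 * sig0, sigma = sig0)
        })
      }
    ),
    weibull_min = list(
      par = c("shape", "scale"), positive = c(TRUE, TRUE),
      d = function(x, p, log = FALSE) stats::dweibull(x, p["shape"], p["scale"], log = log),
      p = function(q, p) stats::pweibull(q, p["shape"], p["scale"]),
      q = function(pr, p) stats::qweibull(pr, p["shape"], p["scale"]),
      r = function(n, p) stats::rweibull(n, p["shape"], p["scale"]),
      start = function(x) {
        cv <- stats::sd(x) / mean(x)
        sh <- max(cv^-1.086, 0.3)
        list(c(shape = sh, scale = mean(x) / gamma(1 + 1 / sh)))
      }
    ),
    nct = list(
      par = c("df", "ncp", "loc", "scale"), positive = c(TRUE, FALSE, FALSE, TRUE),
      d = function(x, p, log = FALSE) dnctls(x, p["df"], p["ncp"], p["loc"], p["scale"], log),
      p = function(q, p) pnctls(q, p["df"], p["ncp"], p["loc"], p["scale"]),
      q = function(pr, p) qnctls(pr, p["df"], p["ncp"], p["loc"], p["scale"]),
      r = function(n, p) p["loc"] + p["scale"] * stats::rt(n, p["df"], p["ncp"]),
      start = function(x) {
        sk <- max(min(skewness(x), 3), -3)
        list(c(df = 5, ncp = sk, loc = stats::median(x) - sk * stats::sd(x) / 2,
               scale = max(stats::sd(x) / 2, 1e-8)))
      }
    ),
    gamma = list(
      par = c("shape", "rate"), positive = c(TRUE, TRUE),
      d = function(x, p, log = FALSE) stats::dgamma(x, p["shape"], p["rate"], log = log),
      p = function(q, p) stats::pgamma(q, p["shape"], p["rate"]),
      q = function(pr, p) stats::qgamma(pr, p["shape"], p["rate"]),
      r = function(n, p) stats::rgamma(n, p["shape"], p["rate"]),
      start = function(x) {
        m <- mean(x); v <- max(stats::var(x), 1e-16)
        list(c(shape = m^2 / v, rate = m / v))
      }
    ),
    beta = list(
      par = c("shape1", "shape2"), positive = c(TRUE, TRUE),
      d = function(x, p, log = FALSE) stats::dbeta(x, p["shape1"], p["shape2"], log = log),
      p = function(q, p) stats::pbeta(q, p["shape1"], p["shape2"]),
      q = function(pr, p) stats::qbeta(pr, p["shape1"], p["shape2"]),
      r = function(n, p) stats::rbeta(n, p["shape1"], p["shape2"]),
      start = function(x) {
        m <- mean(x); v <- max(stats::var(x), 1e-16)
        k <- max(m * (1 - m) / v - 1, 0.01)
        list(c(shape1 = m * k, shape2 = (1 - m) * k))
      }
    ),
    johnsonsu = list(
      par = c("gamma", "delta", "xi", "lambda"), positive = c(FALSE, TRUE, FALSE, TRUE),
      d = function(x, p, log = FALSE) djohnsonsu(x, p["gamma"], p["delta"], p["xi"], p["lambda"], log),
      p = function(q, p) pjohnsonsu(q, p["gamma"], p["delta"], p["xi"], p["lambda"]),
      q = function(pr, p) qjohnsonsu(pr, p["gamma"], p["delta"], p["xi"], p["lambda"]),
      r = function(n, p) qjohnsonsu(stats::runif(n), p["gamma"], p["delta"], p["xi"], p["lambda"]),
      start = function(x) {
        list(c(gamma = -1, delta = 1.2, xi = stats::median(x),
               lambda = max(stats::mad(x), stats::sd(x) / 2, 1e-8)),
             c(gamma = 0, delta = 1, xi = stats::median(x),
               lambda = max(stats::sd(x), 1e-8)))
      }
    )
  )
}

#' Candidate distribution families for background-site AF fitting
#'
#' The fixed candidate set used when fitting per-site background AF
#' distributions: double Weibull, log-normal, alpha, exponentially
#' modified normal, minimum Weibull, noncentral t, gamma, beta and
#' Johnson SU. The set is an extension point: unknown names are rejected.
#'
#' @param names Optional subset/reordering of the candidate names.
#' @return Character vector of distribution names.
#' @export
candidate_distributions <- function(names = NULL) {
  all <- names(vb_dist_registry())
  if (is.null(names)) return(all)
  if (length(names) == 0) stop("candidate set must not be empty")
  bad <- setdiff(names, all)
  if (length(bad)) stop("unknown distribution(s): ", paste(bad, collapse = ", "))
  names
}

#' Distribution function access
#'
#' Density, CDF, quantile and random generation for a named candidate
#' family with a fitted parameter vector.
#'
#' @param name Distribution name from [candidate_distributions()].
#' @param x,q,p,n Usual arguments.
#' @param params Named numeric parameter vector.
#' @param log Return log-density.
#' @return Numeric vector.
#' @export
dist_pdf <- function(name, x, params, log = FALSE) {
  vb_dist_registry()[[match.arg(name, candidate_distributions())]]$d(x, params, log)
}

#' @rdname dist_pdf
#' @export
dist_cdf <- function(name, q, params) {
  vb_dist_registry()[[match.arg(name, candidate_distributions())]]$p(q, params)
}

#' @rdname dist_pdf
#' @export
dist_quantile <- function(name, p, params) {
  vb_dist_registry()[[match.arg(name, candidate_distributions())]]$q(p, params)
}

#' @rdname dist_pdf
#' @export
dist_random <- function(name, n, params) {
  vb_dist_registry()[[match.arg(name, candidate_distributions())]]$r(n, params)
}

# MLE for one family; returns list(par, loglik) or NULL on failure
fit_one_dist <- function(x, name) {
  reg <- vb_dist_registry()[[name]]
  if (!is.null(reg$closed_form)) {
    par <- reg$closed_form(x)
    ll <- sum(reg$d(x, par, log = TRUE))
    if (is.finite(ll)) return(list(par = par, loglik = ll))
    return(NULL)
  }
  pos <- reg$positive
  nll <- function(theta) {
    par <- theta
    par[pos] <- exp(par[pos])
    names(par) <- reg$par
    lf <- reg$d(x, par, log = TRUE)
    if (any(!is.finite(lf))) return(1e10)
    -sum(lf)
  }
  best <- NULL
  for (st in reg$start(x)) {
    theta0 <- st
    theta0[pos] <- log(pmax(theta0[pos], 1e-10))
    fit <- tryCatch(
      stats::optim(theta0, nll, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  par <- best$par
  par[pos] <- exp(par[pos])
  names(par) <- reg$par
  list(par = par, loglik = -best$value)
}

#' Fit the best background AF distribution for a site
#'
#' Fits every candidate family to the site's AF sample by maximum
#' likelihood, scores each fit by AIC, BIC, the sum of squared errors
#' between fitted and empirical CDF at the sorted sample, and the
#' correlation R between fitted quantiles and the sorted sample, and picks
#' the winner by rank-sum over the four scores (ties broken by lower AIC).
#'
#' @param af_values Numeric AF sample in (0, 1).
#' @param candidates Candidate family names (default all nine).
#' @param min_fit_n Minimum sample size to attempt a fit (default 8).
#' @return List with `dist_name`, `params`, `scores` (one row per fitted
#'   candidate), and `degenerate = FALSE`; for a zero-variance sample,
#'   `list(degenerate = TRUE, value = <the constant>)`.
#' @export
fit_site_distribution <- function(af_values,
                                  candidates = candidate_distributions(),
                                  min_fit_n = 8L) {
  x <- as.numeric(af_values)
  if (length(x) < min_fit_n) {
    stop("need at least ", min_fit_n, " AF values to fit (got ", length(x), ")")
  }
  if (stats::sd(x) < 1e-12) {
    return(list(degenerate = TRUE, value = x[1], dist_name = NA_character_,
                params = NULL, scores = NULL))
  }
  candidates <- candidate_distributions(candidates)
  n <- length(x)
  xs <- sort(x)
  pp <- (seq_len(n) - 0.5) / n
  reg <- vb_dist_registry()
  rows <- list()
  for (nm in candidates) {
    fit <- tryCatch(fit_one_dist(x, nm), error = function(e) NULL)
    if (is.null(fit)) {
      warning("fit failed for candidate '", nm, "'; skipped")
      next
    }
    k <- length(fit$par)
    cdf <- reg[[nm]]$p(xs, fit$par)
    qq <- tryCatch(reg[[nm]]$q(pp, fit$par), error = function(e) rep(NA_real_, n))
    sse <- sum((cdf - pp)^2)
    r <- suppressWarnings(stats::cor(qq, xs))
    if (!is.finite(r)) r <- -1
    rows[[nm]] <- tibble::tibble(
      dist_name = nm,
      aic = 2 * k - 2 * fit$loglik,
      bic = k * log(n) - 2 * fit$loglik,
      sse = sse, r = r,
      params = list(fit$par)
    )
  }
  if (!length(rows)) stop("all candidate distribution fits failed")
  scores <- dplyr::bind_rows(rows)
  rank_sum <- rank(scores$aic) + rank(scores$bic) + rank(scores$sse) +
    rank(-scores$r)
  scores$rank_sum <- rank_sum
  best <- which(rank_sum == min(rank_sum))
  if (length(best) > 1L) best <- best[which.min(scores$aic[best])]
  list(degenerate = FALSE,
       dist_name = scores$dist_name[best],
       params = scores$params[[best]],
       scores = dplyr::select(scores, -"params"))
}

#' AF cutoff from a fitted site distribution
#'
#' The polishing cutoff is the `confidence` quantile of the site's fitted
#' background AF distribution, clamped into (0, 1).
#'
#' @param dist_name Fitted family name.
#' @param params Fitted parameter vector.
#' @param confidence Confidence level in \[0.8, 0.995\].
#' @return AF cutoff in (0, 1).
#' @export
af_cutoff <- function(dist_name, params, confidence = 0.99) {
  if (confidence < 0.8 || confidence > 0.995) {
    stop("confidence must lie in [0.8, 0.995]")
  }
  q <- dist_quantile(dist_name, confidence, params)
  min(max(q, 1e-12), 1 - 1e-12)
}
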