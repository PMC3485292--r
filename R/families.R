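# Candidate distribution families for heavy-tailed expression data.
#
# Each family is a list with a fixed contract:
#   name        short id used throughout the package
#   n_params    length of the parameter vector
#   param_names names, in the order the vector is stored
#   lower/upper box constraints for maximum-likelihood fitting
#   support(par)       -> c(lo, hi)
#   dens(x, par, log)  density
#   cdf(q, par)        distribution function, monotone 0 -> 1 on support
#   quantile(p, par)   inverse of cdf
#   rand(n, par)       sampler (inverse-CDF unless a simpler exact route exists)
#   init(x)            moment/quantile-based starting values for fitting
#   moments(par)       closed-form mean/var/skewness/excess kurtosis, or NULL
#
# Parameterizations follow common distribution-fitting conventions:
#   normal      (mean, sd)
#   laplace     (location, scale)
#   logistic    (location, scale)
#   hypsecant   (location, scale): f(x) = sech(pi (x - m) / (2 s)) / (2 s),
#               so the density at the location is 1/(2 s) and the standard
#               (m = 0, s = 1) variant has unit variance
#   johnson_su  (gamma, delta, xi, lambda): X = xi + lambda sinh((Z - gamma)/delta)
#   loglogistic3 (shape beta, scale alpha, location), support x > location
#   dagum4      (shape a, shape p, scale b, location), support x > location
#   burr4       Burr XII (shape k, shape c, scale s, location), x > location

.family_registry <- new.env(parent = emptyenv())

#' Register a candidate distribution family
#'
#' Adds a family to the fitting catalog. The built-in catalog holds the eight
#' families used in the analysis; additional families (toward a fuller
#' heavy-tailed catalog) can be plugged in without touching the fitting code.
#'
#' @param family A family object as produced by the internal constructors;
#'   must carry `name`, `n_params`, `param_names`, `lower`, `upper`,
#'   `support`, `dens`, `cdf`, `quantile`, `rand`, `init` and (optionally)
#'   `moments`.
#' @param overwrite Replace an existing family of the same name.
#' @return The family object, invisibly.
#' @export
register_family <- function(family, overwrite = FALSE) {
  stopifnot(is.list(family), is.character(family$name))
  needed <- c("n_params", "param_names", "lower", "upper", "support",
              "dens", "cdf", "quantile", "rand", "init")
  missing <- setdiff(needed, names(family))
  if (length(missing) > 0L)
    stop("family '", family$name, "' is missing fields: ",
         paste(missing, collapse = ", "))
  if (!overwrite && family$name %in% ls(.family_registry))
    stop("family '", family$name, "' is already registered")
  assign(family$name, family, envir = .family_registry)
  invisible(family)
}

#' Look up a registered distribution family
#'
#' @param name Family id, e.g. `"johnson_su"`.
#' @return The family object.
#' @export
get_family <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stop("family name must be a single string")
  if (!name %in% ls(.family_registry))
    stop("unknown distribution family '", name, "'; registered: ",
         paste(list_families(), collapse = ", "))
  get(name, envir = .family_registry)
}

#' List registered family names
#' @return Character vector of family ids.
#' @export
list_families <- function() sort(ls(.family_registry))

check_params <- function(family, params) {
  fam <- if (is.character(family)) get_family(family) else family
  params <- as.numeric(params)
  if (length(params) != fam$n_params)
    stop("family '", fam$name, "' takes ", fam$n_params,
         " parameters (", paste(fam$param_names, collapse = ", "),
         "), got ", length(params))
  if (any(!is.finite(params)))
    stop("family '", fam$name, "': non-finite parameters")
  if (any(params < fam$lower - 1e-12) || any(params > fam$upper + 1e-12))
    stop("family '", fam$name, "': parameters out of range (",
         paste(fam$param_names, "=", signif(params, 4), collapse = ", "), ")")
  names(params) <- fam$param_names
  params
}

## ---- individual families ---------------------------------------------------

.fam_normal <- function() {
  list(
    name = "normal", n_params = 2L, param_names = c("mean", "sd"),
    lower = c(-Inf, 1e-12), upper = c(Inf, Inf),
    support = function(par) c(-Inf, Inf),
    dens = function(x, par, log = FALSE) stats::dnorm(x, par[1], par[2], log = log),
    cdf = function(q, par) stats::pnorm(q, par[1], par[2]),
    quantile = function(p, par) stats::qnorm(p, par[1], par[2]),
    rand = function(n, par) stats::rnorm(n, par[1], par[2]),
    init = function(x) c(mean(x), stats::sd(x)),
    moments = function(par) list(mean = par[1], var = par[2]^2, skew = 0, exkurt = 0)
  )
}

.fam_laplace <- function() {
  list(
    name = "laplace", n_params = 2L, param_names = c("location", "scale"),
    lower = c(-Inf, 1e-12), upper = c(Inf, Inf),
    support = function(par) c(-Inf, Inf),
    dens = function(x, par, log = FALSE) {
      ld <- -abs(x - par[1]) / par[2] - log(2 * par[2])
      if (log) ld else exp(ld)
    },
    cdf = function(q, par) {
      z <- (q - par[1]) / par[2]
      ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
    },
    quantile = function(p, par) {
      par[1] - par[2] * sign(p - 0.5) * log(1 - 2 * abs(p - 0.5))
    },
    rand = function(n, par) {
      u <- stats::runif(n) - 0.5
      par[1] - par[2] * sign(u) * log(1 - 2 * abs(u))
    },
    init = function(x) c(stats::median(x), mean(abs(x - stats::median(x)))),
    moments = function(par) list(mean = par[1], var = 2 * par[2]^2, skew = 0, exkurt = 3)
  )
}

.fam_logistic <- function() {
  list(
    name = "logistic", n_params = 2L, param_names = c("location", "scale"),
    lower = c(-Inf, 1e-12), upper = c(Inf, Inf),
    support = function(par) c(-Inf, Inf),
    dens = function(x, par, log = FALSE) stats::dlogis(x, par[1], par[2], log = log),
    cdf = function(q, par) stats::plogis(q, par[1], par[2]),
    quantile = function(p, par) stats::qlogis(p, par[1], par[2]),
    rand = function(n, par) stats::rlogis(n, par[1], par[2]),
    init = function(x) c(mean(x), stats::sd(x) * sqrt(3) / pi),
    moments = function(par) list(mean = par[1], var = pi^2 * par[2]^2 / 3,
                                 skew = 0, exkurt = 1.2)
  )
}

.fam_hypsecant <- function() {
  list(
    name = "hypsecant", n_params = 2L, param_names = c("location", "scale"),
    lower = c(-Inf, 1e-12), upper = c(Inf, Inf),
    support = function(par) c(-Inf, Inf),
    dens = function(x, par, log = FALSE) {
      z <- pi * (x - par[1]) / (2 * par[2])
      # log sech(z) = -|z| - log1p(exp(-2|z|)) + log 2, stable for large |z|
      ld <- log(2) - abs(z) - log1p(exp(-2 * abs(z))) - log(2 * par[2])
      if (log) ld else exp(ld)
    },
    cdf = function(q, par) {
      z <- pi * (q - par[1]) / (2 * par[2])
      (2 / pi) * atan(exp(z))
    },
    quantile = function(p, par) {
      par[1] + (2 * par[2] / pi) * log(tan(pi * p / 2))
    },
    rand = function(n, par) {
      u <- stats::runif(n)
      par[1] + (2 * par[2] / pi) * log(tan(pi * u / 2))
    },
    init = function(x) c(mean(x), stats::sd(x)),
    moments = function(par) list(mean = par[1], var = par[2]^2, skew = 0, exkurt = 2)
  )
}

# Closed-form Johnson SU moments (omega = exp(1/delta^2), Omega = gamma/delta).
jsu_moments <- function(par) {
  gamma <- par[1]; delta <- par[2]; xi <- par[3]; lambda <- par[4]
  w <- exp(delta^-2)
  Om <- gamma / delta
  m <- xi - lambda * sqrt(w) * sinh(Om)
  v <- lambda^2 / 2 * (w - 1) * (w * cosh(2 * Om) + 1)
  skew <- -(lambda^3 * sqrt(w) * (w - 1)^2 *
              (w * (w + 2) * sinh(3 * Om) + 3 * sinh(Om))) / (4 * v^1.5)
  kurt <- (lambda^4 * (w - 1)^2 *
             (w^2 * (w^4 + 2 * w^3 + 3 * w^2 - 3) * cosh(4 * Om) +
                4 * w^2 * (w + 2) * cosh(2 * Om) + 3 * (2 * w + 1))) / (8 * v^2)
  list(mean = m, var = v, skew = skew, exkurt = kurt - 3)
}

.fam_johnson_su <- function() {
  list(
    name = "johnson_su", n_params = 4L,
    param_names = c("gamma", "delta", "xi", "lambda"),
    lower = c(-Inf, 1e-8, -Inf, 1e-12), upper = c(Inf, Inf, Inf, Inf),
    support = function(par) c(-Inf, Inf),
    dens = function(x, par, log = FALSE) {
      z <- (x - par[3]) / par[4]
      r <- par[1] + par[2] * asinh(z)
      ld <- log(par[2]) - log(par[4]) - 0.5 * log1p(z^2) + stats::dnorm(r, log = TRUE)
      if (log) ld else exp(ld)
    },
    cdf = function(q, par) stats::pnorm(par[1] + par[2] * asinh((q - par[3]) / par[4])),
    quantile = function(p, par) par[3] + par[4] * sinh((stats::qnorm(p) - par[1]) / par[2]),
    rand = function(n, par) par[3] + par[4] * sinh((stats::rnorm(n) - par[1]) / par[2]),
    init = function(x) {
      # quantile-based start: map sample quartiles through a unit-delta sinh
      m <- stats::median(x)
      s <- stats::IQR(x)
      if (s <= 0) s <- max(stats::sd(x), 1e-3)
      g1 <- sample_skewness(x)
      c(gamma = -sign(g1), delta = 1.5, xi = m, lambda = s)
    },
    moments = jsu_moments
  )
}

# Starting value for a shifted-support location parameter: just below the
# sample minimum, offset on a tail-robust (IQR) scale so heavy right tails
# do not drag the start far from the support boundary.
shifted_location_init <- function(x) {
  s <- stats::IQR(x)
  if (s <= 0) s <- max(stats::sd(x), 1e-3)
  min(x) - 0.05 * s - 1e-8
}

.fam_loglogistic3 <- function() {
  list(
    name = "loglogistic3", n_params = 3L,
    param_names = c("shape", "scale", "location"),
    lower = c(1e-8, 1e-12, -Inf), upper = c(Inf, Inf, Inf),
    support = function(par) c(par[3], Inf),
    dens = function(x, par, log = FALSE) {
      b <- par[1]; a <- par[2]; g <- par[3]
      z <- (x - g) / a
      ld <- ifelse(z > 0,
                   log(b) - log(a) + (b - 1) * log(z) - 2 * log1p(z^b),
                   -Inf)
      if (log) ld else exp(ld)
    },
    cdf = function(q, par) {
      z <- pmax((q - par[3]) / par[2], 0)
      z^par[1] / (1 + z^par[1])
    },
    quantile = function(p, par) par[3] + par[2] * (p / (1 - p))^(1 / par[1]),
    rand = function(n, par) {
      u <- stats::runif(n)
      par[3] + par[2] * (u / (1 - u))^(1 / par[1])
    },
    init = function(x) {
      g <- shifted_location_init(x)
      y <- x - g
      # quartile ratio gives the shape; median the scale
      b <- 2 * log(3) / (log(stats::quantile(y, 0.75, names = FALSE)) -
                           log(stats::quantile(y, 0.25, names = FALSE)))
      c(shape = min(max(b, 0.5), 10), scale = stats::median(y), location = g)
    },
    moments = NULL
  )
}

.fam_dagum4 <- function() {
  list(
    name = "dagum4", n_params = 4L,
    param_names = c("shape_a", "shape_p", "scale", "location"),
    lower = c(1e-8, 1e-8, 1e-12, -Inf), upper = c(Inf, Inf, Inf, Inf),
    support = function(par) c(par[4], Inf),
    dens = function(x, par, log = FALSE) {
      a <- par[1]; p <- par[2]; b <- par[3]; l <- par[4]
      z <- (x - l) / b
      ld <- ifelse(z > 0,
                   log(a) + log(p) - log(b) + (a * p - 1) * log(z) -
                     (p + 1) * log1p(z^a),
                   -Inf)
      if (log) ld else exp(ld)
    },
    cdf = function(q, par) {
      z <- pmax((q - par[4]) / par[3], 0)
      (1 + z^(-par[1]))^(-par[2])
    },
    quantile = function(p, par) {
      par[4] + par[3] * (p^(-1 / par[2]) - 1)^(-1 / par[1])
    },
    rand = function(n, par) {
      u <- stats::runif(n)
      par[4] + par[3] * (u^(-1 / par[2]) - 1)^(-1 / par[1])
    },
    init = function(x) {
      l <- shifted_location_init(x)
      y <- x - l
      b <- 2 * log(3) / (log(stats::quantile(y, 0.75, names = FALSE)) -
                           log(stats::quantile(y, 0.25, names = FALSE)))
      c(shape_a = min(max(b, 0.5), 10), shape_p = 1,
        scale = stats::median(y), location = l)
    },
    moments = NULL
  )
}

.fam_burr4 <- function() {
  list(
    name = "burr4", n_params = 4L,
    param_names = c("shape_k", "shape_c", "scale", "location"),
    lower = c(1e-8, 1e-8, 1e-12, -Inf), upper = c(Inf, Inf, Inf, Inf),
    support = function(par) c(par[4], Inf),
    dens = function(x, par, log = FALSE) {
      k <- par[1]; cc <- par[2]; s <- par[3]; l <- par[4]
      z <- (x - l) / s
      ld <- ifelse(z > 0,
                   log(cc) + log(k) - log(s) + (cc - 1) * log(z) -
                     (k + 1) * log1p(z^cc),
                   -Inf)
      if (log) ld else exp(ld)
    },
    cdf = function(q, par) {
      z <- pmax((q - par[4]) / par[3], 0)
      1 - (1 + z^par[2])^(-par[1])
    },
    quantile = function(p, par) {
      par[4] + par[3] * ((1 - p)^(-1 / par[1]) - 1)^(1 / par[2])
    },
    rand = function(n, par) {
      u <- stats::runif(n)
      par[4] + par[3] * ((1 - u)^(-1 / par[1]) - 1)^(1 / par[2])
    },
    init = function(x) {
      l <- shifted_location_init(x)
      y <- x - l
      b <- 2 * log(3) / (log(stats::quantile(y, 0.75, names = FALSE)) -
                           log(stats::quantile(y, 0.25, names = FALSE)))
      c(shape_k = 1, shape_c = min(max(b, 0.5), 10),
        scale = stats::median(y), location = l)
    },
    moments = NULL
  )
}

local({
  register_family(.fam_normal())
  register_family(.fam_laplace())
  register_family(.fam_logistic())
  register_family(.fam_hypsecant())
  register_family(.fam_johnson_su())
  register_family(.fam_loglogistic3())
  register_family(.fam_dagum4())
  register_family(.fam_burr4())
})
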