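#' Single-hit multi-target survival function
#'
#' Target theory for ionizing radiation: an organism with N equivalent
#' targets survives unless every target is hit, giving
#' \eqn{S(D) = 1 - (1 - e^{-D/D_0})^N}. With N = 1 this is the pure
#' exponential \eqn{e^{-D/D_0}}; larger N produces the low-dose shoulder.
#'
#' @param dose dose in Gy (vectorized, >= 0).
#' @param D0 mean lethal dose per target (Gy, > 0).
#' @param N extrapolation number (>= 1).
#' @return Surviving fraction in (0, 1].
#' @examples
#' shmtSurvival(c(0, 50, 112.3), D0 = 34.85, N = 17.04)
#' @export
shmtSurvival <- function(dose, D0, N) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (D0 <= 0) stop("D0 must be > 0")
  if (N < 1) stop("N must be >= 1")
  # -expm1(N log1p(-e^{-D/D0})) = 1 - (1 - e^{-D/D0})^N without underflow
  -expm1(N * log1p(-exp(-dose / D0)))
}

#' Dose giving an arbitrary relative response
#'
#' Closed-form inverse of the SHMT curve:
#' \eqn{D(f) = -D_0 \ln(1 - (1 - f)^{1/N})}, the unique dose with
#' S(D) = f.
#'
#' @param frac target surviving fraction, in (0, 1).
#' @param D0,N SHMT parameters.
#' @return Dose in Gy.
#' @examples
#' shmtDoseAt(0.5, D0 = 34.85, N = 17.04) # the LD50
#' @export
shmtDoseAt <- function(frac, D0, N) {
  if (any(frac <= 0 | frac >= 1)) stop("frac must lie in (0, 1)")
  if (D0 <= 0) stop("D0 must be > 0")
  if (N < 1) stop("N must be >= 1")
  -D0 * log(1 - (1 - frac)^(1 / N))
}

.shmtDerived <- function(D0, N) {
  list(Dq = D0 * log(N), LD50 = shmtDoseAt(0.5, D0, N))
}

#' Fit the SHMT model to dose-response data
#'
#' Bounded nonlinear least squares on the relative-response scale with a
#' deterministic multi-start grid (D0 in \{10, 20, 40, 80, 160\} Gy, N in
#' \{1, 2, 5, 10, 20, 50\}); the best residual sum of squares wins, so the
#' fit is reproducible without a random seed. Shoulder dose
#' \eqn{D_q = D_0 \ln N} and LD50 are attached.
#'
#' @param data data.frame with columns \code{dose_gy} and \code{response}
#'   (fraction of control; replicates as repeated rows). At least four
#'   distinct doses including dose 0 are required.
#' @return An \linkS4class{SHMTFit}.
#' @examples
#' d <- data.frame(dose_gy = seq(0, 300, 25))
#' d$response <- shmtSurvival(d$dose_gy, 34.9, 17)
#' fitShmt(d)
#' @export
fitShmt <- function(data) {
  stopifnot(all(c("dose_gy", "response") %in% names(data)))
  data <- data[complete.cases(data[, c("dose_gy", "response")]), ]
  if (any(data$dose_gy < 0)) stop("doses must be >= 0")
  if (length(unique(data$dose_gy)) < 4)
    stop("need at least 4 distinct doses")
  if (!any(data$dose_gy == 0)) stop("a dose-0 control is required")
  mean0 <- mean(data$response[data$dose_gy == 0])
  meanMax <- mean(data$response[data$dose_gy == max(data$dose_gy)])
  if (meanMax > mean0)
    stop("response increases with dose: not survival-like ",
         "(consider fitHormesis)")
  grid <- expand.grid(D0 = c(10, 20, 40, 80, 160), N = c(1, 2, 5, 10, 20, 50))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(response ~ 1 - (1 - exp(-dose_gy / D0))^N,
                        data = data,
                        start = list(D0 = grid$D0[i], N = grid$N[i]),
                        lower = c(D0 = 1e-6, N = 1),
                        upper = c(D0 = Inf, N = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("SHMT fit failed to converge from every start")
  p <- coef(best$fit)
  der <- .shmtDerived(p[["D0"]], p[["N"]])
  new("SHMTFit", D0 = p[["D0"]], N = p[["N"]], Dq = der$Dq,
      LD50 = der$LD50, rss = best$rss,
      converged = best$fit$convInfo$isConv, data = data)
}

#' Derived doses from a fitted SHMT model
#'
#' @param fit an \linkS4class{SHMTFit}.
#' @param frac optional surviving fractions to invert (defaults to 0.5).
#' @return List with Dq, LD50 and \code{dose_at} (doses for \code{frac}).
#' @examples
#' d <- data.frame(dose_gy = seq(0, 300, 25))
#' d$response <- shmtSurvival(d$dose_gy, 34.9, 17)
#' derivedQuantities(fitShmt(d), frac = c(0.1, 0.5, 0.9))
#' @export
derivedQuantities <- function(fit, frac = 0.5) {
  list(Dq = fit@Dq, LD50 = fit@LD50,
       dose_at = setNames(shmtDoseAt(frac, fit@D0, fit@N),
                          as.character(frac)))
}

#' Recover SHMT parameters from shoulder dose and LD50
#'
#' Solves the two-equation system \eqn{D_q = D_0 \ln N} and
#' \eqn{S(LD_{50}) = 1/2} for (D0, N) by one-dimensional root finding in N,
#' then verifies the forward computation reproduces both inputs.
#'
#' @param Dq shoulder dose (Gy).
#' @param LD50 dose of 50\% survival (Gy); must exceed \code{Dq} minus
#'   nothing in particular but the pair must be consistent with N > 1.
#' @param tol verification tolerance in Gy (default 1e-6).
#' @return List with D0 and N.
#' @examples
#' shmtFromDqLd50(Dq = 98.82, LD50 = 112.30)
#' @export
shmtFromDqLd50 <- function(Dq, LD50, tol = 1e-6) {
  if (Dq <= 0 || LD50 <= 0) stop("Dq and LD50 must be > 0")
  gap <- function(N) {
    D0 <- Dq / log(N)
    shmtDoseAt(0.5, D0, N) - LD50
  }
  sol <- uniroot(gap, lower = 1 + 1e-9, upper = 1e6, tol = 1e-12)
  N <- sol$root
  D0 <- Dq / log(N)
  if (abs(D0 * log(N) - Dq) > tol ||
      abs(shmtDoseAt(0.5, D0, N) - LD50) > tol)
    stop("round-trip verification failed")
  list(D0 = D0, N = N)
}

#' Fit a Brain-Cousens hormesis curve
#'
#' Some endpoints rise above the control at low doses before declining
#' (stimulation, or hormesis). The Brain-Cousens modification of the
#' log-logistic, \eqn{y(D) = c + (d - c + f D)/(1 + e^{b(\ln D - \ln e)})},
#' captures this with the linear stimulation term \eqn{f D}. When the data
#' show no low-dose rise the monotone log-logistic (f = 0) is fitted
#' instead and flagged via \code{fallback}.
#'
#' @param data data.frame with \code{dose_gy} and \code{response}.
#' @return A \linkS4class{HormesisFit}.
#' @export
fitHormesis <- function(data) {
  stopifnot(all(c("dose_gy", "response") %in% names(data)))
  means <- vapply(split(data$response, data$dose_gy), mean, numeric(1))
  doses <- as.numeric(names(means))
  ctrl <- unname(if (any(doses == 0)) means[doses == 0]
                 else means[which.min(doses)])
  stimulated <- any(means[doses > 0] > ctrl)
  bc <- function(D, b, c, d, e, f) {
    out <- c + (d - c + f * D) / (1 + exp(b * (log(pmax(D, 1e-12)) - log(e))))
    out[D == 0] <- d
    out
  }
  starts <- expand.grid(b = c(1, 2, 5), e = c(50, 100, 200))
  fitOne <- function(useF) {
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      init <- list(b = starts$b[i], c = 0, d = ctrl, e = starts$e[i])
      lower <- c(b = 0.01, c = -Inf, d = -Inf, e = 1e-6)
      form <- response ~ bc(dose_gy, b, c, d, e, f)
      if (useF) {
        init$f <- 0.001
        lower <- c(lower, f = 0)
      } else {
        form <- response ~ bc(dose_gy, b, c, d, e, 0)
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = data, start = init, lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
    best
  }
  if (stimulated) {
    best <- fitOne(TRUE)
    fallback <- FALSE
  } else {
    warning("no low-dose stimulation signal; fitting monotone model (f = 0)")
    best <- fitOne(FALSE)
    fallback <- TRUE
  }
  if (is.null(best)) stop("hormesis fit failed to converge from every start")
  p <- coef(best$fit)
  new("HormesisFit", b = p[["b"]], c = p[["c"]], d = p[["d"]], e = p[["e"]],
      f = if (fallback) 0 else p[["f"]], rss = best$rss,
      converged = best$fit$convInfo$isConv, fallback = fallback,
      data = data)
}
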