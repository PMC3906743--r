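#' Fit a two-component normal mixture to DE or PIF scores
#'
#' Genome-wide DE (or PIF) score distributions are well described by a
#' dominant null component centred near zero plus a wider, shifted
#' alternative component carrying the real effects. This fits
#' `pi0 * N(mu0, sigma0^2) + (1 - pi0) * N(mu1, sigma1^2)` by
#' expectation-maximisation. Initialization splits the scores at the 90th
#' percentile of `|score|` to seed the alternative component; `n_restarts`
#' jittered restarts guard against local optima and the best fit by final
#' log-likelihood is kept. The component with the larger mixing weight is
#' labelled null (ties broken by the mean closer to zero). A variance floor
#' of `1e-6 * var(scores)` prevents degenerate collapse; if it engages, the
#' fit is flagged.
#'
#' @param scores Numeric vector of at least 50 finite scores.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param n_restarts Number of jittered restarts (default 5).
#' @param seed Integer seed driving the restart jitter; fixed seed gives a
#'   bit-identical fit.
#' @return An object of class `mixture_fit` with elements `pi0`, `mu0`,
#'   `sigma0`, `mu1`, `sigma1`, `posterior` (per-score probability of the
#'   alternative component), `loglik_trace`, `converged`, `n_iter`,
#'   `floor_engaged`.
#' @export
fit_two_component <- function(scores, tol = 1e-8, max_iter = 2000L,
                              n_restarts = 5L, seed = 1L) {
  if (length(scores) < 50L) abort("need at least 50 scores")
  if (!all(is.finite(scores))) abort("scores must be finite")
  v <- var(scores)
  if (v == 0) abort("all scores identical; mixture is undefined")
  floor_var <- 1e-6 * v

  thr <- quantile(abs(scores), 0.9, names = FALSE)
  alt0 <- abs(scores) > thr
  if (!any(alt0) || all(alt0)) alt0 <- scores > stats::median(scores)
  init0 <- list(
    pi0 = 0.9,
    mu0 = mean(scores[!alt0]), s0 = max(sd(scores[!alt0]), sqrt(floor_var)),
    mu1 = mean(scores[alt0]), s1 = max(sd(scores[alt0]), sqrt(floor_var))
  )

  run_em <- function(init) {
    pi0 <- init$pi0; mu0 <- init$mu0; s0 <- init$s0
    mu1 <- init$mu1; s1 <- init$s1
    trace <- numeric(0L)
    ll_old <- -Inf
    converged <- FALSE
    floor_engaged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      d0 <- pi0 * dnorm(scores, mu0, s0)
      d1 <- (1 - pi0) * dnorm(scores, mu1, s1)
      mix <- d0 + d1
      mix[mix < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(log(mix))
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
        converged <- TRUE
        break
      }
      if (it >= max_iter) break
      ll_old <- ll
      g1 <- d1 / mix
      g0 <- 1 - g1
      n0 <- sum(g0); n1 <- sum(g1)
      pi0 <- n0 / length(scores)
      mu0 <- sum(g0 * scores) / n0
      mu1 <- sum(g1 * scores) / n1
      v0 <- sum(g0 * (scores - mu0)^2) / n0
      v1 <- sum(g1 * (scores - mu1)^2) / n1
      if (v0 < floor_var || v1 < floor_var) floor_engaged <- TRUE
      s0 <- sqrt(max(v0, floor_var))
      s1 <- sqrt(max(v1, floor_var))
    }
    list(pi0 = pi0, mu0 = mu0, s0 = s0, mu1 = mu1, s1 = s1,
         trace = trace, converged = converged, n_iter = it,
         floor_engaged = floor_engaged, loglik = trace[length(trace)])
  }

  fits <- with_local_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      init <- init0
      if (k > 1L) {
        init$mu0 <- init$mu0 + rnorm(1L, sd = 0.25 * sqrt(v))
        init$mu1 <- init$mu1 + rnorm(1L, sd = 0.5 * sqrt(v))
        init$pi0 <- min(max(init$pi0 + runif(1L, -0.2, 0.05), 0.05), 0.95)
      }
      run_em(init)
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "loglik"))]]

  # larger-weight component is the null; tie broken by mean closer to zero
  w0 <- best$pi0
  w1 <- 1 - w0
  swap <- w1 > w0 || (w1 == w0 && abs(best$mu1) < abs(best$mu0))
  if (swap) {
    best <- list(pi0 = w1, mu0 = best$mu1, s0 = best$s1,
                 mu1 = best$mu0, s1 = best$s0, trace = best$trace,
                 converged = best$converged, n_iter = best$n_iter,
                 floor_engaged = best$floor_engaged, loglik = best$loglik)
  }
  d0 <- best$pi0 * dnorm(scores, best$mu0, best$s0)
  d1 <- (1 - best$pi0) * dnorm(scores, best$mu1, best$s1)
  if (best$floor_engaged) {
    warn("variance floor engaged during EM; a component nearly collapsed")
  }
  structure(
    list(pi0 = best$pi0, mu0 = best$mu0, sigma0 = best$s0,
         mu1 = best$mu1, sigma1 = best$s1,
         posterior = d1 / pmax(d0 + d1, .Machine$double.xmin),
         loglik_trace = best$trace, converged = best$converged,
         n_iter = best$n_iter, floor_engaged = best$floor_engaged,
         scores = as.numeric(scores)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> pi0 = %.3f, null N(%.3f, %.3f^2), alt N(%.3f, %.3f^2)\n",
    x$pi0, x$mu0, x$sigma0, x$mu1, x$sigma1))
  cat(sprintf("  %d iterations, %sconverged, loglik %.2f\n", x$n_iter,
              if (x$converged) "" else "NOT ", max(x$loglik_trace)))
  invisible(x)
}

#' @rdname fit_two_component
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = c("null", "alternative"),
         weight = c(x$pi0, 1 - x$pi0),
         mean = c(x$mu0, x$mu1),
         sd = c(x$sigma0, x$sigma1))
}

#' @rdname fit_two_component
#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(pi0 = x$pi0, mu0 = x$mu0, sigma0 = x$sigma0, mu1 = x$mu1,
         sigma1 = x$sigma1, loglik = max(x$loglik_trace),
         n_iter = x$n_iter, converged = x$converged,
         floor_engaged = x$floor_engaged)
}

#' Call DE probes at a target experiment-wise FDR
#'
#' Chooses two-sided thresholds from the fitted mixture: on each side of the
#' null mean, the least extreme observed score `t` at which the tail-area
#' FDR — `pi0 * (null tail mass beyond t) / (empirical tail mass beyond t)`
#' — is at or below `fdr_target`. Scores at or beyond a threshold are called
#' `up` / `down`; everything else is `null`. Up and down thresholds are
#' chosen independently, so asymmetric score distributions give asymmetric
#' calls. If no threshold on a side achieves the target, that side gets no
#' calls (reported, not an error).
#'
#' @param fit A converged [fit_two_component()] result.
#' @param scores Scores to classify; defaults to the scores the mixture was
#'   fitted to.
#' @param fdr_target Target FDR in `(0, 1)`, default 0.01.
#' @param probe_id Optional identifiers for the output.
#' @return A tibble of class `de_calls` with columns `probe_id`, `score`,
#'   `posterior_alt`, `call` (`up`/`down`/`null`), `fdr_at_threshold`;
#'   attributes `thresholds` (named numeric, `low`/`high`, possibly
#'   infinite) and `fdr_target`.
#' @export
classify_de <- function(fit, scores = NULL, fdr_target = 0.01,
                        probe_id = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) {
    # a max-iter fit is still a usable mixture: under a pure null the
    # alternative component is weakly identified and EM can creep along a
    # likelihood ridge without ever meeting a tight relative tolerance
    warn("mixture fit stopped at max_iter without meeting tol; classifying anyway")
  }
  if (!(fdr_target > 0 && fdr_target < 1)) {
    abort("`fdr_target` must lie in (0, 1)")
  }
  if (is.null(scores)) scores <- fit$scores
  n <- length(scores)
  if (is.null(probe_id)) probe_id <- sprintf("P%05d", seq_len(n))

  # tail-area FDR over all observed candidate thresholds at once:
  # count of scores >= / <= each unique value via cumulative tabulation
  u <- sort(unique(scores))
  cts <- tabulate(match(scores, u), length(u))
  n_ge <- rev(cumsum(rev(cts)))
  n_le <- cumsum(cts)

  up <- u > fit$mu0
  fdr_up <- pmin(fit$pi0 *
                   pnorm(u[up], fit$mu0, fit$sigma0, lower.tail = FALSE) /
                   (n_ge[up] / n), 1)
  ok_up <- which(fdr_up <= fdr_target)
  t_high <- if (length(ok_up)) u[up][min(ok_up)] else Inf
  fdr_high <- if (length(ok_up)) fdr_up[min(ok_up)] else NA_real_

  dn <- u < fit$mu0
  fdr_dn <- pmin(fit$pi0 * pnorm(u[dn], fit$mu0, fit$sigma0) /
                   (n_le[dn] / n), 1)
  ok_dn <- which(fdr_dn <= fdr_target)
  t_low <- if (length(ok_dn)) u[dn][max(ok_dn)] else -Inf
  fdr_low <- if (length(ok_dn)) fdr_dn[max(ok_dn)] else NA_real_

  call <- rep("null", n)
  call[scores >= t_high] <- "up"
  call[scores <= t_low] <- "down"
  post <- {
    d0 <- fit$pi0 * dnorm(scores, fit$mu0, fit$sigma0)
    d1 <- (1 - fit$pi0) * dnorm(scores, fit$mu1, fit$sigma1)
    d1 / pmax(d0 + d1, .Machine$double.xmin)
  }
  fdr_col <- rep(NA_real_, n)
  fdr_col[call == "up"] <- fdr_high
  fdr_col[call == "down"] <- fdr_low
  out <- tibble(probe_id = probe_id, score = as.numeric(scores),
                posterior_alt = post, call = call,
                fdr_at_threshold = fdr_col)
  attr(out, "thresholds") <- c(low = t_low, high = t_high)
  attr(out, "fdr_target") <- fdr_target
  class(out) <- c("de_calls", class(out))
  out
}

#' Plot a fitted score mixture
#'
#' Histogram of the scores with the fitted null and alternative component
#' densities (scaled by their weights) overlaid.
#'
#' @param object A [fit_two_component()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, bins = 60, ...) {
  df <- tibble(score = object$scores)
  grid <- tibble(score = seq(min(df$score), max(df$score), length.out = 400))
  grid <- tidyr::pivot_longer(
    dplyr::mutate(
      grid,
      null = object$pi0 * dnorm(.data$score, object$mu0, object$sigma0),
      alternative = (1 - object$pi0) *
        dnorm(.data$score, object$mu1, object$sigma1)
    ),
    c("null", "alternative"), names_to = "component", values_to = "density"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(y = .data$density, colour = .data$component),
      linewidth = 0.8) +
    ggplot2::labs(x = "score", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
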