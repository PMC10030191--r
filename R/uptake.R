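#' Gating thresholds for imaging-flow-cytometry events
#'
#' Focused cells are kept when the gradient-RMS focus score is at least
#' `focus_min` (default 50); single cells are kept by a high-aspect-ratio /
#' low-area rule.
#'
#' @param focus_min Minimum gradient-RMS focus score. Default 50.
#' @param aspect_min Minimum aspect ratio for singlets (doublets are
#'   elongated, hence low aspect ratio). Default 0.6.
#' @param area_max Absolute pixel-area ceiling for singlets; `NULL` (default)
#'   uses `area_max_factor` times the median event area instead.
#' @param area_max_factor Multiple of the median event area used as the area
#'   ceiling when `area_max` is `NULL`. Default 1.5.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(focus_min = 50, aspect_min = 0.6, area_max = NULL,
                      area_max_factor = 1.5) {
  if (focus_min < 0) stop("'focus_min' must be >= 0", call. = FALSE)
  structure(list(focus_min = focus_min, aspect_min = aspect_min,
                 area_max = area_max, area_max_factor = area_max_factor),
            class = "gate_spec")
}

#' Gate an event table to focused single cells
#'
#' Keeps events with `focus_rms >= focus_min`, `aspect_ratio >= aspect_min`
#' and `area_px` below the area ceiling. Row order is preserved; the counts
#' removed at each stage are attached as the `gating_counts` attribute.
#'
#' @param events Data.frame with columns `focus_rms`, `aspect_ratio`,
#'   `area_px` (plus any payload columns such as `bead_count`).
#' @param gate A [gate_spec()].
#' @return The gated subset of `events` with attribute `gating_counts`.
#' @export
gate_events <- function(events, gate = gate_spec()) {
  if (!inherits(gate, "gate_spec")) stop("'gate' must be a gate_spec",
                                         call. = FALSE)
  need <- c("focus_rms", "aspect_ratio", "area_px")
  if (!all(need %in% names(events)))
    stop("events need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(events) == 0L) {
    attr(events, "gating_counts") <- c(input = 0L, focused = 0L, singlet = 0L)
    return(events)
  }
  focused <- events$focus_rms >= gate$focus_min
  ceiling_px <- if (!is.null(gate$area_max)) gate$area_max else
    gate$area_max_factor * stats::median(events$area_px)
  singlet <- events$aspect_ratio >= gate$aspect_min &
    events$area_px <= ceiling_px
  out <- events[focused & singlet, , drop = FALSE]
  attr(out, "gating_counts") <- c(input = nrow(events),
                                  focused = sum(focused),
                                  singlet = sum(focused & singlet))
  out
}

#' Uptake fraction per rigidity and replicate
#'
#' The headline flow-cytometry readout: the percentage of the (gated) cell
#' population that internalized any number of beads, i.e. events with
#' `bead_count >= 1`, computed per rigidity x replicate (and per bead radius
#' when a `radius_um` column is present).
#'
#' @param events A gated event table with columns `rigidity_kpa`, `replicate`,
#'   `bead_count` (optionally `radius_um`).
#' @return Data.frame with `rigidity_kpa`, `replicate` (and `radius_um`),
#'   `n_events`, `n_uptaking` and `fraction_pct`; partition cells with zero
#'   events carry `NA` fractions.
#' @export
uptake_fraction <- function(events) {
  need <- c("rigidity_kpa", "replicate", "bead_count")
  if (!all(need %in% names(events)))
    stop("events need columns ", paste(need, collapse = ", "), call. = FALSE)
  by <- list(rigidity_kpa = events$rigidity_kpa, replicate = events$replicate)
  if ("radius_um" %in% names(events)) by$radius_um <- events$radius_um
  agg <- stats::aggregate(
    cbind(n_events = rep(1L, nrow(events)),
          n_uptaking = as.integer(events$bead_count >= 1)),
    by = by, FUN = sum)
  agg$fraction_pct <- ifelse(agg$n_events > 0,
                             100 * agg$n_uptaking / agg$n_events, NA_real_)
  ord <- do.call(order, agg[intersect(c("radius_um", "rigidity_kpa",
                                        "replicate"), names(agg))])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Test an uptake curve for non-monotonic (meandering) rigidity dependence
#'
#' Fits three shape-constrained least-squares regressions to the per-rigidity
#' replicate fractions: monotone (best of nondecreasing/nonincreasing),
#' rise-fall (increasing then decreasing, split point free) and fall-rise.
#' The verdict is the smallest-RSS shape class, with ties resolved toward
#' monotone (the rise-fall class nests every monotone fit). A residual
#' bootstrap under the monotone null - within-rigidity residuals resampled
#' around the monotone fit - calibrates the RSS improvement of the best
#' non-monotone shape and yields a p-value for rejecting monotonicity.
#'
#' @param fractions Data.frame with columns `rigidity_kpa`, `replicate` and a
#'   fraction column (`fraction_pct` or `value`), e.g. from
#'   [uptake_fraction()]. Needs >= 4 rigidities with >= 2 replicates each.
#' @param n_boot Bootstrap draws. Default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `meander_test`: list with `verdict` (one of
#'   `"monotone"`, `"unimodal_rise_fall"`, `"other"`), `p_value`, `rss`
#'   (named RSS of the three classes, replicate-mean level), `monotone_direction`,
#'   `fits` (fitted means per class), `rigidities`, `n_boot`.
#' @export
detect_nonmonotonicity <- function(fractions, n_boot = 1000, seed = 1) {
  ycol <- intersect(c("fraction_pct", "value"), names(fractions))[1]
  if (is.na(ycol) || !all(c("rigidity_kpa") %in% names(fractions)))
    stop("'fractions' needs 'rigidity_kpa' and a 'fraction_pct'/'value' column",
         call. = FALSE)
  ok <- !is.na(fractions[[ycol]])
  xi <- fractions$rigidity_kpa[ok]
  y <- fractions[[ycol]][ok]
  lev <- sort(unique(xi))
  m <- length(lev)
  if (m < 4L)
    stop("insufficient data: need >= 4 distinct rigidities", call. = FALSE)
  groups <- split(y, factor(xi, levels = lev))
  n_i <- lengths(groups)
  if (any(n_i < 2L))
    stop("insufficient data: need >= 2 replicates per rigidity", call. = FALSE)
  ybar <- vapply(groups, mean, numeric(1))
  # centered residuals understate the group sd by sqrt((n-1)/n); correct so
  # the null bootstrap is not anticonservative with few replicates
  res <- lapply(groups, function(g)
    (g - mean(g)) * sqrt(length(g) / (length(g) - 1)))
  w <- as.numeric(n_i)

  shape_stats <- function(yb) {
    mono <- fit_monotone(yb, w)
    rf <- fit_rise_fall(yb, w)
    fr <- fit_fall_rise(yb, w)
    list(mono = mono, rf = rf, fr = fr,
         t = mono$rss - min(rf$rss, fr$rss))
  }
  obs <- shape_stats(ybar)
  tol <- 1e-10 * (1 + obs$mono$rss)
  verdict <- if (obs$mono$rss <= min(obs$rf$rss, obs$fr$rss) + tol) {
    "monotone"
  } else if (obs$rf$rss <= obs$fr$rss + tol) {
    "unimodal_rise_fall"
  } else {
    "other"
  }

  null_fit <- obs$mono$fit
  t_star <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    yb <- vapply(seq_len(m), function(i) {
      null_fit[i] + mean(sample(res[[i]], n_i[i], replace = TRUE))
    }, numeric(1))
    shape_stats(yb)$t
  }, numeric(1)))
  p <- (1 + sum(t_star >= obs$t - tol)) / (n_boot + 1)

  structure(list(verdict = verdict, p_value = p,
                 rss = c(monotone = obs$mono$rss,
                         unimodal_rise_fall = obs$rf$rss,
                         other = obs$fr$rss),
                 monotone_direction = obs$mono$direction,
                 fits = list(monotone = obs$mono$fit,
                             unimodal_rise_fall = obs$rf$fit,
                             other = obs$fr$fit),
                 rigidities = lev, means = ybar, n_boot = n_boot),
            class = "meander_test")
}

#' @export
print.meander_test <- function(x, ...) {
  cat("Meandering-uptake shape test\n")
  cat(sprintf("  verdict: %s (monotone direction: %s)\n",
              x$verdict, x$monotone_direction))
  cat(sprintf("  p-value for rejecting monotonicity: %.4g (%d bootstrap draws)\n",
              x$p_value, x$n_boot))
  cat("  RSS by shape class:\n")
  print(signif(x$rss, 4))
  invisible(x)
}

#' Aggregate a gated event table into uptake counts
#'
#' @param events Gated event table with `rigidity_kpa`, `bead_count` and
#'   optionally `radius_um`.
#' @return Data.frame with `rigidity_kpa` (and `radius_um`), `k` (events with
#'   at least one bead) and `n` (events), replicates pooled.
#' @export
uptake_counts <- function(events) {
  by <- list(rigidity_kpa = events$rigidity_kpa)
  if ("radius_um" %in% names(events)) by$radius_um <- events$radius_um
  agg <- stats::aggregate(
    cbind(k = as.integer(events$bead_count >= 1),
          n = rep(1L, nrow(events))),
    by = by, FUN = sum)
  agg[do.call(order, agg[intersect(c("radius_um", "rigidity_kpa"),
                                   names(agg))]), , drop = FALSE]
}

# Negative binomial-log-likelihood of the zero-class link
# p_i = 1 - exp(-lambda * A * a * g).
uptake_nll <- function(par, free, base, counts) {
  p <- base
  p[free] <- par
  if (any(par <= 0) || p[["beta_func"]] < 0) return(1e10)
  mp <- mechanics_params(delta_gamma = p[["delta_gamma"]],
                         kappa = p[["kappa"]], E_max = p[["E_max"]],
                         alpha_A = p[["alpha_A"]], alpha_E = p[["alpha_E"]],
                         beta_func = p[["beta_func"]],
                         xi_half = p[["xi_half"]])
  rate <- numeric(nrow(counts))
  for (r in unique(counts$radius_um)) {
    idx <- counts$radius_um == r
    rate[idx] <- p[["lambda_scale"]] *
      uptake_propensity(counts$rigidity_kpa[idx], r, mp,
                        include_functionality = TRUE)
  }
  pr <- pmin(pmax(1 - exp(-rate), 1e-12), 1 - 1e-12)
  -sum(counts$k * log(pr) + (counts$n - counts$k) * log(1 - pr))
}

#' Fit the mechanics model to uptake counts by binomial maximum likelihood
#'
#' The per-cell internalized-bead count is modelled as Poisson with mean
#' `lambda_scale * A(xi) * a(xi, R) * g(xi)`, so the probability that a cell
#' internalizes at least one bead is the zero-class complement
#' `p = 1 - exp(-rate)`. The binomial log-likelihood of the observed
#' uptake counts is maximised over the requested free parameters with
#' seeded multistart; profile-likelihood confidence intervals are reported.
#' Bead size enters only through the contact area `a(R)`: the calibration
#' constant `lambda_scale` is shared across sizes.
#'
#' @param counts Data.frame from [uptake_counts()]: `rigidity_kpa`,
#'   `radius_um`, `k`, `n`.
#' @param params0 Starting [mechanics_params()].
#' @param free Character vector naming the free parameters, a subset of
#'   `c("lambda_scale", "beta_func", "xi_half", "E_max")`. Default
#'   `"lambda_scale"`.
#' @param lambda0 Starting value of the calibration constant. Default 1.
#' @param n_starts Number of multistart points (>= 1; first start is
#'   unperturbed). Default 5.
#' @param seed Seed for the multistart perturbations.
#' @param conf_level Profile-likelihood confidence level. Default 0.95.
#' @return An object of class `uptake_fit`: `estimates` (named vector),
#'   `loglik`, `converged`, `boundary` (TRUE when `lambda_scale` collapsed to
#'   its lower bound, e.g. all-zero counts), `identifiability_warning`, `ci`
#'   (matrix with `lower`/`upper` per free parameter), `free`.
#' @export
fit_uptake_model <- function(counts, params0 = mechanics_params(),
                             free = "lambda_scale", lambda0 = 1,
                             n_starts = 5, seed = 1, conf_level = 0.95) {
  need <- c("rigidity_kpa", "radius_um", "k", "n")
  if (!all(need %in% names(counts)))
    stop("counts need columns ", paste(need, collapse = ", "), call. = FALSE)
  allowed <- c("lambda_scale", "beta_func", "xi_half", "E_max")
  if (!all(free %in% allowed))
    stop("'free' must be a subset of ", paste(allowed, collapse = ", "),
         call. = FALSE)
  params0 <- as_mechanics_params(params0)
  base <- c(unlist(unclass(params0)), lambda_scale = lambda0)
  # beta_func = 0 exactly kills the gradient of xi_half; nudge when fit jointly
  if ("beta_func" %in% free && base[["beta_func"]] <= 0)
    base[["beta_func"]] <- 0.1

  n_rig <- length(unique(counts$rigidity_kpa))
  n_rad <- length(unique(counts$radius_um))
  ident_warn <- length(free) >= 4 && n_rad < 2 && n_rig < 5

  lower <- c(lambda_scale = 1e-9, beta_func = 1e-9, xi_half = 1e-3,
             E_max = 1e-3)[free]
  start0 <- base[free]
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    if (s == 1) start0 else
      pmax(start0 * exp(stats::runif(length(free), -1.5, 1.5)), lower * 2)
  }))

  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    fit <- try(stats::optim(st, uptake_nll, free = free, base = base,
                            counts = counts, method = "L-BFGS-B",
                            lower = lower,
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  est <- best$par
  names(est) <- free
  boundary <- "lambda_scale" %in% free &&
    est[["lambda_scale"]] <= 2 * lower[["lambda_scale"]]

  # profile-likelihood intervals
  crit <- stats::qchisq(conf_level, df = 1)
  prof_dev <- function(name, value) {
    others <- setdiff(free, name)
    base2 <- base
    base2[name] <- value
    if (length(others) == 0L) {
      2 * (uptake_nll(value, free = name, base = base, counts = counts) -
             best$value)
    } else {
      f <- stats::optim(est[others], uptake_nll, free = others, base = base2,
                        counts = counts, method = "L-BFGS-B",
                        lower = lower[others], control = list(maxit = 300))
      2 * (f$value - best$value)
    }
  }
  ci <- t(vapply(free, function(nm) {
    hat <- est[[nm]]
    bound_one <- function(direction) {
      fac <- if (direction > 0) 2 else 0.5
      lo_lim <- lower[[nm]]
      v <- hat
      for (i in 1:40) {
        v2 <- max(v * fac, lo_lim)
        if (prof_dev(nm, v2) >= crit || (direction < 0 && v2 <= lo_lim)) {
          if (direction < 0 && v2 <= lo_lim && prof_dev(nm, v2) < crit)
            return(lo_lim)
          return(tryCatch(
            stats::uniroot(function(x) prof_dev(nm, x) - crit,
                           lower = min(v, v2), upper = max(v, v2),
                           tol = 1e-6 * max(hat, 1e-6))$root,
            error = function(e) v2))
        }
        v <- v2
      }
      v
    }
    c(lower = bound_one(-1), upper = bound_one(+1))
  }, numeric(2)))
  rownames(ci) <- free

  structure(list(estimates = est, loglik = -best$value, converged = any_conv,
                 boundary = boundary, identifiability_warning = ident_warn,
                 ci = ci, free = free, conf_level = conf_level,
                 n_starts = n_starts),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat("Binomial fit of the uptake mechanics model\n")
  cat(sprintf("  log-likelihood: %.3f  converged: %s%s%s\n", x$loglik,
              x$converged,
              if (x$boundary) "  [lambda at boundary]" else "",
              if (x$identifiability_warning)
                "  [identifiability warning]" else ""))
  est <- cbind(estimate = x$estimates, x$ci)
  print(signif(est, 4))
  invisible(x)
}
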