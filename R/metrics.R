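# Population-activity statistics: spiking profiles, subthreshold
# summaries, excitation/inhibition balance, intrinsic timescales,
# effective time constants and rate transfer functions.

split_spikes <- function(spikes, ids) {
  lapply(stats::setNames(ids, ids), function(i)
    spikes$time[spikes$id == i])
}

#' Spike-train statistics of a population
#'
#' Computes, over an observation window: mean pairwise spike-count
#' correlation (`CC`, Pearson on binned counts over `n_pairs` random
#' disjoint neuron pairs), coefficient of variation of inter-spike
#' intervals (`CV_ISI`), the 5th percentile of the ISI distribution
#' (`ISI_5`, seconds; low values indicate burstiness), the entropy of the
#' binned natural-log ISI density (`H_ISI`, bits; Freedman-Diaconis
#' binning) and mean firing rates. Neurons with fewer than `min_isi` ISIs
#' are excluded from the ISI-based statistics; neurons with zero count
#' variance are excluded from CC. Exclusion counts are reported.
#'
#' @param spikes data.frame with `time` (ms) and `id`.
#' @param ids neuron ids forming the population.
#' @param window `c(start, end)` in ms.
#' @param n_pairs number of disjoint random pairs for CC.
#' @param cc_binsize bin size (ms) for the count correlation.
#' @param min_isi minimum ISI count for inclusion.
#' @param seed optional seed for the pair sampling.
#' @return list of population summaries and per-neuron vectors.
#' @export
spike_statistics <- function(spikes, ids, window, n_pairs = 500,
                             cc_binsize = 2, min_isi = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(window) == 2, window[2] > window[1])
  sp <- spikes[spikes$time >= window[1] & spikes$time <= window[2], ]
  trains <- split_spikes(sp, ids)
  nsp <- lengths(trains)
  dur_s <- diff(window) / 1000
  rates <- nsp / dur_s

  isis <- lapply(trains, diff)
  eligible <- lengths(isis) >= min_isi
  cv <- vapply(isis[eligible], function(x) sd(x) / mean(x), numeric(1))
  isi5 <- vapply(isis[eligible], function(x)
    unname(quantile(x, 0.05)) / 1000, numeric(1))
  h <- vapply(isis[eligible], function(x) {
    lx <- log(x)
    bw <- 2 * stats::IQR(lx) / length(lx)^(1 / 3)
    if (bw <= 0) return(0)
    br <- seq(min(lx) - bw / 2, max(lx) + bw, by = bw)
    p <- tabulate(findInterval(lx, br), nbins = length(br))
    p <- p / sum(p); p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))

  # pairwise count correlations over disjoint random pairs
  active <- ids[nsp >= 2]
  cc <- numeric(0)
  if (length(active) >= 4) {
    npair <- min(n_pairs, floor(length(active) / 2))
    perm <- sample(active)
    breaks <- seq(window[1], window[2], by = cc_binsize)
    counts <- function(i) {
      x <- trains[[as.character(i)]]
      tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
               nbins = length(breaks) - 1)
    }
    cc <- vapply(seq_len(npair), function(k) {
      a <- counts(perm[2 * k - 1]); b <- counts(perm[2 * k])
      if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    }, numeric(1))
  }
  list(rate = mean(rates), rates = rates,
       CC = mean(cc, na.rm = TRUE), cc_values = cc,
       CV_ISI = mean(cv), cv_values = cv,
       ISI_5 = mean(isi5), isi5_values = isi5,
       H_ISI = mean(h), h_values = h,
       n_excluded_isi = sum(!eligible),
       n_excluded_cc = sum(is.na(cc)),
       fraction_active = mean(nsp > 0),
       cc_binsize = cc_binsize, window = window)
}

#' Excitation/inhibition balance
#'
#' Per-neuron mean excitatory and inhibitory synaptic currents, the
#' absolute difference of the means, and the zero-lag Pearson correlation
#' between the two current traces.
#'
#' @param result a `simulation_result` with current traces recorded.
#' @param ids neuron ids (must be among `result$record_c_idx`); default
#'   all recorded neurons.
#' @return list with per-neuron vectors and population summaries.
#' @export
ei_balance <- function(result, ids = NULL) {
  if (is.null(result$I_exc)) stop("current traces were not recorded")
  idx <- if (is.null(ids)) seq_along(result$record_c_idx)
         else match(ids, result$record_c_idx)
  if (anyNA(idx)) stop("requested neurons lack current traces")
  Ie <- result$I_exc[idx, , drop = FALSE]
  Ii <- result$I_inh[idx, , drop = FALSE]
  mean_exc <- rowMeans(Ie)
  mean_inh <- rowMeans(Ii)
  cc <- vapply(seq_len(nrow(Ie)), function(i) {
    if (sd(Ie[i, ]) == 0 || sd(Ii[i, ]) == 0) NA_real_
    else cor(Ie[i, ], Ii[i, ])
  }, numeric(1))
  list(mean_exc = mean_exc, mean_inh = mean_inh,
       abs_diff = abs(mean_inh + mean_exc),
       cc = cc,
       CC = mean(cc, na.rm = TRUE), CC_sd = sd(cc, na.rm = TRUE),
       summary = c(exc = mean(mean_exc), inh = mean(mean_inh),
                   diff = mean(abs(mean_inh + mean_exc))))
}

#' Intrinsic timescale of a trace
#'
#' Empirical autocorrelation of a (membrane-potential) trace fitted by
#' \eqn{R(\tau) = a[\exp(-\tau/\tau_{int}) + b]} over lags
#' `(0, max_lag]`. Returns the fitted decay constant and diagnostics; a
#' non-decaying autocorrelation is flagged and `tau_int` reported as the
#' upper bound `max_lag`.
#'
#' @param trace numeric vector, regularly sampled.
#' @param dt sampling interval (ms).
#' @param max_lag maximum lag (ms).
#' @return list with `tau_int` (ms), `a`, `b`, `ok`, and the
#'   autocorrelation (`lags`, `acf`).
#' @export
intrinsic_timescale <- function(trace, dt = 1, max_lag = 500) {
  nlag <- round(max_lag / dt)
  stopifnot(length(trace) >= 10 * nlag)
  if (sd(trace) == 0)
    return(list(tau_int = NA_real_, a = NA, b = NA, ok = FALSE,
                lags = numeric(0), acf = numeric(0)))
  ac <- acf(trace, lag.max = nlag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1) * dt
  keep <- lags > 0
  lag <- lags[keep]; r <- ac[keep]
  # already below the 1/e point at the first lag: the decay is unresolved
  # by the sampling grid; report it directly from the first-lag value
  if (r[1] < exp(-1))
    return(list(tau_int = if (r[1] > 0) -dt / log(r[1]) else 0,
                a = NA, b = NA, ok = TRUE, lags = lag, acf = r))
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ a * (exp(-lag / tau) + b),
                      start = list(a = max(r[1], 0.1), tau = lag[max(which(r > r[1] / exp(1)), 1)],
                                   b = max(min(r), 0)),
                      lower = c(a = 0, tau = dt / 10, b = -1),
                      upper = c(a = Inf, tau = 50 * max_lag, b = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_int = max_lag, a = NA, b = NA, ok = FALSE,
                lags = lag, acf = r))
  cf <- coef(fit)
  ok <- cf[["tau"]] < 10 * max_lag
  list(tau_int = unname(cf[["tau"]]), a = unname(cf[["a"]]),
       b = unname(cf[["b"]]), ok = ok, lags = lag, acf = r)
}

#' Population intrinsic-timescale summary
#'
#' Applies [intrinsic_timescale()] to each recorded membrane-potential
#' trace and summarizes the distribution of fitted decay constants.
#'
#' @param result a `simulation_result` with V traces.
#' @param ids neuron ids (default: all recorded).
#' @param max_lag maximum lag (ms).
#' @return list with per-neuron `tau` values (valid fits only), the
#'   population mean/median, and the number of excluded neurons.
#' @export
population_timescale <- function(result, ids = NULL, max_lag = 1000) {
  if (is.null(result$V)) stop("V traces were not recorded")
  idx <- if (is.null(ids)) seq_along(result$record_v_idx)
         else match(ids, result$record_v_idx)
  dt <- diff(result$trace_times[1:2])
  taus <- vapply(idx, function(i) {
    f <- intrinsic_timescale(result$V[i, ], dt = dt, max_lag = max_lag)
    if (isTRUE(f$ok)) f$tau_int else NA_real_
  }, numeric(1))
  list(tau = taus[!is.na(taus)], mean = mean(taus, na.rm = TRUE),
       median = stats::median(taus, na.rm = TRUE),
       n_excluded = sum(is.na(taus)))
}

#' Effective membrane time constant
#'
#' `tau_eff = C_m / <G_total>` per neuron, where `G_total` includes the
#' leak and all synaptic conductances; bounded above by the baseline
#' `tau_0 = C_m / g_leak`.
#'
#' @param result a `simulation_result` with `gtot` recorded.
#' @param circuit the simulated `microcircuit`.
#' @return list with per-neuron `tau_eff`, `tau_0` and class summaries.
#' @export
effective_time_constant <- function(result, circuit) {
  if (is.null(result$G_total)) stop("conductance traces were not recorded")
  arr <- circuit_arrays(circuit)
  idx <- result$record_c_idx
  Cm <- arr$npar[idx, "C_m"]; gl <- arr$npar[idx, "g_leak"]
  tau_eff <- Cm / rowMeans(result$G_total)
  tau_0 <- Cm / gl
  cls <- neuron_classes(circuit)[idx]
  list(tau_eff = tau_eff, tau_0 = tau_0, class = cls,
       by_class = vapply(split(tau_eff, cls), mean, numeric(1)))
}

#' Rate transfer functions and gain/offset changes
#'
#' Simulates a condition over a grid of background rates and summarizes
#' the population rate transfer function; optionally compares against a
#' baseline (homogeneous) result as a change in absolute gain (percent)
#' and offset.
#'
#' @param condition condition name passed to [build_microcircuit()].
#' @param nu_grid background rates (spikes/s), sorted.
#' @param N circuit size.
#' @param duration per-point simulated time (ms).
#' @param seeds integer vector; results are averaged over seeds.
#' @param baseline optional result of a previous `rate_transfer` call used
#'   as the reference for `delta_gain` / `delta_offset`.
#' @param rate_threshold rate (spikes/s) above which a population counts
#'   as responsive (offset definition).
#' @return list with `rates` (array class x grid), `fraction_active`,
#'   per-class `gain`, `offset`, and (if baseline given) `delta_gain`
#'   (percent) and `delta_offset`.
#' @export
rate_transfer <- function(condition, nu_grid, N = 2500, duration = 10000,
                          seeds = 1, baseline = NULL,
                          rate_threshold = 0.01) {
  stopifnot(!is.unsorted(nu_grid), length(seeds) >= 1)
  rates <- array(0, c(3, length(nu_grid)),
                 dimnames = list(CLASSES, nu_grid))
  frac <- rates
  for (s in seeds) {
    mc <- build_microcircuit(N, condition, seed = s)
    cls <- neuron_classes(mc)
    for (g in seq_along(nu_grid)) {
      res <- simulate_circuit(mc, stimulus_program(nu_in = nu_grid[g]),
                              duration = duration, seed = s + 1000L,
                              record = character(0))
      for (k in seq_along(CLASSES)) {
        ids <- which(cls == CLASSES[k])
        rates[k, g] <- rates[k, g] +
          sum(res$spikes$id %in% ids) / length(ids) / (duration / 1000)
        frac[k, g] <- frac[k, g] + mean(ids %in% res$spikes$id)
      }
    }
  }
  rates <- rates / length(seeds); frac <- frac / length(seeds)
  gain <- offset <- stats::setNames(rep(NA_real_, 3), CLASSES)
  for (k in 1:3) {
    act <- which(rates[k, ] > rate_threshold)
    if (length(act)) {
      offset[k] <- nu_grid[act[1]]
      upper <- act[act >= stats::median(act)]
      if (length(upper) >= 2)
        gain[k] <- unname(coef(lm(rates[k, upper] ~ nu_grid[upper]))[2])
    }
  }
  out <- list(condition = condition, nu_grid = nu_grid, rates = rates,
              fraction_active = frac, gain = gain, offset = offset)
  if (!is.null(baseline)) {
    out$delta_gain <- 100 * (gain - baseline$gain) / abs(baseline$gain)
    out$delta_offset <- offset - baseline$offset
  }
  out
}
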