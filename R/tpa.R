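#' Construct a texture-profile-analysis force-time curve
#'
#' A TPA run compresses a meat cylinder twice at constant probe speed
#' and records force (gf) against time (s). The curve object keeps the
#' raw series plus the contact threshold below which the probe is
#' considered off-sample.
#'
#' @param time Strictly increasing time series, s.
#' @param force Force series, gf, same length as `time`.
#' @param contact_threshold Force above which the probe is in contact
#'   with the sample (same units as `force`, applied after baseline
#'   correction).
#' @return A `tpa_curve` object.
#' @export
tpa_curve <- function(time, force, contact_threshold = 0) {
  time <- as.numeric(time); force <- as.numeric(force)
  if (length(time) != length(force)) stop("time/force length mismatch")
  if (length(time) < 4) stop("curve too short (need >= 4 samples)")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(is.na(force))) stop("missing force values")
  structure(list(time = time, force = force,
                 contact_threshold = contact_threshold),
            class = "tpa_curve")
}

#' Read a TPA curve from CSV
#'
#' Expects columns `time_s` and `force_gf`.
#'
#' @param path CSV path.
#' @param contact_threshold See [tpa_curve()].
#' @return A `tpa_curve`.
#' @export
read_tpa_curve <- function(path, contact_threshold = 0) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force_gf") %in% names(df)))
    stop("TPA curve CSV must contain columns time_s and force_gf")
  tpa_curve(df$time_s, df$force_gf, contact_threshold)
}

#' Write a TPA curve to CSV
#' @param curve A `tpa_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpa_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tpa_curve"))
  utils::write.csv(data.frame(time_s = curve$time, force_gf = curve$force),
                   path, row.names = FALSE)
  invisible(path)
}

# Modal off-sample force. Exact tie-count mode when the series has many
# repeated values (noise-free logger output at rest); otherwise the
# kernel-density mode, which the concentrated off-sample level dominates.
modal_baseline <- function(force, digits = 6) {
  r <- round(force, digits)
  tab <- table(r)
  if (max(tab) >= max(5, 0.01 * length(force)))
    return(as.numeric(names(tab)[which.max(tab)]))
  d <- stats::density(force, n = 1024)
  d$x[which.max(d$y)]
}

# Linear interpolation of the time at which force crosses `level`
# between samples i and i+1.
crossing_time <- function(t0, f0, t1, f1, level) {
  if (f1 == f0) return(t0)
  t0 + (level - f0) * (t1 - t0) / (f1 - f0)
}

#' Segment a two-cycle TPA curve into compression/withdrawal episodes
#'
#' The force series is baseline-corrected by subtracting the modal
#' off-sample force, then split into maximal runs above the contact
#' threshold. Episode boundaries are refined by linear interpolation of
#' the threshold crossings so durations and areas are exact for
#' piecewise-linear curves. When noise produces more than two runs, the
#' two with the highest peak force are taken (in time order). Within an
#' episode, compression runs up to the force peak and withdrawal after
#' it.
#'
#' @param curve A [tpa_curve()].
#' @return List of two episodes, each a list with `time`, `force`
#'   (boundary-interpolated), `peak` (gf), `peak_time`, `duration` (s),
#'   `area_total`, `area_compression`, `area_withdrawal` (gf s,
#'   trapezoidal).
#' @export
segment_cycles <- function(curve) {
  stopifnot(inherits(curve, "tpa_curve"))
  t <- curve$time
  f <- curve$force - modal_baseline(curve$force)
  thr <- curve$contact_threshold
  above <- f > thr
  if (!any(above)) stop("single-cycle curve: no above-threshold episode")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) < 2)
    stop("single-cycle curve: two compression cycles are required")
  if (nrow(runs) > 2) {
    pk <- vapply(seq_len(nrow(runs)), function(i)
      max(f[runs$start[i]:runs$end[i]]), numeric(1))
    runs <- runs[order(-pk)[1:2], , drop = FALSE]
    runs <- runs[order(runs$start), , drop = FALSE]
  }
  lapply(seq_len(2), function(i) {
    i0 <- runs$start[i]; i1 <- runs$end[i]
    tt <- t[i0:i1]; ff <- f[i0:i1]
    if (i0 > 1) {
      tc <- crossing_time(t[i0 - 1], f[i0 - 1], t[i0], f[i0], thr)
      tt <- c(tc, tt); ff <- c(thr, ff)
    }
    if (i1 < length(t)) {
      tc <- crossing_time(t[i1], f[i1], t[i1 + 1], f[i1 + 1], thr)
      tt <- c(tt, tc); ff <- c(ff, thr)
    }
    ipk <- which.max(ff)
    trapz <- function(x, y) if (length(x) < 2) 0 else
      sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    list(time = tt, force = ff, peak = max(ff), peak_time = tt[ipk],
         duration = tt[length(tt)] - tt[1],
         area_total = trapz(tt, ff),
         area_compression = trapz(tt[1:ipk], ff[1:ipk]),
         area_withdrawal = trapz(tt[ipk:length(tt)], ff[ipk:length(ff)]))
  })
}

#' Derive the four standard TPA parameters from a two-cycle curve
#'
#' * hardness — peak force of the first cycle (gf);
#' * cohesiveness — total area of cycle 2 / total area of cycle 1;
#' * springiness — contact duration of cycle 2 / cycle 1 (at constant
#'   probe speed this equals the conventional distance ratio);
#' * resilience — withdrawal area / compression area within cycle 1.
#'
#' Areas are trapezoidal integrals of force over time.
#'
#' @param curve A [tpa_curve()].
#' @return List of class `tpa_params` with elements `hardness`,
#'   `cohesiveness`, `springiness`, `resilience`.
#' @export
compute_tpa <- function(curve) {
  cyc <- segment_cycles(curve)
  if (cyc[[1]]$area_total <= 0) stop("zero first-cycle area")
  if (cyc[[1]]$area_compression <= 0)
    stop("zero first-cycle compression area")
  structure(list(hardness = cyc[[1]]$peak,
                 cohesiveness = cyc[[2]]$area_total / cyc[[1]]$area_total,
                 springiness = cyc[[2]]$duration / cyc[[1]]$duration,
                 resilience = cyc[[1]]$area_withdrawal /
                   cyc[[1]]$area_compression),
            class = "tpa_params")
}

#' @export
print.tpa_params <- function(x, ...) {
  cat(sprintf(paste0("TPA: hardness %.4g gf | cohesiveness %.4g | ",
                     "springiness %.4g | resilience %.4g\n"),
              x$hardness, x$cohesiveness, x$springiness, x$resilience))
  invisible(x)
}

#' Simulate a two-cycle TPA curve with known parameters
#'
#' Builds a piecewise-linear double-pulse curve whose analytic TPA
#' parameters equal `true_params` exactly: cycle 1 is a triangle of peak
#' `hardness` over `cycle1_duration` with the peak placed at fraction
#' `1 / (1 + resilience)` of the pulse; cycle 2 is a symmetric triangle
#' with duration `springiness x cycle1_duration` and area `cohesiveness`
#' times cycle 1's. Gaussian noise of SD `noise_sd` gf is added
#' pointwise. Sampling uses a uniform grid plus the exact knot times, so
#' with `noise_sd = 0` [compute_tpa()] recovers `true_params` to
#' machine precision. Consumes the current RNG stream.
#'
#' @param true_params List with `hardness`, `cohesiveness`,
#'   `springiness`, `resilience` (all > 0).
#' @param noise_sd Additive force noise SD, gf.
#' @param sample_rate Sampling rate, Hz.
#' @param cycle1_duration First-pulse contact duration, s.
#' @param rest Off-sample span between pulses (also leads/trails), s.
#' @return A [tpa_curve()] with `contact_threshold = 6 * noise_sd`.
#' @export
simulate_tpa_curve <- function(true_params, noise_sd = 0,
                               sample_rate = 1000, cycle1_duration = 20,
                               rest = 2) {
  p <- true_params
  stopifnot(p$hardness > 0, p$cohesiveness > 0, p$springiness > 0,
            p$resilience > 0)
  D1 <- cycle1_duration
  fpk <- 1 / (1 + p$resilience)          # peak position fraction, cycle 1
  D2 <- p$springiness * D1
  H2 <- p$cohesiveness * p$hardness / p$springiness  # area-matched peak
  t0 <- rest
  knots_t <- c(0, t0, t0 + fpk * D1, t0 + D1,
               t0 + D1 + rest, t0 + D1 + rest + D2 / 2,
               t0 + D1 + rest + D2, t0 + 2 * rest + D1 + D2)
  knots_f <- c(0, 0, p$hardness, 0, 0, H2, 0, 0)
  grid <- sort(unique(c(seq(0, max(knots_t), by = 1 / sample_rate),
                        knots_t)))
  force <- stats::approx(knots_t, knots_f, xout = grid)$y
  if (noise_sd > 0)
    force <- force + stats::rnorm(length(force), 0, noise_sd)
  tpa_curve(grid, force, contact_threshold = 6 * noise_sd)
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares every treatment group mean to the control under the Dunnett
#' multivariate-t null: two-sided adjusted p-values are
#' `1 - P(max_j |T_j| <= |t_i|)` where `(T_1, ..., T_k)` follows a
#' central multivariate t with `N - k - 1` error degrees of freedom and
#' correlation `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`,
#' evaluated with [mvtnorm::pmvt()]. With a single treatment group this
#' reduces exactly to the two-sample pooled t-test. The familywise error
#' rate over all comparisons is controlled at `alpha`.
#'
#' Degenerate input: when the pooled variance is zero and all group
#' means are equal, all adjusted p-values are 1 by convention; zero
#' pooled variance with unequal means is an error.
#'
#' @param values Numeric response vector (e.g. hardness per sample).
#' @param groups Group labels, same length as `values`.
#' @param control Label of the control group (e.g. `"raw"`).
#' @param alpha Familywise significance level.
#' @return Data frame with one row per treatment group: `group`, `n`,
#'   `mean`, `sd`, `diff` (group - control), `t`, `df`, `p_adj`,
#'   `significant`; attributes `control`, `alpha`.
#' @export
dunnett_vs_control <- function(values, groups, control, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), is.numeric(values))
  labs <- unique(groups)
  if (!control %in% labs) stop("control group '", control, "' not found")
  if (length(labs) < 2) stop("need at least one treatment group")
  ns <- table(groups)
  if (any(ns < 2)) stop("every group needs n >= 2")
  trt <- setdiff(labs, control)
  k <- length(trt)
  means <- tapply(values, groups, mean)
  ss <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  N <- length(values)
  df <- N - (k + 1)
  s2 <- sum(ss) / df
  if (s2 == 0) {
    if (max(means) - min(means) == 0) {
      out <- data.frame(group = trt, n = as.integer(ns[trt]),
                        mean = as.numeric(means[trt]),
                        sd = 0, diff = 0, t = 0, df = df, p_adj = 1,
                        significant = FALSE, stringsAsFactors = FALSE)
      attr(out, "control") <- control; attr(out, "alpha") <- alpha
      return(out)
    }
    stop("zero pooled variance with unequal group means")
  }
  n0 <- as.numeric(ns[control])
  ni <- as.numeric(ns[trt])
  tstat <- (as.numeric(means[trt]) - as.numeric(means[control])) /
    sqrt(s2 * (1 / ni + 1 / n0))
  lam <- sqrt(ni / (ni + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_adj <- vapply(tstat, function(ti) {
    q <- abs(ti)
    pr <- mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                        df = df, corr = corr,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-6))
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1))
  out <- data.frame(group = trt, n = as.integer(ni),
                    mean = as.numeric(means[trt]),
                    sd = as.numeric(tapply(values, groups, stats::sd)[trt]),
                    diff = as.numeric(means[trt]) - as.numeric(means[control]),
                    t = tstat, df = df, p_adj = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "control") <- control
  attr(out, "alpha") <- alpha
  out
}

#' TPA group comparison report
#'
#' Per-group summary with Dunnett-adjusted p-values against the control
#' and conventional significance flags (`*` p < 0.05, `**` p < 0.01).
#'
#' @inheritParams dunnett_vs_control
#' @return Data frame `group`, `n`, `mean`, `sd`, `p_adj`, `flag`
#'   (control row first with empty p/flag).
#' @export
tpa_group_report <- function(values, groups, control, alpha = 0.05) {
  dn <- dunnett_vs_control(values, groups, control, alpha)
  ctrl_v <- values[groups == control]
  ctrl <- data.frame(group = control, n = length(ctrl_v),
                     mean = mean(ctrl_v), sd = stats::sd(ctrl_v),
                     p_adj = NA_real_, flag = "",
                     stringsAsFactors = FALSE)
  trt <- data.frame(group = dn$group, n = dn$n, mean = dn$mean,
                    sd = dn$sd, p_adj = dn$p_adj,
                    flag = ifelse(dn$p_adj < 0.01, "**",
                                  ifelse(dn$p_adj < 0.05, "*", "")),
                    stringsAsFactors = FALSE)
  rbind(ctrl, trt)
}
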