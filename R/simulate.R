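#' Specification of a synthetic resting-state cohort
#'
#' Collects every parameter of the synthetic-cohort generator. The generator
#' draws, per subject, a parcellated time series from a zero-mean Gaussian
#' whose correlation structure is a low-rank factor model
#' \eqn{\Sigma = \Lambda\Lambda^\top + \psi I} (rescaled to unit diagonal):
#' one global factor and seven network factors produce the within/between
#' network correlation block structure, and two smooth "axis" loading columns
#' plant the two-dimensional gradient geometry (a visual-to-sensorimotor axis
#' and a sensory-to-transmodal axis) that the diffusion-map embedding is meant
#' to recover.
#'
#' Patient-group modifications: `group_effect_size` is added to the axis-1
#' loadings of the sensorimotor network (shifting its position along the first
#' gradient), the whole axis-2 loading column is multiplied by
#' `axis2_compression` (compressing the secondary gradient), and a per-subject
#' latent coupling `delta` scales the default-mode entries of the axis-2
#' column. The cognition score is generated from `delta` alone
#' (`sdmt = sdmt_intercept + sdmt_slope * (delta - 1) + noise`), so recovering
#' the SDMT association through the gradient pipeline is a genuine end-to-end
#' test, not a tautology.
#'
#' @param P,K,T_len parcels, networks, timepoints (defaults 200, 7, 240).
#' @param tr sampling interval in seconds (default 1.5).
#' @param n_per_group named integer vector, subjects per group
#'   (default `c(MS = 60, HC = 60)`; first label is the patient group).
#' @param within_network_corr,between_network_corr within/between-network
#'   correlations of the factor block structure (defaults 0.35, 0.05).
#' @param axis_strength numeric length-2, loading amplitudes of the two
#'   gradient axes (default `c(0.6, 0.5)`, axis 1 dominant).
#' @param baseline_strength amplitude of the shared baseline-connectivity
#'   ("hubness") loading carried by every parcel (default 1.2); hub parcels
#'   keep the sparsified affinity graph densely connected.
#' @param hub_spread relative within-network variation of the baseline
#'   loading (default 0.6).
#' @param local_corr_strength amplitude of the smooth local-neighbourhood
#'   correlation along the canonical parcel ordering (default 0.45),
#'   emulating the spatial autocorrelation of cortical connectivity
#'   profiles; realised as overlapping Gaussian-bump loading columns, it is
#'   what lets the sparsified affinity graph stay connected across network
#'   boundaries, as it does in real connectomes. Set 0 for a pure block
#'   model.
#' @param local_corr_scale correlation length of the neighbourhood structure
#'   in parcels (Gaussian bump width; default 3).
#' @param group_effect_size magnitude of the patients' sensorimotor
#'   hierarchy disruption: the sensorimotor axis-1 loadings are pulled toward
#'   the hierarchy centre by this amount (default 0.6).
#' @param axis2_compression multiplier in (0, 1] on patients' axis-2 loadings
#'   (default 0.7; 1 = no compression).
#' @param delta_sd standard deviation of the patients' latent default-mode
#'   coupling `delta` around 1 (default 0.4); controls (healthy) subjects have
#'   `delta = 1`.
#' @param sdmt_intercept,sdmt_slope,sdmt_noise_sd linear model tying the
#'   cognition score to `delta` (defaults 38.8, 25, 4.5 score points, sized so
#'   the score mean/spread resemble a symbol digit modalities test).
#' @param age_mean,age_sd,sex_p_female per-group covariate distributions
#'   (length-2 vectors, patient group first).
#' @param fd_meanlog,fd_sdlog lognormal parameters of mean framewise
#'   displacement in mm (default median ~ 0.096 mm).
#' @param ar1 optional AR(1) coefficient for temporal smoothing of the
#'   simulated series (default 0 = temporally white).
#' @param seed integer master seed for the cohort.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(P = 200L, K = 7L, T_len = 240L, tr = 1.5,
                            n_per_group = c(MS = 60L, HC = 60L),
                            within_network_corr = 0.35,
                            between_network_corr = 0.05,
                            axis_strength = c(0.6, 0.5),
                            baseline_strength = 1.2, hub_spread = 0.6,
                            local_corr_strength = 0.1,
                            local_corr_scale = 3,
                            group_effect_size = 0.6,
                            axis2_compression = 0.7,
                            delta_sd = 0.4,
                            sdmt_intercept = 38.8, sdmt_slope = 25,
                            sdmt_noise_sd = 4.5,
                            age_mean = c(37.6, 38.1), age_sd = c(9.9, 12.0),
                            sex_p_female = c(84 / 122, 56 / 97),
                            fd_meanlog = log(0.096), fd_sdlog = 0.4,
                            ar1 = 0,
                            seed = 1L) {
  if (K != 7L) stop("the canonical geometry is defined for K = 7 networks")
  if (!(between_network_corr >= 0 && between_network_corr < within_network_corr &&
        within_network_corr < 1))
    stop("need 0 <= between_network_corr < within_network_corr < 1")
  if (!(axis2_compression > 0 && axis2_compression <= 1))
    stop("axis2_compression must be in (0, 1]")
  if (is.null(names(n_per_group)) || length(n_per_group) != 2L)
    stop("n_per_group must be a named length-2 vector (patient group first)")
  spec <- list(P = as.integer(P), K = as.integer(K), T_len = as.integer(T_len),
               tr = tr, n_per_group = n_per_group,
               within_network_corr = within_network_corr,
               between_network_corr = between_network_corr,
               axis_strength = axis_strength,
               baseline_strength = baseline_strength, hub_spread = hub_spread,
               local_corr_strength = local_corr_strength,
               local_corr_scale = local_corr_scale,
               group_effect_size = group_effect_size,
               axis2_compression = axis2_compression,
               delta_sd = delta_sd,
               sdmt_intercept = sdmt_intercept, sdmt_slope = sdmt_slope,
               sdmt_noise_sd = sdmt_noise_sd,
               age_mean = age_mean, age_sd = age_sd,
               sex_p_female = sex_p_female,
               fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
               ar1 = ar1, seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  spec
}

# Overlapping Gaussian-bump loading columns along the canonical parcel
# ordering. Rows are normalized so every parcel receives exactly `strength`
# variance from this block; the induced covariance between parcels i, j then
# decays smoothly as ~ strength * exp(-(i-j)^2 / (4 scale^2)).
local_bumps <- function(P, strength, scale) {
  if (strength <= 0) return(matrix(numeric(0), P, 0))
  centers <- seq(1, P, by = max(1, round(scale)))
  B <- outer(seq_len(P), centers, function(i, c) exp(-(i - c)^2 / (2 * scale^2)))
  B * sqrt(strength / rowSums(B^2))
}

# Smooth axis loading profiles over parcels: two centred contrast columns
# place every parcel in the plane spanned by the visual<->sensorimotor axis
# (axis 1) and the sensory<->transmodal axis (axis 2). Network anchor values
# are interpolated with a deterministic within-network ramp (axis 1) and an
# alternating pattern (axis 2), giving a reproducible two-axis geometry with
# nonzero within-network dispersion.
axis_profiles <- function(assign) {
  anchors <- rbind(
    Vis    = c(-0.90, -0.70),
    SMN    = c( 1.10, -0.20),
    DAN    = c( 0.60, -0.10),
    VAN    = c(-0.60,  0.10),
    Limbic = c( 0.40,  0.40),
    FPN    = c(-0.40,  0.40),
    DMN    = c( 0.00,  1.10))
  # within-network spread of positions along both axes; the attention
  # networks are modelled as spatially heterogeneous (wide), the primary
  # sensory networks as compact
  spreads <- c(Vis = 0.5, SMN = 0.5, DAN = 1.4, VAN = 1.4,
               Limbic = 0.5, FPN = 0.8, DMN = 0.8)
  lv <- levels(assign$network)
  if (!all(lv %in% rownames(anchors)))
    stop("axis anchors are defined for the canonical network labels only")
  prof <- anchors[as.character(assign$network), , drop = FALSE]
  for (k in lv) {
    idx <- which(assign$network == k)
    m <- length(idx)
    ramp <- if (m > 1) seq(-0.5, 0.5, length.out = m) else 0
    wave <- cos(2 * pi * seq_len(m) / max(m, 2) * 2) / 2
    prof[idx, 1] <- prof[idx, 1] + spreads[k] * ramp
    prof[idx, 2] <- prof[idx, 2] + spreads[k] * wave
  }
  dimnames(prof) <- list(NULL, c("axis1", "axis2"))
  prof
}

# Baseline connectivity-strength ("hubness") loading column: every parcel
# carries a shared positive factor whose amplitude varies smoothly within each
# network. Hub parcels correlate with everything and keep the sparsified
# affinity graph densely connected, as association hubs do in real
# connectomes; this column is identical in both groups.
hub_profile <- function(assign, strength, spread) {
  h <- numeric(nrow(assign))
  for (k in levels(assign$network)) {
    idx <- which(assign$network == k)
    m <- length(idx)
    h[idx] <- 1 + spread * sin(2 * pi * (seq_len(m) - 0.5) / m)
  }
  strength * h
}

#' Build a group's parcel covariance matrix
#'
#' Constructs the factor-model correlation matrix
#' \eqn{\Sigma = \Lambda\Lambda^\top + \psi I} for one group and one value of
#' the latent default-mode coupling `delta`. `Lambda` stacks a global factor,
#' seven network factors and the two axis columns; `psi = 1 -
#' within_network_corr` so that with the axes zeroed the matrix is exactly the
#' within/between block correlation matrix. The result is rescaled to unit
#' diagonal and checked for positive semi-definiteness.
#'
#' @param spec a [simulation_spec()].
#' @param group group label; the first label of `spec$n_per_group` is treated
#'   as the patient group and receives the planted effects.
#' @param delta latent default-mode axis-2 coupling (1 = nominal).
#' @param assign optional `network_assignment`; defaults to
#'   [canonical_networks()] at `spec$P`.
#' @return P x P correlation matrix (unit diagonal, PSD).
#' @export
build_group_covariance <- function(spec, group, delta = 1,
                                   assign = canonical_networks(spec$P)) {
  gl <- group_loadings(spec, group, delta, assign)
  Sigma <- tcrossprod(gl$Lambda) + diag(gl$psi, spec$P)
  Sigma <- Sigma / tcrossprod(gl$scale)
  Sigma <- (Sigma + t(Sigma)) / 2
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10)
    stop("constructed covariance is not positive semi-definite (min eigenvalue ",
         format(ev_min), ")")
  Sigma
}

# Factor-model loadings for one group and one delta; the covariance is
# Sigma = S^-1 (Lambda Lambda' + psi I) S^-1 with S = diag(scale) the
# unit-diagonal rescale.
group_loadings <- function(spec, group, delta = 1,
                           assign = canonical_networks(spec$P)) {
  stopifnot(inherits(spec, "simulation_spec"))
  P <- spec$P
  if (nrow(assign) != P) stop("network assignment does not match spec$P")
  patient <- identical(as.character(group), names(spec$n_per_group)[1])

  prof <- axis_profiles(assign)
  a1 <- spec$axis_strength[1] * prof[, "axis1"]
  a2 <- spec$axis_strength[2] * prof[, "axis2"]
  if (patient) {
    # hierarchy disruption: the sensorimotor network is pulled from its
    # axis-1 pole toward the centre of the hierarchy
    a1[assign$network == "SMN"] <- a1[assign$network == "SMN"] - spec$group_effect_size
    a2 <- a2 * spec$axis2_compression
  }
  a2[assign$network == "DMN"] <- delta * a2[assign$network == "DMN"]

  Lambda <- cbind(
    global = rep(sqrt(spec$between_network_corr), P),
    sapply(levels(assign$network), function(k)
      sqrt(spec$within_network_corr - spec$between_network_corr) *
        (assign$network == k)),
    baseline = hub_profile(assign, spec$baseline_strength, spec$hub_spread),
    axis1 = a1, axis2 = a2,
    local_bumps(P, spec$local_corr_strength, spec$local_corr_scale))
  psi <- 1 - spec$within_network_corr
  list(Lambda = Lambda, psi = psi,
       scale = sqrt(rowSums(Lambda^2) + psi))
}

#' Simulate one subject's parcellated time series
#'
#' Draws `T_len` temporally independent samples (optionally AR(1)-smoothed)
#' from a zero-mean Gaussian with the given parcel covariance.
#'
#' @param Sigma P x P PSD covariance matrix.
#' @param T_len number of timepoints (>= 2).
#' @param seed optional integer seed (set for reproducibility).
#' @param tr sampling interval in seconds.
#' @param subject_id subject identifier attached to the result.
#' @param ar1 AR(1) coefficient in [0, 1); 0 keeps the series temporally white.
#' @return A [parcel_timeseries()] (P x T matrix plus `tr` and `subject_id`).
#' @export
simulate_subject <- function(Sigma, T_len, seed = NULL, tr = 1.5,
                             subject_id = "sim", ar1 = 0) {
  if (T_len < 2) stop("T_len must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(Sigma)
  L <- chol_psd(Sigma)
  Z <- matrix(stats::rnorm(T_len * P), T_len, P)
  if (ar1 > 0) {
    for (t in 2:T_len) Z[t, ] <- ar1 * Z[t - 1, ] + sqrt(1 - ar1^2) * Z[t, ]
  }
  X <- t(Z %*% L)  # P x T
  parcel_timeseries(X, tr = tr, subject_id = subject_id)
}

# AR(1) smoothing along rows, preserving unit marginal variance.
ar1_rows <- function(Z, ar1) {
  for (t in 2:ncol(Z)) Z[, t] <- ar1 * Z[, t - 1] + sqrt(1 - ar1^2) * Z[, t]
  Z
}

# Cholesky-like factor for PSD (possibly rank-deficient) matrices via
# eigendecomposition; returns R with crossprod(R) = Sigma.
chol_psd <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(vals) * t(e$vectors)))
}

#' Simulate a full cohort
#'
#' Generates the manifest (group, age, sex, mean FD, clinical scores), one
#' parcellated time series per subject, and the ground-truth record used by
#' parameter-recovery tests. Clinical scores other than SDMT (EDSS, disease
#' duration, lesion load, BPF) are drawn independently of the signal and act
#' as null variables for calibration; SDMT is tied to the latent coupling
#' `delta`.
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `synthetic_cohort`:
#' \describe{
#'   \item{manifest}{data.frame, one row per subject.}
#'   \item{ts}{named list of [parcel_timeseries()].}
#'   \item{lookup}{the `network_assignment` used.}
#'   \item{ground_truth}{data.frame with per-subject `delta` and planted-effect
#'     metadata in attributes.}
#' }
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  assign <- canonical_networks(spec$P)
  groups <- names(spec$n_per_group)
  n <- sum(spec$n_per_group)

  group <- rep(groups, times = spec$n_per_group)
  idx_in_group <- unlist(lapply(spec$n_per_group, seq_len), use.names = FALSE)
  subject_id <- sprintf("%s%03d", group, idx_in_group)
  gi <- match(group, groups)

  age <- pmin(65, pmax(18, stats::rnorm(n, spec$age_mean[gi], spec$age_sd[gi])))
  sex <- ifelse(stats::runif(n) < spec$sex_p_female[gi], "F", "M")
  mean_fd <- stats::rlnorm(n, spec$fd_meanlog, spec$fd_sdlog)

  patient <- gi == 1L
  delta <- ifelse(patient, stats::rnorm(n, 1, spec$delta_sd), 1)
  sdmt <- ifelse(patient,
                 spec$sdmt_intercept + spec$sdmt_slope * (delta - 1) +
                   stats::rnorm(n, 0, spec$sdmt_noise_sd),
                 NA_real_)
  disease_duration <- ifelse(patient, stats::rgamma(n, shape = 1.5, scale = 7), NA_real_)
  edss <- ifelse(patient, round(pmin(6.5, pmax(0, stats::rnorm(n, 2, 1.2))) * 2) / 2,
                 NA_real_)
  lesion_load <- ifelse(patient, stats::rlnorm(n, log(3), 0.8), NA_real_)
  bpf <- pmin(1, pmax(0.5, stats::rnorm(n, ifelse(patient, 0.71, 0.74),
                                        ifelse(patient, 0.04, 0.02))))

  manifest <- data.frame(subject_id = subject_id, group = group, age = age,
                         sex = sex, mean_fd = mean_fd, sdmt = sdmt,
                         edss = edss, disease_duration = disease_duration,
                         lesion_load = lesion_load, bpf = bpf,
                         stringsAsFactors = FALSE)

  # draw each subject directly from the factor model
  # X = S^-1 (Lambda eta + sqrt(psi) eps): exact for Sigma = Lambda Lambda' + psi I
  subject_seeds <- spec$seed + seq_len(n)
  ts <- vector("list", n)
  names(ts) <- subject_id
  for (i in seq_len(n)) {
    gl <- group_loadings(spec, group[i], delta[i], assign)
    set.seed(subject_seeds[i])
    q <- ncol(gl$Lambda)
    eta <- matrix(stats::rnorm(q * spec$T_len), q, spec$T_len)
    eps <- matrix(stats::rnorm(spec$P * spec$T_len), spec$P, spec$T_len)
    if (spec$ar1 > 0) {
      eta <- ar1_rows(eta, spec$ar1)
      eps <- ar1_rows(eps, spec$ar1)
    }
    X <- (gl$Lambda %*% eta + sqrt(gl$psi) * eps) / gl$scale
    ts[[i]] <- parcel_timeseries(X, tr = spec$tr, subject_id = subject_id[i])
  }

  gt <- data.frame(subject_id = subject_id, group = group, delta = delta,
                   sdmt = sdmt, stringsAsFactors = FALSE)
  attr(gt, "affected_network") <- "SMN"
  attr(gt, "group_effect_size") <- spec$group_effect_size
  attr(gt, "axis2_compression") <- spec$axis2_compression

  structure(list(manifest = manifest, ts = ts, lookup = assign,
                 ground_truth = gt, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$manifest), "subjects (",
      paste(sprintf("%s=%d", names(table(x$manifest$group)),
                    as.integer(table(x$manifest$group))), collapse = ", "),
      "); P =", x$spec$P, ", T =", x$spec$T_len, ", TR =", x$spec$tr, "s\n")
  invisible(x)
}
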