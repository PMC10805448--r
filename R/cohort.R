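# Clinical copula: duration of epilepsy and age at seizure onset are jointly
# Gaussian, truncated to the positive orthant by rejection. Because the
# configured moments describe the *observed* (nonnegative) data, the latent
# Gaussian parameters are moment-matched numerically so the truncated sample
# reproduces the configured means, SDs and correlation.

# Moments of a bivariate normal truncated to [0, Inf)^2, by 2D Gauss-Legendre
# quadrature. Returns c(mean1, mean2, sd1, sd2, cor).
truncated_bvn_moments <- function(mu, s, r, nq = 64L) {
  gl <- pracma::gaussLegendre(nq, 0, 1)
  up <- mu + 10 * s
  x <- gl$x * up[1]; wx <- gl$w * up[1]
  y <- gl$x * up[2]; wy <- gl$w * up[2]
  X <- matrix(x, nq, nq)
  Y <- matrix(y, nq, nq, byrow = TRUE)
  W <- outer(wx, wy)
  det <- 1 - r^2
  zx <- (X - mu[1]) / s[1]
  zy <- (Y - mu[2]) / s[2]
  dens <- exp(-(zx^2 - 2 * r * zx * zy + zy^2) / (2 * det)) /
    (2 * pi * s[1] * s[2] * sqrt(det))
  Z <- sum(W * dens)
  m1 <- sum(W * dens * X) / Z
  m2 <- sum(W * dens * Y) / Z
  v1 <- sum(W * dens * X^2) / Z - m1^2
  v2 <- sum(W * dens * Y^2) / Z - m2^2
  cv <- sum(W * dens * X * Y) / Z - m1 * m2
  c(m1, m2, sqrt(v1), sqrt(v2), cv / sqrt(v1 * v2))
}

# Latent (mu, sigma, rho) whose positive-orthant truncation has the target
# moments. Cached per target vector; deterministic (quadrature + Nelder-Mead).
latent_bvn_params <- function(mean1, mean2, sd1, sd2, r) {
  target <- c(mean1, mean2, sd1, sd2, r)
  key <- paste(signif(target, 10), collapse = "|")
  hit <- .fanet_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(p) {
    m <- truncated_bvn_moments(p[1:2], exp(p[3:4]), tanh(p[5]))
    sum(((m - target) / c(1, 1, 1, 1, 0.1))^2)
  }
  p0 <- c(mean1, mean2, log(sd1), log(sd2), atanh(r))
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  if (fit$value > 1e-6) {
    stop("clinical copula calibration failed to converge for the requested ",
         "moments (residual ", signif(fit$value, 3), ")", call. = FALSE)
  }
  out <- list(mu = fit$par[1:2], s = exp(fit$par[3:4]), r = tanh(fit$par[5]))
  .fanet_cache[[key]] <- out
  out
}

# n pairs from the truncated bivariate normal (rejection of negative draws).
rtruncated_bvn <- function(n, mu, s, r) {
  d <- numeric(0); o <- numeric(0)
  while (length(d) < n) {
    m <- max(2L * (n - length(d)), 16L)
    z1 <- rnorm(m)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(m)
    x <- mu[1] + s[1] * z1
    y <- mu[2] + s[2] * z2
    keep <- x >= 0 & y >= 0
    d <- c(d, x[keep]); o <- c(o, y[keep])
  }
  cbind(duration = d[seq_len(n)], onset = o[seq_len(n)])
}

# Normal draws resampled to stay >= lower (no point mass at the bound).
rnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic clinical cohort
#'
#' Draws one subject table for a two-group (patient/control) cohort. Gender
#' counts match the configured counts exactly; ages are group-specific
#' normals truncated at 18 y (adult cohort); verbal and performance IQ are
#' group-specific normals rounded to integer scores. Patients additionally
#' carry epilepsy duration and age at seizure onset from a negatively
#' correlated bivariate Gaussian copula truncated at zero by rejection, with
#' latent parameters calibrated so the delivered sample matches the
#' configured means/SDs/correlation. Controls carry `NA` for both fields.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return A data.frame of class `subject_table` with columns `subject_id`,
#'   `group`, `age`, `gender`, `duration`, `onset`, `verbal_iq`,
#'   `performance_iq`.
#' @export
#' @examples
#' subjects <- generate_clinical_cohort(cohort_params(), seed = 1)
#' table(subjects$group, subjects$gender)
generate_clinical_cohort <- function(params = cohort_params(), seed = 1L) {
  validate_cohort_params(params)
  np <- params$n_patients
  nc <- params$n_controls
  # copula calibration (degenerate SDs bypass the latent solve)
  if (params$duration_sd == 0 || params$onset_sd == 0) {
    lat <- NULL
  } else {
    lat <- latent_bvn_params(params$duration_mean, params$onset_mean,
                             params$duration_sd, params$onset_sd,
                             params$duration_onset_r)
  }
  with_seed(seed, {
    grp <- function(v, g) v[[g]]
    age <- c(rnorm_lower(np, grp(params$age_mean, "patient"),
                         grp(params$age_sd, "patient"), 18),
             rnorm_lower(nc, grp(params$age_mean, "control"),
                         grp(params$age_sd, "control"), 18))
    gender <- c(
      sample(rep(c("male", "female"),
                 c(params$male_count[["patient"]],
                   np - params$male_count[["patient"]]))),
      sample(rep(c("male", "female"),
                 c(params$male_count[["control"]],
                   nc - params$male_count[["control"]])))
    )
    if (is.null(lat)) {
      do <- cbind(duration = rep(params$duration_mean, np),
                  onset = rep(params$onset_mean, np))
      if (params$duration_sd > 0) {
        do[, "duration"] <- rnorm_lower(np, params$duration_mean,
                                        params$duration_sd, 0)
      }
      if (params$onset_sd > 0) {
        do[, "onset"] <- rnorm_lower(np, params$onset_mean,
                                     params$onset_sd, 0)
      }
    } else {
      do <- rtruncated_bvn(np, lat$mu, lat$s, lat$r)
    }
    viq <- round(c(rnorm(np, params$viq_mean[["patient"]],
                         params$viq_sd[["patient"]]),
                   rnorm(nc, params$viq_mean[["control"]],
                         params$viq_sd[["control"]])))
    piq <- round(c(rnorm(np, params$piq_mean[["patient"]],
                         params$piq_sd[["patient"]]),
                   rnorm(nc, params$piq_mean[["control"]],
                         params$piq_sd[["control"]])))
    subjects <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(np + nc)),
      group = factor(rep(c("patient", "control"), c(np, nc)),
                     levels = c("patient", "control")),
      age = age,
      gender = factor(gender, levels = c("male", "female")),
      duration = c(do[, "duration"], rep(NA_real_, nc)),
      onset = c(do[, "onset"], rep(NA_real_, nc)),
      verbal_iq = viq,
      performance_iq = piq,
      stringsAsFactors = FALSE
    )
    class(subjects) <- c("subject_table", "data.frame")
    subjects
  })
}
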