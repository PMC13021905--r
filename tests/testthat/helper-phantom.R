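# Shared fixtures: phantoms are generated in code, never stored.

default_params <- list(a = -0.5, b = 2, c = 30000, d = 8)

make_transfer <- function(noise_sd = 0) {
  transfer_model(a = default_params$a, b = default_params$b,
                 c = default_params$c, d = default_params$d,
                 noise_sd = noise_sd)
}

make_phantom <- function(..., noise_sd = 0) {
  generate_phantom(step_wedge_spec(), keel_phantom_spec(...),
                   make_transfer(noise_sd))
}

# Exact calibration pairs generated straight from the forward model.
exact_pairs <- function(tm = make_transfer(),
                        thickness = wedge_thickness_series(step_wedge_spec())) {
  data.frame(thickness = thickness,
             mean_gray = render_gray(tm, thickness),
             n_pixels = 1L)
}

# Independent log-rank oracle for two groups: explicit 2x2 hypergeometric
# table enumeration over the distinct event times (standard variance, no
# continuity correction).
logrank_oracle_2g <- function(records) {
  records$group <- as.character(records$group %||% records$genotype)
  groups <- sort(unique(records$group))
  stopifnot(length(groups) == 2)
  event_times <- sort(unique(records$time[records$status == 1]))
  O1 <- E1 <- V <- 0
  for (t in event_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & records$group == groups[1])
    d <- sum(records$time == t & records$status == 1)
    d1 <- sum(records$time == t & records$status == 1 &
                records$group == groups[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct binomial-tail root-finding oracle for the exact interval (percent).
clopper_pearson_oracle <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = 100 * lower, upper = 100 * upper)
}
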