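# Shared fixtures: the two published case studies, built in code.

frog_problem <- function(abundance = 1) {
  mu <- if (abundance == 1) 0.67 else 2.2   # detections per hour
  design_problem(B = 10, c = 1, rate = rate_prior(mu, theta = 2.5))
}

frog_sp <- function(abundance = 1) scale_problem(frog_problem(abundance))

plant_sp <- function(species = c("lomandra", "atriplex"), B = 15, c = 0.25) {
  species <- match.arg(species)
  rate <- if (species == "lomandra") rate_prior(0.56, sigma = 0.64)
          else rate_prior(0.55, sigma = 0.60)
  scale_problem(design_problem(B, c, rate))
}

qc05 <- function() satisficing_target(Q_c = 0.05)

# Monte Carlo estimate of E[Q] and Pr(Q < Qc) under the moment-matched
# lognormal itself (not the sum), for validating the quadrature/closed form
# without Fenton-Wilkinson bias.
mm_mc <- function(n, sp, Qc = NULL, reps = 2e5, seed = 1) {
  mm <- moment_match(n, sp)
  set.seed(seed)
  a <- stats::rlnorm(reps, mm$m, sqrt(mm$v))
  q <- exp(-a)
  out <- list(eq = mean(q), se_eq = stats::sd(q) / sqrt(reps))
  if (!is.null(Qc)) {
    hit <- q < Qc
    out$pt <- mean(hit)
    out$se_pt <- stats::sd(hit) / sqrt(reps)
  }
  out
}
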