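# Independent oracles for the equilibrium solver, kept deliberately
# separate from the implementation: plain bisection on the host mass
# balance, and the closed-form 1:1 quadratic for the guest-free case.

bisect_free_host <- function(Ht, It, Gt, KI, KG, rel_tol = 1e-12) {
  if (Ht == 0) return(0)
  f <- function(h) h + KG * h * Gt / (1 + KG * h) + KI * h * It / (1 + KI * h) - Ht
  # bisect to *relative* convergence: the root can sit many orders of
  # magnitude below Ht when the host is strongly sequestered
  lo <- 0; hi <- Ht
  while ((hi - lo) > rel_tol * hi && (hi - lo) > 1e-300) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# positive root of K*h^2 + (1 + K*(It - Ht))*h - Ht = 0 (guest absent),
# in the cancellation-free form 2*Ht / (b + sqrt(b^2 + 4*K*Ht))
quadratic_free_host <- function(Ht, It, KI) {
  if (KI == 0) return(Ht)
  b <- 1 + KI * (It - Ht)
  2 * Ht / (b + sqrt(b^2 + 4 * KI * Ht))
}

# forward-model absorbance without touching the package's solver
oracle_absorbance <- function(h, It, b, KI, eps_I, eps_HI) {
  It / (1 + KI * h) * (eps_I * b + eps_HI * b * KI * h)
}

# random assay systems spanning the documented ranges
random_systems <- function(n, seed) {
  set.seed(seed)
  data.frame(
    Ht = 10^runif(n, -7, 0),
    It = 10^runif(n, -7, 0),
    Gt = 10^runif(n, -7, 0),
    KI = 10^runif(n, 0, 6),
    KG = 10^runif(n, 0, 6)
  )
}
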