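# Independent brute-force root oracle for the reduced (Fa, Bu) system.
# Pure sign-scan bisection: a coarse sign-partition scan (with a log-spaced
# sub-grid near the origin) locates candidate cells, and each candidate is
# refined by recursive 8x8 sub-grid sign scans. Near-tangential nullcline
# passages die out under refinement; transversal crossings survive at every
# resolution. No derivatives, no Newton steps: fully independent of the
# package's polisher.

field_eval <- function(p, FA, BU) {
  Ga <- p$total_actin - p$phi_fp * (FA + BU)
  fb <- p$alpha_f * Ga * FA^p$hill_h / (FA^p$hill_h + p$k^p$hill_h)
  nuc <- if (is.null(p$nucleation_n)) p$gamma_f else p$nucleation_n
  list(dFa = fb + p$gamma_f * Ga * FA + 2 * nuc * Ga * Ga -
         p$alpha_b * FA * (2 * FA + BU) - p$beta_f * FA,
       dBu = p$alpha_b * FA * (2 * FA + BU) + p$gamma_b * Ga * BU -
         p$beta_b * BU)
}

both_change <- function(sf, sb) {
  i <- seq_len(nrow(sf) - 1); j <- seq_len(ncol(sf) - 1)
  ch <- function(s) (s[i, j] != s[i + 1, j]) | (s[i, j] != s[i, j + 1]) |
    (s[i, j] != s[i + 1, j + 1])
  ch(sf) & ch(sb)
}

refine_cell <- function(p, fa0, fa1, bu0, bu1, depth) {
  fa <- seq(fa0, fa1, length.out = 9); bu <- seq(bu0, bu1, length.out = 9)
  FA <- matrix(fa, 9, 9); BU <- matrix(bu, 9, 9, byrow = TRUE)
  v <- field_eval(p, FA, BU)
  cand <- which(both_change(sign(v$dFa), sign(v$dBu)), arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  if (depth == 0) {
    k <- cand[1, ]
    return(c((fa[k[1]] + fa[k[1] + 1]) / 2, (bu[k[2]] + bu[k[2] + 1]) / 2))
  }
  for (r in seq_len(nrow(cand))) {
    k <- cand[r, ]
    res <- refine_cell(p, fa[k[1]], fa[k[1] + 1], bu[k[2]], bu[k[2] + 1],
                       depth - 1)
    if (!is.null(res)) return(res)
  }
  NULL
}

oracle_roots <- function(p, n = 400, depth = 5) {
  lim <- p$total_actin / p$phi_fp
  g <- sort(unique(c(seq(0, lim, length.out = n),
                     lim * 10^seq(-6, -1.2, length.out = 40))))
  FA <- matrix(g, length(g), length(g)); BU <- t(FA)
  v <- field_eval(p, FA, BU)
  keep <- FA[-length(g), -length(g)] + BU[-length(g), -length(g)] <= lim
  cand <- which(both_change(sign(v$dFa), sign(v$dBu)) & keep, arr.ind = TRUE)
  roots <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    res <- refine_cell(p, max(g[i] - (g[i + 1] - g[i]) / 2, 0),
                       g[i + 1] + (g[i + 1] - g[i]) / 2,
                       max(g[j] - (g[j + 1] - g[j]) / 2, 0),
                       g[j + 1] + (g[j + 1] - g[j]) / 2, depth)
    if (is.null(res)) next
    if (nrow(roots) == 0 ||
        all(pmax(abs(roots[, 1] - res[1]),
                 abs(roots[, 2] - res[2])) > 1e-4 * lim))
      roots <- rbind(roots, res)
  }
  roots
}

# the stated box for random-set oracle comparisons
random_kinetics <- function() {
  kinetic_params(alpha_f = runif(1, 0.05, 0.5),
                 gamma_f = 10^runif(1, -3.5, -2),
                 beta_f = 10^runif(1, -1.5, -0.8),
                 alpha_b = runif(1, 0.01, 0.06),
                 gamma_b = 10^runif(1, -3, -2),
                 beta_b = 10^runif(1, -2.3, -1.5),
                 total_actin = runif(1, 0.3, 0.8))
}
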