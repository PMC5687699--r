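# Shared fixtures, built in code at test time.

# small synthetic cine plus the full peri-ventricular analysis
run_small_pipeline <- function(grad = 0.7, seed = 1, dim = 64, dur = 12,
                               arteriovenous = FALSE, ...) {
  g <- generate_cine(dim = c(dim, dim), fs = 30, duration = dur,
                     cardiac_freq = 2.5, ventral_dorsal_gradient = grad,
                     seed = seed, ...)
  pa <- periventricular_analysis(g$cine, g$truth$contour, g$blob_roi,
                                 arteriovenous = arteriovenous,
                                 n_permutations = 500)
  list(g = g, pa = pa)
}

# cine whose pixels all carry the same signal
uniform_cine <- function(signal, h = 8, w = 8, fs = 30) {
  cine_sequence(array(rep(signal, each = h * w), c(h, w, length(signal))), fs)
}

# straight horizontal open contour of a given length
straight_contour <- function(len = 300, y = 50, x0 = 10) {
  cbind(x = seq(x0, x0 + len, length.out = 61), y = rep(y, 61))
}

# direct-definition circular mean/sd for oracle comparisons
brute_circ <- function(th) {
  C <- sum(cos(th)); S <- sum(sin(th))
  r <- sqrt(C^2 + S^2) / length(th)
  list(mean = atan2(S, C), sd = sqrt(-2 * log(r)), rbar = r)
}
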