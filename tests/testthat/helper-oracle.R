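## Independent brute-force oracle for two-site CPMG propagation, kept
## deliberately separate from the package's code path: the matrix
## exponential is a scaling-and-squaring Taylor series on the full complex
## 2x2 matrix, and the echo train is propagated pulse by pulse with
## explicit conjugation of the magnetisation vector.

expm_taylor <- function(A) {
  nrm <- max(Mod(A))
  j <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 1L)
  As <- A / 2^j
  S <- diag(2) + 0i
  term <- diag(2) + 0i
  for (k in 1:30) {
    term <- (term %*% As) / k
    S <- S + term
  }
  for (k in seq_len(j)) S <- S %*% S
  S
}

bm_r2eff_oracle <- function(k_ex, p_B, dw_rad, r20, t_relax, nu) {
  p_A <- 1 - p_B
  k_ab <- p_B * k_ex
  k_ba <- p_A * k_ex
  n <- max(2L, as.integer(2 * round(nu * t_relax)))
  tau <- t_relax / (2 * n)
  L <- matrix(c(-r20 - k_ab, k_ab, k_ba,
                complex(real = -r20 - k_ba, imaginary = -dw_rad)), 2, 2)
  E <- expm_taylor(L * tau)
  M <- c(p_A, p_B) + 0i
  for (p in seq_len(n)) M <- E %*% Conj(E %*% M)
  as.numeric(-log(Mod(M[1]) / p_A) / t_relax)
}

## small helpers used across test files
both_fields <- function() default_fields()

methyl_subset <- function(dataset, key) {
  rid <- sub("\\.[^.]*$", "", key)
  mid <- sub("^.*\\.", "", key)
  dataset[dataset$residue_id == rid & dataset$methyl_id == mid, ,
          drop = FALSE]
}
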