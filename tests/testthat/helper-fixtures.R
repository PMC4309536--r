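# shared fixtures: small populations and field states built in code

sig <- signaling_params()
mech <- mechanics_params()

# independent steady-state oracle: dense brute-force sign-change scan of the
# reduced scalar map (A, R eliminated by the cascade), kept separate from the
# package's solver
oracle_equilibria_M <- function(G, p = sig, n = 20001, M_max = 10) {
  A_of <- function(M) p$S1 + p$lambda3 * p$lambda4^2 / (p$lambda4^2 + p$beta * M^2)
  f <- function(M) {
    A <- A_of(M)
    p$lambda_g * G + p$lambda1 * p$lambda2^2 / (p$lambda2^2 + p$alpha * A^2) - M
  }
  Ms <- seq(0, M_max, length.out = n)
  fv <- f(Ms)
  idx <- which(fv[-1] * fv[-n] < 0)
  vapply(idx, function(i) uniroot(f, c(Ms[i], Ms[i + 1]), tol = 1e-13)$root,
         numeric(1))
}

# a small hexagonally packed cluster around a focal centre cell
hex_cluster <- function(spacing = 18) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  new_cells(x = c(500, 500 + spacing * cos(ang)),
            y = c(500, 500 + spacing * sin(ang)))
}

tiny_field <- function(n = 21, L = 2, ...) {
  field_state(L = L, n = n, params = field_params(...))
}
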