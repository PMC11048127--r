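# Frozen high-precision oracle values, computed once with an
# independent arbitrary-precision evaluation (mpmath, 50 digits) of the
# documented closed forms.
oracle <- list(
  spiral_L_1turn = 1.9016128229282225e-10,   # n=1, d_avg=200um, rho=0.5
  circinate_C = 7.861366001170053e-14,       # LC=1mm, a=10um, b=20um, eps=12.85, t=0.2um
  penetration_depth = 1.3430511959120961e-2, # eps'=50, eps''=20, f=1.28GHz
  single_shell_eps = 59.147369418946496,     # mem 6, cyto 60, R=7.5um, d=10nm
  mg_mixture = 2.1974602448232468,           # incl 59.15, host 1, phi 0.3
  f_1nH_1pF = 5032921210.4487035             # 1/(2*pi*sqrt(1e-21))
)

# Independent re-evaluation of the spiral-inductance closed form,
# written as a literal transcription (separate code path from the
# package's implementation).
brute_spiral_inductance <- function(n, d_avg, rho) {
  mu0 <- 1.25663706212e-6
  term <- log(2.16) - log(rho) + 0.00 * rho + 0.20 * rho * rho
  mu0 * n * n * d_avg * 0.5 * 1.00 * term
}

# Brute-force single-shell permittivity straight from its definition.
brute_single_shell <- function(eps_mem, eps_cyto, R, d) {
  g <- R / (R - d)
  A <- (eps_cyto - eps_mem) / (eps_cyto + 2 * eps_mem)
  eps_mem * (g^3 + 2 * A) / (g^3 - A)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

expect_rel <- function(x, ref, tol) {
  expect_lt(rel_err(x, ref), tol)
}
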