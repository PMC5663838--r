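# default-parameter models used across tests (k+1 a = 0.5, k-1 = 3, k+2 = k-2 = 1)
model_b4_100 <- function() schloegl(b = 4, omega = 100)
model_b4_10 <- function() schloegl(b = 4, omega = 10)
model_eq <- function(omega = 100) schloegl(b = 1 / 6, omega = omega)

# frozen cubic roots of x^3 - 4x^2 + 3x - 0.5 (independent polynomial
# root-finder, numpy.roots) and derived quantities at b = 4
ROOTS_B4 <- c(0.237286219578, 0.684551193092, 3.078162587329)
DSI_B4_HIGH <- 27.758672   # F * [ln(w+1/w-1) + ln(w+2/w-2)] at the high root
DSI_B4_LOW <- 0.67329822   # same at the low root

tv_dist <- function(p, q) {
  n <- max(length(p), length(q))
  0.5 * sum(abs(c(p, numeric(n - length(p))) - c(q, numeric(n - length(q)))))
}
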