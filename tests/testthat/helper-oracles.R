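# Closed-form oracles used across tests, independent of the package's own
# computational paths.

# survival function of a chi-square: nu = 2 and nu = 4 closed forms
surv_chisq2 <- function(x) exp(-x / 2)
surv_chisq4 <- function(x) exp(-x / 2) * (1 + x / 2)

# survival function of a central F(2, nu2)
surv_F2 <- function(x, nu2) (1 + 2 * x / nu2)^(-nu2 / 2)

# Horner evaluation of a coefficient vector (index 1 = x^0)
eval_poly <- function(cf, x) {
  v <- 0
  for (c0 in rev(cf)) v <- v * x + c0
  v
}

# default dims used in many worked examples
d420 <- mi_dims(4, 20)
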