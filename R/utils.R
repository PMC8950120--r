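# internal numeric helpers

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Boltzmann constant in kcal/(mol K)
#' @noRd
KB_KCAL <- 0.0019872041

# Coulomb constant e^2/(4 pi eps0) in kcal A / (mol e^2)
#' @noRd
COULOMB_KCAL <- 332.0636

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)
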