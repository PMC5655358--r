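## Shared objects for the suite: one default model, built once.
sd_test_model <- local({
  mod <- NULL
  function() {
    if (is.null(mod)) mod <<- sd_model()
    mod
  }
})

## independent trapezoid-rule integrator used as an oracle in several tests
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
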