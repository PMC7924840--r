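# Shared objects for the suite: fixture compounds, a mono-exponential
# profile builder, and a random positive layer-set generator.

oxy <- load_fixture_compound("oxycodone")
bup <- load_fixture_compound("buprenorphine")

mono_exp_profile <- function(c0, k, t_end, n, label = "plasma") {
  t <- seq(0, t_end, length.out = n)
  conc_profile(t, c0 * exp(-k * t), label = label)
}

random_layer_k <- function() {
  # log-uniform permeabilities spanning the physiological range
  stats::setNames(10^stats::runif(3, -5, 0), c("sc", "ve", "de"))
}
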