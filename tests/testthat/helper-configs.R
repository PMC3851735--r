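# zero-noise, zero-bias configuration shared by the exactness tests
noise_free_config <- function(seed = 1L, ...) {
  synthetic_config(
    replicate_noise_sd = 0, observer_effect_sd = 0,
    device_brachial_bias = c(doppler = 0, vicorder = 0,
                             vascular_explorer = 0),
    device_ankle_bias = c(doppler = 0, vicorder = 0, vascular_explorer = 0),
    second_set_drop = list(vicorder = c(brachial = 0, ankle = 0),
                           vascular_explorer = c(brachial = 0, ankle = 0)),
    seed = seed, ...
  )
}
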