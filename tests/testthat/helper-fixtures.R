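# small builders shared across test files

six_layer_profile <- function(activity, date = "2023-04-15", ...) {
  soil_profile(date, activity, ...)
}

random_activity <- function(n = 6) stats::runif(n, min = 1, max = 200)

study_model <- function(k = 0.024) chain_model(k)
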