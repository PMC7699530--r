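# Shared fixtures for the test suite. Everything is built in code; the
# bundled extdata files are only touched by the I/O tests.

default_model <- function(...) {
  cea_model(settings = cea_settings(...))
}

# A model whose transition structure is fully inert: no recurrence, no
# breast-cancer death, optional flat background mortality.
zeroed_parameters <- function(qx = 0) {
  p <- default_parameters()
  trans <- c(
    "p_early_distant", "p_early_local", "p_local_distant",
    "p_death_distant", "p_death_local",
    "p_nonbrc_death_exercise", "p_nonbrc_death_usual",
    "p_brc_death_exercise", "p_brc_death_usual",
    "p_recurrence_exercise", "p_recurrence_usual"
  )
  p$mean[p$name %in% trans] <- 0
  p$low[p$name %in% trans] <- 0
  p$high[p$name %in% trans] <- 0
  p
}

flat_life_table <- function(qx, ages = 40:100) {
  tibble::tibble(age = as.integer(ages), qx = qx)
}

# Split-less recurrence breaks the local:distant ratio when both literature
# probabilities are zero, so keep a tiny distant probability where a split
# is still needed.
set_param <- function(parameters, name, mean, low = mean, high = mean) {
  parameters$mean[parameters$name == name] <- mean
  parameters$low[parameters$name == name] <- low
  parameters$high[parameters$name == name] <- high
  parameters
}

get_param <- function(parameters, name) {
  parameters$mean[parameters$name == name]
}
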