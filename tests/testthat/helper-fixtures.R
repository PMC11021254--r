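# Hand-built trial frames and small generating models shared across tests.

make_trials <- function(item_type, response, rt_ms = 1000,
                        participant = "p1", condition = "words",
                        serial_position = NA_integer_, session = 1L) {
  n <- max(length(item_type), length(response), length(rt_ms))
  df <- data.frame(participant = rep_len(participant, n),
                   session = rep_len(session, n),
                   condition = rep_len(condition, n),
                   item_type = rep_len(item_type, n),
                   serial_position = rep_len(serial_position, n),
                   response = as.integer(rep_len(response, n)),
                   rt_ms = rep_len(rt_ms, n),
                   stringsAsFactors = FALSE)
  df$serial_position[df$item_type == "lure"] <- NA_integer_
  df
}

demo_criteria <- c(-1, -0.4, 0.2, 0.8, 1.5)

demo_params <- function(mu = 1.2, sl = 0.8, variant = "UV_free") {
  sdt_params(mu, sigma_target = 1, sigma_lure = sl, criteria = demo_criteria,
             variant = variant)
}

# one-condition generator at fixed, known group values
demo_config <- function(n_participants = 6, n_trials = 200,
                        s_loc = log(0.72), s_scale = 0.1,
                        mu_loc = 1.4, contamination = 0) {
  generator_config(
    design = "study_test", n_participants = n_participants,
    n_trials = n_trials,
    conditions = list(words = list(
      loc = list(mu = mu_loc, s = s_loc, c1 = -0.8, g = log(0.55)),
      scale = list(mu = 0.3, s = s_scale, c1 = 0.3, g = 0.2))),
    rt = list(meanlog = log(900), sdlog = 0.35,
              contamination = contamination))
}
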