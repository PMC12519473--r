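# Shared fixtures: a tiny congener set and quick configurations used across
# the module tests. All synthetic; built in code at test time.

fx_congener <- function(id = "PCB4") default_congeners()[[id]]

# A quick nonshaken setup with a coarse particle mesh, for tests where
# runtime matters more than mesh resolution.
fx_ns_params <- function(...) {
  rtm_params(..., particle = particle_grid(n_shells = 12))
}

# Small congener table written by hand: 2 peaks x 2 groups x 3 replicates
# at one day, one matrix.
fx_small_table <- function(day = 35, matrix = "PUF") {
  expand_rows <- expand.grid(replicate = 1:3,
                             group = c("control", "treatment"),
                             peak_id = c("PCB4", "PCB118"),
                             stringsAsFactors = FALSE)
  data.frame(experiment_id = "fx", day = day, replicate = expand_rows$replicate,
             group = expand_rows$group, matrix = matrix,
             peak_id = expand_rows$peak_id,
             mass_ng = c(100, 110, 90, 50, 55, 45, 10, 12, 8, 9, 11, 10))
}
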