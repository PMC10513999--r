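# Small networks and hand-built ensembles used across test files.

net3 <- function() {
  component_network(
    labels = c("a", "b", "c"),
    weights = matrix(c(0, 0.4, 0.2,
                       0.4, 0, 0,
                       0.2, 0, 0), 3, 3, byrow = TRUE),
    thresholds = c(-1, -0.5, 0.2)
  )
}

zero_net <- function(n = 4, tau = 0) {
  component_network(paste0("v", seq_len(n)), matrix(0, n, n), rep(tau, n))
}

# Wrap a runs x sweeps intensity matrix as a trajectory_ensemble so episode
# analytics can be tested on exactly known trajectories.
manual_ensemble <- function(intensity, schedule) {
  structure(
    list(states = NULL,
         intensity = intensity,
         field = event_field(schedule),
         schedule = schedule,
         config = sim_config(runs = nrow(intensity)),
         intensity_nodes = NULL,
         labels = NULL),
    class = "trajectory_ensemble"
  )
}
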