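# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_protocol <- function() fixture("protocol", default_protocol())

# chest-only low-intensity session for cycle detection / classification tests
fixture_chest_session <- function() {
  fixture("chest_li", generate_session(fixture_protocol(), "LI", seed = 101,
                                       streams = c("chest")))
}

# wrist + ski session for contact-detection tests
fixture_contact_session <- function() {
  fixture("contact_li", generate_session(fixture_protocol(), "LI", seed = 202,
                                         streams = c("wrist", "ski")))
}

# pole + marker session for power tests
fixture_power_session <- function() {
  fixture("power_li", generate_session(fixture_protocol(), "LI", seed = 303,
                                       streams = c("pole", "markers")))
}

# a small in-memory protocol config list (editable copy of the default)
protocol_config <- function() {
  yaml::read_yaml(system.file("extdata", "protocol_default.yaml",
                              package = "skifuse"))
}

# align all IMU streams of a session to the master clock
align_imus <- function(session) {
  session$streams <- lapply(session$streams, function(s) {
    if (s$placement %in% c("chest", "wrist_L", "wrist_R", "ski_L", "ski_R")) {
      align_stream(s, session$truth$sync_master)
    } else s
  })
  session
}

# match detected events to truth events of one side by initial-contact time
match_events <- function(detected, truth, tol = 0.2) {
  j <- findInterval(detected$initial, truth$initial - tol)
  ok <- j >= 1 & abs(detected$initial - truth$initial[pmax(j, 1)]) < tol
  data.frame(det_initial = detected$initial[ok],
             det_terminal = detected$terminal[ok],
             ref_initial = truth$initial[j[ok]],
             ref_terminal = truth$terminal[j[ok]])
}
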