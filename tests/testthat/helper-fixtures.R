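# Shared fixtures: everything is generated in code at test time.

# a config with a lighter bootstrap for unit tests
test_config <- function(...) {
  args <- utils::modifyList(list(bootstrap_n = 200), list(...))
  do.call(pipeline_config, args)
}

# noiseless default scenario
clean_scenario <- function(...) {
  scenario_default(area_noise = 0, myosin_noise = 0, bg_noise = 0,
                   phase_jitter = 0, ...)
}

# single-frequency noiseless scenario at nu Hz
tone_scenario <- function(nu = 5e-3, eps0 = 0.05, c0 = 0.2, lag = pi, ...) {
  clean_scenario(nu_start = nu, nu_end = nu, eps0_start = eps0,
                 eps0_end = eps0, c0_start = c0, c0_end = c0,
                 lag_start = lag, lag_end = lag, ...)
}

# processed-signals table straight from analytic signals (bypasses preprocess)
proc_table <- function(cells, t, dt = 10) {
  out <- data.table::rbindlist(lapply(names(cells), function(id) {
    data.table::data.table(embryo_id = "e", cell_id = id, time_s = t,
                           strain = cells[[id]]$strain,
                           myosin = cells[[id]]$myosin)
  }))
  attr(out, "dt") <- dt
  out
}
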