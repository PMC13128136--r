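# Scenario runs shared by the acceptance tests (computed once per session;
# the equilibrated default scene is additionally memoized inside the package).

scenario_run <- function(name) {
  memo(paste0("scenario_", name), run_scenario(name))
}
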